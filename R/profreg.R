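#' Assemble a profile-regression dataset
#'
#' Bundles, per subject, the categorical outcome (the latent trajectory class
#' from the first stage), the binary biomarker flags, and the standardised
#' continuous biomarkers that the Dirichlet-process mixture clusters on.
#'
#' @param data Data frame with one row per subject.
#' @param outcome Column holding the class label (integers 1..G); may be
#'   `NA`-free for training data, or absent/`NA` for prediction profiles.
#' @param binary Columns of 0/1 flags (missing allowed).
#' @param continuous Columns of standardised continuous covariates (missing
#'   allowed).
#' @param n_outcome_levels Number of outcome categories G; defaults to the
#'   maximum observed label.
#' @return Object of class `profreg_data`.
#' @export
profreg_data <- function(data,
                         outcome = "class",
                         binary = c("ad_positive", "mta_positive", "fsd_positive",
                                    "fspv_positive", "arwmc_positive"),
                         continuous = c("hv", "vv", "hv_rate", "vv_rate"),
                         n_outcome_levels = NULL) {
  data <- tibble::as_tibble(data)
  y <- if (!is.null(outcome) && outcome %in% names(data)) {
    as.integer(data[[outcome]])
  } else {
    rep(NA_integer_, nrow(data))
  }
  miss <- setdiff(c(binary, continuous), names(data))
  if (length(miss)) abort(paste("missing columns:", paste(miss, collapse = ", ")))
  Wd <- as.matrix(data[binary]); storage.mode(Wd) <- "double"
  if (any(!Wd %in% c(0, 1, NA))) abort("binary covariates must be 0/1 or NA")
  Wc <- as.matrix(data[continuous]); storage.mode(Wc) <- "double"
  all_missing <- rowSums(!is.na(Wd)) + rowSums(!is.na(Wc)) == 0L
  if (any(all_missing)) abort("profiles with every covariate missing are not usable")
  G <- n_outcome_levels %||% max(y, na.rm = TRUE)
  if (any(!is.na(y) & (y < 1L | y > G))) abort("outcome labels must lie in 1..G")
  structure(list(
    ids = if ("subject_id" %in% names(data)) data$subject_id else seq_len(nrow(data)),
    y = y, Wd = Wd, Wc = Wc, n = nrow(data), G = as.integer(G),
    binary = binary, continuous = continuous
  ), class = "profreg_data")
}

#' Prior settings for the Dirichlet-process mixture
#'
#' Conjugate priors throughout: Beta for each Bernoulli flag, a symmetric
#' Dirichlet for the outcome simplex, normal--inverse-Wishart for the
#' Gaussian block, and a Gamma prior on the concentration alpha. Defaults
#' are weakly informative on standardised covariates.
#'
#' @param n_outcome_levels Outcome categories G.
#' @param n_continuous Dimension of the Gaussian block.
#' @param a0,b0 Beta prior for each binary covariate.
#' @param delta Symmetric Dirichlet mass for the outcome.
#' @param mu0,kappa0,nu0,Psi0 Normal--inverse-Wishart hyperparameters
#'   (`nu0` defaults to `n_continuous + 2`, `Psi0` to the identity).
#' @param alpha_shape,alpha_rate Gamma prior on alpha.
#' @param H Truncation level of the stick-breaking representation.
#' @return Object of class `profreg_priors`.
#' @export
profreg_priors <- function(n_outcome_levels, n_continuous = 4L,
                           a0 = 1, b0 = 1, delta = 1,
                           mu0 = rep(0, n_continuous), kappa0 = 0.01,
                           nu0 = n_continuous + 2, Psi0 = diag(n_continuous),
                           alpha_shape = 2, alpha_rate = 1, H = 50L) {
  if (nu0 <= n_continuous + 1) abort("`nu0` must exceed n_continuous + 1")
  if (H < 1L) abort("`H` must be >= 1")
  structure(list(
    G = as.integer(n_outcome_levels), C = as.integer(n_continuous),
    a0 = a0, b0 = b0, delta = delta, mu0 = mu0, kappa0 = kappa0,
    nu0 = nu0, Psi0 = Psi0, Psi0_inv = solve(Psi0),
    alpha_shape = alpha_shape,
    alpha_rate = alpha_rate, H = as.integer(H)
  ), class = "profreg_priors")
}

#' MCMC options for one profile-regression chain
#'
#' @param n_iter Total sweeps.
#' @param burn_in Discarded initial sweeps.
#' @param thin Keep every `thin`-th sweep after burn-in.
#' @param seed Integer seed.
#' @param init_clusters Number of clusters allocations are spread over at
#'   initialisation.
#' @return List of class `profreg_control`.
#' @export
profreg_control <- function(n_iter = 20000L, burn_in = 5000L, thin = 10L,
                            seed = 1L, init_clusters = 10L) {
  stopifnot(n_iter > burn_in, thin >= 1L)
  structure(list(
    n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
    thin = as.integer(thin), seed = as.integer(seed),
    init_clusters = as.integer(init_clusters)
  ), class = "profreg_control")
}

# Draw one inverse-Wishart matrix IW(nu, Psi).
riwish1 <- function(nu, Psi) {
  W <- rWishart(1L, nu, solve(Psi))[, , 1L]
  solve(W)
}

# Sample (mu, Sigma) from the normal-inverse-Wishart posterior given the
# rows of Xc (possibly none -> prior draw).
niw_draw <- function(Xc, pr) {
  n <- nrow(Xc)
  if (n == 0L) {
    Sigma <- riwish1(pr$nu0, pr$Psi0)
    mu <- pr$mu0 + drop(rnorm(pr$C) %*% chol(Sigma)) / sqrt(pr$kappa0)
    return(list(mu = mu, Sigma = Sigma))
  }
  xbar <- colMeans(Xc)
  kn <- pr$kappa0 + n
  nun <- pr$nu0 + n
  mun <- (pr$kappa0 * pr$mu0 + n * xbar) / kn
  Xc_c <- sweep(Xc, 2L, xbar)
  S <- crossprod(Xc_c)
  dev <- xbar - pr$mu0
  Psin <- pr$Psi0 + S + (pr$kappa0 * n / kn) * tcrossprod(dev)
  Psin <- (Psin + t(Psin)) / 2
  Sigma <- riwish1(nun, Psin)
  mu <- mun + drop(rnorm(pr$C) %*% chol(Sigma)) / sqrt(kn)
  list(mu = mu, Sigma = Sigma)
}

profreg_init <- function(data, priors, control) {
  set.seed(control$seed)
  H <- priors$H
  n <- data$n
  alloc <- sample.int(min(control$init_clusters, H), n, replace = TRUE)
  alpha <- rgamma(1L, priors$alpha_shape, priors$alpha_rate)
  V <- c(rbeta(H - 1L, 1, alpha), 1)
  theta_o <- rdirichlet_rows(matrix(priors$delta, H, data$G))
  theta_d <- matrix(rbeta(H * ncol(data$Wd), priors$a0, priors$b0), H)
  mu <- matrix(0, H, priors$C)
  Sigma <- array(0, c(priors$C, priors$C, H))
  for (h in seq_len(H)) {
    d <- niw_draw(matrix(numeric(0), 0L, priors$C), priors)
    mu[h, ] <- d$mu
    Sigma[, , h] <- d$Sigma
  }
  Wd <- data$Wd
  if (anyNA(Wd)) {
    p_col <- colMeans(Wd, na.rm = TRUE)
    for (q in seq_len(ncol(Wd))) {
      na <- is.na(Wd[, q])
      Wd[na, q] <- rbinom(sum(na), 1L, p_col[q])
    }
  }
  Wc <- data$Wc
  if (anyNA(Wc)) {
    m_col <- colMeans(Wc, na.rm = TRUE)
    for (q in seq_len(ncol(Wc))) Wc[is.na(Wc[, q]), q] <- m_col[q]
  }
  list(alloc = alloc, V = V, theta_o = theta_o, theta_d = theta_d,
       mu = mu, Sigma = Sigma, alpha = alpha, Wd = Wd, Wc = Wc)
}

# log stick weights from the stick fractions V (V_H = 1).
stick_logweights <- function(V) {
  lv <- log(pmax(V, 1e-300))
  l1v <- log1p(-pmin(V[-length(V)], 1 - 1e-12))
  lv + c(0, cumsum(l1v))
}

# n x H log-density of the Gaussian block.
gauss_loglik_matrix <- function(Wc, mu, Sigma) {
  n <- nrow(Wc); H <- nrow(mu); C <- ncol(Wc)
  out <- matrix(0, n, H)
  for (h in seq_len(H)) {
    ch <- chol(Sigma[, , h])
    z <- forwardsolve(t(ch), t(Wc) - mu[h, ])
    out[, h] <- -0.5 * (C * log(2 * pi) + colSums(z^2)) - sum(log(diag(ch)))
  }
  out
}

# One full blocked-Gibbs sweep; `state` carries imputed complete data.
profreg_sweep <- function(state, data, priors) {
  H <- priors$H; n <- data$n
  # (1) allocations
  lw <- stick_logweights(state$V)
  Lo <- matrix(0, n, H)
  obs_y <- !is.na(data$y)
  if (any(obs_y)) {
    lto <- log(pmax(state$theta_o, 1e-300))
    Lo[obs_y, ] <- t(lto[, data$y[obs_y], drop = FALSE])
  }
  ltd <- log(pmax(state$theta_d, 1e-300))
  ltd1 <- log(pmax(1 - state$theta_d, 1e-300))
  Ld <- state$Wd %*% t(ltd) + (1 - state$Wd) %*% t(ltd1)
  Lc <- gauss_loglik_matrix(state$Wc, state$mu, state$Sigma)
  P <- sweep(Lo + Ld + Lc, 2L, lw, "+")
  gum <- -log(-log(matrix(runif(n * H), n, H)))
  state$alloc <- max.col(P + gum, ties.method = "first")
  # allocation-conditional log density of the data plus log mixture weights
  state$logdens <- sum(P[cbind(seq_len(n), state$alloc)])
  # (2) sticks
  nh <- tabulate(state$alloc, H)
  greater <- sum(nh) - cumsum(nh)
  V <- rbeta(H - 1L, 1 + nh[-H], state$alpha + greater[-H])
  state$V <- c(pmin(pmax(V, 1e-12), 1 - 1e-12), 1)
  # (3) component parameters (conjugate posteriors; empty components draw
  # from the prior)
  fac <- factor(state$alloc, levels = seq_len(H))
  counts_o <- matrix(0, H, data$G)
  if (any(obs_y)) {
    tab <- table(fac[obs_y], factor(data$y[obs_y], levels = seq_len(data$G)))
    counts_o <- counts_o + unclass(tab)
  }
  state$theta_o <- rdirichlet_rows(priors$delta + counts_o)
  sums_d <- matrix(0, H, ncol(state$Wd))
  tmp <- rowsum(state$Wd, fac)
  sums_d[as.integer(rownames(tmp)), ] <- tmp
  state$theta_d <- matrix(
    rbeta(H * ncol(state$Wd), priors$a0 + sums_d, priors$b0 + nh - sums_d), H
  )
  occ <- which(nh > 0L)
  for (h in occ) {
    d <- niw_draw(state$Wc[state$alloc == h, , drop = FALSE], priors)
    state$mu[h, ] <- d$mu
    state$Sigma[, , h] <- d$Sigma
  }
  emp <- which(nh == 0L)
  if (length(emp)) {
    W <- rWishart(length(emp), priors$nu0, priors$Psi0_inv %||% solve(priors$Psi0))
    for (j in seq_along(emp)) {
      Sigma <- chol2inv(chol(W[, , j]))
      state$Sigma[, , emp[j]] <- Sigma
      state$mu[emp[j], ] <- priors$mu0 +
        drop(rnorm(priors$C) %*% chol(Sigma)) / sqrt(priors$kappa0)
    }
  }
  # (4) concentration: Escobar-West auxiliary-variable update driven by the
  # number of occupied clusters (the fully conjugate update through the
  # truncation's empty sticks mixes poorly: small alpha shrinks the empty
  # sticks, which in turn inflates alpha)
  k <- sum(nh > 0L)
  eta <- rbeta(1L, state$alpha + 1, n)
  a <- priors$alpha_shape; b <- priors$alpha_rate
  odds <- (a + k - 1) / (n * (b - log(eta)))
  shape <- if (runif(1L) < odds / (1 + odds)) a + k else a + k - 1
  state$alpha <- rgamma(1L, shape, b - log(eta))
  # (5) re-impute missing covariates from the allocated component
  if (anyNA(data$Wd)) {
    for (q in seq_len(ncol(data$Wd))) {
      na <- which(is.na(data$Wd[, q]))
      if (length(na)) {
        state$Wd[na, q] <- rbinom(length(na), 1L, state$theta_d[state$alloc[na], q])
      }
    }
  }
  if (anyNA(data$Wc)) {
    miss_rows <- which(rowSums(is.na(data$Wc)) > 0L)
    for (i in miss_rows) {
      h <- state$alloc[i]
      m <- is.na(data$Wc[i, ])
      if (all(m)) {
        state$Wc[i, ] <- state$mu[h, ] +
          drop(rnorm(priors$C) %*% chol(state$Sigma[, , h]))
      } else {
        So <- state$Sigma[!m, !m, h, drop = FALSE][, , 1L]
        Smo <- state$Sigma[m, !m, h, drop = FALSE][, , 1L]
        A <- Smo %*% solve(So)
        cond_mu <- state$mu[h, m] + drop(A %*% (state$Wc[i, !m] - state$mu[h, !m]))
        cond_S <- state$Sigma[m, m, h] - A %*% t(Smo)
        cond_S <- (cond_S + t(cond_S)) / 2
        state$Wc[i, m] <- cond_mu + drop(rnorm(sum(m)) %*% chol(cond_S))
      }
    }
  }
  state
}

#' Run one profile-regression MCMC chain
#'
#' Truncated blocked Gibbs sampling of the Dirichlet-process mixture: each
#' sweep resamples allocations, stick fractions, component parameters from
#' their conjugate posteriors, the concentration alpha, and any imputed
#' missing covariates. Kept iterations store everything needed for posterior
#' similarity matrices, cluster-parameter posteriors and held-out prediction.
#'
#' @param data A [profreg_data()].
#' @param priors A [profreg_priors()]; defaults to `profreg_priors(data$G)`.
#' @param control A [profreg_control()].
#' @return Object of class `profreg_chain`: `alloc` (kept x n), `theta_o`
#'   (kept x H x G), `theta_d` (kept x H x Q), `mu` (kept x H x C), `Sigma`
#'   (kept x H x C x C), `logw` (kept x H), `alpha` (kept), `n_occupied`
#'   (kept), plus `ids`, `priors`, `control`.
#' @export
run_chain <- function(data, priors = NULL, control = profreg_control()) {
  stopifnot(inherits(data, "profreg_data"))
  priors <- priors %||% profreg_priors(data$G, ncol(data$Wc))
  H <- priors$H
  state <- profreg_init(data, priors, control)
  n_keep <- (control$n_iter - control$burn_in) %/% control$thin
  Q <- ncol(data$Wd); C <- priors$C
  out <- list(
    alloc = matrix(NA_integer_, n_keep, data$n),
    theta_o = array(NA_real_, c(n_keep, H, data$G)),
    theta_d = array(NA_real_, c(n_keep, H, Q)),
    mu = array(NA_real_, c(n_keep, H, C)),
    Sigma = array(NA_real_, c(n_keep, H, C, C)),
    logw = matrix(NA_real_, n_keep, H),
    alpha = numeric(n_keep),
    n_occupied = integer(n_keep),
    logdens = numeric(n_keep)
  )
  r <- 0L
  last_occupied <- FALSE
  for (it in seq_len(control$n_iter)) {
    state <- profreg_sweep(state, data, priors)
    if (it > control$burn_in && (it - control$burn_in) %% control$thin == 0L) {
      r <- r + 1L
      out$alloc[r, ] <- state$alloc
      out$theta_o[r, , ] <- state$theta_o
      out$theta_d[r, , ] <- state$theta_d
      out$mu[r, , ] <- state$mu
      out$Sigma[r, , , ] <- aperm(state$Sigma, c(3L, 1L, 2L))
      out$logw[r, ] <- stick_logweights(state$V)
      out$alpha[r] <- state$alpha
      out$n_occupied[r] <- length(unique(state$alloc))
      out$logdens[r] <- state$logdens
      if (any(state$alloc == H)) last_occupied <- TRUE
    }
  }
  if (last_occupied && H > 1L) {
    warn("the last truncation component was occupied; consider raising `H`")
  }
  structure(c(out, list(ids = data$ids, priors = priors, control = control,
                        binary = data$binary, continuous = data$continuous)),
            class = "profreg_chain")
}

#' @export
print.profreg_chain <- function(x, ...) {
  cat(sprintf(
    "<profreg_chain> %d kept iterations, %d subjects, H = %d\n",
    nrow(x$alloc), ncol(x$alloc), x$priors$H
  ))
  cat(sprintf("  occupied clusters: median %d (range %d-%d) | mean alpha %.2f\n",
              stats::median(x$n_occupied), min(x$n_occupied),
              max(x$n_occupied), mean(x$alpha)))
  invisible(x)
}

#' Run several independent chains
#'
#' @inheritParams run_chain
#' @param n_chains Number of chains; each gets a seed derived from
#'   `control$seed` and its chain index.
#' @return List of `profreg_chain` objects.
#' @export
run_chains <- function(data, priors = NULL, n_chains = 6L,
                       control = profreg_control()) {
  purrr::map(seq_len(n_chains), function(j) {
    ctl <- control
    ctl$seed <- derive_seed(control$seed, j)
    run_chain(data, priors, ctl)
  })
}

#' Per-iteration allocation of held-out profiles
#'
#' For each kept iteration, allocates each new subject to a mixture
#' component with probability proportional to the stick weight times the
#' covariate likelihood only -- the outcome factor is omitted, since the
#' held-out subjects' classes are exactly what is being predicted. Missing
#' covariates contribute no factor (their density is marginalised out).
#'
#' @param chain A `profreg_chain`.
#' @param new_profiles A [profreg_data()] for the held-out subjects (the
#'   outcome column, if present, is ignored).
#' @param seed Integer seed for the allocation draws.
#' @return Integer matrix (kept iterations x new subjects).
#' @export
predict_allocation <- function(chain, new_profiles, seed = 1L) {
  stopifnot(inherits(chain, "profreg_chain"), inherits(new_profiles, "profreg_data"))
  set.seed(seed)
  H <- chain$priors$H
  m <- new_profiles$n
  R <- nrow(chain$alloc)
  Wd <- new_profiles$Wd
  Wc <- new_profiles$Wc
  out <- matrix(NA_integer_, R, m)
  obs_d <- !is.na(Wd)
  Wd0 <- ifelse(is.na(Wd), 0, Wd)
  for (r in seq_len(R)) {
    td <- matrix(chain$theta_d[r, , ], H)
    ltd <- log(pmax(td, 1e-300)); ltd1 <- log(pmax(1 - td, 1e-300))
    Ld <- Wd0 %*% t(ltd) + ((1 - Wd0) * obs_d) %*% t(ltd1)
    Lc <- matrix(0, m, H)
    mu_r <- matrix(chain$mu[r, , ], H)
    if (!anyNA(Wc)) {
      Sig_r <- array(chain$Sigma[r, , , ], c(H, chain$priors$C, chain$priors$C))
      Lc <- gauss_loglik_matrix(Wc, mu_r, aperm(Sig_r, c(2, 3, 1)))
    } else {
      for (h in seq_len(H)) {
        Sh <- matrix(chain$Sigma[r, h, , ], chain$priors$C)
        for (i in seq_len(m)) {
          o <- !is.na(Wc[i, ])
          if (!any(o)) next
          So <- Sh[o, o, drop = FALSE]
          ch <- chol(So)
          z <- forwardsolve(t(ch), Wc[i, o] - mu_r[h, o])
          Lc[i, h] <- -0.5 * (sum(o) * log(2 * pi) + sum(z^2)) - sum(log(diag(ch)))
        }
      }
    }
    P <- sweep(Ld + Lc, 2L, chain$logw[r, ], "+")
    gum <- -log(-log(matrix(runif(m * H), m, H)))
    out[r, ] <- max.col(P + gum, ties.method = "first")
  }
  out
}
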