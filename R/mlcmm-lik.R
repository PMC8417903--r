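# Internal fitting structure: subjects grouped by observation pattern so the
# likelihood evaluates as dense matrix algebra per pattern.
#
# outcomes: tibble (subject_id, outcome, time_years, value); covariates:
# tibble (subject_id + spec covariates). Returns NULL-free structure or
# errors, unless `on_missing_covariate = "skip"` (prediction path).
mlcmm_build_data <- function(outcomes, covariates, spec,
                             on_missing_covariate = c("error", "skip")) {
  on_missing_covariate <- match.arg(on_missing_covariate)
  bad <- setdiff(unique(outcomes$outcome), spec$outcomes)
  if (length(bad)) abort(paste("unknown outcome(s):", paste(bad, collapse = ", ")))
  miss <- setdiff(spec$covariates, names(covariates))
  if (length(miss)) abort(paste("missing covariate column(s):", paste(miss, collapse = ", ")))

  ids <- intersect(unique(outcomes$subject_id), covariates$subject_id)
  X_all <- as.matrix(covariates[match(ids, covariates$subject_id), spec$covariates, drop = FALSE])
  complete <- complete.cases(X_all)
  if (!all(complete)) {
    if (on_missing_covariate == "error") {
      abort(sprintf("%d subject(s) have missing covariates", sum(!complete)))
    }
    inform(sprintf("skipping %d subject(s) with missing covariates", sum(!complete)))
    ids <- ids[complete]
    X_all <- X_all[complete, , drop = FALSE]
  }
  obs <- outcomes |>
    dplyr::filter(.data$subject_id %in% ids, !is.na(.data$value)) |>
    dplyr::mutate(k = match(.data$outcome, spec$outcomes)) |>
    dplyr::arrange(match(.data$subject_id, ids), .data$time_years, .data$k)
  if (!all(ids %in% obs$subject_id)) {
    drop <- setdiff(ids, unique(obs$subject_id))
    if (on_missing_covariate == "skip") {
      inform(sprintf("skipping %d subject(s) with no observed outcomes", length(drop)))
      keep <- ids %in% obs$subject_id
      ids <- ids[keep]; X_all <- X_all[keep, , drop = FALSE]
    } else {
      abort("every subject must have at least one observed outcome")
    }
  }
  by_subj <- split(obs, factor(obs$subject_id, levels = ids))
  pattern <- vapply(by_subj, function(d) paste(d$k, d$time_years, collapse = ";"),
                    character(1))
  groups <- lapply(split(seq_along(ids), pattern), function(rows) {
    d0 <- by_subj[[rows[1]]]
    list(
      idx = rows,
      Y = do.call(rbind, lapply(by_subj[rows], function(d) d$value)),
      k = d0$k,
      t = d0$time_years
    )
  })
  list(ids = ids, X = X_all, groups = unname(groups), n = length(ids))
}

# N x G matrix of per-subject, per-class log densities on the observed scale.
mlcmm_ll_matrix <- function(par, data, layout) {
  G <- layout$G
  sig2 <- par$sigma^2
  Xb <- if (layout$p > 0) drop(data$X %*% par$beta) else numeric(data$n)
  out <- matrix(NA_real_, data$n, G)
  for (grp in data$groups) {
    k <- grp$k; tt <- grp$t; d <- length(k)
    Ytil <- sweep(sweep(grp$Y, 2L, par$eta1[k], "-"), 2L, par$eta2[k], "/")
    dinv <- 1 / sig2[k]
    s <- sum(dinv)
    const <- -0.5 * (d * log(2 * pi) + sum(log(sig2[k]))) - sum(log(par$eta2[k]))
    R0 <- Ytil - Xb[grp$idx] # recycles down columns: subtract x_i' beta
    for (g in seq_len(G)) {
      R <- sweep(R0, 2L, par$g0[g] + par$g1[g] * tt, "-")
      a <- drop(R %*% dinv)
      q <- drop((R * R) %*% dinv) - (par$omega[g] / (1 + par$omega[g] * s)) * a^2
      out[grp$idx, g] <- const - 0.5 * (log1p(par$omega[g] * s) + q)
    }
  }
  out
}

#' Latent-process mean for one class
#'
#' `x' beta + gamma0_g + gamma1_g * t` on the latent scale.
#'
#' @param params Parameter list with entries `beta`, `g0`, `g1` (see
#'   [fit_mlcmm()]'s `$params`).
#' @param class Class index g.
#' @param x Named or ordered covariate vector matching `beta`; no missing
#'   values allowed.
#' @param t Time(s) in study, years.
#' @return Numeric vector along `t`.
#' @export
latent_mean <- function(params, class, x, t) {
  if (length(x) != length(params$beta)) abort("covariate vector length mismatch")
  if (anyNA(x)) abort("missing covariate value")
  sum(x * params$beta) + params$g0[class] + params$g1[class] * t
}

#' Log-likelihood of one subject's outcomes under one class
#'
#' The log density of the subject's stacked observations under the class-g
#' multivariate normal implied by the linear links (random intercept of
#' variance `omega_g`, independent measurement errors), evaluated on the
#' observed-outcome scale (the -log eta2 Jacobian term per observation is
#' included).
#'
#' @param params Natural-scale parameter list (`beta`, `g0`, `g1`, `eta1`,
#'   `eta2`, `sigma`, `omega`).
#' @param obs Tibble with columns `k` (outcome index), `time_years`, `value`.
#' @param x Covariate vector.
#' @param class Class index g.
#' @return Scalar log-likelihood.
#' @export
subject_class_loglik <- function(params, obs, x, class) {
  stopifnot(nrow(obs) >= 1L)
  data <- list(
    n = 1L,
    X = matrix(x, nrow = 1L),
    groups = list(list(idx = 1L, Y = matrix(obs$value, nrow = 1L),
                       k = obs$k, t = obs$time_years))
  )
  layout <- list(G = length(params$g1), p = length(params$beta))
  mlcmm_ll_matrix(params, data, layout)[1L, class]
}

#' Mixture log-likelihood of a dataset
#'
#' `sum_i log sum_g pi_g exp(loglik_ig)` with log-sum-exp stabilisation.
#'
#' @param params Natural-scale parameter list including `xi`.
#' @param outcomes,covariates Long outcome table and covariate table as
#'   produced by [prepare_mlcmm_data()].
#' @param spec An [mlcmm_spec()].
#' @return Scalar log-likelihood.
#' @export
mlcmm_loglik <- function(params, outcomes, covariates, spec) {
  layout <- mlcmm_layout(spec)
  data <- mlcmm_build_data(outcomes, covariates, spec)
  ll <- mlcmm_ll_matrix(params, data, layout)
  logpi <- log(softmax_full(params$xi))
  sum(logsumexp_rows(sweep(ll, 2L, logpi, "+")))
}

softmax_full <- function(xi) {
  e <- exp(xi - max(xi))
  e / sum(e)
}

# Centre/scale outcomes and covariates of a built dataset; the returned
# moments let estimates be mapped back to the raw scale.
mlcmm_standardise_data <- function(data, layout) {
  K <- layout$K
  m <- numeric(K); s <- rep(1, K)
  for (k in seq_len(K)) {
    vals <- unlist(lapply(data$groups, function(g) g$Y[, g$k == k, drop = FALSE]))
    m[k] <- mean(vals)
    s[k] <- max(sd(vals), 1e-6)
    if (!is.finite(s[k])) s[k] <- 1
  }
  mu_x <- numeric(layout$p); s_x <- rep(1, layout$p)
  if (layout$p > 0) {
    mu_x <- colMeans(data$X)
    s_x <- apply(data$X, 2L, sd)
    s_x[!is.finite(s_x) | s_x == 0] <- 1
  }
  std_data <- data
  std_data$X <- sweep(sweep(data$X, 2L, mu_x), 2L, s_x, "/")
  std_data$groups <- lapply(data$groups, function(g) {
    g$Y <- sweep(sweep(g$Y, 2L, m[g$k]), 2L, s[g$k], "/")
    g
  })
  list(data = std_data, m = m, s = s, mu_x = mu_x, s_x = s_x)
}

# Map a parameter vector estimated on the standardised scale back to the
# raw outcome/covariate scale (the class structure is untouched; the links
# absorb the outcome moments and the covariate centring constant).
mlcmm_destandardise_theta <- function(theta_star, std, layout) {
  par <- mlcmm_unpack(theta_star, layout)
  beta <- par$beta / std$s_x
  c0 <- if (layout$p > 0) -sum(beta * std$mu_x) else 0
  out <- par
  out$beta <- beta
  out$eta1 <- std$m + std$s * (par$eta1 + par$eta2 * c0)
  out$eta2 <- std$s * par$eta2
  mlcmm_pack(out, layout)
}

numeric_jacobian <- function(f, x, eps = 1e-6) {
  f0 <- f(x)
  J <- matrix(0, length(f0), length(x))
  for (j in seq_along(x)) {
    h <- eps * max(1, abs(x[j]))
    xp <- x; xp[j] <- xp[j] + h
    xm <- x; xm[j] <- xm[j] - h
    J[, j] <- (f(xp) - f(xm)) / (2 * h)
  }
  J
}
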