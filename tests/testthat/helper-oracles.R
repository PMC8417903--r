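# Independent oracles used across the suite. These deliberately avoid the
# package's computational paths: quadrature instead of the closed form,
# dense covariance matrices instead of the rank-one update, pair counting
# and exhaustive enumeration instead of contingency-table algebra.

# Adaptive Gauss-Hermite quadrature over the random intercept for one
# subject/class: nodes are centred and scaled at the conditional posterior
# of the random intercept, so the rule is exact for this Gaussian integrand.
gh_subject_loglik <- function(params, obs, x, class, n_nodes = 60) {
  gh <- pracma::gaussHermite(n_nodes)
  omega <- params$omega[class]
  mu <- sum(x * params$beta) + params$g0[class] + params$g1[class] * obs$time_years
  ytil <- (obs$value - params$eta1[obs$k]) / params$eta2[obs$k]
  sig <- params$sigma[obs$k]
  prec <- 1 / max(omega, 1e-12) + sum(1 / sig^2)
  m_hat <- sum((ytil - mu) / sig^2) / prec
  v_hat <- 1 / prec
  # integrand: product of measurement densities times the N(0, omega) prior
  logg <- vapply(gh$x, function(z) {
    u <- m_hat + sqrt(2 * v_hat) * z
    sum(stats::dnorm(ytil, mu + u, sig, log = TRUE)) +
      stats::dnorm(u, 0, sqrt(omega), log = TRUE)
  }, numeric(1))
  w <- log(gh$w) + gh$x^2 + logg
  m <- max(w)
  log(sum(exp(w - m))) + m + 0.5 * log(2 * v_hat) -
    sum(log(params$eta2[obs$k]))
}

# Observed-scale multivariate normal log density with a dense covariance:
# Cov(Y_a, Y_b) = eta2_a eta2_b (omega + [a == b] sigma_a^2).
dense_subject_loglik <- function(params, obs, x, class) {
  k <- obs$k
  mean <- params$eta1[k] + params$eta2[k] *
    (sum(x * params$beta) + params$g0[class] + params$g1[class] * obs$time_years)
  Sig <- outer(params$eta2[k], params$eta2[k]) * params$omega[class] +
    diag((params$eta2[k] * params$sigma[k])^2, nrow = length(k))
  r <- obs$value - mean
  ch <- chol(Sig)
  z <- forwardsolve(t(ch), r)
  -0.5 * (length(k) * log(2 * pi) + sum(z^2)) - sum(log(diag(ch)))
}

# All set partitions of n items as label vectors (restricted growth strings).
all_partitions <- function(n) {
  out <- list()
  rec <- function(prefix, m) {
    if (length(prefix) == n) {
      out[[length(out) + 1L]] <<- prefix
      return(invisible())
    }
    for (v in seq_len(m + 1L)) rec(c(prefix, v), max(m, v))
  }
  rec(integer(0), 0L)
  out
}

# Adjusted Rand index by explicit pair counting.
ari_bruteforce <- function(la, lb) {
  n <- length(la)
  a <- b <- cc <- d <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      sa <- la[i] == la[j]
      sb <- lb[i] == lb[j]
      if (sa && sb) a <- a + 1
      else if (sa && !sb) b <- b + 1
      else if (!sa && sb) cc <- cc + 1
      else d <- d + 1
    }
  }
  den <- (a + b) * (b + d) + (a + cc) * (cc + d)
  if (den == 0) return(1)
  2 * (a * d - b * cc) / den
}

# Cohen's kappa from first principles on a shared label space.
kappa_bruteforce <- function(la, lb) {
  lev <- union(unique(la), unique(lb))
  po <- mean(la == lb)
  pe <- sum(vapply(lev, function(l) mean(la == l) * mean(lb == l), numeric(1)))
  if (abs(1 - pe) < 1e-12) return(NA_real_)
  (po - pe) / (1 - pe)
}

# Average silhouette width from its definition.
silhouette_bruteforce <- function(d, labels) {
  d <- as.matrix(d)
  n <- nrow(d)
  ks <- unique(labels)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i])
    if (length(own) == 1L) {
      s[i] <- 0
      next
    }
    a <- mean(d[i, setdiff(own, i)])
    b <- min(vapply(setdiff(ks, labels[i]), function(k) {
      mean(d[i, labels == k])
    }, numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# Globally optimal k-medoids cost by exhaustive enumeration of medoid sets.
pam_bruteforce_cost <- function(d, k) {
  d <- as.matrix(d)
  n <- nrow(d)
  best <- Inf
  sets <- utils::combn(n, k)
  for (j in seq_len(ncol(sets))) {
    cost <- sum(apply(d[, sets[, j], drop = FALSE], 1L, min))
    best <- min(best, cost)
  }
  best
}

# A small fitted-scale truth object for the crisp two-class scenario.
crisp2_truth_params <- function(cfg) {
  list(
    xi = c(cfg$class_logits),
    beta = unname(cfg$beta),
    g0 = cfg$class_intercepts,
    g1 = cfg$class_slopes,
    eta1 = unname(cfg$eta1),
    eta2 = unname(cfg$eta2),
    sigma = unname(cfg$sigma),
    omega = cfg$omega
  )
}

random_obs <- function(n_obs, K = 2) {
  tibble::tibble(
    k = sample(seq_len(K), n_obs, replace = TRUE),
    time_years = sort(round(stats::runif(n_obs, 0, 3), 2)),
    value = stats::rnorm(n_obs, 3, 2)
  )
}

random_params <- function(G = 2, p = 3, K = 2) {
  list(
    xi = c(stats::rnorm(G - 1, 0, 0.7), 0),
    beta = stats::rnorm(p, 0, 0.3),
    g0 = c(0, stats::rnorm(G - 1, 0, 2)),
    g1 = stats::rnorm(G, 0, 0.8),
    eta1 = c(2, 50),
    eta2 = c(0.8, 4),
    sigma = stats::runif(K, 0.4, 1.5),
    omega = c(stats::runif(G - 1, 0.2, 2), 1)
  )
}
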