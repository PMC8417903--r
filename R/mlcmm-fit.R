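#' Control options for MLCMM estimation
#'
#' @param n_starts Number of optimiser starts: one data-driven start built
#'   from per-subject least-squares summaries and k-means, the rest random
#'   perturbations of it.
#' @param max_iter Maximum outer iterations per start.
#' @param rel_tol Relative convergence tolerance on the objective.
#' @param seed Integer seed making the start sequence reproducible.
#' @param compute_se Compute the observed-information standard errors?
#' @return List of class `mlcmm_control`.
#' @export
mlcmm_control <- function(n_starts = 30L, max_iter = 500L, rel_tol = 1e-8,
                          seed = 1L, compute_se = TRUE) {
  structure(list(
    n_starts = as.integer(n_starts), max_iter = as.integer(max_iter),
    rel_tol = rel_tol, seed = as.integer(seed), compute_se = compute_se
  ), class = "mlcmm_control")
}

# Data-driven starting value: standardise outcomes, per-subject least squares
# on the pooled standardised values, k-means the (intercept, slope) pairs.
mlcmm_start <- function(data, layout, seed) {
  spec <- layout$spec
  G <- layout$G; K <- layout$K
  m <- numeric(K); s <- numeric(K)
  for (k in seq_len(K)) {
    vals <- unlist(lapply(data$groups, function(g) g$Y[, g$k == k, drop = FALSE]))
    m[k] <- mean(vals)
    s[k] <- max(sd(vals), 1e-3)
  }
  subj <- matrix(0, data$n, 2L)
  for (grp in data$groups) {
    Ytil <- sweep(sweep(grp$Y, 2L, m[grp$k], "-"), 2L, s[grp$k], "/")
    tt <- grp$t
    if (length(unique(tt)) > 1L) {
      tc <- tt - mean(tt)
      slope <- drop(Ytil %*% tc) / sum(tc^2)
      subj[grp$idx, 1L] <- rowMeans(Ytil) - slope * mean(tt)
      subj[grp$idx, 2L] <- slope
    } else {
      subj[grp$idx, 1L] <- rowMeans(Ytil)
    }
  }
  set.seed(seed)
  if (G > 1L) {
    km <- kmeans(subj, centers = G, nstart = 10L)
    ord <- order(km$centers[, 1L], decreasing = TRUE)
    centers <- km$centers[ord, , drop = FALSE]
    shares <- pmax(km$size[ord] / data$n, 1e-3)
  } else {
    centers <- matrix(colMeans(subj), 1L)
    shares <- 1
  }
  shift <- centers[spec$ref_intercept, 1L]
  par <- list(
    xi = log(shares) - log(shares[spec$ref_membership]),
    beta = rep(0, layout$p),
    g0 = centers[, 1L] - shift,
    g1 = centers[, 2L],
    eta1 = m + s * shift,
    eta2 = s,
    sigma = rep(0.5, K),
    omega = rep(1, G)
  )
  par$xi[spec$ref_membership] <- 0
  par$g0[spec$ref_intercept] <- 0
  par$omega[spec$ref_variance] <- 1
  mlcmm_pack(par, layout)
}

mlcmm_jitter <- function(theta0, layout, seed) {
  set.seed(seed)
  theta <- theta0
  theta[layout$idx$xi] <- theta[layout$idx$xi] + rnorm(length(layout$idx$xi), 0, 0.5)
  theta[layout$idx$g0] <- theta[layout$idx$g0] + rnorm(length(layout$idx$g0), 0, 0.7)
  theta[layout$idx$g1] <- theta[layout$idx$g1] + rnorm(length(layout$idx$g1), 0, 0.4)
  theta[layout$idx$eta1] <- theta[layout$idx$eta1] +
    rnorm(layout$K, 0, 0.2) * pmax(exp(theta[layout$idx$leta2]), 0.1)
  theta[layout$idx$leta2] <- theta[layout$idx$leta2] + rnorm(layout$K, 0, 0.2)
  theta[layout$idx$lsigma] <- theta[layout$idx$lsigma] + rnorm(layout$K, 0, 0.3)
  theta[layout$idx$lomega] <- theta[layout$idx$lomega] +
    rnorm(length(layout$idx$lomega), 0, 0.5)
  theta
}

mlcmm_bounds <- function(layout) {
  lower <- rep(-Inf, layout$n_params)
  upper <- rep(Inf, layout$n_params)
  lower[layout$idx$leta2] <- -8; upper[layout$idx$leta2] <- 10
  lower[layout$idx$lsigma] <- -7; upper[layout$idx$lsigma] <- 6
  lower[layout$idx$lomega] <- -12; upper[layout$idx$lomega] <- 6
  list(lower = lower, upper = upper)
}

#' Fit the multivariate latent-class linear mixed model
#'
#' Maximum-likelihood estimation by direct quasi-Newton maximisation of the
#' observed-data mixture log-likelihood (log-sum-exp over classes) in an
#' unconstrained parameterisation (log scale for `eta2`, `sigma`, `omega`),
#' with multiple starts. The best converged start is returned; the whole
#' procedure is deterministic given `control$seed`.
#'
#' @param outcomes Long tibble (`subject_id`, `outcome`, `time_years`,
#'   `value`) of transformed outcomes, e.g. from [prepare_mlcmm_data()].
#'   Subjects contribute whatever observations they have (missing at random).
#' @param covariates Tibble with `subject_id` and the spec's covariates;
#'   must be complete for fitted subjects.
#' @param spec An [mlcmm_spec()], or an integer number of classes (the
#'   default outcome and covariate sets are then assumed).
#' @param control An [mlcmm_control()].
#' @return An object of class `mlcmm_fit` with elements `params`
#'   (natural-scale list), `theta` and `se_theta` (unconstrained scale),
#'   `vcov`, `loglik`, `bic`, `entropy`, `n_params`, `posterior` (N x G),
#'   `labels`, `converged`, `n_starts_used`, `start_logliks`, `subject_ids`,
#'   `covariate_means`, `spec`.
#' @export
fit_mlcmm <- function(outcomes, covariates, spec, control = mlcmm_control()) {
  if (is.numeric(spec)) spec <- mlcmm_spec(spec)
  stopifnot(inherits(spec, "mlcmm_spec"))
  layout <- mlcmm_layout(spec)
  data <- mlcmm_build_data(outcomes, covariates, spec)

  # Optimise on an internally standardised scale (outcomes and covariates
  # centred and scaled) so every coordinate is O(1); quasi-Newton methods
  # with numerical derivatives stall on the raw scale, where coordinates
  # differ by four orders of magnitude.
  std <- mlcmm_standardise_data(data, layout)
  negll <- function(theta) {
    par <- mlcmm_unpack(theta, layout)
    ll <- mlcmm_ll_matrix(par, std$data, layout)
    logpi <- log(softmax_full(par$xi))
    v <- -sum(logsumexp_rows(sweep(ll, 2L, logpi, "+")))
    if (!is.finite(v)) 1e10 else v
  }
  b <- mlcmm_bounds(layout)
  theta0 <- mlcmm_start(std$data, layout, derive_seed(control$seed, 0L))
  best <- NULL
  start_logliks <- rep(NA_real_, control$n_starts)
  converged <- logical(control$n_starts)
  ctl <- list(iter.max = control$max_iter,
              # numerical differencing spends ~n_params calls per gradient,
              # so the call budget must scale with the parameter count
              eval.max = 100L * control$max_iter,
              rel.tol = min(control$rel_tol, 1e-9))
  for (j in seq_len(control$n_starts)) {
    th <- if (j == 1L) theta0 else mlcmm_jitter(theta0, layout, derive_seed(control$seed, j))
    opt <- tryCatch(
      nlminb(th, negll, lower = b$lower, upper = b$upper, control = ctl),
      error = function(e) NULL
    )
    if (is.null(opt)) next
    # restarting re-initialises the quasi-Newton model, which often makes
    # further progress along slow ridges
    for (polish in 1:2) {
      opt2 <- tryCatch(
        nlminb(opt$par, negll, lower = b$lower, upper = b$upper, control = ctl),
        error = function(e) NULL
      )
      if (is.null(opt2) || opt$objective - opt2$objective < 1e-6) break
      opt <- opt2
    }
    start_logliks[j] <- -opt$objective
    converged[j] <- opt$convergence == 0L
    if (is.null(best) || opt$objective < best$objective) best <- opt
  }
  if (is.null(best)) abort("all optimiser starts failed")
  theta <- mlcmm_destandardise_theta(best$par, std, layout)
  par <- mlcmm_unpack(theta, layout)
  ll_mat <- mlcmm_ll_matrix(par, data, layout)
  post <- mlcmm_posterior_matrix(par$xi, ll_mat)
  loglik <- sum(logsumexp_rows(sweep(ll_mat, 2L, log(softmax_full(par$xi)), "+")))
  vc <- se <- NULL
  if (control$compute_se) {
    H <- tryCatch(optimHess(best$par, negll), error = function(e) NULL)
    if (!is.null(H)) {
      vc_int <- tryCatch(solve(H), error = function(e) NULL)
      if (!is.null(vc_int)) {
        J <- numeric_jacobian(function(t) mlcmm_destandardise_theta(t, std, layout),
                              best$par)
        vc <- J %*% vc_int %*% t(J)
        dg <- diag(vc)
        se <- ifelse(dg > 0, sqrt(pmax(dg, 0)), NA_real_)
      }
    }
    if (is.null(se)) warn("observed information not invertible; no standard errors")
  }
  fit <- structure(list(
    spec = spec, layout = layout,
    params = par, theta = setNames(theta, layout$names),
    se_theta = if (!is.null(se)) setNames(se, layout$names) else NULL,
    vcov = vc,
    loglik = loglik,
    n_params = layout$n_params,
    n_subjects = data$n,
    bic = -2 * loglik + layout$n_params * log(data$n),
    entropy = relative_entropy(post),
    posterior = post,
    labels = hard_assign(post),
    converged = any(converged),
    convergence_by_start = converged,
    start_logliks = start_logliks,
    n_starts_used = sum(!is.na(start_logliks)),
    subject_ids = data$ids,
    covariate_means = colMeans(data$X),
    seed = control$seed
  ), class = "mlcmm_fit")
  fit
}

mlcmm_posterior_matrix <- function(xi, ll_mat) {
  lp <- sweep(ll_mat, 2L, log(softmax_full(xi)), "+")
  post <- exp(lp - logsumexp_rows(lp))
  post / rowSums(post)
}

#' Posterior class-membership probabilities
#'
#' Bayes' rule with the fitted class proportions and per-class likelihood
#' contributions: `p_ig = pi_g L_ig / sum_l pi_l L_il`.
#'
#' @param fit An [fit_mlcmm()] object.
#' @param outcomes,covariates Optional new data (defaults: not stored; pass
#'   the training tables to recompute, or new subjects to classify). Subjects
#'   with missing covariates are skipped with a message; each subject needs
#'   at least one observed outcome.
#' @return Tibble with `subject_id`, one `prob_class*` column per class, and
#'   the hard `class` assignment.
#' @export
posterior_class_probs <- function(fit, outcomes = NULL, covariates = NULL) {
  stopifnot(inherits(fit, "mlcmm_fit"))
  if (is.null(outcomes)) {
    post <- fit$posterior
    ids <- fit$subject_ids
  } else {
    data <- mlcmm_build_data(outcomes, covariates, fit$spec,
                             on_missing_covariate = "skip")
    ll <- mlcmm_ll_matrix(fit$params, data, fit$layout)
    post <- mlcmm_posterior_matrix(fit$params$xi, ll)
    ids <- data$ids
  }
  out <- tibble::as_tibble(as.data.frame(post))
  names(out) <- paste0("prob_class", seq_len(ncol(post)))
  dplyr::bind_cols(tibble::tibble(subject_id = ids), out) |>
    dplyr::mutate(class = hard_assign(post))
}

#' Predict class membership for new subjects
#'
#' Applies the fitted model's posterior classification rule to unseen
#' subjects (used by the split-half stability assessment).
#'
#' @inheritParams posterior_class_probs
#' @return As [posterior_class_probs()].
#' @export
predict_class_newdata <- function(fit, outcomes, covariates) {
  posterior_class_probs(fit, outcomes, covariates)
}

#' Hard class assignment from a posterior matrix
#'
#' Row-wise argmax; exact ties break toward the lowest class index with a
#' warning.
#'
#' @param posterior N x G matrix with rows summing to 1.
#' @return Integer class labels in 1..G.
#' @export
hard_assign <- function(posterior) {
  posterior <- as.matrix(posterior)
  lab <- max.col(posterior, ties.method = "first")
  n_tied <- sum(apply(posterior, 1L, function(r) sum(r == max(r)) > 1L))
  if (n_tied > 0L) warn(sprintf("%d tie(s) broken toward the lowest class index", n_tied))
  lab
}

#' Relative entropy of a posterior classification
#'
#' `1 - (-sum_i sum_g p_ig log p_ig) / (N log G)`: 1 for a crisp
#' classification, 0 for uniformly uncertain rows; defined as 1 when G = 1.
#'
#' @param posterior N x G matrix of class-membership probabilities.
#' @return Scalar in \[0, 1\].
#' @export
relative_entropy <- function(posterior) {
  posterior <- as.matrix(posterior)
  G <- ncol(posterior)
  if (G == 1L) return(1)
  pl <- posterior * log(posterior)
  pl[posterior == 0] <- 0
  1 - (-sum(pl)) / (nrow(posterior) * log(G))
}

#' Model-selection metrics
#'
#' `BIC = -2 loglik + n_params log N` with the free-parameter count of
#' [count_free_parameters()], and the relative entropy of the posterior.
#'
#' @param loglik Maximised log-likelihood.
#' @param n_params Free-parameter count.
#' @param n_subjects Number of subjects N.
#' @param posterior Optional posterior matrix for the entropy.
#' @param digits Decimal places for the reported BIC (the conventional
#'   printing is two).
#' @return List with `bic`, `entropy` (or `NA`), `n_params`.
#' @export
mlcmm_metrics <- function(loglik, n_params, n_subjects, posterior = NULL,
                          digits = 2) {
  bic <- round(-2 * loglik + n_params * log(n_subjects), digits)
  list(
    bic = bic,
    entropy = if (is.null(posterior)) NA_real_ else relative_entropy(posterior),
    n_params = n_params
  )
}

#' @export
print.mlcmm_fit <- function(x, ...) {
  cat(sprintf(
    "<mlcmm_fit> G = %d classes, N = %d subjects, %d free parameters\n",
    x$spec$n_classes, x$n_subjects, x$n_params
  ))
  cat(sprintf("  log-likelihood %.2f | BIC %.2f | relative entropy %.3f\n",
              x$loglik, x$bic, x$entropy))
  cat("  class sizes:", paste(tabulate(x$labels, x$spec$n_classes), collapse = ", "), "\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the fitted parameters
#'
#' One row per free parameter with natural-scale estimates; standard errors
#' for log-parameterised quantities are mapped by the delta method. Wald
#' z-statistics and two-sided p-values are included where a standard error
#' exists.
#'
#' @param x An `mlcmm_fit`.
#' @param ... Unused.
#' @return Tibble with `term`, `estimate`, `std.error`, `statistic`,
#'   `p.value`.
#' @export
tidy.mlcmm_fit <- function(x, ...) {
  layout <- x$layout
  est <- x$theta
  se <- x$se_theta %||% rep(NA_real_, length(est))
  log_idx <- c(layout$idx$leta2, layout$idx$lsigma, layout$idx$lomega)
  nat <- est; nat[log_idx] <- exp(est[log_idx])
  nat_se <- se; nat_se[log_idx] <- se[log_idx] * exp(est[log_idx])
  term <- sub("^log_", "", layout$names)
  z <- est / se # Wald test on the estimation scale
  tibble::tibble(
    term = term, estimate = nat, std.error = nat_se,
    statistic = z, p.value = 2 * stats::pnorm(-abs(z))
  )
}

#' One-row model summary
#'
#' @param x An `mlcmm_fit`.
#' @param ... Unused.
#' @return Tibble with `n_classes`, `n_subjects`, `n_params`, `logLik`,
#'   `BIC`, `entropy`, `converged`.
#' @export
glance.mlcmm_fit <- function(x, ...) {
  tibble::tibble(
    n_classes = x$spec$n_classes, n_subjects = x$n_subjects,
    n_params = x$n_params, logLik = x$loglik, BIC = x$bic,
    entropy = x$entropy, converged = x$converged
  )
}
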