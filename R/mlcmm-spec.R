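#' Specify a multivariate latent-class linear mixed model
#'
#' The model assumes a latent disease process generates K longitudinal
#' outcomes through outcome-specific linear links
#' `Y_ijk = eta1_k + eta2_k * (Lambda_i(t) + eps_ijk)`, where
#' `Lambda_i(t) | class g = x' beta + gamma0_g + gamma1_g * t + u_i`,
#' with a class-specific random intercept `u_i ~ N(0, omega_g)` and
#' independent measurement errors `eps_ijk ~ N(0, sigma_k^2)`. Class
#' membership follows a covariate-free multinomial logistic submodel with
#' intercepts `xi_g`. Identifiability conventions: the fixed intercept of
#' `ref_intercept` is 0, the random-intercept variance of `ref_variance` is 1
#' (this pins the latent scale), and the membership logit of `ref_membership`
#' is 0.
#'
#' @param n_classes Number of latent classes G >= 1.
#' @param outcomes Character vector of outcome names (K entries).
#' @param covariates Character vector of class-independent covariate names.
#' @param ref_intercept,ref_variance,ref_membership Reference class indices
#'   for the three conventions (defaults: first class for the intercept, last
#'   class for the variance and the membership logit).
#' @return An object of class `mlcmm_spec`.
#' @export
mlcmm_spec <- function(n_classes,
                       outcomes = c("tcdrsb", "nmmse"),
                       covariates = c("age", "sex_male", "edu2", "edu3",
                                      "family_history", "apoe4"),
                       ref_intercept = 1L,
                       ref_variance = n_classes,
                       ref_membership = n_classes) {
  G <- as.integer(n_classes)
  if (G < 1L) abort("`n_classes` must be >= 1")
  for (r in c(ref_intercept, ref_variance, ref_membership)) {
    if (!(r %in% seq_len(G))) abort("reference class indices must be in 1..n_classes")
  }
  structure(list(
    n_classes = G,
    outcomes = outcomes,
    covariates = covariates,
    ref_intercept = as.integer(ref_intercept),
    ref_variance = as.integer(ref_variance),
    ref_membership = as.integer(ref_membership)
  ), class = "mlcmm_spec")
}

# Index layout of the unconstrained parameter vector.
mlcmm_layout <- function(spec) {
  G <- spec$n_classes
  K <- length(spec$outcomes)
  p <- length(spec$covariates)
  free_xi <- setdiff(seq_len(G), spec$ref_membership)
  free_g0 <- setdiff(seq_len(G), spec$ref_intercept)
  free_om <- setdiff(seq_len(G), spec$ref_variance)
  sizes <- c(
    xi = length(free_xi), beta = p, g0 = length(free_g0), g1 = G,
    eta1 = K, leta2 = K, lsigma = K, lomega = length(free_om)
  )
  ends <- cumsum(sizes)
  starts <- ends - sizes + 1L
  idx <- purrr::map2(starts, ends, function(a, b) if (b >= a) seq(a, b) else integer(0))
  names(idx) <- names(sizes)
  nm <- c(
    if (length(free_xi)) paste0("xi_class", free_xi),
    if (p) paste0("beta_", spec$covariates),
    if (length(free_g0)) paste0("intercept_class", free_g0),
    paste0("slope_class", seq_len(G)),
    paste0("eta1_", spec$outcomes),
    paste0("log_eta2_", spec$outcomes),
    paste0("log_sigma_", spec$outcomes),
    if (length(free_om)) paste0("log_omega_class", free_om)
  )
  list(
    spec = spec, G = G, K = K, p = p,
    free_xi = free_xi, free_g0 = free_g0, free_om = free_om,
    idx = idx, n_params = sum(sizes), names = nm
  )
}

#' Count the free parameters of a model specification
#'
#' Counts only estimated parameters: G-1 membership intercepts, G-1 free
#' class intercepts, G class slopes, the class-independent covariate effects,
#' two link parameters and one error standard deviation per outcome, and G-1
#' free random-intercept proportionality factors.
#'
#' @param spec An [mlcmm_spec()].
#' @return Integer count.
#' @export
#' @examples
#' count_free_parameters(mlcmm_spec(4)) # 25
count_free_parameters <- function(spec) {
  stopifnot(inherits(spec, "mlcmm_spec"))
  mlcmm_layout(spec)$n_params
}

# theta (unconstrained) -> natural-scale parameter list.
mlcmm_unpack <- function(theta, layout) {
  G <- layout$G; K <- layout$K
  xi <- numeric(G); xi[layout$free_xi] <- theta[layout$idx$xi]
  g0 <- numeric(G); g0[layout$free_g0] <- theta[layout$idx$g0]
  omega <- rep(1, G); omega[layout$free_om] <- exp(theta[layout$idx$lomega])
  list(
    xi = xi,
    beta = theta[layout$idx$beta],
    g0 = g0,
    g1 = theta[layout$idx$g1],
    eta1 = theta[layout$idx$eta1],
    eta2 = exp(theta[layout$idx$leta2]),
    sigma = exp(theta[layout$idx$lsigma]),
    omega = omega
  )
}

# Natural-scale list -> unconstrained theta.
mlcmm_pack <- function(par, layout) {
  theta <- numeric(layout$n_params)
  theta[layout$idx$xi] <- par$xi[layout$free_xi]
  theta[layout$idx$beta] <- par$beta
  theta[layout$idx$g0] <- par$g0[layout$free_g0]
  theta[layout$idx$g1] <- par$g1
  theta[layout$idx$eta1] <- par$eta1
  theta[layout$idx$leta2] <- log(par$eta2)
  theta[layout$idx$lsigma] <- log(par$sigma)
  theta[layout$idx$lomega] <- log(par$omega[layout$free_om])
  theta
}

#' Class-membership probabilities from the logistic submodel
#'
#' Softmax of the membership intercepts with the reference logit fixed at 0.
#'
#' @param xi0 Numeric vector of G-1 free membership intercepts (or length-0
#'   for a single-class model).
#' @param ref Position of the reference class in the returned simplex
#'   (default: last).
#' @return Probability vector of length `length(xi0) + 1` summing to 1.
#' @export
#' @examples
#' class_probabilities(c(1.30, -1.04, -0.87))
class_probabilities <- function(xi0, ref = length(xi0) + 1L) {
  G <- length(xi0) + 1L
  if (!(ref %in% seq_len(G))) abort("`ref` must index one of the G classes")
  full <- append(xi0, 0, after = ref - 1L)
  e <- exp(full - max(full))
  e / sum(e)
}
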