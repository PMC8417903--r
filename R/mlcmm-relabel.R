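#' Re-express MLCMM parameters under a permutation of class labels
#'
#' The latent-class model is invariant to relabelling the classes, but the
#' identifiability conventions (reference intercept 0, reference
#' random-intercept variance 1, reference membership logit 0) are tied to
#' class positions, so a relabelled model must be re-anchored: the latent
#' scale is divided by the new reference class's random-intercept standard
#' deviation and the latent origin shifted to the new reference intercept,
#' with the link parameters absorbing both. The implied observed-data
#' distribution -- and hence the log-likelihood -- is unchanged.
#'
#' @param params Natural-scale parameter list (as in `fit$params`).
#' @param perm Integer permutation: `perm[new]` is the old class placed at
#'   position `new`.
#' @param spec The [mlcmm_spec()] carrying the reference positions.
#' @return Re-anchored parameter list.
#' @export
mlcmm_relabel <- function(params, perm, spec) {
  G <- spec$n_classes
  stopifnot(length(perm) == G, setequal(perm, seq_len(G)))
  c2 <- params$omega[perm[spec$ref_variance]]
  cc <- sqrt(c2)
  shift <- params$g0[perm[spec$ref_intercept]]
  out <- params
  out$xi <- params$xi[perm] - params$xi[perm[spec$ref_membership]]
  out$g0 <- (params$g0[perm] - shift) / cc
  out$g1 <- params$g1[perm] / cc
  out$beta <- params$beta / cc
  out$omega <- params$omega[perm] / c2
  out$eta1 <- params$eta1 + params$eta2 * shift
  out$eta2 <- params$eta2 * cc
  out$sigma <- params$sigma / cc
  out
}
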