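#' @importFrom rlang .data abort warn inform %||%
#' @importFrom stats rnorm runif rbinom rgamma rbeta rWishart sd var cor
#'   qnorm quantile setNames kmeans nlminb optimHess lm coef complete.cases
#' @importFrom utils head
NULL

# Numerically stable log(sum(exp(x))) along rows of a matrix.
logsumexp_rows <- function(m) {
  mx <- m[, 1L]
  for (j in seq_len(ncol(m))[-1L]) mx <- pmax(mx, m[, j])
  mx + log(rowSums(exp(m - mx)))
}

# One Dirichlet draw per row of the (positive) shape matrix.
rdirichlet_rows <- function(shape) {
  g <- matrix(rgamma(length(shape), shape = shape, rate = 1), nrow = nrow(shape))
  g / rowSums(g)
}

# Derive a per-task seed from a base seed, kept inside 32-bit integer range.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1000003 + offset) %% .Machine$integer.max)
}

assert_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper) {
    abort(sprintf("`%s` must be a single number in [%s, %s]", name, lower, upper))
  }
  invisible(x)
}
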