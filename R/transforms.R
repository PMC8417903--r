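#' Logistic transformation of CDR Sum of Boxes
#'
#' Maps CDRSB from its bounded 0--18 range to an unbounded scale, removing
#' floor and ceiling effects before linear mixed modelling:
#' `tCDRSB = -log((CDRSB + 0.1) / (18 - CDRSB + 0.1))`.
#' The transform is strictly decreasing (higher tCDRSB = better functioning),
#' antisymmetric about CDRSB = 9, and maps the endpoints to roughly +/- 5.198.
#'
#' @param cdrsb Numeric vector of CDRSB scores in \[0, 18\]; `NA` passes through.
#' @return Numeric vector of transformed scores.
#' @seealso [inv_transform_cdrsb()]
#' @export
#' @examples
#' transform_cdrsb(c(0, 9, 18))
transform_cdrsb <- function(cdrsb) {
  if (!is.numeric(cdrsb)) abort("`cdrsb` must be numeric")
  bad <- !is.na(cdrsb) & (cdrsb < 0 | cdrsb > 18)
  if (any(bad)) abort("CDRSB values must lie in [0, 18]")
  -log((cdrsb + 0.1) / (18 - cdrsb + 0.1))
}

#' Inverse of the CDRSB logistic transformation
#'
#' @param tcdrsb Numeric vector on the transformed scale.
#' @return CDRSB values in \[0, 18\] (continuous; not snapped to the 0.5 grid).
#' @export
inv_transform_cdrsb <- function(tcdrsb) {
  e <- exp(-tcdrsb)
  (18.1 * e - 0.1) / (1 + e)
}

#' MMSE normalisation lookup table
#'
#' The Mini-Mental State Examination is curvilinear: one raw point lost near
#' the 30-point ceiling reflects a larger cognitive change than one point in
#' mid-range. Normalisation maps the 0--30 raw scale onto a 0--100 scale on
#' which differences are closer to interval-scaled. The published reference
#' table for this correction is not redistributable, so the `"curvilinear"`
#' table shipped here is a synthetic, package-constructed stand-in: a monotone
#' power-law map `nMMSE = 100 * (mmse/30)^2.2`, which stretches the top of the
#' scale and pins the endpoints at exactly 0 and 100. The `"linear"` method is
#' the plain rescaling `mmse/30 * 100`.
#'
#' @param method `"curvilinear"` (default) or `"linear"`.
#' @return A 31-row tibble with integer column `mmse` (0--30) and numeric
#'   column `nmmse` (0--100), monotone non-decreasing.
#' @export
#' @examples
#' mmse_normalisation_table()
mmse_normalisation_table <- function(method = c("curvilinear", "linear")) {
  method <- match.arg(method)
  mmse <- 0:30
  nmmse <- switch(method,
    curvilinear = 100 * (mmse / 30)^2.2,
    linear = mmse / 30 * 100
  )
  tibble::tibble(mmse = mmse, nmmse = round(nmmse, 1))
}

#' Normalise MMSE scores through a lookup table
#'
#' @param mmse Integer vector of raw MMSE scores (0--30); `NA` passes through.
#' @param table Lookup table as returned by [mmse_normalisation_table()]; any
#'   31-row data frame with columns `mmse` (0:30) and `nmmse` mapping the
#'   endpoints to 0 and 100 monotonically is accepted.
#' @return Numeric vector of normalised scores on 0--100.
#' @export
normalise_mmse <- function(mmse, table = mmse_normalisation_table()) {
  stopifnot(is.data.frame(table), all(c("mmse", "nmmse") %in% names(table)))
  table <- table[order(table$mmse), ]
  if (!identical(as.integer(table$mmse), 0:30)) {
    abort("`table` must have one row per integer MMSE score 0..30")
  }
  if (is.unsorted(table$nmmse) || table$nmmse[1] != 0 || table$nmmse[31] != 100) {
    abort("`table$nmmse` must be monotone non-decreasing with endpoints 0 and 100")
  }
  ok <- is.na(mmse) | (mmse >= 0 & mmse <= 30 & mmse == round(mmse))
  if (!all(ok)) abort("MMSE values must be integers in [0, 30]")
  out <- rep(NA_real_, length(mmse))
  out[!is.na(mmse)] <- table$nmmse[mmse[!is.na(mmse)] + 1L]
  out
}

#' Invert the MMSE normalisation (nearest raw score)
#'
#' Used by the synthetic generator to turn simulated normalised scores back
#' into integer MMSE values: returns the raw score whose table entry is
#' closest to `nmmse` (ties toward the higher raw score), after clamping to
#' \[0, 100\].
#'
#' @inheritParams normalise_mmse
#' @param nmmse Numeric vector on the normalised 0--100 scale.
#' @return Integer MMSE scores.
#' @export
inv_normalise_mmse <- function(nmmse, table = mmse_normalisation_table()) {
  table <- table[order(table$mmse), ]
  x <- pmin(pmax(nmmse, 0), 100)
  idx <- vapply(x, function(v) {
    if (is.na(v)) return(NA_integer_)
    d <- abs(table$nmmse - v)
    max(which(d == min(d))) - 1L
  }, integer(1))
  idx
}

#' Annualised change in a volumetric biomarker
#'
#' `(v_last - v0) / dt`, the per-year change between the baseline and last
#' observed head-size-adjusted volume.
#'
#' @param v0,v_last Baseline and last observed volumes (mm^3); `NA` propagates.
#' @param dt Time between the two measurements in years; must be positive
#'   wherever both volumes are present.
#' @return Numeric vector in mm^3/year.
#' @export
annualised_change <- function(v0, v_last, dt) {
  n <- max(length(v0), length(v_last), length(dt))
  v0 <- rep_len(v0, n); v_last <- rep_len(v_last, n); dt <- rep_len(dt, n)
  have <- !is.na(v0) & !is.na(v_last)
  if (any(have & (is.na(dt) | dt <= 0))) {
    abort("`dt` must be positive wherever both volumes are observed")
  }
  out <- rep(NA_real_, n)
  out[have] <- (v_last[have] - v0[have]) / dt[have]
  out
}

#' Standardise a numeric vector
#'
#' Centres and scales by the sample (n-1) standard deviation of the
#' non-missing entries; missing values are preserved.
#'
#' @param values Numeric vector with at least two non-missing entries.
#' @return Standardised vector of the same length.
#' @export
standardise <- function(values) {
  obs <- values[!is.na(values)]
  if (length(obs) < 2L) abort("need at least 2 non-missing values to standardise")
  s <- sd(obs)
  if (!is.finite(s) || s == 0) abort("cannot standardise a constant vector")
  (values - mean(obs)) / s
}
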