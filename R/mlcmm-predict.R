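#' Predicted class trajectories on the latent and outcome scales
#'
#' The latent-process mean line for each class at a fixed covariate profile
#' (by default the training-sample covariate means), with a delta-method 95%
#' confidence band from the observed-information covariance of
#' (beta, gamma0_g, gamma1_g). Outcome-scale curves invert the linear links
#' (`Y = eta1 + eta2 * Lambda`); the CDRSB-scale curve additionally inverts
#' the logistic transformation (a decreasing map, so its band limits swap).
#'
#' @param fit An [fit_mlcmm()] object.
#' @param times Numeric grid of times in study (years).
#' @param profile Named covariate vector; defaults to training means.
#' @param classes Classes to predict (default all).
#' @param level Confidence level for the band.
#' @return Tibble with columns `class`, `time`, `latent`, `se`,
#'   `latent_lower`, `latent_upper`, then per outcome `<name>`,
#'   `<name>_lower`, `<name>_upper`, and (when `tcdrsb` is an outcome)
#'   `cdrsb`, `cdrsb_lower`, `cdrsb_upper`.
#' @export
predict_trajectory <- function(fit, times = seq(0, 3, by = 0.25),
                               profile = NULL,
                               classes = seq_len(fit$spec$n_classes),
                               level = 0.95) {
  stopifnot(inherits(fit, "mlcmm_fit"))
  layout <- fit$layout
  x <- profile %||% fit$covariate_means
  if (!is.null(names(x))) x <- x[fit$spec$covariates]
  if (anyNA(x) || length(x) != layout$p) abort("`profile` must cover every model covariate")
  zq <- qnorm(1 - (1 - level) / 2)
  rows <- purrr::map(classes, function(g) {
    lat <- latent_mean(fit$params, g, x, times)
    se <- rep(NA_real_, length(times))
    if (!is.null(fit$vcov)) {
      for (i in seq_along(times)) {
        grad <- numeric(layout$n_params)
        grad[layout$idx$beta] <- x
        if (g %in% layout$free_g0) {
          grad[layout$idx$g0[match(g, layout$free_g0)]] <- 1
        }
        grad[layout$idx$g1[g]] <- times[i]
        se[i] <- sqrt(max(drop(grad %*% fit$vcov %*% grad), 0))
      }
    }
    tibble::tibble(class = g, time = times, latent = lat, se = se,
                   latent_lower = lat - zq * se, latent_upper = lat + zq * se)
  })
  out <- dplyr::bind_rows(rows)
  for (k in seq_along(fit$spec$outcomes)) {
    nm <- fit$spec$outcomes[k]
    e1 <- fit$params$eta1[k]; e2 <- fit$params$eta2[k]
    out[[nm]] <- e1 + e2 * out$latent
    out[[paste0(nm, "_lower")]] <- e1 + e2 * out$latent_lower
    out[[paste0(nm, "_upper")]] <- e1 + e2 * out$latent_upper
  }
  if ("tcdrsb" %in% fit$spec$outcomes) {
    # the inverse logistic map is decreasing: upper latent -> lower CDRSB
    clamp <- function(v) pmin(pmax(v, 0), 18)
    out$cdrsb <- clamp(inv_transform_cdrsb(out$tcdrsb))
    out$cdrsb_lower <- clamp(inv_transform_cdrsb(out$tcdrsb_upper))
    out$cdrsb_upper <- clamp(inv_transform_cdrsb(out$tcdrsb_lower))
  }
  out
}

#' Plot predicted class trajectories
#'
#' @param object An `mlcmm_fit`.
#' @param scale `"latent"` or one of the outcome names.
#' @param ... Passed to [predict_trajectory()].
#' @return A ggplot object.
#' @export
autoplot.mlcmm_fit <- function(object, scale = "latent", ...) {
  traj <- predict_trajectory(object, ...)
  ycol <- if (scale == "latent") "latent" else scale
  lo <- if (scale == "latent") "latent_lower" else paste0(scale, "_lower")
  hi <- if (scale == "latent") "latent_upper" else paste0(scale, "_upper")
  ggplot2::ggplot(traj, ggplot2::aes(
    x = .data$time, y = .data[[ycol]],
    colour = factor(.data$class), fill = factor(.data$class)
  )) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data[[lo]], ymax = .data[[hi]]),
      alpha = 0.2, colour = NA
    ) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(
      x = "Time in study (years)", y = scale,
      colour = "Class", fill = "Class"
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
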