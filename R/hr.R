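# Hazard-ratio distribution inference ------------------------------------

#' Log-scale standard deviation from a Wald confidence interval
#'
#' Inverts the standard Wald interval on the ratio scale:
#' `(ln hi - ln lo) / (2 z)`, with `z` the `(1 + level)/2` normal quantile.
#'
#' @param lo,hi Interval endpoints on the ratio scale, `0 < lo < hi`.
#' @param level Confidence level of the interval (default 0.95).
#' @return The standard deviation of the log hazard ratio.
#' @export
logsd_from_ci <- function(lo, hi, level = 0.95) {
  if (any(lo <= 0) || any(hi <= lo)) {
    .cr_stop("confidence interval must satisfy 0 < lo < hi",
      class = "wolfcr_domain_error"
    )
  }
  if (level <= 0 || level >= 1) {
    .cr_stop("level must lie in (0, 1)", class = "wolfcr_domain_error")
  }
  (log(hi) - log(lo)) / (2 * qnorm((1 + level) / 2))
}

#' Lognormal hazard-ratio distribution
#'
#' The sampling distribution of a hazard ratio visualized as an
#' exponentiated normal: log-mean from the point estimate (or a fitted
#' coefficient) and log-sd recovered from the Wald CI (or a robust SE).
#' When a fit is available its unrounded coefficient and robust SE take
#' precedence; printed-value mode reconstructs the distribution from a
#' published point estimate and CI alone.
#'
#' @param hr Point estimate on the ratio scale.
#' @param lo,hi Confidence-interval endpoints at `level`; alternatively
#'   supply `se`.
#' @param se Log-scale standard error (overrides `lo`/`hi` when given).
#' @param level Confidence level of `lo`/`hi`.
#' @return A `cr_hrdist` object: `point`, `logmean`, `logsd`, `level`.
#' @export
hr_distribution <- function(hr, lo = NULL, hi = NULL, se = NULL, level = 0.95) {
  if (hr <= 0) .cr_stop("hr must be positive", class = "wolfcr_domain_error")
  logsd <- if (!is.null(se)) se else logsd_from_ci(lo, hi, level)
  if (logsd <= 0) .cr_stop("log-sd must be positive", class = "wolfcr_domain_error")
  out <- list(point = hr, logmean = log(hr), logsd = logsd, level = level)
  class(out) <- "cr_hrdist"
  out
}

#' @export
print.cr_hrdist <- function(x, ...) {
  ci <- exp(x$logmean + c(-1, 1) * qnorm((1 + x$level) / 2) * x$logsd)
  cat(sprintf(
    "HR distribution: point %.3f, log-sd %.4f, %g%% CI %.3f-%.3f\n",
    x$point, x$logsd, 100 * x$level, ci[1], ci[2]
  ))
  cat(sprintf(
    "  P(HR > 1) = %.3f, P(HR < 1) = %.3f\n",
    prob_hr_side(x, side = "above")$raw, prob_hr_side(x, side = "below")$raw
  ))
  invisible(x)
}

#' Probability mass of a hazard-ratio distribution beyond a threshold
#'
#' Normal tail mass of `ln(threshold)` under the lognormal HR distribution:
#' the probability that the hazard ratio lies above (or below) the threshold,
#' reported raw and rounded half-up to a whole percent for annotation.
#'
#' @param hr A `cr_hrdist`, or a point estimate (then give `ci`).
#' @param ci Length-2 CI on the ratio scale when `hr` is numeric.
#' @param side `"above"` or `"below"`.
#' @param threshold Ratio-scale threshold (default 1, no effect).
#' @param level Confidence level of `ci`.
#' @return List with `raw` (probability) and `percent` (integer percent).
#' @export
prob_hr_side <- function(hr, ci = NULL, side = c("above", "below"),
                         threshold = 1, level = 0.95) {
  side <- match.arg(side)
  dist <- if (inherits(hr, "cr_hrdist")) {
    hr
  } else {
    hr_distribution(hr, lo = ci[1], hi = ci[2], level = level)
  }
  z <- (log(threshold) - dist$logmean) / dist$logsd
  p <- if (side == "above") pnorm(z, lower.tail = FALSE) else pnorm(z)
  list(raw = p, percent = .percent(p))
}

#' Hazard ratio composed with a time-varying coefficient
#'
#' A per-year multiplicative tvc composes as
#' `HR(t) = baseline_hr * tvc_per_year ^ years` (continuous years allowed):
#' e.g. a baseline winter HR of 3.13 with tvc 0.69/year gives 2.16 at one
#' year and 1.49 at two years of monitoring.
#'
#' @param baseline_hr Hazard ratio at time zero.
#' @param tvc_per_year Multiplicative change in the HR per year.
#' @param years Years of analysis time (>= 0).
#' @return The composed hazard ratio.
#' @export
hr_at_time <- function(baseline_hr, tvc_per_year, years) {
  if (any(baseline_hr <= 0) || any(tvc_per_year <= 0) || any(years < 0)) {
    .cr_stop("hr_at_time requires positive ratios and nonnegative years",
      class = "wolfcr_domain_error"
    )
  }
  baseline_hr * tvc_per_year^years
}

#' Density series of a hazard-ratio distribution
#'
#' Log-spaced grid with lognormal density values, for bell-curve plots of
#' HR distributions.
#'
#' @param dist A `cr_hrdist`.
#' @param n Grid size.
#' @param width Half-width of the grid in log-sd units.
#' @return Data frame with columns `hr` and `density`.
#' @export
hr_density <- function(dist, n = 201, width = 4) {
  lg <- seq(dist$logmean - width * dist$logsd,
    dist$logmean + width * dist$logsd,
    length.out = n
  )
  data.frame(hr = exp(lg), density = stats::dlnorm(exp(lg), dist$logmean, dist$logsd))
}

#' @export
plot.cr_hrdist <- function(x, ...) {
  d <- hr_density(x)
  plot(d$hr, d$density,
    type = "l", log = "x", xlab = "hazard ratio",
    ylab = "density", ...
  )
  graphics::abline(v = 1, col = "black")
  graphics::abline(v = x$point, lty = 2)
  invisible(x)
}
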