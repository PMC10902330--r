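#' Least-squares cosinor fit at a fixed period
#'
#' Fits the single-component cosinor model
#' \deqn{y = m + a\cos(2\pi t/T) + b\sin(2\pi t/T)}
#' by the exact normal-equation (QR) solution, with no iterative
#' optimizer. Replicate observations enter as independent points.
#'
#' The fit is reported in the polar parameterisation used throughout the
#' package: `mesor` (rhythm-adjusted mean, `m`), `amplitude` as
#' peak-to-trough distance `2*sqrt(a^2 + b^2)` on the scale of `values`
#' (for log2 data, amplitude 1 is roughly a 2-fold change), and `phase`
#' as the peak position in radians, `atan2(b, a) mod 2pi`, so the peak
#' occurs at time `phase * period / (2*pi)` after the time origin
#' (t = 0, the first sample of the analysed segment).
#'
#' @param values numeric vector of (typically log2) expression values.
#' @param times numeric vector of sampling times in hours, same length
#'   as `values`. At least 4 observations at 3 or more distinct times
#'   are required.
#' @param period period in hours (> 0).
#' @param amplitude_tol fits with amplitude below this are treated as
#'   flat and reported with `phase = 0`.
#' @return An object of class `"cosinor"`: a list with components
#'   `period`, `mesor`, `amplitude`, `phase`, `rss`, `rss_null`
#'   (intercept-only residual sum of squares), `coefficients`
#'   (`mesor`, `cos`, `sin`), `fitted.values`, `residuals`, `times`,
#'   `values`, `df.residual`.
#' @examples
#' t <- seq(0, 44, by = 4)
#' y <- 2 + cos(2 * pi * t / 24)
#' fit <- fit_cosinor(y, t, period = 24)
#' coef(fit)
#' @seealso [scan_periods()] to choose the period over a grid,
#'   [rhythm_test()] for genome-wide testing.
#' @export
fit_cosinor <- function(values, times, period, amplitude_tol = 1e-8) {
  stopifnot(is.numeric(values), is.numeric(times))
  if (length(values) != length(times))
    stop("'values' and 'times' must have the same length")
  if (anyNA(values) || anyNA(times) || any(!is.finite(values)))
    stop("'values' and 'times' must be finite and non-missing")
  if (length(period) != 1L || !is.finite(period) || period <= 0)
    stop("'period' must be a single positive number")
  if (length(values) < 4L)
    stop("cosinor fit needs at least 4 observations")
  if (length(unique(times)) < 3L)
    stop("degenerate design: cosinor fit needs at least 3 distinct times")

  X <- cosinor_design(times, period)
  qx <- qr(X)
  if (qx$rank < 3L)
    stop("degenerate design: cosinor design matrix is rank-deficient")
  cf <- qr.coef(qx, values)
  fitted <- drop(X %*% cf)
  res <- values - fitted
  rss <- sum(res^2)
  rss_null <- sum((values - mean(values))^2)
  # numerical guard: the 3-parameter model nests the intercept-only model
  if (rss > rss_null) rss <- rss_null

  a <- cf[2L]
  b <- cf[3L]
  amplitude <- 2 * sqrt(a^2 + b^2)
  phase <- if (amplitude < amplitude_tol) 0 else atan2(b, a) %% (2 * pi)

  structure(list(
    period = period,
    mesor = unname(cf[1L]),
    amplitude = unname(amplitude),
    phase = unname(phase),
    rss = rss,
    rss_null = rss_null,
    coefficients = c(mesor = unname(cf[1L]), cos = unname(a), sin = unname(b)),
    fitted.values = fitted,
    residuals = res,
    times = times,
    values = values,
    df.residual = length(values) - 3L
  ), class = "cosinor")
}

# design matrix for the cosinor model at one period
cosinor_design <- function(times, period) {
  w <- 2 * pi * times / period
  cbind(intercept = 1, cos = cos(w), sin = sin(w))
}

#' Best cosinor fit over a period grid
#'
#' Fits the cosinor model at every period on a regular grid and returns
#' the fit with the smallest residual sum of squares. Ties are broken
#' toward the shortest period.
#'
#' @inheritParams fit_cosinor
#' @param period_min,period_max endpoints of the period window in hours
#'   (e.g. 20-28 h for circadian, 8-10 h for the larval molting clock).
#' @param period_step grid step in hours (default 0.5).
#' @return The best `"cosinor"` fit; the grid searched is attached as
#'   attribute `"period_grid"` and the per-period RSS as `"grid_rss"`.
#' @examples
#' t <- seq(0, 44, by = 4)
#' y <- 1.5 + 0.8 * cos(2 * pi * t / 24 - pi / 3)
#' scan_periods(y, t, 20, 28)$period
#' @export
scan_periods <- function(values, times, period_min, period_max,
                         period_step = 0.5) {
  if (period_min > period_max) stop("'period_min' must be <= 'period_max'")
  if (period_step <= 0) stop("'period_step' must be positive")
  grid <- period_grid(period_min, period_max, period_step)
  rss <- rep(NA_real_, length(grid))
  best <- NULL
  for (i in seq_along(grid)) {
    fit <- fit_cosinor(values, times, grid[i])
    rss[i] <- fit$rss
    # strict '<' keeps the shortest period on ties
    if (is.null(best) || fit$rss < best$rss) best <- fit
  }
  attr(best, "period_grid") <- grid
  attr(best, "grid_rss") <- rss
  best
}

period_grid <- function(period_min, period_max, period_step) {
  grid <- seq(period_min, period_max, by = period_step)
  if (grid[length(grid)] < period_max - 1e-9)
    grid <- c(grid, period_max)
  if (length(grid) == 0L) stop("empty period grid")
  grid
}

#' @export
print.cosinor <- function(x, digits = 4, ...) {
  cat("Cosinor fit (period ", format(x$period, digits = digits), " h)\n",
      sep = "")
  cat("  mesor:     ", format(x$mesor, digits = digits), "\n", sep = "")
  cat("  amplitude: ", format(x$amplitude, digits = digits),
      " (peak-to-trough)\n", sep = "")
  cat("  phase:     ", format(x$phase, digits = digits), " rad (peak at t = ",
      format(x$phase * x$period / (2 * pi), digits = digits), " h)\n",
      sep = "")
  cat("  RSS: ", format(x$rss, digits = digits), " on ", x$df.residual,
      " residual df (null RSS ", format(x$rss_null, digits = digits), ")\n",
      sep = "")
  invisible(x)
}

#' @export
coef.cosinor <- function(object, ...) object$coefficients

#' @export
fitted.cosinor <- function(object, ...) object$fitted.values

#' @export
residuals.cosinor <- function(object, ...) object$residuals

#' Predict from a cosinor fit
#'
#' @param object a `"cosinor"` fit.
#' @param times times (hours) at which to evaluate the fitted curve;
#'   defaults to the times used in fitting.
#' @param ... ignored.
#' @return numeric vector of fitted values.
#' @export
predict.cosinor <- function(object, times = object$times, ...) {
  drop(cosinor_design(times, object$period) %*% object$coefficients)
}

#' Variance explained by a cosinor fit
#'
#' The periodicity statistic used by [rhythm_test()]:
#' `1 - rss / rss_null`, the proportion of variance around the mean
#' captured by the best-fitting cosine.
#'
#' @param fit a `"cosinor"` fit.
#' @return a number in \[0, 1\] (0 for a constant series).
#' @export
variance_explained <- function(fit) {
  if (fit$rss_null <= 0) return(0)
  1 - fit$rss / fit$rss_null
}
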