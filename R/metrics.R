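# Agreement statistics between an estimated and a reference angle trace:
# RMSE on circularly wrapped differences, regression slope/intercept,
# range of motion, and drift (slope of the error over time).

#' Wrap an angle difference to the minimal circular distance
#'
#' Differences are mapped into (-180, 180] so that, e.g., a raw difference
#' of 350 degrees is reported as -10 degrees.
#'
#' @param est,ref Angles in degrees (vectors recycled as usual).
#' @return Wrapped differences \code{est - ref} in degrees.
#' @export
wrap_difference <- function(est, ref = 0) {
  d <- est - ref
  .check_finite(d, "est - ref")
  out <- d - 360 * floor((d + 180) / 360)
  out[out == -180] <- 180
  out
}

#' Root mean square error between two angle traces
#'
#' The square root of the mean squared wrapped difference; zero iff the
#' traces are identical modulo 360 degrees.
#'
#' @param est,ref Angle traces in degrees, equal length.
#' @return RMSE in degrees.
#' @export
angle_rmse <- function(est, ref) {
  if (length(est) != length(ref))
    stop("est and ref must have equal length", call. = FALSE)
  if (length(est) < 1) stop("need at least one sample", call. = FALSE)
  sqrt(mean(wrap_difference(est, ref)^2))
}

#' Regression of an estimated trace on a reference trace
#'
#' Ordinary least squares with the reference as the independent variable.
#' The slope quantifies tracking of changes (1 is perfect); the intercept
#' quantifies bias.  Slopes within 0.1 of 1 are conventionally rated
#' excellent, within 0.3 good, within 0.5 moderate.
#'
#' @param est,ref Equal-length numeric traces (degrees).
#' @return List with \code{slope}, \code{intercept}, \code{r} (Pearson
#'   correlation).
#' @export
agreement_regression <- function(est, ref) {
  if (length(est) != length(ref))
    stop("est and ref must have equal length", call. = FALSE)
  if (length(est) < 3) stop("need at least 3 samples", call. = FALSE)
  if (stats::sd(ref) < 1e-12)
    stop("degenerate regressor: reference trace is constant", call. = FALSE)
  fit <- stats::lm.fit(cbind(1, ref), est)
  list(slope = unname(fit$coefficients[2]),
       intercept = unname(fit$coefficients[1]),
       r = stats::cor(est, ref))
}

#' Range of motion of an angle trace
#'
#' Maximum minus minimum.  For trials longer than 30 s the first 10 s are
#' excluded so start-up transients do not inflate the range.
#'
#' @param trace Angle trace, degrees.
#' @param t Time stamps, s (same length).
#' @return Range of motion in degrees.
#' @export
range_of_motion <- function(trace, t) {
  if (length(trace) == 0) stop("empty trace", call. = FALSE)
  if (length(trace) != length(t))
    stop("trace and t must have equal length", call. = FALSE)
  dur <- t[length(t)] - t[1]
  keep <- if (dur > 30) t - t[1] >= 10 else rep(TRUE, length(t))
  x <- trace[keep]
  if (length(x) == 0)
    stop("insufficient data after start-up exclusion", call. = FALSE)
  max(x) - min(x)
}

#' Drift of an estimated trace relative to a reference
#'
#' Ordinary least-squares slope of the wrapped angle difference against
#' time, with the slope's two-sided p-value.  A non-zero slope indicates
#' unbounded error growth during long non-stationary tasks.
#'
#' @param est,ref Angle traces, degrees.
#' @param t Time stamps, s.
#' @return List with \code{slope} (degrees/s) and \code{p_value}.
#' @export
drift_slope <- function(est, ref, t) {
  if (length(est) < 3) stop("need at least 3 samples", call. = FALSE)
  d <- wrap_difference(est, ref)
  fit <- stats::lm(d ~ t)
  cf <- summary(fit)$coefficients
  list(slope = unname(cf["t", "Estimate"]),
       p_value = unname(cf["t", "Pr(>|t|)"]))
}

#' Wilcoxon signed-rank test of drift slopes across subjects
#'
#' Two-sided one-sample test of the null hypothesis that the distribution
#' of per-subject drift slopes is centered on zero (exact for n <= 25).
#'
#' @param slopes Vector of per-subject drift slopes, degrees/s.
#' @return An object of class \code{htest}.
#' @export
drift_wilcoxon <- function(slopes) {
  stats::wilcox.test(slopes, mu = 0, alternative = "two.sided",
                     exact = length(slopes) <= 25)
}

#' All agreement statistics between two angle traces
#'
#' @param est,ref Angle traces, degrees.
#' @param t Time stamps, s.
#' @return An object of class \code{agreement_stats}: list with
#'   \code{rmse}, \code{slope}, \code{intercept}, \code{r}, \code{romd}
#'   (range-of-motion difference, est minus ref), \code{drift},
#'   \code{drift_p}, \code{n}.
#' @export
agreement_stats <- function(est, ref, t) {
  reg <- agreement_regression(est, ref)
  dr <- drift_slope(est, ref, t)
  structure(list(
    rmse = angle_rmse(est, ref),
    slope = reg$slope, intercept = reg$intercept, r = reg$r,
    romd = range_of_motion(est, t) - range_of_motion(ref, t),
    drift = dr$slope, drift_p = dr$p_value,
    n = length(est)), class = "agreement_stats")
}

#' @export
print.agreement_stats <- function(x, ...) {
  cat(sprintf(paste0("<agreement_stats> n = %d\n",
                     "  RMSE %.3f deg | slope %.3f | intercept %.3f deg | ",
                     "r %.3f\n  ROMD %.3f deg | drift %.4f deg/s (p = %.3g)\n"),
              x$n, x$rmse, x$slope, x$intercept, x$r, x$romd, x$drift,
              x$drift_p))
  invisible(x)
}
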