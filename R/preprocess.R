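# Signal conditioning applied before filtering and calibration, plus the
# rate conversion used when comparing angle traces between systems.

#' Construct a synchronized IMU recording
#'
#' Container for one magneto-inertial sensor's time series.  All channels
#' must share the same uniformly spaced time base.
#'
#' @param t Time stamps in seconds, uniformly spaced.
#' @param gyro N x 3 angular velocity, rad/s, sensor frame.
#' @param accel N x 3 specific force (accelerometer reading), m/s^2,
#'   sensor frame.  A sensor at rest reads +G along the "up" direction.
#' @param mag N x 3 magnetic field, any consistent units, sensor frame.
#' @param fs Sampling rate in Hz.  Defaults to \code{1 / median(diff(t))}.
#' @return An object of class \code{imu_recording}: a list with elements
#'   \code{t}, \code{gyro}, \code{accel}, \code{mag}, \code{fs}, \code{n}.
#' @export
imu_recording <- function(t, gyro, accel, mag, fs = NULL) {
  gyro <- as.matrix(gyro); accel <- as.matrix(accel); mag <- as.matrix(mag)
  n <- length(t)
  if (n < 2) stop("an imu_recording needs at least 2 samples", call. = FALSE)
  if (ncol(gyro) != 3 || ncol(accel) != 3 || ncol(mag) != 3)
    stop("gyro, accel and mag must have 3 columns", call. = FALSE)
  if (nrow(gyro) != n || nrow(accel) != n || nrow(mag) != n)
    stop("all channels must have the same length as t", call. = FALSE)
  .check_finite(t, "t"); .check_finite(gyro, "gyro")
  .check_finite(accel, "accel"); .check_finite(mag, "mag")
  dt <- diff(t)
  if (is.null(fs)) fs <- 1 / stats::median(dt)
  if (any(abs(dt - 1 / fs) > 1e-6))
    stop("time stamps must be uniformly spaced at 1/fs within 1e-6 s",
         call. = FALSE)
  structure(list(t = t, gyro = gyro, accel = accel, mag = mag,
                 fs = fs, n = n),
            class = "imu_recording")
}

#' @export
print.imu_recording <- function(x, ...) {
  cat(sprintf("<imu_recording> %d samples at %.6g Hz (%.2f s)\n",
              x$n, x$fs, x$n / x$fs))
  invisible(x)
}

# One forward pass of an IIR filter started from the steady state that the
# first sample would produce (exact for a constant input, since the
# Butterworth low-pass has unit DC gain).
.filter_steady <- function(b, a, x) {
  as.numeric(signal::filter(b, a, x,
                            init.x = rep(x[1], length(b) - 1),
                            init.y = rep(x[1], length(a) - 1)))
}

#' Zero-phase low-pass filter
#'
#' Fourth-order low-pass Butterworth filter applied forward and backward
#' (squaring the magnitude response, cancelling the phase).  Edge effects
#' are controlled by odd-symmetric end extension plus steady-state filter
#' initialization, so a constant signal passes through unchanged.
#'
#' @param x Numeric vector or N x k matrix (filtered column-wise).
#' @param fc Cutoff frequency, Hz.  Must be below the Nyquist rate.
#' @param fs Sampling rate, Hz.
#' @param order Filter order of each pass (default 4).
#' @return Filtered signal, same shape as \code{x}.
#' @export
lowpass_zero_phase <- function(x, fc, fs, order = 4) {
  if (!is.numeric(fc) || fc <= 0 || fc >= fs / 2)
    stop("invalid parameter: fc must satisfy 0 < fc < fs/2", call. = FALSE)
  mat <- is.matrix(x)
  xm <- if (mat) x else matrix(x, ncol = 1)
  .check_finite(xm, "x")
  bf <- signal::butter(order, fc / (fs / 2))
  b <- bf$b; a <- bf$a
  n <- nrow(xm)
  # long enough for the slowest pole's transient to decay below 1e-8,
  # keeping the forward-backward pass time-reversal symmetric at the ends
  pad <- 9 * (length(b) + length(a))
  if (n <= pad + 1)
    stop(sprintf("insufficient data: need more than %d samples to filter",
                 pad + 1), call. = FALSE)
  out <- xm
  for (j in seq_len(ncol(xm))) {
    xc <- xm[, j]
    # odd reflection about the end points
    xe <- c(2 * xc[1] - xc[(pad + 1):2], xc, 2 * xc[n] - xc[(n - 1):(n - pad)])
    y <- .filter_steady(b, a, xe)
    y <- rev(.filter_steady(b, a, rev(y)))
    out[, j] <- y[(pad + 1):(pad + n)]
  }
  if (mat) out else out[, 1]
}

#' Angular acceleration from angular velocity
#'
#' Second-order central differences at interior samples,
#' \code{(w[k+1] - w[k-1]) / (2 dt)}, with first-order one-sided differences
#' at the two end points.  Optionally zero-phase low-pass filtered afterwards
#' (12 Hz by default, matching the pipeline's preprocessing).
#'
#' @param gyro N x 3 angular velocity, rad/s.
#' @param dt Sample interval, s.
#' @param fc Cutoff of the post-differentiation low-pass filter in Hz, or
#'   \code{NULL} to skip filtering.
#' @return N x 3 angular acceleration, rad/s^2.
#' @export
angular_acceleration <- function(gyro, dt, fc = NULL) {
  gyro <- as.matrix(gyro)
  n <- nrow(gyro)
  if (n < 3) stop("insufficient data: need at least 3 samples", call. = FALSE)
  .check_finite(gyro, "gyro"); .check_finite(dt, "dt")
  wd <- gyro
  wd[2:(n - 1), ] <- (gyro[3:n, ] - gyro[1:(n - 2), ]) / (2 * dt)
  wd[1, ] <- (gyro[2, ] - gyro[1, ]) / dt
  wd[n, ] <- (gyro[n, ] - gyro[n - 1, ]) / dt
  if (!is.null(fc)) wd <- lowpass_zero_phase(wd, fc, 1 / dt)
  wd
}

#' Resample a trace to a lower rate by linear interpolation
#'
#' Places a uniform grid at \code{fs_out} spanning the same interval and
#' interpolates linearly.  Intended for angle traces (orientation traces are
#' not slerped; the pipeline downsamples extracted angles, not rotations).
#'
#' @param t Time stamps of the input, s.
#' @param x Numeric vector or N x k matrix aligned with \code{t}.
#' @param fs_out Output sampling rate, Hz.
#' @return List with elements \code{t} (new time stamps) and \code{x}.
#' @export
resample_trace <- function(t, x, fs_out) {
  if (!is.numeric(fs_out) || fs_out <= 0)
    stop("invalid parameter: fs_out must be positive", call. = FALSE)
  mat <- is.matrix(x)
  xm <- if (mat) x else matrix(x, ncol = 1)
  .check_finite(t, "t"); .check_finite(xm, "x")
  t_out <- seq(t[1], t[length(t)], by = 1 / fs_out)
  out <- matrix(0, length(t_out), ncol(xm))
  for (j in seq_len(ncol(xm)))
    out[, j] <- stats::approx(t, xm[, j], xout = t_out)$y
  list(t = t_out, x = if (mat) out else out[, 1])
}

#' Preprocess an IMU recording for estimation
#'
#' Applies the standard conditioning used by the pipeline: all three channels
#' zero-phase low-pass filtered at \code{fc} (15 Hz by default).
#'
#' @param imu An \code{\link{imu_recording}}.
#' @param fc Low-pass cutoff for all channels, Hz.
#' @return A filtered \code{imu_recording}.
#' @export
preprocess_recording <- function(imu, fc = 15) {
  stopifnot(inherits(imu, "imu_recording"))
  imu_recording(imu$t,
                lowpass_zero_phase(imu$gyro, fc, imu$fs),
                lowpass_zero_phase(imu$accel, fc, imu$fs),
                lowpass_zero_phase(imu$mag, fc, imu$fs),
                fs = imu$fs)
}
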