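# Columnar time-series I/O.
#
# The on-disk dialect is a plain CSV with a header naming the columns
# time, gyro_x, gyro_y, gyro_z, accel_x, accel_y, accel_z, mag_x, mag_y,
# mag_z (SI units); angle traces use time, fe, aa, ier, side.

.imu_cols <- c("time",
               "gyro_x", "gyro_y", "gyro_z",
               "accel_x", "accel_y", "accel_z",
               "mag_x", "mag_y", "mag_z")

#' Write an IMU recording to CSV
#'
#' @param imu An \code{\link{imu_recording}}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_imu_csv <- function(imu, path) {
  stopifnot(inherits(imu, "imu_recording"))
  df <- data.frame(imu$t, imu$gyro, imu$accel, imu$mag)
  names(df) <- .imu_cols
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read an IMU recording from CSV
#'
#' @param path File written by \code{\link{write_imu_csv}} (or any CSV with
#'   the same header).
#' @param fs Sampling rate; inferred from the time stamps when omitted.
#' @return An \code{\link{imu_recording}}.
#' @export
read_imu_csv <- function(path, fs = NULL) {
  df <- utils::read.csv(path)
  missing <- setdiff(.imu_cols, names(df))
  if (length(missing))
    stop("missing columns: ", paste(missing, collapse = ", "), call. = FALSE)
  imu_recording(df$time,
                as.matrix(df[, c("gyro_x", "gyro_y", "gyro_z")]),
                as.matrix(df[, c("accel_x", "accel_y", "accel_z")]),
                as.matrix(df[, c("mag_x", "mag_y", "mag_z")]),
                fs = fs)
}

#' Write an angle trace to CSV
#'
#' @param trace An \code{angle_trace} data frame
#'   (\code{\link{compute_hip_angles}}).
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_angle_csv <- function(trace, path) {
  df <- data.frame(time = trace$t, fe = trace$fe, aa = trace$aa,
                   ier = trace$ier, side = trace$side)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read an angle trace from CSV
#'
#' @param path File written by \code{\link{write_angle_csv}}.
#' @return An \code{angle_trace} data frame.
#' @export
read_angle_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("time", "fe", "aa", "ier")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("missing columns: ", paste(missing, collapse = ", "), call. = FALSE)
  structure(data.frame(t = df$time, fe = df$fe, aa = df$aa, ier = df$ier,
                       side = if ("side" %in% names(df)) df$side else NA),
            class = c("angle_trace", "data.frame"))
}
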