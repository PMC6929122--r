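# Sensor-to-segment anatomical calibration.
#
# Builds constant anatomical frames for the pelvis and thigh(s), expressed
# in the respective sensor frames, from functionally estimated joint-center
# locations and a static standing trial.  Axis direction conventions follow
# the International Society of Biomechanics: pelvis Z points right (along
# the inter-hip-center line), thigh y points proximally (knee to hip), and
# the floating axis is e2 = e3 x e1 per side.

#' Find the most still window of a recording
#'
#' Scans every window of the requested length and returns the one minimizing
#' the summed variance of the gyroscope and accelerometer norm signals
#' (first window on ties).
#'
#' @param imu An \code{\link{imu_recording}}.
#' @param window Window length in seconds (default 1).
#' @return Integer vector \code{c(first, last)} sample indices.
#' @export
find_still_period <- function(imu, window = 1) {
  stopifnot(inherits(imu, "imu_recording"))
  w <- round(window * imu$fs)
  if (w < 2) w <- 2L
  if (imu$n < w)
    stop("insufficient data: recording shorter than the still window",
         call. = FALSE)
  score_sig <- cbind(sqrt(rowSums(imu$gyro^2)), sqrt(rowSums(imu$accel^2)))
  # rolling variance via cumulative sums: var = E[x^2] - E[x]^2 (biased form,
  # monotone-equivalent to the unbiased one for fixed window length)
  roll_var <- function(x) {
    cs <- cumsum(c(0, x)); cs2 <- cumsum(c(0, x^2))
    m <- (cs[(w + 1):(imu$n + 1)] - cs[1:(imu$n - w + 1)]) / w
    (cs2[(w + 1):(imu$n + 1)] - cs2[1:(imu$n - w + 1)]) / w - m^2
  }
  tot <- roll_var(score_sig[, 1]) + roll_var(score_sig[, 2])
  start <- which.min(pmax(tot, 0))
  c(start, start + w - 1L)
}

#' Pelvis fixed axis from the two hip-center locations
#'
#' The unit vector from the left to the right hip joint center, expressed in
#' the pelvis-sensor frame; serves as e1 (the ISB pelvis Z axis, pointing
#' right).
#'
#' @param hip_left,hip_right Hip joint-center positions relative to the
#'   pelvis sensor origin, pelvis-sensor frame, m.  (If \code{r1} is the
#'   estimated joint-center-to-sensor offset, the center position is
#'   \code{-r1}.)
#' @return Unit 3-vector.
#' @export
pelvis_fixed_axis <- function(hip_left, hip_right) {
  .check_finite(hip_left, "hip_left"); .check_finite(hip_right, "hip_right")
  d <- hip_right - hip_left
  n <- sqrt(sum(d^2))
  if (n < 1e-6)
    stop("degenerate geometry: hip centers coincide", call. = FALSE)
  d / n
}

#' Thigh fixed axis from the hip and knee center locations
#'
#' The unit vector from the knee center to the hip center, expressed in the
#' thigh-sensor frame; serves as e3 (the ISB thigh y axis, pointing
#' proximally).
#'
#' @param hip,knee Joint-center positions relative to the thigh sensor
#'   origin, thigh-sensor frame, m.
#' @return Unit 3-vector.
#' @export
thigh_fixed_axis <- function(hip, knee) {
  .check_finite(hip, "hip"); .check_finite(knee, "knee")
  d <- hip - knee
  n <- sqrt(sum(d^2))
  if (n < 1e-6)
    stop("degenerate geometry: hip and knee centers coincide", call. = FALSE)
  d / n
}

.orthonormalize_axis <- function(v, ref) {
  v <- v - sum(v * ref) * ref
  n <- sqrt(sum(v^2))
  if (n < 1e-9) stop("degenerate pose: axes are parallel", call. = FALSE)
  v / n
}

#' Build constant anatomical frames for the pelvis and thigh(s)
#'
#' Implements the joint-coordinate-system construction evaluated during the
#' still period of a static standing trial:
#' \enumerate{
#'   \item rotate each thigh fixed axis (e3) into the pelvis-sensor frame
#'     using the still-pose relative orientation;
#'   \item per side, the floating axis e2 = e3 x e1;
#'   \item pelvis frame: Z = e1, X = normalized mean of the left/right e2,
#'     Y = Z x X (re-orthogonalized);
#'   \item thigh frame (per side): y = e3, x = that side's e2 rotated back
#'     into the thigh-sensor frame, z = x x y (re-orthogonalized).
#' }
#' With a single instrumented side, the pelvis X axis uses that side's e2
#' alone (unilateral variant).
#'
#' @param pelvis_axis Unit e1 in the pelvis-sensor frame
#'   (\code{\link{pelvis_fixed_axis}}).
#' @param thigh_axis_left,thigh_axis_right Unit e3 per side in the
#'   respective thigh-sensor frames; either may be \code{NULL} (at least one
#'   required).
#' @param q21_left,q21_right Still-pose quaternions rotating the respective
#'   thigh-sensor frame into the pelvis-sensor frame (e.g. the mean SSRO
#'   output over the still window).
#' @param still_window Optional \code{c(first, last)} sample range retained
#'   for audit.
#' @return An object of class \code{anatomical_calibration}: list with
#'   \code{pelvis_frame} (columns X, Y, Z in the pelvis-sensor frame),
#'   \code{thigh_frame_left}/\code{thigh_frame_right} (columns x, y, z in
#'   the thigh-sensor frames), the construction vectors in
#'   \code{fixed_axes}, and \code{still_window}.
#' @export
build_anatomical_frames <- function(pelvis_axis,
                                    thigh_axis_left = NULL,
                                    thigh_axis_right = NULL,
                                    q21_left = NULL, q21_right = NULL,
                                    still_window = NULL) {
  if (is.null(thigh_axis_left) && is.null(thigh_axis_right))
    stop("at least one thigh axis is required", call. = FALSE)
  e1 <- pelvis_axis / sqrt(sum(pelvis_axis^2))
  side_e2 <- list()
  for (side in c("left", "right")) {
    ax <- if (side == "left") thigh_axis_left else thigh_axis_right
    qq <- if (side == "left") q21_left else q21_right
    if (is.null(ax)) next
    if (is.null(qq))
      stop(sprintf("missing still-pose orientation for the %s side", side),
           call. = FALSE)
    e3_p <- quat_rotate(qq, ax / sqrt(sum(ax^2)))   # thigh axis, pelvis frame
    if (abs(sum(e3_p * e1)) > 1 - 1e-9)
      stop("degenerate pose: thigh axis parallel to pelvis axis",
           call. = FALSE)
    e2 <- cross3(e3_p, e1)
    side_e2[[side]] <- e2 / sqrt(sum(e2^2))
  }
  X <- Reduce(`+`, side_e2) / length(side_e2)
  X <- X / sqrt(sum(X^2))
  Z <- e1
  X <- .orthonormalize_axis(X, Z)
  Y <- cross3(Z, X)
  pelvis_frame <- cbind(X = X, Y = Y, Z = Z)
  if (det(pelvis_frame) < 0)
    stop("left/right labeling error: pelvis frame is left-handed",
         call. = FALSE)
  thigh_frames <- list(left = NULL, right = NULL)
  for (side in names(side_e2)) {
    ax <- if (side == "left") thigh_axis_left else thigh_axis_right
    qq <- if (side == "left") q21_left else q21_right
    y <- ax / sqrt(sum(ax^2))
    x <- quat_rotate(quat_conjugate(qq), side_e2[[side]])  # back to thigh frame
    x <- .orthonormalize_axis(x, y)
    z <- cross3(x, y)
    fr <- cbind(x = x, y = y, z = z)
    if (det(fr) < 0)
      stop(sprintf("left/right labeling error: %s thigh frame is left-handed",
                   side), call. = FALSE)
    thigh_frames[[side]] <- fr
  }
  structure(list(pelvis_frame = pelvis_frame,
                 thigh_frame_left = thigh_frames$left,
                 thigh_frame_right = thigh_frames$right,
                 fixed_axes = list(e1 = e1, e2 = side_e2,
                                   e3_left = thigh_axis_left,
                                   e3_right = thigh_axis_right),
                 still_window = still_window),
            class = "anatomical_calibration")
}

#' @export
print.anatomical_calibration <- function(x, ...) {
  sides <- c(if (!is.null(x$thigh_frame_left)) "left",
             if (!is.null(x$thigh_frame_right)) "right")
  cat(sprintf("<anatomical_calibration> sides: %s\n",
              paste(sides, collapse = ", ")))
  invisible(x)
}

#' Save an anatomical calibration to a YAML file
#'
#' Persists the frames, construction axes and still window in a documented
#' key-value schema so that angle computation can be re-run on later trials
#' without repeating calibration.
#'
#' @param calib An \code{anatomical_calibration}.
#' @param path Output file path (YAML).
#' @return \code{path}, invisibly.
#' @export
save_calibration <- function(calib, path) {
  stopifnot(inherits(calib, "anatomical_calibration"))
  ser_mat <- function(m) if (is.null(m)) NULL else apply(m, 2, as.numeric,
                                                         simplify = FALSE)
  out <- list(
    schema = "hipkin-calibration-v1",
    pelvis_frame = ser_mat(calib$pelvis_frame),
    thigh_frame_left = ser_mat(calib$thigh_frame_left),
    thigh_frame_right = ser_mat(calib$thigh_frame_right),
    fixed_axes = list(
      e1 = as.numeric(calib$fixed_axes$e1),
      e2 = lapply(calib$fixed_axes$e2, as.numeric),
      e3_left = if (is.null(calib$fixed_axes$e3_left)) NULL
                else as.numeric(calib$fixed_axes$e3_left),
      e3_right = if (is.null(calib$fixed_axes$e3_right)) NULL
                 else as.numeric(calib$fixed_axes$e3_right)
    ),
    still_window = if (is.null(calib$still_window)) NULL
                   else as.integer(calib$still_window)
  )
  yaml::write_yaml(out, path, precision = 17)
  invisible(path)
}

#' Load an anatomical calibration from a YAML file
#'
#' @param path File written by \code{\link{save_calibration}}.
#' @return An \code{anatomical_calibration}.
#' @export
load_calibration <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!identical(raw$schema, "hipkin-calibration-v1"))
    stop("not a hipkin calibration file", call. = FALSE)
  de_mat <- function(l, cols) {
    if (is.null(l)) return(NULL)
    m <- do.call(cbind, lapply(l, as.numeric))
    colnames(m) <- cols
    m
  }
  structure(list(
    pelvis_frame = de_mat(raw$pelvis_frame, c("X", "Y", "Z")),
    thigh_frame_left = de_mat(raw$thigh_frame_left, c("x", "y", "z")),
    thigh_frame_right = de_mat(raw$thigh_frame_right, c("x", "y", "z")),
    fixed_axes = list(
      e1 = as.numeric(raw$fixed_axes$e1),
      e2 = lapply(raw$fixed_axes$e2, as.numeric),
      e3_left = if (is.null(raw$fixed_axes$e3_left)) NULL
                else as.numeric(raw$fixed_axes$e3_left),
      e3_right = if (is.null(raw$fixed_axes$e3_right)) NULL
                 else as.numeric(raw$fixed_axes$e3_right)
    ),
    still_window = if (is.null(raw$still_window)) NULL
                   else as.integer(raw$still_window)
  ), class = "anatomical_calibration")
}
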