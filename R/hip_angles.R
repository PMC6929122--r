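# Hip joint angles in the ISB joint coordinate system, and the end-to-end
# pipeline: relative orientation -> joint centers -> anatomical frames ->
# angle traces.
#
# Angle conventions (both sides): flexion positive, extension negative;
# adduction/abduction with the side-dependent sign of the ISB convention;
# internal rotation positive.

.clamp1 <- function(x) pmax(-1, pmin(1, x))

#' Hip angles from pelvis and thigh axis triads at one time point
#'
#' Evaluates the joint-coordinate-system angle equations: e1 is the pelvis
#' Z axis, e3 the thigh y axis, and e2 = e3 x e1 the floating axis.
#' Flexion-extension is the signed angle from the pelvis X axis to e2 about
#' Z; internal-external rotation the signed angle from the thigh x axis to
#' e2 about y (side-dependent sign); ad/abduction derives from the angle
#' between e1 and e3 with the side's offset and sign.
#'
#' @param pelvis_axes 3x3 matrix, columns X, Y, Z (orthonormal), in any
#'   common frame.
#' @param thigh_axes 3x3 matrix, columns x, y, z, same frame.
#' @param side \code{"left"} or \code{"right"}.
#' @return Named numeric vector \code{c(fe, aa, ier)} in degrees.
#' @export
hip_angles_at_sample <- function(pelvis_axes, thigh_axes,
                                 side = c("right", "left")) {
  side <- match.arg(side)
  X <- pelvis_axes[, 1]; Z <- pelvis_axes[, 3]
  x <- thigh_axes[, 1]; y <- thigh_axes[, 2]
  e1 <- Z; e3 <- y
  d13 <- sum(e1 * e3)
  if (abs(d13) > 1 - 1e-9)
    stop("singular pose: thigh long axis parallel to pelvis Z axis",
         call. = FALSE)
  e2 <- cross3(e3, e1)
  cxe <- cross3(X, e2)
  eta_a <- sign(sum(cxe * Z))
  fe <- atan2(eta_a * sqrt(sum(cxe^2)), sum(X * e2))
  cxx <- cross3(x, e2)
  eta_g <- if (side == "right") sign(sum(cxx * (-y))) else sign(sum(cxx * y))
  ier <- atan2(eta_g * sqrt(sum(cxx^2)), sum(x * e2))
  aa <- if (side == "right") -pi / 2 + acos(.clamp1(d13))
        else pi / 2 - acos(.clamp1(d13))
  c(fe = fe, aa = aa, ier = ier) * 180 / pi
}

# Elementary rotation quaternion traces about the coordinate axes
# (angles in radians, vectorized).
.qx_rows <- function(a) cbind(cos(a / 2), sin(a / 2), 0, 0)
.qy_rows <- function(a) cbind(cos(a / 2), 0, sin(a / 2), 0)
.qz_rows <- function(a) cbind(cos(a / 2), 0, 0, sin(a / 2))

# Quaternion trace of the thigh-relative-to-pelvis anatomical rotation
# realizing prescribed joint angles (degrees, vectorized).
.jcs_quat_rows <- function(fe, aa, ier, side) {
  d2r <- pi / 180
  b <- if (side == "right") -aa else aa
  g <- if (side == "right") ier else -ier
  quat_multiply_rows(
    quat_multiply_rows(.qz_rows(fe * d2r), .qx_rows(b * d2r)),
    .qy_rows(g * d2r))
}

#' Thigh-relative-to-pelvis rotation realizing given hip angles
#'
#' Forward construction of the joint coordinate system: returns the rotation
#' matrix whose columns are the thigh anatomical axes expressed in the
#' pelvis anatomical frame, such that \code{\link{hip_angles_at_sample}}
#' recovers \code{(fe, aa, ier)} exactly (away from the \code{|aa| = 90}
#' singularity).
#'
#' @param fe,aa,ier Hip angles in degrees.
#' @param side \code{"left"} or \code{"right"}.
#' @return 3x3 rotation matrix.
#' @export
jcs_rotation <- function(fe, aa, ier, side = c("right", "left")) {
  side <- match.arg(side)
  q <- .jcs_quat_rows(fe, aa, ier, side)
  quat_to_matrix(q[1, ])
}

#' Hip angle trace from a calibration and an SSRO quaternion trace
#'
#' Rotates the constant thigh anatomical frame into the pelvis-sensor frame
#' at every sample using the sensor-to-sensor orientation, then evaluates
#' the joint-coordinate-system angles against the constant pelvis frame.
#'
#' @param calib An \code{anatomical_calibration}
#'   (\code{\link{build_anatomical_frames}}).
#' @param q21_trace N x 4 quaternion trace rotating thigh-sensor vectors
#'   into the pelvis-sensor frame (from \code{\link{run_ssro}}).
#' @param side \code{"left"} or \code{"right"}.
#' @param t Optional time stamps (defaults to sample index at \code{fs}).
#' @param fs Sampling rate, Hz (for the default time base).
#' @return A data frame of class \code{angle_trace} with columns \code{t},
#'   \code{fe}, \code{aa}, \code{ier}, \code{side}.
#' @export
compute_hip_angles <- function(calib, q21_trace, side = c("right", "left"),
                               t = NULL, fs = NULL) {
  side <- match.arg(side)
  stopifnot(inherits(calib, "anatomical_calibration"))
  thigh_frame <- if (side == "right") calib$thigh_frame_right
                 else calib$thigh_frame_left
  if (is.null(thigh_frame))
    stop(sprintf("calibration has no %s thigh frame", side), call. = FALSE)
  n <- nrow(q21_trace)
  if (is.null(t)) {
    if (is.null(fs)) fs <- 1
    t <- (seq_len(n) - 1) / fs
  }
  out <- matrix(0, n, 3)
  for (k in seq_len(n)) {
    R21 <- quat_to_matrix(q21_trace[k, ])
    ang <- tryCatch(
      hip_angles_at_sample(calib$pelvis_frame, R21 %*% thigh_frame, side),
      error = function(e)
        stop(sprintf("%s (sample %d)", conditionMessage(e), k),
             call. = FALSE))
    out[k, ] <- ang
  }
  structure(data.frame(t = t, fe = out[, 1], aa = out[, 2], ier = out[, 3],
                       side = side),
            class = c("angle_trace", "data.frame"), fs = fs)
}

.stage <- function(expr, stage) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[stage %s] %s", stage, conditionMessage(e)), call. = FALSE))
}

# Sign-aligned mean of a window of quaternion rows, renormalized.
.mean_quat <- function(Q) {
  ref <- Q[1, ]
  s <- sign(Q %*% ref)
  s[s == 0] <- 1
  q <- colMeans(Q * drop(s))
  quat_canonical(q / sqrt(sum(q^2)))
}

#' Run the full hip-angle pipeline on a simulated or recorded protocol
#'
#' Orchestrates the complete method: SSRO on every sensor pair, functional
#' hip joint centers from the dynamic calibration trial, knee centers with
#' hinge-axis correction when shank recordings are present, anatomical
#' frames from the most still period of the static trial, and finally hip
#' angle traces on the activity trial.  Deterministic given its inputs.
#'
#' Each trial is a named list of \code{\link{imu_recording}}s with elements
#' \code{pelvis}, \code{thigh_left}, \code{thigh_right}, and (dynamic trial
#' only, for knee-center estimation) \code{shank_left}, \code{shank_right}.
#'
#' @param static_trial Static standing trial (pelvis + thighs).
#' @param dynamic_trial Calibration trial exercising the hip in 3D
#'   (pelvis + thighs + shanks).
#' @param activity_trial Trial on which angles are computed.
#' @param params A \code{\link{kf_params}} object.
#' @param n_min Minimum high-motion observations for joint-center
#'   estimation.
#' @param still_window Still-window length in the static trial, s.
#' @param preprocess_fc Low-pass cutoff applied to all channels, Hz
#'   (\code{NULL} to skip).
#' @return List with \code{angles} (named list of \code{angle_trace}s per
#'   side), \code{calibration}, and \code{joint_centers} (per-side hip and
#'   knee results).
#' @export
run_pipeline <- function(static_trial, dynamic_trial, activity_trial,
                         params = kf_params(), n_min = 1500,
                         still_window = 1, preprocess_fc = 15) {
  sides <- c("left", "right")
  need <- c("pelvis", paste0("thigh_", sides))
  for (trial in list(static_trial, dynamic_trial, activity_trial))
    if (!all(need %in% names(trial)))
      stop("each trial needs pelvis, thigh_left and thigh_right recordings",
           call. = FALSE)
  prep <- function(trial) {
    if (is.null(preprocess_fc)) return(trial)
    lapply(trial, preprocess_recording, fc = preprocess_fc)
  }
  static_trial <- .stage(prep(static_trial), "preprocess/static")
  dynamic_trial <- .stage(prep(dynamic_trial), "preprocess/dynamic")
  activity_trial <- .stage(prep(activity_trial), "preprocess/activity")

  jc <- list(); hip_pelvis <- list(); thigh_axes <- list()
  for (side in sides) {
    thigh <- dynamic_trial[[paste0("thigh_", side)]]
    sso <- .stage(run_ssro(dynamic_trial$pelvis, thigh, params),
                  paste0("ssro/dynamic/", side))
    Rtr <- ssro_matrices(sso$q21)
    hip <- .stage(
      estimate_joint_center(dynamic_trial$pelvis, thigh, Rtr, n_min = n_min),
      paste0("joint_center/hip/", side))
    hip_pelvis[[side]] <- -hip$r1
    hip_thigh <- -hip$r2
    knee <- NULL
    shank <- dynamic_trial[[paste0("shank_", side)]]
    if (!is.null(shank)) {
      sso_k <- .stage(run_ssro(thigh, shank, params),
                      paste0("ssro/knee/", side))
      knee_raw <- .stage(
        estimate_joint_center(thigh, shank, ssro_matrices(sso_k$q21),
                              n_min = n_min),
        paste0("joint_center/knee/", side))
      axes <- .stage(estimate_hinge_axes(thigh$gyro, shank$gyro),
                     paste0("hinge_axes/", side))
      corr <- correct_hinge_center(knee_raw$r1, knee_raw$r2, axes)
      knee <- list(raw = knee_raw, axes = axes, r1 = corr$r1, r2 = corr$r2)
      knee_thigh <- -corr$r1
    } else {
      stop(sprintf(paste0("dynamic trial lacks a %s shank recording needed ",
                          "for knee-center (thigh axis) estimation"), side),
           call. = FALSE)
    }
    thigh_axes[[side]] <- .stage(thigh_fixed_axis(hip_thigh, knee_thigh),
                                 paste0("thigh_axis/", side))
    jc[[side]] <- list(hip = hip, knee = knee)
  }
  pelvis_axis <- .stage(pelvis_fixed_axis(hip_pelvis$left, hip_pelvis$right),
                        "pelvis_axis")

  win <- .stage(find_still_period(static_trial$pelvis, still_window),
                "still_period")
  q_still <- list()
  for (side in sides) {
    sso_s <- .stage(run_ssro(static_trial$pelvis,
                             static_trial[[paste0("thigh_", side)]], params),
                    paste0("ssro/static/", side))
    q_still[[side]] <- .mean_quat(sso_s$q21[win[1]:win[2], , drop = FALSE])
  }
  calib <- .stage(
    build_anatomical_frames(pelvis_axis,
                            thigh_axis_left = thigh_axes$left,
                            thigh_axis_right = thigh_axes$right,
                            q21_left = q_still$left,
                            q21_right = q_still$right,
                            still_window = win),
    "anatomical_frames")

  angles <- list()
  for (side in sides) {
    sso_a <- .stage(run_ssro(activity_trial$pelvis,
                             activity_trial[[paste0("thigh_", side)]],
                             params),
                    paste0("ssro/activity/", side))
    angles[[side]] <- .stage(
      compute_hip_angles(calib, sso_a$q21, side,
                         t = activity_trial$pelvis$t,
                         fs = activity_trial$pelvis$fs),
      paste0("angles/", side))
  }
  list(angles = angles, calibration = calib, joint_centers = jc)
}
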