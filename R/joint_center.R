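# Functional joint-center estimation from rigid-body kinematic constraints.
#
# Two sensors on segments linked by a ball joint must compute the same
# joint-center acceleration up to the relative rotation of their frames:
#   a1 - (w1x w1x + w1dot x) r1 = R21 (a2 - (w2x w2x + w2dot x) r2)
# Stacking this over many high-angular-velocity samples yields an
# over-determined linear system in the fixed offsets r1, r2 (the vectors
# from the joint center to each sensor origin, each in its own sensor
# frame).  Gravity cancels from the constraint because it enters both
# accelerometers as the same world-frame vector.

#' Select the highest-angular-velocity samples for joint-center estimation
#'
#' Ranks samples by the sum of the two sensors' instantaneous angular
#' velocity norms and returns at least \code{n_min} indices (ties broken by
#' earlier index), sorted ascending in time.
#'
#' @param w1,w2 N x 3 angular velocities, rad/s.
#' @param n_min Minimum number of observations (default 1500).
#' @return Integer vector of sample indices, ascending.
#' @export
select_high_motion_samples <- function(w1, w2, n_min = 1500) {
  w1 <- as.matrix(w1); w2 <- as.matrix(w2)
  n <- nrow(w1)
  if (nrow(w2) != n) stop("w1 and w2 must have equal length", call. = FALSE)
  if (n < n_min)
    stop(sprintf("insufficient data: %d samples available, %d required",
                 n, n_min), call. = FALSE)
  score <- sqrt(rowSums(w1^2)) + sqrt(rowSums(w2^2))
  sort(order(-score, seq_len(n))[seq_len(n_min)])
}

#' Estimate ball-joint center offsets from two sensors
#'
#' Solves the stacked least-squares system for \code{r1} and \code{r2}, the
#' vectors from the joint center to each sensor's origin expressed in the
#' respective sensor frames.  Angular accelerations are computed by central
#' differences and low-pass filtered at 12 Hz unless supplied.
#'
#' @param imu1,imu2 Synchronized \code{\link{imu_recording}}s.
#' @param R21_trace 3 x 3 x N array of frame-2-to-frame-1 rotation matrices
#'   aligned with the samples (typically from \code{\link{ssro_matrices}}).
#' @param indices Sample indices to use; default selects the
#'   \code{n_min} highest-motion samples.
#' @param n_min Minimum observations when \code{indices} is NULL.
#' @param wdot1,wdot2 Optional precomputed N x 3 angular accelerations.
#' @param cond_max Condition-number threshold above which the motion is
#'   declared degenerate (insufficient 3D rotation).
#' @return An object of class \code{joint_center_result}: list with
#'   \code{r1}, \code{r2} (m), \code{residual} (RMS, m/s^2), \code{n_obs},
#'   and \code{condition}.
#' @export
estimate_joint_center <- function(imu1, imu2, R21_trace, indices = NULL,
                                  n_min = 1500, wdot1 = NULL, wdot2 = NULL,
                                  cond_max = 1e8) {
  stopifnot(inherits(imu1, "imu_recording"), inherits(imu2, "imu_recording"))
  n <- imu1$n
  if (dim(R21_trace)[3] != n)
    stop("R21_trace must be aligned with the recordings", call. = FALSE)
  if (is.null(indices))
    indices <- select_high_motion_samples(imu1$gyro, imu2$gyro, n_min)
  dt <- 1 / imu1$fs
  if (is.null(wdot1)) wdot1 <- angular_acceleration(imu1$gyro, dt, fc = 12)
  if (is.null(wdot2)) wdot2 <- angular_acceleration(imu2$gyro, dt, fc = 12)
  m <- length(indices)
  A <- matrix(0, 3 * m, 6)
  b <- numeric(3 * m)
  for (i in seq_len(m)) {
    k <- indices[i]
    K1 <- skew(imu1$gyro[k, ]) %*% skew(imu1$gyro[k, ]) + skew(wdot1[k, ])
    K2 <- skew(imu2$gyro[k, ]) %*% skew(imu2$gyro[k, ]) + skew(wdot2[k, ])
    R <- R21_trace[, , k]
    rows <- (3 * i - 2):(3 * i)
    A[rows, 1:3] <- K1
    A[rows, 4:6] <- -R %*% K2
    b[rows] <- imu1$accel[k, ] - drop(R %*% imu2$accel[k, ])
  }
  sv <- svd(A, nu = 0, nv = 0)$d
  condition <- sv[1] / sv[length(sv)]
  if (!is.finite(condition) || condition > cond_max)
    stop(sprintf(paste0("degenerate motion: insufficient 3D rotation for ",
                        "joint-center estimation (condition number %.3g)"),
                 condition), call. = FALSE)
  x <- qr.solve(A, b)
  res <- sqrt(mean((A %*% x - b)^2))
  structure(list(r1 = x[1:3], r2 = x[4:6], residual = res,
                 n_obs = m, condition = condition),
            class = "joint_center_result")
}

#' @export
print.joint_center_result <- function(x, ...) {
  cat(sprintf("<joint_center_result> n_obs = %d, residual = %.4g m/s^2\n",
              x$n_obs, x$residual))
  cat(sprintf("  r1 = (%.4f, %.4f, %.4f) m\n", x$r1[1], x$r1[2], x$r1[3]))
  cat(sprintf("  r2 = (%.4f, %.4f, %.4f) m\n", x$r2[1], x$r2[2], x$r2[3]))
  invisible(x)
}

.sph_to_unit <- function(theta, phi)
  c(sin(theta) * cos(phi), sin(theta) * sin(phi), cos(theta))

.unit_to_sph <- function(v) {
  v <- v / sqrt(sum(v^2))
  c(acos(max(-1, min(1, v[3]))), atan2(v[2], v[1]))
}

#' Estimate the hinge (functional flexion) axis in both sensor frames
#'
#' For a predominantly single-axis joint such as the knee, the angular
#' velocity components perpendicular to the hinge axis must agree between
#' the two sensors: \code{||w1 x j1|| = ||w2 x j2||} at every sample.  The
#' unit axes are found by minimizing the summed squared mismatch, each axis
#' parameterized by spherical angles (guaranteeing unit norm), with a
#' quasi-Newton local optimizer started from a deterministic set of initial
#' axes (the eight diagonal directions plus the dominant angular-velocity
#' direction of each sensor).
#'
#' @param w1,w2 N x 3 angular velocities, rad/s.
#' @return An object of class \code{hinge_axes}: list with unit vectors
#'   \code{j1}, \code{j2}, the final \code{cost}, and \code{convergence}.
#'   Axis signs are chosen so the two projected angular velocities
#'   correlate positively; the overall pair sign remains arbitrary.
#' @export
estimate_hinge_axes <- function(w1, w2) {
  w1 <- as.matrix(w1); w2 <- as.matrix(w2)
  n1sq <- rowSums(w1^2); n2sq <- rowSums(w2^2)
  cost <- function(p) {
    j1 <- .sph_to_unit(p[1], p[2]); j2 <- .sph_to_unit(p[3], p[4])
    c1 <- sqrt(pmax(0, n1sq - drop(w1 %*% j1)^2))
    c2 <- sqrt(pmax(0, n2sq - drop(w2 %*% j2)^2))
    sum((c1 - c2)^2)
  }
  diag_dirs <- as.matrix(expand.grid(x = c(-1, 1), y = c(-1, 1), z = 1))
  diag_dirs <- diag_dirs / sqrt(3)
  pca_dir <- function(w) {
    e <- eigen(crossprod(w), symmetric = TRUE)
    e$vectors[, 1]
  }
  starts <- lapply(seq_len(nrow(diag_dirs)), function(i) {
    s <- .unit_to_sph(diag_dirs[i, ])
    c(s, s)
  })
  starts <- c(starts,
              list(c(.unit_to_sph(pca_dir(w1)), .unit_to_sph(pca_dir(w2)))),
              list(c(.unit_to_sph(c(1, 0, 0)), .unit_to_sph(c(1, 0, 0)))),
              list(c(.unit_to_sph(c(0, 1, 0)), .unit_to_sph(c(0, 1, 0)))),
              list(c(.unit_to_sph(c(0, 0, 1)), .unit_to_sph(c(0, 0, 1)))))
  best <- NULL
  any_conv <- FALSE
  for (p0 in starts) {
    fit <- stats::optim(p0, cost, method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-14))
    if (fit$convergence == 0) any_conv <- TRUE
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (!any_conv)
    stop(sprintf("hinge-axis optimization failed to converge (final cost %.3g)",
                 best$value), call. = FALSE)
  j1 <- .sph_to_unit(best$par[1], best$par[2])
  j2 <- .sph_to_unit(best$par[3], best$par[4])
  p1 <- drop(w1 %*% j1); p2 <- drop(w2 %*% j2)
  if (sum(p1 * p2) < 0) j2 <- -j2
  structure(list(j1 = j1, j2 = j2, cost = best$value,
                 convergence = any_conv),
            class = "hinge_axes")
}

#' @export
print.hinge_axes <- function(x, ...) {
  cat(sprintf("<hinge_axes> cost = %.4g\n", x$cost))
  cat(sprintf("  j1 = (%.4f, %.4f, %.4f)\n", x$j1[1], x$j1[2], x$j1[3]))
  cat(sprintf("  j2 = (%.4f, %.4f, %.4f)\n", x$j2[1], x$j2[2], x$j2[3]))
  invisible(x)
}

#' Correct a hinge-joint center estimate along the rotation axis
#'
#' Pure hinge motion leaves the joint-center component along the hinge axis
#' unobservable; this correction removes the mean axial component, shifting
#' the estimated center to the perpendicular foot point near the sensors.
#' The corrected offsets satisfy \code{r1.j1 + r2.j2 = 0}.
#'
#' @param r_hat1,r_hat2 Initial joint-center-to-sensor offsets, m.
#' @param axes A \code{\link{estimate_hinge_axes}} result (or any list with
#'   unit vectors \code{j1}, \code{j2}).
#' @return List with corrected \code{r1} and \code{r2}.
#' @export
correct_hinge_center <- function(r_hat1, r_hat2, axes) {
  j1 <- axes$j1; j2 <- axes$j2
  s <- (sum(r_hat1 * j1) + sum(r_hat2 * j2)) / 2
  list(r1 = r_hat1 - j1 * s, r2 = r_hat2 - j2 * s)
}
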