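# Rigid-body IMU simulator.
#
# Forward-generates exactly the data structure the estimation pipeline
# assumes: two (or more) rigid segments joined at ball or hinge joints,
# sensors rigidly mounted at fixed offsets with arbitrary mounting
# rotations, gravity, a shared homogeneous magnetic field, and additive
# white sensor noise.  Angular velocities and sensor accelerations are
# derived from the prescribed orientation and position profiles by
# high-order Richardson-stencil differentiation with a step far below the
# sample interval, so the pre-noise channels satisfy the rigid-body
# joint-constraint identity to well below measurement scale and the ground
# truth carries no sample-rate discretization error.

# 5-point first derivative of a vectorized matrix-valued function of time.
.d1 <- function(f, tv, h = 1e-4) {
  (-f(tv + 2 * h) + 8 * f(tv + h) - 8 * f(tv - h) + f(tv - 2 * h)) / (12 * h)
}

# 5-point second derivative.
.d2 <- function(f, tv, h = 1e-4) {
  (-f(tv + 2 * h) + 16 * f(tv + h) - 30 * f(tv) + 16 * f(tv - h) -
     f(tv - 2 * h)) / (12 * h^2)
}

.const_rows <- function(v, n) matrix(v, n, 3, byrow = TRUE)

# Body angular velocity (rad/s) of an orientation trace given its
# quaternion-valued function of time (sign-continuous).
.gyro_fun <- function(qfun) {
  function(tv) {
    Q <- qfun(tv)
    Qd <- .d1(qfun, tv)
    2 * quat_multiply_rows(quat_conjugate_rows(Q), Qd)[, 2:4, drop = FALSE]
  }
}

# Pre-noise sensor channels from the sensor's world orientation (quaternion
# function) and world position (function), plus the shared world field.
.sensor_channels <- function(qfun, posfun, tv, mag_world, G) {
  Q <- qfun(tv)
  Qc <- quat_conjugate_rows(Q)
  n <- length(tv)
  gyro <- .gyro_fun(qfun)(tv)
  acc_w <- .d2(posfun, tv)                       # world acceleration
  spec_w <- sweep(acc_w, 2, c(0, 0, -G))         # specific force, world frame
  accel <- quat_rotate_rows(Qc, spec_w)
  mag <- quat_rotate_rows(Qc, .const_rows(mag_world, n))
  wdot <- .d1(.gyro_fun(qfun), tv, h = 1e-3)
  list(gyro = gyro, accel = accel, mag = mag, wdot = wdot)
}

.canonical_rows <- function(Q) {
  s <- sign(Q[, 1]); s[s == 0] <- 1
  Q * s
}

.rand_unit_quat <- function() {
  q <- stats::rnorm(4)
  quat_canonical(q / sqrt(sum(q^2)))
}

.check_noise <- function(noise) {
  noise <- noise[c("gyro", "accel", "mag")]
  if (anyNA(noise) || any(noise < 0))
    stop("invalid parameter: noise must be named non-negative sigmas for ",
         "gyro, accel and mag", call. = FALSE)
  noise
}

.add_noise <- function(ch, noise) {
  n <- nrow(ch$gyro)
  list(gyro = ch$gyro + matrix(stats::rnorm(3 * n, sd = noise["gyro"]), n, 3),
       accel = ch$accel + matrix(stats::rnorm(3 * n, sd = noise["accel"]), n, 3),
       mag = ch$mag + matrix(stats::rnorm(3 * n, sd = noise["mag"]), n, 3))
}

#' Sinusoidal motion profile
#'
#' Convenience constructor for the vectorized angle/position profile
#' functions the simulator consumes.
#'
#' @param amplitude Amplitude (degrees for angle profiles, m for positions).
#' @param freq Frequency, Hz.
#' @param phase Phase offset, radians.
#' @param offset Constant offset added to the sinusoid.
#' @return A vectorized function of time.
#' @export
profile_sinusoid <- function(amplitude, freq, phase = 0, offset = 0) {
  force(amplitude); force(freq); force(phase); force(offset)
  function(t) offset + amplitude * sin(2 * pi * freq * t + phase)
}

.zero_fun <- function(t) numeric(length(t))

#' Smooth onset ramp for motion profiles
#'
#' An infinitely differentiable ramp rising from 0 to 1 between \code{t0}
#' and \code{t1} (the standard bump-function smoothstep
#' \code{s(u) / (s(u) + s(1 - u))} with \code{s(x) = exp(-1/x)}).
#' Multiplying angle profiles by a ramp starts trials from rest; profiles
#' fed to the simulator must be smooth, since kinks in the angle
#' trajectories imply impulsive accelerations and even curvature jumps
#' leave visible residue in the stencil-differentiated ground truth.
#'
#' @param t0,t1 Ramp start and end times, s.
#' @return A vectorized function of time.
#' @export
smooth_ramp <- function(t0 = 1, t1 = 3) {
  force(t0); force(t1)
  s <- function(x) ifelse(x > 0, exp(-1 / pmax(x, 1e-12)), 0)
  function(t) {
    u <- pmin(1, pmax(0, (t - t0) / (t1 - t0)))
    s(u) / (s(u) + s(1 - u))
  }
}

# profile multiplied by a smooth onset ramp
.ramped <- function(f, t0 = 1, t1 = 3) {
  r <- smooth_ramp(t0, t1)
  function(t) r(t) * f(t)
}

#' Geometry of a two-segment sensor chain
#'
#' @param r1,r2 Joint-center-to-sensor-origin offsets, m, each expressed in
#'   its sensor's frame (the quantities the functional joint-center
#'   estimator recovers).
#' @param mount1,mount2 Unit quaternions rotating sensor-frame vectors into
#'   the respective segment frames (identity = sensor axes aligned with the
#'   segment).
#' @param hinge_axis Optional unit hinge axis in the segment frames, for
#'   1-DoF joints.
#' @return An object of class \code{chain_geometry}.
#' @export
chain_geometry <- function(r1 = c(0.05, 0.25, 0.02),
                           r2 = c(-0.03, -0.20, 0.01),
                           mount1 = c(1, 0, 0, 0), mount2 = c(1, 0, 0, 0),
                           hinge_axis = NULL) {
  .check_finite(r1, "r1"); .check_finite(r2, "r2")
  structure(list(r1 = r1, r2 = r2,
                 mount1 = quat_normalize(mount1),
                 mount2 = quat_normalize(mount2),
                 hinge_axis = hinge_axis),
            class = "chain_geometry")
}

# Pelvis-style orientation profile (list of rx, ry, rz degree functions)
# to a sign-continuous quaternion trace function.
.orientation_fun <- function(profile) {
  if (is.null(profile)) return(function(tv) {
    n <- length(tv); cbind(rep(1, n), 0, 0, 0)
  })
  d2r <- pi / 180
  rx <- profile$rx %||% .zero_fun
  ry <- profile$ry %||% .zero_fun
  rz <- profile$rz %||% .zero_fun
  function(tv)
    quat_multiply_rows(
      quat_multiply_rows(.qz_rows(rz(tv) * d2r), .qx_rows(rx(tv) * d2r)),
      .qy_rows(ry(tv) * d2r))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Core two-segment simulation shared by the ball and hinge front ends.
# qjoint_fun maps time to the segment-2-in-segment-1 rotation quaternion.
.simulate_pair <- function(qjoint_fun, geometry, fs, duration, noise,
                           mag_field, seed, pelvis_profile, origin_fun, G) {
  noise <- .check_noise(noise)
  n <- round(duration * fs)
  if (n < 2) stop("duration * fs must be at least 2", call. = FALSE)
  tv <- (seq_len(n) - 1) / fs
  q1seg <- .orientation_fun(pelvis_profile)
  origin <- origin_fun %||% function(t) matrix(0, length(t), 3)
  m1 <- geometry$mount1; m2 <- geometry$mount2
  qs1 <- function(t) quat_multiply_rows(q1seg(t),
                                        .const_quat_rows(m1, length(t)))
  qs2 <- function(t) quat_multiply_rows(
    quat_multiply_rows(q1seg(t), qjoint_fun(t)),
    .const_quat_rows(m2, length(t)))
  pos1 <- function(t) origin(t) +
    quat_rotate_rows(qs1(t), .const_rows(geometry$r1, length(t)))
  pos2 <- function(t) origin(t) +
    quat_rotate_rows(qs2(t), .const_rows(geometry$r2, length(t)))
  ch1 <- .sensor_channels(qs1, pos1, tv, mag_field, G)
  ch2 <- .sensor_channels(qs2, pos2, tv, mag_field, G)
  if (!is.null(seed)) set.seed(seed)
  n1 <- .add_noise(ch1, noise); n2 <- .add_noise(ch2, noise)
  q21 <- .canonical_rows(
    quat_multiply_rows(quat_conjugate_rows(qs1(tv)), qs2(tv)))
  list(tv = tv, ch1 = ch1, ch2 = ch2, n1 = n1, n2 = n2, q21 = q21)
}

.const_quat_rows <- function(q, n) matrix(q, n, 4, byrow = TRUE)

#' Simulate two IMUs on segments linked by a ball joint
#'
#' The proximal segment follows an optional orientation profile; the distal
#' segment's orientation is prescribed by hip-style joint angle profiles
#' through the joint-coordinate-system forward construction.  Sensor
#' channels are angular velocity in each sensor frame, specific force
#' (joint-center acceleration plus centripetal/tangential terms plus
#' gravity, rotated into the sensor frame), and a shared homogeneous world
#' magnetic field rotated into each sensor frame, with optional additive
#' white noise.  Ground-truth channels are exact and pre-noise.
#'
#' @param profile List of vectorized degree-valued functions \code{fe},
#'   \code{aa}, \code{ier} of time (missing entries default to zero); see
#'   \code{\link{profile_sinusoid}}.
#' @param geometry A \code{\link{chain_geometry}}.
#' @param fs Sampling rate, Hz.
#' @param duration Trial length, s.
#' @param noise Named vector of noise standard deviations
#'   (\code{gyro} rad/s, \code{accel} m/s^2, \code{mag} field units).
#' @param mag_field World magnetic field vector (default: unit field with a
#'   60 degree downward inclination).
#' @param seed Integer seed making the noise reproducible (\code{NULL} for
#'   none).
#' @param side Which hip the profiles describe.
#' @param pelvis_profile Optional list of degree functions \code{rx},
#'   \code{ry}, \code{rz} for the proximal segment orientation.
#' @param origin_fun Optional vectorized function of time returning the
#'   N x 3 world trajectory of the joint center.
#' @param G Gravitational acceleration, m/s^2.
#' @return An object of class \code{simulation_output}: list with
#'   \code{imu1}, \code{imu2} (\code{\link{imu_recording}}s, noise applied),
#'   \code{truth} (pre-noise channels, exact \code{q21} trace, prescribed
#'   angles, angular accelerations, geometry), \code{seed}, \code{fs}.
#' @export
simulate_ball_joint <- function(profile = list(), geometry = chain_geometry(),
                                fs = 128, duration = 60,
                                noise = c(gyro = 0.005, accel = 0.08,
                                          mag = 0.01),
                                mag_field = c(0.5, 0, -sqrt(3) / 2),
                                seed = NULL, side = "right",
                                pelvis_profile = NULL, origin_fun = NULL,
                                G = 9.81) {
  fe <- profile$fe %||% .zero_fun
  aa <- profile$aa %||% .zero_fun
  ier <- profile$ier %||% .zero_fun
  qjoint <- function(t) .jcs_quat_rows(fe(t), aa(t), ier(t), side)
  sim <- .simulate_pair(qjoint, geometry, fs, duration, noise, mag_field,
                        seed, pelvis_profile, origin_fun, G)
  .package_sim(sim, fs, seed, geometry,
               angles = data.frame(t = sim$tv, fe = fe(sim$tv),
                                   aa = aa(sim$tv), ier = ier(sim$tv),
                                   side = side))
}

#' Simulate two IMUs on segments linked by a hinge joint
#'
#' As \code{\link{simulate_ball_joint}} but the relative rotation is about a
#' single fixed axis; the ground truth includes the hinge axis expressed in
#' each sensor's frame.
#'
#' @param angle_profile Vectorized degree-valued function of time.
#' @param axis Unit hinge axis in the segment frames (it is fixed in both).
#' @inheritParams simulate_ball_joint
#' @return A \code{simulation_output}; \code{truth$j1}, \code{truth$j2} hold
#'   the hinge axis in the two sensor frames.
#' @export
simulate_hinge_joint <- function(angle_profile, axis = c(0, 0, 1),
                                 geometry = chain_geometry(),
                                 fs = 128, duration = 30,
                                 noise = c(gyro = 0.005, accel = 0.08,
                                           mag = 0.01),
                                 mag_field = c(0.5, 0, -sqrt(3) / 2),
                                 seed = NULL, pelvis_profile = NULL,
                                 origin_fun = NULL, G = 9.81) {
  axis <- axis / sqrt(sum(axis^2))
  d2r <- pi / 180
  qjoint <- function(t) {
    a <- angle_profile(t) * d2r
    cbind(cos(a / 2), sin(a / 2) %o% axis)
  }
  sim <- .simulate_pair(qjoint, geometry, fs, duration, noise, mag_field,
                        seed, pelvis_profile, origin_fun, G)
  out <- .package_sim(sim, fs, seed, geometry,
                      angles = data.frame(t = sim$tv,
                                          angle = angle_profile(sim$tv)))
  out$truth$j1 <- quat_rotate(quat_conjugate(geometry$mount1), axis)
  out$truth$j2 <- quat_rotate(quat_conjugate(geometry$mount2), axis)
  out
}

.package_sim <- function(sim, fs, seed, geometry, angles) {
  structure(list(
    imu1 = imu_recording(sim$tv, sim$n1$gyro, sim$n1$accel, sim$n1$mag, fs),
    imu2 = imu_recording(sim$tv, sim$n2$gyro, sim$n2$accel, sim$n2$mag, fs),
    truth = list(q21 = sim$q21,
                 angles = angles,
                 gyro1 = sim$ch1$gyro, accel1 = sim$ch1$accel,
                 mag1 = sim$ch1$mag, wdot1 = sim$ch1$wdot,
                 gyro2 = sim$ch2$gyro, accel2 = sim$ch2$accel,
                 mag2 = sim$ch2$mag, wdot2 = sim$ch2$wdot,
                 geometry = geometry),
    seed = seed, fs = fs), class = "simulation_output")
}

#' @export
print.simulation_output <- function(x, ...) {
  cat(sprintf("<simulation_output> %d samples at %g Hz\n",
              x$imu1$n, x$fs))
  invisible(x)
}

# ---- full study-like protocol -------------------------------------------

# Body geometry of the simulated subject (segment-frame coordinates, m).
.protocol_geometry <- function() {
  list(
    hip_right = c(0, -0.09, 0.09),     # hip centers in the pelvis frame
    hip_left = c(0, -0.09, -0.09),
    pelvis_sensor = c(-0.10, 0.02, 0), # lumbar sensor, pelvis frame
    thigh_sensor = c(0.05, -0.20, 0.005), # from hip center, thigh frame
    knee = c(0, -0.40, 0),             # knee center from hip, thigh frame
    shank_sensor = c(0.04, -0.15, 0.005), # from knee center, shank frame
    knee_axis = c(0, 0, 1)             # knee flexion axis, thigh/shank frame
  )
}

#' Simulate a full calibration-plus-activity measurement protocol
#'
#' Produces the trial bundle the pipeline expects, from one simulated
#' subject: a 30 s static standing trial, a multi-plane star-like
#' calibration trial (~55 s, large slow 3D hip excursions with knee
#' flexion, so both the hip ball joints and the knee hinges are exercised),
#' and a 60 s periodic walking-like trial (flexion-dominant ~1 Hz
#' sinusoids with smaller ad/abduction and rotation components, pelvis
#' sway and vertical bob).  Five sensors are generated: pelvis, both
#' thighs and (for knee-center estimation) both shanks, each with an
#' independent random mounting rotation drawn from the seed, constant
#' across trials.
#'
#' @param seed Integer seed; mountings and noise derive from it.
#' @param fs Sampling rate, Hz.
#' @param noise Named noise sigmas as in \code{\link{simulate_ball_joint}};
#'   use zeros for noiseless data.
#' @param mag_field World magnetic field vector.
#' @param durations Named vector of trial lengths, s.
#' @param random_mounting If \code{FALSE}, all sensors are mounted aligned
#'   with their segments.
#' @param G Gravitational acceleration, m/s^2.
#' @return List with elements \code{static}, \code{star}, \code{walking}
#'   (each a named list of \code{\link{imu_recording}}s ready for
#'   \code{\link{run_pipeline}}) and \code{truth} (prescribed hip angle
#'   traces per side and trial, true sensor offsets \code{r1}/\code{r2} per
#'   joint, true hinge axes, the mounting quaternions, and the seed).
#' @export
simulate_protocol <- function(seed = 1, fs = 128,
                              noise = c(gyro = 0.005, accel = 0.08,
                                        mag = 0.01),
                              mag_field = c(0.5, 0, -sqrt(3) / 2),
                              durations = c(static = 30, star = 55,
                                            walking = 60),
                              random_mounting = TRUE, G = 9.81) {
  noise <- .check_noise(noise)
  geom <- .protocol_geometry()
  set.seed(seed)
  mounts <- if (random_mounting) {
    list(pelvis = .rand_unit_quat(),
         thigh_left = .rand_unit_quat(), thigh_right = .rand_unit_quat(),
         shank_left = .rand_unit_quat(), shank_right = .rand_unit_quat())
  } else {
    id <- c(1, 0, 0, 0)
    list(pelvis = id, thigh_left = id, thigh_right = id,
         shank_left = id, shank_right = id)
  }

  specs <- list(
    static = list(
      duration = durations[["static"]],
      pelvis = NULL, origin = NULL,
      hip = list(left = list(), right = list()),
      knee = list(left = .zero_fun, right = .zero_fun),
      shanks = FALSE),
    star = list(
      duration = durations[["star"]],
      pelvis = list(rx = .ramped(profile_sinusoid(18, 0.35, 0.4)),
                    ry = .ramped(profile_sinusoid(15, 0.28, 1.1)),
                    rz = .ramped(profile_sinusoid(15, 0.40, 2.0))),
      origin = function(t) {
        r <- smooth_ramp()(t)
        cbind(r * 0.02 * sin(2 * pi * 0.2 * t),
              r * 0.02 * sin(2 * pi * 0.26 * t + 1),
              r * 0.01 * sin(2 * pi * 0.34 * t))
      },
      hip = list(
        left = list(fe = .ramped(profile_sinusoid(40, 0.20, 0.3)),
                    aa = .ramped(profile_sinusoid(25, 0.34, 1.3)),
                    ier = .ramped(profile_sinusoid(20, 0.26, 2.1))),
        right = list(fe = .ramped(profile_sinusoid(40, 0.20, 3.4)),
                     aa = .ramped(profile_sinusoid(25, 0.34, 0.2)),
                     ier = .ramped(profile_sinusoid(20, 0.26, 1.0)))),
      knee = list(left = .ramped(profile_sinusoid(25, 0.42, 0.5, offset = 30)),
                  right = .ramped(profile_sinusoid(25, 0.42, 2.6, offset = 30))),
      shanks = TRUE),
    walking = list(
      duration = durations[["walking"]],
      pelvis = list(rx = .ramped(profile_sinusoid(2, 2.0, 0.0)),
                    ry = .ramped(profile_sinusoid(4, 1.0, 0.5)),
                    rz = .ramped(profile_sinusoid(3, 1.0, 1.5))),
      origin = function(t) {
        r <- smooth_ramp()(t)
        cbind(r * 0.01 * sin(2 * pi * 1 * t + 0.2),
              r * 0.02 * sin(2 * pi * 2 * t),
              r * 0.02 * sin(2 * pi * 1 * t))
      },
      hip = list(
        left = list(fe = .ramped(profile_sinusoid(30, 1.0, pi, offset = -5)),
                    aa = .ramped(profile_sinusoid(10, 1.0, pi + 0.7)),
                    ier = .ramped(profile_sinusoid(10, 1.0, pi + 1.9))),
        right = list(fe = .ramped(profile_sinusoid(30, 1.0, 0, offset = -5)),
                     aa = .ramped(profile_sinusoid(10, 1.0, 0.7)),
                     ier = .ramped(profile_sinusoid(10, 1.0, 1.9)))),
      knee = list(left = .ramped(profile_sinusoid(25, 1.0, pi + 0.6, offset = 30)),
                  right = .ramped(profile_sinusoid(25, 1.0, 0.6, offset = 30))),
      shanks = FALSE)
  )

  d2r <- pi / 180
  trials <- list(); truth_angles <- list()
  for (trial in names(specs)) {
    sp <- specs[[trial]]
    n <- round(sp$duration * fs)
    tv <- (seq_len(n) - 1) / fs
    qp <- .orientation_fun(sp$pelvis)
    origin <- sp$origin %||% function(t) matrix(0, length(t), 3)
    qfun_thigh <- list(); qfun_shank <- list()
    for (side in c("left", "right")) {
      hp <- sp$hip[[side]]
      fe <- hp$fe %||% .zero_fun; aa <- hp$aa %||% .zero_fun
      ier <- hp$ier %||% .zero_fun
      kf <- sp$knee[[side]]
      local({
        fe <- fe; aa <- aa; ier <- ier; kf <- kf; side <- side
        qfun_thigh[[side]] <<- function(t)
          quat_multiply_rows(qp(t), .jcs_quat_rows(fe(t), aa(t), ier(t), side))
        qfun_shank[[side]] <<- function(t) {
          a <- -kf(t) * d2r
          quat_multiply_rows(qfun_thigh[[side]](t),
                             cbind(cos(a / 2),
                                   sin(a / 2) %o% geom$knee_axis))
        }
      })
    }
    hip_pos <- function(side) {
      cs <- if (side == "left") geom$hip_left else geom$hip_right
      function(t) origin(t) + quat_rotate_rows(qp(t), .const_rows(cs, length(t)))
    }
    sensors <- list(
      pelvis = list(
        qfun = function(t) quat_multiply_rows(
          qp(t), .const_quat_rows(mounts$pelvis, length(t))),
        posfun = function(t) origin(t) +
          quat_rotate_rows(qp(t), .const_rows(geom$pelvis_sensor, length(t)))))
    for (side in c("left", "right")) {
      local({
        side <- side
        hp <- hip_pos(side)
        qt <- qfun_thigh[[side]]; qs <- qfun_shank[[side]]
        mt <- mounts[[paste0("thigh_", side)]]
        ms <- mounts[[paste0("shank_", side)]]
        sensors[[paste0("thigh_", side)]] <<- list(
          qfun = function(t) quat_multiply_rows(
            qt(t), .const_quat_rows(mt, length(t))),
          posfun = function(t) hp(t) +
            quat_rotate_rows(qt(t), .const_rows(geom$thigh_sensor, length(t))))
        if (sp$shanks)
          sensors[[paste0("shank_", side)]] <<- list(
            qfun = function(t) quat_multiply_rows(
              qs(t), .const_quat_rows(ms, length(t))),
            posfun = function(t) hp(t) +
              quat_rotate_rows(qt(t), .const_rows(geom$knee, length(t))) +
              quat_rotate_rows(qs(t), .const_rows(geom$shank_sensor,
                                                  length(t))))
      })
    }
    recs <- list()
    for (nm in names(sensors)) {
      ch <- .sensor_channels(sensors[[nm]]$qfun, sensors[[nm]]$posfun,
                             tv, mag_field, G)
      nz <- .add_noise(ch, noise)
      recs[[nm]] <- imu_recording(tv, nz$gyro, nz$accel, nz$mag, fs)
    }
    trials[[trial]] <- recs
    truth_angles[[trial]] <- lapply(c(left = "left", right = "right"),
      function(side) {
        hp <- sp$hip[[side]]
        data.frame(t = tv,
                   fe = (hp$fe %||% .zero_fun)(tv),
                   aa = (hp$aa %||% .zero_fun)(tv),
                   ier = (hp$ier %||% .zero_fun)(tv),
                   side = side)
      })
  }

  inv_rot <- function(mount, v) quat_rotate(quat_conjugate(mount), v)
  truth_geom <- list()
  for (side in c("left", "right")) {
    cs <- if (side == "left") geom$hip_left else geom$hip_right
    mt <- mounts[[paste0("thigh_", side)]]
    ms <- mounts[[paste0("shank_", side)]]
    truth_geom[[side]] <- list(
      hip = list(r1 = inv_rot(mounts$pelvis, geom$pelvis_sensor - cs),
                 r2 = inv_rot(mt, geom$thigh_sensor)),
      knee = list(r1 = inv_rot(mt, geom$thigh_sensor - geom$knee),
                  r2 = inv_rot(ms, geom$shank_sensor),
                  j1 = inv_rot(mt, geom$knee_axis),
                  j2 = inv_rot(ms, geom$knee_axis)))
  }
  list(static = trials$static, star = trials$star, walking = trials$walking,
       truth = list(angles = truth_angles, geometry = truth_geom,
                    mounts = mounts, body = geom, seed = seed))
}
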