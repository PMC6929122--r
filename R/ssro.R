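# Sensor-to-sensor relative orientation (SSRO).
#
# A Kalman filter over the 10-element state [g1; g2; q21]: the unit gravity
# direction in each sensor's frame and the quaternion rotating frame-2
# vectors into frame 1.  Gyroscopes drive the time update; accelerometers
# provide the gravity measurement through a first-order autoregressive model
# of the true (non-gravitational) acceleration; gravity estimates plus
# magnetometer readings provide a direct quaternion measurement.  The
# magnetic field is assumed homogeneous across the two closely spaced
# sensors, so magnetic disturbances affect both equally and cancel from the
# relative orientation.
#
# The state-update, observation, process-noise and measurement-noise
# matrices are all block-diagonal over (g1, g2, q21), so the filter algebra
# decouples into three blocks; they are run blockwise and the full 10x10
# covariance is assembled on request.

#' Kalman filter parameters for SSRO
#'
#' Defaults are the tuned values for low-noise MEMS sensors sampled at
#' 128 Hz.
#'
#' @param sigma_w Gyroscope noise standard deviation, rad/s (its square
#'   enters the process noise).
#' @param sigma_a Accelerometer noise variance, (m/s^2)^2 (the gravity
#'   measurement noise floor).
#' @param c First-order autoregressive constant of the true-acceleration
#'   model, in (0, 1).
#' @param n_ma Moving-average window length (samples) for the dynamic part
#'   of the gravity measurement noise.
#' @param mu Error-factor weighting the quaternion measurement noise by the
#'   current true-acceleration magnitudes (dimensionless).
#' @param g Gravitational acceleration, m/s^2.
#' @return An object of class \code{kf_params}.
#' @export
kf_params <- function(sigma_w = 1e-3, sigma_a = 6e-3, c = 0.003,
                      n_ma = 64, mu = 5e-8, g = 9.81) {
  if (!(c > 0 && c < 1)) stop("c must lie in (0, 1)", call. = FALSE)
  if (n_ma < 1) stop("n_ma must be >= 1", call. = FALSE)
  if (sigma_w <= 0 || sigma_a <= 0 || mu < 0 || g <= 0)
    stop("sigma_w, sigma_a, g must be positive and mu non-negative",
         call. = FALSE)
  structure(list(sigma_w = sigma_w, sigma_a = sigma_a, c = c,
                 n_ma = as.integer(n_ma), mu = mu, g = g),
            class = "kf_params")
}

#' Read Kalman filter parameters from a YAML or JSON config file
#'
#' Recognized keys: \code{sigma_w}, \code{sigma_a}, \code{c}, \code{n_ma},
#' \code{mu}, \code{g}.  Missing keys keep their defaults.
#'
#' @param path Path to a \code{.yaml}/\code{.yml} or \code{.json} file.
#' @return A \code{\link{kf_params}} object.
#' @export
kf_params_from_file <- function(path) {
  ext <- tolower(tools::file_ext(path))
  vals <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
          else if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE)
          else stop("config must be YAML or JSON", call. = FALSE)
  allowed <- c("sigma_w", "sigma_a", "c", "n_ma", "mu", "g")
  unknown <- setdiff(names(vals), allowed)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(kf_params, vals)
}

#' Gravity measurement from the true-acceleration AR model
#'
#' The accelerometer reads gravity plus true acceleration; modelling the
#' true acceleration as a first-order autoregression with constant \code{c}
#' yields the measurement \code{zeta_g = a_k - c * a_tilde_prev}, observed
#' through \code{H_g = G * I3} acting on the unit gravity direction.
#'
#' @param a_k Current accelerometer sample, m/s^2 (3-vector).
#' @param a_tilde_prev Previous true-acceleration estimate, m/s^2.
#' @param c AR constant in (0, 1).
#' @param G Gravitational acceleration, m/s^2.
#' @return List with \code{zeta} (3-vector) and \code{H} (3x3 matrix).
#' @export
gravity_measurement <- function(a_k, a_tilde_prev, c, G) {
  .check_finite(a_k, "a_k"); .check_finite(a_tilde_prev, "a_tilde_prev")
  list(zeta = a_k - c * a_tilde_prev, H = G * diag(3))
}

#' Quaternion measurement from gravity and magnetic field vectors
#'
#' Constructs the frame-2-to-frame-1 rotation in two stages: a shortest-arc
#' rotation aligning the gravity estimates, then a rotation about the shared
#' gravity direction aligning the gravity-orthogonal (horizontal) components
#' of the magnetic field readings.
#'
#' @param g1_hat,g2_hat Unit gravity direction estimates in each frame.
#' @param m1,m2 Magnetic field readings in each frame (any consistent units).
#' @return Unit quaternion rotating frame-2 vectors into frame 1.
#' @export
quaternion_measurement <- function(g1_hat, g2_hat, m1, m2) {
  .check_finite(m1, "m1"); .check_finite(m2, "m2")
  g1_hat <- g1_hat / sqrt(sum(g1_hat^2))
  g2_hat <- g2_hat / sqrt(sum(g2_hat^2))
  # gravity alignment (partial rotation, heading unresolved); at (near)
  # antiparallel gravity directions any axis perpendicular to g1 maps g2
  # onto g1, and the choice is absorbed by the heading stage below
  d <- sum(g1_hat * g2_hat)
  q2d <- if (d > 1 - 5e-13) c(1, 0, 0, 0)
         else if (d < -1 + 1e-8) c(0, .any_perpendicular(g1_hat))
         else quat_from_two_vectors(g2_hat, g1_hat)
  # horizontal magnetic components
  mxy1 <- m1 - sum(m1 * g1_hat) * g1_hat
  mxy2 <- m2 - sum(m2 * g2_hat) * g2_hat
  n1 <- sqrt(sum(mxy1^2)); n2 <- sqrt(sum(mxy2^2))
  if (n1 < 1e-9 * max(1, sqrt(sum(m1^2))) ||
      n2 < 1e-9 * max(1, sqrt(sum(m2^2))))
    stop("degenerate heading: magnetic field (near) parallel to gravity",
         call. = FALSE)
  m2_rot <- quat_rotate(q2d, mxy2 / n2)
  dm <- sum(m2_rot * mxy1 / n1)
  qd1 <- if (dm > 1 - 5e-13) c(1, 0, 0, 0)
         else if (dm < -1 + 1e-8) c(0, g1_hat)  # 180 degree heading flip
         else quat_from_two_vectors(m2_rot, mxy1 / n1)
  quat_multiply(qd1, q2d)
}

# a unit vector perpendicular to v
.any_perpendicular <- function(v) {
  e <- if (abs(v[1]) <= abs(v[2]) && abs(v[1]) <= abs(v[3])) c(1, 0, 0)
       else if (abs(v[2]) <= abs(v[3])) c(0, 1, 0) else c(0, 0, 1)
  p <- cross3(v, e)
  p / sqrt(sum(p^2))
}

#' Measurement noise covariance for the SSRO filter
#'
#' Gravity blocks combine the static accelerometer noise floor with a
#' moving-average estimate of the true-acceleration outer product; the
#' quaternion block scales with the current true-acceleration magnitudes so
#' the magnetic/gravity quaternion measurement is discounted during dynamics.
#'
#' @param a_tilde_hist1,a_tilde_hist2 Matrices (up to \code{n_ma} x 3) of
#'   recent true-acceleration estimates, most recent last.
#' @param params A \code{\link{kf_params}} object.
#' @return 10x10 block-diagonal measurement noise covariance.
#' @export
measurement_noise <- function(a_tilde_hist1, a_tilde_hist2, params) {
  blocks <- .measurement_noise_blocks(as.matrix(a_tilde_hist1),
                                      as.matrix(a_tilde_hist2), params)
  M <- matrix(0, 10, 10)
  M[1:3, 1:3] <- blocks$Mg1
  M[4:6, 4:6] <- blocks$Mg2
  M[7:10, 7:10] <- blocks$Mq
  M
}

.measurement_noise_blocks <- function(h1, h2, params) {
  mg <- function(h) {
    nw <- nrow(h)
    params$sigma_a * diag(3) + (params$c^2 / nw) * crossprod(h)
  }
  a1 <- h1[nrow(h1), ]; a2 <- h2[nrow(h2), ]
  mq <- params$mu * (sum(a1^2) + sum(a2^2))
  list(Mg1 = mg(h1), Mg2 = mg(h2), Mq = mq * diag(4))
}

# Right-multiplication matrix W(omega) with W %*% q == q (x) (0, omega).
# This is the 4x4 angular-velocity operator of the quaternion kinematics
# q_dot = 1/2 q (x) (0, omega_diff).
.omega_operator <- function(w) {
  matrix(c(0, -w[1], -w[2], -w[3],
           w[1], 0, w[3], -w[2],
           w[2], -w[3], 0, w[1],
           w[3], w[2], -w[1], 0), nrow = 4, byrow = TRUE)
}

.assemble_P <- function(st) {
  P <- matrix(0, 10, 10)
  P[1:3, 1:3] <- st$Pg1
  P[4:6, 4:6] <- st$Pg2
  P[7:10, 7:10] <- st$Pq
  P
}

#' Initialize the SSRO filter state
#'
#' Gravity directions are the normalized means of the first \code{n_init}
#' accelerometer samples; the relative quaternion is the direct
#' gravity-plus-magnetometer measurement evaluated on those means.
#'
#' @param imu1,imu2 Synchronized \code{\link{imu_recording}}s at the same
#'   sampling rate (sensor 1 proximal, e.g. pelvis; sensor 2 distal).
#' @param params A \code{\link{kf_params}} object.
#' @param n_init Number of initial samples averaged (default: one
#'   moving-average window, \code{params$n_ma}).
#' @param p0 Initial state variance (scalar; \code{P0 = p0 * I10}).
#' @return A list state with elements \code{g1}, \code{g2}, \code{q21},
#'   covariance blocks, true-acceleration histories, and \code{P} (10x10).
#' @export
ssro_initialize <- function(imu1, imu2, params = kf_params(),
                            n_init = params$n_ma, p0 = 1e-2) {
  stopifnot(inherits(imu1, "imu_recording"), inherits(imu2, "imu_recording"))
  if (imu1$n != imu2$n || abs(imu1$fs - imu2$fs) > 1e-9)
    stop("recordings must be synchronized with equal length and rate",
         call. = FALSE)
  n_init <- min(n_init, imu1$n)
  a1 <- colMeans(imu1$accel[seq_len(n_init), , drop = FALSE])
  a2 <- colMeans(imu2$accel[seq_len(n_init), , drop = FALSE])
  if (sqrt(sum(a1^2)) < 0.1 * params$g || sqrt(sum(a2^2)) < 0.1 * params$g)
    stop("initialization error: near-zero mean acceleration (free fall?)",
         call. = FALSE)
  g1 <- a1 / sqrt(sum(a1^2))
  g2 <- a2 / sqrt(sum(a2^2))
  m1 <- colMeans(imu1$mag[seq_len(n_init), , drop = FALSE])
  m2 <- colMeans(imu2$mag[seq_len(n_init), , drop = FALSE])
  q21 <- quaternion_measurement(g1, g2, m1, m2)
  st <- list(g1 = g1, g2 = g2, q21 = q21,
             Pg1 = p0 * diag(3), Pg2 = p0 * diag(3), Pq = p0 * diag(4),
             a1_hist = matrix(0, 1, 3), a2_hist = matrix(0, 1, 3))
  st$P <- .assemble_P(st)
  st
}

#' One Kalman time update of the SSRO state
#'
#' Propagates each gravity direction by its sensor's angular velocity and
#' the relative quaternion by the angular velocity difference
#' \code{w2 - t(R21) w1}; grows the covariance by the gyro-driven process
#' noise.  State norms are restored after the linear propagation.
#'
#' @param state State list as returned by \code{\link{ssro_initialize}}.
#' @param w1,w2 Angular velocity samples of sensors 1 and 2, rad/s
#'   (treated as constant over the step when \code{w1_next}/\code{w2_next}
#'   are absent).
#' @param dt Sample interval, s.
#' @param params A \code{\link{kf_params}} object.
#' @param w1_next,w2_next Optional angular velocity samples at the end of
#'   the step; when supplied, the propagation uses trapezoidal averaging
#'   with a two-sample coning correction, which keeps the strap-down
#'   integration error negligible over minute-long trials.
#' @return The predicted state.
#' @export
ssro_time_update <- function(state, w1, w2, dt, params = kf_params(),
                             w1_next = NULL, w2_next = NULL) {
  .check_finite(w1, "w1"); .check_finite(w2, "w2")
  q <- state$q21
  Rt <- function(v) quat_rotate(quat_conjugate(q), v)
  # per-step rotation vectors (rad): trapezoid + coning term when two
  # samples are available, rectangle rule otherwise
  rotvec <- function(wa, wb) {
    if (is.null(wb)) return(dt * wa)
    dt * (wa + wb) / 2 + dt^2 / 12 * cross3(wa, wb)
  }
  phi1 <- rotvec(w1, w1_next)
  phi2 <- rotvec(w2, w2_next)
  wd_a <- w2 - Rt(w1)
  phid <- if (is.null(w1_next)) dt * wd_a else {
    wd_b <- w2_next - Rt(w1_next)
    dt * (wd_a + wd_b) / 2 + dt^2 / 12 * cross3(wd_a, wd_b)
  }
  # covariance Jacobians: first-order in the step rotation
  Ag1 <- diag(3) - skew(phi1)
  Ag2 <- diag(3) - skew(phi2)
  Aq <- diag(4) + 0.5 * .omega_operator(phid)
  # process noise, evaluated at the pre-update state
  Qg1 <- dt^2 * params$sigma_w^2 * tcrossprod(skew(state$g1))
  Qg2 <- dt^2 * params$sigma_w^2 * tcrossprod(skew(state$g2))
  Qq <- (dt^2 / 2) * params$sigma_w^2 * (diag(4) - tcrossprod(q))
  # state mean: exact rotation by the step rotation vector (the linear
  # matrices above serve only as covariance Jacobians); gravity obeys
  # g_dot = -w x g, i.e. rotation by -phi
  qexp <- function(phi) {
    a <- sqrt(sum(phi^2))
    if (a < 1e-12) c(1, 0, 0, 0) else c(cos(a / 2), sin(a / 2) * phi / a)
  }
  rot_exp <- function(g, phi) quat_rotate(quat_conjugate(qexp(phi)), g)
  g1 <- rot_exp(state$g1, phi1); g1 <- g1 / sqrt(sum(g1^2))
  g2 <- rot_exp(state$g2, phi2); g2 <- g2 / sqrt(sum(g2^2))
  # the relative quaternion step factorizes exactly over the per-sensor
  # step rotations: q21 <- E1* (x) q21 (x) E2 (E_i = exp(phi_i / 2)), which
  # avoids mapping the frame-1 rate across a rotation that changes within
  # the step; phid above is only the covariance Jacobian's linearization
  qn <- quat_multiply(quat_multiply(quat_conjugate(qexp(phi1)), q),
                      qexp(phi2))
  qn <- qn / sqrt(sum(qn^2))
  sym <- function(M) (M + t(M)) / 2
  state$g1 <- g1; state$g2 <- g2; state$q21 <- qn
  state$Pg1 <- sym(Ag1 %*% state$Pg1 %*% t(Ag1) + Qg1)
  state$Pg2 <- sym(Ag2 %*% state$Pg2 %*% t(Ag2) + Qg2)
  state$Pq <- sym(Aq %*% state$Pq %*% t(Aq) + Qq)
  state$P <- .assemble_P(state)
  state
}

#' Run the SSRO Kalman filter over two synchronized recordings
#'
#' Standard predict/correct cycle: gyroscope-driven time update, then the
#' gravity and quaternion measurement updates.  After every update the
#' gravity directions and quaternion are renormalized and the true
#' acceleration \code{a - G g} is appended to the moving-average history.
#'
#' @param imu1,imu2 Synchronized \code{\link{imu_recording}}s (sensor 1
#'   proximal, sensor 2 distal).
#' @param params A \code{\link{kf_params}} object.
#' @param n_init Samples averaged for initialization.
#' @param predict_only If \code{TRUE}, skip all measurement updates; the
#'   filter reduces to strap-down integration of the angular velocity
#'   difference.
#' @param keep_P If \code{TRUE}, store the full 10x10 covariance at every
#'   sample (as a 10 x 10 x N array) in the result.
#' @return List with \code{t}, \code{q21} (N x 4 canonical quaternion trace),
#'   \code{g1}, \code{g2} (N x 3 gravity direction traces), \code{a_tilde1},
#'   \code{a_tilde2} (N x 3 true-acceleration traces), final \code{state},
#'   and optionally \code{P_trace}.
#' @export
run_ssro <- function(imu1, imu2, params = kf_params(), n_init = params$n_ma,
                     predict_only = FALSE, keep_P = FALSE) {
  st <- ssro_initialize(imu1, imu2, params, n_init = n_init)
  n <- imu1$n
  dt <- 1 / imu1$fs
  G <- params$g
  cA <- params$c
  n_ma <- params$n_ma
  Q <- matrix(0, n, 4); G1 <- matrix(0, n, 3); G2 <- matrix(0, n, 3)
  AT1 <- matrix(0, n, 3); AT2 <- matrix(0, n, 3)
  if (keep_P) P_trace <- array(0, c(10, 10, n))
  record <- function(k) {
    Q[k, ] <<- quat_canonical(st$q21)
    G1[k, ] <<- st$g1; G2[k, ] <<- st$g2
    AT1[k, ] <<- st$a1_hist[nrow(st$a1_hist), ]
    AT2[k, ] <<- st$a2_hist[nrow(st$a2_hist), ]
    if (keep_P) P_trace[, , k] <<- .assemble_P(st)
  }
  push_hist <- function(h, a, cap) {
    h <- rbind(h, a)
    if (nrow(h) > cap) h[(nrow(h) - cap + 1):nrow(h), , drop = FALSE] else h
  }
  # true acceleration at the initial sample
  st$a1_hist <- matrix(imu1$accel[1, ] - G * st$g1, 1, 3)
  st$a2_hist <- matrix(imu2$accel[1, ] - G * st$g2, 1, 3)
  record(1)
  I3 <- diag(3); I4 <- diag(4)
  sym <- function(M) (M + t(M)) / 2
  for (k in 2:n) {
    st <- ssro_time_update(st, imu1$gyro[k - 1, ], imu2$gyro[k - 1, ],
                           dt, params,
                           w1_next = imu1$gyro[k, ],
                           w2_next = imu2$gyro[k, ])
    if (!predict_only) {
      a1k <- imu1$accel[k, ]; a2k <- imu2$accel[k, ]
      Mb <- .measurement_noise_blocks(st$a1_hist, st$a2_hist, params)
      # gravity updates: H = G * I3
      for (i in 1:2) {
        gi <- if (i == 1) st$g1 else st$g2
        Pi <- if (i == 1) st$Pg1 else st$Pg2
        Mi <- if (i == 1) Mb$Mg1 else Mb$Mg2
        ak <- if (i == 1) a1k else a2k
        ap <- if (i == 1) st$a1_hist[nrow(st$a1_hist), ]
              else st$a2_hist[nrow(st$a2_hist), ]
        zeta <- ak - cA * ap
        S <- G^2 * Pi + Mi
        K <- G * Pi %*% solve(S)
        gi <- gi + drop(K %*% (zeta - G * gi))
        Pi <- sym((I3 - G * K) %*% Pi)
        gi <- gi / sqrt(sum(gi^2))
        if (i == 1) { st$g1 <- gi; st$Pg1 <- Pi }
        else { st$g2 <- gi; st$Pg2 <- Pi }
      }
      # quaternion update: H = I4
      zq <- quaternion_measurement(st$g1, st$g2, imu1$mag[k, ], imu2$mag[k, ])
      if (sum(zq * st$q21) < 0) zq <- -zq
      # tiny ridge keeps the innovation covariance invertible when the
      # true-acceleration history (hence Mq) is identically zero
      Sq <- st$Pq + Mb$Mq + 1e-12 * I4
      Kq <- st$Pq %*% solve(Sq)
      qn <- st$q21 + drop(Kq %*% (zq - st$q21))
      st$q21 <- qn / sqrt(sum(qn^2))
      st$Pq <- sym((I4 - Kq) %*% st$Pq)
      # true acceleration and moving-average history
      st$a1_hist <- push_hist(st$a1_hist, a1k - G * st$g1, n_ma)
      st$a2_hist <- push_hist(st$a2_hist, a2k - G * st$g2, n_ma)
    }
    dmin <- min(diag(st$Pg1), diag(st$Pg2), diag(st$Pq))
    if (!is.finite(dmin) || dmin < -1e-8)
      stop(sprintf("numerical failure: covariance not PSD at sample %d", k),
           call. = FALSE)
    record(k)
  }
  st$P <- .assemble_P(st)
  out <- list(t = imu1$t, q21 = Q, g1 = G1, g2 = G2,
              a_tilde1 = AT1, a_tilde2 = AT2, state = st)
  if (keep_P) out$P_trace <- P_trace
  out
}

#' Convert an SSRO quaternion trace to rotation matrices
#'
#' @param q21 N x 4 quaternion trace.
#' @return 3 x 3 x N array of rotation matrices.
#' @export
ssro_matrices <- function(q21) {
  n <- nrow(q21)
  R <- array(0, c(3, 3, n))
  for (k in seq_len(n)) R[, , k] <- quat_to_matrix(q21[k, ])
  R
}
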