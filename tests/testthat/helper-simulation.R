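# Shared fixtures for the test suite.  Expensive simulations are memoised so
# several test files can reuse them within one run.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    val <- force(expr)
    if (is.null(val)) stop("fixture '", name, "' has not been built yet")
    assign(name, val, envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

noise_off <- c(gyro = 0, accel = 0, mag = 0)
noise_default <- c(gyro = 0.005, accel = 0.08, mag = 0.01)

rand_quat <- function(seed) {
  set.seed(seed)
  q <- stats::rnorm(4)
  q / sqrt(sum(q^2))
}

# walking-like hip profiles with a smooth onset so trials start from rest
walking_profiles <- function(f = 1) {
  r <- smooth_ramp()
  list(fe = function(t) r(t) * 30 * sin(2 * pi * f * t),
       aa = function(t) r(t) * 10 * sin(2 * pi * f * t + 0.7),
       ier = function(t) r(t) * 10 * sin(2 * pi * f * t + 1.9))
}

walking_pelvis <- function() {
  r <- smooth_ramp()
  list(rx = function(t) r(t) * 2 * sin(2 * pi * 2 * t),
       ry = function(t) r(t) * 4 * sin(2 * pi * 1 * t + 0.5),
       rz = function(t) r(t) * 3 * sin(2 * pi * 1 * t + 1.5))
}

walking_origin <- function() {
  r <- smooth_ramp()
  function(t) cbind(r(t) * 0.01 * sin(2 * pi * t + 0.2),
                    r(t) * 0.02 * sin(2 * pi * 2 * t),
                    r(t) * 0.02 * sin(2 * pi * t))
}

# star-like rich 3D calibration profiles
star_profiles <- function() {
  r <- smooth_ramp()
  list(fe = function(t) r(t) * 40 * sin(2 * pi * 0.20 * t + 0.3),
       aa = function(t) r(t) * 25 * sin(2 * pi * 0.34 * t + 1.3),
       ier = function(t) r(t) * 20 * sin(2 * pi * 0.26 * t + 2.1))
}

star_pelvis <- function() {
  r <- smooth_ramp()
  list(rx = function(t) r(t) * 18 * sin(2 * pi * 0.35 * t + 0.4),
       ry = function(t) r(t) * 15 * sin(2 * pi * 0.28 * t + 1.1),
       rz = function(t) r(t) * 15 * sin(2 * pi * 0.40 * t + 2.0))
}

star_origin <- function() {
  r <- smooth_ramp()
  function(t) cbind(r(t) * 0.02 * sin(2 * pi * 0.2 * t),
                    r(t) * 0.02 * sin(2 * pi * 0.26 * t + 1),
                    r(t) * 0.01 * sin(2 * pi * 0.34 * t))
}

# angle between two unit vectors, degrees, sign-insensitive when abs = TRUE
vec_angle <- function(a, b, abs = FALSE) {
  d <- sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  if (abs) d <- base::abs(d)
  180 / pi * acos(max(-1, min(1, d)))
}

# axis-angle error trace (degrees) between two quaternion traces
quat_trace_error <- function(Q1, Q2) {
  2 * acos(pmin(1, abs(rowSums(Q1 * Q2)))) * 180 / pi
}
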