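# Shared star-calibration fixtures for joint-center tests
star_geom <- function() chain_geometry(r1 = c(0.05, 0.25, 0.02),
                                       r2 = c(-0.03, -0.20, 0.01),
                                       mount1 = rand_quat(101),
                                       mount2 = rand_quat(102))

star_sim <- function(noise, seed = 2) {
  simulate_ball_joint(star_profiles(), star_geom(), duration = 50,
                      noise = noise, seed = seed,
                      pelvis_profile = star_pelvis(),
                      origin_fun = star_origin())
}

test_that("high-motion sample selection matches a full sort oracle", {
  n <- 3000
  # all-zero except a block with unit angular velocity
  w <- matrix(0, n, 3)
  hot <- 501:2000
  w[hot, 1] <- 1
  expect_equal(select_high_motion_samples(w, w, 1500), hot)
  # monotone increasing magnitude: the last n_min indices are forced
  w2 <- matrix(seq_len(n) / n, n, 3)
  expect_equal(select_high_motion_samples(w2, w2, 1500), 1501:3000)
  # random magnitudes against a brute-force sort
  set.seed(40)
  wa <- matrix(rnorm(3 * n), n, 3)
  wb <- matrix(rnorm(3 * n), n, 3)
  got <- select_high_motion_samples(wa, wb, 1500)
  score <- sqrt(rowSums(wa^2)) + sqrt(rowSums(wb^2))
  want <- sort(sort.int(score, decreasing = TRUE,
                        index.return = TRUE)$ix[1:1500])
  expect_equal(got, want)
  expect_error(select_high_motion_samples(wa[1:100, ], wb[1:100, ], 1500),
               "1500")
})

test_that("joint-center offsets are recovered from a rich 3D simulation", {
  geom <- star_geom()
  sim <- fixture("star_noiseless", star_sim(noise_off))
  Rtr <- ssro_matrices(sim$truth$q21)
  jc <- estimate_joint_center(sim$imu1, sim$imu2, Rtr)
  expect_s3_class(jc, "joint_center_result")
  expect_gte(jc$n_obs, 1500)
  expect_lt(max(abs(jc$r1 - geom$r1)), 0.005)
  expect_lt(max(abs(jc$r2 - geom$r2)), 0.005)
  # noisy recovery within 15 mm per component
  simn <- fixture("star_noisy", star_sim(noise_default))
  i1 <- preprocess_recording(simn$imu1)
  i2 <- preprocess_recording(simn$imu2)
  jcn <- estimate_joint_center(i1, i2, ssro_matrices(simn$truth$q21))
  expect_lt(max(abs(jcn$r1 - geom$r1)), 0.015)
  expect_lt(max(abs(jcn$r2 - geom$r2)), 0.015)
  expect_gt(jcn$residual, 0)
})

test_that("single-axis motion is reported as degenerate", {
  r <- smooth_ramp()
  prof <- list(fe = function(t) r(t) * 40 * sin(2 * pi * 0.3 * t))
  sim <- simulate_ball_joint(prof, star_geom(), duration = 20,
                             noise = noise_off)
  expect_error(
    estimate_joint_center(sim$imu1, sim$imu2, ssro_matrices(sim$truth$q21)),
    "degenerate motion")
})

test_that("the least-squares solution matches a pseudo-inverse oracle", {
  sim <- fixture("star_noiseless", star_sim(noise_off))
  idx <- select_high_motion_samples(sim$imu1$gyro, sim$imu2$gyro, 1500)
  jc <- estimate_joint_center(sim$imu1, sim$imu2,
                              ssro_matrices(sim$truth$q21), indices = idx)
  # independent reconstruction of the stacked system and SVD pseudo-inverse
  dt <- 1 / sim$imu1$fs
  wd1 <- angular_acceleration(sim$imu1$gyro, dt, fc = 12)
  wd2 <- angular_acceleration(sim$imu2$gyro, dt, fc = 12)
  A <- NULL; b <- NULL
  for (k in idx[seq(1, length(idx), by = 10)]) {
    K1 <- skew(sim$imu1$gyro[k, ]) %*% skew(sim$imu1$gyro[k, ]) + skew(wd1[k, ])
    K2 <- skew(sim$imu2$gyro[k, ]) %*% skew(sim$imu2$gyro[k, ]) + skew(wd2[k, ])
    R <- quat_to_matrix(sim$truth$q21[k, ])
    A <- rbind(A, cbind(K1, -R %*% K2))
    b <- c(b, sim$imu1$accel[k, ] - drop(R %*% sim$imu2$accel[k, ]))
  }
  sv <- svd(A)
  x_pinv <- sv$v %*% ((t(sv$u) %*% b) / sv$d)
  jc_sub <- estimate_joint_center(sim$imu1, sim$imu2,
                                  ssro_matrices(sim$truth$q21),
                                  indices = idx[seq(1, length(idx), by = 10)],
                                  n_min = 150)
  expect_lt(max(abs(c(jc_sub$r1, jc_sub$r2) - drop(x_pinv))), 1e-8)
  # scattered observations: order must not matter
  set.seed(41)
  shuf <- sample(idx)
  jc_shuf <- estimate_joint_center(sim$imu1, sim$imu2,
                                   ssro_matrices(sim$truth$q21),
                                   indices = shuf)
  expect_equal(jc_shuf$r1, jc$r1, tolerance = 1e-9)
})

test_that("joint-center estimates are equivariant under sensor-2 re-mounting", {
  sim <- fixture("star_noiseless", star_sim(noise_off))
  geom <- star_geom()
  Rf <- quat_to_matrix(quat_from_axis_angle(c(1, 2, -1), 0.8))
  # rotate sensor-2 channels and the relative rotation accordingly
  imu2r <- imu_recording(sim$imu2$t,
                         sim$imu2$gyro %*% Rf,   # rows times t(t(Rf)) = R^T v
                         sim$imu2$accel %*% Rf,
                         sim$imu2$mag %*% Rf, sim$imu2$fs)
  n <- sim$imu1$n
  Rtr <- ssro_matrices(sim$truth$q21)
  Rtr_r <- array(0, c(3, 3, n))
  for (k in 1:n) Rtr_r[, , k] <- Rtr[, , k] %*% Rf
  jc <- estimate_joint_center(sim$imu1, sim$imu2, Rtr)
  jcr <- estimate_joint_center(sim$imu1, imu2r, Rtr_r)
  expect_equal(jcr$r1, jc$r1, tolerance = 1e-6)
  expect_equal(drop(jcr$r2), drop(t(Rf) %*% jc$r2), tolerance = 1e-6)
})

test_that("hinge axes minimize the angular-velocity mismatch cost", {
  geom <- chain_geometry(r1 = c(0.04, 0.20, 0.03), r2 = c(0.03, -0.15, 0.02),
                         mount1 = rand_quat(111), mount2 = rand_quat(112),
                         hinge_axis = c(0, 0, 1))
  r <- smooth_ramp()
  angp <- function(t) r(t) * (30 + 25 * sin(2 * pi * 0.4 * t))
  pel <- list(rx = function(t) r(t) * 10 * sin(2 * pi * 0.3 * t),
              ry = function(t) r(t) * 12 * sin(2 * pi * 0.25 * t + 1),
              rz = function(t) r(t) * 8 * sin(2 * pi * 0.35 * t + 2))
  sim <- fixture("hinge_noiseless", simulate_hinge_joint(
    angp, c(0, 0, 1), geom, duration = 30, noise = noise_off,
    pelvis_profile = pel))
  ax <- estimate_hinge_axes(sim$imu1$gyro, sim$imu2$gyro)
  expect_lt(vec_angle(ax$j1, sim$truth$j1, abs = TRUE), 1)
  expect_lt(vec_angle(ax$j2, sim$truth$j2, abs = TRUE), 1)
  expect_equal(sqrt(sum(ax$j1^2)), 1, tolerance = 1e-9)
  # the optimum beats 1000 random unit-vector pairs
  w1 <- sim$imu1$gyro; w2 <- sim$imu2$gyro
  cost_at <- function(j1, j2) {
    c1 <- sqrt(pmax(0, rowSums(w1^2) - drop(w1 %*% j1)^2))
    c2 <- sqrt(pmax(0, rowSums(w2^2) - drop(w2 %*% j2)^2))
    sum((c1 - c2)^2)
  }
  set.seed(42)
  rand_costs <- replicate(1000, {
    u <- rnorm(3); v <- rnorm(3)
    cost_at(u / sqrt(sum(u^2)), v / sqrt(sum(v^2)))
  })
  expect_lte(ax$cost, min(rand_costs))
  expect_lte(ax$cost, cost_at(sim$truth$j1, sim$truth$j2) + 1e-8)
})

test_that("identical angular velocities give identical axes up to sign", {
  set.seed(43)
  w <- cbind(2 * sin(2 * pi * (1:2000) / 300), 0.1, 0.05) +
    matrix(rnorm(6000, sd = 0.02), 2000, 3)
  ax <- estimate_hinge_axes(w, w)
  expect_lt(vec_angle(ax$j1, ax$j2, abs = TRUE), 1e-3)
})

test_that("hinge center correction removes the unobservable axial offset", {
  axes <- list(j1 = c(0, 0, 1), j2 = c(0, 1, 0))
  # offsets orthogonal to the axes pass through unchanged
  co <- correct_hinge_center(c(0.1, 0.2, 0), c(0.3, 0, 0.4), axes)
  expect_equal(co$r1, c(0.1, 0.2, 0))
  expect_equal(co$r2, c(0.3, 0, 0.4))
  # offsets equal to the axes collapse to zero
  co2 <- correct_hinge_center(axes$j1, axes$j2, axes)
  expect_equal(co2$r1, c(0, 0, 0))
  expect_equal(co2$r2, c(0, 0, 0))
  # corrected offsets always satisfy the axial-balance constraint
  set.seed(44)
  for (i in 1:20) {
    j1 <- rnorm(3); j1 <- j1 / sqrt(sum(j1^2))
    j2 <- rnorm(3); j2 <- j2 / sqrt(sum(j2^2))
    cc <- correct_hinge_center(rnorm(3), rnorm(3), list(j1 = j1, j2 = j2))
    expect_lt(abs(sum(cc$r1 * j1) + sum(cc$r2 * j2)), 1e-9)
  }
})

test_that("corrected hinge centers land on the perpendicular foot points", {
  sim <- fixture("hinge_noiseless", {
    geom <- chain_geometry(r1 = c(0.04, 0.20, 0.03), r2 = c(0.03, -0.15, 0.02),
                           mount1 = rand_quat(111), mount2 = rand_quat(112),
                           hinge_axis = c(0, 0, 1))
    r <- smooth_ramp()
    simulate_hinge_joint(
      function(t) r(t) * (30 + 25 * sin(2 * pi * 0.4 * t)), c(0, 0, 1), geom,
      duration = 30, noise = noise_off,
      pelvis_profile = list(rx = function(t) r(t) * 10 * sin(2 * pi * 0.3 * t),
                            ry = function(t) r(t) * 12 * sin(2 * pi * 0.25 * t + 1),
                            rz = function(t) r(t) * 8 * sin(2 * pi * 0.35 * t + 2)))
  })
  geom <- sim$truth$geometry
  sso <- run_ssro(sim$imu1, sim$imu2)
  jc <- estimate_joint_center(sim$imu1, sim$imu2, ssro_matrices(sso$q21),
                              cond_max = 1e10)
  ax <- estimate_hinge_axes(sim$imu1$gyro, sim$imu2$gyro)
  co <- correct_hinge_center(jc$r1, jc$r2, ax)
  s_true <- (sum(geom$r1 * sim$truth$j1) + sum(geom$r2 * sim$truth$j2)) / 2
  foot1 <- geom$r1 - sim$truth$j1 * s_true
  foot2 <- geom$r2 - sim$truth$j2 * s_true
  expect_lt(sqrt(sum((co$r1 - foot1)^2)), 0.01)
  expect_lt(sqrt(sum((co$r2 - foot2)^2)), 0.01)
})

test_that("recovery improves with the number of high-motion observations", {
  # expectation over seeds: more observations reduce the mean error
  geom <- star_geom()
  errs <- sapply(1:6, function(s) {
    sim <- star_sim(noise_default, seed = 100 + s)
    i1 <- preprocess_recording(sim$imu1)
    i2 <- preprocess_recording(sim$imu2)
    Rtr <- ssro_matrices(sim$truth$q21)
    idx_all <- select_high_motion_samples(i1$gyro, i2$gyro, 1500)
    sapply(c(100, 1500), function(m) {
      jc <- estimate_joint_center(i1, i2, Rtr, indices = idx_all[seq_len(m)],
                                  n_min = m)
      sqrt(sum((jc$r1 - geom$r1)^2) + sum((jc$r2 - geom$r2)^2))
    })
  })
  expect_lt(mean(errs[2, ]), mean(errs[1, ]))
})
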