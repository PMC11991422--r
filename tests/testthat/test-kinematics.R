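const_stream <- function(q, n = 120, rate = 60) {
  pose_stream(seq(0, by = 1 / rate, length.out = n),
              matrix(as.numeric(q), n, 4, byrow = TRUE), rate_hz = rate)
}

test_that("relative orientation re-zeroes against the neutral reference", {
  set.seed(21)
  q <- quat(random_unit_quats(1)[1, ])
  expect_equal(as.numeric(relative_orientation(q, neutral_calibration(q))),
               c(1, 0, 0, 0), tolerance = 1e-12)
  expect_equal(as.numeric(relative_orientation(quat_identity(),
                                               neutral_calibration(quat_identity()))),
               c(1, 0, 0, 0))
  # two rotations about the vertical axis compose to their angle difference
  theta <- 73; phi <- 21
  q1 <- quat_from_axis_angle(c(0, 1, 0), theta)
  q0 <- quat_from_axis_angle(c(0, 1, 0), phi)
  rel <- relative_orientation(q1, neutral_calibration(q0))
  expect_equal(quat_to_matrix(rel),
               t(rot_axis(c(0, 1, 0), phi)) %*% rot_axis(c(0, 1, 0), theta),
               tolerance = 1e-12)
  expect_equal(quat_to_matrix(rel), rot_axis(c(0, 1, 0), theta - phi),
               tolerance = 1e-12)
})

test_that("identity decomposes to zero and single-plane axes map to single channels", {
  z <- decompose_angles(quat_identity())
  expect_equal(unclass(z), c(flexion_extension = 0, lateral_flexion = 0, rotation = 0))
  # vertical-axis rotation in the right-rotation sense: clockwise seen
  # from above is a negative rotation about the +Y (up) axis
  a <- decompose_angles(quat_from_axis_angle(c(0, 1, 0), -45))
  expect_equal(a[["rotation"]], 45, tolerance = 1e-9)
  expect_equal(a[["flexion_extension"]], 0, tolerance = 1e-9)
  expect_equal(a[["lateral_flexion"]], 0, tolerance = 1e-9)
})

test_that("compose/decompose round trip is the identity within 1e-9 degrees", {
  grid <- expand.grid(fe = seq(-80, 80, by = 20),
                      lat = seq(-60, 60, by = 30),
                      rot = seq(-90, 90, by = 30))
  for (i in seq_len(nrow(grid))) {
    a <- c(grid$fe[i], grid$lat[i], grid$rot[i])
    back <- decompose_angles(compose_from_angles(a))
    expect_equal(as.numeric(unclass(back)), a, tolerance = 1e-9)
  }
  # the flexion rig-trial angle specifically
  expect_equal(unname(unclass(decompose_angles(compose_from_angles(c(34, 0, 0))))),
               c(34, 0, 0), tolerance = 1e-9)
})

test_that("decomposition is hemisphere-invariant", {
  set.seed(22)
  Q <- random_unit_quats(50)
  for (i in seq_len(nrow(Q))) {
    a1 <- suppressWarnings(decompose_angles(quat(Q[i, ], normalize = TRUE)))
    a2 <- suppressWarnings(decompose_angles(quat(-Q[i, ], normalize = TRUE)))
    expect_equal(unclass(a1), unclass(a2), tolerance = 1e-12)
  }
})

test_that("decomposition agrees with the rotation-matrix oracle on 1000 random orientations", {
  set.seed(23)
  Q <- random_unit_quats(1000)
  worst <- 0
  for (i in seq_len(nrow(Q))) {
    got <- suppressWarnings(decompose_angles(quat(Q[i, ])))
    want <- oracle_angles_from_matrix(oracle_quat_matrix(Q[i, ]))
    worst <- max(worst, max(abs(as.numeric(unclass(got)) - as.numeric(want))))
  }
  expect_lt(worst, 1e-6)
})

test_that("composition matches independently composed elementary rotations", {
  set.seed(24)
  for (i in 1:25) {
    a <- c(stats::runif(1, -80, 80), stats::runif(1, -60, 60), stats::runif(1, -90, 90))
    expect_equal(quat_to_matrix(compose_from_angles(a)),
                 oracle_matrix_from_angles(a), tolerance = 1e-12)
  }
})

test_that("gimbal proximity warns but still returns angles", {
  expect_warning(a <- decompose_angles(compose_from_angles(c(88, 0, 0))),
                 "gimbal")
  expect_equal(a[["flexion_extension"]], 88, tolerance = 1e-6)
})

test_that("neutral estimation averages a still window and rejects motion", {
  q0 <- quat_from_axis_angle(c(1, 2, 3), 15)
  calib <- estimate_neutral(const_stream(q0))
  expect_equal(quat_angle_deg(calib$q_ref, q0), 0, tolerance = 1e-9)

  # Monte-Carlo: component noise sd 1e-3 keeps the mean within 0.1 deg
  set.seed(25)
  errs <- replicate(100, {
    n <- 60
    Q <- matrix(as.numeric(q0), n, 4, byrow = TRUE) +
      matrix(stats::rnorm(4 * n, sd = 1e-3), n, 4)
    st <- suppressWarnings(pose_stream(seq(0, by = 1 / 60, length.out = n), Q))
    quat_angle_deg(estimate_neutral(st, window_s = 0.98)$q_ref, q0)
  })
  expect_lt(max(errs), 0.1)

  # head turning at 20 deg/s during the window is a calibration error
  t <- seq(0, by = 1 / 60, length.out = 90)
  Q <- t(vapply(t, function(tt) as.numeric(quat_from_axis_angle(c(0, 1, 0), 20 * tt)),
                numeric(4)))
  expect_error(estimate_neutral(pose_stream(t, Q)), "calibration instability")
  expect_error(estimate_neutral(const_stream(q0, n = 30), window_s = 1), "shorter")
})

test_that("angle time series decomposes per sample and re-zeroes to its first pose", {
  q0 <- quat_from_axis_angle(c(0.3, 1, -0.2), 25)
  ser <- angles_timeseries(const_stream(q0))
  expect_equal(nrow(ser), 120)
  expect_equal(names(ser), c("t_s", "flexion_extension", "lateral_flexion", "rotation"))
  expect_true(all(abs(as_angle_matrix(ser)) < 1e-9))

  # any stream measured against its own first sample starts at (0,0,0)
  sim <- simulate_protocol(protocol_config(seed = 9, noise_sd_deg = 0))
  ser2 <- angles_timeseries(sim$stream, neutral_calibration(sim$stream$q[1, ]))
  expect_equal(as.numeric(as_angle_matrix(ser2)[1, ]), c(0, 0, 0), tolerance = 1e-9)
})

test_that("pose stream validation catches rate mismatch and bad timestamps", {
  q0 <- quat_identity()
  expect_warning(pose_stream(seq(0, by = 0.05, length.out = 50),
                             matrix(as.numeric(q0), 50, 4, byrow = TRUE),
                             rate_hz = 60),
                 "rate mismatch")
  expect_error(pose_stream(c(0, 0.1, 0.1), matrix(as.numeric(q0), 3, 4, byrow = TRUE)),
               "strictly increasing")
})
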