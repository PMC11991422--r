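rig_fit <- function(plane, angle) {
  sim <- simulate_rig_trial(rig_trial_spec(plane, angle))
  analyze_session(sim$stream)
}

test_that("rig-trial ROM is the signed extremum with the clinical sign map", {
  f <- rig_fit("flexion", 34)
  expect_equal(f$rom$rom_signed_deg, 34, tolerance = 1e-6)
  l <- rig_fit("left_rotation", 40)
  expect_lt(l$rom$rom_signed_deg, 0)
  expect_equal(l$rom$rom_signed_deg, -40, tolerance = 1e-6)
  rl <- rig_fit("right_lateral", 30)
  expect_equal(rl$rom$rom_signed_deg, -30, tolerance = 1e-6)
})

test_that("digital twin: whole-degree pipeline ROM equals the goniometer reading", {
  trials <- data.frame(plane = c("flexion", "right_rotation", "right_lateral"),
                       angle_deg = c(34, 45, 30))
  for (i in seq_len(nrow(trials))) {
    sim <- simulate_rig_trial(rig_trial_spec(trials$plane[i], trials$angle_deg[i]))
    fit <- analyze_session(sim$stream)
    expect_equal(round(abs(fit$rom$rom_signed_deg)),
                 abs(sim$truth$goniometer_reading_deg))
  }
  # non-integer commanded angles still agree after whole-degree rounding
  sim <- simulate_rig_trial(rig_trial_spec("flexion", 33.6))
  fit <- analyze_session(sim$stream)
  expect_equal(round(fit$rom$rom_signed_deg), sim$truth$goniometer_reading_deg)
  expect_equal(sim$truth$goniometer_reading_deg, 34)
})

test_that("zero-amplitude windows yield zero ROM and empty windows error", {
  ser <- angle_series(seq(0, 2, by = 1 / 60), 0 * seq(0, 2, by = 1 / 60),
                      rep(0, 121), rep(0, 121))
  ep <- data.frame(label = "flexion", start_s = 0.5, end_s = 1.5,
                   primary_channel = "flexion_extension")
  expect_equal(compute_rom(ep, ser)$rom_signed_deg, 0)
  ep_bad <- transform(ep, start_s = 5, end_s = 6)
  expect_error(compute_rom(ep_bad, ser), "no samples")
})

test_that("duration asymmetry is the signed left-minus-right difference", {
  mk <- function(label, rom, dur) data.frame(label = label, rom_signed_deg = rom,
                                             duration_s = dur)
  expect_equal(duration_asymmetry(mk("left_rotation", -45, 3),
                                  mk("right_rotation", 45, 3)),
               list(duration_diff_s = 0, rom_diff_deg = 0))
  a <- duration_asymmetry(mk("left_rotation", -45, 3.1),
                          mk("right_rotation", 40, 3.4))
  expect_equal(a$rom_diff_deg, 5)
  expect_equal(a$duration_diff_s, -0.3, tolerance = 1e-12)
  expect_error(duration_asymmetry(mk("flexion", 30, 3), mk("left_lateral", 30, 3)),
               "paired directions")
  expect_error(duration_asymmetry(mk("flexion", 30, 3), mk("flexion", 30, 3)),
               "paired directions")
})

test_that("simulated rotation-pair asymmetry recovers the injected timing difference", {
  ms <- default_movements_with <- cervrom:::default_movements()
  ms[[5]] <- movement_spec("left_rotation", 70, rise_s = 1.0)
  ms[[6]] <- movement_spec("right_rotation", 70, rise_s = 1.4)
  sim <- simulate_protocol(protocol_config(movements = ms, seed = 12))
  fit <- analyze_session(sim$stream)
  asym <- fit$asymmetry$rotation
  # rise+return each differ by 0.4 s; speed thresholds clip the detected
  # windows at both ends, so allow a quarter second of slack
  expect_lt(abs(asym$duration_diff_s - (-0.8)), 0.25)
  expect_lt(abs(asym$rom_diff_deg), 1)
})

test_that("pure single-plane trials report zero off-plane peaks and no flags", {
  sim <- simulate_rig_trial(rig_trial_spec("right_rotation", 45))
  fit <- analyze_session(sim$stream)
  cr <- detect_compensations(fit$episodes[1, ], fit$angles)
  expect_true(all(abs(cr$offplane$peak_signed_deg) < 1e-9))
  expect_length(cr$flags, 0L)
})

test_that("injected coupling ratios are recovered within 0.05", {
  for (c_in in c(0.1, 0.2, 0.3)) {
    ms <- cervrom:::default_movements()
    ms[[3]] <- movement_spec("left_lateral", 40,
                             coupling = c(left_rotation = c_in))
    sim <- simulate_protocol(protocol_config(movements = ms, seed = round(100 * c_in)))
    fit <- analyze_session(sim$stream)
    i <- which(fit$episodes$label == "left_lateral")
    cr <- fit$compensations[[i]]
    got <- cr$offplane[cr$offplane$channel == "rotation", ]
    # left rotation carries a negative sign; ratio against a positive
    # primary peak is therefore negative
    expect_lt(abs(got$coupling_ratio - (-c_in)), 0.05)
    expect_lt(got$peak_signed_deg, 0)
    if (c_in >= 0.2) expect_length(grep("co-movement: rotation", cr$flags), 1L)
  }
})

test_that("norm exceedance is flagged against configured limits only", {
  f <- rig_fit("flexion", 55)
  cr <- detect_compensations(f$episodes[1, ], f$angles,
                             norms = normative_ranges(flexion = 50))
  expect_length(grep("norm exceedance", cr$flags), 1L)
  cr2 <- detect_compensations(f$episodes[1, ], f$angles,
                              norms = normative_ranges(flexion = 60))
  expect_length(grep("norm exceedance", cr2$flags), 0L)
  expect_error(normative_ranges(flexion = -10))
  expect_error(normative_ranges(shrug = 10))
})

test_that("session summaries aggregate min/max/mean per movement", {
  mk <- function(rom) data.frame(label = "flexion", rom_signed_deg = rom,
                                 duration_s = 3)
  one <- summarize_sessions(list(mk(34)))
  expect_equal(one$per_movement$min_deg, 34)
  expect_equal(one$per_movement$max_deg, 34)
  expect_equal(one$per_movement$mean_deg, 34)

  three <- summarize_sessions(list(mk(30), mk(40), mk(50)))
  expect_equal(unlist(three$per_movement[, c("min_deg", "max_deg", "mean_deg")],
                      use.names = FALSE), c(30, 50, 40))
  expect_true(with(three$per_movement, min_deg <= mean_deg && mean_deg <= max_deg))

  expect_warning(summarize_sessions(list(mk(30), mk(-30))), "sign convention")
  expect_error(summarize_sessions(list()), "no sessions")
})

test_that("summary of concatenated sessions equals direct aggregation", {
  sessions <- lapply(1:3, function(s) {
    sim <- simulate_protocol(protocol_config(seed = s))
    analyze_session(sim$stream)$rom
  })
  smry <- summarize_sessions(sessions)
  all_rows <- do.call(rbind, sessions)
  for (i in seq_len(nrow(smry$per_movement))) {
    r <- all_rows[all_rows$label == smry$per_movement$movement[i], ]
    expect_equal(smry$per_movement$min_deg[i], min(r$rom_signed_deg))
    expect_equal(smry$per_movement$max_deg[i], max(r$rom_signed_deg))
    expect_equal(smry$per_movement$mean_deg[i], mean(r$rom_signed_deg))
  }
})

test_that("commanded peaks are recovered within 1 degree at 0.5 degree noise over 20 seeds", {
  worst <- 0
  for (seed in 1:20) {
    sim <- simulate_protocol(protocol_config(seed = seed, noise_sd_deg = 0.5))
    fit <- analyze_session(sim$stream)
    tr <- sim$truth$episodes
    m <- merge(tr, fit$rom, by = "label")
    expect_equal(nrow(m), 6L)
    worst <- max(worst, abs(abs(m$rom_signed_deg) - abs(m$peak_signed_deg)))
  }
  expect_lt(worst, 1)
})

test_that("between-session comparison returns per-movement deltas and validates sets", {
  sim <- simulate_protocol(protocol_config(seed = 30, noise_sd_deg = 0))
  s1 <- summary(analyze_session(sim$stream))
  expect_true(all(compare_sessions(s1, s1)$rom_delta_deg == 0))
  expect_true(all(compare_sessions(s1, s1)$duration_delta_s == 0))

  ms <- cervrom:::default_movements()
  ms[[1]] <- movement_spec("flexion", ms[[1]]$peak_deg + 5)
  sim2 <- simulate_protocol(protocol_config(movements = ms, seed = 30,
                                            noise_sd_deg = 0))
  s2 <- summary(analyze_session(sim2$stream))
  d <- compare_sessions(s1, s2)
  expect_equal(d$rom_delta_deg[d$movement == "flexion"], 5, tolerance = 0.2)
  expect_true(all(abs(d$rom_delta_deg[d$movement != "flexion"]) < 0.2))

  s3 <- s1; s3$per_movement <- s3$per_movement[-1, ]
  expect_error(compare_sessions(s1, s3), "different movement sets")
})
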