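test_that("archives have the programmed sampling rates", {
  s <- small_archive(n_days = 7)
  expect_equal(nrow(s$archive$depth), 7 * 1440)   # 1-min depth
  expect_equal(nrow(s$archive$temp), 7 * 144)     # 10-min temperature
  expect_equal(s$archive$meta$depth_interval_s, 60)
  expect_equal(s$archive$meta$temp_interval_s, 600)
})

test_that("resting depth equals seabed depth when tide and noise vanish", {
  env <- flat_env(depth_m = 40)
  env$tide_amp_m[] <- 0
  tr <- simulate_track(env, 3, mid_cell(env), D_res = 0, D_mig = 0,
                       seed = 1)
  arc <- record_tag(tr, env, seed = 2, depth_noise_sd = 0)
  rs <- arc$meta$rest_start_min[2]; dur <- arc$meta$rest_dur_min[2]
  rest_idx <- 1440 + (rs:(rs + dur - 1)) + 1
  expect_equal(arc$depth$depth_m[rest_idx], rep(40, dur))
})

test_that("recorded depth never exceeds seabed + tide range + noise bound", {
  s <- small_archive(n_days = 8)
  rc <- bassgeo:::cell_rc(s$env, s$track$cell)
  bound <- s$env$bathy_m[rc] + s$env$tide_amp_m[rc] +
    3 * s$archive$meta$depth_noise_sd
  daymax <- tapply(s$archive$depth$depth_m, s$archive$depth$day, max)
  expect_true(all(daymax <= bound + 1e-9))
  expect_true(all(s$archive$depth$depth_m >= 0))
})

test_that("a noiseless resting window refits to the cell's amp and phase", {
  env <- flat_env(depth_m = 50)
  tr <- simulate_track(env, 3, mid_cell(env), D_res = 0, D_mig = 0,
                       seed = 3)
  arc <- record_tag(tr, env, seed = 4, depth_noise_sd = 0)
  rc <- bassgeo:::cell_rc(env, tr$cell[1])
  tw <- detect_tidal_windows(arc, quiescence_sd_m = 0.05)
  expect_gt(nrow(tw), 0)
  # independent oracle: direct least squares on the known resting span
  rs <- arc$meta$rest_start_min[1]; dur <- arc$meta$rest_dur_min[1]
  idx <- (rs:(rs + dur - 1)) + 1
  o <- bassgeo:::fit_sinusoid(as.numeric(arc$depth$time[idx]),
                              arc$depth$depth_m[idx])
  expect_equal(tw$amplitude_m[1], o$amplitude_m, tolerance = 1e-6)
  expect_equal(env$tide_amp_m[rc], o$amplitude_m, tolerance = 1e-6)
  dphi <- bassgeo:::wrap_angle(tw$phase_rad[1] - env$tide_phase_rad[rc])
  expect_lt(abs(dphi), 1e-4)
})

test_that("event injection matches its contracts", {
  env <- flat_env(depth_m = 45, n_days = 40)
  tr <- simulate_track(env, 35, mid_cell(env), seed = 5)
  arc <- record_tag(tr, env, seed = 6)

  # premature detachment: everything after the event day floats
  prem <- inject_event(arc, list(kind = "premature_detachment",
                                 event_day = 12, drift_days = 5),
                       env, tr, seed = 7)
  after <- prem$depth$depth_m[prem$depth$day > 12]
  expect_true(all(after <= 1))
  expect_equal(max(prem$depth$day), 17)  # float day + drift
  # samples before the event day are untouched
  n_pre <- sum(arc$depth$day < 12)
  expect_identical(prem$depth$depth_m[1:n_pre], arc$depth$depth_m[1:n_pre])

  # predation: supra-threshold span lasts stomach_days (Table-1 style
  # scenario with 10.36 days in the predator's stomach)
  pred <- inject_event(arc, list(kind = "predation", event_day = 5,
                                 stomach_days = 10.36, drift_days = 3),
                       env, tr, seed = 8)
  hot <- pred$temp$temp_c > 35
  span <- (max(as.numeric(pred$temp$time[hot])) -
             min(as.numeric(pred$temp$time[hot])) + 600) / 86400
  expect_lt(abs(span - 10.36), 0.05)
  expect_true(all(pred$temp$temp_c[hot] >= 36))

  # capture + discard: the event day's temperature range exceeds every
  # earlier day's range (brute-force daily scan)
  cap <- inject_event(arc, list(kind = "capture_discard", event_day = 30,
                                drift_days = 2), env, tr, seed = 9)
  rng <- tapply(cap$temp$temp_c, cap$temp$day, function(x) diff(range(x)))
  expect_true(rng[["30"]] > max(rng[as.character(1:29)]))

  # inconsistent events are rejected
  expect_error(inject_event(arc, list(kind = "capture_discard",
                                      event_day = 10, stomach_days = 2),
                            env, tr, seed = 1), "stomach")
  expect_error(inject_event(arc, list(kind = "predation", event_day = 10),
                            env, tr, seed = 1), "stomach")
})
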