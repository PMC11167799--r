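make_fate_setup <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      env <- flat_env(depth_m = 45, n_days = 50, nx = 15, ny = 15)
      tr <- simulate_track(env, 45, mid_cell(env), seed = 21)
      arc <- record_tag(tr, env, seed = 22)
      profs <- lapply(1:3, function(i) {
        t2 <- simulate_track(env, 45, mid_cell(env), seed = 30 + i)
        behaviour_profile(record_tag(t2, env, seed = 40 + i))
      })
      cache <<- list(env = env, track = tr, archive = arc,
                     baseline = build_baseline(profs))
    }
    cache
  }
})

test_that("float-up detection finds the terminal surface span", {
  s <- make_fate_setup()
  prem <- inject_event(s$archive, list(kind = "premature_detachment",
                                       event_day = 20, drift_days = 6),
                       s$env, s$track, seed = 1)
  fl <- detect_floatup(prem)
  expect_equal(fl$floatup_day, 20)
  expect_false(fl$never_attached)
  # fishery recovery at depth: no float phase
  fish <- inject_event(s$archive, list(kind = "fishery_recovery",
                                       event_day = 30),
                       s$env, s$track, seed = 2)
  expect_null(detect_floatup(fish))
})

test_that("a short surface bout does not trigger float-up", {
  s <- make_fate_setup()
  arc <- inject_event(s$archive, list(kind = "premature_detachment",
                                      event_day = 40, drift_days = 4),
                      s$env, s$track, seed = 3)
  # inject a 2-h surface bout on day 10
  bout <- which(arc$depth$day == 10)[300 + (1:120)]
  arc$depth$depth_m[bout] <- 0.3
  fl <- detect_floatup(arc)
  expect_equal(fl$floatup_day, 40)
  # brute-force oracle at the sample level: the first sample from which
  # depth stays <= tol to the end for >= 24 h marks the float-up day
  n <- nrow(arc$depth)
  ok <- sapply(seq_len(n), function(i)
    all(arc$depth$depth_m[i:n] <= 1) &&
      (as.numeric(arc$depth$time[n]) -
         as.numeric(arc$depth$time[i])) >= 24 * 3600)
  expect_equal(fl$floatup_day, arc$depth$day[which(ok)[1]])
})

test_that("behaviour profiles count seabed and surface time per day", {
  day1 <- as.POSIXct("2015-01-01", tz = "UTC") + (0:1439) * 60
  const <- structure(list(depth = data.frame(time = day1, depth_m = 40,
                                             day = 1L),
                          temp = data.frame()), class = "tag_archive")
  p <- behaviour_profile(const)
  expect_equal(p$seabed_fraction, 1)
  expect_equal(p$surface_fraction, 0)
  # 2 m constant: within 5 m of the surface AND within 20% of the 2 m
  # daily max -- the shallow degenerate overlap
  shallow <- const; shallow$depth$depth_m <- 2
  p2 <- behaviour_profile(shallow)
  expect_equal(p2$seabed_fraction, 1)
  expect_equal(p2$surface_fraction, 1)
  # half the day at 50 m, half at 3 m: counting oracle gives 0.5 / 0.5
  half <- const; half$depth$depth_m <- rep(c(50, 3), each = 720)
  p3 <- behaviour_profile(half)
  expect_equal(p3$seabed_fraction, 0.5)
  expect_equal(p3$surface_fraction, 0.5)
})

test_that("fates are classified from their injected signatures", {
  s <- make_fate_setup()
  pred <- inject_event(s$archive, list(kind = "predation", event_day = 15,
                                       stomach_days = 2.0, drift_days = 4),
                       s$env, s$track, seed = 4)
  rep <- classify_fate(pred, s$baseline)
  expect_equal(rep$fate, "predated")
  expect_lt(abs(rep$stomach_days - 2.0), 0.1)
  expect_equal(rep$drift_days, 4)

  # Table-1 style scenario: 0.84 days in a predator's stomach
  pr2 <- inject_event(s$archive, list(kind = "predation", event_day = 25,
                                      stomach_days = 0.84, drift_days = 2),
                      s$env, s$track, seed = 5)
  rep2 <- classify_fate(pr2, s$baseline)
  expect_equal(rep2$fate, "predated")
  expect_lt(abs(rep2$stomach_days - 0.84), 0.1)

  cap <- inject_event(s$archive, list(kind = "capture_discard",
                                      event_day = 18, drift_days = 3),
                      s$env, s$track, seed = 6)
  expect_equal(classify_fate(cap, s$baseline)$fate, "caught_discarded")

  prem <- inject_event(s$archive, list(kind = "premature_detachment",
                                       event_day = 22, drift_days = 5),
                       s$env, s$track, seed = 7)
  rp <- classify_fate(prem, s$baseline)
  expect_equal(rp$fate, "premature")
  expect_equal(rp$drift_days, 5)

  # no temperature channel: only float timing, label unknown
  mute <- prem; mute$temp <- mute$temp[0, ]
  expect_equal(classify_fate(mute, s$baseline)$fate, "unknown")
})

test_that("classification is invariant to finer temperature resampling", {
  s <- make_fate_setup()
  pred <- inject_event(s$archive, list(kind = "predation", event_day = 15,
                                       stomach_days = 1.5, drift_days = 3),
                       s$env, s$track, seed = 8)
  lab1 <- classify_fate(pred, s$baseline)
  # resample the temperature channel to 5-min by interpolation
  t5 <- seq(min(as.numeric(pred$temp$time)), max(as.numeric(pred$temp$time)),
            by = 300)
  fine <- pred
  fine$temp <- data.frame(
    time = as.POSIXct(t5, origin = "1970-01-01", tz = "UTC"),
    temp_c = approx(as.numeric(pred$temp$time), pred$temp$temp_c,
                    xout = t5)$y,
    day = bassgeo:::day_index(as.POSIXct(t5, origin = "1970-01-01",
                                         tz = "UTC"),
                              pred$meta$start_date))
  fine$meta$temp_interval_s <- 300
  lab2 <- classify_fate(fine, s$baseline)
  expect_equal(lab2$fate, lab1$fate)
  expect_lt(abs(lab2$stomach_days - lab1$stomach_days), 0.05)
})
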