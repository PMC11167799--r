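test_that("bathymetric masking matches a brute-force cell scan", {
  env <- small_env(nx = 20, ny = 20)
  m <- bathymetry_mask(60, env)
  brute <- matrix(FALSE, env$ny, env$nx)
  for (r in 1:env$ny) for (cc in 1:env$nx)
    brute[r, cc] <- !env$land[r, cc] && !is.na(env$bathy_m[r, cc]) &&
      env$bathy_m[r, cc] >= 60
  expect_equal(as.vector(m), as.vector(brute))
  # vacuous constraint masks only land
  m0 <- bathymetry_mask(0, env)
  expect_equal(as.vector(m0), as.vector(env$sea))
  # contradiction on a flat 40 m sea: fallback relaxes in 5 m steps
  fe <- flat_env(depth_m = 40)
  mf <- bathymetry_mask(50, fe)
  expect_true(attr(mf, "fallback"))
  expect_true(any(mf))
  expect_equal(attr(mf, "relaxed_m"), 10)
})

test_that("tidal likelihood is a wrapped Gaussian match", {
  env <- small_env(nx = 10, ny = 10)
  rc <- c(5, 5)
  fit <- data.frame(amplitude_m = env$tide_amp_m[rc[1], rc[2]],
                    phase_rad = env$tide_phase_rad[rc[1], rc[2]])
  w <- tidal_likelihood(fit, env)
  expect_equal(w[rc[1], rc[2]], max(w))  # exact match is the argmax
  # phase mismatch of pi with sigma = pi/6 suppresses by exp(-18)
  env2 <- env
  env2$tide_amp_m[] <- 1
  env2$tide_phase_rad[] <- 0
  env2$tide_phase_rad[3, 3] <- pi
  w2 <- tidal_likelihood(data.frame(amplitude_m = 1, phase_rad = 0),
                         env2, sigma_amp_m = 0.3,
                         sigma_phase_rad = pi / 6)
  expect_equal(w2[3, 3] / w2[5, 5], exp(-18), tolerance = 1e-10)
  # random field: argmax equals exhaustive evaluation
  set.seed(2)
  env$tide_amp_m[] <- runif(100, 0, 3)
  env$tide_phase_rad[] <- runif(100, 0, 2 * pi)
  fit <- data.frame(amplitude_m = 1.2, phase_rad = 3.0)
  w3 <- tidal_likelihood(fit, env, 0.3, 0.25)
  brute <- exp(-(env$tide_amp_m - 1.2)^2 / (2 * 0.3^2) -
                 bassgeo:::wrap_angle(env$tide_phase_rad - 3.0)^2 /
                 (2 * 0.25^2))
  expect_equal(which.max(w3), which.max(brute))
  expect_error(tidal_likelihood(fit, env, 0, 0.2), "sigmas")
})

test_that("temperature likelihood multiplies per-sample Gaussians", {
  env <- flat_env(depth_m = 60, n_days = 4)
  # uniform field gives a flat surface
  env$sst_c[2, , ] <- 10
  for (l in seq_along(env$levels_m)) env$tdep_c[2, , , l] <- 9
  w <- temperature_likelihood(data.frame(depth_m = 30, temp_c = 9.5),
                              env, 2)
  expect_true(all(abs(w - 1) < 1e-12))
  # unique matching cell is the argmax
  env$tdep_c[2, 4, 7, ] <- 12
  w2 <- temperature_likelihood(data.frame(depth_m = 30, temp_c = 12),
                               env, 2)
  expect_equal(which(w2 == max(w2), arr.ind = TRUE)[1, ],
               c(row = 4, col = 7))
  # five samples on a stratified field equal the direct per-cell product
  env2 <- small_env(n_days = 6)
  set.seed(3)
  samples <- data.frame(depth_m = runif(5, 2, 80),
                        temp_c = runif(5, 7, 12))
  w3 <- temperature_likelihood(samples, env2, 3, sigma_t_c = 0.7)
  brute <- matrix(0, env2$ny, env2$nx)
  for (i in 1:5) {
    fld <- bassgeo:::env_temp_field(env2, 3, samples$depth_m[i], 5)
    brute <- brute - (samples$temp_c[i] - fld)^2 / (2 * 0.7^2)
  }
  brute[env2$land] <- -Inf
  brute <- exp(brute - max(brute[env2$sea]))
  brute[env2$land] <- 0
  expect_equal(w3, brute, tolerance = 1e-12)
})

test_that("endpoint anchors concentrate the stated mass", {
  env <- make_environment(nx = 101, ny = 101, seed = 1, style = "flat",
                          depth_m = 50, n_days = 2)
  ctr <- cbind(env$lon[51], env$lat[51])
  rel <- endpoint_anchor(env, ctr[1], ctr[2], "release")
  rel <- rel / sum(rel)
  expect_gt(rel[51, 51], 0.99)   # ~all mass in the release cell
  fsh <- endpoint_anchor(env, ctr[1], ctr[2], "fishery_recovery")
  fsh <- fsh / sum(fsh)
  ll <- bassgeo:::cell_lonlat(env, seq_len(101 * 101))
  d <- haversine_km(cbind(rep(ctr[1], nrow(ll)), rep(ctr[2], nrow(ll))), ll)
  # a 2-D Gaussian holds 1 - exp(-2) ~ 86% of its mass within 2 sd and
  # >98% within 3 sd; check both against direct summation
  expect_gt(sum(fsh[matrix(d <= 10, 101, 101)]), 0.80)
  expect_gt(sum(fsh[matrix(d <= 15, 101, 101)]), 0.95)
  # beach anchors decay with the documented 200 km sd
  bch <- endpoint_anchor(env, ctr[1], ctr[2], "beach_recovery")
  d_off <- haversine_km(ctr, c(env$lon[91], env$lat[51]))
  expect_equal(bch[51, 91] / bch[51, 51], exp(-d_off^2 / (2 * 200^2)),
               tolerance = 1e-6)
  expect_error(endpoint_anchor(env, 50, 50, "release"), "off-grid")
})

test_that("daily layers combine, renormalise and fall back in order", {
  env <- small_env(nx = 8, ny = 8, n_days = 5)
  obs <- structure(list(day = 2, max_depth_m = 30,
                        temp_samples = data.frame(depth_m = numeric(),
                                                  temp_c = numeric()),
                        tidal_fits = data.frame()), class = "daily_obs")
  # only the mask: uniform over unmasked cells
  dl <- build_daily_likelihood(obs, env)
  msk <- bathymetry_mask(30, env)
  expect_equal(dl$w[msk], rep(1 / sum(msk), sum(msk)))
  expect_equal(sum(dl$w), 1)
  expect_true(all(dl$w[env$land] == 0))
  # random layers multiply like the direct product (order-invariant)
  set.seed(4)
  obs2 <- summarize_day(small_archive(seed = 9, n_days = 3)$archive, 2)
  envA <- small_env(seed = 9, n_days = 5)
  dl2 <- build_daily_likelihood(obs2, envA, env_day = 2)
  mask <- bathymetry_mask(obs2$max_depth_m, envA)
  parts <- list(matrix(as.numeric(mask), envA$ny, envA$nx))
  if (nrow(obs2$tidal_fits))
    parts <- c(parts, list(tidal_likelihood(obs2$tidal_fits, envA)))
  if (nrow(obs2$temp_samples))
    parts <- c(parts, list(temperature_likelihood(obs2$temp_samples,
                                                  envA, 2)))
  for (perm in list(parts, rev(parts))) {
    brute <- Reduce(`*`, perm)
    brute <- brute / sum(brute)
    expect_equal(dl2$w, brute, tolerance = 1e-12)
  }
  # impossible observations walk down the fallback ladder
  fe <- flat_env(depth_m = 40, n_days = 4)
  obs3 <- structure(list(day = 1, max_depth_m = 80,
                         temp_samples = data.frame(),
                         tidal_fits = data.frame()), class = "daily_obs")
  dl3 <- build_daily_likelihood(obs3, fe)
  expect_equal(sum(dl3$w), 1)
  expect_true(dl3$fallback > 0 || dl3$mask_relaxed)
})
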