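test_that("the diffusion kernel has the right moments and support", {
  # zero diffusivity: identity on any surface
  env <- flat_env(nx = 9, ny = 9)
  k0 <- diffusion_kernel(env, 0)
  set.seed(1)
  M <- matrix(runif(81), 9, 9)
  expect_equal(apply_kernel(k0, M), M)
  # point mass on open sea: per-axis second moment ~ 2 D dt
  big <- make_environment(nx = 41, ny = 41, seed = 1, style = "flat",
                          depth_m = 50, n_days = 2)
  kd <- diffusion_kernel(big, 50, 1)
  pm <- matrix(0, 41, 41); pm[21, 21] <- 1
  out <- apply_kernel(kd, pm)
  expect_equal(sum(out), 1, tolerance = 1e-12)
  xs <- (col(out) - 21) * big$cell_km
  ys <- (row(out) - 21) * big$cell_km
  expect_lt(abs(sum(out * xs^2) - 2 * 50) / (2 * 50), 0.05)
  expect_lt(abs(sum(out * ys^2) - 2 * 50) / (2 * 50), 0.05)
  # beside land: no leakage, mass conserved
  env2 <- small_env(nx = 9, ny = 9)
  kl <- diffusion_kernel(env2, 80)
  pm2 <- matrix(0, 9, 9); pm2[2, 5] <- 1   # adjacent to the coast row
  out2 <- apply_kernel(kl, pm2)
  expect_equal(sum(out2), 1, tolerance = 1e-12)
  expect_true(all(out2[env2$land] == 0))
  expect_error(diffusion_kernel(env2, -1), "nonnegative")
})

test_that("smoothing matches exhaustive enumeration on small instances", {
  for (sd in 1:3) {
    set.seed(sd)
    env <- make_environment(nx = 3, ny = 3, seed = sd,
                            style = if (sd == 1) "flat" else
                              "coastal_gradient", n_days = 5)
    m <- behaviour_model(runif(1, 0, 20), runif(1, 30, 200),
                         matrix(c(0.8, 0.2, 0.3, 0.7), 2, byrow = TRUE))
    lik <- array(runif(9 * 4, 0.01, 1), dim = c(3, 3, 4))
    lik[cbind(rep(which(env$land), 4), rep(1:4, each = sum(env$land)))] <- 0
    for (t in 1:4) lik[, , t][env$land] <- 0
    init <- matrix(as.numeric(env$sea), 3, 3); init <- init / sum(init)
    o <- oracle_enumerate(env, m, lik, init, c(0.5, 0.5))
    post <- forward_backward(lik, env, m, init = init)
    expect_equal(post$loglik, log(o$likelihood), tolerance = 1e-12)
    for (t in 1:4)
      expect_equal(c(post$smoothed[, , t]), o$marginals[, t],
                   tolerance = 1e-10)
    vit <- viterbi(lik, env, m, init = init)
    vj <- vit$cell + (match(vit$behaviour,
                            c("resident", "migratory")) - 1) * 9
    expect_equal(vj, unname(o$map_path))
    expect_equal(attr(vit, "logprob"), log(o$map_prob), tolerance = 1e-10)
  }
})

test_that("a degenerate bridge pins the posterior to the anchor cell", {
  env <- flat_env(nx = 7, ny = 7, n_days = 8)
  nd <- 6
  anchor_cell <- bassgeo:::rc_cell(env, 4, 4)
  lik <- array(1 / 49, dim = c(7, 7, nd))
  delta <- matrix(1e-12, 7, 7); delta[4, 4] <- 1
  lik[, , 1] <- delta; lik[, , nd] <- delta
  m <- behaviour_model(0, 0, diag(2))
  post <- forward_backward(lik, env, m)
  for (t in 1:nd)
    expect_gt(post$smoothed[4, 4, t], 1 - 1e-6)
})

test_that("an uninformative day changes nothing once diffusion mixes fully", {
  env <- flat_env(nx = 5, ny = 5, n_days = 8)
  set.seed(2)
  lik3 <- array(runif(25 * 3, 0.05, 1), dim = c(5, 5, 3))
  m <- behaviour_model(2e4, 2e4)   # sd >> grid: one step mixes fully
  post3 <- forward_backward(lik3, env, m)
  lik4 <- array(0, dim = c(5, 5, 4))
  lik4[, , c(1, 2, 4)] <- lik3
  lik4[, , 3] <- 1 / 25
  post4 <- forward_backward(lik4, env, m)
  for (t in 1:2)
    expect_equal(post3$smoothed[, , t], post4$smoothed[, , t],
                 tolerance = 0.02)
  expect_equal(post3$smoothed[, , 3], post4$smoothed[, , 4],
               tolerance = 0.02)
})

test_that("estimation improves the likelihood and flags collapsed models", {
  env <- small_env(nx = 12, ny = 12, n_days = 42)
  tr <- simulate_track(env, 40, mid_cell(env), D_res = 30, D_mig = 30,
                       seed = 12,
                       behaviour_seq = rep(c("resident", "migratory"), 20))
  arc <- record_tag(tr, env, seed = 13)
  st <- build_likelihood_stack(arc, env,
                               config = likelihood_config(mask_slack_m = 3))
  init <- behaviour_model(10, 60)
  est <- estimate_parameters(st, env, init = init, nstart = 1, maxit = 120,
                             reltol = 1e-4, seed = 1)
  expect_gte(attr(est, "loglik"), forward_loglik(st, env, init))
  expect_lte(est$D_res, est$D_mig)
  # data generated with equal diffusivities: estimates collapse
  expect_lt(est$D_mig / est$D_res, 2)
  expect_true(attr(est, "unidentifiable_switch"))
})

test_that("mode positions summarise the posterior with HPD areas", {
  env <- flat_env(nx = 6, ny = 6, n_days = 4)
  sm <- array(0, dim = c(6, 6, 3))
  sm[, , 1] <- 0; sm[3, 4, 1] <- 1                      # delta
  sm[, , 2] <- 1 / 36                                   # uniform
  sm[, , 3] <- 0; sm[2, 2, 3] <- 0.6; sm[5, 5, 3] <- 0.4  # bimodal
  post <- structure(list(smoothed = sm, days = 1:3), class = "posterior_track")
  mp <- mode_positions(post, env)
  expect_equal(mp$hpd_area_km2[1], 5.2^2)               # one cell
  expect_equal(mp$hpd_area_km2[2], ceiling(0.95 * 36) * 5.2^2)
  expect_equal(c(mp$row[3], mp$col[3]), c(2, 2))        # heavier mode wins
  expect_false(mp$tie[1])
  expect_true(mp$tie[2])                                # uniform slice ties
})

test_that("single-support likelihoods force the Viterbi path", {
  env <- flat_env(nx = 6, ny = 6, n_days = 6)
  cells <- c(8, 9, 15, 21, 22)
  lik <- array(0, dim = c(6, 6, 5))
  for (t in 1:5) lik[, , t][cells[t]] <- 1
  m <- behaviour_model(10, 80)
  vit <- viterbi(lik, env, m)
  expect_equal(vit$cell, cells)
  # MAP dominance over the daily-mode sequence
  post <- forward_backward(lik, env, m)
  mp <- mode_positions(post, env)
  beh <- ifelse(post$behaviour_prob[, 1] >= 0.5, 1, 2)
  expect_gte(attr(vit, "logprob") + 1e-9,
             path_logprob(lik, env, m, mp$cell, beh))
})
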