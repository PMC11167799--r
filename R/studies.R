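#' Standard synthetic migration scenario
#'
#' The package's reference test bed: a 60 x 60 grid of 5.2 km cells
#' with a coastal gradient, 180 days starting 1 October, and a scripted
#' seasonal offshore migration (resident inshore for 60 days, migratory
#' for 60 days, resident again for the final 60), recorded as a full
#' tag archive. Sizes can be scaled down for quick checks.
#'
#' @param seed integer seed.
#' @param nx,ny,n_days scenario size.
#' @param fish_id archive identifier.
#' @return list: `env`, `track`, `archive`.
#' @export
standard_scenario <- function(seed, nx = 60, ny = 60, n_days = 180,
                              fish_id = "STD001") {
  env <- make_environment(nx = nx, ny = ny, seed = seed,
                          style = "coastal_gradient",
                          n_days = n_days + 1,
                          start_date = "2015-10-01")
  third <- n_days %/% 3
  beh <- c(rep("resident", third), rep("migratory", third),
           rep("resident", n_days - 2 * third))
  release_cell <- rc_cell(env, 3, round(nx / 2))
  track <- simulate_track(env, n_days, release_cell,
                          D_res = 5, D_mig = 120,
                          seed = seed, start_date = "2015-10-01",
                          behaviour_seq = beh)
  archive <- record_tag(track, env, seed = seed + 1, fish_id = fish_id)
  list(env = env, track = track, archive = archive)
}

#' Diffusivity recovery study
#'
#' Simulates fish with known movement parameters (truth
#' `D_res = 5`, `D_mig = 120` km^2/day, sticky behaviour switching),
#' records full tag archives, builds tidal + temperature likelihood
#' stacks and re-estimates the model by maximum likelihood, reporting
#' the per-fish estimates and relative errors.
#'
#' @param n_fish number of simulated fish.
#' @param n_days track length (days).
#' @param seed integer seed.
#' @param nx,ny grid size.
#' @param D_res,D_mig true diffusivities (km^2/day).
#' @param nstart Nelder-Mead starts per fish.
#' @return data.frame with one row per fish: estimates, log-likelihood
#'   and relative errors.
#' @export
study_parameter_recovery <- function(n_fish = 20, n_days = 300, seed = 1,
                                     nx = 40, ny = 40,
                                     D_res = 5, D_mig = 120, nstart = 3) {
  env <- make_environment(nx = nx, ny = ny, seed = seed,
                          style = "coastal_gradient",
                          n_days = n_days + 1)
  sw <- matrix(c(0.95, 0.05, 0.10, 0.90), 2, 2, byrow = TRUE)
  release_cell <- rc_cell(env, round(ny / 2), round(nx / 2))
  cfg <- likelihood_config(mask_slack_m = 3)
  out <- vector("list", n_fish)
  for (i in seq_len(n_fish)) {
    fseed <- seed * 1000L + i
    track <- simulate_track(env, n_days, release_cell,
                            D_res = D_res, D_mig = D_mig,
                            switch_matrix = sw, seed = fseed)
    archive <- record_tag(track, env, seed = fseed + 1,
                          fish_id = sprintf("PR%03d", i))
    stack <- build_likelihood_stack(archive, env, config = cfg)
    est <- estimate_parameters(stack, env, nstart = nstart, seed = fseed)
    out[[i]] <- data.frame(
      fish = i, D_res_hat = est$D_res, D_mig_hat = est$D_mig,
      loglik = attr(est, "loglik"),
      rel_err_res = abs(est$D_res - D_res) / D_res,
      rel_err_mig = abs(est$D_mig - D_mig) / D_mig,
      factor_res = pmax(est$D_res / D_res, D_res / est$D_res),
      factor_mig = pmax(est$D_mig / D_mig, D_mig / est$D_mig))
  }
  res <- do.call(rbind, out)
  attr(res, "truth") <- c(D_res = D_res, D_mig = D_mig)
  res
}

#' Track recovery study
#'
#' Runs the standard seasonal-migration scenario for several fish,
#' geolocates each with the full likelihood stack and with an
#' uninformative (uniform) stack that keeps only the endpoint anchors,
#' and reports daily mode-position errors in grid cells against the
#' simulated truth.
#'
#' @param seed integer seed.
#' @param n_fish number of scenario fish.
#' @param nx,ny,n_days scenario size (see [standard_scenario()]).
#' @return list: per-day errors, `median_cells` (informative stack),
#'   `median_cells_uniform` (anchor-only control).
#' @export
study_track_recovery <- function(seed = 1, n_fish = 3, nx = 60, ny = 60,
                                 n_days = 180) {
  errs <- list(); errs_u <- list()
  cfg <- likelihood_config(mask_slack_m = 3)
  for (i in seq_len(n_fish)) {
    sc <- standard_scenario(seed * 1000L + 37L * i, nx = nx, ny = ny,
                            n_days = n_days,
                            fish_id = sprintf("TR%03d", i))
    stack <- build_likelihood_stack(sc$archive, sc$env, config = cfg)
    est <- estimate_parameters(stack, sc$env, nstart = 1,
                               seed = seed + i)
    post <- forward_backward(stack, sc$env, est)
    modes <- mode_positions(post, sc$env)

    uarr <- stack$arr
    sea_u <- matrix(as.numeric(sc$env$sea), sc$env$ny, sc$env$nx)
    for (t in seq_len(dim(uarr)[3]))
      uarr[, , t] <- sea_u / sum(sea_u)
    uarr[, , 1] <- stack$arr[, , 1]          # keep endpoint anchors
    uarr[, , dim(uarr)[3]] <- stack$arr[, , dim(uarr)[3]]
    ustack <- structure(list(arr = uarr, days = stack$days),
                        class = "lik_stack")
    post_u <- forward_backward(ustack, sc$env, est)
    modes_u <- mode_positions(post_u, sc$env)

    tr <- sc$track[match(modes$day, sc$track$day), ]
    errs[[i]] <- sqrt((modes$row - tr$row)^2 + (modes$col - tr$col)^2)
    tru <- sc$track[match(modes_u$day, sc$track$day), ]
    errs_u[[i]] <- sqrt((modes_u$row - tru$row)^2 + (modes_u$col - tru$col)^2)
  }
  e <- unlist(errs); eu <- unlist(errs_u)
  list(errors_cells = e, errors_cells_uniform = eu,
       median_cells = median(e), median_cells_uniform = median(eu))
}

#' Fate classification study
#'
#' Generates archives with injected events of the three beached fates
#' (predation, capture-and-discard, premature detachment) at separable
#' parameters, classifies each against a clean-archive baseline, and
#' tallies agreement with the injected truth, including exactness of
#' the recovered drift duration.
#'
#' @param n_archives number of event archives (balanced across fates).
#' @param seed integer seed.
#' @param n_days archive length before truncation.
#' @param nx,ny flat-environment grid size.
#' @return list: `confusion` (truth x label table), `accuracy`,
#'   `drift_exact` (fraction of archives whose recovered drift matches
#'   the injected value), `details` data.frame.
#' @export
study_fate_classification <- function(n_archives = 200, seed = 11,
                                      n_days = 35, nx = 25, ny = 25) {
  env <- make_environment(nx = nx, ny = ny, seed = seed, style = "flat",
                          depth_m = 45, n_days = n_days + 1)
  release_cell <- rc_cell(env, round(ny / 2), round(nx / 2))
  kinds <- rep(c("predation", "capture_discard", "premature_detachment"),
               length.out = n_archives)
  set.seed(seed)
  ev_day <- sample(10:20, n_archives, replace = TRUE)
  stomach <- round(runif(n_archives, 0.5, 3), 2)
  drift <- sample(1:8, n_archives, replace = TRUE)

  # baseline from clean reference archives
  profs <- lapply(1:5, function(i) {
    tr <- simulate_track(env, n_days, release_cell, seed = seed * 100 + i)
    behaviour_profile(record_tag(tr, env, seed = seed * 100 + i + 50))
  })
  baseline <- build_baseline(profs)

  lab_map <- c(predation = "predated", capture_discard = "caught_discarded",
               premature_detachment = "premature")
  rows <- vector("list", n_archives)
  for (i in seq_len(n_archives)) {
    fseed <- seed * 10000L + i
    tr <- simulate_track(env, n_days, release_cell, seed = fseed)
    arc <- record_tag(tr, env, seed = fseed + 1,
                      fish_id = sprintf("FC%03d", i))
    ev <- list(kind = kinds[i], event_day = ev_day[i],
               drift_days = drift[i])
    if (kinds[i] == "predation") ev$stomach_days <- stomach[i]
    arc <- inject_event(arc, ev, env, tr, seed = fseed + 2)
    rep <- classify_fate(arc, baseline)
    rows[[i]] <- data.frame(
      truth = lab_map[[kinds[i]]], label = rep$fate,
      drift_true = drift[i],
      drift_hat = rep$drift_days,
      stomach_true = if (kinds[i] == "predation") stomach[i] else NA,
      stomach_hat = rep$stomach_days)
  }
  det <- do.call(rbind, rows)
  list(confusion = table(truth = det$truth, label = det$label),
       accuracy = mean(det$truth == det$label),
       drift_exact = mean(det$drift_true == det$drift_hat),
       details = det)
}
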