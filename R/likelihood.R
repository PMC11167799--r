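#' Default likelihood-layer configuration
#'
#' Gaussian widths and related knobs for the daily likelihood layers.
#' The tidal amplitude/phase widths and the temperature width fold
#' together field error and sensor error; the tidal phase width is the
#' phase equivalent of a 30-min timing error on the M2 constituent.
#'
#' @param sigma_amp_m tidal amplitude width (m).
#' @param sigma_phase_rad tidal phase width (rad).
#' @param sigma_t_c temperature width (deg C).
#' @param mask_slack_m slack subtracted from the observed maximum depth
#'   before bathymetric masking, to absorb tidal elevation above the
#'   seabed; 0 reproduces strict masking.
#' @param thin_temp_h keep at most one temperature sample per this many
#'   hours in the temperature layer (limits within-day dependence).
#' @param sst_max_depth samples shallower than this (m) match SST.
#' @param window_h,step_min,quiescence_sd_m tidal window detection, see
#'   [detect_tidal_windows()].
#' @return named list of settings.
#' @export
likelihood_config <- function(sigma_amp_m = 0.3,
                              sigma_phase_rad = 2 * pi * 0.5 / 12.42,
                              sigma_t_c = 0.7,
                              mask_slack_m = 0,
                              thin_temp_h = 1,
                              sst_max_depth = 5,
                              window_h = 3, step_min = 20,
                              quiescence_sd_m = 0.25) {
  list(sigma_amp_m = sigma_amp_m, sigma_phase_rad = sigma_phase_rad,
       sigma_t_c = sigma_t_c, mask_slack_m = mask_slack_m,
       thin_temp_h = thin_temp_h, sst_max_depth = sst_max_depth,
       window_h = window_h, step_min = step_min,
       quiescence_sd_m = quiescence_sd_m)
}

#' Summarise one day of a tag archive for geolocation
#'
#' Extracts the daily observations the likelihood layers use: maximum
#' recorded depth (1-min series), thinned (depth, temperature) pairs
#' from simultaneous samples, and tidal amplitude/phase fits from
#' resting windows.
#'
#' @param archive a `tag_archive`.
#' @param day day index.
#' @param tidal_windows optional precomputed [detect_tidal_windows()]
#'   output for the whole archive (computed on the fly otherwise).
#' @param config see [likelihood_config()].
#' @return a `daily_obs` list: day, max_depth_m, temp_samples
#'   (data.frame depth_m, temp_c), tidal_fits (data.frame).
#' @export
summarize_day <- function(archive, day, tidal_windows = NULL,
                          config = likelihood_config()) {
  dsub <- archive$depth[archive$depth$day == day, , drop = FALSE]
  tsub <- archive$temp[archive$temp$day == day, , drop = FALSE]
  if (is.null(tidal_windows)) {
    tidal_windows <- detect_tidal_windows(
      archive, window_h = config$window_h, step_min = config$step_min,
      quiescence_sd_m = config$quiescence_sd_m)
  }
  fits <- tidal_windows[tidal_windows$day == day, , drop = FALSE]
  temp_samples <- data.frame(depth_m = numeric(), temp_c = numeric())
  if (nrow(tsub)) {
    m <- match(as.numeric(tsub$time), as.numeric(dsub$time))
    keep <- !is.na(m)
    temp_samples <- data.frame(depth_m = dsub$depth_m[m[keep]],
                               temp_c = tsub$temp_c[keep])
    if (nrow(temp_samples)) {
      step <- max(1L, as.integer(config$thin_temp_h * 3600 /
                                   archive$meta$temp_interval_s))
      temp_samples <- temp_samples[seq(1, nrow(temp_samples), by = step), ,
                                   drop = FALSE]
    }
  }
  structure(list(day = day,
                 max_depth_m = if (nrow(dsub)) max(dsub$depth_m) else NA_real_,
                 temp_samples = temp_samples,
                 tidal_fits = fits),
            class = "daily_obs")
}

#' Bathymetric mask for one day
#'
#' Masks out (weight 0) cells whose seabed is shallower than the day's
#' maximum recorded depth; land is always masked. If every sea cell is
#' masked the constraint is relaxed in 5 m steps until some cell
#' survives, and the relaxation is flagged.
#'
#' @param max_depth_m the day's maximum recorded depth (m; `NA` masks
#'   only land).
#' @param env an `env_grid`.
#' @param slack_m subtracted from `max_depth_m` before comparison.
#' @return logical matrix (TRUE = allowed), with attributes
#'   `relaxed_m` (metres of relaxation applied) and `fallback`.
#' @export
bathymetry_mask <- function(max_depth_m, env, slack_m = 0) {
  if (is.na(max_depth_m)) {
    m <- env$sea
    attr(m, "relaxed_m") <- 0; attr(m, "fallback") <- FALSE
    return(m)
  }
  need <- max(0, max_depth_m - slack_m)
  relax <- 0
  repeat {
    m <- env$sea & !is.na(env$bathy_m) & env$bathy_m >= (need - relax)
    m[is.na(m)] <- FALSE
    if (any(m) || need - relax <= 0) break
    relax <- relax + 5
  }
  if (!any(m)) m <- env$sea
  attr(m, "relaxed_m") <- relax
  attr(m, "fallback") <- relax > 0
  m
}

#' Tidal likelihood surface
#'
#' Gaussian match of fitted tidal amplitude/phase to the grid's M2
#' fields: `w ~ exp(-dA^2 / 2 sA^2) * exp(-dphi^2 / 2 sphi^2)` with the
#' phase difference wrapped to (-pi, pi]. Multiple fits in one day
#' multiply.
#'
#' @param fits data.frame with `amplitude_m`, `phase_rad` (one row per
#'   accepted resting window).
#' @param env an `env_grid`.
#' @param sigma_amp_m,sigma_phase_rad Gaussian widths.
#' @return weight matrix (ny x nx), zero on land, max 1.
#' @export
tidal_likelihood <- function(fits, env, sigma_amp_m = 0.3,
                             sigma_phase_rad = 2 * pi * 0.5 / 12.42) {
  if (sigma_amp_m <= 0 || sigma_phase_rad <= 0) stop("sigmas must be > 0")
  logw <- matrix(0, env$ny, env$nx)
  for (i in seq_len(nrow(fits))) {
    da <- env$tide_amp_m - fits$amplitude_m[i]
    dp <- wrap_angle(env$tide_phase_rad - fits$phase_rad[i])
    logw <- logw - da^2 / (2 * sigma_amp_m^2) - dp^2 / (2 * sigma_phase_rad^2)
  }
  logw[env$land] <- -Inf
  w <- exp(logw - max(logw[env$sea]))
  w[env$land] <- 0
  w
}

#' Temperature-at-depth likelihood surface
#'
#' Per-cell Gaussian product over the day's (depth, temperature) pairs,
#' comparing recorded temperature with the environment temperature at
#' the corresponding depth in each cell (linear interpolation between
#' depth levels; samples deeper than a cell's seabed take the bottom
#' temperature; near-surface samples match SST).
#'
#' @param temp_samples data.frame with `depth_m`, `temp_c`.
#' @param env an `env_grid`.
#' @param day day index into the environment's daily fields.
#' @param sigma_t_c Gaussian width (deg C).
#' @param sst_max_depth samples at or above this depth match SST.
#' @return weight matrix (ny x nx), zero on land, max 1.
#' @export
temperature_likelihood <- function(temp_samples, env, day, sigma_t_c = 0.7,
                                   sst_max_depth = 5) {
  logw <- matrix(0, env$ny, env$nx)
  for (i in seq_len(nrow(temp_samples))) {
    fld <- env_temp_field(env, day, temp_samples$depth_m[i], sst_max_depth)
    logw <- logw - (temp_samples$temp_c[i] - fld)^2 / (2 * sigma_t_c^2)
  }
  logw[env$land] <- -Inf
  w <- exp(logw - max(logw[env$sea]))
  w[env$land] <- 0
  w
}

#' Release/recovery anchor surface
#'
#' Gaussian bump at a known endpoint. Release positions are treated as
#' near-exact (sd of a quarter cell); tags recovered by a fishing
#' vessel carry < 5 km error; beached tags may have drifted, so the
#' anchor is very wide (200 km).
#'
#' @param env an `env_grid`.
#' @param lon,lat anchor position (decimal degrees, on the grid).
#' @param kind `"release"`, `"fishery_recovery"` or `"beach_recovery"`.
#' @return weight matrix (ny x nx), zero on land, max 1.
#' @export
endpoint_anchor <- function(env, lon, lat,
                            kind = c("release", "fishery_recovery",
                                     "beach_recovery")) {
  kind <- match.arg(kind)
  if (lon < min(env$lon) - 1 || lon > max(env$lon) + 1 ||
      lat < min(env$lat) - 1 || lat > max(env$lat) + 1)
    stop("anchor location off-grid")
  sd_km <- switch(kind, release = env$cell_km / 4,
                  fishery_recovery = 5, beach_recovery = 200)
  ll <- cell_lonlat(env, seq_len(env$ny * env$nx))
  d <- haversine_km(cbind(rep(lon, nrow(ll)), rep(lat, nrow(ll))), ll)
  w <- matrix(exp(-d^2 / (2 * sd_km^2)), env$ny, env$nx)
  w[env$land] <- 0
  w / max(w)
}

#' Build one day's combined likelihood layer
#'
#' Elementwise product of the bathymetric mask, tidal layer,
#' temperature layer and any endpoint anchor, renormalised to sum to 1.
#' If the product is empty a staged fallback ladder is applied and
#' recorded: (1) drop the tidal layer, (2) double the temperature
#' width, (3) relax the bathymetric mask in 5 m steps (uniform over the
#' masked-in cells), (4) uniform over all sea cells.
#'
#' @param obs a `daily_obs` from [summarize_day()].
#' @param env an `env_grid`.
#' @param env_day day index into the environment fields.
#' @param anchor optional anchor surface (matrix) to multiply in.
#' @param config see [likelihood_config()].
#' @return a `daily_lik` list: `day`, `w` (ny x nx, sums to 1),
#'   `layers` (character vector applied), `fallback` (stage reached,
#'   0 = none).
#' @export
build_daily_likelihood <- function(obs, env, env_day = obs$day,
                                   anchor = NULL,
                                   config = likelihood_config()) {
  mask <- bathymetry_mask(obs$max_depth_m, env, config$mask_slack_m)
  has_tide <- nrow(obs$tidal_fits %||% data.frame()) > 0
  has_temp <- nrow(obs$temp_samples %||% data.frame()) > 0
  tid <- if (has_tide)
    tidal_likelihood(obs$tidal_fits, env, config$sigma_amp_m,
                     config$sigma_phase_rad)
  tmp <- if (has_temp)
    temperature_likelihood(obs$temp_samples, env, env_day,
                           config$sigma_t_c, config$sst_max_depth)

  compose <- function(use_tide, sigma_scale, mask_m) {
    w <- matrix(as.numeric(mask_m), env$ny, env$nx)
    if (use_tide && has_tide) w <- w * tid
    if (has_temp) {
      wt <- if (sigma_scale == 1) tmp else
        temperature_likelihood(obs$temp_samples, env, env_day,
                               config$sigma_t_c * sigma_scale,
                               config$sst_max_depth)
      w <- w * wt
    }
    if (!is.null(anchor)) w <- w * anchor
    w
  }

  stages <- list(
    list(tide = TRUE, scale = 1, stage = 0L),
    list(tide = FALSE, scale = 1, stage = 1L),
    list(tide = FALSE, scale = 2, stage = 2L)
  )
  w <- NULL; stage <- 0L
  for (s in stages) {
    w <- compose(s$tide, s$scale, mask)
    stage <- s$stage
    if (sum(w) > 0) break
  }
  if (sum(w) == 0) {           # relax the mask, uniform over allowed cells
    relax <- 5; stage <- 3L
    repeat {
      m2 <- bathymetry_mask(max(0, obs$max_depth_m - relax), env,
                            config$mask_slack_m)
      w <- matrix(as.numeric(m2), env$ny, env$nx)
      if (!is.null(anchor)) w <- w * anchor
      if (sum(w) > 0 || relax > max(env$bathy_m, na.rm = TRUE)) break
      relax <- relax + 5
    }
  }
  if (sum(w) == 0) {
    w <- matrix(as.numeric(env$sea), env$ny, env$nx)
    stage <- 4L
    if (sum(w) == 0) stop("no sea cells: environment misconfigured")
  }
  layers <- c("mask",
              if (has_tide && stage == 0L) "tidal",
              if (has_temp && stage <= 2L) "temperature",
              if (!is.null(anchor)) "anchor")
  structure(list(day = obs$day, w = w / sum(w), layers = layers,
                 fallback = stage,
                 mask_relaxed = attr(mask, "fallback")),
            class = "daily_lik")
}

#' Build the full likelihood stack for an archive
#'
#' Runs tidal window detection once, then builds one combined daily
#' layer per day from `days[1]` to `days[2]`, applying the release
#' anchor on the first day and the recovery anchor (confidence chosen
#' from the recovery method) on the last day.
#'
#' @param archive a `tag_archive`.
#' @param env an `env_grid`.
#' @param days integer range of archive days to geolocate (default all
#'   days); truncate at the float-up/event day for dead or detached
#'   tags, since drifting days say nothing about the fish.
#' @param config see [likelihood_config()].
#' @param anchor_release,anchor_recovery logical; apply endpoint
#'   anchors.
#' @return a `lik_stack` list: `arr` (ny x nx x n_days array),
#'   `days`, `provenance` data.frame (layers applied, fallback stage).
#' @export
build_likelihood_stack <- function(archive, env, days = NULL,
                                   config = likelihood_config(),
                                   anchor_release = TRUE,
                                   anchor_recovery = TRUE) {
  all_days <- sort(unique(archive$depth$day))
  if (is.null(days)) days <- c(min(all_days), max(all_days))
  day_seq <- days[1]:days[2]
  tw <- detect_tidal_windows(archive, window_h = config$window_h,
                             step_min = config$step_min,
                             quiescence_sd_m = config$quiescence_sd_m)
  arr <- array(0, dim = c(env$ny, env$nx, length(day_seq)))
  prov <- data.frame(day = day_seq, n_tidal_fits = 0L, n_temp = 0L,
                     fallback = 0L)
  rec_kind <- if (identical(archive$recovery$method, "beached"))
    "beach_recovery" else "fishery_recovery"
  for (k in seq_along(day_seq)) {
    dd <- day_seq[k]
    obs <- summarize_day(archive, dd, tidal_windows = tw, config = config)
    anchor <- NULL
    if (anchor_release && k == 1)
      anchor <- endpoint_anchor(env, archive$release$lon,
                                archive$release$lat, "release")
    if (anchor_recovery && k == length(day_seq))
      anchor <- endpoint_anchor(env, archive$recovery$lon,
                                archive$recovery$lat, rec_kind)
    dl <- build_daily_likelihood(obs, env,
                                 env_day = min(dd, env$n_days),
                                 anchor = anchor, config = config)
    arr[, , k] <- dl$w
    prov$n_tidal_fits[k] <- nrow(obs$tidal_fits)
    prov$n_temp[k] <- nrow(obs$temp_samples)
    prov$fallback[k] <- dl$fallback
  }
  structure(list(arr = arr, days = day_seq, provenance = prov),
            class = "lik_stack")
}
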