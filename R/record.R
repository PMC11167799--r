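#' Record a synthetic tag archive along a true track
#'
#' Emulates a buoyant archival data-storage tag: depth (pressure) is
#' sampled every minute and temperature every 10 minutes. Each day
#' contains at least one seabed "resting" window (duration >= 3 h by
#' default) during which recorded depth equals the occupied cell's
#' seabed depth plus the local M2 tidal elevation plus sensor noise --
#' the tidal "wave" that the geolocation later matches to the tidal
#' fields. Outside resting windows the fish swims between the surface
#' and the seabed (deeper by day than by night), and recorded
#' temperature is the environment temperature at the instantaneous
#' depth plus sensor noise.
#'
#' @param track a `true_track` from [simulate_track()].
#' @param env the `env_grid` the track was simulated on.
#' @param seed integer seed.
#' @param depth_noise_sd,temp_noise_sd sensor noise sd (m, deg C).
#' @param rest_hours range (h) of the daily resting-window duration.
#' @param day_frac,night_frac depth ranges while swimming, as fractions
#'   of local seabed depth, during day (08-18 UTC) and night.
#' @param fish_id identifier stored in the archive.
#' @return a `tag_archive`: release/recovery metadata plus `depth`
#'   (1-min) and `temp` (10-min) series.
#' @export
record_tag <- function(track, env, seed,
                       depth_noise_sd = 0.1, temp_noise_sd = 0.1,
                       rest_hours = c(3, 6),
                       day_frac = c(0.35, 0.95), night_frac = c(0.05, 0.6),
                       fish_id = "SIM001") {
  if (missing(seed) || is.null(seed)) stop("a seed is required")
  set.seed(as.integer(seed))
  n_days <- nrow(track)
  t0 <- as.POSIXct(paste(track$date[1], "00:00:00"), tz = "UTC")
  omega <- 2 * pi / (M2_PERIOD_H * 3600)

  nmin <- n_days * 1440L
  depth <- numeric(nmin)
  minute_of_day <- rep(0:1439, n_days)
  day_of <- rep(seq_len(n_days), each = 1440L)
  tsec <- as.numeric(t0) + (seq_len(nmin) - 1) * 60

  rc <- cell_rc(env, track$cell)
  amp <- env$tide_amp_m[rc]
  phase <- env$tide_phase_rad[rc]
  bathy <- env$bathy_m[rc]

  rest_dur <- pmin(round(runif(n_days, rest_hours[1], rest_hours[2]) * 60),
                   1380)
  rest_start <- floor(runif(n_days, 0, 1440 - rest_dur))
  knot_step <- 30L

  for (d in seq_len(n_days)) {
    i0 <- (d - 1L) * 1440L
    mins <- 0:1439
    # swimming profile: linear interpolation between 30-min knots whose
    # depths are fractions of the seabed depth (diel modulation)
    kn <- seq(0, 1440, by = knot_step)
    is_day <- kn %/% 60 >= 8 & kn %/% 60 < 18
    fr <- ifelse(is_day,
                 runif(length(kn), day_frac[1], day_frac[2]),
                 runif(length(kn), night_frac[1], night_frac[2]))
    dep <- approx(kn, fr * max(bathy[d] - 0.5, 1), xout = mins)$y
    # resting window: pressure = seabed + tide
    rs <- rest_start[d]; re <- rs + rest_dur[d] - 1L
    in_rest <- mins >= rs & mins <= re
    tt <- tsec[i0 + mins + 1L]
    tide <- amp[d] * cos(omega * tt - phase[d])
    dep[in_rest] <- bathy[d] + tide[in_rest]
    depth[i0 + mins + 1L] <- pmax(0, dep + rnorm(1440, 0, depth_noise_sd))
  }

  temp_idx <- seq(1L, nmin, by = 10L)
  temp_day <- day_of[temp_idx]
  temp_c <- env_temp_at(env, temp_day, track$cell[temp_day],
                        depth[temp_idx]) +
    rnorm(length(temp_idx), 0, temp_noise_sd)

  rel_ll <- cell_lonlat(env, track$cell[1])
  rec_ll <- cell_lonlat(env, track$cell[n_days])
  structure(list(
    fish_id = fish_id,
    release = list(date = track$date[1], lon = rel_ll[, "lon"],
                   lat = rel_ll[, "lat"]),
    recovery = list(date = track$date[n_days], lon = rec_ll[, "lon"],
                    lat = rec_ll[, "lat"], method = "fishery_net"),
    depth = data.frame(time = as.POSIXct(tsec, origin = "1970-01-01",
                                         tz = "UTC"),
                       depth_m = depth, day = day_of),
    temp = data.frame(time = as.POSIXct(tsec[temp_idx],
                                        origin = "1970-01-01", tz = "UTC"),
                      temp_c = temp_c, day = temp_day),
    length_cm = NA_real_, sex = NA_character_,
    meta = list(depth_interval_s = 60, temp_interval_s = 600,
                depth_noise_sd = depth_noise_sd,
                temp_noise_sd = temp_noise_sd,
                rest_start_min = rest_start, rest_dur_min = rest_dur,
                start_date = track$date[1], n_days = n_days)
  ), class = "tag_archive")
}

#' @export
print.tag_archive <- function(x, ...) {
  cat(sprintf("tag_archive %s: %d depth samples (1-min), %d temperature samples (10-min)\n",
              x$fish_id, nrow(x$depth), nrow(x$temp)))
  cat(sprintf("  released %s, recovered %s (%s)\n", format(x$release$date),
              format(x$recovery$date), x$recovery$method))
  invisible(x)
}

#' Inject a mortality/recovery event into a tag archive
#'
#' Overwrites the archive from the event onwards with the signature of
#' the requested fate, leaving all earlier samples untouched:
#' \describe{
#'   \item{predation}{from midday of `event_day` the tag records
#'     predator stomach temperatures (>= 36 deg C) for `stomach_days`
#'     days with frequent near-surface depths, then floats up.}
#'   \item{capture_discard}{a step temperature excursion (air exposure,
#'     default +12 deg C for 30 min) at midday of `event_day`, then
#'     float-up.}
#'   \item{premature_detachment}{immediate float-up at midday of
#'     `event_day`.}
#'   \item{fishery_recovery}{the series simply ends at `event_day`.}
#' }
#' During float phases depth stays below 1 m and temperature tracks the
#' SST of cells visited by a surface random-walk drift; the series ends
#' `drift_days` days after float-up (beached recovery).
#'
#' @param archive a `tag_archive`.
#' @param event list with `kind`, `event_day`, and for predation
#'   `stomach_days` (> 0), plus `drift_days` (default 0) for beached
#'   recoveries.
#' @param env the `env_grid` (needed for drift SST).
#' @param track the `true_track` (drift starts from the cell occupied at
#'   the event).
#' @param seed integer seed.
#' @param drift_speed_km surface drift speed (km/day).
#' @param air_excursion_c temperature step (deg C) of the air-exposure
#'   signature.
#' @return the modified `tag_archive`.
#' @export
inject_event <- function(archive, event, env, track, seed,
                         drift_speed_km = 15, air_excursion_c = 12) {
  if (missing(seed) || is.null(seed)) stop("a seed is required")
  set.seed(as.integer(seed))
  kind <- match.arg(event$kind, c("predation", "capture_discard",
                                  "premature_detachment",
                                  "fishery_recovery"))
  ev_day <- as.integer(event$event_day)
  n_days <- archive$meta$n_days
  if (ev_day < 1 || ev_day > n_days) stop("event_day outside archive span")
  stomach <- event$stomach_days %||% NA_real_
  if (kind == "predation" && (is.na(stomach) || stomach <= 0))
    stop("predation requires stomach_days > 0")
  if (kind != "predation" && !is.na(stomach))
    stop("stomach_days only applies to predation events")
  drift_days <- as.integer(event$drift_days %||% 0L)

  dn <- archive$meta$depth_noise_sd
  tn <- archive$meta$temp_noise_sd
  t0 <- as.numeric(archive$depth$time[1])
  ev_t <- t0 + (ev_day - 1) * 86400 + 12 * 3600   # midday of event day

  if (kind == "fishery_recovery") {
    cut <- t0 + ev_day * 86400
    return(truncate_archive(archive, cut, env, track$cell[ev_day],
                            method = "fishery_net"))
  }

  float_t <- switch(kind,
                    predation = ev_t + stomach * 86400,
                    capture_discard = ev_t + 30 * 60,
                    premature_detachment = ev_t)
  float_day <- floor((float_t - t0) / 86400) + 1
  end_t <- t0 + min(n_days, float_day + drift_days) * 86400

  dts <- as.numeric(archive$depth$time)
  tts <- as.numeric(archive$temp$time)

  if (kind == "predation") {
    sto <- dts >= ev_t & dts < float_t
    # predator: oscillating shallow dives, >= 50% of time within 5 m
    kn_t <- seq(ev_t, float_t + 600, by = 600)
    kn_d <- ifelse(runif(length(kn_t)) < 0.55, runif(length(kn_t), 0, 3),
                   runif(length(kn_t), 3, 15))
    archive$depth$depth_m[sto] <-
      pmax(0, approx(kn_t, kn_d, xout = dts[sto])$y +
             rnorm(sum(sto), 0, dn))
    stot <- tts >= ev_t & tts < float_t
    archive$temp$temp_c[stot] <- pmax(36.2, 37 + rnorm(sum(stot), 0, 0.3))
  }
  if (kind == "capture_discard") {
    exc <- tts >= ev_t & tts < float_t
    archive$temp$temp_c[exc] <- archive$temp$temp_c[exc] + air_excursion_c
    dexc <- dts >= ev_t & dts < float_t
    archive$depth$depth_m[dexc] <- pmax(0, rnorm(sum(dexc), 0.2, 0.05))
  }

  # float + drift phase
  fl_d <- dts >= float_t & dts < end_t
  archive$depth$depth_m[fl_d] <-
    pmin(1, pmax(0, rnorm(sum(fl_d), 0.25, 0.08)))
  fl_t <- tts >= float_t & tts < end_t
  if (any(fl_t)) {
    drift_cells <- surface_drift(env, track$cell[min(ev_day, nrow(track))],
                                 n_days = max(1, drift_days + 1),
                                 speed_km = drift_speed_km)
    dday <- floor((tts[fl_t] - float_t) / 86400) + 1
    dday <- pmin(dday, length(drift_cells))
    abs_day <- pmin(floor((tts[fl_t] - t0) / 86400) + 1, env$n_days)
    archive$temp$temp_c[fl_t] <-
      env_temp_at(env, abs_day, drift_cells[dday], rep(0.2, sum(fl_t))) +
      rnorm(sum(fl_t), 0, tn)
    end_cell <- drift_cells[length(drift_cells)]
  } else {
    end_cell <- track$cell[min(ev_day, nrow(track))]
  }

  out <- truncate_archive(archive, end_t, env, end_cell, method = "beached")
  out$meta$event <- list(kind = kind, event_day = ev_day,
                         stomach_days = stomach, drift_days = drift_days,
                         float_day = float_day)
  out
}

# surface random walk over sea cells (one cell entry per drift day)
surface_drift <- function(env, start_cell, n_days, speed_km = 15) {
  cells <- integer(n_days)
  cells[1] <- start_cell
  step_cells <- max(1L, round(speed_km / env$cell_km))
  for (d in seq_len(n_days - 1)) {
    rc <- cell_rc(env, cells[d])
    for (try in 1:50) {
      r2 <- rc[, "row"] + sample(-step_cells:step_cells, 1)
      c2 <- rc[, "col"] + sample(-step_cells:step_cells, 1)
      if (r2 >= 1 && r2 <= env$ny && c2 >= 1 && c2 <= env$nx &&
          !env$land[r2, c2]) break
      r2 <- rc[, "row"]; c2 <- rc[, "col"]
    }
    cells[d + 1] <- rc_cell(env, r2, c2)
  }
  cells
}

truncate_archive <- function(archive, end_t, env, end_cell, method) {
  keep_d <- as.numeric(archive$depth$time) < end_t
  keep_t <- as.numeric(archive$temp$time) < end_t
  archive$depth <- archive$depth[keep_d, , drop = FALSE]
  archive$temp <- archive$temp[keep_t, , drop = FALSE]
  ll <- cell_lonlat(env, end_cell)
  last_day <- max(archive$depth$day)
  archive$recovery <- list(
    date = archive$meta$start_date + last_day - 1,
    lon = ll[, "lon"], lat = ll[, "lat"], method = method)
  archive$meta$n_days <- last_day
  archive
}
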