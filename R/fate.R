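#' Daily seabed/surface occupancy profile
#'
#' For each calendar day of an archive, the proportion of 1-min depth
#' samples spent close to the assumed seabed (within 20% of that day's
#' maximum depth) and within 5 m of the sea surface. In very shallow
#' water the two bands overlap and both fractions can approach 1.
#'
#' @param archive a `tag_archive`.
#' @param seabed_frac seabed band as a fraction of the daily maximum
#'   depth (default 0.2, i.e. within 20%).
#' @param surface_m surface band in metres (default 5).
#' @param min_coverage days with fewer than this fraction of the 1440
#'   expected samples are flagged `low_coverage`.
#' @return data.frame: day, seabed_fraction, surface_fraction,
#'   coverage, low_coverage.
#' @export
behaviour_profile <- function(archive, seabed_frac = 0.2, surface_m = 5,
                              min_coverage = 0.5) {
  d <- archive$depth
  if (nrow(d) < 1440) stop("need at least one full day of depth data")
  dmax <- tapply(d$depth_m, d$day, max)
  nsamp <- tapply(d$depth_m, d$day, length)
  thr <- dmax[as.character(d$day)] * (1 - seabed_frac)
  seabed <- tapply(d$depth_m >= thr, d$day, mean)
  surface <- tapply(d$depth_m <= surface_m, d$day, mean)
  days <- as.integer(names(dmax))
  data.frame(day = days,
             seabed_fraction = as.numeric(seabed),
             surface_fraction = as.numeric(surface),
             max_depth_m = as.numeric(dmax),
             coverage = as.numeric(nsamp) / 1440,
             low_coverage = as.numeric(nsamp) / 1440 < min_coverage)
}

#' Pool behaviour profiles into a "typical bass" baseline
#'
#' @param profiles list of data.frames from [behaviour_profile()] (or a
#'   single one) computed on reference archives/days without events.
#' @return baseline list with pooled means/sds and the 95th percentile
#'   of the daily surface fraction.
#' @export
build_baseline <- function(profiles) {
  if (is.data.frame(profiles)) profiles <- list(profiles)
  pool <- do.call(rbind, profiles)
  pool <- pool[!pool$low_coverage, ]
  list(surface_mean = mean(pool$surface_fraction),
       surface_sd = max(sd(pool$surface_fraction), 1e-6),
       surface_q95 = quantile(pool$surface_fraction, 0.95, names = FALSE),
       seabed_mean = mean(pool$seabed_fraction),
       seabed_sd = max(sd(pool$seabed_fraction), 1e-6),
       n_days = nrow(pool))
}

#' Detect the day a buoyant tag started floating
#'
#' The float-up day is the earliest day from which depth stays within
#' `depth_tol_m` of the surface continuously until the end of the
#' series, provided that terminal surface span lasts at least
#' `min_hours`. Returns `NULL` when the fish was recovered at depth
#' (e.g. fishery capture, no float phase). An archive at the surface
#' from the first sample is flagged `never_attached`.
#'
#' @param archive a `tag_archive`.
#' @param depth_tol_m surface tolerance (m).
#' @param min_hours minimum duration (h) of the terminal surface span.
#' @return list(floatup_day, floatup_time, never_attached) or `NULL`.
#' @export
detect_floatup <- function(archive, depth_tol_m = 1, min_hours = 24) {
  d <- archive$depth
  if (nrow(d) == 0) stop("empty archive")
  deep <- which(d$depth_m > depth_tol_m)
  if (length(deep) == 0) {
    warning("archive at surface from day 0: tag may never have attached")
    return(list(floatup_day = min(d$day), floatup_time = d$time[1],
                never_attached = TRUE))
  }
  first_surf <- max(deep) + 1L
  if (first_surf > nrow(d)) return(NULL)
  span_h <- as.numeric(d$time[nrow(d)]) - as.numeric(d$time[first_surf])
  if (span_h / 3600 < min_hours) return(NULL)
  list(floatup_day = d$day[first_surf], floatup_time = d$time[first_surf],
       never_attached = FALSE)
}

#' Classify the fate of a recovered tag
#'
#' Implements the three beached-tag fate criteria, applied in order
#' after float-up detection:
#' \describe{
#'   \item{predated}{some pre-float window holds temperature above
#'     `temp_thresh_c` for at least `min_event_minutes` (single short
#'     spikes are ignored), with the surface fraction during that span
#'     above the baseline's 95th percentile (when a baseline is given);
#'     `stomach_days` is the duration of the supra-threshold span.}
#'   \item{caught_discarded}{the float-start day's temperature range
#'     exceeds the deployment's median daily range by at least
#'     `air_margin_c` (air exposure on capture).}
#'   \item{premature}{otherwise; evidence is reported as z-scores of
#'     the final week's seabed/surface fractions against the baseline.}
#' }
#' Archives with no float phase are labelled `caught` (tag recovered in
#' the fishery); archives without a temperature channel are labelled
#' `unknown` with float timing only.
#'
#' @param archive a `tag_archive`.
#' @param baseline optional baseline from [build_baseline()].
#' @param temp_thresh_c predator stomach temperature threshold (deg C).
#' @param air_margin_c air-exposure margin (deg C) over the median
#'   daily temperature range.
#' @param min_event_minutes minimum duration of a supra-threshold
#'   temperature span.
#' @param depth_tol_m,min_hours passed to [detect_floatup()].
#' @return a `fate_report` list.
#' @export
classify_fate <- function(archive, baseline = NULL, temp_thresh_c = 35,
                          air_margin_c = 8, min_event_minutes = 30,
                          depth_tol_m = 1, min_hours = 24) {
  fl <- detect_floatup(archive, depth_tol_m, min_hours)
  last_day <- max(archive$depth$day)
  rep0 <- list(fish_id = archive$fish_id, fate = NA_character_,
               floatup_day = if (is.null(fl)) NA_integer_ else fl$floatup_day,
               event_day = NA_integer_, drift_days = NA_integer_,
               stomach_days = NA_real_, evidence = list())
  class(rep0) <- "fate_report"

  if (nrow(archive$temp) == 0) {
    rep0$fate <- "unknown"
    return(rep0)
  }
  if (is.null(fl)) {
    rep0$fate <- "caught"
    rep0$drift_days <- 0L
    return(rep0)
  }
  rep0$drift_days <- last_day - fl$floatup_day

  tt <- archive$temp
  pre <- tt[as.numeric(tt$time) < as.numeric(fl$floatup_time), ,
            drop = FALSE]
  rep0$evidence$max_temp_c <- if (nrow(pre)) max(pre$temp_c) else NA_real_

  # predation: runs of supra-threshold temperature before float-up
  if (nrow(pre)) {
    hot <- pre$temp_c > temp_thresh_c
    r <- rle(hot)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (i in which(r$values)) {
      t_first <- as.numeric(pre$time[starts[i]])
      t_last <- as.numeric(pre$time[ends[i]])
      dt <- median(diff(as.numeric(pre$time)))
      dur_min <- (t_last - t_first + dt) / 60
      if (dur_min < min_event_minutes) next
      span_days <- pre$day[starts[i]]:pre$day[ends[i]]
      ok_surface <- TRUE
      if (!is.null(baseline)) {
        prof <- behaviour_profile(archive)
        sf <- mean(prof$surface_fraction[prof$day %in% span_days])
        rep0$evidence$surface_fraction_event <- sf
        ok_surface <- sf > baseline$surface_q95
      }
      if (ok_surface) {
        rep0$fate <- "predated"
        rep0$event_day <- pre$day[starts[i]]
        rep0$stomach_days <- dur_min / 1440
        return(rep0)
      }
    }
  }

  # capture + discard: air-exposure temperature range on the float day
  rng <- tapply(tt$temp_c, tt$day, function(x) diff(range(x)))
  fd <- as.character(fl$floatup_day)
  med_rng <- median(rng[names(rng) != fd], na.rm = TRUE)
  rep0$evidence$air_exposure_range_c <- unname(rng[fd])
  rep0$evidence$median_daily_range_c <- unname(med_rng)
  if (!is.na(rng[fd]) && !is.na(med_rng) && rng[fd] >= med_rng + air_margin_c) {
    rep0$fate <- "caught_discarded"
    rep0$event_day <- fl$floatup_day
    return(rep0)
  }

  # premature detachment; evidence vs typical behaviour
  rep0$fate <- "premature"
  rep0$event_day <- fl$floatup_day
  if (!is.null(baseline)) {
    prof <- behaviour_profile(archive)
    wk <- prof[prof$day >= fl$floatup_day - 7 & prof$day < fl$floatup_day, ]
    if (nrow(wk)) {
      rep0$evidence$seabed_z <-
        (mean(wk$seabed_fraction) - baseline$seabed_mean) / baseline$seabed_sd
      rep0$evidence$surface_z <-
        (mean(wk$surface_fraction) - baseline$surface_mean) / baseline$surface_sd
    }
  }
  rep0
}

#' @export
print.fate_report <- function(x, ...) {
  cat(sprintf("fate_report %s: %s", x$fish_id, x$fate))
  if (!is.na(x$floatup_day))
    cat(sprintf(" (float-up day %d, drift %d d)", x$floatup_day,
                x$drift_days))
  if (!is.na(x$stomach_days))
    cat(sprintf(", %.2f days in predator stomach", x$stomach_days))
  cat("\n")
  invisible(x)
}
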