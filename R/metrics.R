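#' Classify partial-migration strategy from maximum displacement
#'
#' Fish at liberty more than half a year (182 days) are classified by
#' the maximum straight-line distance from release: short (< 50 km),
#' intermediate (50-200 km) or long (> 200 km) distance migrators.
#' Boundary values (exactly 50 or 200 km) fall in the lower category.
#' Shorter liberties or missing distances are `unassigned`.
#'
#' @param max_distance_km maximum straight-line displacement (km).
#' @param liberty_days days at liberty.
#' @param thresholds the two category boundaries (km).
#' @param min_liberty_days minimum liberty for assignment.
#' @return character vector: `short`, `intermediate`, `long` or
#'   `unassigned`.
#' @export
classify_strategy <- function(max_distance_km, liberty_days,
                              thresholds = c(50, 200),
                              min_liberty_days = 182) {
  n <- max(length(max_distance_km), length(liberty_days))
  d <- rep_len(max_distance_km, n); l <- rep_len(liberty_days, n)
  if (any(d < 0, na.rm = TRUE) || any(l < 0, na.rm = TRUE))
    stop("negative inputs")
  out <- rep("unassigned", n)
  ok <- !is.na(d) & !is.na(l) & l > min_liberty_days
  out[ok & d <= thresholds[1]] <- "short"
  out[ok & d > thresholds[1] & d <= thresholds[2]] <- "intermediate"
  out[ok & d > thresholds[2]] <- "long"
  out
}

#' Maximum straight-line distance from release
#'
#' @param positions data.frame with `lon`, `lat` (daily positions).
#' @param release `c(lon, lat)` of the release location.
#' @return maximum great-circle distance (km).
#' @export
max_distance_from_release <- function(positions, release) {
  if (nrow(positions) == 0) stop("empty track")
  max(haversine_km(cbind(positions$lon, positions$lat),
                   matrix(release, nrow(positions), 2, byrow = TRUE)))
}

#' Quarterly 2-D kernel density of daily positions
#'
#' Gaussian kernel density (MASS::kde2d, normal-reference bandwidth)
#' of daily positions falling in one calendar quarter, evaluated in
#' local km coordinates and renormalised to integrate to 1. Daily
#' positions are serially dependent, so the surface is a visualisation
#' of space use, not an estimate of independent draws; this caveat is
#' carried in the result.
#'
#' @param positions data.frame with `lon`, `lat` and `date`.
#' @param quarter calendar quarter 1-4.
#' @param n evaluation grid size per axis.
#' @param bw optional bandwidth (km), recycled to both axes.
#' @param min_positions minimum number of positions required.
#' @return list: `x`, `y` (km), `lon`, `lat`, `z` (density, 1/km^2),
#'   `quarter`, `n_positions`, `bandwidth_km`, `independence_caveat`.
#' @export
quarterly_density <- function(positions, quarter, n = 100, bw = NULL,
                              min_positions = 10) {
  q <- (as.integer(format(as.Date(positions$date), "%m")) - 1) %/% 3 + 1
  sub <- positions[q == quarter, , drop = FALSE]
  if (nrow(sub) == 0) stop("no positions in quarter ", quarter)
  if (nrow(sub) < min_positions)
    stop("need at least ", min_positions, " positions in the quarter")
  lat0 <- mean(sub$lat)
  x <- (sub$lon - min(sub$lon)) * 111.19 * cos(lat0 * pi / 180)
  y <- (sub$lat - min(sub$lat)) * 111.19
  bwx <- bw %||% max(MASS::bandwidth.nrd(x), 1)
  bwy <- if (is.null(bw)) max(MASS::bandwidth.nrd(y), 1) else bw
  pad <- 3 * max(bwx, bwy)
  kd <- MASS::kde2d(x, y, h = c(bwx, bwy), n = n,
                    lims = c(min(x) - pad, max(x) + pad,
                             min(y) - pad, max(y) + pad))
  dx <- diff(kd$x[1:2]); dy <- diff(kd$y[1:2])
  kd$z <- kd$z / (sum(kd$z) * dx * dy)
  list(x = kd$x, y = kd$y,
       lon = min(sub$lon) + kd$x / (111.19 * cos(lat0 * pi / 180)),
       lat = min(sub$lat) + kd$y / 111.19,
       z = kd$z, quarter = quarter, n_positions = nrow(sub),
       bandwidth_km = c(bwx, bwy),
       independence_caveat = "daily positions are serially dependent; density visualises space use only")
}

#' Daily vertical-behaviour metrics
#'
#' Per calendar day: maximum depth, mean temperature (native 10-min
#' resolution) and mean vertical speed, defined as total absolute depth
#' change over elapsed time on consecutive 1-min samples. Days with
#' less than half the expected samples are flagged. Mean vertical speed
#' above the spawning-activity threshold (0.25 m/s) raises
#' `speed_flag`.
#'
#' @param archive a `tag_archive`.
#' @param speed_thresh_m_s vertical-speed flag threshold (m/s).
#' @return data.frame: day, max_depth_m, mean_temp_c,
#'   mean_vertical_speed_m_s, coverage, low_coverage, speed_flag.
#' @export
daily_metrics <- function(archive, speed_thresh_m_s = 0.25) {
  d <- archive$depth
  dd <- diff(d$depth_m); dt <- diff(as.numeric(d$time))
  same_day <- diff(d$day) == 0
  spd_day <- d$day[-1][same_day]
  num <- tapply(abs(dd[same_day]), spd_day, sum)
  den <- tapply(dt[same_day], spd_day, sum)
  days <- sort(unique(d$day))
  speed <- rep(NA_real_, length(days)); names(speed) <- days
  speed[names(num)] <- num / den
  dmax <- tapply(d$depth_m, d$day, max)[as.character(days)]
  nsamp <- tapply(d$depth_m, d$day, length)[as.character(days)]
  mtemp <- rep(NA_real_, length(days)); names(mtemp) <- days
  if (nrow(archive$temp)) {
    mt <- tapply(archive$temp$temp_c, archive$temp$day, mean)
    mtemp[names(mt)] <- mt
  }
  data.frame(day = days,
             max_depth_m = as.numeric(dmax),
             mean_temp_c = as.numeric(mtemp),
             mean_vertical_speed_m_s = as.numeric(speed),
             coverage = as.numeric(nsamp) / 1440,
             low_coverage = as.numeric(nsamp) / 1440 < 0.5,
             speed_flag = !is.na(speed) & speed > speed_thresh_m_s)
}

#' Flag candidate spawning days and cells
#'
#' A day is a spawning candidate when, within the first half of the
#' year (Q1-Q2, the regional spawning window), (a) the daily position
#' lies in the deepest quartile of the cells visited by the track,
#' (b) the temperature experienced lies in the spawning window
#' (8.5-11 deg C), and (c) the mean vertical speed exceeds the
#' activity threshold (0.25 m/s). If the archive has no temperature
#' channel, criterion (b) is skipped and noted.
#'
#' @param positions data.frame with `day`, `date`, `cell` (daily track).
#' @param metrics output of [daily_metrics()] for the same fish.
#' @param env an `env_grid`.
#' @param temp_window spawning temperature window (deg C).
#' @param speed_thresh_m_s vertical speed threshold (m/s).
#' @param depth_quantile quantile defining "deepest" visited cells.
#' @param quarters calendar quarters considered.
#' @return list: `days` (flagged day data.frame), `cells` (unique
#'   candidate cells), `criteria_used`.
#' @export
spawning_candidates <- function(positions, metrics, env,
                                temp_window = c(8.5, 11),
                                speed_thresh_m_s = 0.25,
                                depth_quantile = 0.75,
                                quarters = c(1, 2)) {
  m <- merge(positions, metrics, by = "day")
  q <- (as.integer(format(as.Date(m$date), "%m")) - 1) %/% 3 + 1
  rc <- cell_rc(env, m$cell)
  cell_depth <- env$bathy_m[rc]
  thr <- quantile(env$bathy_m[cell_rc(env, unique(m$cell))],
                  depth_quantile, na.rm = TRUE, names = FALSE)
  crit_a <- !is.na(cell_depth) & cell_depth >= thr
  has_temp <- any(!is.na(m$mean_temp_c))
  crit_b <- if (has_temp)
    !is.na(m$mean_temp_c) & m$mean_temp_c >= temp_window[1] &
      m$mean_temp_c <= temp_window[2]
  else rep(TRUE, nrow(m))
  crit_c <- !is.na(m$mean_vertical_speed_m_s) &
    m$mean_vertical_speed_m_s > speed_thresh_m_s
  flag <- q %in% quarters & crit_a & crit_b & crit_c
  list(days = m[flag, c("day", "date", "cell")],
       cells = unique(m$cell[flag]),
       criteria_used = c("deep_quartile",
                         if (has_temp) "temperature_window",
                         "vertical_speed"),
       note = if (!has_temp) "no temperature channel: criterion (b) skipped")
}

#' Population summary of the recovery table
#'
#' Reproduces the population-level quantities reported for the
#' recovered electronic tags: counts by release area, fate and
#' recovery method, migration-strategy tallies, liberty and recovery
#' distance summaries (censored liberties enter at their printed
#' bound and are counted), per-area maximum straight-line migration
#' distance, and per-area maximum recorded depth (both over all fish
#' of the area and over "residents", i.e. fish without a cross-area
#' migration annotation).
#'
#' @param rt a `recovery_table` from [load_recovery_table()].
#' @param n_released total tags released per area (defaults to the
#'   published 48/64/59 for EC/NS/IS).
#' @return a `population_summary` list.
#' @export
summarize_population <- function(rt, n_released = c(EC = 48, NS = 64,
                                                    IS = 59)) {
  if (nrow(rt) == 0) stop("empty recovery table")
  area <- factor(rt$release_area, levels = c("EC", "NS", "IS"))
  n_area <- table(area)
  fate_counts <- table(rt$fate, useNA = "no")
  method_counts <- table(area, rt$recovery_method)
  beach_pct <- 100 * tapply(rt$recovery_method == "beached", area, mean)
  lib <- rt$liberty_days
  dist <- rt$distance_recovered_km
  strat <- table(area, factor(rt$strategy,
                              levels = c("short", "intermediate", "long")))
  maxdist_area <- tapply(rt$max_distance_km, area, max, na.rm = TRUE)
  maxdepth_area <- tapply(rt$max_depth_m, area, max, na.rm = TRUE)
  resident <- is.na(rt$destination) | rt$destination == rt$release_area
  maxdepth_resident <- tapply(rt$max_depth_m[resident], area[resident],
                              max, na.rm = TRUE)
  structure(list(
    n_recovered = nrow(rt),
    n_by_area = c(n_area),
    pct_recovered_by_area = round(100 * c(n_area) /
                                    n_released[names(n_area)], 1),
    pct_recovered_total = round(100 * nrow(rt) / sum(n_released), 1),
    fate_counts = c(fate_counts),
    n_fate_missing = sum(is.na(rt$fate)),
    method_counts = method_counts,
    beach_pct_by_area = round(c(beach_pct), 1),
    liberty = c(min = min(lib), max = max(lib), mean = mean(lib),
                sd = sd(lib)),
    n_liberty_censored = sum(rt$liberty_censored),
    distance_recovered = c(min = min(dist, na.rm = TRUE),
                           max = max(dist, na.rm = TRUE),
                           mean = mean(dist, na.rm = TRUE),
                           sd = sd(dist, na.rm = TRUE)),
    strategy_by_area = strat,
    n_strategy_assigned = c(table(area[!is.na(rt$strategy)])),
    max_distance_by_area = c(maxdist_area),
    max_depth_by_area = c(maxdepth_area),
    max_depth_residents = c(maxdepth_resident)
  ), class = "population_summary")
}

#' @export
print.population_summary <- function(x, ...) {
  cat(sprintf("Recovered electronic tags: %d (EC %d, NS %d, IS %d)\n",
              x$n_recovered, x$n_by_area["EC"], x$n_by_area["NS"],
              x$n_by_area["IS"]))
  cat("Fates:", paste(names(x$fate_counts), x$fate_counts,
                      collapse = ", ", sep = " "),
      sprintf("(+%d unlabelled)\n", x$n_fate_missing))
  cat(sprintf("Liberty %.0f-%.0f days (%.1f +/- %.1f), %d censored\n",
              x$liberty["min"], x$liberty["max"], x$liberty["mean"],
              x$liberty["sd"], x$n_liberty_censored))
  cat(sprintf("Recovered %.0f-%.0f km from release (%.1f +/- %.1f)\n",
              x$distance_recovered["min"], x$distance_recovered["max"],
              x$distance_recovered["mean"], x$distance_recovered["sd"]))
  cat("Strategy tallies (rows = area):\n")
  print(x$strategy_by_area)
  cat("Max straight-line distance by area (km):",
      paste(names(x$max_distance_by_area), x$max_distance_by_area,
            sep = " ", collapse = ", "), "\n")
  invisible(x)
}
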