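#' Generate a synthetic shelf-sea environment grid
#'
#' Builds the gridded fields the geolocation likelihoods draw on:
#' bathymetry, amplitude and phase of a single dominant semidiurnal tidal
#' constituent (M2, period 12.42 h), daily sea-surface temperature and
#' daily temperature at standard depth levels, on a regular grid of
#' square cells (default 5.2 km). Coordinates are WGS84 decimal degrees;
#' the grid is indexed row-major from the southwest corner with cell
#' registration at centres.
#'
#' Two bathymetry styles are available. `"flat"` gives a constant seabed
#' depth with no land. `"coastal_gradient"` places a land "coast" along
#' the southern edge (row 1) and increases depth monotonically away from
#' it, with a small seeded perturbation whose amplitude is below half the
#' row-to-row depth step, so depth ordering across rows is preserved.
#'
#' SST follows a sinusoidal annual cycle (peak mid August) plus a
#' north-south gradient; temperature at depth equals SST minus a
#' seasonally varying stratification that increases with depth level, so
#' temperature never increases with depth.
#'
#' @param nx,ny grid dimensions (columns = longitude, rows = latitude);
#'   both must be >= 3.
#' @param seed integer seed; required, all fields are reproducible.
#' @param style bathymetry style, `"coastal_gradient"` or `"flat"`.
#' @param cell_km cell size in km (default 5.2).
#' @param depth_m seabed depth for `style = "flat"`.
#' @param depth_range shallowest/deepest seabed depth (m) for the
#'   coastal gradient.
#' @param origin `c(lon, lat)` of the southwest cell centre.
#' @param n_days number of daily fields to generate.
#' @param start_date first calendar day (UTC) of the daily fields.
#' @param levels standard depth levels (m) for temperature at depth.
#' @param sst_mean,sst_seasonal_amp annual mean and seasonal amplitude
#'   of SST (deg C).
#' @param sst_lat_gradient SST change per degree latitude (deg C);
#'   negative means colder to the north.
#' @param strat_max_c maximum summer surface-to-bottom stratification
#'   (deg C).
#' @param tide_amp_range range of M2 amplitude (m) across the grid
#'   (gradient along longitude).
#' @param phase_cycles number of full phase cycles across the grid
#'   longitudinally.
#' @param field_noise_sd sd (deg C) of cell-level temperature noise.
#' @return an object of class `env_grid`.
#' @export
make_environment <- function(nx = 30, ny = 30, seed,
                             style = c("coastal_gradient", "flat"),
                             cell_km = 5.2,
                             depth_m = 40,
                             depth_range = c(15, 110),
                             origin = c(-5, 49),
                             n_days = 365,
                             start_date = "2015-01-01",
                             levels = c(0, 20, 40, 60, 80, 120),
                             sst_mean = 12, sst_seasonal_amp = 4,
                             sst_lat_gradient = -1.0,
                             strat_max_c = 2.5,
                             tide_amp_range = c(0.5, 2.5),
                             phase_cycles = 1.5,
                             field_noise_sd = 0.05) {
  style <- match.arg(style)
  if (missing(seed) || is.null(seed)) stop("a seed is required")
  if (nx < 3 || ny < 3) stop("grid dimensions must be at least 3x3")
  set.seed(as.integer(seed))

  lat <- origin[2] + (seq_len(ny) - 1) * cell_km / 111.19
  lat_mid <- mean(lat)
  lon <- origin[1] + (seq_len(nx) - 1) * cell_km /
    (111.19 * cos(lat_mid * pi / 180))

  land <- matrix(FALSE, ny, nx)
  if (style == "flat") {
    bathy <- matrix(depth_m, ny, nx)
  } else {
    land[1, ] <- TRUE
    step <- diff(depth_range) / max(1, ny - 2)
    base <- depth_range[1] + pmax(0, row(land) - 2) * step
    jitter <- matrix(runif(ny * nx, -0.4 * step, 0.4 * step), ny, nx)
    bathy <- base + jitter
    bathy[land] <- NA_real_
  }

  amp <- matrix(rep(seq(tide_amp_range[1], tide_amp_range[2],
                        length.out = nx), each = ny), ny, nx)
  amp <- amp + 0.2 * sin(2 * pi * (row(amp) - 1) / ny)
  amp <- pmax(amp, 0.05)
  phase <- (2 * pi * phase_cycles * (col(amp) - 1) / nx +
              0.8 * pi * (row(amp) - 1) / ny) %% (2 * pi)
  amp[land] <- NA_real_
  phase[land] <- NA_real_

  dates <- as.Date(start_date) + seq_len(n_days) - 1
  yday <- as.integer(format(dates, "%j"))
  seasonal <- sst_seasonal_amp * cos(2 * pi * (yday - 228) / 365.25)
  lat_term <- sst_lat_gradient * (lat - origin[2])

  sst <- array(0, dim = c(n_days, ny, nx))
  for (d in seq_len(n_days)) {
    sst[d, , ] <- sst_mean + seasonal[d] + lat_term +
      matrix(rnorm(ny * nx, 0, field_noise_sd), ny, nx)
  }

  # seasonal stratification, zero in winter, max in late summer
  strat <- strat_max_c * pmax(0, cos(2 * pi * (yday - 228) / 365.25))
  ramp <- pmin(levels, 60) / 60
  tdep <- array(0, dim = c(n_days, ny, nx, length(levels)))
  for (l in seq_along(levels)) {
    tdep[, , , l] <- sst - array(rep(strat * ramp[l], ny * nx),
                                 dim = c(n_days, ny, nx))
  }

  structure(list(
    cell_km = cell_km, nx = nx, ny = ny,
    lon = lon, lat = lat,
    bathy_m = bathy, land = land, sea = !land,
    tide_amp_m = amp, tide_phase_rad = phase,
    sst_c = sst, tdep_c = tdep, levels_m = levels,
    dates = dates, n_days = n_days,
    params = list(style = style, seed = seed, depth_range = depth_range,
                  sst_mean = sst_mean, sst_seasonal_amp = sst_seasonal_amp,
                  sst_lat_gradient = sst_lat_gradient,
                  strat_max_c = strat_max_c,
                  tide_amp_range = tide_amp_range,
                  phase_cycles = phase_cycles)
  ), class = "env_grid")
}

#' @export
print.env_grid <- function(x, ...) {
  cat(sprintf("env_grid: %d x %d cells of %.1f km (%d sea, %d land)\n",
              x$ny, x$nx, x$cell_km, sum(x$sea), sum(x$land)))
  cat(sprintf("  %d daily fields from %s; depth %s m\n", x$n_days,
              format(x$dates[1]),
              paste(round(range(x$bathy_m, na.rm = TRUE)), collapse = "-")))
  invisible(x)
}

# row/col <-> linear cell index (column-major, matching R matrices)
cell_rc <- function(env, cell) {
  cell <- as.integer(cell)
  r <- ((cell - 1L) %% env$ny) + 1L
  c <- ((cell - 1L) %/% env$ny) + 1L
  cbind(row = r, col = c)
}

rc_cell <- function(env, row, col) (as.integer(col) - 1L) * env$ny + as.integer(row)

cell_lonlat <- function(env, cell) {
  rc <- cell_rc(env, cell)
  cbind(lon = env$lon[rc[, "col"]], lat = env$lat[rc[, "row"]])
}

nearest_cell <- function(env, lon, lat) {
  r <- pmin(env$ny, pmax(1L, round((lat - env$lat[1]) /
                                     (env$lat[2] - env$lat[1])) + 1L))
  c <- pmin(env$nx, pmax(1L, round((lon - env$lon[1]) /
                                     (env$lon[2] - env$lon[1])) + 1L))
  rc_cell(env, r, c)
}

# km offsets of cell centres from the southwest cell centre
cell_xy_km <- function(env, cell) {
  rc <- cell_rc(env, cell)
  cbind(x = (rc[, "col"] - 1) * env$cell_km,
        y = (rc[, "row"] - 1) * env$cell_km)
}

#' Tidal elevation of a cell at given times
#'
#' Elevation of the single M2 constituent,
#' `amp * cos(omega * t - phase)` with `t` in seconds since the Unix
#' epoch (UTC) and `omega = 2 pi / 12.42 h`. The same convention is used
#' when fitting tidal windows, so fitted phases are directly comparable
#' with the grid's phase field.
#'
#' @param env an `env_grid`.
#' @param cell linear cell index.
#' @param time POSIXct time(s).
#' @return elevation(s) in metres.
#' @export
tide_elevation <- function(env, cell, time) {
  rc <- cell_rc(env, cell)
  omega <- 2 * pi / (M2_PERIOD_H * 3600)
  env$tide_amp_m[rc] * cos(omega * as.numeric(time) - env$tide_phase_rad[rc])
}

# temperature field (ny x nx matrix) at a scalar depth on a given day;
# depth is clamped to each cell's seabed so over-deep queries take the
# bottom temperature; depths above sst_max_depth use SST
env_temp_field <- function(env, day, depth, sst_max_depth = 5) {
  day <- max(1L, min(env$n_days, as.integer(day)))
  if (depth <= sst_max_depth) {
    return(matrix(env$sst_c[day, , ], env$ny, env$nx))
  }
  eff <- pmin(as.vector(env$bathy_m), depth)
  eff[is.na(eff)] <- depth
  lev <- env$levels_m
  i <- findInterval(eff, lev, rightmost.closed = TRUE)
  i <- pmin(pmax(i, 1L), length(lev) - 1L)
  w <- (eff - lev[i]) / (lev[i + 1] - lev[i])
  w <- pmin(pmax(w, 0), 1)
  sl <- array(env$tdep_c[day, , , ], dim = c(env$ny, env$nx, length(lev)))
  rows <- rep(seq_len(env$ny), env$nx)
  cols <- rep(seq_len(env$nx), each = env$ny)
  out <- (1 - w) * sl[cbind(rows, cols, i)] + w * sl[cbind(rows, cols, i + 1L)]
  matrix(out, env$ny, env$nx)
}

# scalar temperature experienced in one cell at one depth on one day
env_temp_at <- function(env, day, cell, depth, sst_max_depth = 5) {
  rc <- cell_rc(env, cell)
  day <- pmax(1L, pmin(env$n_days, as.integer(day)))
  n <- max(length(day), length(cell), length(depth))
  day <- rep_len(day, n); depth <- rep_len(depth, n)
  r <- rep_len(rc[, "row"], n); cc <- rep_len(rc[, "col"], n)
  bat <- env$bathy_m[cbind(r, cc)]
  eff <- pmin(depth, ifelse(is.na(bat), depth, bat))
  lev <- env$levels_m
  i <- pmin(pmax(findInterval(eff, lev, rightmost.closed = TRUE), 1L),
            length(lev) - 1L)
  w <- pmin(pmax((eff - lev[i]) / (lev[i + 1] - lev[i]), 0), 1)
  lo <- env$tdep_c[cbind(day, r, cc, i)]
  hi <- env$tdep_c[cbind(day, r, cc, i + 1L)]
  out <- (1 - w) * lo + w * hi
  shallow <- depth <= sst_max_depth
  if (any(shallow)) out[shallow] <- env$sst_c[cbind(day, r, cc)][shallow]
  out
}
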