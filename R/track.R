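#' Simulate a two-behaviour fish track on an environment grid
#'
#' Daily positions follow an isotropic Gaussian random walk whose
#' per-axis variance is `2 * D * dt` (km^2) with `dt` one day, where the
#' diffusivity `D` depends on the current behaviour (resident or
#' migratory). Steps landing on land or outside the grid are rejected
#' and resampled. Behaviour evolves by a first-order Markov chain with
#' row-stochastic switch matrix, unless an explicit behaviour sequence
#' is supplied (useful to script seasonal migrations).
#'
#' @param env an `env_grid`.
#' @param n_days track length in days.
#' @param release_cell linear index of the release cell (must be sea).
#' @param D_res,D_mig resident and migratory diffusivities (km^2/day);
#'   `D_res <= D_mig` is required.
#' @param switch_matrix 2x2 row-stochastic behaviour transition matrix,
#'   rows/cols ordered (resident, migratory).
#' @param seed integer seed.
#' @param start_date calendar date (UTC) of day 1.
#' @param behaviour_seq optional character vector of length `n_days`
#'   with values `"resident"`/`"migratory"` overriding the Markov chain.
#' @param start_behaviour behaviour on day 1 when simulating the chain.
#' @return a `true_track` data.frame with day, date, cell, row, col,
#'   continuous positions (km), lon/lat and behaviour.
#' @export
simulate_track <- function(env, n_days, release_cell,
                           D_res = 5, D_mig = 120,
                           switch_matrix = matrix(c(0.95, 0.05, 0.10, 0.90),
                                                  2, 2, byrow = TRUE),
                           seed,
                           start_date = "2015-01-01",
                           behaviour_seq = NULL,
                           start_behaviour = "resident") {
  if (missing(seed) || is.null(seed)) stop("a seed is required")
  if (D_res > D_mig) stop("D_res must not exceed D_mig")
  if (any(abs(rowSums(switch_matrix) - 1) > 1e-8) || any(switch_matrix < 0))
    stop("switch_matrix rows must be nonnegative and sum to 1")
  rc0 <- cell_rc(env, release_cell)
  if (env$land[rc0]) stop("release cell is on land")
  set.seed(as.integer(seed))

  if (is.null(behaviour_seq)) {
    beh <- character(n_days)
    beh[1] <- start_behaviour
    states <- c("resident", "migratory")
    for (d in seq_len(n_days - 1)) {
      i <- match(beh[d], states)
      beh[d + 1] <- sample(states, 1, prob = switch_matrix[i, ])
    }
  } else {
    stopifnot(length(behaviour_seq) == n_days)
    beh <- behaviour_seq
  }

  Dvals <- c(resident = D_res, migratory = D_mig)
  xmax <- (env$nx - 1) * env$cell_km
  ymax <- (env$ny - 1) * env$cell_km
  x <- numeric(n_days); y <- numeric(n_days)
  xy0 <- cell_xy_km(env, release_cell)
  x[1] <- xy0[, "x"]; y[1] <- xy0[, "y"]
  cellv <- integer(n_days); cellv[1] <- release_cell

  on_sea <- function(xk, yk) {
    if (xk < -env$cell_km / 2 || xk > xmax + env$cell_km / 2 ||
        yk < -env$cell_km / 2 || yk > ymax + env$cell_km / 2) return(NA)
    r <- pmin(env$ny, pmax(1L, round(yk / env$cell_km) + 1L))
    cc <- pmin(env$nx, pmax(1L, round(xk / env$cell_km) + 1L))
    if (env$land[r, cc]) NA else rc_cell(env, r, cc)
  }

  for (d in seq_len(n_days - 1)) {
    sdk <- sqrt(2 * Dvals[beh[d + 1]])
    for (try in 1:200) {
      xp <- x[d] + rnorm(1, 0, sdk)
      yp <- y[d] + rnorm(1, 0, sdk)
      cl <- on_sea(xp, yp)
      if (!is.na(cl)) break
    }
    if (is.na(cl)) { xp <- x[d]; yp <- y[d]; cl <- cellv[d] }
    x[d + 1] <- xp; y[d + 1] <- yp; cellv[d + 1] <- cl
  }

  rc <- cell_rc(env, cellv)
  ll <- cell_lonlat(env, cellv)
  out <- data.frame(day = seq_len(n_days),
                    date = as.Date(start_date) + seq_len(n_days) - 1,
                    cell = cellv, row = rc[, "row"], col = rc[, "col"],
                    x_km = x, y_km = y,
                    lon = ll[, "lon"], lat = ll[, "lat"],
                    behaviour = beh)
  attr(out, "release_cell") <- release_cell
  attr(out, "model") <- list(D_res = D_res, D_mig = D_mig,
                             switch_matrix = switch_matrix)
  class(out) <- c("true_track", "data.frame")
  out
}
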