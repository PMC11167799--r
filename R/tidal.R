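M2_OMEGA <- 2 * pi / (12.42 * 3600)   # rad/s

# closed-form least squares of depth ~ c + a*cos(wt) + b*sin(wt)
# t in seconds since the Unix epoch (same convention as tide_elevation)
fit_sinusoid <- function(t, y) {
  cw <- cos(M2_OMEGA * t); sw <- sin(M2_OMEGA * t)
  X <- cbind(1, cw, sw)
  beta <- solve(crossprod(X), crossprod(X, y))
  res <- y - X %*% beta
  amp <- sqrt(beta[2]^2 + beta[3]^2)
  list(mean = beta[1], amplitude_m = amp,
       phase_rad = atan2(beta[3], beta[2]) %% (2 * pi),
       rmse_m = sqrt(mean(res^2)), n = length(y))
}

#' Detect tidal "waves" in a 1-min depth series
#'
#' Slides fixed-length windows over the depth record and fits a single
#' M2 sinusoid (12.42 h period, closed-form least squares) to each.
#' Windows whose residual RMSE is at or below the quiescence threshold
#' are taken as seabed-resting intervals carrying the tidal pressure
#' signal; overlapping accepted windows are merged and refitted, so the
#' result is one amplitude/phase pair per resting bout. Active swimming
#' leaves large residuals and is rejected. Phases are reported relative
#' to the Unix epoch, matching the environment's phase convention.
#'
#' The sliding fits are computed from cumulative sums of the sinusoid
#' basis cross-products, so cost is linear in series length.
#'
#' @param archive a `tag_archive` (or a data.frame with `time`,
#'   `depth_m`, `day`).
#' @param window_h window length in hours.
#' @param step_min step between window starts in minutes.
#' @param quiescence_sd_m RMSE acceptance threshold (m); about the
#'   depth-sensor noise plus a small margin.
#' @return data.frame of merged fits: day (of window midpoint), t_start,
#'   t_end (POSIXct), amplitude_m, phase_rad, rmse_m, n.
#' @export
detect_tidal_windows <- function(archive, window_h = 3, step_min = 20,
                                 quiescence_sd_m = 0.25) {
  d <- if (inherits(archive, "tag_archive")) archive$depth else archive
  t <- as.numeric(d$time); y <- d$depth_m
  n <- length(t)
  L <- as.integer(window_h * 60)
  empty <- data.frame(day = integer(), t_start = as.POSIXct(character()),
                      t_end = as.POSIXct(character()),
                      amplitude_m = numeric(), phase_rad = numeric(),
                      rmse_m = numeric(), n = integer())
  if (n < L) return(empty)

  cw <- cos(M2_OMEGA * t); sw <- sin(M2_OMEGA * t)
  cs <- function(x) cumsum(x)
  C <- list(one = cs(rep(1, n)), c = cs(cw), s = cs(sw),
            cc = cs(cw * cw), ss = cs(sw * sw), csx = cs(cw * sw),
            y = cs(y), yc = cs(y * cw), ys = cs(y * sw), yy = cs(y * y))
  wsum <- function(v, i0, i1) v[i1] - ifelse(i0 > 1, v[pmax(i0 - 1, 1)], 0)

  starts <- seq(1L, n - L + 1L, by = step_min)
  # windows must be contiguous 1-min samples
  contiguous <- (t[starts + L - 1L] - t[starts]) == (L - 1L) * 60
  starts <- starts[contiguous]
  if (!length(starts)) return(empty)
  i1 <- starts + L - 1L

  S1 <- wsum(C$one, starts, i1); Sc <- wsum(C$c, starts, i1)
  Ss <- wsum(C$s, starts, i1); Scc <- wsum(C$cc, starts, i1)
  Sss <- wsum(C$ss, starts, i1); Scs <- wsum(C$csx, starts, i1)
  Sy <- wsum(C$y, starts, i1); Syc <- wsum(C$yc, starts, i1)
  Sys <- wsum(C$ys, starts, i1); Syy <- wsum(C$yy, starts, i1)

  # solve the 3x3 normal equations by Cramer's rule, vectorised
  a11 <- S1; a12 <- Sc; a13 <- Ss
  a22 <- Scc; a23 <- Scs; a33 <- Sss
  det <- a11 * (a22 * a33 - a23 * a23) - a12 * (a12 * a33 - a23 * a13) +
    a13 * (a12 * a23 - a22 * a13)
  d1 <- Sy * (a22 * a33 - a23 * a23) - a12 * (Syc * a33 - a23 * Sys) +
    a13 * (Syc * a23 - a22 * Sys)
  d2 <- a11 * (Syc * a33 - a23 * Sys) - Sy * (a12 * a33 - a23 * a13) +
    a13 * (a12 * Sys - Syc * a13)
  d3 <- a11 * (a22 * Sys - Syc * a23) - a12 * (a12 * Sys - Syc * a13) +
    Sy * (a12 * a23 - a22 * a13)
  b0 <- d1 / det; b1 <- d2 / det; b2 <- d3 / det
  sse <- Syy - (b0 * Sy + b1 * Syc + b2 * Sys)
  rmse <- sqrt(pmax(sse, 0) / S1)

  ok <- which(is.finite(rmse) & rmse <= quiescence_sd_m)
  if (!length(ok)) return(empty)

  # merge overlapping accepted windows and refit each merged span
  o <- ok[order(starts[ok])]
  m_start <- starts[o[1]]; m_end <- i1[o[1]]
  spans <- list()
  for (w in o[-1]) {
    if (starts[w] <= m_end + 1L) {
      m_end <- max(m_end, i1[w])
    } else {
      spans[[length(spans) + 1L]] <- c(m_start, m_end)
      m_start <- starts[w]; m_end <- i1[w]
    }
  }
  spans[[length(spans) + 1L]] <- c(m_start, m_end)

  out <- lapply(spans, function(sp) {
    idx <- sp[1]:sp[2]
    f <- fit_sinusoid(t[idx], y[idx])
    mid <- idx[ceiling(length(idx) / 2)]
    data.frame(day = d$day[mid],
               t_start = d$time[sp[1]], t_end = d$time[sp[2]],
               amplitude_m = f$amplitude_m, phase_rad = f$phase_rad,
               rmse_m = f$rmse_m, n = f$n)
  })
  do.call(rbind, out)
}
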