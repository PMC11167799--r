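#' Wrap an angle to (-pi, pi]
#'
#' @param x angle(s) in radians.
#' @return wrapped angle(s).
#' @keywords internal
wrap_angle <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  y[y <= -pi] <- pi
  y
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Great-circle distance between points (haversine)
#'
#' Distance on a sphere of radius 6371 km. Inputs are recycled; either
#' argument may be a length-2 vector `c(lon, lat)` or a two-column
#' matrix/data.frame with columns lon, lat (decimal degrees, WGS84).
#'
#' @param p1,p2 positions as `c(lon, lat)` or two-column matrices.
#' @return distance(s) in km.
#' @export
#' @examples
#' haversine_km(c(0, 0), c(1, 0))  # ~111.19 km along the equator
haversine_km <- function(p1, p2) {
  as_m <- function(p) {
    if (is.data.frame(p)) p <- as.matrix(p)
    if (is.null(dim(p))) p <- matrix(p, ncol = 2)
    p
  }
  p1 <- as_m(p1); p2 <- as_m(p2)
  if (any(abs(c(p1[, 2], p2[, 2])) > 90)) stop("latitude outside [-90, 90]")
  rad <- pi / 180
  dlat <- (p2[, 2] - p1[, 2]) * rad
  dlon <- (p2[, 1] - p1[, 1]) * rad
  a <- sin(dlat / 2)^2 + cos(p1[, 2] * rad) * cos(p2[, 2] * rad) * sin(dlon / 2)^2
  a <- pmin(1, pmax(0, a))
  2 * EARTH_RADIUS_KM * asin(sqrt(a))
}

#' Parse a possibly right-censored table entry
#'
#' Printed recovery tables report some values as lower bounds, e.g.
#' `"> 787"` for a fish whose tag stopped recording before recovery.
#' Empty cells and dashes are missing values, not zeros.
#'
#' @param text character vector of printed entries.
#' @return data.frame with columns `value` (numeric) and `censored`
#'   (logical); missing entries give `NA` value and `FALSE` censored.
#' @export
#' @examples
#' parse_censored(c("1435", "> 787", ""))
parse_censored <- function(text) {
  text <- trimws(as.character(text))
  censored <- grepl("^>", text)
  num <- trimws(sub("^>", "", text))
  missing <- is.na(text) | num == "" | num %in% c("-", "–", "—")
  value <- rep(NA_real_, length(text))
  bad <- !missing & grepl("[^0-9.eE+-]", num)
  if (any(bad)) stop("non-numeric entry: ", paste(text[bad], collapse = ", "))
  value[!missing] <- as.numeric(num[!missing])
  data.frame(value = value, censored = censored & !missing)
}

# integer day index (1-based) of POSIXct times relative to an origin date
day_index <- function(time, origin) {
  t0 <- as.numeric(as.POSIXct(as.character(origin), tz = "UTC"))
  as.integer(floor((as.numeric(time) - t0) / 86400)) + 1L
}
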