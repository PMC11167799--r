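#' Write a tag archive as delimited text
#'
#' One row per depth sample (1-min): ISO 8601 UTC timestamp, depth (m),
#' and temperature (deg C, blank on minutes without a temperature
#' sample). Deployment metadata are stored in `#key=value` header lines.
#' Values are written with enough digits to round-trip exactly.
#'
#' @param archive a `tag_archive`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_tag_archive <- function(archive, path) {
  con <- file(path, "w")
  on.exit(close(con))
  h <- function(k, v) writeLines(sprintf("#%s=%s", k, v), con)
  h("fish_id", archive$fish_id)
  h("release_date", format(archive$release$date))
  h("release_lon", sprintf("%.17g", archive$release$lon))
  h("release_lat", sprintf("%.17g", archive$release$lat))
  h("recovery_date", format(archive$recovery$date))
  h("recovery_lon", sprintf("%.17g", archive$recovery$lon))
  h("recovery_lat", sprintf("%.17g", archive$recovery$lat))
  h("recovery_method", archive$recovery$method)
  h("length_cm", archive$length_cm)
  h("sex", archive$sex)
  temp_at <- rep(NA_real_, nrow(archive$depth))
  m <- match(as.numeric(archive$temp$time), as.numeric(archive$depth$time))
  temp_at[m[!is.na(m)]] <- archive$temp$temp_c[!is.na(m)]
  writeLines("timestamp,depth_m,temp_c", con)
  writeLines(paste(format(archive$depth$time, "%Y-%m-%dT%H:%M:%SZ"),
                   sprintf("%.17g", archive$depth$depth_m),
                   ifelse(is.na(temp_at), "", sprintf("%.17g", temp_at)),
                   sep = ","), con)
  invisible(path)
}

#' Read a tag archive written by [write_tag_archive()]
#'
#' Rows are returned in time order; if the file rows were out of order
#' they are sorted and the reordering is flagged with a warning and the
#' `reordered` attribute. Malformed timestamps and negative depths are
#' rejected with the offending row number.
#'
#' @param path archive file.
#' @return a `tag_archive`.
#' @export
read_tag_archive <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  hdr <- grep("^#", lines)
  meta <- list()
  for (l in lines[hdr]) {
    kv <- strsplit(sub("^#", "", l), "=", fixed = TRUE)[[1]]
    meta[[kv[1]]] <- if (length(kv) > 1) kv[2] else NA_character_
  }
  body <- lines[-c(hdr, hdr[length(hdr)] + 1)]  # drop header rows + column row
  parts <- strsplit(body, ",", fixed = TRUE)
  ts_chr <- vapply(parts, `[`, "", 1)
  tm <- as.POSIXct(ts_chr, format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  if (anyNA(tm))
    stop("malformed timestamp at data row ", which(is.na(tm))[1])
  dep <- as.numeric(vapply(parts, `[`, "", 2))
  if (anyNA(dep))
    stop("malformed depth at data row ", which(is.na(dep))[1])
  if (any(dep < 0))
    stop("negative depth at data row ", which(dep < 0)[1])
  tc_chr <- vapply(parts, function(p) if (length(p) >= 3) p[3] else "", "")
  reordered <- is.unsorted(as.numeric(tm), strictly = TRUE)
  if (reordered) {
    warning("rows were not in time order; sorted on read")
    o <- order(tm)
    tm <- tm[o]; dep <- dep[o]; tc_chr <- tc_chr[o]
  }
  start_date <- as.Date(meta$release_date)
  dayi <- day_index(tm, start_date)
  has_t <- tc_chr != ""
  depth_int <- if (length(tm) > 1) median(diff(as.numeric(tm))) else NA
  temp_tm <- tm[has_t]
  temp_int <- if (sum(has_t) > 1) median(diff(as.numeric(temp_tm))) else NA
  num_or_na <- function(x) suppressWarnings(as.numeric(x))
  out <- structure(list(
    fish_id = meta$fish_id,
    release = list(date = start_date,
                   lon = num_or_na(meta$release_lon),
                   lat = num_or_na(meta$release_lat)),
    recovery = list(date = as.Date(meta$recovery_date),
                    lon = num_or_na(meta$recovery_lon),
                    lat = num_or_na(meta$recovery_lat),
                    method = meta$recovery_method),
    depth = data.frame(time = tm, depth_m = dep, day = dayi),
    temp = data.frame(time = temp_tm, temp_c = num_or_na(tc_chr[has_t]),
                      day = dayi[has_t]),
    length_cm = num_or_na(meta$length_cm),
    sex = if (identical(meta$sex, "NA")) NA_character_ else meta$sex,
    meta = list(depth_interval_s = depth_int, temp_interval_s = temp_int,
                start_date = start_date, n_days = max(dayi))
  ), class = "tag_archive")
  attr(out, "reordered") <- reordered
  out
}
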