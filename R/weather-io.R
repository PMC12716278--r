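#' Read a canonical temperature CSV
#'
#' Canonical long format: header `station_id,timestamp,temp_c`, one station
#' per file, ISO-8601 timestamps at a fixed resolution.  Rows are sorted by
#' time, duplicate timestamps are collapsed by the mean of their
#' temperatures, and the resolution is inferred from the spacing.
#'
#' @param path Path to a CSV file.
#' @param tz Time zone used to parse timestamps; fixed-offset zones only
#'   (the pipeline does no daylight-saving arithmetic).
#' @return A [temperature_series].
#' @export
read_canonical_series <- function(path, tz = "UTC") {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("station_id", "timestamp", "temp_c")
  if (!all(need %in% names(d)))
    stop("read_canonical_series: missing columns ",
         paste(setdiff(need, names(d)), collapse = ", "))
  ids <- unique(d$station_id)
  if (length(ids) != 1L)
    stop("read_canonical_series: expected one station per file, found ",
         length(ids))
  ts <- tryCatch(
    as.POSIXct(d$timestamp, tz = tz,
               tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S",
                              "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M")),
    error = function(e) NA)
  if (anyNA(ts)) stop("read_canonical_series: unparseable timestamps in ", path)
  o <- order(ts)
  ts <- ts[o]; temp <- d$temp_c[o]
  if (anyDuplicated(ts)) {
    agg <- tapply(temp, as.numeric(ts), mean)
    ts <- as.POSIXct(as.numeric(names(agg)), origin = "1970-01-01", tz = tz)
    temp <- as.numeric(agg)
  }
  temperature_series(ids, ts, temp)
}

#' Write a temperature series as canonical CSV
#'
#' @param series A [temperature_series].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_canonical_series <- function(series, path) {
  stopifnot(inherits(series, "temperature_series"))
  utils::write.csv(
    data.frame(station_id = series$station_id,
               timestamp = format(series$timestamps, "%Y-%m-%dT%H:%M:%S"),
               temp_c = series$temp_c),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Best-effort reader for ASOS one-minute surface records
#'
#' Parses the NOAA one-minute surface observation page format (DSI-6405
#' family, fixed-width): characters 1-9 carry the station identifier (WBAN
#' number plus call sign), the first run of 12 digits after it is the local
#' timestamp `YYYYMMDDHHMM`, and the dry-bulb temperature in degrees
#' Fahrenheit is the second-to-last whitespace-separated numeric token of
#' the line.  Temperatures are converted to Celsius.  Lines that do not
#' yield a timestamp and a finite temperature are skipped and counted; a
#' file with more than half its lines unparseable is rejected.
#'
#' @param path Path to a one-minute ASOS page file.
#' @param tz Fixed-offset zone for the local timestamps.
#' @return A [temperature_series] with attribute `n_skipped`.
#' @export
read_asos_onemin <- function(path, tz = "UTC") {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("read_asos_onemin: empty file ", path)
  station <- trimws(substr(lines[1L], 1, 9))
  ts <- character(length(lines)); tf <- rep(NA_real_, length(lines))
  m <- regmatches(lines, regexpr("[0-9]{12}", lines))
  has_ts <- lengths(regmatches(lines, gregexpr("[0-9]{12}", lines))) > 0
  ts[has_ts] <- substr(m, 1, 12)
  for (i in seq_along(lines)) {
    tok <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    if (length(tok) >= 2L) {
      v <- suppressWarnings(as.numeric(tok[length(tok) - 1L]))
      if (is.finite(v)) tf[i] <- v
    }
  }
  when <- as.POSIXct(ts, format = "%Y%m%d%H%M", tz = tz)
  ok <- !is.na(when) & is.finite(tf)
  n_skip <- sum(!ok)
  if (n_skip > length(lines) / 2)
    stop("read_asos_onemin: ", n_skip, " of ", length(lines),
         " lines unparseable in ", path)
  temp_c <- (tf[ok] - 32) * 5 / 9
  o <- order(when[ok])
  s <- temperature_series(station, when[ok][o], temp_c[o])
  attr(s, "n_skipped") <- n_skip
  s
}

#' Split a multi-year series into July-June winter years
#'
#' Slices at July 1 00:00 boundaries so that no single winter is split
#' across files; slices are labelled `"YYYY-YYYY+1"`.  Partial years at the
#' ends are emitted as-is and judged later by QC.
#'
#' @param series A [temperature_series].
#' @return A named list of [temperature_series], in time order.
#' @export
split_winter_years <- function(series) {
  stopifnot(inherits(series, "temperature_series"))
  if (!length(series$temp_c)) return(list())
  yr <- as.integer(format(series$timestamps, "%Y"))
  mo <- as.integer(format(series$timestamps, "%m"))
  wy <- ifelse(mo >= 7, yr, yr - 1L)       # winter year = year of its July
  out <- lapply(sort(unique(wy)), function(w) {
    idx <- which(wy == w)
    temperature_series(series$station_id, series$timestamps[idx],
                       series$temp_c[idx],
                       resolution_min = series$resolution_min)
  })
  names(out) <- paste0(sort(unique(wy)), "-", sort(unique(wy)) + 1L)
  out
}

#' Oct-Apr completeness of one winter-year series
#'
#' Fraction of the expected October 1 - April 30 records actually present
#' (non-missing), given the series resolution.
#'
#' @param series A [temperature_series] covering (part of) one winter year.
#' @return A fraction in `[0, 1]`.
#' @export
winter_completeness <- function(series) {
  stopifnot(inherits(series, "temperature_series"))
  if (!length(series$temp_c)) return(0)
  mo <- as.integer(format(series$timestamps, "%m"))
  core <- mo >= 10 | mo <= 4
  n_obs <- sum(core & !is.na(series$temp_c))
  # Oct 1 through Apr 30: 212 days (213 when February has 29)
  yr <- as.integer(substr(format(series$timestamps[1], "%Y"), 1, 4))
  feb_year <- if (mo[1] >= 7) yr + 1L else yr
  leap <- (feb_year %% 4 == 0 & feb_year %% 100 != 0) | feb_year %% 400 == 0
  n_exp <- (212 + leap) * 24 * 60 / series$resolution_min
  min(n_obs / n_exp, 1)
}

#' Station-level quality control
#'
#' Applies the study's inclusion rules to one station: the station must lie
#' inside the contiguous-US bounding region, each winter year must not be
#' missing more than `max_missing` of its October-April records, and at
#' least `min_years` winter years must survive that screen.
#'
#' @param lat,lon Station coordinates (decimal degrees, WGS84).
#' @param winters Named list of winter-year [temperature_series] (as from
#'   [split_winter_years()]).
#' @param min_years Minimum count of QC-passing winter years (default 10).
#' @param max_missing Maximum tolerated missing fraction of Oct-Apr records
#'   per winter year (default 0.25).
#' @param bbox Bounding region `c(lat_min, lat_max, lon_min, lon_max)`;
#'   default covers the contiguous United States.
#' @return A list with `include` (logical), `reasons` (character vector,
#'   empty when included), `years_kept` (labels), and `completeness` (named
#'   per-year fractions).
#' @export
station_qc <- function(lat, lon, winters, min_years = 10, max_missing = 0.25,
                       bbox = c(24, 50, -125, -66)) {
  stopifnot(is.list(winters))
  comp <- vapply(winters, winter_completeness, numeric(1))
  keep <- comp >= 1 - max_missing
  reasons <- character(0)
  if (!(lat >= bbox[1] && lat <= bbox[2] && lon >= bbox[3] && lon <= bbox[4]))
    reasons <- c(reasons, "outside contiguous-US bounding region")
  if (sum(keep) < min_years)
    reasons <- c(reasons,
                 sprintf("fewer than %d qualifying winter years (%d)",
                         min_years, sum(keep)))
  list(include = length(reasons) == 0L, reasons = reasons,
       years_kept = names(winters)[keep], completeness = comp)
}

#' Summarize annual peak mortalities for a station
#'
#' Arithmetic mean and sample standard deviation (n - 1 denominator) of
#' the per-winter-year peak monthly mortalities.
#'
#' @param peaks Numeric vector of annual peak mortalities (`NA`s dropped).
#' @return A list with `n_years`, `mean_peak`, `sd_peak` (`NA` when fewer
#'   than two years).
#' @export
summarize_station <- function(peaks) {
  peaks <- peaks[!is.na(peaks)]
  if (!length(peaks)) stop("summarize_station: need at least one annual peak")
  list(n_years = length(peaks), mean_peak = mean(peaks),
       sd_peak = if (length(peaks) >= 2) stats::sd(peaks) else NA_real_)
}

#' QC, accumulate and summarize a network of stations
#'
#' Convenience pipeline: for each station, split its series into winter
#' years, apply [station_qc()], compute each qualifying year's peak monthly
#' mortality under `params`, and summarize.
#'
#' @param series_list Named list of multi-year [temperature_series], one
#'   per station.
#' @param meta Data frame with `station_id`, `lat`, `lon`.
#' @param params A [chill_params] object.
#' @param ... Passed to [station_qc()] (`min_years`, `max_missing`, `bbox`).
#' @param completeness Monthly completeness threshold for
#'   [monthly_mortality()].
#' @return A data frame `station_id, lat, lon, included, n_years,
#'   mean_peak_mortality, sd_peak_mortality` (summary columns `NA` for
#'   excluded stations).
#' @export
summarize_station_network <- function(series_list, meta, params, ...,
                                      completeness = 0.75) {
  stopifnot(all(c("station_id", "lat", "lon") %in% names(meta)))
  rows <- lapply(names(series_list), function(id) {
    m <- meta[meta$station_id == id, , drop = FALSE]
    if (nrow(m) != 1L) stop("summarize_station_network: no metadata for ", id)
    winters <- split_winter_years(series_list[[id]])
    qc <- station_qc(m$lat, m$lon, winters, ...)
    if (!qc$include)
      return(data.frame(station_id = id, lat = m$lat, lon = m$lon,
                        included = FALSE, n_years = NA_integer_,
                        mean_peak_mortality = NA_real_,
                        sd_peak_mortality = NA_real_))
    peaks <- vapply(winters[qc$years_kept], function(w)
      peak_winter_mortality(monthly_mortality(w, params, completeness)),
      numeric(1))
    s <- summarize_station(peaks)
    data.frame(station_id = id, lat = m$lat, lon = m$lon, included = TRUE,
               n_years = s$n_years, mean_peak_mortality = s$mean_peak,
               sd_peak_mortality = s$sd_peak)
  })
  do.call(rbind, rows)
}
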