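#' Fixed-resolution temperature series for one station
#'
#' @param station_id Single station identifier.
#' @param timestamps `POSIXct` instants, strictly increasing. Timestamps
#'   are interpreted in the station's local standard time; the package does
#'   no daylight-saving arithmetic (store and parse in a fixed-offset zone,
#'   conventionally `"UTC"`).
#' @param temp_c Temperatures in degrees C, one per instant; physical
#'   bounds `[-60, 60]` are enforced.
#' @param resolution_min Minutes between consecutive records.  If `NULL`,
#'   inferred as the most common positive difference; gaps (larger
#'   multiples of the resolution) are allowed and recorded, irregular
#'   spacing is an error.
#' @return An object of class `temperature_series`: a list with
#'   `station_id`, `timestamps`, `temp_c`, `resolution_min`, and `x`, the
#'   step length in hours (`resolution_min / 60`) used by the mortality
#'   accumulator.
#' @export
temperature_series <- function(station_id, timestamps, temp_c,
                               resolution_min = NULL) {
  stopifnot(length(station_id) == 1L, inherits(timestamps, "POSIXct"),
            length(timestamps) == length(temp_c))
  if (anyNA(timestamps)) stop("temperature_series: NA timestamps")
  n <- length(timestamps)
  if (n > 1L) {
    dt <- as.numeric(diff(timestamps), units = "mins")
    if (any(dt <= 0))
      stop("temperature_series: timestamps must be strictly increasing")
    if (is.null(resolution_min)) {
      tab <- table(dt)
      resolution_min <- as.numeric(names(tab)[which.max(tab)])
      off <- dt %% resolution_min
      if (any(pmin(off, resolution_min - off) > 1e-6))
        stop("temperature_series: cannot infer a fixed resolution; ",
             "spacings are not multiples of ", resolution_min, " min")
    }
  } else if (is.null(resolution_min)) {
    stop("temperature_series: resolution_min required for series of length <= 1")
  }
  ok <- is.finite(temp_c) & temp_c >= -60 & temp_c <= 60
  if (!all(ok | is.na(temp_c)))
    stop("temperature_series: temperatures outside physical bounds [-60, 60]")
  structure(list(station_id = as.character(station_id),
                 timestamps = timestamps, temp_c = as.numeric(temp_c),
                 resolution_min = as.numeric(resolution_min),
                 x = as.numeric(resolution_min) / 60),
            class = "temperature_series")
}

#' @export
print.temperature_series <- function(x, ...) {
  cat("Temperature series, station", x$station_id, "\n")
  cat("  ", length(x$temp_c), "records at", x$resolution_min, "min resolution\n")
  if (length(x$timestamps))
    cat("  ", format(min(x$timestamps)), "to", format(max(x$timestamps)), "\n")
  cat("  temp range:", paste(round(range(x$temp_c, na.rm = TRUE), 2),
                             collapse = " to "), "degC\n")
  invisible(x)
}

#' @export
length.temperature_series <- function(x) length(x$temp_c)

# survival floor: the equivalent-exposure form diverges as S -> 0, so the
# running survival is clamped here before any logit
.S_FLOOR <- 1e-12

#' One increment of the chill-injury mortality recursion
#'
#' Advances the running survival across one temperature record.  For a
#' record at temperature `temp <= c` (the ULCIZ), the previously
#' accumulated survival is converted to the equivalent exposure time at
#' `temp` that would have produced it,
#' \deqn{t_i = \frac{\mathrm{logit}(S_{i-1}) - a}{b (T_i - c)} + x,}
#' and survival is re-read from the constant-exposure model at `t_i`.  On
#' the logit scale this whole detour collapses to one addition,
#' `logit(S_i) = logit(S_{i-1}) + b x (T_i - c)`, which is how it is
#' computed (no division, so `temp = c` is a well-defined no-op).  Records
#' above the ULCIZ leave survival unchanged: no injury, and by assumption
#' no recovery between chill events.
#'
#' @param S_prev Running survival, strictly inside (0, 1).
#' @param temp Temperature of the record, degrees C.
#' @param params A [chill_params] object.
#' @param x Step length in hours (series resolution / 60).
#' @return A list with `t_i` (equivalent exposure in hours, `NA` when
#'   `temp >= c`; audit only), `S_i`, `M_i` (incremental mortality
#'   `S_prev - S_i`), and `injurious`.
#' @export
chill_step <- function(S_prev, temp, params, x) {
  stopifnot(inherits(params, "chill_params"), length(S_prev) == 1L)
  if (!is.finite(S_prev) || S_prev <= 0 || S_prev >= 1)
    stop("chill_step: S_prev must lie strictly in (0, 1)")
  S_prev <- max(S_prev, .S_FLOOR)
  if (temp > params$c) {
    return(list(t_i = NA_real_, S_i = S_prev, M_i = 0, injurious = FALSE))
  }
  L_prev <- stats::qlogis(S_prev)
  L_new <- max(L_prev + params$b * x * (temp - params$c),
               stats::qlogis(.S_FLOOR))
  t_i <- if (temp < params$c)
    (L_prev - params$a) / (params$b * (temp - params$c)) + x
  else NA_real_
  S_i <- stats::plogis(L_new)
  list(t_i = t_i, S_i = S_i, M_i = S_prev - S_i, injurious = TRUE)
}

#' Cumulative chill-injury mortality over a fluctuating series
#'
#' Runs the mortality recursion over a temperature series in time order,
#' starting from the zero-exposure survival `S_0 = plogis(a)`.  Each record
#' below or at the ULCIZ lowers the survival logit by `b x (T_i - c)`
#' (the per-record dose of degree-hours below threshold); warmer records
#' and recording gaps contribute neither injury nor recovery.  Cumulative
#' mortality is the telescoping sum of the increments, `S_0 - S_final`.
#'
#' @param series A [temperature_series]. Records with `NA` temperature are
#'   treated as gaps.
#' @param params A [chill_params] object.
#' @return An object of class `mortality_trace`: a list with the per-step
#'   data frame `steps` (`timestamp`, `temp_c`, `injurious`, `t_i`, `S`,
#'   `M_inc`, `M_cum`) and scalars `S0`, `S_final`, `M_cumulative`.
#' @examples
#' p <- published_chill_params("amynothrips")
#' s <- gen_temperature_series(weather_scenario(annual_mean_c = 8, seed = 1),
#'                             "2010-07-01", "2011-07-01")
#' accumulate_mortality(s, p)$M_cumulative
#' @export
accumulate_mortality <- function(series, params) {
  stopifnot(inherits(series, "temperature_series"),
            inherits(params, "chill_params"))
  a <- params$a; b <- params$b; cc <- params$c; x <- series$x
  S0 <- stats::plogis(a)
  tc <- series$temp_c
  n <- length(tc)
  if (n == 0L) {
    return(structure(list(
      steps = data.frame(timestamp = series$timestamps,
                         temp_c = numeric(0), injurious = logical(0),
                         t_i = numeric(0), S = numeric(0),
                         M_inc = numeric(0), M_cum = numeric(0)),
      S0 = S0, S_final = S0, M_cumulative = 0,
      station_id = series$station_id), class = "mortality_trace"))
  }
  inj <- !is.na(tc) & tc <= cc
  dose <- ifelse(inj, b * x * (tc - cc), 0)       # logit decrements, <= 0
  L <- pmax(a + cumsum(dose), stats::qlogis(.S_FLOOR))
  S <- stats::plogis(L)
  S_prev <- c(S0, S[-n])
  M_inc <- S_prev - S
  L_prev <- c(a, L[-n])
  t_i <- rep(NA_real_, n)
  strict <- inj & tc < cc
  t_i[strict] <- (L_prev[strict] - a) / (b * (tc[strict] - cc)) + x
  structure(list(
    steps = data.frame(timestamp = series$timestamps, temp_c = tc,
                       injurious = inj, t_i = t_i, S = S, M_inc = M_inc,
                       M_cum = cumsum(M_inc)),
    S0 = S0, S_final = S[n], M_cumulative = S0 - S[n],
    station_id = series$station_id), class = "mortality_trace")
}

#' @export
print.mortality_trace <- function(x, ...) {
  cat("Chill-injury mortality trace, station", x$station_id, "\n")
  cat("  ", nrow(x$steps), "steps,", sum(x$steps$injurious), "injurious\n")
  cat("  S0 =", round(x$S0, 4), " S_final =", round(x$S_final, 4),
      " M_cumulative =", round(x$M_cumulative, 4), "\n")
  invisible(x)
}

#' Per-month cumulative mortality over a winter year
#'
#' Splits a series at calendar-month boundaries, resets survival to the
#' zero-exposure intercept at the start of each month, and accumulates
#' mortality independently within each month.  A month is reported only if
#' its record count reaches a completeness threshold relative to the count
#' expected from the series resolution; incomplete months get `NA`.
#'
#' @param series A [temperature_series] (conventionally one July-June
#'   winter year).
#' @param params A [chill_params] object.
#' @param completeness Minimum fraction of expected records for a month to
#'   be reportable (default 0.75).
#' @return A data frame with one row per calendar month present: `month`
#'   (`"YYYY-MM"`), `n_records`, `expected`, `complete`, `m_cum`.
#' @export
monthly_mortality <- function(series, params, completeness = 0.75) {
  stopifnot(inherits(series, "temperature_series"))
  if (length(series$temp_c) == 0L)
    return(data.frame(month = character(0), n_records = integer(0),
                      expected = numeric(0), complete = logical(0),
                      m_cum = numeric(0)))
  ym <- format(series$timestamps, "%Y-%m")
  months <- unique(ym)            # time order is guaranteed by the class
  res <- lapply(months, function(m) {
    idx <- which(ym == m)
    sub <- temperature_series(series$station_id, series$timestamps[idx],
                              series$temp_c[idx],
                              resolution_min = series$resolution_min)
    dim_days <- .days_in_month(m)
    expected <- dim_days * 24 * 60 / series$resolution_min
    n_rec <- sum(!is.na(sub$temp_c))
    ok <- n_rec >= completeness * expected
    data.frame(month = m, n_records = n_rec, expected = expected,
               complete = ok,
               m_cum = if (ok) accumulate_mortality(sub, params)$M_cumulative
                       else NA_real_)
  })
  do.call(rbind, res)
}

.days_in_month <- function(ym) {
  first <- as.Date(paste0(ym, "-01"))
  as.integer(seq(first, by = "1 month", length.out = 2)[2] - first)
}

#' Peak monthly winter mortality
#'
#' The mortality of the worst month of a winter year: the maximum of the
#' per-month cumulative mortalities, ties resolved to the earliest month.
#'
#' @param monthly Output of [monthly_mortality()], or a named numeric
#'   vector of per-month mortalities (`NA` = month missing).
#' @return A single mortality proportion; `NA` if every month is missing.
#' @export
peak_winter_mortality <- function(monthly) {
  m <- if (is.data.frame(monthly)) monthly$m_cum else as.numeric(monthly)
  if (all(is.na(m))) return(NA_real_)
  max(m, na.rm = TRUE)    # which.max would give the month; ties -> earliest
}
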