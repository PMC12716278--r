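#' Simulate a cold-exposure survival experiment
#'
#' Draws binomial death counts per design cell from the logistic
#' time-temperature survival model: `n_dead ~ Binomial(n, 1 - S(t, T))`.
#' Pure function of `(params, design, seed)`.
#'
#' @param params Generating [chill_params].
#' @param design Data frame with columns `temperature_c`, `exposure_h`,
#'   `n` (insects per cell); see [design_table1()] / [design_table2()] for
#'   the two published layouts.
#' @param seed Integer seed.
#' @return A [survival_assay] data frame.
#' @export
gen_survival_experiment <- function(params, design, seed) {
  stopifnot(all(c("temperature_c", "exposure_h", "n") %in% names(design)),
            all(design$n >= 1))
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  p_dead <- 1 - chill_survival(design$exposure_h, design$temperature_c,
                               params, truncate_warm = TRUE)
  dead <- stats::rbinom(nrow(design), size = design$n, prob = p_dead)
  survival_assay(design$temperature_c, design$exposure_h, design$n,
                 n_dead = dead,
                 species = if (!is.null(params$species)) params$species
                           else NA)
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Published assay designs
#'
#' `design_table1()` is the thrips layout: the incomplete cross of
#' temperatures `3, 0, -3, -6, -9, -12` degrees C by exposures
#' `6, 12, 24, 48, 96, 192, 384` h with the short exposures absent at the
#' mild temperatures and the long exposures absent at the severe ones (33
#' populated cells, 50 insects each).  `design_table2()` is the flea
#' beetle layout: the complete `2, -2, -4, -6` by `6, 12, 24, 48, 96` h
#' cross with a configurable per-cell `n`.
#'
#' @param n Insects per cell.
#' @return A data frame `temperature_c, exposure_h, n`.
#' @export
design_table1 <- function(n = 50) {
  fix <- assay_fixture("amynothrips")
  data.frame(temperature_c = fix$temperature_c, exposure_h = fix$exposure_h,
             n = n)
}

#' @rdname design_table1
#' @export
design_table2 <- function(n = 68) {
  d <- expand.grid(exposure_h = c(6, 12, 24, 48, 96),
                   temperature_c = c(2, -2, -4, -6), KEEP.OUT.ATTRS = FALSE)
  data.frame(temperature_c = d$temperature_c, exposure_h = d$exposure_h,
             n = n)
}

#' Weather scenario for the synthetic temperature generator
#'
#' Parameters of a seasonally and diurnally structured synthetic
#' temperature process: an annual sinusoid (coldest mid-January), a diurnal
#' sinusoid (coldest just before dawn), stationary AR(1) noise, and a
#' schedule of rectangular cold snaps subtracted from the baseline.
#' Defaults describe a temperate mid-latitude station; a Gulf-Coast-like
#' station is obtained by raising `annual_mean_c` (see the package
#' vignette).
#'
#' @param annual_mean_c Annual mean temperature, degrees C.
#' @param annual_amplitude_c Half-range of the annual cycle (>= 0).
#' @param diurnal_amplitude_c Half-range of the daily cycle (>= 0).
#' @param ar_sd Marginal standard deviation of the AR(1) noise (>= 0).
#' @param ar_coef AR(1) coefficient in `[0, 1)`.
#' @param snaps Cold-snap schedule: data frame `start` (timestamp, parsed
#'   in `tz`), `duration_h`, `depth_c`; or `NULL`.
#' @param resolution_min Recording resolution in minutes.
#' @param seed Integer seed; fixes the whole series.
#' @return A list of class `weather_scenario`.
#' @export
weather_scenario <- function(annual_mean_c = 12, annual_amplitude_c = 14,
                             diurnal_amplitude_c = 4, ar_sd = 2.5,
                             ar_coef = 0.8, snaps = NULL,
                             resolution_min = 60, seed = 1) {
  stopifnot(annual_amplitude_c >= 0, diurnal_amplitude_c >= 0, ar_sd >= 0,
            ar_coef >= 0, ar_coef < 1, resolution_min > 0)
  structure(list(annual_mean_c = annual_mean_c,
                 annual_amplitude_c = annual_amplitude_c,
                 diurnal_amplitude_c = diurnal_amplitude_c,
                 ar_sd = ar_sd, ar_coef = ar_coef, snaps = snaps,
                 resolution_min = resolution_min, seed = seed),
            class = "weather_scenario")
}

#' Generate a synthetic temperature series
#'
#' `temp(t) = annual sinusoid + diurnal sinusoid + AR(1) noise - scheduled
#' snap depressions`; deterministic given the scenario (which carries its
#' seed).  The annual term is coldest around January 15 and the diurnal
#' term around 05:00 local.
#'
#' @param scenario A [weather_scenario].
#' @param start,end Timestamps (parsed in `tz`); `end` exclusive.
#' @param station_id Station label.
#' @param tz Fixed-offset zone.
#' @return A [temperature_series].
#' @export
gen_temperature_series <- function(scenario, start, end,
                                   station_id = "SYN1", tz = "UTC") {
  stopifnot(inherits(scenario, "weather_scenario"))
  start <- as.POSIXct(start, tz = tz); end <- as.POSIXct(end, tz = tz)
  if (end <= start) stop("gen_temperature_series: end must be after start")
  ts <- seq(start, end, by = scenario$resolution_min * 60)
  ts <- ts[ts < end]
  yday <- as.POSIXlt(ts)$yday + as.POSIXlt(ts)$hour / 24
  hour <- as.POSIXlt(ts)$hour + as.POSIXlt(ts)$min / 60
  base <- scenario$annual_mean_c -
    scenario$annual_amplitude_c * cos(2 * pi * (yday - 14) / 365.25) -
    scenario$diurnal_amplitude_c * cos(2 * pi * (hour - 5) / 24)
  noise <- 0
  if (scenario$ar_sd > 0) {
    old <- .save_rng(); on.exit(.restore_rng(old))
    set.seed(scenario$seed)
    eps_sd <- scenario$ar_sd * sqrt(1 - scenario$ar_coef^2)
    noise <- as.numeric(stats::arima.sim(
      list(ar = scenario$ar_coef), n = length(ts), sd = eps_sd))
  }
  temp <- base + noise
  if (!is.null(scenario$snaps) && nrow(scenario$snaps)) {
    for (i in seq_len(nrow(scenario$snaps))) {
      s0 <- as.POSIXct(scenario$snaps$start[i], tz = tz)
      s1 <- s0 + scenario$snaps$duration_h[i] * 3600
      inwin <- ts >= s0 & ts < s1
      temp[inwin] <- temp[inwin] - scenario$snaps$depth_c[i]
    }
  }
  temperature_series(station_id, ts, pmax(pmin(temp, 60), -60),
                     resolution_min = scenario$resolution_min)
}

#' Generate a synthetic station network with a latitudinal severity
#' gradient
#'
#' Places stations on a jittered lat/lon grid across the south-to-north
#' span of the contiguous US and gives each a multi-year synthetic series
#' whose annual mean falls with latitude at `gradient` degrees C per
#' degree of latitude, so winter severity (and hence chill mortality under
#' any valid parameter set) increases northward.  Each station gets
#' `n_years` full winter years so the default QC passes.
#'
#' @param n_stations Number of stations (>= 3).
#' @param gradient Cooling rate, degrees C of annual mean per degree
#'   latitude (0 makes stations exchangeable).
#' @param seed Integer seed.
#' @param n_years Complete July-June winter years per station (default 12).
#' @param start_year First July (default 2002).
#' @param resolution_min Recording resolution (default 60).
#' @param base_mean_c Annual mean at the southern edge (lat 26; default
#'   21).
#' @param ar_sd,ar_coef Noise parameters passed to [weather_scenario()].
#' @return A list with `meta` (data frame `station_id, lat, lon`) and
#'   `series` (named list of [temperature_series]).
#' @export
gen_station_network <- function(n_stations, gradient = 0.9, seed = 1,
                                n_years = 12, start_year = 2002,
                                resolution_min = 60, base_mean_c = 21,
                                ar_sd = 2, ar_coef = 0.7) {
  stopifnot(n_stations >= 3)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  lat <- seq(26, 47, length.out = n_stations) +
    stats::runif(n_stations, -0.4, 0.4)
  lon <- stats::runif(n_stations, -98, -80)
  meta <- data.frame(station_id = sprintf("SYN%03d", seq_len(n_stations)),
                     lat = lat, lon = lon)
  start <- sprintf("%d-07-01 00:00:00", start_year)
  end <- sprintf("%d-07-01 00:00:00", start_year + n_years)
  series <- lapply(seq_len(n_stations), function(i) {
    sc <- weather_scenario(
      annual_mean_c = base_mean_c - gradient * (lat[i] - 26),
      annual_amplitude_c = 12 + 0.15 * (lat[i] - 26),
      ar_sd = ar_sd, ar_coef = ar_coef,
      resolution_min = resolution_min, seed = seed * 1000 + i)
    gen_temperature_series(sc, start, end, station_id = meta$station_id[i])
  })
  names(series) <- meta$station_id
  list(meta = meta, series = series)
}

#' Generate clustered occurrence records
#'
#' Draws points from a mixture of Gaussian clusters (isotropic scatter in
#' km converted to degrees at each cluster's latitude); used to exercise
#' spatial thinning and grid extraction.
#'
#' @param n Total number of records (>= 1).
#' @param clusters Data frame `lat, lon, spread_km` (one row per cluster;
#'   records are assigned round-robin).
#' @param seed Integer seed.
#' @return A data frame `id, lat, lon` with ids `occ0001, ...`.
#' @export
gen_occurrences <- function(n, clusters, seed) {
  stopifnot(n >= 1, all(c("lat", "lon", "spread_km") %in% names(clusters)))
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  ci <- rep_len(seq_len(nrow(clusters)), n)
  lat0 <- clusters$lat[ci]; lon0 <- clusters$lon[ci]
  sd_deg_lat <- clusters$spread_km[ci] / 111.32
  sd_deg_lon <- clusters$spread_km[ci] / (111.32 * cos(lat0 * pi / 180))
  data.frame(id = sprintf("occ%04d", seq_len(n)),
             lat = stats::rnorm(n, lat0, sd_deg_lat),
             lon = stats::rnorm(n, lon0, sd_deg_lon))
}
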