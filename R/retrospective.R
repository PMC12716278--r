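#' Logistic regression of assay mortality on time and temperature drop
#'
#' Binomial GLM (logit link) of per-cell mortality on exposure time in
#' hours and temperature drop (the negated treatment temperature, so the
#' coefficient reads as log-odds of mortality per degree C of cooling),
#' weighted by the insects per cell.  When the table stores cell-mean
#' proportions, death counts are rounded to the nearest integer so the
#' binomial likelihood is exact.
#'
#' @param assays A [survival_assay] data frame.
#' @return A list with `coef_time` (per hour), `coef_tdrop` (per degree C),
#'   their standard errors `se_time`, `se_tdrop`, p-values `p_time`,
#'   `p_tdrop`, and the underlying `glm` fit.
#' @examples
#' assay_logistic_regression(assay_fixture("amynothrips"))$coef_tdrop
#' @export
assay_logistic_regression <- function(assays) {
  stopifnot(inherits(assays, "data.frame"),
            all(c("temperature_c", "exposure_h", "n_exposed",
                  "proportion_dead") %in% names(assays)))
  d <- data.frame(dead = round(assays$proportion_dead * assays$n_exposed),
                  n = round(assays$n_exposed),
                  time_h = assays$exposure_h,
                  tdrop = -assays$temperature_c)
  fit <- stats::glm(cbind(dead, n - dead) ~ time_h + tdrop,
                    family = stats::binomial(), data = d)
  s <- summary(fit)$coefficients
  list(coef_time = s["time_h", "Estimate"],
       coef_tdrop = s["tdrop", "Estimate"],
       se_time = s["time_h", "Std. Error"],
       se_tdrop = s["tdrop", "Std. Error"],
       p_time = s["time_h", "Pr(>|z|)"],
       p_tdrop = s["tdrop", "Pr(>|z|)"],
       fit = fit)
}

#' Annual winter mortality at a collection site
#'
#' For each winter year, finds the nearest station (great-circle) whose
#' series passes the Oct-Apr completeness screen that year and returns the
#' peak monthly mortality computed there.  Years with no adequate station
#' are dropped and listed.
#'
#' @param series_list Named list of multi-year [temperature_series], one
#'   per station.
#' @param meta Data frame `station_id, lat, lon`.
#' @param params A [chill_params] object.
#' @param site_lat,site_lon Collection-site coordinates.
#' @param max_missing Per-year Oct-Apr missing-data tolerance (default
#'   0.25).
#' @param completeness Monthly completeness threshold (default 0.75).
#' @return A list with `mortality` (named by winter-year label),
#'   `station` (the station used per year), and `dropped` (named reasons).
#' @export
annual_site_mortality <- function(series_list, meta, params,
                                  site_lat, site_lon,
                                  max_missing = 0.25, completeness = 0.75) {
  stopifnot(all(names(series_list) %in% meta$station_id))
  meta <- meta[match(names(series_list), meta$station_id), ]
  d <- haversine_km(site_lat, site_lon, meta$lat, meta$lon)
  ord <- order(d)
  winters <- lapply(series_list, split_winter_years)
  labels <- sort(unique(unlist(lapply(winters, names))))
  mort <- numeric(0); used <- character(0); dropped <- character(0)
  for (lab in labels) {
    found <- FALSE
    for (i in ord) {
      w <- winters[[i]][[lab]]
      if (is.null(w)) next
      if (winter_completeness(w) < 1 - max_missing) next
      pk <- peak_winter_mortality(monthly_mortality(w, params, completeness))
      if (is.na(pk)) next
      mort[lab] <- pk
      used[lab] <- meta$station_id[i]
      found <- TRUE
      break
    }
    if (!found)
      dropped[lab] <- "no station with adequate weather data"
  }
  list(mortality = mort, station = used, dropped = dropped)
}

#' Regress spring collection counts on predicted winter mortality
#'
#' Ordinary least squares of the number of insects collected in spring on
#' the predicted mortality of the preceding winter, with mortality
#' expressed in percent (0-100) so the slope reads as the change in
#' collection count per percentage-point increase in predicted mortality.
#'
#' @param data Data frame with columns `collected` (count) and
#'   `predicted_mortality` (proportion in `[0, 1]`); needs >= 3 complete
#'   rows.
#' @return A list with `slope` (per percent), `se`, `t`, `p`, `r_squared`,
#'   `intercept`, `n`, and the `lm` fit.
#' @export
regress_collections <- function(data) {
  stopifnot(all(c("collected", "predicted_mortality") %in% names(data)))
  d <- data[stats::complete.cases(data[, c("collected",
                                           "predicted_mortality")]), ]
  if (nrow(d) < 3)
    stop("regress_collections: need at least 3 years with both fields")
  if (stats::var(d$predicted_mortality) == 0)
    stop("regress_collections: predictor has zero variance")
  d$mortality_pct <- 100 * d$predicted_mortality
  fit <- stats::lm(collected ~ mortality_pct, data = d)
  s <- summary(fit)
  list(slope = s$coefficients["mortality_pct", "Estimate"],
       se = s$coefficients["mortality_pct", "Std. Error"],
       t = s$coefficients["mortality_pct", "t value"],
       p = s$coefficients["mortality_pct", "Pr(>|t|)"],
       r_squared = s$r.squared,
       intercept = s$coefficients["(Intercept)", "Estimate"],
       n = nrow(d), fit = fit)
}
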