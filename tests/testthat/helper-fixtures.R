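# Shared fixtures: published parameter sets and a tiny deterministic series
thrips_params <- function() published_chill_params("amynothrips")
beetle_params <- function() published_chill_params("agasicles")

# a short hourly series with a prescribed temperature vector
hourly_series <- function(temps, start = "2010-01-01 00:00:00",
                          station = "TST") {
  ts <- seq(as.POSIXct(start, tz = "UTC"), by = 3600,
            length.out = length(temps))
  temperature_series(station, ts, temps, resolution_min = 60)
}

# closed-form survival after the whole series: logit-additive one-liner
closed_form_final_survival <- function(temps, p, x = 1) {
  dose <- sum(pmin(temps - p$c, 0))
  stats::plogis(p$a + p$b * x * dose)
}

# brute-force greedy thinning oracle (independent of the implementation)
thin_oracle <- function(records, radius_km = 15) {
  rec <- records[order(records$id), , drop = FALSE]
  kept <- list()
  for (i in seq_len(nrow(rec))) {
    ok <- TRUE
    for (k in kept) {
      d <- geosphere::distHaversine(c(rec$lon[i], rec$lat[i]),
                                    c(k$lon, k$lat), r = 6371.0088)
      if (d < radius_km) { ok <- FALSE; break }
    }
    if (ok) kept[[length(kept) + 1]] <- rec[i, ]
  }
  do.call(rbind, kept)
}
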