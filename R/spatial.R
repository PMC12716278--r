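#' Great-circle distances in kilometres
#'
#' Haversine distance on a sphere of mean Earth radius 6371.0088 km,
#' computed by [geosphere::distHaversine()].
#'
#' @param lat1,lon1,lat2,lon2 Decimal-degree coordinates (vectorized).
#' @return Distances in km.
#' @export
haversine_km <- function(lat1, lon1, lat2, lon2) {
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                           r = 6371.0088)
}

# full pairwise distance matrix in km
.dist_matrix_km <- function(lat, lon) {
  n <- length(lat)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) {
    d[i, ] <- haversine_km(lat[i], lon[i], lat, lon)
  }
  (d + t(d)) / 2      # symmetrize roundoff
}

#' Empirical semivariogram (Matheron estimator)
#'
#' Bins the pairwise great-circle distances into `n_bins` equal-width lags
#' up to half the maximum pairwise distance and computes the classical
#' estimator \eqn{\gamma(h) = \frac{1}{2 N(h)} \sum (z_i - z_j)^2} per bin.
#'
#' @param lat,lon Point coordinates (>= 10 points).
#' @param values Numeric values at the points.
#' @param n_bins Number of distance bins (default 15).
#' @return A data frame of class `empirical_variogram`: `dist` (bin
#'   midpoint, km), `gamma`, `n_pairs`; attribute `flat` is `TRUE` when all
#'   values are identical (variogram is all zero).
#' @export
empirical_variogram <- function(lat, lon, values, n_bins = 15) {
  n <- length(values)
  stopifnot(length(lat) == n, length(lon) == n)
  if (n < 10) stop("empirical_variogram: need at least 10 points")
  D <- .dist_matrix_km(lat, lon)
  iu <- which(upper.tri(D))
  h <- D[iu]
  sq <- outer(values, values, function(a, b) (a - b)^2)[iu]
  hmax <- max(h) / 2
  edges <- seq(0, hmax, length.out = n_bins + 1)
  bin <- findInterval(h, edges, rightmost.closed = TRUE)
  keep <- bin >= 1 & bin <= n_bins
  g <- vapply(seq_len(n_bins), function(j) {
    s <- sq[keep & bin == j]
    if (length(s)) sum(s) / (2 * length(s)) else NA_real_
  }, numeric(1))
  np <- vapply(seq_len(n_bins), function(j) sum(keep & bin == j), integer(1))
  out <- data.frame(dist = (edges[-1] + edges[-(n_bins + 1)]) / 2,
                    gamma = g, n_pairs = np)
  out <- out[np > 0, ]
  attr(out, "flat") <- all(abs(out$gamma) < .Machine$double.eps * 100)
  class(out) <- c("empirical_variogram", "data.frame")
  out
}

# spherical model gamma(h)
.sph_gamma <- function(h, nugget, psill, range) {
  g <- ifelse(h <= 0, 0,
              ifelse(h < range,
                     nugget + psill * (1.5 * h / range - 0.5 * (h / range)^3),
                     nugget + psill))
  g
}

#' Fit a spherical semivariogram model
#'
#' Weighted least squares with the pair counts as weights:
#' \eqn{\gamma(h) = nugget + psill (1.5 h/r - 0.5 (h/r)^3)} for `h < r`,
#' levelling at `nugget + psill` beyond the range `r`.  All three
#' parameters are constrained non-negative.  Optimization is a multi-start
#' box-constrained quasi-Newton search; if nothing converges the fit falls
#' back to a pure-nugget-free default (nugget 0, sill = variogram mean,
#' range = half the maximum lag) with a warning.
#'
#' @param vg An [empirical_variogram] with at least 3 populated bins.
#' @return A list of class `variogram_model`: `nugget`, `psill`, `range`
#'   (km), `sill` (= nugget + psill), `converged`, `pure_nugget`.
#' @export
fit_spherical <- function(vg) {
  stopifnot(inherits(vg, "data.frame"), nrow(vg) >= 3)
  h <- vg$dist; g <- vg$gamma; w <- vg$n_pairs
  if (isTRUE(attr(vg, "flat")) || all(abs(g) < 1e-15)) {
    warning("fit_spherical: flat variogram; returning pure-nugget fallback")
    return(structure(list(nugget = 0, psill = 0, range = max(h) / 2,
                          sill = 0, converged = FALSE, pure_nugget = TRUE),
                     class = "variogram_model"))
  }
  obj <- function(p) sum(w * (g - .sph_gamma(h, p[1], p[2], p[3]))^2)
  sill0 <- max(g); best <- NULL
  for (r0 in stats::quantile(h, c(0.3, 0.6, 0.9, 1))) {
    for (n0 in c(0, 0.1 * sill0)) {
      o <- tryCatch(
        stats::optim(c(n0, sill0 - n0, r0), obj, method = "L-BFGS-B",
                     lower = c(0, 1e-10, 1e-6),
                     upper = c(sill0 * 2, sill0 * 4, max(h) * 4)),
        error = function(e) NULL)
      if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
    }
  }
  if (is.null(best)) {
    warning("fit_spherical: optimization failed; using fallback ",
            "(nugget 0, sill = mean gamma, range = max lag / 2)")
    return(structure(list(nugget = 0, psill = mean(g), range = max(h) / 2,
                          sill = mean(g), converged = FALSE,
                          pure_nugget = FALSE), class = "variogram_model"))
  }
  structure(list(nugget = best$par[1], psill = best$par[2],
                 range = best$par[3], sill = best$par[1] + best$par[2],
                 converged = TRUE, pure_nugget = best$par[2] <= 1e-9),
            class = "variogram_model")
}

#' @export
print.variogram_model <- function(x, ...) {
  cat(sprintf(
    "Spherical variogram model: nugget %.4g, partial sill %.4g, range %.4g km%s\n",
    x$nugget, x$psill, x$range,
    if (x$pure_nugget) " [pure nugget]" else ""))
  invisible(x)
}

#' Regular lat/lon prediction lattice
#'
#' @param lat,lon Coordinates whose bounding box the grid should cover
#'   (typically the stations).
#' @param resolution Cell size in degrees (default 0.25).
#' @return A data frame `lat, lon` of cell centers.
#' @export
make_grid <- function(lat, lon, resolution = 0.25) {
  stopifnot(resolution > 0)
  la <- seq(min(lat), max(lat), by = resolution)
  lo <- seq(min(lon), max(lon), by = resolution)
  expand.grid(lat = la, lon = lo, KEEP.OUT.ATTRS = FALSE)
}

#' Ordinary kriging of station mortalities onto a grid
#'
#' For each grid cell the `k` nearest stations (great-circle) enter the
#' standard ordinary-kriging system: the semivariance matrix among
#' neighbours, augmented with the unbiasedness row forcing the weights to
#' sum to 1, solved against the semivariances to the prediction point.
#' Predictions are clipped to `[0, 1]`.  A singular neighbourhood system
#' gets its semivariance diagonal jittered by `1e-10` and is retried once;
#' if still singular the cell is flagged missing.
#'
#' @param lat,lon,values Station coordinates and mortalities.
#' @param grid Data frame `lat, lon` of prediction cells (see
#'   [make_grid()]).
#' @param model A `variogram_model` from [fit_spherical()].
#' @param k Neighbours per prediction (default 12; reduced to `n` when
#'   fewer stations exist; `k = n` gives the dense, all-station solve).
#' @param clip Clip predictions into `[0, 1]` (default `TRUE`).
#' @return A data frame of class `suitability_grid`: `lat, lon, mortality,
#'   class`; kriging weight sums are attached as attribute `weight_sums`.
#' @export
krige <- function(lat, lon, values, grid, model, k = 12, clip = TRUE) {
  n <- length(values)
  stopifnot(length(lat) == n, length(lon) == n,
            inherits(model, "variogram_model"))
  k <- min(k, n)
  preds <- rep(NA_real_, nrow(grid))
  wsums <- rep(NA_real_, nrow(grid))
  D <- .dist_matrix_km(lat, lon)
  for (g in seq_len(nrow(grid))) {
    d0 <- haversine_km(grid$lat[g], grid$lon[g], lat, lon)
    nb <- order(d0)[seq_len(k)]
    G <- .sph_gamma(D[nb, nb, drop = FALSE], model$nugget, model$psill,
                    model$range)
    diag(G) <- 0
    A <- rbind(cbind(G, 1), c(rep(1, k), 0))
    rhs <- c(.sph_gamma(d0[nb], model$nugget, model$psill, model$range), 1)
    sol <- tryCatch(solve(A, rhs), error = function(e) NULL)
    if (is.null(sol)) {
      A2 <- A
      diag(A2)[seq_len(k)] <- diag(A2)[seq_len(k)] + 1e-10
      sol <- tryCatch(solve(A2, rhs), error = function(e) NULL)
    }
    if (is.null(sol)) next
    w <- sol[seq_len(k)]
    wsums[g] <- sum(w)
    preds[g] <- sum(w * values[nb])
  }
  if (clip) preds <- pmin(pmax(preds, 0), 1)
  out <- data.frame(lat = grid$lat, lon = grid$lon, mortality = preds,
                    class = classify_suitability(pmin(pmax(preds, 0), 1)))
  attr(out, "weight_sums") <- wsums
  class(out) <- c("suitability_grid", "data.frame")
  out
}

#' Suitability classes
#'
#' Five habitat-suitability labels partitioning predicted mortality in
#' `[0, 1]` into half-open bins: `[0, 0.25]` highly suitable,
#' `(0.25, 0.50]` moderately suitable, `(0.50, 0.75]` moderately
#' unsuitable, `(0.75, 0.95]` highly unsuitable, `(0.95, 1]` completely
#' unsuitable.  The published bin edges had small gaps and one overlap at
#' the printed precision; this partition keeps the printed lower anchors
#' and closes each bin on the right so every value gets exactly one label.
#'
#' @param mortality Values in `[0, 1]` (`NA` passes through).
#' @return An ordered factor with the five labels.
#' @export
classify_suitability <- function(mortality) {
  if (any(mortality < 0 | mortality > 1, na.rm = TRUE))
    stop("classify_suitability: mortality must lie in [0, 1]")
  cut(mortality, breaks = c(0, 0.25, 0.50, 0.75, 0.95, 1),
      labels = suitability_levels(), include.lowest = TRUE,
      right = TRUE, ordered_result = TRUE)
}

#' @rdname classify_suitability
#' @export
suitability_levels <- function() {
  c("highly suitable", "moderately suitable", "moderately unsuitable",
    "highly unsuitable", "completely unsuitable")
}

#' Spatial thinning of occurrence records
#'
#' Deterministic greedy scan in ascending record-id order: a record is kept
#' iff its great-circle distance to every already-kept record is at least
#' `radius_km`.  Exact duplicates of kept points are therefore dropped, and
#' rerunning on the thinned output is a no-op.
#'
#' @param records Data frame with columns `id`, `lat`, `lon`.
#' @param radius_km Minimum pairwise distance (default 15 km).
#' @return The retained subset, in scan order.
#' @export
thin_occurrences <- function(records, radius_km = 15) {
  stopifnot(all(c("id", "lat", "lon") %in% names(records)))
  if (!nrow(records)) return(records)
  rec <- records[order(records$id), , drop = FALSE]
  keep <- integer(0)
  for (i in seq_len(nrow(rec))) {
    if (!length(keep) ||
        all(haversine_km(rec$lat[i], rec$lon[i],
                         rec$lat[keep], rec$lon[keep]) >= radius_km))
      keep <- c(keep, i)
  }
  rec[keep, , drop = FALSE]
}

#' Extract grid mortality at occurrence records and summarize
#'
#' Assigns each record the predicted mortality of its nearest grid cell,
#' classifies it, and tabulates the percentage of records per suitability
#' class plus the combined suitable (highly + moderately suitable) versus
#' unsuitable split.  Records farther than one cell diagonal from every
#' grid cell are counted as outside the grid and excluded from the
#' percentages, with a warning.
#'
#' @param grid A `suitability_grid` from [krige()].
#' @param records Data frame `id, lat, lon`.
#' @return A list with `records` (input plus `mortality`, `class`),
#'   `pct_by_class` (named percentages over the five classes),
#'   `pct_suitable`, `pct_unsuitable`, `n_outside`.
#' @export
extract_and_summarize <- function(grid, records) {
  stopifnot(inherits(grid, "data.frame"),
            all(c("lat", "lon", "mortality") %in% names(grid)))
  if (!nrow(records)) {
    pct <- stats::setNames(rep(NA_real_, 5), suitability_levels())
    return(list(records = cbind(records, mortality = numeric(0),
                                class = character(0)),
                pct_by_class = pct, pct_suitable = NA_real_,
                pct_unsuitable = NA_real_, n_outside = 0L))
  }
  # nearest-cell tolerance: one cell diagonal, from the grid spacing
  ulat <- sort(unique(grid$lat)); ulon <- sort(unique(grid$lon))
  step <- max(if (length(ulat) > 1) min(diff(ulat)) else 0.25,
              if (length(ulon) > 1) min(diff(ulon)) else 0.25)
  tol_km <- step * sqrt(2) * 111.32
  mort <- rep(NA_real_, nrow(records))
  outside <- logical(nrow(records))
  for (i in seq_len(nrow(records))) {
    d <- haversine_km(records$lat[i], records$lon[i], grid$lat, grid$lon)
    j <- which.min(d)
    if (d[j] > tol_km) outside[i] <- TRUE else mort[i] <- grid$mortality[j]
  }
  if (any(outside))
    warning(sum(outside), " record(s) outside the grid; excluded from ",
            "percentages")
  cls <- classify_suitability(mort)
  inb <- !outside & !is.na(mort)
  tab <- table(factor(cls[inb], levels = suitability_levels()))
  pct <- 100 * as.numeric(tab) / sum(inb)
  names(pct) <- suitability_levels()
  list(records = cbind(records, mortality = mort, class = cls),
       pct_by_class = pct,
       pct_suitable = sum(pct[1:2]),
       pct_unsuitable = sum(pct[3:5]),
       n_outside = sum(outside))
}
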