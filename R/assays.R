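#' Survival assay tables
#'
#' A survival assay table holds one row per treatment cell of a cold
#' exposure experiment: a temperature, an exposure duration, the number of
#' insects exposed and the number dead (equivalently the proportion dead).
#' Missing design cells are simply absent rows.
#'
#' @param temperature_c Treatment temperature, degrees C.
#' @param exposure_h Exposure duration, hours (>= 0).
#' @param n_exposed Insects exposed per cell (>= 1).
#' @param n_dead Insects dead per cell; give either this or
#'   `proportion_dead`.
#' @param proportion_dead Proportion dead in `[0, 1]`; used with
#'   `n_exposed` as weight when replicate counts were averaged (cell means
#'   need not give integer death counts).
#' @param species Optional label recycled across rows.
#' @return A `data.frame` of class `survival_assay` with columns `species`,
#'   `temperature_c`, `exposure_h`, `n_exposed`, `proportion_dead`.
#' @export
survival_assay <- function(temperature_c, exposure_h, n_exposed,
                           n_dead = NULL, proportion_dead = NULL,
                           species = NA_character_) {
  n <- length(temperature_c)
  stopifnot(length(exposure_h) == n)
  n_exposed <- rep_len(n_exposed, n)
  if (is.null(proportion_dead)) {
    if (is.null(n_dead)) stop("survival_assay: give n_dead or proportion_dead")
    stopifnot(length(n_dead) == n)
    if (any(n_dead < 0) || any(n_dead > n_exposed))
      stop("survival_assay: need 0 <= n_dead <= n_exposed")
    proportion_dead <- n_dead / n_exposed
  }
  if (any(proportion_dead < 0) || any(proportion_dead > 1))
    stop("survival_assay: proportion_dead must lie in [0, 1]")
  if (any(exposure_h < 0)) stop("survival_assay: exposure_h must be >= 0")
  if (any(n_exposed < 1)) stop("survival_assay: n_exposed must be >= 1")
  out <- data.frame(species = rep_len(species, n),
                    temperature_c = as.numeric(temperature_c),
                    exposure_h = as.numeric(exposure_h),
                    n_exposed = as.numeric(n_exposed),
                    proportion_dead = as.numeric(proportion_dead))
  class(out) <- c("survival_assay", "data.frame")
  out
}

#' Read a survival assay CSV
#'
#' Expects columns `species`, `temperature_c`, `exposure_h`, `n_exposed`
#' and either `n_dead` or `proportion_dead`.  The file records mortality;
#' conversion to survival happens once, inside the model fit.
#'
#' @param path Path to a CSV file.
#' @return A [survival_assay] data frame.
#' @seealso [assay_fixture()] for the packaged published tables.
#' @export
read_assay_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("temperature_c", "exposure_h", "n_exposed")
  if (!all(need %in% names(d)))
    stop("read_assay_csv: missing columns ",
         paste(setdiff(need, names(d)), collapse = ", "))
  survival_assay(d$temperature_c, d$exposure_h, d$n_exposed,
                 n_dead = d$n_dead, proportion_dead = d$proportion_dead,
                 species = if ("species" %in% names(d)) d$species else NA)
}

#' Packaged published assay tables
#'
#' Cell-mean mortality tables for the two alligatorweed biological control
#' agents, transcribed cell by cell from the published incomplete
#' time-by-temperature cross for the thrips (33 populated cells, 50
#' individuals per cell) and the complete 5 x 4 cross for the flea beetle
#' (20 cells; per-cell replication was unequal and unpublished, so
#' `n_exposed` is the study-wide average of 68 and fits on this table
#' should weight cells equally).
#'
#' @param which `"amynothrips"` (thrips) or `"agasicles"` (flea beetle).
#' @return A [survival_assay] data frame.
#' @export
assay_fixture <- function(which = c("amynothrips", "agasicles")) {
  which <- match.arg(which)
  f <- c(amynothrips = "amynothrips_assays.csv",
         agasicles = "agasicles_assays.csv")[[which]]
  read_assay_csv(system.file("extdata", f, package = "chillmap",
                             mustWork = TRUE))
}

#' Fit the chill-injury survival model by nonlinear least squares
#'
#' Minimizes the (optionally weighted) sum of squared differences between
#' observed cell survival (`1 - proportion_dead`) and the logistic
#' time-temperature model.  The objective is non-convex in the ULCIZ `c`,
#' so the fit runs a deterministic multi-start: `c` starts on a grid from
#' the lowest observed temperature up to +10 degrees C in 2-degree steps,
#' `b` starts at `1e-4, 1e-3, 1e-2, 1e-1`, and `a` starts at the logit of
#' the survival observed under the mildest condition (shortest exposure at
#' the warmest temperature).  Each start is polished by Levenberg-Marquardt
#' least squares ([minpack.lm::nlsLM()]); the lowest SSE wins, with ties
#' broken toward smaller `|b|`, so the result is reproducible.
#'
#' @param assays A [survival_assay] data frame with at least 4 cells
#'   spanning at least 2 temperatures and 2 exposure times, and at least
#'   one cell showing injury.
#' @param weighting `"counts"` weights each cell by `n_exposed` (the
#'   default; equals equal-weight cells under balanced replication);
#'   `"cells"` weights all cells equally, the mode for published cell-mean
#'   tables whose replication is unknown.
#' @return A [chill_params] object with asymptotic standard errors; the
#'   fitted `nls` object and the winning SSE are attached as attributes
#'   `fit` and `sse`.
#' @examples
#' fit_chill_model(assay_fixture("agasicles"), weighting = "cells")
#' @export
fit_chill_model <- function(assays, weighting = c("counts", "cells")) {
  weighting <- match.arg(weighting)
  stopifnot(inherits(assays, "data.frame"))
  d <- data.frame(S = 1 - assays$proportion_dead,
                  t = assays$exposure_h, temp = assays$temperature_c,
                  w = if (weighting == "counts") assays$n_exposed
                      else rep(1, nrow(assays)))
  if (nrow(d) < 4 || length(unique(d$temp)) < 2 || length(unique(d$t)) < 2)
    stop("fit_chill_model: need >= 4 cells spanning >= 2 temperatures ",
         "and >= 2 exposure times")
  if (all(d$S >= 1))
    stop("fit_chill_model: degenerate data, no cell shows injury")
  if (all(d$S <= 0))
    stop("fit_chill_model: degenerate data, all cells fully dead")

  # logit of survival under the mildest condition, clamped off 0/1
  mild <- d[order(-d$temp, d$t), ][1L, ]
  a0 <- stats::qlogis(min(max(mild$S, 1e-3), 1 - 1e-3))
  c_grid <- seq(min(d$temp), max(d$temp) + 10, by = 2)
  b_grid <- c(1e-4, 1e-3, 1e-2, 1e-1)

  best <- NULL
  best_sse_any <- Inf
  for (c0 in c_grid) for (b0 in b_grid) {
    f <- tryCatch(
      minpack.lm::nlsLM(
        S ~ stats::plogis(a + b * t * (temp - c)),
        data = d, weights = d$w,
        start = list(a = a0, b = b0, c = c0),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL, warning = function(w) NULL)
    if (is.null(f)) next
    best_sse_any <- min(best_sse_any, sum(d$w * stats::resid(f)^2))
    co <- stats::coef(f)
    if (!all(is.finite(co)) || co[["b"]] <= 0) next
    sse <- sum(d$w * stats::resid(f)^2)
    take <- is.null(best) || sse < best$sse - 1e-10 ||
      (abs(sse - best$sse) <= 1e-10 && abs(co[["b"]]) < abs(best$b))
    if (take) best <- list(fit = f, sse = sse, b = co[["b"]])
  }
  if (is.null(best)) {
    stop("fit_chill_model: no start converged to a valid optimum (b > 0); ",
         "best weighted SSE seen was ",
         if (is.finite(best_sse_any)) signif(best_sse_any, 6) else "none ",
         " -- try rescaling exposures or adding injurious cells")
  }
  co <- stats::coef(best$fit)
  se <- tryCatch(sqrt(diag(stats::vcov(best$fit))),
                 error = function(e) c(a = NA, b = NA, c = NA))
  p <- chill_params(co[["a"]], co[["b"]], co[["c"]],
                    se_a = se[["a"]], se_b = se[["b"]], se_c = se[["c"]],
                    species = assays$species[1L])
  attr(p, "fit") <- best$fit
  attr(p, "sse") <- best$sse
  p
}
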