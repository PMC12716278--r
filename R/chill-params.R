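#' Chill-injury model parameters
#'
#' Container for the fitted triple (a, b, c) of the logistic time-temperature
#' survival model
#' \deqn{S(t, T) = \frac{e^{a + b t (T - c)}}{1 + e^{a + b t (T - c)}}}{
#'       S(t,T) = plogis(a + b t (T - c))}
#' where `t` is exposure time in hours and `T` temperature in degrees C.
#' The parameter `c` is the upper limit of the chill injury zone (ULCIZ),
#' the lowest temperature at which no chill injury accrues; `b` is the
#' injury rate per hour and per degree below `c`; `a` sets the
#' zero-exposure (handling) survival `plogis(a)`.  The ratio `-a/b` is the
#' sum of injurious temperatures (SIT), the degree-hour budget below the
#' ULCIZ that halves survival.
#'
#' @param a Dimensionless logit-scale intercept.
#' @param b Injury rate, per (hour * degree C); must be positive.
#' @param c ULCIZ in degrees C.
#' @param se_a,se_b,se_c Optional non-negative asymptotic standard errors.
#' @param species Optional free-text label for the organism.
#'
#' @return An object of class `chill_params`: a named list with elements
#'   `a`, `b`, `c`, `se_a`, `se_b`, `se_c`, `species`.
#' @seealso [fit_chill_model()], [sit()], [lt50_time()], [chill_survival()]
#' @examples
#' p <- chill_params(a = 1.367, b = 4.45e-3, c = -2.941,
#'                   species = "Amynothrips andersoni")
#' sit(p)
#' @export
chill_params <- function(a, b, c, se_a = NA_real_, se_b = NA_real_,
                         se_c = NA_real_, species = NA_character_) {
  stopifnot(is.numeric(a), is.numeric(b), is.numeric(c),
            length(a) == 1L, length(b) == 1L, length(c) == 1L)
  if (!is.finite(a) || !is.finite(b) || !is.finite(c))
    stop("chill_params: a, b, c must be finite")
  if (b <= 0)
    stop("chill_params: injury rate b must be positive")
  for (se in list(se_a, se_b, se_c))
    if (!is.na(se) && se < 0) stop("chill_params: standard errors must be >= 0")
  structure(list(a = as.numeric(a), b = as.numeric(b), c = as.numeric(c),
                 se_a = as.numeric(se_a), se_b = as.numeric(se_b),
                 se_c = as.numeric(se_c), species = species),
            class = "chill_params")
}

#' @export
print.chill_params <- function(x, ...) {
  cat("Chill-injury survival model parameters")
  if (!is.na(x$species)) cat(" [", x$species, "]", sep = "")
  cat("\n")
  fmt <- function(v, se) {
    if (is.na(se)) sprintf("%.5g", v) else sprintf("%.5g (se %.3g)", v, se)
  }
  cat("  a (intercept):        ", fmt(x$a, x$se_a), "\n")
  cat("  b (injury rate /h/C): ", fmt(x$b, x$se_b), "\n")
  cat("  c (ULCIZ, degC):      ", fmt(x$c, x$se_c), "\n")
  cat("  SIT (a/b):            ", sprintf("%.4g", sit(x)), "degree-hours\n")
  cat("  survival at t = 0:    ", sprintf("%.4f", stats::plogis(x$a)), "\n")
  invisible(x)
}

#' Published parameter sets for the two alligatorweed agents
#'
#' Point estimates and standard errors (half of the reported 2*SD
#' intervals) for the alligatorweed thrips *Amynothrips andersoni* and the
#' alligatorweed flea beetle *Agasicles hygrophila*, as determined by
#' nonlinear least squares on laboratory cold-exposure assays.
#'
#' @param species `"amynothrips"` (thrips) or `"agasicles"` (flea beetle).
#' @return A [chill_params] object.
#' @examples
#' sit(published_chill_params("amynothrips"))
#' @export
published_chill_params <- function(species = c("amynothrips", "agasicles")) {
  species <- match.arg(species)
  switch(species,
    amynothrips = chill_params(a = 1.367, b = 4.45e-3, c = -2.941,
                               se_a = 0.348 / 2, se_b = 1.36e-3 / 2,
                               se_c = 0.717 / 2,
                               species = "Amynothrips andersoni"),
    agasicles   = chill_params(a = 2.895, b = 0.01152, c = 4.520,
                               se_a = 0.325 / 2, se_b = 0.00169 / 2,
                               se_c = 0.411 / 2,
                               species = "Agasicles hygrophila"))
}

#' Read or write chill-model parameters as JSON
#'
#' The JSON object stores `a`, `b`, `c`, the standard errors and the
#' species label; the format the `chillmap fit` command emits.
#'
#' @param params A [chill_params] object.
#' @param path File path.
#' @return `write_chill_params()` returns `path` invisibly;
#'   `read_chill_params()` returns a [chill_params] object.
#' @export
write_chill_params <- function(params, path) {
  stopifnot(inherits(params, "chill_params"))
  jsonlite::write_json(unclass(params)[c("a", "b", "c", "se_a", "se_b",
                                         "se_c", "species")],
                       path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_chill_params
#' @export
read_chill_params <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  num <- function(v) if (is.null(v) || is.na(suppressWarnings(as.numeric(v))))
    NA_real_ else as.numeric(v)
  chill_params(num(j$a), num(j$b), num(j$c), se_a = num(j$se_a),
               se_b = num(j$se_b), se_c = num(j$se_c),
               species = if (is.null(j$species)) NA_character_
                         else as.character(j$species))
}

#' Survival after constant cold exposure
#'
#' Evaluates the logistic time-temperature survival model at exposure `t`
#' hours and temperature `temp` degrees C.  Computed on the logit scale, so
#' it underflows gracefully to values in (0, 1) rather than overflowing.
#' At `temp = c` the time term vanishes and survival equals the
#' zero-exposure intercept `plogis(a)`; above the ULCIZ the raw regression
#' surface is extrapolating (survival nominally rises with time) — the
#' mortality accumulator never uses that branch, but it is the surface the
#' model is fitted on, so it is what this function returns unless
#' `truncate_warm = TRUE`.
#'
#' @param t Exposure duration in hours (vectorized, must be >= 0).
#' @param temp Temperature in degrees C (vectorized).
#' @param params A [chill_params] object.
#' @param truncate_warm If `TRUE`, hold temperatures above the ULCIZ at the
#'   zero-injury boundary (`survival(t, T) = survival(0, T)` for `T >= c`),
#'   the physically meaningful surface for prediction and plotting.
#' @return Survival proportions in (0, 1).
#' @examples
#' p <- published_chill_params("amynothrips")
#' chill_survival(0, 0, p)          # zero-exposure intercept, ~0.797
#' chill_survival(48, -12, p)
#' @export
chill_survival <- function(t, temp, params, truncate_warm = FALSE) {
  stopifnot(inherits(params, "chill_params"))
  if (any(!is.finite(t)) || any(!is.finite(temp)))
    stop("chill_survival: non-finite inputs")
  if (any(t < 0)) stop("chill_survival: exposure time t must be >= 0")
  dT <- temp - params$c
  if (truncate_warm) dT <- pmin(dT, 0)
  stats::plogis(params$a + params$b * t * dT)
}

#' Sum of injurious temperatures
#'
#' SIT is the degree-hour budget below the ULCIZ that reduces survival to
#' 50%: the magnitude of `-a/b`.  Under this package's sign convention
#' (`b > 0`, injury accruing as `b t (T - c)` with `T < c`) that is
#' `a / b`, which equals the LT50 exposure time exactly one degree below
#' the ULCIZ, `lt50_time(c - 1, params)`.
#'
#' @param params A [chill_params] object.
#' @return A single number on the degree-hour scale (positive when
#'   zero-exposure survival exceeds one half).
#' @export
sit <- function(params) {
  stopifnot(inherits(params, "chill_params"))
  if (params$b <= 0) stop("sit: requires b > 0")
  params$a / params$b
}

#' Exposure time to 50% survival at a constant temperature
#'
#' Setting `S = 0.5` in the survival model and solving for time gives
#' `t = -a / (b (T - c))`, defined only below the ULCIZ where chill injury
#' accrues.  The time shrinks as the temperature falls further below `c`.
#'
#' @param temp Temperature in degrees C; must be strictly below the ULCIZ.
#' @param params A [chill_params] object.
#' @return LT50 exposure time in hours (vectorized over `temp`).
#' @examples
#' p <- published_chill_params("amynothrips")
#' lt50_time(p$c - 1, p)   # equals sit(p)
#' @export
lt50_time <- function(temp, params) {
  stopifnot(inherits(params, "chill_params"))
  if (any(!is.finite(temp))) stop("lt50_time: non-finite temperature")
  if (any(temp >= params$c))
    stop("lt50_time: no chill injury at or above the ULCIZ (T >= c)")
  -params$a / (params$b * (temp - params$c))
}
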