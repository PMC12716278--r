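---
title: "Chill-injury accumulation and overwintering suitability: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chill-injury accumulation and overwintering suitability: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chillmap)
```

## The problem

Tropical and subtropical insects released as weed biological control agents
often fail at temperate latitudes because winters kill them. For the
alligatorweed system — the flea beetle *Agasicles hygrophila* and the thrips
*Amynothrips andersoni*, both released against *Alternanthera philoxeroides*
in the southeastern USA — the limiting injury is not freezing but *chill
injury*: non-freezing damage that accumulates with both the depth of cold
below a species-specific threshold and the time spent there. chillmap
implements a mechanistic pipeline that turns laboratory cold-exposure assays
into maps of predicted overwintering mortality: fit a time-temperature
survival model, run its parameters over multi-year weather-station records,
interpolate station mortalities across a region, and classify habitat
suitability.

## The survival model

Survival of a population after `t` hours at constant temperature `T` (degC)
is modelled as a logistic surface

$$S(t, T) = \frac{e^{a + b\,t\,(T - c)}}{1 + e^{a + b\,t\,(T - c)}}.$$

* `c` is the **upper limit of the chill injury zone (ULCIZ)**, degC: the
  warmest temperature at which chill injury accrues. Above `c` the model is
  never evaluated for injury.
* `b` (per hour per degC, `b > 0`) scales how fast injury converts
  degree-hours below `c` into mortality on the log-odds scale.
* `a` is the zero-exposure logit: `S(0, T) = e^a / (1 + e^a)` absorbs
  handling/control mortality.
* **SIT**, the sum of injurious temperatures, is the degree-hour budget
  below the ULCIZ that halves survival. With our sign convention (`b > 0`)
  it equals `a / b`, which is also the LT50 exposure time exactly one degree
  below `c`: setting `S = 0.5` gives `t = -a / (b (T - c))`, implemented in
  `lt50_time()`.

All evaluation is done on the logit scale (`plogis`/`qlogis`), so logits of
magnitude several hundred neither overflow nor produce `NaN`; the deep lower
tail underflows gracefully toward 0 rather than through `exp()`.

### Fitting

`fit_chill_model()` minimizes the weighted sum of squared differences
between observed cell survival (1 − mortality) and the model. The objective
is non-convex in `c` — in real assay tables it can have several shallow
basins — so the optimizer is a *deterministic multi-start*: `c` starts on a
grid from the coldest observed treatment up to +10 degC in 2-degree steps,
`b` at `1e-4, 1e-3, 1e-2, 1e-1`, `a` at the logit of survival under the
mildest condition; each start is polished by Levenberg–Marquardt least
squares and the lowest SSE wins, ties going to the smaller `|b|`. Two
weighting modes exist: `"counts"` (cells weighted by insects exposed, the
default) and `"cells"` (equal weights, appropriate for published cell-mean
tables whose replication is unknown). Under balanced replication the two
coincide.

A caution that falls straight out of the flat SSE surface: on the packaged
thrips cell-mean table the global optimum sits at `c ≈ -5.17` while the
surface is nearly as good (within ~2% SSE) anywhere in `c ∈ [-5.2, -2.9]`.
Single-start NLS from a mild initial value will stop at the shallow end of
that plateau near `c ≈ -2.94`; the multi-start reports the true minimum.
Users comparing against published single-start fits should expect this kind
of divergence whenever the assay design leaves `c` weakly identified —
standard errors on `c` of ±0.4-0.7 degC are the symptom. The beetle table,
a complete cross, has a much better-conditioned optimum.

Degenerate tables (all cells alive, all dead, fewer than two temperatures
or exposure times) are rejected with explicit errors rather than returning
a boundary fit.

## The mortality accumulator

Field temperatures fluctuate, so constant-exposure survival cannot be read
off directly. The accumulator converts the previously accumulated survival
`S_{i-1}` into the *equivalent exposure time* at the current temperature —
the constant exposure at `T_i` that would have produced `S_{i-1}` — advances
it by one recording interval `x` (hours), and re-reads the survival curve:

$$t_i = \frac{\mathrm{logit}(S_{i-1}) - a}{b (T_i - c)} + x, \qquad
  S_i = S(t_i, T_i), \qquad M_i = S_{i-1} - S_i.$$

Algebraically the whole detour is one addition on the logit scale:

$$\mathrm{logit}(S_i) = \mathrm{logit}(S_{i-1}) + b\,x\,(T_i - c),$$

and that is how `accumulate_mortality()` computes it — a cumulative sum of
logit decrements over injurious records. This form has three consequences
the tests exercise directly:

* **Closed form**: `logit(S_final) = a + b x \sum_{T_i \le c} (T_i - c)`,
  an independent one-line oracle the recursion must match to 1e-10.
* **Path independence**: cumulative mortality depends on the multiset of
  injurious temperatures, not their order.
* **Telescoping**: `sum(M_i) = S_0 - S_final` exactly.

Design choices at the edges:

* Records with `T_i > c` leave survival unchanged: no injury, and — by
  assumption — *no recovery between chill events*. The model therefore
  over-predicts mortality to the extent real populations repair chill
  injury during warm spells; a recovery term is deliberately out of scope.
* `T_i = c` is treated as an injurious boundary no-op (decrement exactly
  zero). The logit-additive form has no division, so the `t_i` singularity
  of the textbook formula never arises; `t_i` is reported for audit only
  and is `NA` at or above the threshold.
* The equivalent-exposure form diverges as `S -> 0`, so survival is floored
  at 1e-12 before any logit. Once a trajectory saturates the closed-form
  identity above no longer applies (deliberately); tests of that identity
  use doses sized to stay off the floor.
* Recording gaps contribute neither injury nor time: each record advances
  the exposure clock by exactly `x` hours regardless of wall-clock gaps.

### Monthly windows and the winter year

`monthly_mortality()` resets survival to `S_0` at every calendar-month
boundary and accumulates each month independently; `peak_winter_mortality()`
takes the worst month of a July–June *winter year* (so a single winter
never straddles two files). The one-month window is a biological choice:
both agents develop in roughly 28 days, so a month approximates the
exposure of a single overwintering generation, and month-reset accumulation
(rather than truncating a season-long accumulation) is the reading we
implement. A month is reportable only if at least 75% (configurable) of its
expected records are present; month boundaries use the timestamps as
recorded (local standard time), with no daylight-saving arithmetic.

## Weather-station organization and QC

`read_canonical_series()` ingests the package's long CSV format
(`station_id,timestamp,temp_c`), sorting and collapsing duplicate
timestamps by mean; `read_asos_onemin()` is a best-effort fixed-width
parser for one-minute ASOS surface pages (station in columns 1–9, first
12-digit run as local `YYYYMMDDHHMM`, dry-bulb degF as the second-to-last
numeric token), skipping and counting unparseable lines and rejecting files
more than half unparseable. The packaged example file is synthetic, built
to that layout.

`station_qc()` mirrors the study's screen: stations must sit inside a
contiguous-US bounding box (default lat 24–50, lon −125 to −66 — a box, not
a polygon, since no geometry was published), each winter year must retain
at least 75% of its pooled October–April records (the "pooled" reading of
an ambiguous rule; a per-month variant can be had by applying the monthly
completeness flag), and at least 10 *qualifying* winter years must remain —
we count QC-passing years, not calendar span.

## Spatial interpolation and classification

Station mean peak mortalities are interpolated by **ordinary kriging**:
per prediction cell, the 12 nearest stations (the nearest-neighbor reading
of a "variable search radius of 12 points") enter the standard OK system —
semivariances among neighbors augmented with the unbiasedness constraint
forcing weights to sum to 1. The semivariogram is the Matheron estimator on
great-circle distances (haversine, mean Earth radius 6371.0088 km), binned
to half the maximum pairwise distance, with a **spherical model** fitted by
pair-count-weighted least squares. Zero-nugget kriging is an exact
interpolator, and the 12-neighbor solution must match a dense all-station
solve on small instances — both are tested rather than assumed. Singular
neighborhood systems get one diagonal jitter of 1e-10, then the cell is
flagged missing. Predictions are clipped to [0, 1]; the lattice is a plain
lat/lon grid (default 0.25 deg) over the station bounding box with no
land/water masking.

Predicted mortality maps to five suitability classes. The published bin
edges contain a gap and an overlap at printed precision, so the classifier
uses the half-open partition that keeps the printed lower anchors:
`[0, 0.25]` highly suitable, `(0.25, 0.50]` moderately suitable,
`(0.50, 0.75]` moderately unsuitable, `(0.75, 0.95]` highly unsuitable,
`(0.95, 1]` completely unsuitable — so 0.75 is moderately unsuitable and
every value has exactly one label.

`thin_occurrences()` reduces occurrence records so no two retained points
lie within 15 km: a greedy scan in ascending record-id order, chosen
because it is deterministic and reproducible (the GIS tool originally used
does not document its order). `extract_and_summarize()` assigns each
record its nearest cell's mortality and tallies class percentages.

## The retrospective regression

`regress_collections()` relates spring collection counts of the flea
beetle to predicted mortality of the preceding winter by ordinary least
squares, with mortality expressed in **percent** so the slope reads
"insects per percentage point of winter kill" — documented to prevent
silent 100-fold slope confusions. `annual_site_mortality()` supplies the
per-year predictor from the nearest station passing the completeness
screen that year (nearest-station is the testable default; a kriged
alternative can be assembled from the spatial layer).
`assay_logistic_regression()` provides the companion binomial GLM of assay
mortality on exposure time and temperature drop; cell-mean proportions are
rounded to integer death counts so the binomial likelihood is exact.

## What the synthetic generators emulate

Every pipeline input has a seeded generator, so the full chain is testable
offline:

* `gen_survival_experiment()` draws binomial deaths from a known parameter
  set over either published design (the thrips incomplete cross at 50 per
  cell; the beetle complete cross), closing the simulate-fit loop for
  parameter-recovery tests.
* `gen_temperature_series()` builds annual + diurnal sinusoids (coldest
  mid-January and pre-dawn), stationary AR(1) noise, and rectangular cold
  snaps. Defaults (annual mean 12 degC, amplitudes 14/4 degC, AR sd 2.5
  with coefficient 0.8, hourly resolution) describe a plausible temperate
  mid-latitude station; raising the annual mean toward 21 degC gives a
  Gulf-Coast-like station with near-zero beetle mortality, mirroring the
  qualitative south-north contrast of the mapped predictions.
* `gen_station_network()` arranges stations along a latitudinal
  severity gradient with 12 winter years each (so default QC passes);
  `gen_occurrences()` scatters clustered presence points for thinning
  tests.

What the generators do **not** emulate: spatially correlated weather
between stations beyond the latitude trend, heat waves and fronts with
realistic spectra, instrument drift, or the actual ASOS cleaning history.
Passing tests on synthetic data therefore validate the algebra, the
bookkeeping, and the statistical machinery — not climatological realism.

## Problem sizes and numerical tolerances

The test-suite problem sizes are chosen as the smallest that make each
property informative: closed-form accumulator checks use 300-record hourly
series; parameter-recovery uses 200 replicate simulated experiments at the
thrips design with 50 insects per cell (median absolute error of the
fitted ULCIZ must be at most 1 degC); the variogram-refit check simulates
one 150-point spherical Gaussian field; kriging equivalence checks use 5-
and 12-station configurations against a dense solve at 1e-8. Recursion
identities are asserted at 1e-10 to 1e-12; solver-based recoveries at
1e-6.

## Known limitations

* No recovery between chill events: mortality is over-predicted in
  climates with strong mid-winter warm spells.
* Adults only; life-stage-specific thresholds and acclimation are not
  modelled.
* The ULCIZ is weakly identified by sparse incomplete assay designs; report
  and propagate its standard error rather than treating the point estimate
  as sharp, and prefer complete crosses when designing assays.
* Kriging assumes second-order stationarity of station mortalities;
  mountain and coastal microclimates violate it at scales below typical
  station spacing.
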