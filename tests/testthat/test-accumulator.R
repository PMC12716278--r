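test_that("a warm record is a no-injury no-recovery step", {
  p <- thrips_params()
  for (temp in c(-2.9, 0, 10)) {
    st <- chill_step(0.6, temp, p, x = 1)
    expect_equal(st$S_i, 0.6)
    expect_equal(st$M_i, 0)
    expect_false(st$injurious)
    expect_true(is.na(st$t_i))
  }
  # the ULCIZ itself is the injurious boundary: zero decrement, no blowup
  st <- chill_step(0.6, p$c, p, x = 1)
  expect_true(st$injurious)
  expect_equal(st$S_i, 0.6, tolerance = 1e-12)
  expect_true(is.na(st$t_i))
  expect_error(chill_step(0, -5, p, 1), "strictly in")
  expect_error(chill_step(1, -5, p, 1), "strictly in")
})

test_that("one step matches the direct inversion of the survival model", {
  p <- thrips_params()
  st <- chill_step(plogis(p$a), -12.941, p, x = 1)
  # ten degrees below the ULCIZ for one hour: logit drops by b*10
  expect_equal(qlogis(st$S_i), p$a - p$b * 10, tolerance = 1e-12)
  expect_equal(round(st$S_i, 4), 0.7896)
  expect_equal(round(st$M_i, 4), 0.0073)
  # equivalent-exposure audit: re-reading Eq.-1 at (t_i, T) gives S_i
  expect_equal(chill_survival(st$t_i, -12.941, p), st$S_i, tolerance = 1e-12)
  # two half-steps equal one double step
  s1 <- chill_step(0.7, -8, p, x = 1)
  s2 <- chill_step(s1$S_i, -8, p, x = 1)
  expect_equal(s2$S_i, chill_step(0.7, -8, p, x = 2)$S_i, tolerance = 1e-12)
})

test_that("constant cold reproduces the closed-form survival curve exactly", {
  p <- beetle_params()
  for (temp in c(-6, 0, 4)) {
    s <- hourly_series(rep(temp, 240))
    tr <- accumulate_mortality(s, p)
    expect_equal(tr$S_final, chill_survival(240, temp, p, truncate_warm = TRUE),
                 tolerance = 1e-12)
  }
})

test_that("the recursion matches the logit-additive closed form on arbitrary series", {
  set.seed(11)
  for (rep in 1:5) {
    # doses sized to keep survival above the 1e-12 floor, where the pure
    # logit-additive closed form is exact
    p <- chill_params(a = runif(1, 0.5, 3), b = runif(1, 1e-3, 5e-3),
                      c = runif(1, -5, 5))
    temps <- runif(300, p$c - 10, p$c + 10)
    tr <- accumulate_mortality(hourly_series(temps), p)
    expect_equal(qlogis(tr$S_final),
                 p$a + p$b * 1 * sum(pmin(temps - p$c, 0)),
                 tolerance = 1e-10)
    # telescoping: increments sum to the total
    expect_equal(sum(tr$steps$M_inc), tr$S0 - tr$S_final, tolerance = 1e-12)
    expect_equal(tr$M_cumulative, tr$S0 - tr$S_final, tolerance = 1e-12)
    # path independence: a shuffled series accumulates the same mortality
    tr2 <- accumulate_mortality(hourly_series(sample(temps)), p)
    expect_equal(tr2$M_cumulative, tr$M_cumulative, tolerance = 1e-12)
    # monotonicity: appending an injurious step never lowers the total
    tr3 <- accumulate_mortality(hourly_series(c(temps, p$c - 3)), p)
    expect_gte(tr3$M_cumulative, tr$M_cumulative - 1e-15)
  }
})

test_that("all-warm and empty series yield zero cumulative mortality", {
  p <- thrips_params()
  warm <- hourly_series(runif(100, 5, 20))
  expect_equal(accumulate_mortality(warm, p)$M_cumulative, 0)
  empty <- temperature_series("E", as.POSIXct(character(), tz = "UTC"),
                              numeric(0), resolution_min = 60)
  tr <- accumulate_mortality(empty, p)
  expect_equal(tr$M_cumulative, 0)
  expect_equal(nrow(tr$steps), 0)
})

test_that("survival floor keeps the recursion finite once mortality saturates", {
  p <- chill_params(a = 2, b = 0.1, c = 0)
  tr <- accumulate_mortality(hourly_series(rep(-30, 5000)), p)
  expect_true(is.finite(tr$S_final))
  expect_gt(tr$S_final, 0)
  expect_lte(tr$M_cumulative, tr$S0)
})

test_that("monthly mortality resets survival at month boundaries", {
  p <- thrips_params()
  # mild year except a deep January: only January shows mortality
  ts <- seq(as.POSIXct("2004-07-01", tz = "UTC"),
            as.POSIXct("2005-06-30 23:00:00", tz = "UTC"), by = 3600)
  temps <- rep(15, length(ts))
  jan <- format(ts, "%Y-%m") == "2005-01"
  temps[jan] <- -10
  s <- temperature_series("M", ts, temps, resolution_min = 60)
  mm <- monthly_mortality(s, p)
  expect_equal(sum(mm$m_cum > 0), 1)
  expect_equal(mm$month[mm$m_cum > 0], "2005-01")
  # the cold month matches the constant-exposure closed form
  expect_equal(mm$m_cum[mm$month == "2005-01"],
               plogis(p$a) - chill_survival(sum(jan), -10, p),
               tolerance = 1e-12)
  # a 31-day month at c - 5 equals S0 - S(744, c-5)
  s2 <- temperature_series("M2",
    seq(as.POSIXct("2005-01-01", tz = "UTC"), by = 3600, length.out = 744),
    rep(p$c - 5, 744), resolution_min = 60)
  mm2 <- monthly_mortality(s2, p)
  expect_equal(mm2$m_cum, plogis(p$a) - chill_survival(744, p$c - 5, p),
               tolerance = 1e-12)
})

test_that("splitting a month across files does not change its mortality", {
  p <- thrips_params()   # dose stays off the survival floor at these temps
  set.seed(21)
  ts <- seq(as.POSIXct("2003-01-01", tz = "UTC"), by = 3600,
            length.out = 744)
  temps <- runif(744, -10, 8)
  whole <- monthly_mortality(temperature_series("S", ts, temps, 60), p)
  # accumulate the two halves with carried survival via the full-series API
  tr_whole <- accumulate_mortality(temperature_series("S", ts, temps, 60), p)
  tr1 <- accumulate_mortality(temperature_series("S", ts[1:300],
                                                 temps[1:300], 60), p)
  # resume: survival is logit-additive, so the two pieces compose
  resumed <- qlogis(tr1$S_final) +
    p$b * sum(pmin(temps[301:744] - p$c, 0))
  expect_equal(qlogis(tr_whole$S_final), resumed, tolerance = 1e-10)
  expect_equal(whole$m_cum, tr_whole$M_cumulative, tolerance = 1e-12)
})

test_that("incomplete months are flagged missing", {
  p <- thrips_params()
  ts <- seq(as.POSIXct("2003-01-01", tz = "UTC"), by = 3600,
            length.out = 300)   # well under 75% of 744
  mm <- monthly_mortality(temperature_series("S", ts, rep(-8, 300), 60), p)
  expect_false(mm$complete)
  expect_true(is.na(mm$m_cum))
})

test_that("peak winter mortality takes the worst month, ties to the earliest", {
  expect_equal(peak_winter_mortality(c(Dec = 0.2, Jan = 0.5, Feb = 0.4)), 0.5)
  expect_equal(peak_winter_mortality(c(Dec = 0, Jan = 0, Feb = 0)), 0)
  expect_equal(peak_winter_mortality(c(Dec = 0.3, Jan = NA, Feb = 0.3)), 0.3)
  expect_true(is.na(peak_winter_mortality(c(Dec = NA, Jan = NA))))
  # seeded winter with a January cold snap: January is the peak month
  p <- thrips_params()
  sc <- weather_scenario(annual_mean_c = 14, ar_sd = 1, seed = 7,
                         snaps = data.frame(start = "2011-01-10",
                                            duration_h = 96, depth_c = 25))
  s <- gen_temperature_series(sc, "2010-07-01", "2011-07-01")
  mm <- monthly_mortality(s, p)
  expect_equal(mm$month[which.max(mm$m_cum)], "2011-01")
  expect_equal(peak_winter_mortality(mm), max(mm$m_cum, na.rm = TRUE))
})
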