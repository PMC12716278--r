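test_that("empirical variogram matches hand-computed semivariances", {
  # a 10-point two-cluster layout engineered so one bin holds one pair
  lat <- c(30, 30.001, 30.002, 30.003, 30.004,
           32, 32.001, 32.002, 32.003, 32.004)
  lon <- rep(-90, 10)
  vals <- c(rep(0, 5), rep(1, 5))
  vg <- empirical_variogram(lat, lon, vals, n_bins = 4)
  # short-range bins (within clusters) have gamma 0, max-lag info: 0.5
  expect_true(all(vg$gamma[vg$dist < 1] < 1e-20))
  # constant field -> flat, flagged
  vg0 <- empirical_variogram(lat, lon, rep(0.4, 10), n_bins = 4)
  expect_true(attr(vg0, "flat"))
  expect_true(all(vg0$gamma == 0))
  expect_error(empirical_variogram(lat[1:5], lon[1:5], vals[1:5]),
               "at least 10")
})

test_that("spherical model fit recovers an exactly sampled curve", {
  h <- seq(10, 200, length.out = 10)
  g <- chillmap:::.sph_gamma(h, 0, 1, 100)
  vg <- data.frame(dist = h, gamma = g, n_pairs = rep(20, 10))
  fit <- fit_spherical(vg)
  expect_equal(fit$nugget, 0, tolerance = 1e-4)
  expect_equal(fit$psill, 1, tolerance = 1e-3)
  expect_equal(fit$range, 100, tolerance = 0.1)
  # flat variogram falls back to pure nugget with a warning
  vgf <- data.frame(dist = h, gamma = rep(0, 10), n_pairs = rep(20, 10))
  attr(vgf, "flat") <- TRUE
  expect_warning(ff <- fit_spherical(vgf), "flat")
  expect_true(ff$pure_nugget)
  expect_equal(ff$range, max(h) / 2)
})

test_that("a simulated spherical random field refits within 25% of the true range", {
  set.seed(101)
  n <- 150
  lat <- runif(n, 28, 42); lon <- runif(n, -100, -80)
  true_range <- 500; true_sill <- 1
  D <- chillmap:::.dist_matrix_km(lat, lon)
  C <- true_sill - chillmap:::.sph_gamma(D, 0, true_sill, true_range)
  z <- as.numeric(t(chol(C + diag(1e-8, n))) %*% rnorm(n))
  vg <- empirical_variogram(lat, lon, z, n_bins = 12)
  fit <- fit_spherical(vg)
  expect_lt(abs(fit$range - true_range) / true_range, 0.25)
})

test_that("ordinary kriging is an exact interpolator and its weights sum to one", {
  set.seed(55)
  n <- 12
  lat <- runif(n, 28, 40); lon <- runif(n, -98, -82)
  vals <- runif(n)
  model <- structure(list(nugget = 0, psill = 0.05, range = 800,
                          sill = 0.05, converged = TRUE,
                          pure_nugget = FALSE), class = "variogram_model")
  at_data <- krige(lat, lon, vals, data.frame(lat = lat, lon = lon), model)
  expect_equal(at_data$mortality, vals, tolerance = 1e-8)
  grid <- make_grid(lat, lon, resolution = 1)
  pred <- krige(lat, lon, vals, grid, model)
  expect_true(all(abs(attr(pred, "weight_sums") - 1) < 1e-10))
  expect_true(all(pred$mortality >= 0 & pred$mortality <= 1))
  # constant data -> constant prediction everywhere
  same <- krige(lat, lon, rep(0.37, n), grid, model)
  expect_equal(same$mortality, rep(0.37, nrow(grid)), tolerance = 1e-10)
})

test_that("neighbourhood kriging equals the dense solve when k covers all stations", {
  set.seed(56)
  n <- 5
  lat <- runif(n, 30, 36); lon <- runif(n, -92, -86)
  vals <- runif(n)
  model <- structure(list(nugget = 0.01, psill = 0.08, range = 400,
                          sill = 0.09, converged = TRUE,
                          pure_nugget = FALSE), class = "variogram_model")
  grid <- make_grid(lat, lon, resolution = 0.5)
  k12 <- krige(lat, lon, vals, grid, model, k = 12, clip = FALSE)
  dense <- krige(lat, lon, vals, grid, model, k = n, clip = FALSE)
  expect_equal(k12$mortality, dense$mortality, tolerance = 1e-8)
})

test_that("suitability classes partition [0,1] with the published anchors", {
  lv <- suitability_levels()
  expect_equal(as.character(classify_suitability(0)), lv[1])
  expect_equal(as.character(classify_suitability(0.25)), lv[1])
  expect_equal(as.character(classify_suitability(0.26)), lv[2])
  expect_equal(as.character(classify_suitability(0.50)), lv[2])
  expect_equal(as.character(classify_suitability(0.75)), lv[3])
  expect_equal(as.character(classify_suitability(0.95)), lv[4])
  expect_equal(as.character(classify_suitability(0.951)), lv[5])
  expect_equal(as.character(classify_suitability(1)), lv[5])
  # every random value gets exactly one class
  set.seed(77)
  v <- c(runif(500), 0, 0.25, 0.5, 0.75, 0.95, 1)
  cls <- classify_suitability(v)
  expect_false(anyNA(cls))
  expect_error(classify_suitability(1.2), "\\[0, 1\\]")
  expect_error(classify_suitability(-0.1), "\\[0, 1\\]")
})

test_that("thinning keeps far pairs, drops near ones, and is deterministic", {
  two_near <- data.frame(id = c("a", "b"), lat = c(30, 30.05), lon = -90)
  expect_equal(nrow(thin_occurrences(two_near, 15)), 1)
  two_far <- data.frame(id = c("a", "b"), lat = c(30, 30.2), lon = -90)
  expect_equal(nrow(thin_occurrences(two_far, 15)), 2)
  # ascending-id priority: the lower id of a near pair is the one kept
  expect_equal(thin_occurrences(two_near, 15)$id, "a")
})

test_that("thinning matches the brute-force greedy oracle on clustered points", {
  cl <- data.frame(lat = c(30, 30.6, 33), lon = c(-90, -90.4, -88),
                   spread_km = c(8, 20, 3))
  occ <- gen_occurrences(200, cl, seed = 13)
  th <- thin_occurrences(occ, 15)
  or <- thin_oracle(occ, 15)
  expect_equal(th$id, or$id)
  # all retained pairwise distances >= 15 km
  if (nrow(th) > 1) {
    D <- chillmap:::.dist_matrix_km(th$lat, th$lon)
    expect_true(all(D[upper.tri(D)] >= 15))
  }
  # duplicating the input does not change the retained set
  dup <- rbind(occ, transform(occ, id = paste0("z", id)))
  expect_equal(thin_occurrences(dup, 15)$lat, th$lat)
})

test_that("grid extraction classifies records and tallies percentages", {
  grid <- expand.grid(lat = seq(30, 32, 0.5), lon = seq(-92, -90, 0.5))
  grid$mortality <- 0.1
  grid$mortality[grid$lat > 31] <- 0.8
  grid$class <- classify_suitability(grid$mortality)
  class(grid) <- c("suitability_grid", "data.frame")
  rec <- data.frame(id = sprintf("r%02d", 1:10),
                    lat = c(rep(30.2, 6), rep(31.8, 4)),
                    lon = rep(-91, 10))
  out <- extract_and_summarize(grid, rec)
  expect_equal(unname(out$pct_by_class["highly suitable"]), 60)
  expect_equal(unname(out$pct_by_class["highly unsuitable"]), 40)
  expect_equal(out$pct_suitable, 60)
  expect_equal(out$pct_unsuitable, 40)
  expect_equal(out$n_outside, 0)
  # a record far outside the grid is excluded with a warning
  rec2 <- rbind(rec, data.frame(id = "r99", lat = 45, lon = -70))
  expect_warning(out2 <- extract_and_summarize(grid, rec2), "outside")
  expect_equal(out2$n_outside, 1)
  expect_equal(out2$pct_suitable, 60)
  # empty record set: empty summary, no crash
  out0 <- extract_and_summarize(grid, rec[0, ])
  expect_equal(out0$n_outside, 0)
  expect_true(all(is.na(out0$pct_by_class)))
})
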