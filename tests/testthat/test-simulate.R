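# Synthetic generator: AR(1) structure, missingness accounting, climate
# statistics, decline injection, GPP coupling and scene assembly.

test_that("white-noise vegetation anomalies have near-zero lag-1 autocorrelation", {
  s <- simulate_vegetation_series(0, n_years = 21, seasonal_amplitude = 0,
                                  noise_sd = 0.05, seed = 1)
  n <- length(s$values)
  r <- stats::cor(s$values[-n], s$values[-1])
  expect_lt(abs(r), 2 / sqrt(n))
})

test_that("generated lag-1 autocorrelation matches an independent AR(1) oracle", {
  set.seed(42)
  mine <- replicate(200, {
    s <- simulate_vegetation_series(0.6, n_years = 21,
                                    seasonal_amplitude = 0,
                                    noise_sd = 0.05)
    v <- s$values
    stats::cor(v[-length(v)], v[-1])
  })
  oracle <- replicate(200, {
    x <- stats::arima.sim(list(ar = 0.6), 21 * 23)
    stats::cor(x[-length(x)], x[-1])
  })
  # same small-sample bias as the independent simulator
  expect_lt(abs(mean(mine) - mean(oracle)), 0.02)
  expect_lt(abs(mean(mine) - 0.6), 0.05)
})

test_that("missingness flags exactly the requested count and inputs are validated", {
  s <- simulate_vegetation_series(0.3, n_years = 21,
                                  missing_fraction = 0.4, seed = 3)
  expect_identical(sum(s$qa != 0L), as.integer(floor(0.4 * 21 * 23)))
  expect_error(simulate_vegetation_series(1.0, n_years = 21), "stationary")
  expect_error(simulate_vegetation_series(c(0.9, 0.9, 0.9) + c(0, 0, 0.2),
                                          n_years = 3), "stationary")
  expect_error(simulate_vegetation_series(0.5, n_years = 2), "at least 3")
  expect_error(simulate_vegetation_series(0.5, n_years = 21,
                                          missing_fraction = 0.6), "0.5")
})

test_that("climate series honours requested mean, cv and lag-1 autocorrelation", {
  cs <- simulate_climate_series(mean = 100, cv = 0.2, lag1_ac = 0.5,
                                n_years = 500, seed = 7)
  v <- cs$value
  expect_lt(abs(mean(v) - 100) / 100, 0.05)
  expect_lt(abs(stats::sd(v) / mean(v) - 0.2) / 0.2, 0.05)
  r <- stats::cor(v[-length(v)], v[-1])
  expect_lt(abs(r - 0.5) / 0.5, 0.05)
})

test_that("climate series degenerate and boundary cases", {
  cs <- simulate_climate_series(mean = 5, cv = 0, lag1_ac = 0,
                                n_years = 3, seed = 1)
  expect_true(all(cs$value == 5))
  expect_silent(simulate_climate_series(10, 0.1, 0.99, 3, seed = 1))
  expect_error(simulate_climate_series(10, 0.1, 1.0, 3), "lag1_ac")
  expect_error(simulate_climate_series(0, 0.2, 0, 3), "zero mean")
})

test_that("injected decline hits the antecedent-referenced target", {
  s <- simulate_vegetation_series(0.3, n_years = 21,
                                  seasonal_amplitude = 0.1,
                                  noise_sd = 0.02, seed = 5)
  out <- inject_abrupt_decline(s, year = 2015, severity_sigma = 3)
  ann <- function(ps, y) mean(ps$values[ps$calendar$year == y])
  ant <- vapply(2005:2014, function(y) ann(s, y), numeric(1))
  expect_lt(ann(out, 2015), mean(ant) - 3 * stats::sd(ant))
  expect_equal(ann(out, 2015), mean(ant) - 3 * stats::sd(ant) - 1e-6,
               tolerance = 1e-10)
  # persistence: later years equally depressed
  expect_equal(ann(out, 2018), ann(s, 2018) - (ann(s, 2015) - ann(out, 2015)),
               tolerance = 1e-10)
})

test_that("zero-severity injection is a near-identity and preconditions hold", {
  s <- simulate_vegetation_series(0.3, n_years = 21,
                                  seasonal_amplitude = 0,
                                  noise_sd = 0.02, seed = 6)
  out <- inject_abrupt_decline(s, year = 2015, severity_sigma = 0)
  # shift is only the sampling fluctuation of the year mean (~sd/sqrt(23))
  expect_lt(max(abs(out$values - s$values)), 4 * 0.02 / sqrt(23) + 1e-6)
  expect_error(inject_abrupt_decline(s, year = 2004, severity_sigma = 3),
               "antecedent")
})

test_that("GPP coupling controls the Spearman correlation with the state", {
  state <- seq(0.2, 0.6, length.out = 21)
  g1 <- simulate_gpp(state, coupling = 1, noise_sd = 0, seed = 1)
  expect_equal(stats::cor(g1, state, method = "spearman"), 1)
  gneg <- simulate_gpp(state, coupling = -1, noise_sd = 10, seed = 2)
  expect_lt(stats::cor(gneg, state, method = "spearman"), 0)
  set.seed(3)
  rho0 <- replicate(100, {
    st <- stats::rnorm(21)
    stats::cor(simulate_gpp(st, coupling = 0, noise_sd = 50), st,
               method = "spearman")
  })
  expect_lt(abs(mean(rho0)), 2 / sqrt(100))
  expect_error(simulate_gpp(state, coupling = 2, noise_sd = 0), "coupling")
})

test_that("scene building is deterministic, shaped and counted correctly", {
  cfg <- scene_config(grid_shape = c(6L, 8L), seed = 11L)
  s1 <- build_scene(cfg)
  s2 <- build_scene(cfg)
  expect_identical(s1$ndvi, s2$ndvi)
  expect_identical(s1$gpp, s2$gpp)
  expect_identical(s1$truth$phi, s2$truth$phi)
  s3 <- build_scene(scene_config(grid_shape = c(6L, 8L), seed = 12L))
  expect_false(identical(s1$ndvi, s3$ndvi))
  expect_identical(dim(s1$ndvi), c(48L, 21L * 23L))
  expect_identical(dim(s1$truth$phi), c(48L, 21L))
  # intact fraction is exact per region
  for (r in levels(s1$region)) {
    idx <- s1$region == r
    expect_identical(sum(s1$intact[idx]),
                     as.integer(round(
                       cfg$region_params[[r]]$intact_fraction * sum(idx))))
  }
})

test_that("per-pixel anomaly autocorrelation tracks the truth phi", {
  sc <- build_scene(uniform_scene_config(phi0 = 0.4, seed = 21L,
                                         missing_fraction = 0))
  an <- compute_anomalies(sc$ndvi, sc$qa, sc$calendar)
  tac <- lag1_autocorrelation(an)
  expect_lt(abs(mean(tac) - 0.4), 0.05)
  # ordering across planted region levels
  blk <- function(p) list(phi0 = p, phi_jitter_sd = 0,
                          missing_fraction = 0)
  sc2 <- build_scene(scene_config(
    grid_shape = c(12L, 12L), seed = 22L,
    region_params = list(boreal = blk(0.1), temperate = blk(0.3),
                         arid = blk(0.5), tropical = blk(0.7))))
  an2 <- compute_anomalies(sc2$ndvi, sc2$qa, sc2$calendar)
  m <- tapply(lag1_autocorrelation(an2), sc2$region, mean, na.rm = TRUE)
  expect_true(all(diff(m[c("boreal", "temperate", "arid", "tropical")]) > 0))
})

test_that("scene config validates region names and stationarity", {
  expect_error(scene_config(region_params = list(alpine = list(phi0 = 0))),
               "unknown region")
  expect_error(scene_config(region_params = list(
    boreal = list(phi0 = 0.9, phi_trend = 0.02))), "leaves")
})
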