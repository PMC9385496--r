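# Attribution: predictor construction, the RF model, diagnostics and the
# factorial counterfactuals.

test_that("predictor set has the 14 grouped columns and recovers generator targets", {
  sc <- small_scene()
  X <- build_predictors(sc, mode = "long_term")
  groups <- predictor_groups()
  expect_identical(ncol(X), 14L)
  expect_identical(lengths(groups), c(forest_density = 2L,
                                      background_climate = 4L,
                                      climate_variability = 4L,
                                      climate_ac = 4L))
  expect_setequal(colnames(X), unlist(groups))
  # tropical precipitation block: mean 200 +/- 20% jitter, ac 0.3
  trop <- sc$region == "tropical"
  expect_lt(abs(mean(X$precip_mean[trop]) - 200) / 200, 0.1)
  expect_lt(abs(mean(X$precip_ac[trop]) - 0.3), 0.1)
  expect_lt(abs(mean(X$temp_mean[trop]) - 26), 1.5)
  # annual mode aligns with the rolling TAC windows
  Xa <- build_predictors(sc, mode = "annual", window = 3)
  expect_identical(names(Xa), as.character(sc$years[-(1:2)]))
  expect_identical(colnames(Xa[[1]]), colnames(X))
})

test_that("constant climate gives cv 0 and a flagged zero autocorrelation", {
  blk <- list(climate = list(
    precip = list(mean = 100, cv = 0, ac = 0, seasonal = 0)))
  sc <- build_scene(scene_config(grid_shape = c(4L, 4L), seed = 2L,
                                 region_params = list(boreal = blk,
                                                      temperate = blk,
                                                      arid = blk,
                                                      tropical = blk)))
  X <- build_predictors(sc, mode = "long_term")
  expect_true(all(X$precip_cv == 0))
  expect_true(all(X$precip_ac == 0))
  expect_true(all(attr(X, "ac_flagged")))
})

test_that("the RF model recovers a planted function and rejects noise", {
  X <- random_predictors(1500, seed = 30)
  y <- 1.2 * X$temp_mean + 0.5 * X$precip_cv^2 + 0.4 * sin(pi * X$fc)
  m <- fit_attribution_model(X, y, seed = 31)
  expect_gte(m$metrics$r2, 0.9)
  y_noise <- stats::rnorm(nrow(X), 0, 0.1)
  m0 <- fit_attribution_model(X, y_noise, seed = 31)
  expect_lte(m0$metrics$r2, 0.1)
  # permuting y breaks the fit
  set.seed(32)
  mp <- fit_attribution_model(X, sample(y), seed = 31)
  expect_lt(mp$metrics$r2, m$metrics$r2)
  expect_error(fit_attribution_model(X, rep(1, nrow(X)), seed = 1),
               "constant")
  expect_error(fit_attribution_model(X[1:10, ], y[1:10], seed = 1),
               "at least")
})

test_that("identical seed reproduces the fit; split is 60/40 held out", {
  X <- random_predictors(600, seed = 33)
  y <- X$fc + 0.2 * stats::rnorm(nrow(X))
  m1 <- fit_attribution_model(X, y, seed = 5)
  m2 <- fit_attribution_model(X, y, seed = 5)
  expect_identical(m1$metrics, m2$metrics)
  expect_identical(m1$calib_idx, m2$calib_idx)
  expect_identical(length(m1$calib_idx), as.integer(round(0.6 * nrow(X))))
  expect_length(intersect(m1$calib_idx, m1$valid_idx), 0)
})

test_that("diagnostics rank the planted driver first and flat predictors stay flat", {
  X <- random_predictors(1200, seed = 34)
  y <- 2 * X$temp_mean + 0.3 * X$precip_cv
  m <- fit_attribution_model(X, y, seed = 35)
  d <- model_diagnostics(m, seed = 36)
  expect_identical(d$importance$predictor[1], "temp_mean")
  # partial dependence: monotone for the dominant driver
  pd <- d$partial_dependence$temp_mean
  expect_gt(stats::cor(pd$x, pd$yhat), 0.99)
  # unused predictor: flat within noise, range << dominant range
  pd0 <- d$partial_dependence$rad_ac
  expect_lt(diff(range(pd0$yhat)), 0.1 * diff(range(pd$yhat)))
})

test_that("freezing time-constant groups yields exactly zero contributions", {
  X <- random_predictors(800, seed = 37)
  y <- X$temp_mean + X$precip_ac
  m <- fit_attribution_model(X, y, seed = 38)
  n <- 50
  Xt <- X[1:n, , drop = FALSE]
  X_annual <- stats::setNames(rep(list(Xt), 5), 2002:2006)
  tac_xac <- factor_out_climate_ac(m, X_annual)
  expect_true(all(tac_xac == 0))
  contrib <- driver_contributions(m, X_annual, min_years = 3)
  for (cm in contrib$contributions) expect_true(all(cm == 0))
  expect_error(forestcsd:::.counterfactual(m, X_annual, "nope"),
               "unknown predictor")
})

test_that("the climate-AC counterfactual tracks a planted generating term", {
  # y = 0.5 * precip_ac; precip_ac ramps per pixel over the years
  X <- random_predictors(900, seed = 39)
  X$precip_ac <- stats::runif(nrow(X), 0, 0.6)
  y <- 0.5 * X$precip_ac + stats::rnorm(nrow(X), 0, 0.01)
  m <- fit_attribution_model(X, y, seed = 40)
  n <- 150
  base <- X[1:n, , drop = FALSE]
  base$precip_ac <- stats::runif(n, 0.05, 0.25)
  years <- 2002:2019
  X_annual <- list()
  for (t in seq_along(years)) {
    Xt <- base
    Xt$precip_ac <- base$precip_ac + 0.015 * (t - 1)
    X_annual[[as.character(years[t])]] <- Xt
  }
  tac_xac <- factor_out_climate_ac(m, X_annual)
  expect_true(all(tac_xac[, 1] == 0))
  truth <- outer(rep(0.5, n), 0.015 * (seq_along(years) - 1))
  expect_gt(stats::cor(as.vector(tac_xac), as.vector(truth)), 0.9)
  expect_lt(mean(abs(tac_xac - truth)), 0.05)
})

test_that("enhanced TAC subtracts the counterfactual and preserves trends", {
  raw <- matrix(seq(0.1, 0.4, length.out = 10), 1,
                dimnames = list(NULL, 2002:2011))
  zero <- matrix(0, 1, 10, dimnames = list(NULL, 2002:2011))
  expect_identical(enhanced_tac(raw, zero), raw)
  # constant offset leaves the trend unchanged
  off <- zero + 0.07
  expect_equal(tac_trend(enhanced_tac(raw, off), min_years = 5),
               tac_trend(raw, min_years = 5))
  # matching ramp cancels the trend
  expect_equal(tac_trend(enhanced_tac(raw, raw), min_years = 5)[1], 0)
  bad <- matrix(0, 1, 3, dimnames = list(NULL, 1990:1992))
  expect_error(enhanced_tac(raw, bad), "common years")
})

test_that("additive generators decompose into the correct group trends", {
  # y = temp_mean + fc; only background_climate varies in time
  X <- random_predictors(1000, seed = 41)
  y <- X$temp_mean + X$fc + stats::rnorm(nrow(X), 0, 0.01)
  m <- fit_attribution_model(X, y, seed = 42)
  n <- 100
  base <- X[1:n, , drop = FALSE]
  base$temp_mean <- stats::runif(n, 0.1, 0.4)
  years <- 2002:2016
  X_annual <- list()
  for (t in seq_along(years)) {
    Xt <- base
    Xt$temp_mean <- base$temp_mean + 0.02 * (t - 1)
    X_annual[[as.character(years[t])]] <- Xt
  }
  dc <- driver_contributions(m, X_annual)
  # time-constant groups contribute nothing
  expect_true(all(dc$contributions$climate_ac == 0))
  expect_true(all(dc$contributions$forest_density == 0))
  # the varying group's trend matches the planted 0.02 per year
  expect_lt(abs(mean(dc$trends[, "background_climate"]) - 0.02), 0.005)
  # sum of contributions matches the total factorial change
  total <- dc$contributions$background_climate +
    dc$contributions$climate_variability +
    dc$contributions$forest_density + dc$contributions$climate_ac
  full <- forestcsd:::.counterfactual(m, X_annual,
                                      unlist(predictor_groups()))
  expect_gt(stats::cor(as.vector(total), as.vector(full)), 0.9)
})
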