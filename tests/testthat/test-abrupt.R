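# Abrupt-decline detection, early-warning statistics and the critical
# threshold machinery.

# A 21-year annual record whose first 10 years have mean 0.50, sd 0.02,
# with controlled later values.
fixture_gs <- function(values_after, seed = 70) {
  set.seed(seed)
  base <- stats::rnorm(10, 0.5, 0.02)
  base <- (base - mean(base)) / stats::sd(base) * 0.02 + 0.5
  gs <- c(base, values_after)
  matrix(gs, 1, dimnames = list(NULL, seq(2000, by = 1,
                                          length.out = length(gs))))
}

test_that("detector severity arithmetic: 0.43 under mean 0.50 sd 0.02 trips n <= 3 only", {
  gs <- fixture_gs(c(0.43, rep(0.5, 10)))
  for (n in 1:3) {
    ev <- detect_ad(gs, severity = n)
    expect_identical(ev$year, 2010)
  }
  for (n in 4:6) {
    expect_identical(nrow(detect_ad(gs, severity = n)), 0L)
  }
})

test_that("detection is monotone in severity and flat series never trip", {
  gs <- fixture_gs(c(0.46, 0.38, rep(0.5, 9)))
  detected <- vapply(1:6, function(n) nrow(detect_ad(gs, severity = n)) > 0,
                     logical(1))
  # once detection stops at some severity it never resumes
  expect_true(all(diff(detected) <= 0))
  flat <- matrix(0.5, 1, 21, dimnames = list(NULL, 2000:2020))
  for (n in 1:6) expect_identical(nrow(detect_ad(flat, severity = n)), 0L)
})

test_that("only the first occurrence is recorded and antecedent stats are stored", {
  gs <- fixture_gs(c(0.40, 0.5, 0.40, rep(0.5, 8)))
  ev <- detect_ad(gs, severity = 3)
  expect_identical(nrow(ev), 1L)
  expect_identical(ev$year, 2010)
  expect_equal(ev$ant_mean, 0.5, tolerance = 1e-10)
  expect_equal(ev$ant_sd, 0.02, tolerance = 1e-10)
  expect_error(detect_ad(matrix(0.5, 1, 5), 2000:2004, severity = 1),
               "at least 11")
})

test_that("injected declines are recovered at the injected severity", {
  set.seed(71)
  for (sev in c(2, 4)) {
    s <- simulate_vegetation_series(0.3, n_years = 21,
                                    seasonal_amplitude = 0.1,
                                    noise_sd = 0.02)
    inj <- inject_abrupt_decline(s, year = 2014, severity_sigma = sev)
    gs <- growing_season_mean(inj$values, inj$calendar, rep(TRUE, 12))
    ev <- detect_ad(matrix(gs, 1, dimnames = list(NULL, names(gs))),
                    severity = sev)
    expect_identical(ev$year, 2014)
  }
})

test_that("antecedent trend uses only pre-decline years", {
  yrs <- 2002:2020
  tac <- 0.2 + 0.01 * (yrs - 2002)
  names(tac) <- yrs
  tr <- antecedent_trend(tac, ad_year = 2015)
  expect_equal(tr, 0.01, tolerance = 1e-10)
  # consistency with tac_trend on the truncated series
  expect_equal(tr, tac_trend(matrix(tac[yrs < 2015], 1), yrs[yrs < 2015],
                             min_years = 8)[1], tolerance = 1e-12)
  # AD in the last year uses all but the final value
  expect_equal(antecedent_trend(tac, ad_year = 2020),
               tac_trend(matrix(tac[-19], 1), yrs[-19], min_years = 8)[1])
  expect_true(is.na(antecedent_trend(tac, ad_year = 2006)))
})

test_that("control sampling is uniform over qualifying neighbours", {
  grid <- c(5L, 5L)
  ad <- rep(FALSE, 25)
  centre <- 13L  # row 3, col 3
  set.seed(72)
  picks <- replicate(4000, sample_control(ad, grid, centre))
  tab <- table(picks)
  expect_identical(length(tab), 8L)
  expect_true(all(abs(tab / 4000 - 1 / 8) < 0.03))
  # single qualifying neighbour is always chosen
  ad1 <- rep(TRUE, 25); ad1[14] <- FALSE
  expect_identical(sample_control(ad1, grid, centre), 14L)
  # fully disturbed neighbourhood drops the event
  expect_true(is.na(sample_control(rep(TRUE, 25), grid, centre)))
  # corner pixel has only 3 neighbours
  picks2 <- unique(replicate(200, sample_control(ad, grid, 1L)))
  expect_setequal(picks2, c(2L, 6L, 7L))
})

test_that("conditional probability counts strict exceedances with a tie rule", {
  a <- seq(0.01, 0.1, length.out = 10)
  expect_identical(conditional_probability(a, a - 0.01)$probability, 1)
  expect_identical(conditional_probability(a, a)$probability, 0)
  expect_identical(conditional_probability(a, a, ties = "half")$probability,
                   0.5)
  expect_error(conditional_probability(a[1:5], a[1:5]), "at least 10")
  # i.i.d. null is near one half
  set.seed(73)
  p <- mean(replicate(200, {
    conditional_probability(stats::rnorm(50), stats::rnorm(50))$probability
  }))
  expect_lt(abs(p - 0.5), 0.02)
})

test_that("TAC_AD extraction indexes t-1 and filters on progressive loss", {
  yrs <- 2002:2020
  tac <- stats::setNames(seq(0.2, 0.5, length.out = 19), yrs)
  tac["2014"] <- 0.42
  expect_equal(extract_tac_ad(tac, ad_year = 2015,
                              antecedent_delta_tac = 0.01), 0.42)
  expect_true(is.na(extract_tac_ad(tac, ad_year = 2015,
                                   antecedent_delta_tac = -0.01)))
  expect_true(is.na(extract_tac_ad(tac, ad_year = 1999,
                                   antecedent_delta_tac = 0.01)))
})

test_that("tolerance and proximity satisfy their arithmetic identities", {
  expect_equal(ad_tolerance(0.5, 0.3), 0.2)
  expect_identical(ad_tolerance(0.4, 0.4), 0)
  expect_equal(proximity(0.40, 0.50), 0.10)
  expect_equal(proximity(0.55, 0.50), -0.05)
  expect_identical(proximity(0.5, 0.5), 0)
  tac_ad <- 0.47; pre <- 0.31; final <- 0.42
  expect_equal(ad_tolerance(tac_ad, pre) + pre, tac_ad)
  expect_equal(proximity(final, tac_ad) + final, tac_ad)
})

test_that("threshold model recovers a planted function on reduced predictors", {
  X <- random_predictors(1200, seed = 74)
  Xr <- X[, setdiff(colnames(X), predictor_groups()$climate_ac)]
  expect_identical(ncol(Xr), 10L)
  y <- 0.3 + 0.5 * Xr$etdef_mean + 0.3 * Xr$fc^2
  g <- fit_threshold_model(Xr, y, seed = 75)
  expect_gte(g$metrics$r2, 0.9)
  set.seed(76)
  g0 <- fit_threshold_model(Xr, sample(y), seed = 75)
  expect_lte(g0$metrics$r2, 0.1)
  expect_error(fit_threshold_model(X, y, seed = 1), "must not contain")
})

test_that("critical exposure extrapolates GPP and sums over the critical mask", {
  yrs <- 2000:2018
  gpp <- matrix(rep(100 + 2 * (yrs - 2000), times = 10), 10, byrow = TRUE,
                dimnames = list(NULL, yrs))
  prox <- c(rep(-0.1, 4), rep(0.1, 6))
  dtac <- c(rep(0.01, 2), rep(-0.01, 2), rep(0.01, 6))
  ce <- critical_exposure(prox, dtac, gpp, target_year = 2020)
  expect_identical(sum(ce$critical_mask), 2L)
  expect_equal(ce$exposed_gpp, 2 * 140, tolerance = 1e-8)
  # empty mask -> zero exposure
  ce0 <- critical_exposure(rep(0.2, 10), dtac, gpp, target_year = 2020)
  expect_identical(ce0$exposed_gpp, 0)
  # ten critical pixels of one unit each
  g1 <- matrix(1, 10, 19, dimnames = list(NULL, yrs))
  ce1 <- critical_exposure(rep(-0.1, 10), rep(0.01, 10), g1,
                           target_year = 2020)
  expect_equal(ce1$exposed_gpp, 10)
})
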