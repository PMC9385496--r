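# Synthetic-scene generator. Emulates the statistical structure of the
# satellite inputs (16-day vegetation index with quality flags, monthly
# climate drivers, annual forest cover and GPP, static region/intact/season
# masks) with per-pixel ground truth, so every downstream indicator can be
# tested against known parameters.

# Stationary AR(1) anomalies, vectorized over pixels. `phi` is n_pix x n_obs
# (per-observation coefficient); `marginal_sd` is the stationary standard
# deviation of the anomaly, so innovations have sd marginal_sd*sqrt(1-phi^2).
.sim_ar1 <- function(n_pix, phi, marginal_sd, n_obs) {
  if (length(marginal_sd) == 1L) marginal_sd <- rep(marginal_sd, n_pix)
  x <- matrix(0, n_pix, n_obs)
  x[, 1L] <- stats::rnorm(n_pix, 0, marginal_sd)
  innov_sd <- marginal_sd * sqrt(pmax(1 - phi^2, 0))
  for (t in 2:n_obs) {
    x[, t] <- phi[, t] * x[, t - 1L] + stats::rnorm(n_pix, 0, innov_sd[, t])
  }
  x
}

.seasonal_cycle <- function(doy, amplitude, peak_doy = 196) {
  amplitude * cos(2 * pi * (doy - peak_doy) / 365)
}

#' Simulate one pixel's vegetation-index time series
#'
#' Generates an NDVI-like series at 16-day cadence (23 composites per year):
#' a baseline plus additive sinusoidal seasonal cycle, a linear long-term
#' trend, and AR(1) anomalies whose lag-1 coefficient may vary by year. A
#' fixed fraction of observations is flagged as poor quality (missing),
#' uniformly at random.
#'
#' @param phi AR(1) coefficient of the anomalies; scalar or one value per
#'   year, each in (-1, 1).
#' @param n_years Number of calendar years (>= 3).
#' @param seasonal_amplitude Amplitude of the seasonal cycle (index units).
#' @param noise_sd Stationary standard deviation of the anomalies (index
#'   units).
#' @param trend_per_year Linear trend of the index (index units per year).
#' @param missing_fraction Fraction of observations flagged as missing,
#'   in [0, 0.5); exactly `floor(missing_fraction * N)` observations are
#'   flagged.
#' @param baseline Mean index level.
#' @param start_year First calendar year.
#' @param seed Optional integer seed.
#' @return An object of class `pixel_series`: list with `values` (index,
#'   clamped to [-1, 1]), `qa` (0 = good, 3 = flagged missing) and
#'   `calendar` (see [make_calendar()]). The true per-year phi is stored in
#'   attribute `phi`.
#' @export
simulate_vegetation_series <- function(phi, n_years,
                                       seasonal_amplitude = 0.15,
                                       noise_sd = 0.05,
                                       trend_per_year = 0,
                                       missing_fraction = 0,
                                       baseline = 0.6,
                                       start_year = 2000L,
                                       seed = NULL) {
  if (n_years < 3)
    stop("`n_years` must be at least 3 (rolling TAC needs a 3-year window)",
         call. = FALSE)
  if (length(phi) == 1L) phi <- rep(phi, n_years)
  if (length(phi) != n_years)
    stop("`phi` must be scalar or one value per year", call. = FALSE)
  if (any(abs(phi) >= 1))
    stop("non-stationary AR(1): |phi| must be < 1 for every year",
         call. = FALSE)
  .check_scalar(missing_fraction, "missing_fraction", 0, 0.5, strict = FALSE)
  if (missing_fraction >= 0.5)
    stop("`missing_fraction` must be < 0.5 (pixels must pass the missing-data mask)",
         call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  cal <- make_calendar(start_year + seq_len(n_years) - 1L)
  n_obs <- nrow(cal)
  phi_obs <- matrix(rep(phi, each = 23L), nrow = 1L)
  anom <- .sim_ar1(1L, phi_obs, noise_sd, n_obs)[1L, ]
  values <- baseline +
    .seasonal_cycle(cal$doy, seasonal_amplitude) +
    trend_per_year * (cal$frac_year - cal$frac_year[1L]) +
    anom
  values <- pmin(pmax(values, -1), 1)
  qa <- rep(0L, n_obs)
  n_miss <- floor(missing_fraction * n_obs)
  if (n_miss > 0) qa[sample.int(n_obs, n_miss)] <- 3L
  structure(list(values = values, qa = qa, calendar = cal),
            class = "pixel_series", phi = phi)
}

#' @export
print.pixel_series <- function(x, ...) {
  cat(sprintf("<pixel_series> %d obs, %d-%d, %.0f%% flagged\n",
              length(x$values), min(x$calendar$year), max(x$calendar$year),
              100 * mean(x$qa != 0L)))
  invisible(x)
}

#' Simulate a monthly climate-driver series
#'
#' AR(1) anomalies around a mean level with optional additive seasonal
#' cycle. The controlled quantities are the long-run mean, the coefficient
#' of variation (sd of anomalies / mean) and the lag-1 autocorrelation of
#' the anomalies.
#'
#' @param mean Long-run mean (driver units); must be nonzero when `cv > 0`.
#' @param cv Coefficient of variation (>= 0).
#' @param lag1_ac Lag-1 autocorrelation of the anomalies, |lag1_ac| < 1.
#' @param n_years Number of years (12 monthly values each).
#' @param seasonal_amplitude Amplitude of an additive seasonal cycle.
#' @param start_year First calendar year.
#' @param seed Optional integer seed.
#' @return A data frame with columns `year`, `month`, `value`.
#' @export
simulate_climate_series <- function(mean, cv, lag1_ac, n_years,
                                    seasonal_amplitude = 0,
                                    start_year = 2000L, seed = NULL) {
  if (cv < 0) stop("`cv` must be >= 0", call. = FALSE)
  if (mean == 0 && cv > 0)
    stop("`cv` is undefined for zero mean", call. = FALSE)
  if (abs(lag1_ac) >= 1)
    stop("|lag1_ac| must be < 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n <- 12L * n_years
  month <- rep(1:12, n_years)
  sd <- cv * abs(mean)
  anom <- if (sd > 0) {
    .sim_ar1(1L, matrix(lag1_ac, 1L, n), sd, n)[1L, ]
  } else rep(0, n)
  value <- mean + seasonal_amplitude * cos(2 * pi * (month - 7) / 12) + anom
  data.frame(year = rep(start_year + seq_len(n_years) - 1L, each = 12L),
             month = month, value = value)
}

#' Inject a persistent abrupt decline into a vegetation series
#'
#' Depresses the series from the given year onward so that the modified
#' year's growing-season mean (in the state space defined by `transform`)
#' equals the 10-year antecedent mean minus `severity_sigma` antecedent
#' standard deviations, minus a small `epsilon` so strict exceedance holds.
#' The shift persists in later years (a step change in the state, not a
#' one-year spike).
#'
#' @param series A `pixel_series`.
#' @param year Calendar year of the decline; at least 10 antecedent years
#'   must exist.
#' @param severity_sigma Severity in antecedent standard deviations (0-6).
#' @param season_mask Logical vector of length 12 (months in the growing
#'   season); default all months.
#' @param transform,inverse State transform applied before computing annual
#'   means and its inverse (e.g. [kndvi_transform()] and its inverse when
#'   detection operates on kNDVI); defaults to identity.
#' @param epsilon Strict-exceedance offset (state units).
#' @return The modified `pixel_series`, with attribute `ad_truth`
#'   (`year`, `severity`).
#' @export
inject_abrupt_decline <- function(series, year, severity_sigma,
                                  season_mask = NULL,
                                  transform = identity, inverse = identity,
                                  epsilon = 1e-6) {
  stopifnot(inherits(series, "pixel_series"))
  .check_scalar(severity_sigma, "severity_sigma", 0, 6)
  cal <- series$calendar
  years <- sort(unique(cal$year))
  n_before <- sum(years < year)
  if (n_before < 10)
    stop("at least 10 antecedent years are required before the decline year",
         call. = FALSE)
  if (!year %in% years) stop("`year` is outside the series", call. = FALSE)
  if (is.null(season_mask)) season_mask <- rep(TRUE, 12L)
  in_season <- season_mask[cal$month]

  st <- transform(series$values)
  ann <- vapply(years, function(y) mean(st[cal$year == y & in_season]),
                numeric(1))
  ant <- ann[match((year - 10):(year - 1), years)]
  target <- mean(ant) - severity_sigma * stats::sd(ant) - epsilon
  shift <- ann[match(year, years)] - target
  idx <- cal$year >= year
  st[idx] <- st[idx] - shift
  out <- series
  out$values <- inverse(st)
  attr(out, "ad_truth") <- data.frame(year = year, severity = severity_sigma)
  attr(out, "phi") <- attr(series, "phi")
  out
}

#' Simulate annual GPP coupled to the vegetation state
#'
#' Annual gross primary productivity as an affine function of the
#' (standardized) growing-season vegetation state plus Gaussian noise. The
#' sign of the realized Spearman correlation between GPP and the state
#' follows the sign of `coupling`.
#'
#' @param state Annual vegetation-state values (e.g. growing-season kNDVI
#'   means).
#' @param coupling Coupling strength in [-1, 1].
#' @param noise_sd Noise standard deviation (GPP units).
#' @param base_gpp Mean GPP level (g C m-2 yr-1).
#' @param sensitivity Relative GPP change per standard deviation of state.
#' @param seed Optional integer seed.
#' @return Numeric vector of annual GPP values.
#' @export
simulate_gpp <- function(state, coupling, noise_sd, base_gpp = 1500,
                         sensitivity = 0.2, seed = NULL) {
  .check_scalar(coupling, "coupling", -1, 1)
  if (!is.null(seed)) set.seed(seed)
  s <- stats::sd(state)
  z <- if (is.na(s) || s == 0) rep(0, length(state)) else (state - mean(state)) / s
  base_gpp * (1 + sensitivity * coupling * z) +
    stats::rnorm(length(state), 0, noise_sd)
}
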