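# Abrupt-decline (AD) analysis: detection of sudden drops in the
# growing-season vegetation state, antecedent dTAC as an early-warning
# signal tested against matched undisturbed controls, the empirical
# critical threshold TAC_AD with its tolerance, the RF threshold model g,
# and proximity / critical-exposure maps.

#' Detect the first abrupt decline
#'
#' An AD occurs in the first year whose growing-season mean state falls
#' strictly more than `severity` local standard deviations below the local
#' mean, both computed over the 10-year antecedent window. Only the first
#' occurrence per pixel is recorded. Detection is scanned over years from
#' `analysis_start` on (every candidate needs 10 antecedent years).
#'
#' @param gs Annual growing-season means: vector or pixels x years matrix
#'   (years as column names).
#' @param years Calendar years (defaults to column names).
#' @param severity Severity `n` in antecedent standard deviations
#'   (1 to 6).
#' @param antecedent Antecedent window length in years (default 10).
#' @param analysis_start First year scanned (default: first year with a
#'   full antecedent window).
#' @return Data frame of events: `pixel`, `year`, `value`, `ant_mean`,
#'   `ant_sd`, `severity` (zero rows when nothing is detected).
#' @export
detect_ad <- function(gs, years = NULL, severity = 3,
                      antecedent = 10L, analysis_start = NULL) {
  m <- .as_row_matrix(gs)
  if (is.null(years)) {
    years <- suppressWarnings(as.numeric(colnames(m)))
    if (anyNA(years)) stop("supply `years` or name the columns", call. = FALSE)
  }
  .check_scalar(severity, "severity", 0, 6)
  if (ncol(m) < antecedent + 1L)
    stop(sprintf("need at least %d annual values", antecedent + 1L),
         call. = FALSE)
  if (is.null(analysis_start)) analysis_start <- years[antecedent + 1L]
  found <- rep(FALSE, nrow(m))
  out <- list()
  for (yi in seq_along(years)) {
    if (yi <= antecedent || years[yi] < analysis_start) next
    ant <- m[, (yi - antecedent):(yi - 1L), drop = FALSE]
    am <- rowMeans(ant, na.rm = TRUE)
    asd <- apply(ant, 1L, stats::sd, na.rm = TRUE)
    v <- m[, yi]
    hit <- !found & !is.na(v) & is.finite(am) & is.finite(asd) &
      v < am - severity * asd
    if (any(hit)) {
      out[[length(out) + 1L]] <- data.frame(
        pixel = which(hit), year = years[yi], value = v[hit],
        ant_mean = am[hit], ant_sd = asd[hit], severity = severity
      )
      found[hit] <- TRUE
    }
  }
  if (!length(out))
    return(data.frame(pixel = integer(), year = numeric(),
                      value = numeric(), ant_mean = numeric(),
                      ant_sd = numeric(), severity = numeric()))
  res <- do.call(rbind, out)
  res[order(res$pixel), , drop = FALSE]
}

#' Antecedent dTAC before an abrupt decline
#'
#' OLS slope of the annual (enhanced) TAC series restricted to years
#' strictly before the AD year, so the trend is independent of the
#' vegetation changes associated with the decline itself.
#'
#' @param annual_tac Annual TAC values (vector, years as names, or with
#'   `years` supplied).
#' @param years Calendar years.
#' @param ad_year AD year `t`; the trend is over the record up to `t - 1`.
#' @param min_years Minimum valid annual values before `t` (default 8);
#'   fewer gives NA (the event is excluded).
#' @return The antecedent trend (per year), or NA.
#' @export
antecedent_trend <- function(annual_tac, years = NULL, ad_year,
                             min_years = 8L) {
  v <- as.numeric(annual_tac)
  if (is.null(years)) {
    years <- suppressWarnings(as.numeric(names(annual_tac)))
    if (anyNA(years)) stop("supply `years` or name the values", call. = FALSE)
  }
  sel <- years < ad_year
  .trend_slope(matrix(v[sel], 1L), years[sel], min_n = min_years)[1L]
}

#' Sample an undisturbed control pixel
#'
#' Picks uniformly at random one of the 8-neighbourhood pixels of an AD
#' pixel that has no AD at the same severity. Events without any
#' qualifying neighbour return NA (to be dropped from the paired
#' analysis).
#'
#' @param ad_pixels Logical per pixel: TRUE where an AD was detected at
#'   the severity of interest.
#' @param grid_dim Integer c(n_lat, n_lon); column-major pixel order.
#' @param pixel Index of the AD pixel.
#' @param seed Optional integer seed.
#' @return Control pixel index, or NA.
#' @export
sample_control <- function(ad_pixels, grid_dim, pixel, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n_lat <- grid_dim[1L]; n_lon <- grid_dim[2L]
  rr <- (pixel - 1L) %% n_lat + 1L
  cc <- (pixel - 1L) %/% n_lat + 1L
  nb <- expand.grid(dr = -1:1, dc = -1:1)
  nb <- nb[!(nb$dr == 0 & nb$dc == 0), ]
  r2 <- rr + nb$dr; c2 <- cc + nb$dc
  ok <- r2 >= 1 & r2 <= n_lat & c2 >= 1 & c2 <= n_lon
  cand <- (c2[ok] - 1L) * n_lat + r2[ok]
  cand <- cand[!ad_pixels[cand]]
  if (!length(cand)) return(NA_integer_)
  cand[sample.int(length(cand), 1L)]
}

#' Probability of abrupt decline conditional on dTAC
#'
#' Given paired antecedent dTAC samples from AD pixels and their matched
#' undisturbed controls, the probability is the frequency of pairs in
#' which the AD pixel's dTAC strictly exceeds the control's (with an
#' optional half-credit tie rule). Significance of the difference in the
#' two sampled means comes from a two-sided Welch t-test.
#'
#' @param ad_trends,control_trends Paired samples (equal length, NA pairs
#'   dropped), at least 10 pairs.
#' @param ties `"strict"` (default: ties count as non-exceedance) or
#'   `"half"` (ties count 0.5).
#' @return List with `probability`, `p_value`, `mean_diff` and `n`.
#' @export
conditional_probability <- function(ad_trends, control_trends,
                                    ties = c("strict", "half")) {
  ties <- match.arg(ties)
  stopifnot(length(ad_trends) == length(control_trends))
  ok <- !is.na(ad_trends) & !is.na(control_trends)
  a <- ad_trends[ok]; b <- control_trends[ok]
  if (length(a) < 10)
    stop("need at least 10 complete pairs", call. = FALSE)
  p <- mean(a > b)
  if (ties == "half") p <- p + 0.5 * mean(a == b)
  ht <- two_sample_ttest(a, b)
  list(probability = p, p_value = ht$p_value,
       mean_diff = ht$mean_diff, n = length(a))
}

#' TAC in the year preceding an abrupt decline (TAC_AD)
#'
#' The empirical critical-resilience threshold: the annual TAC value at
#' `t - 1` for a pixel with an AD at year `t`, retained only when the
#' decline followed a progressive loss of resilience (antecedent dTAC
#' strictly positive).
#'
#' @param annual_tac Annual (enhanced) TAC values (vector; years as names
#'   or via `years`).
#' @param years Calendar years.
#' @param ad_year AD year `t`.
#' @param antecedent_delta_tac Antecedent dTAC of the event.
#' @return TAC at `t - 1`, or NA when the event is excluded (no
#'   progressive loss, or TAC missing at `t - 1`).
#' @export
extract_tac_ad <- function(annual_tac, years = NULL, ad_year,
                           antecedent_delta_tac) {
  v <- as.numeric(annual_tac)
  if (is.null(years)) {
    years <- suppressWarnings(as.numeric(names(annual_tac)))
    if (anyNA(years)) stop("supply `years` or name the values", call. = FALSE)
  }
  if (is.na(antecedent_delta_tac) || antecedent_delta_tac <= 0)
    return(NA_real_)
  i <- match(ad_year - 1, years)
  if (is.na(i)) return(NA_real_)
  v[i]
}

#' Tolerance to abrupt decline
#'
#' The difference between the local critical threshold TAC_AD and the TAC
#' averaged over pre-disturbance conditions (the first decade of the
#' record): the autocorrelation increase an ecosystem in equilibrium can
#' absorb before reaching critical conditions.
#'
#' @param tac_ad TAC_AD value(s).
#' @param pre_disturbance_mean_tac Mean TAC over the pre-disturbance
#'   window.
#' @return `tac_ad - pre_disturbance_mean_tac`.
#' @export
ad_tolerance <- function(tac_ad, pre_disturbance_mean_tac) {
  tac_ad - pre_disturbance_mean_tac
}

#' Fit the critical-threshold model
#'
#' Random-forest regression of observed TAC_AD on the environmental
#' predictors excluding the four climate-autocorrelation terms (10
#' predictors), with the same calibration/validation protocol as
#' [fit_attribution_model()]. Used to predict the critical threshold for
#' undisturbed pixels.
#'
#' @param X_reduced Predictor data frame without climate-autocorrelation
#'   columns.
#' @param tac_ad Observed TAC_AD per record.
#' @param ... Passed to [fit_attribution_model()] (seed, grids, ...).
#' @return An `rf_attribution` object.
#' @export
fit_threshold_model <- function(X_reduced, tac_ad, ...) {
  banned <- intersect(predictor_groups()$climate_ac, colnames(X_reduced))
  if (length(banned))
    stop("X_reduced must not contain climate-autocorrelation predictors: ",
         paste(banned, collapse = ", "), call. = FALSE)
  fit_attribution_model(X_reduced, tac_ad, ...)
}

#' Proximity to the critical resilience threshold
#'
#' Signed margin between the (predicted) critical threshold TAC_AD and
#' the TAC at the end of the record: zero or negative where the threshold
#' has already been reached (`tac_final >= tac_ad`), positive where a
#' margin remains.
#'
#' @param tac_final_year TAC in the final year per pixel.
#' @param predicted_tac_ad Predicted (or observed) TAC_AD per pixel.
#' @return `predicted_tac_ad - tac_final_year`.
#' @export
proximity <- function(tac_final_year, predicted_tac_ad) {
  predicted_tac_ad - tac_final_year
}

#' Critical conditions and exposed GPP
#'
#' Critical pixels have reached or overpassed their threshold
#' (`proximity <= 0`) while still losing resilience (`delta_tac > 0`).
#' GPP is extrapolated to `target_year` by per-pixel OLS over the
#' available annual values and summed (times pixel area) over the
#' critical mask.
#'
#' @param prox Per-pixel proximity values.
#' @param delta_tac Per-pixel dTAC.
#' @param gpp_annual Pixels x years matrix of annual GPP.
#' @param years Calendar years of the GPP columns (defaults to column
#'   names).
#' @param target_year Year to extrapolate GPP to (default: last GPP year
#'   plus 1).
#' @param area Pixel area (scalar or per pixel; default 1).
#' @param min_years Minimum annual GPP values for the extrapolation
#'   (default 5); pixels below are excluded and counted.
#' @return List with `critical_mask` (logical; NA-safe), `exposed_gpp`
#'   (sum over the mask), `gpp_extrapolated` and `n_excluded`.
#' @export
critical_exposure <- function(prox, delta_tac, gpp_annual, years = NULL,
                              target_year = NULL, area = 1,
                              min_years = 5L) {
  m <- .as_row_matrix(gpp_annual)
  if (is.null(years)) {
    years <- suppressWarnings(as.numeric(colnames(m)))
    if (anyNA(years)) stop("supply `years` or name the columns", call. = FALSE)
  }
  if (is.null(target_year)) target_year <- max(years) + 1
  fit <- .row_ols(m, as.numeric(years), min_n = min_years)
  gpp_ext <- fit$intercept + fit$slope * target_year
  n_excluded <- sum(is.na(gpp_ext))
  mask <- !is.na(prox) & !is.na(delta_tac) & prox <= 0 & delta_tac > 0
  usable <- mask & !is.na(gpp_ext)
  exposed <- sum((gpp_ext * area)[usable])
  list(critical_mask = mask, exposed_gpp = exposed,
       gpp_extrapolated = gpp_ext, n_excluded = n_excluded)
}
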