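# Critical-slowing-down indicators: lag-1 temporal autocorrelation (TAC)
# of vegetation anomalies over the full record and over annual rolling
# windows, the dTAC trend, the decadal TAC difference, and the one-sample
# t-test used for bin-level significance.

.anom_matrix <- function(x, use_gapfilled = TRUE) {
  if (inherits(x, "anomaly_series") || (is.list(x) && !is.null(x$anom))) {
    anom <- .as_row_matrix(x$anom)
    if (!use_gapfilled && !is.null(x$gapfilled)) anom[x$gapfilled] <- NA
    list(anom = anom, calendar = x$calendar)
  } else {
    list(anom = .as_row_matrix(x), calendar = NULL)
  }
}

#' Lag-1 temporal autocorrelation
#'
#' Pearson correlation between a series and its one-step lag, computed over
#' pairs in which both members are valid (non-missing). This is the TAC
#' resilience indicator: higher TAC means slower recovery from
#' perturbations, i.e. lower resilience.
#'
#' @param x An `anomaly_series`, numeric vector, or pixels x time matrix.
#' @param min_pairs Minimum number of valid consecutive pairs (default 20);
#'   fewer gives NA. Constant series also give NA.
#' @param use_gapfilled Include gap-filled (climatological zero) anomalies
#'   in the pairs (default TRUE, matching the gap-fill-then-compute
#'   order); FALSE restricts to observed anomalies.
#' @return Numeric vector (one TAC per pixel) in [-1, 1].
#' @export
lag1_autocorrelation <- function(x, min_pairs = 20L, use_gapfilled = TRUE) {
  .row_lag1(.anom_matrix(x, use_gapfilled)$anom, min_pairs = min_pairs)
}

#' Long-term TAC over the full record
#'
#' TAC computed on the whole anomaly record of each pixel — the static
#' "slowness" of the pixel. Identical to [lag1_autocorrelation()] on the
#' full series; provided as the named long-term indicator.
#'
#' @inheritParams lag1_autocorrelation
#' @return Numeric vector of long-term TAC per pixel.
#' @export
long_term_tac <- function(x, min_pairs = 20L, use_gapfilled = TRUE) {
  lag1_autocorrelation(x, min_pairs = min_pairs,
                       use_gapfilled = use_gapfilled)
}

#' Annual rolling-window TAC
#'
#' TAC at an annual time step using a trailing window: the value for year
#' `t` uses all observations in years `[t - window + 1, t]` (default
#' 3-year window, i.e. 2-year lagged). The first `window - 1` years are
#' undefined.
#'
#' @param x An `anomaly_series`, or matrix/vector with `calendar`.
#' @param calendar Calendar data frame when `x` is not an
#'   `anomaly_series`.
#' @param window Window length in years (default 3).
#' @param min_pairs Minimum valid pairs per window (default 20).
#' @param use_gapfilled Include gap-filled anomalies (default TRUE).
#' @return Pixels x years matrix of annual TAC (years as column names);
#'   NA outside full windows or where pairs are insufficient.
#' @export
rolling_tac <- function(x, calendar = NULL, window = 3L, min_pairs = 20L,
                        use_gapfilled = TRUE) {
  a <- .anom_matrix(x, use_gapfilled)
  cal <- a$calendar %||% calendar
  if (is.null(cal)) stop("`calendar` is required", call. = FALSE)
  years <- sort(unique(cal$year))
  if (length(years) < window)
    stop(sprintf("need at least %d years of anomalies", window),
         call. = FALSE)
  out <- matrix(NA_real_, nrow(a$anom), length(years),
                dimnames = list(NULL, years))
  for (yi in seq_along(years)) {
    if (yi < window) next
    cols <- cal$year %in% years[(yi - window + 1L):yi]
    out[, yi] <- .row_lag1(a$anom[, cols, drop = FALSE],
                           min_pairs = min_pairs)
  }
  out
}

# Row-wise OLS slope against calendar year, requiring min_n valid values.
.trend_slope <- function(values, years, min_n) {
  v <- .as_row_matrix(values)
  stopifnot(length(years) == ncol(v))
  fit <- .row_ols(v, as.numeric(years), min_n = min_n)
  fit$slope
}

#' Trend of the annual TAC series (dTAC)
#'
#' OLS slope of annual TAC against calendar year, per pixel. Positive
#' dTAC indicates rising autocorrelation and thus declining resilience.
#'
#' @param annual_tac Pixels x years matrix (or vector) of annual TAC; NA
#'   entries are skipped.
#' @param years Calendar years (defaults to column names).
#' @param min_years Minimum valid annual values (default 10); fewer gives
#'   NA.
#' @return Numeric vector of trends (per year).
#' @export
tac_trend <- function(annual_tac, years = NULL, min_years = 10L) {
  m <- .as_row_matrix(annual_tac)
  if (is.null(years)) {
    years <- suppressWarnings(as.numeric(colnames(m)))
    if (anyNA(years)) stop("supply `years` or name the columns", call. = FALSE)
  }
  .trend_slope(m, years, min_n = min_years)
}

#' Decadal TAC difference
#'
#' TAC over the late period minus TAC over the early period, the two
#' periods being consecutive and independent halves of the record (by
#' default years before `split_year` versus from `split_year` on,
#' mirroring 2000-2010 versus 2011-2020).
#'
#' @param x An `anomaly_series`, or matrix/vector with `calendar`.
#' @param calendar Calendar when `x` is not an `anomaly_series`.
#' @param split_year First year of the late period (default 2011).
#' @param min_pairs Minimum valid pairs per period (default 20).
#' @param use_gapfilled Include gap-filled anomalies (default TRUE).
#' @return Numeric vector: TAC(late) - TAC(early); NA if either period is
#'   undefined.
#' @export
decadal_difference <- function(x, calendar = NULL, split_year = 2011L,
                               min_pairs = 20L, use_gapfilled = TRUE) {
  a <- .anom_matrix(x, use_gapfilled)
  cal <- a$calendar %||% calendar
  if (is.null(cal)) stop("`calendar` is required", call. = FALSE)
  early <- cal$year < split_year
  late <- !early
  if (!any(early) || !any(late))
    stop("`split_year` must fall inside the record", call. = FALSE)
  .row_lag1(a$anom[, late, drop = FALSE], min_pairs) -
    .row_lag1(a$anom[, early, drop = FALSE], min_pairs)
}

#' Two-sided one-sample t-test against zero
#'
#' Used for bin-level significance of dTAC and decadal differences. A
#' zero-variance sample yields p = 0 when its mean is nonzero (the
#' departure is unambiguous) and p = 1 when the mean is zero.
#'
#' @param values Numeric sample (NA dropped); needs n >= 2.
#' @return List with `mean`, `p_value` and `n`.
#' @export
one_sample_ttest <- function(values) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 2) stop("need at least 2 values", call. = FALSE)
  m <- mean(values)
  if (stats::sd(values) == 0) {
    return(list(mean = m, p_value = if (m == 0) 1 else 0, n = n))
  }
  ht <- stats::t.test(values, mu = 0)
  list(mean = m, p_value = ht$p.value, n = n)
}
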