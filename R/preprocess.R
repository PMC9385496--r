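# Preprocessing: kNDVI transform, quality filtering, climatology removal,
# linear detrending, climatological gap-filling, growing-season means and
# the forest mask. All functions accept one series (vector / pixel_series)
# or a pixels x time matrix.

#' Kernel NDVI transform
#'
#' `kndvi = tanh(ndvi^2)`, a nonlinear generalization of the NDVI used as a
#' proxy for ecosystem productivity state. Even in `ndvi`, monotone in
#' `|ndvi|`, with range [0, tanh(1)].
#'
#' @param ndvi NDVI values in [-1, 1] (NA allowed).
#' @return kNDVI values of the same shape.
#' @export
kndvi_transform <- function(ndvi) {
  if (any(abs(ndvi) > 1, na.rm = TRUE))
    stop("NDVI values must lie in [-1, 1]", call. = FALSE)
  tanh(ndvi^2)
}

.series_input <- function(x, qa, calendar) {
  if (inherits(x, "pixel_series")) {
    list(values = matrix(x$values, nrow = 1L),
         qa = matrix(x$qa, nrow = 1L), calendar = x$calendar,
         vector_in = TRUE)
  } else {
    x <- .as_row_matrix(x)
    if (is.null(calendar))
      stop("`calendar` is required for matrix/vector input", call. = FALSE)
    if (!is.null(qa)) qa <- .as_row_matrix(qa)
    list(values = x, qa = qa, calendar = calendar,
         vector_in = FALSE)
  }
}

#' Compute stationary vegetation anomalies
#'
#' Removes the multi-year per-period (16-day) sample mean (the climatology)
#' and then a per-pixel OLS linear trend against fractional year, after
#' discarding observations whose quality class is not in `qa_keep`.
#' Periods with fewer than `min_clim_obs` valid cross-year observations get
#' no climatology and are treated as missing.
#'
#' @param x A `pixel_series`, or a numeric vector / pixels x time matrix of
#'   index values (e.g. kNDVI).
#' @param qa Matching quality classes (0 = good, 1 = marginal, larger =
#'   poor); `NULL` means all good.
#' @param calendar Calendar data frame as from [make_calendar()] (taken
#'   from `x` when it is a `pixel_series`).
#' @param qa_keep Quality classes to retain (default good and marginal).
#' @param detrend Remove the per-pixel linear trend (default TRUE).
#' @param min_clim_obs Minimum valid observations per period for a
#'   climatology value (default 2).
#' @return An object of class `anomaly_series`: list with `anom`
#'   (pixels x time, NA where invalid), `valid`, `gapfilled` (all FALSE
#'   here), `climatology` (pixels x 23) and `calendar`.
#' @export
compute_anomalies <- function(x, qa = NULL, calendar = NULL,
                              qa_keep = c(0L, 1L), detrend = TRUE,
                              min_clim_obs = 2L) {
  inp <- .series_input(x, qa, calendar)
  v <- inp$values; cal <- inp$calendar
  stopifnot(nrow(cal) == ncol(v))
  valid <- !is.na(v)
  if (!is.null(inp$qa)) valid <- valid & matrix(inp$qa %in% qa_keep,
                                                nrow(v), ncol(v))
  if (!any(valid))
    stop("no valid observations after quality filtering", call. = FALSE)

  # per-pixel, per-period climatology over valid observations
  n_pix <- nrow(v)
  clim <- matrix(NA_real_, n_pix, 23L)
  v0 <- v; v0[!valid] <- 0
  for (p in 1:23) {
    cols <- which(cal$period == p)
    if (!length(cols)) next
    n <- rowSums(valid[, cols, drop = FALSE])
    m <- rowSums(v0[, cols, drop = FALSE]) / n
    m[n < min_clim_obs] <- NA_real_
    clim[, p] <- m
  }
  anom <- v - clim[, cal$period, drop = FALSE]
  valid <- valid & !is.na(anom)
  anom[!valid] <- NA_real_

  if (detrend) {
    # Trend abscissa is the year centre: after climatology removal the
    # deterministic part of any linear drift is constant within a year,
    # so an annual abscissa removes it exactly (and makes the operation
    # idempotent); a sub-annual abscissa would leave a sawtooth.
    xt <- cal$year + 0.5
    fit <- .row_ols(anom, xt)
    pred <- outer(fit$intercept, rep(1, ncol(anom))) +
      outer(fit$slope, xt)
    ok <- !is.na(fit$slope)
    anom[ok, ] <- anom[ok, , drop = FALSE] - pred[ok, , drop = FALSE]
  }
  structure(list(anom = anom, valid = valid,
                 gapfilled = matrix(FALSE, nrow(anom), ncol(anom)),
                 climatology = clim, calendar = cal),
            class = "anomaly_series")
}

#' @export
print.anomaly_series <- function(x, ...) {
  cat(sprintf("<anomaly_series> %d pixel(s) x %d obs, %.0f%% valid, %.0f%% gap-filled\n",
              nrow(x$anom), ncol(x$anom), 100 * mean(x$valid),
              100 * mean(x$gapfilled)))
  invisible(x)
}

#' Gap-fill anomalies with the climatological value
#'
#' Replaces invalid observations by the climatological index value, which
#' in anomaly space is exactly 0, and flags them in `gapfilled`.
#' Observations in periods without a defined climatology remain missing.
#'
#' @param anoms An `anomaly_series`.
#' @return The gap-filled `anomaly_series`.
#' @export
gap_fill <- function(anoms) {
  stopifnot(inherits(anoms, "anomaly_series"))
  clim_ok <- !is.na(anoms$climatology[, anoms$calendar$period, drop = FALSE])
  fill <- !anoms$valid & clim_ok
  anoms$anom[fill] <- 0
  anoms$gapfilled <- anoms$gapfilled | fill
  anoms$valid <- anoms$valid | fill
  anoms
}

#' Growing-season annual means
#'
#' One value per year: the mean of valid observations whose calendar month
#' falls in the growing-season mask. Years with no valid in-season
#' observation are missing.
#'
#' @param x Numeric vector or pixels x time matrix (e.g. kNDVI), or a
#'   `pixel_series`.
#' @param calendar Calendar data frame (ignored for `pixel_series` input).
#' @param season_mask Logical of length 12, or a pixels x 12 matrix.
#' @param valid Optional logical mask of the same shape as the values.
#' @return Pixels x years matrix (a plain vector for single-series input),
#'   with years as column names.
#' @export
growing_season_mean <- function(x, calendar = NULL, season_mask,
                                valid = NULL) {
  inp <- .series_input(x, NULL, calendar)
  v <- inp$values; cal <- inp$calendar
  if (is.null(valid)) valid <- !is.na(v) else valid <- .as_row_matrix(valid)
  if (!is.matrix(season_mask))
    season_mask <- matrix(season_mask, nrow(v), 12L, byrow = TRUE)
  if (!any(season_mask)) stop("empty growing-season mask", call. = FALSE)
  in_season <- season_mask[, cal$month, drop = FALSE]
  years <- sort(unique(cal$year))
  out <- matrix(NA_real_, nrow(v), length(years),
                dimnames = list(NULL, years))
  v0 <- v; v0[!valid] <- 0
  for (yi in seq_along(years)) {
    cols <- cal$year == years[yi]
    w <- valid[, cols, drop = FALSE] & in_season[, cols, drop = FALSE]
    n <- rowSums(w)
    s <- rowSums(v0[, cols, drop = FALSE] * w)
    out[, yi] <- ifelse(n > 0, s / n, NA_real_)
  }
  if (inp$vector_in || nrow(out) == 1L) drop(out) else out
}

#' Forest analysis mask
#'
#' A pixel enters the analysis when its time-mean forest-cover fraction
#' exceeds `fc_min` and its missing-data fraction is below `miss_max`.
#'
#' @param fc Forest-cover fractions in [0, 1]: vector (per pixel) or
#'   pixels x years matrix (aggregated by time mean).
#' @param missing_fraction Per-pixel fraction of missing/poor-quality
#'   observations in [0, 1].
#' @param fc_min Minimum forest cover (default 0.05).
#' @param miss_max Maximum missing fraction (default 0.5).
#' @return An object of class `forest_mask`: list with logical `mask` and
#'   the per-pixel `fc` and `missing_fraction` used.
#' @export
apply_forest_mask <- function(fc, missing_fraction, fc_min = 0.05,
                              miss_max = 0.5) {
  if (is.matrix(fc)) fc <- rowMeans(fc, na.rm = TRUE)
  if (any(fc < 0 | fc > 1, na.rm = TRUE))
    stop("`fc` must lie in [0, 1]", call. = FALSE)
  stopifnot(length(missing_fraction) == length(fc))
  mask <- !is.na(fc) & fc > fc_min & missing_fraction < miss_max
  structure(list(mask = mask, fc = fc,
                 missing_fraction = missing_fraction,
                 fc_min = fc_min, miss_max = miss_max),
            class = "forest_mask")
}

#' @export
print.forest_mask <- function(x, ...) {
  cat(sprintf("<forest_mask> %d / %d pixels retained (fc > %g, missing < %g)\n",
              sum(x$mask), length(x$mask), x$fc_min, x$miss_max))
  invisible(x)
}
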