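# Attribution of TAC to environmental drivers: the 14-predictor random
# forest TAC = f(X) + eps, permutation importance and partial dependence,
# and the factorial counterfactuals that freeze predictor groups at their
# first-year values to isolate each group's contribution to annual TAC —
# in particular removing the confounding autocorrelation of the climate
# drivers to obtain the enhanced TAC series.

.drivers <- c("precip", "temp", "etdef", "rad")

#' Predictor group membership
#'
#' The 14 environmental predictors, grouped as forest density (forest
#' cover and growing-season kNDVI), background climate (four driver
#' means), climate variability (four coefficients of variation) and
#' climate autocorrelation (four lag-1 autocorrelations).
#'
#' @return Named list of character vectors of column names.
#' @export
predictor_groups <- function() {
  list(
    forest_density = c("fc", "gs_kndvi"),
    background_climate = paste0(.drivers, "_mean"),
    climate_variability = paste0(.drivers, "_cv"),
    climate_ac = paste0(.drivers, "_ac")
  )
}

# Monthly climate anomalies: value minus the per-pixel, per-month
# climatology over the record.
.climate_anomalies <- function(m, clim_cal) {
  clim <- matrix(NA_real_, nrow(m), 12L)
  for (mo in 1:12) {
    cols <- clim_cal$month == mo
    clim[, mo] <- rowMeans(m[, cols, drop = FALSE], na.rm = TRUE)
  }
  m - clim[, clim_cal$month, drop = FALSE]
}

# Per-year mean and within-year CV of a monthly driver matrix.
.annual_climate_stats <- function(m, clim_cal, years, eps = 1e-6) {
  n_pix <- nrow(m)
  amean <- acv <- matrix(NA_real_, n_pix, length(years))
  for (yi in seq_along(years)) {
    cols <- clim_cal$year == years[yi]
    sub <- m[, cols, drop = FALSE]
    mu <- rowMeans(sub)
    sdv <- apply(sub, 1L, stats::sd)
    amean[, yi] <- mu
    acv[, yi] <- sdv / pmax(abs(mu), eps)
  }
  list(mean = amean, cv = acv)
}

#' Build the 14 environmental predictors
#'
#' Long-term mode: annual means and within-year coefficients of variation
#' of each climate driver averaged over the record, lag-1 autocorrelation
#' of the monthly driver anomalies over the whole record, time-mean forest
#' cover and growing-season kNDVI. Annual mode: the same quantities over
#' trailing `window`-year windows aligned with the rolling TAC windows.
#' Undefined autocorrelations (constant series) are set to 0 and flagged.
#'
#' @param scene A `forest_scene`.
#' @param mode `"long_term"` (one row per pixel) or `"annual"` (a list of
#'   per-year data frames starting at the first full window).
#' @param window Window length in years for annual mode (default 3).
#' @param qa_keep Quality classes used for the growing-season kNDVI.
#' @return Long-term mode: data frame with 14 columns. Annual mode: named
#'   list of such data frames, one per year. Both carry attribute
#'   `ac_flagged` (logical per pixel: some autocorrelation was undefined).
#' @export
build_predictors <- function(scene, mode = c("long_term", "annual"),
                             window = 3L, qa_keep = c(0L, 1L)) {
  stopifnot(inherits(scene, "forest_scene"))
  mode <- match.arg(mode)
  years <- scene$years
  n_pix <- nrow(scene$ndvi)
  kn <- kndvi_transform(scene$ndvi)
  valid <- matrix(scene$qa %in% qa_keep, n_pix, ncol(kn))
  gs <- growing_season_mean(kn, scene$calendar, scene$season_mask,
                            valid = valid)
  gs <- .as_row_matrix(gs)

  cstats <- lapply(scene$climate, .annual_climate_stats,
                   clim_cal = scene$clim_calendar, years = years)
  canom <- lapply(scene$climate, .climate_anomalies, scene$clim_calendar)

  ac_flagged <- rep(FALSE, n_pix)
  fill_ac <- function(ac) {
    und <- is.na(ac)
    ac_flagged <<- ac_flagged | und
    ac[und] <- 0
    ac
  }

  if (mode == "long_term") {
    X <- data.frame(fc = rowMeans(scene$fc, na.rm = TRUE),
                    gs_kndvi = rowMeans(gs, na.rm = TRUE))
    for (d in .drivers) X[[paste0(d, "_mean")]] <- rowMeans(cstats[[d]]$mean)
    for (d in .drivers) X[[paste0(d, "_cv")]] <- rowMeans(cstats[[d]]$cv)
    for (d in .drivers)
      X[[paste0(d, "_ac")]] <- fill_ac(.row_lag1(canom[[d]], min_pairs = 12L))
    attr(X, "ac_flagged") <- ac_flagged
    return(X)
  }

  out <- list()
  for (yi in seq_along(years)) {
    if (yi < window) next
    win <- (yi - window + 1L):yi
    mcols <- scene$clim_calendar$year %in% years[win]
    X <- data.frame(
      fc = rowMeans(scene$fc[, win, drop = FALSE], na.rm = TRUE),
      gs_kndvi = rowMeans(gs[, win, drop = FALSE], na.rm = TRUE)
    )
    for (d in .drivers)
      X[[paste0(d, "_mean")]] <-
        rowMeans(cstats[[d]]$mean[, win, drop = FALSE])
    for (d in .drivers)
      X[[paste0(d, "_cv")]] <- rowMeans(cstats[[d]]$cv[, win, drop = FALSE])
    for (d in .drivers)
      X[[paste0(d, "_ac")]] <-
        fill_ac(.row_lag1(canom[[d]][, mcols, drop = FALSE],
                          min_pairs = 12L))
    out[[as.character(years[yi])]] <- X
  }
  attr(out, "ac_flagged") <- ac_flagged
  out
}

.rf_metrics <- function(pred, obs) {
  ss_res <- sum((pred - obs)^2)
  ss_tot <- sum((obs - mean(obs))^2)
  list(r2 = 1 - ss_res / ss_tot,
       mse = mean((pred - obs)^2),
       pbias = 100 * sum(pred - obs) / sum(obs))
}

#' Fit the random-forest attribution model
#'
#' Random forest with `num_trees` regression trees relating a TAC response
#' to environmental predictors. Records are split 60/40 into calibration
#' and validation; tree depth and predictors sampled per split (mtry) are
#' chosen by k-fold cross-validated grid search on the calibration split;
#' R-squared, MSE and percentage bias (PBIAS = 100 * sum(pred - obs) /
#' sum(obs), positive = overestimation) are reported on the held-out
#' validation split only. Deterministic given `seed`.
#'
#' @param X Data frame of predictors.
#' @param y Numeric response (e.g. long-term TAC per pixel).
#' @param seed Integer seed for the split, search and forest.
#' @param num_trees Number of trees (default 100).
#' @param calib_frac Calibration fraction (default 0.6).
#' @param cv_folds Cross-validation folds for the search (default 3).
#' @param mtry_grid,depth_grid Hyperparameter grids; defaults scale with
#'   the predictor count (depth 0 = unlimited).
#' @param min_records Minimum complete records required (default 50).
#' @return Object of class `rf_attribution` with elements `model`
#'   (the ranger forest), `best` (chosen hyperparameters), `metrics`
#'   (validation R2/MSE/PBIAS), `calib_idx`, `valid_idx`, `X`, `y`,
#'   `seed`.
#' @export
fit_attribution_model <- function(X, y, seed = 1L, num_trees = 100L,
                                  calib_frac = 0.6, cv_folds = 3L,
                                  mtry_grid = NULL, depth_grid = c(0L, 8L),
                                  min_records = 50L) {
  stopifnot(is.data.frame(X), length(y) == nrow(X))
  keep <- stats::complete.cases(X) & is.finite(y)
  X <- X[keep, , drop = FALSE]; y <- y[keep]
  if (nrow(X) < min_records)
    stop(sprintf("need at least %d complete records", min_records),
         call. = FALSE)
  if (stats::sd(y) == 0)
    stop("degenerate response: y is constant", call. = FALSE)
  p <- ncol(X)
  if (is.null(mtry_grid))
    mtry_grid <- sort(unique(pmax(1L, round(p * c(1 / 3, 1 / 2, 2 / 3)))))

  set.seed(seed)
  n <- nrow(X)
  calib_idx <- sort(sample.int(n, round(calib_frac * n)))
  valid_idx <- setdiff(seq_len(n), calib_idx)
  Xc <- X[calib_idx, , drop = FALSE]; yc <- y[calib_idx]

  folds <- sample(rep_len(seq_len(cv_folds), length(yc)))
  grid <- expand.grid(mtry = mtry_grid, depth = depth_grid)
  cv_mse <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    errs <- numeric(cv_folds)
    for (k in seq_len(cv_folds)) {
      tr <- folds != k
      fit <- ranger::ranger(
        x = Xc[tr, , drop = FALSE], y = yc[tr],
        num.trees = num_trees, mtry = grid$mtry[g],
        max.depth = grid$depth[g], seed = seed + k,
        num.threads = 1L
      )
      pr <- stats::predict(fit, data = Xc[!tr, , drop = FALSE],
                           num.threads = 1L)$predictions
      errs[k] <- mean((pr - yc[!tr])^2)
    }
    cv_mse[g] <- mean(errs)
  }
  best <- grid[which.min(cv_mse), ]

  model <- ranger::ranger(
    x = Xc, y = yc, num.trees = num_trees, mtry = best$mtry,
    max.depth = best$depth, seed = seed, num.threads = 1L
  )
  pred_valid <- stats::predict(model, data = X[valid_idx, , drop = FALSE],
                               num.threads = 1L)$predictions
  metrics <- .rf_metrics(pred_valid, y[valid_idx])

  structure(list(model = model,
                 best = list(mtry = best$mtry, depth = best$depth,
                             cv_mse = min(cv_mse)),
                 metrics = metrics, calib_idx = calib_idx,
                 valid_idx = valid_idx, X = X, y = y, seed = seed),
            class = "rf_attribution")
}

#' @export
predict.rf_attribution <- function(object, newdata, ...) {
  ok <- stats::complete.cases(newdata)
  out <- rep(NA_real_, nrow(newdata))
  if (any(ok)) {
    out[ok] <- stats::predict(object$model,
                              data = newdata[ok, , drop = FALSE],
                              num.threads = 1L)$predictions
  }
  out
}

#' @export
print.rf_attribution <- function(x, ...) {
  cat(sprintf("<rf_attribution> %d trees, mtry = %d, depth = %s; n = %d (%d calib / %d valid)\n",
              x$model$num.trees, x$best$mtry,
              if (x$best$depth == 0) "unlimited" else x$best$depth,
              length(x$y), length(x$calib_idx), length(x$valid_idx)))
  cat(sprintf("  validation: R2 = %.3f, MSE = %.4g, PBIAS = %.3g%%\n",
              x$metrics$r2, x$metrics$mse, x$metrics$pbias))
  invisible(x)
}

#' @export
summary.rf_attribution <- function(object, ...) {
  print(object)
  cat("  predictors:", paste(colnames(object$X), collapse = ", "), "\n")
  invisible(object)
}

#' Permutation importance and partial dependence
#'
#' Importance: mean increase in validation MSE when one predictor column
#' is permuted (averaged over `n_perm` permutations), ranked. Partial
#' dependence: mean model prediction over the validation records with the
#' predictor fixed at each point of a quantile grid.
#'
#' @param model An `rf_attribution`.
#' @param n_grid Grid points per predictor (default 20).
#' @param n_perm Permutations per predictor (default 5).
#' @param seed Integer seed for the permutations.
#' @return List with `importance` (data frame `predictor`,
#'   `mse_increase`, `rank`) and `partial_dependence` (named list of
#'   data frames `x`, `yhat`).
#' @export
model_diagnostics <- function(model, n_grid = 20L, n_perm = 5L,
                              seed = 1L) {
  stopifnot(inherits(model, "rf_attribution"))
  Xv <- model$X[model$valid_idx, , drop = FALSE]
  yv <- model$y[model$valid_idx]
  base_pred <- predict(model, Xv)
  base_mse <- mean((base_pred - yv)^2)
  set.seed(seed)
  imp <- vapply(colnames(Xv), function(j) {
    mean(vapply(seq_len(n_perm), function(r) {
      Xp <- Xv
      Xp[[j]] <- sample(Xp[[j]])
      mean((predict(model, Xp) - yv)^2) - base_mse
    }, numeric(1)))
  }, numeric(1))
  importance <- data.frame(predictor = names(imp), mse_increase = imp,
                           row.names = NULL)
  importance <- importance[order(-importance$mse_increase), ]
  importance$rank <- seq_len(nrow(importance))

  pdp <- lapply(colnames(Xv), function(j) {
    grid <- unique(stats::quantile(Xv[[j]],
                                   probs = seq(0.02, 0.98,
                                               length.out = n_grid),
                                   names = FALSE))
    yhat <- vapply(grid, function(g) {
      Xg <- Xv
      Xg[[j]] <- g
      mean(predict(model, Xg))
    }, numeric(1))
    data.frame(x = grid, yhat = yhat)
  })
  names(pdp) <- colnames(Xv)
  list(importance = importance, partial_dependence = pdp)
}

# Factorial counterfactual: f(X_t) - f(X_t with `freeze_cols` fixed at
# their first-year values). Returns pixels x years matrix.
.counterfactual <- function(model, X_annual, freeze_cols) {
  stopifnot(length(X_annual) >= 1)
  missing_cols <- setdiff(freeze_cols, colnames(X_annual[[1L]]))
  if (length(missing_cols))
    stop("unknown predictor column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  base <- X_annual[[1L]]
  out <- matrix(NA_real_, nrow(base), length(X_annual),
                dimnames = list(NULL, names(X_annual)))
  for (t in seq_along(X_annual)) {
    Xt <- X_annual[[t]]
    Xf <- Xt
    Xf[freeze_cols] <- base[freeze_cols]
    out[, t] <- predict(model, Xt) - predict(model, Xf)
  }
  out
}

#' Remove the climate-autocorrelation component of annual TAC
#'
#' Factorial counterfactual: for each year `t`, the model prediction with
#' all predictors dynamic minus the prediction with the four
#' climate-autocorrelation predictors frozen at their first-year values.
#' The first year is 0 by construction; so is every year when the
#' climate-autocorrelation predictors are constant in time.
#'
#' @param model An `rf_attribution` fitted on the long-term predictors.
#' @param X_annual Named list of per-year predictor data frames (annual
#'   mode of [build_predictors()]).
#' @return Pixels x years matrix of the TAC component attributable to
#'   climate autocorrelation.
#' @export
factor_out_climate_ac <- function(model, X_annual) {
  .counterfactual(model, X_annual, predictor_groups()$climate_ac)
}

#' Enhanced annual TAC
#'
#' Subtracts the climate-autocorrelation component from the raw annual TAC
#' series, leaving the part of the autocorrelation signal attributable to
#' the ecosystem's own recovery dynamics. The dTAC trend is then computed
#' on this series.
#'
#' @param raw_annual_tac Pixels x years matrix of rolling-window TAC
#'   (years as column names).
#' @param tac_given_xac Pixels x years matrix from
#'   [factor_out_climate_ac()].
#' @return Pixels x years matrix over the common years.
#' @export
enhanced_tac <- function(raw_annual_tac, tac_given_xac) {
  raw_annual_tac <- .as_row_matrix(raw_annual_tac)
  tac_given_xac <- .as_row_matrix(tac_given_xac)
  if (nrow(raw_annual_tac) != nrow(tac_given_xac))
    stop("pixel dimensions differ", call. = FALSE)
  common <- intersect(colnames(raw_annual_tac), colnames(tac_given_xac))
  if (!length(common))
    stop("no common years between the two series", call. = FALSE)
  raw_annual_tac[, common, drop = FALSE] -
    tac_given_xac[, common, drop = FALSE]
}

#' Driver-group contributions to annual TAC
#'
#' For each predictor group, the factorial counterfactual freezing that
#' group at its first-year values, plus the OLS trend of each
#' contribution. A group whose predictors are constant in time contributes
#' exactly zero.
#'
#' @param model An `rf_attribution`.
#' @param X_annual Named list of per-year predictor data frames.
#' @param groups Named list of predictor-name vectors (default
#'   [predictor_groups()]).
#' @param min_years Minimum years for the contribution trend (default 10).
#' @return List with `contributions` (named list of pixels x years
#'   matrices) and `trends` (pixels x groups matrix, per year).
#' @export
driver_contributions <- function(model, X_annual,
                                 groups = predictor_groups(),
                                 min_years = 10L) {
  stopifnot(is.list(groups), !is.null(names(groups)))
  yrs <- as.numeric(names(X_annual))
  contrib <- lapply(groups, function(g) .counterfactual(model, X_annual, g))
  trends <- vapply(contrib, function(m) {
    .trend_slope(m, yrs, min_n = min_years)
  }, numeric(nrow(contrib[[1L]])))
  trends <- matrix(trends, ncol = length(groups),
                   dimnames = list(NULL, names(groups)))
  list(contributions = contrib, trends = trends)
}
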