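# End-to-end orchestration: a single run configuration drives scene
# simulation, preprocessing, TAC indicators, attribution, climate-space
# statistics, GPP interplay and the abrupt-decline analysis, with a
# provenance manifest. Also the sensitivity suite and spatial
# aggregation.

.stage_order <- c("simulate", "preprocess", "tac", "attribution",
                  "climate_space", "interplay", "abrupt_decline")

#' Pipeline run configuration
#'
#' Collects every threshold and seed of the analysis so a run is fully
#' reproducible from its configuration alone.
#'
#' @param scene A [scene_config()] describing the synthetic scene.
#' @param stages Character vector of stages to run, a prefix-closed subset
#'   of `simulate`, `preprocess`, `tac`, `attribution`, `climate_space`,
#'   `interplay`, `abrupt_decline`.
#' @param qa_keep Quality classes retained (default good and marginal).
#' @param fc_min,miss_max Forest-mask thresholds.
#' @param window TAC window length in years.
#' @param split_year First year of the late decadal period.
#' @param min_pairs Minimum valid pairs per TAC estimate.
#' @param severities AD severities scanned (default 1:6).
#' @param threshold_severity Severity used for the TAC_AD / proximity
#'   analysis (default 3).
#' @param nbins,min_bin_count Climate-space grid resolution and bin floor.
#' @param rho_radius Spearman moving-window radius in pixels.
#' @param seed Seed for every random operation downstream of the scene.
#' @return An object of class `run_config`.
#' @export
run_config <- function(scene = scene_config(), stages = .stage_order,
                       qa_keep = c(0L, 1L), fc_min = 0.05, miss_max = 0.5,
                       window = 3L, split_year = 2011L, min_pairs = 20L,
                       severities = 1:6, threshold_severity = 3,
                       nbins = 50L, min_bin_count = 50L, rho_radius = 2L,
                       seed = 1L) {
  stages <- match.arg(stages, .stage_order, several.ok = TRUE)
  structure(list(scene = scene, stages = stages, qa_keep = qa_keep,
                 fc_min = fc_min, miss_max = miss_max, window = window,
                 split_year = split_year, min_pairs = min_pairs,
                 severities = severities,
                 threshold_severity = threshold_severity, nbins = nbins,
                 min_bin_count = min_bin_count, rho_radius = rho_radius,
                 seed = as.integer(seed)),
            class = "run_config")
}

.config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  con <- file(f, "wb")
  serialize(config, con, version = 3L)
  close(con)
  unname(tools::md5sum(f))
}

.require_stage <- function(run, stage, needed) {
  miss <- needed[!needed %in% names(run)]
  if (length(miss))
    stop(sprintf("stage '%s' requires upstream stage '%s' to be enabled",
                 stage, miss[1L]), call. = FALSE)
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in dependency order on a synthetic scene
#' (built from the configuration, or supplied) and returns all stage
#' outputs plus a provenance manifest (configuration hash, seed, package
#' version). Deterministic given the configuration.
#'
#' @param config A [run_config()].
#' @param scene Optional pre-built `forest_scene` (skips simulation).
#' @return An object of class `csd_run`: a named list of stage outputs
#'   with a `manifest` element.
#' @export
run_pipeline <- function(config = run_config(), scene = NULL) {
  stopifnot(inherits(config, "run_config"))
  run <- list()
  stages <- config$stages

  if ("simulate" %in% stages || is.null(scene)) {
    if (is.null(scene)) scene <- build_scene(config$scene)
  }
  run$scene <- scene
  years <- scene$years
  n_pix <- nrow(scene$ndvi)

  if ("preprocess" %in% stages) {
    kn <- kndvi_transform(scene$ndvi)
    anoms <- gap_fill(compute_anomalies(kn, qa = scene$qa,
                                        calendar = scene$calendar,
                                        qa_keep = config$qa_keep))
    miss_frac <- rowMeans(!matrix(scene$qa %in% config$qa_keep,
                                  n_pix, ncol(kn)))
    mask <- apply_forest_mask(scene$fc, miss_frac,
                              fc_min = config$fc_min,
                              miss_max = config$miss_max)
    valid <- matrix(scene$qa %in% config$qa_keep, n_pix, ncol(kn))
    gs <- .as_row_matrix(growing_season_mean(kn, scene$calendar,
                                             scene$season_mask,
                                             valid = valid))
    run$preprocess <- list(kndvi = kn, anomalies = anoms, mask = mask,
                           gs_kndvi = gs, missing_fraction = miss_frac)
  }

  if ("tac" %in% stages) {
    .require_stage(run, "tac", "preprocess")
    anoms <- run$preprocess$anomalies
    run$tac <- list(
      long_term = long_term_tac(anoms, min_pairs = config$min_pairs),
      annual = rolling_tac(anoms, window = config$window,
                           min_pairs = config$min_pairs),
      decadal_diff = decadal_difference(anoms,
                                        split_year = config$split_year,
                                        min_pairs = config$min_pairs)
    )
  }

  if ("attribution" %in% stages) {
    .require_stage(run, "attribution", c("preprocess", "tac"))
    mask <- run$preprocess$mask$mask
    X_lt <- build_predictors(scene, mode = "long_term",
                             qa_keep = config$qa_keep)
    X_ann <- build_predictors(scene, mode = "annual",
                              window = config$window,
                              qa_keep = config$qa_keep)
    y <- run$tac$long_term
    fit_idx <- mask & !is.na(y)
    model <- fit_attribution_model(X_lt[fit_idx, , drop = FALSE],
                                   y[fit_idx], seed = config$seed)
    tac_xac <- factor_out_climate_ac(model, X_ann)
    enh <- enhanced_tac(run$tac$annual, tac_xac)
    dtac <- tac_trend(enh)
    dtac[!mask] <- NA_real_
    contrib <- driver_contributions(model, X_ann)
    run$attribution <- list(model = model, predictors = X_lt,
                            predictors_annual = X_ann,
                            tac_given_xac = tac_xac,
                            enhanced_tac = enh, delta_tac = dtac,
                            contributions = contrib,
                            diagnostics = model_diagnostics(
                              model, seed = config$seed))
  }

  if ("climate_space" %in% stages) {
    .require_stage(run, "climate_space", "attribution")
    Xlt <- run$attribution$predictors
    w <- cos(scene$lat * pi / 180)
    mask <- run$preprocess$mask$mask
    dtac <- run$attribution$delta_tac
    grid <- bin_climate_space(dtac[mask], Xlt$temp_mean[mask],
                              Xlt$precip_mean[mask], weights = w[mask],
                              nbins = config$nbins,
                              min_count = config$min_bin_count)
    lt <- run$tac$long_term
    mi <- mask & scene$intact
    mm <- mask & !scene$intact
    matched <- NULL
    if (sum(mi) >= 2 && sum(mm) >= 2) {
      matched <- match_forest_classes(
        lt[mm], Xlt$temp_mean[mm], Xlt$precip_mean[mm],
        lt[mi], Xlt$temp_mean[mi], Xlt$precip_mean[mi],
        nbins = config$nbins, seed = config$seed
      )
      matched$test <- two_sample_ttest(matched$a, matched$b)
    }
    run$climate_space <- list(dtac_grid = grid,
                              managed_vs_intact = matched)
  }

  if ("interplay" %in% stages) {
    .require_stage(run, "interplay", "attribution")
    enh <- run$attribution$enhanced_tac
    yrs_enh <- colnames(enh)
    gpp <- scene$gpp
    colnames(gpp) <- years
    gpp_sub <- gpp[, yrs_enh, drop = FALSE]
    rho <- spearman_moving_window(gpp_sub, enh, scene$grid_dim,
                                  radius = config$rho_radius)
    dgpp <- gpp_trend(gpp)
    qd <- quadrant_classify(dgpp, run$attribution$delta_tac,
                            ifelse(scene$intact, "intact", "managed"))
    run$interplay <- list(rho = rho, delta_gpp = dgpp, quadrants = qd)
  }

  if ("abrupt_decline" %in% stages) {
    .require_stage(run, "abrupt_decline", c("preprocess", "attribution"))
    mask <- run$preprocess$mask$mask
    gs <- run$preprocess$gs_kndvi
    colnames(gs) <- years
    enh <- run$attribution$enhanced_tac
    enh_years <- as.numeric(colnames(enh))
    set.seed(config$seed)
    ad <- list()
    for (sv in config$severities) {
      ev <- detect_ad(gs, years, severity = sv)
      ev <- ev[mask[ev$pixel] & scene$intact[ev$pixel], , drop = FALSE]
      if (nrow(ev)) {
        ad_flag <- logical(nrow(gs))
        ad_flag[ev$pixel] <- TRUE
        ev$delta_tac <- vapply(seq_len(nrow(ev)), function(i) {
          antecedent_trend(enh[ev$pixel[i], ], enh_years, ev$year[i])
        }, numeric(1))
        ev$control <- vapply(ev$pixel, function(px) {
          sample_control(ad_flag, scene$grid_dim, px)
        }, integer(1))
        ev$control_delta_tac <- vapply(seq_len(nrow(ev)), function(i) {
          if (is.na(ev$control[i])) return(NA_real_)
          antecedent_trend(enh[ev$control[i], ], enh_years, ev$year[i])
        }, numeric(1))
      }
      ad[[as.character(sv)]] <- ev
    }
    cond <- lapply(ad, function(ev) {
      ok <- !is.na(ev$delta_tac) & !is.na(ev$control_delta_tac)
      if (sum(ok) < 10) return(NULL)
      conditional_probability(ev$delta_tac[ok], ev$control_delta_tac[ok])
    })

    thr <- NULL
    ev3 <- ad[[as.character(config$threshold_severity)]]
    if (!is.null(ev3) && nrow(ev3)) {
      ev3$tac_ad <- vapply(seq_len(nrow(ev3)), function(i) {
        extract_tac_ad(enh[ev3$pixel[i], ], enh_years, ev3$year[i],
                       ev3$delta_tac[i])
      }, numeric(1))
      pre_cols <- enh_years < config$split_year - 1
      pre_mean <- rowMeans(enh[, pre_cols, drop = FALSE], na.rm = TRUE)
      ev3$tolerance <- ad_tolerance(ev3$tac_ad, pre_mean[ev3$pixel])
      obs <- !is.na(ev3$tac_ad)
      Xr <- run$attribution$predictors[
        , setdiff(colnames(run$attribution$predictors),
                  predictor_groups()$climate_ac), drop = FALSE]
      g <- NULL
      if (sum(obs) >= 50) {
        g <- fit_threshold_model(Xr[ev3$pixel[obs], , drop = FALSE],
                                 ev3$tac_ad[obs], seed = config$seed)
      }
      undist <- mask & scene$intact
      undist[ev3$pixel] <- FALSE
      prox <- rep(NA_real_, n_pix)
      crit <- NULL
      if (!is.null(g)) {
        pred_tac_ad <- predict(g, Xr)
        tac_final <- enh[, ncol(enh)]
        prox[undist] <- proximity(tac_final[undist], pred_tac_ad[undist])
        gpp <- scene$gpp[, -ncol(scene$gpp), drop = FALSE]
        colnames(gpp) <- years[-length(years)]
        crit <- critical_exposure(prox, run$attribution$delta_tac, gpp,
                                  target_year = max(years))
      }
      thr <- list(events = ev3, model_g = g, proximity = prox,
                  critical = crit)
    }
    run$abrupt_decline <- list(events = ad, conditional = cond,
                               threshold = thr)
  }

  run$manifest <- list(config_hash = .config_hash(config),
                       seed = config$seed,
                       stages = stages,
                       package_version =
                         as.character(utils::packageVersion("forestcsd")))
  structure(run, class = "csd_run")
}

#' @export
print.csd_run <- function(x, ...) {
  cat("<csd_run> stages:", paste(x$manifest$stages, collapse = ", "), "\n")
  cat("  config hash:", x$manifest$config_hash, "\n")
  if (!is.null(x$tac))
    cat(sprintf("  long-term TAC: mean %.3f over %d pixels\n",
                mean(x$tac$long_term, na.rm = TRUE),
                sum(!is.na(x$tac$long_term))))
  if (!is.null(x$attribution))
    cat(sprintf("  attribution model: validation R2 = %.3f\n",
                x$attribution$model$metrics$r2))
  invisible(x)
}

#' Block-aggregate a pixel map
#'
#' Coarsens a per-pixel map by averaging non-missing values in
#' `factor x factor` blocks; edge blocks smaller than the factor are
#' averaged over the cells available.
#'
#' @param map Numeric vector (column-major over the grid) or
#'   n_lat x n_lon matrix.
#' @param grid_dim Integer c(n_lat, n_lon) when `map` is a vector.
#' @param factor Positive integer block size; 1 returns the input map.
#' @return Matrix of block means (ceiling(n_lat/factor) x
#'   ceiling(n_lon/factor)).
#' @export
spatial_aggregate <- function(map, grid_dim = NULL, factor = 1L) {
  if (factor <= 0) stop("`factor` must be positive", call. = FALSE)
  g <- if (is.matrix(map)) map else {
    stopifnot(!is.null(grid_dim), length(map) == prod(grid_dim))
    matrix(map, grid_dim[1L], grid_dim[2L])
  }
  if (factor == 1L) return(g)
  ri <- ceiling(seq_len(nrow(g)) / factor)
  ci <- ceiling(seq_len(ncol(g)) / factor)
  out <- matrix(NA_real_, max(ri), max(ci))
  for (i in seq_len(max(ri))) {
    for (j in seq_len(max(ci))) {
      blk <- g[ri == i, ci == j]
      if (any(!is.na(blk))) out[i, j] <- mean(blk, na.rm = TRUE)
    }
  }
  out
}

#' Sensitivity suite for the decadal TAC difference
#'
#' Recomputes the decadal TAC difference across a grid of analysis
#' choices — quality filter, gap-filling on or off, missing-data and
#' forest-cover thresholds, exclusion of abrupt-decline pixels, spatial
#' aggregation factor and TAC window length for the trend variant — and
#' summarizes the per-region distributions for each configuration.
#'
#' @param scene A `forest_scene`.
#' @param grids Named list of vectors over which to expand the
#'   configuration; recognized names: `qa_keep` (list), `gapfill`
#'   (logical), `miss_max`, `fc_min`, `exclude_ad` (logical),
#'   `agg_factor` (integer), `split_year`.
#' @param min_pairs Minimum valid pairs per TAC estimate.
#' @return Data frame: one row per configuration x region with the
#'   distribution mean, sd, and fraction positive, plus the configuration
#'   columns.
#' @export
sensitivity_suite <- function(scene, grids = list(), min_pairs = 20L) {
  defaults <- list(qa_keep = list(c(0L, 1L)), gapfill = TRUE,
                   miss_max = 0.5, fc_min = 0.05, exclude_ad = FALSE,
                   agg_factor = 1L, split_year = 2011L)
  for (nm in names(grids)) {
    if (!nm %in% names(defaults))
      stop("unknown sensitivity dimension: ", nm, call. = FALSE)
    defaults[[nm]] <- grids[[nm]]
  }
  if (!length(unlist(defaults, recursive = FALSE)))
    stop("empty sensitivity grid", call. = FALSE)
  combos <- expand.grid(lapply(defaults, seq_along))
  kn <- kndvi_transform(scene$ndvi)
  out <- list()
  for (ci in seq_len(nrow(combos))) {
    cfg <- lapply(names(defaults), function(nm) {
      v <- defaults[[nm]]
      if (is.list(v)) v[[combos[ci, nm]]] else v[combos[ci, nm]]
    })
    names(cfg) <- names(defaults)
    anoms <- compute_anomalies(kn, qa = scene$qa,
                               calendar = scene$calendar,
                               qa_keep = cfg$qa_keep)
    if (cfg$gapfill) anoms <- gap_fill(anoms)
    diff <- decadal_difference(anoms, split_year = cfg$split_year,
                               min_pairs = min_pairs)
    miss_frac <- rowMeans(!matrix(scene$qa %in% cfg$qa_keep,
                                  nrow(kn), ncol(kn)))
    mask <- apply_forest_mask(scene$fc, miss_frac, fc_min = cfg$fc_min,
                              miss_max = cfg$miss_max)$mask
    if (cfg$exclude_ad) {
      valid <- matrix(scene$qa %in% cfg$qa_keep, nrow(kn), ncol(kn))
      gs <- .as_row_matrix(growing_season_mean(kn, scene$calendar,
                                               scene$season_mask,
                                               valid = valid))
      ev <- detect_ad(gs, scene$years, severity = 3)
      mask[ev$pixel] <- FALSE
    }
    diff[!mask] <- NA_real_
    if (cfg$agg_factor > 1L) {
      agg <- spatial_aggregate(diff, scene$grid_dim, cfg$agg_factor)
      ragg <- ceiling(seq_len(scene$grid_dim[1L]) / cfg$agg_factor)
      region_blk <- tapply(as.character(scene$region)[
        seq_len(scene$grid_dim[1L])], ragg, function(z) z[1L])
      vals <- as.vector(agg)
      regs <- rep(region_blk, times = ncol(agg))
    } else {
      vals <- diff
      regs <- as.character(scene$region)
    }
    for (r in unique(regs)) {
      v <- vals[regs == r & !is.na(vals)]
      out[[length(out) + 1L]] <- data.frame(
        region = r,
        qa_keep = paste(cfg$qa_keep, collapse = "+"),
        gapfill = cfg$gapfill, miss_max = cfg$miss_max,
        fc_min = cfg$fc_min, exclude_ad = cfg$exclude_ad,
        agg_factor = cfg$agg_factor, split_year = cfg$split_year,
        n = length(v), mean = mean(v), sd = stats::sd(v),
        frac_positive = mean(v > 0)
      )
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
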