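# Scene assembly: a gridded multi-year synthetic study area with four
# latitudinal climate regions (boreal at the northern edge through
# temperate and arid to tropical), per-pixel AR(1) truth, climate drivers,
# forest cover, GPP and optional injected abrupt declines.

.default_region_params <- function() {
  clim <- function(p_mean, p_cv, p_ac, t_mean, t_cv, t_ac, t_seas,
                   e_mean, e_cv, e_ac, r_mean, r_cv, r_ac) {
    list(
      precip = list(mean = p_mean, cv = p_cv, ac = p_ac, seasonal = 0),
      temp   = list(mean = t_mean, cv = t_cv, ac = t_ac, seasonal = t_seas),
      etdef  = list(mean = e_mean, cv = e_cv, ac = e_ac, seasonal = 0),
      rad    = list(mean = r_mean, cv = r_cv, ac = r_ac, seasonal = 0)
    )
  }
  list(
    boreal = list(
      phi0 = 0.20, phi_trend = -0.0015, phi_jitter_sd = 0.05,
      seasonal_amplitude = 0.25, noise_sd = 0.04, missing_fraction = 0.30,
      baseline = 0.55, trend_per_year = 0.001,
      fc_range = c(0.4, 0.9), intact_fraction = 0.5,
      gpp_base = 800, gpp_coupling = 0.8, gpp_noise_sd = 60,
      season_months = 5:9,
      climate = clim(50, 0.5, 0.15, 2, 1.0, 0.30, 14, 10, 0.6, 0.2,
                     120, 0.10, 0.2)
    ),
    temperate = list(
      phi0 = 0.25, phi_trend = 0.0014, phi_jitter_sd = 0.05,
      seasonal_amplitude = 0.18, noise_sd = 0.04, missing_fraction = 0.15,
      baseline = 0.70, trend_per_year = 0.001,
      fc_range = c(0.3, 0.9), intact_fraction = 0.2,
      gpp_base = 1500, gpp_coupling = 0.8, gpp_noise_sd = 100,
      season_months = 4:10,
      climate = clim(80, 0.4, 0.20, 12, 0.30, 0.30, 10, 30, 0.5, 0.2,
                     180, 0.12, 0.2)
    ),
    arid = list(
      phi0 = 0.35, phi_trend = 0.0013, phi_jitter_sd = 0.05,
      seasonal_amplitude = 0.08, noise_sd = 0.05, missing_fraction = 0.10,
      baseline = 0.35, trend_per_year = 0.0005,
      fc_range = c(0.06, 0.5), intact_fraction = 0.2,
      gpp_base = 500, gpp_coupling = 0.8, gpp_noise_sd = 50,
      season_months = 3:10,
      climate = clim(25, 0.8, 0.10, 22, 0.12, 0.30, 8, 60, 0.5, 0.2,
                     260, 0.08, 0.2)
    ),
    tropical = list(
      phi0 = 0.30, phi_trend = 0.0016, phi_jitter_sd = 0.05,
      seasonal_amplitude = 0.05, noise_sd = 0.03, missing_fraction = 0.20,
      baseline = 0.80, trend_per_year = 0.001,
      fc_range = c(0.5, 0.98), intact_fraction = 0.5,
      gpp_base = 3000, gpp_coupling = 0.8, gpp_noise_sd = 150,
      season_months = 1:12,
      climate = clim(200, 0.3, 0.30, 26, 0.04, 0.40, 2, 40, 0.4, 0.3,
                     220, 0.10, 0.2)
    )
  )
}

#' Configuration of a synthetic scene
#'
#' Bundles grid shape, calendar, seed and per-region parameter blocks. The
#' defaults describe a realistic four-region study area: modest positive
#' per-year drift of the AR(1) coefficient in tropical, temperate and arid
#' regions, a negative drift in the boreal region, snow-driven missingness
#' strongest in the north, and region-appropriate climate and productivity
#' levels.
#'
#' @param grid_shape Integer c(n_lat, n_lon).
#' @param years Integer vector of calendar years (>= 3 years).
#' @param seed Integer seed controlling all randomness in
#'   [build_scene()].
#' @param region_params Named list of per-region parameter blocks
#'   (`boreal`, `temperate`, `arid`, `tropical` from north to south);
#'   defaults from `.default_region_params` are modified by any supplied
#'   entries (partial overrides allowed).
#' @param ad_injections Optional data frame (`pixel`, `year`, `severity`)
#'   of abrupt declines to inject.
#' @param spatial_smooth Integer radius (pixels) of an optional box-kernel
#'   smoothing of the vegetation anomalies; 0 (default) keeps pixels
#'   independent.
#' @return An object of class `scene_config`.
#' @export
scene_config <- function(grid_shape = c(20L, 20L), years = 2000:2020,
                         seed = 1L, region_params = list(),
                         ad_injections = NULL, spatial_smooth = 0L) {
  stopifnot(length(grid_shape) == 2L, all(grid_shape >= 1))
  if (length(years) < 3) stop("need at least 3 years", call. = FALSE)
  defaults <- .default_region_params()
  if (length(region_params)) {
    bad <- setdiff(names(region_params), names(defaults))
    if (length(bad))
      stop("unknown region(s): ", paste(bad, collapse = ", "), call. = FALSE)
    for (r in names(region_params))
      defaults[[r]] <- utils::modifyList(defaults[[r]], region_params[[r]])
  }
  n_years <- length(years)
  for (r in names(defaults)) {
    p <- defaults[[r]]
    if (abs(p$phi0) >= 1 || abs(p$phi0 + p$phi_trend * n_years) >= 1)
      stop(sprintf("region %s: phi trajectory leaves (-1, 1)", r),
           call. = FALSE)
    if (p$missing_fraction >= 0.5)
      stop(sprintf("region %s: missing_fraction must be < 0.5", r),
           call. = FALSE)
  }
  if (!is.null(ad_injections)) {
    stopifnot(all(c("pixel", "year", "severity") %in% names(ad_injections)))
    if (any(ad_injections$severity < 0 | ad_injections$severity > 6))
      stop("injection severity must lie in [0, 6]", call. = FALSE)
  }
  structure(list(grid_shape = as.integer(grid_shape),
                 years = as.integer(years), seed = as.integer(seed),
                 region_params = defaults, ad_injections = ad_injections,
                 spatial_smooth = as.integer(spatial_smooth)),
            class = "scene_config")
}

# Separable box blur on the grid, applied column-of-time-wise; NA-safe.
.smooth_grid <- function(m, grid_dim, radius) {
  if (radius <= 0) return(m)
  n_lat <- grid_dim[1L]; n_lon <- grid_dim[2L]
  w <- 2L * radius + 1L
  k <- rep(1, w)
  blur1 <- function(a) {
    # a: matrix; blur along rows (dim 1) with edge renormalization
    num <- apply(a, 2L, function(v) stats::filter(v, k, sides = 2L))
    den <- stats::filter(rep(1, nrow(a)), k, sides = 2L)
    num / den
  }
  for (j in seq_len(ncol(m))) {
    g <- matrix(m[, j], n_lat, n_lon)
    g <- blur1(g)
    g <- t(blur1(t(g)))
    m[, j] <- as.vector(g)
  }
  m
}

.kndvi_inverse <- function(k) {
  k <- pmin(pmax(k, 0), tanh(1) - 1e-9)
  sqrt(atanh(k))
}

#' Build a synthetic gridded scene
#'
#' Draws every pixel's vegetation, climate, forest-cover and GPP series
#' from its region's parameter block, applies any configured abrupt-decline
#' injections (in kNDVI space, so the detector operating on growing-season
#' kNDVI recovers them at the injected severity), and records the full
#' ground truth. Deterministic given `config$seed`.
#'
#' @param config A [scene_config()].
#' @return An object of class `forest_scene`: matrices are pixels x time
#'   (column-major pixel order over the n_lat x n_lon grid). Components:
#'   `ndvi`, `qa`, `calendar`, `climate` (list of four monthly matrices),
#'   `clim_calendar`, `fc`, `gpp` (annual matrices), `years`, `region`
#'   (factor), `intact` (logical), `season_mask` (pixels x 12 logical),
#'   `lat`, `lon`, `grid_dim`, `truth` (list: `phi` pixels x years matrix,
#'   `ad` injection table), `config`.
#' @export
build_scene <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  set.seed(config$seed)
  n_lat <- config$grid_shape[1L]; n_lon <- config$grid_shape[2L]
  n_pix <- n_lat * n_lon
  years <- config$years; n_years <- length(years)
  cal <- make_calendar(years)
  n_obs <- nrow(cal)
  regions <- names(config$region_params)  # north -> south

  lat_row <- seq(65, -15, length.out = n_lat)
  band <- cut(seq_len(n_lat), breaks = length(regions), labels = regions)
  row_of <- rep(seq_len(n_lat), times = n_lon)
  region <- factor(as.character(band)[row_of], levels = regions)
  lat <- lat_row[row_of]
  lon <- rep(seq(0, 20, length.out = n_lon), each = n_lat)

  pget <- function(field) {
    vapply(as.character(region),
           function(r) config$region_params[[r]][[field]], numeric(1),
           USE.NAMES = FALSE)
  }

  # per-pixel phi trajectory
  phi0 <- pget("phi0") + stats::rnorm(n_pix, 0, pget("phi_jitter_sd"))
  phi_tr <- pget("phi_trend")
  phi <- outer(phi0, rep(1, n_years)) +
    outer(phi_tr, seq_len(n_years) - 1L)
  phi <- pmin(pmax(phi, -0.95), 0.95)

  # vegetation index
  phi_obs <- phi[, rep(seq_len(n_years), each = 23L), drop = FALSE]
  anom <- .sim_ar1(n_pix, phi_obs, pget("noise_sd"), n_obs)
  anom <- .smooth_grid(anom, config$grid_shape, config$spatial_smooth)
  seas <- outer(pget("seasonal_amplitude"),
                cos(2 * pi * (cal$doy - 196) / 365))
  trend <- outer(pget("trend_per_year"), cal$frac_year - cal$frac_year[1L])
  ndvi <- pmin(pmax(pget("baseline") + seas + trend + anom, -1), 1)

  qa <- matrix(0L, n_pix, n_obs)
  n_miss <- floor(pget("missing_fraction") * n_obs)
  for (i in seq_len(n_pix)) {
    if (n_miss[i] > 0) qa[i, sample.int(n_obs, n_miss[i])] <- 3L
  }

  # monthly climate drivers
  n_mon <- 12L * n_years
  clim_cal <- data.frame(year = rep(years, each = 12L),
                         month = rep(1:12, n_years))
  climate <- list()
  for (drv in c("precip", "temp", "etdef", "rad")) {
    blk <- lapply(as.character(region),
                  function(r) config$region_params[[r]]$climate[[drv]])
    mu0 <- vapply(blk, `[[`, numeric(1), "mean")
    cv <- vapply(blk, `[[`, numeric(1), "cv")
    ac <- vapply(blk, `[[`, numeric(1), "ac")
    seas_amp <- vapply(blk, `[[`, numeric(1), "seasonal")
    mu <- if (drv == "temp") mu0 + stats::runif(n_pix, -2, 2)
          else mu0 * stats::runif(n_pix, 0.8, 1.2)
    sdv <- cv * abs(mu)
    canom <- .sim_ar1(n_pix, matrix(ac, n_pix, n_mon), sdv, n_mon)
    cseas <- outer(seas_amp, cos(2 * pi * (clim_cal$month - 7) / 12))
    climate[[drv]] <- mu + cseas + canom
  }

  # forest cover (static in time plus small annual wobble)
  fc_lo <- vapply(as.character(region),
                  function(r) config$region_params[[r]]$fc_range[1L],
                  numeric(1), USE.NAMES = FALSE)
  fc_hi <- vapply(as.character(region),
                  function(r) config$region_params[[r]]$fc_range[2L],
                  numeric(1), USE.NAMES = FALSE)
  fc0 <- stats::runif(n_pix, fc_lo, fc_hi)
  fc <- pmin(pmax(fc0 + matrix(stats::rnorm(n_pix * n_years, 0, 0.005),
                               n_pix, n_years), 0), 1)

  # intact mask: fixed fraction per region
  intact <- logical(n_pix)
  for (r in regions) {
    idx <- which(region == r)
    k <- round(config$region_params[[r]]$intact_fraction * length(idx))
    if (k > 0) intact[sample(idx, k)] <- TRUE
  }

  season_mask <- matrix(FALSE, n_pix, 12L)
  for (r in regions) {
    season_mask[region == r,
                config$region_params[[r]]$season_months] <- TRUE
  }

  # abrupt-decline injections (kNDVI state space)
  ad_truth <- data.frame(pixel = integer(), year = integer(),
                         severity = numeric())
  if (!is.null(config$ad_injections)) {
    for (j in seq_len(nrow(config$ad_injections))) {
      inj <- config$ad_injections[j, ]
      ps <- structure(list(values = ndvi[inj$pixel, ],
                           qa = qa[inj$pixel, ], calendar = cal),
                      class = "pixel_series")
      ps <- inject_abrupt_decline(
        ps, inj$year, inj$severity,
        season_mask = season_mask[inj$pixel, ],
        transform = function(v) tanh(v^2), inverse = .kndvi_inverse
      )
      ndvi[inj$pixel, ] <- ps$values
      ad_truth <- rbind(ad_truth,
                        data.frame(pixel = inj$pixel, year = inj$year,
                                   severity = inj$severity))
    }
  }

  # GPP coupled to the growing-season kNDVI state (after injections)
  kn <- tanh(ndvi^2)
  state <- matrix(NA_real_, n_pix, n_years)
  in_season <- season_mask[, cal$month, drop = FALSE]
  for (yi in seq_len(n_years)) {
    colsel <- cal$year == years[yi]
    sel <- in_season[, colsel, drop = FALSE]
    v <- kn[, colsel, drop = FALSE]
    v[!sel] <- NA
    state[, yi] <- rowMeans(v, na.rm = TRUE)
  }
  base <- pget("gpp_base"); coup <- pget("gpp_coupling")
  gnsd <- pget("gpp_noise_sd")
  sm <- rowMeans(state); ss <- apply(state, 1L, stats::sd)
  ss[ss == 0 | is.na(ss)] <- Inf
  z <- (state - sm) / ss
  gpp <- base * (1 + 0.2 * coup * z) +
    matrix(stats::rnorm(n_pix * n_years, 0, rep(gnsd, n_years)),
           n_pix, n_years)

  structure(list(ndvi = ndvi, qa = qa, calendar = cal, climate = climate,
                 clim_calendar = clim_cal, fc = fc, gpp = gpp,
                 years = years, region = region, intact = intact,
                 season_mask = season_mask, lat = lat, lon = lon,
                 grid_dim = config$grid_shape,
                 truth = list(phi = phi, ad = ad_truth),
                 config = config),
            class = "forest_scene")
}

#' @export
print.forest_scene <- function(x, ...) {
  cat(sprintf("<forest_scene> %d x %d grid (%d pixels), %d-%d\n",
              x$grid_dim[1L], x$grid_dim[2L], nrow(x$ndvi),
              min(x$years), max(x$years)))
  cat("  regions:", paste(sprintf("%s=%d", levels(x$region),
                                  tabulate(x$region)), collapse = ", "), "\n")
  cat(sprintf("  intact pixels: %d; injected declines: %d\n",
              sum(x$intact), nrow(x$truth$ad)))
  invisible(x)
}
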