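# Interplay between gross primary productivity and resilience: short-term
# Spearman correlation of annual GPP and TAC pooled over spatial moving
# windows, the long-term GPP trend, and the dGPP/dTAC quadrant
# classification.

#' Spearman correlation of GPP and TAC over a spatial moving window
#'
#' For each pixel, pools all (pixel, year) pairs within a square window
#' centred on it and computes the Spearman rank correlation between annual
#' GPP and annual TAC over the pooled pairs — sampling the joint empirical
#' distribution better than a single pixel's short series.
#'
#' @param gpp,tac Pixels x years matrices with aligned columns.
#' @param grid_dim Integer c(n_lat, n_lon); pixels are in column-major
#'   order.
#' @param radius Window radius in pixels (default 2, i.e. a 5 x 5 window;
#'   use 10 for a 1-degree window at 0.05-degree spacing).
#' @param min_pairs Minimum pooled pairs (default 30); fewer, or a
#'   constant input within the window, gives NA.
#' @return Numeric vector of per-pixel rho in [-1, 1].
#' @export
spearman_moving_window <- function(gpp, tac, grid_dim, radius = 2L,
                                   min_pairs = 30L) {
  stopifnot(all(dim(gpp) == dim(tac)),
            nrow(gpp) == prod(grid_dim))
  n_lat <- grid_dim[1L]; n_lon <- grid_dim[2L]
  rho <- rep(NA_real_, nrow(gpp))
  for (cc in seq_len(n_lon)) {
    cwin <- max(1L, cc - radius):min(n_lon, cc + radius)
    for (rr in seq_len(n_lat)) {
      rwin <- max(1L, rr - radius):min(n_lat, rr + radius)
      pix <- as.vector(outer(rwin, (cwin - 1L) * n_lat, `+`))
      g <- as.vector(gpp[pix, , drop = FALSE])
      a <- as.vector(tac[pix, , drop = FALSE])
      ok <- !is.na(g) & !is.na(a)
      if (sum(ok) < min_pairs) next
      g <- g[ok]; a <- a[ok]
      if (stats::sd(g) == 0 || stats::sd(a) == 0) next
      rho[(cc - 1L) * n_lat + rr] <- stats::cor(g, a, method = "spearman")
    }
  }
  rho
}

#' Trend of annual GPP (dGPP)
#'
#' Per-pixel OLS slope of annual GPP against calendar year.
#'
#' @param gpp_annual Pixels x years matrix (or vector) of annual GPP.
#' @param years Calendar years (defaults to column names).
#' @param min_years Minimum valid annual values (default 10).
#' @return Numeric vector of trends (GPP units per year).
#' @export
gpp_trend <- function(gpp_annual, years = NULL, min_years = 10L) {
  m <- .as_row_matrix(gpp_annual)
  if (is.null(years)) {
    years <- suppressWarnings(as.numeric(colnames(m)))
    if (anyNA(years)) stop("supply `years` or name the columns", call. = FALSE)
  }
  .trend_slope(m, years, min_n = min_years)
}

#' Classify pixels by the signs of dGPP and dTAC
#'
#' Four classes from the sign pair (dGPP, dTAC): `++` (growing but losing
#' resilience), `+-`, `-+`, `--`. Exact-zero trends are classified as
#' positive. Cover fractions are reported per forest type.
#'
#' @param delta_gpp,delta_tac Per-pixel trends.
#' @param forest_type Factor or character per pixel (e.g. managed /
#'   intact); NULL pools everything.
#' @return List with `quadrant` (factor with levels `++`, `+-`, `-+`,
#'   `--`; NA where either trend is missing) and `fractions` (data frame
#'   `forest_type`, `quadrant`, `fraction`; fractions sum to 1 within
#'   type).
#' @export
quadrant_classify <- function(delta_gpp, delta_tac, forest_type = NULL) {
  stopifnot(length(delta_gpp) == length(delta_tac))
  lv <- c("++", "+-", "-+", "--")
  q <- ifelse(delta_gpp >= 0,
              ifelse(delta_tac >= 0, "++", "+-"),
              ifelse(delta_tac >= 0, "-+", "--"))
  q <- factor(q, levels = lv)
  if (is.null(forest_type)) forest_type <- rep("all", length(q))
  ok <- !is.na(q)
  tab <- table(forest_type = forest_type[ok], quadrant = q[ok])
  frac <- as.data.frame(prop.table(tab, margin = 1L),
                        responseName = "fraction")
  list(quadrant = q, fractions = frac)
}
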