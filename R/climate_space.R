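# Climate-space analysis: binning pixel statistics on a temperature x
# precipitation grid with area weights and per-bin tests, the shared-bin
# matched comparison between managed and intact forests, the Welch
# two-sample test, and aridity-gradient binning.

.bin_edges <- function(x, nbins, probs = c(0.01, 0.99)) {
  rng <- stats::quantile(x, probs = probs, na.rm = TRUE, names = FALSE)
  if (rng[1L] == rng[2L]) rng <- rng + c(-0.5, 0.5)
  seq(rng[1L], rng[2L], length.out = nbins + 1L)
}

.bin_index <- function(x, edges) {
  i <- findInterval(x, edges, rightmost.closed = TRUE)
  i[i < 1L | i > length(edges) - 1L] <- NA_integer_
  i
}

#' Bin a pixel statistic in climate space
#'
#' Bins per-pixel values on a temperature x precipitation grid (default
#' 50 x 50, edges spanning the 1st-99th percentile of the pooled climate),
#' reporting the area-weighted mean, the count and a two-sided one-sample
#' t-test against zero per bin. Bins with fewer than `min_count` records
#' are dropped.
#'
#' @param values Per-pixel statistic (e.g. dTAC).
#' @param temp,precip Per-pixel mean annual temperature and precipitation.
#' @param weights Area weights (>= 0); default `cos(latitude)` is the
#'   caller's job — unweighted if NULL.
#' @param nbins Bins per axis (default 50).
#' @param min_count Minimum records per retained bin (default 50).
#' @param temp_edges,precip_edges Optional explicit bin edges.
#' @return Object of class `climate_space_grid`: data frame `bins`
#'   (`bin_t`, `bin_p`, `mean`, `n`, `p_value`) plus the edges.
#' @export
bin_climate_space <- function(values, temp, precip, weights = NULL,
                              nbins = 50L, min_count = 50L,
                              temp_edges = NULL, precip_edges = NULL) {
  ok <- !is.na(values) & !is.na(temp) & !is.na(precip)
  if (!any(ok)) stop("no valid records to bin", call. = FALSE)
  if (is.null(weights)) weights <- rep(1, length(values))
  if (any(weights < 0, na.rm = TRUE))
    stop("weights must be >= 0", call. = FALSE)
  values <- values[ok]; temp <- temp[ok]; precip <- precip[ok]
  weights <- weights[ok]
  temp_edges <- temp_edges %||% .bin_edges(temp, nbins)
  precip_edges <- precip_edges %||% .bin_edges(precip, nbins)
  bt <- .bin_index(temp, temp_edges)
  bp <- .bin_index(precip, precip_edges)
  keep <- !is.na(bt) & !is.na(bp)
  key <- (bt[keep] - 1L) * (length(precip_edges) - 1L) + bp[keep]
  sp <- split(seq_along(key), key)
  rows <- lapply(sp, function(idx) {
    if (length(idx) < min_count) return(NULL)
    v <- values[keep][idx]; w <- weights[keep][idx]
    p <- if (length(v) >= 2) one_sample_ttest(v)$p_value else NA_real_
    data.frame(bin_t = bt[keep][idx[1L]], bin_p = bp[keep][idx[1L]],
               mean = sum(w * v) / sum(w), n = length(v), p_value = p)
  })
  bins <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(bins))
    bins <- data.frame(bin_t = integer(), bin_p = integer(),
                       mean = numeric(), n = integer(),
                       p_value = numeric())
  rownames(bins) <- NULL
  structure(list(bins = bins, temp_edges = temp_edges,
                 precip_edges = precip_edges, min_count = min_count),
            class = "climate_space_grid")
}

#' @export
print.climate_space_grid <- function(x, ...) {
  cat(sprintf("<climate_space_grid> %d occupied bins (min %d records); %d significant at 0.05\n",
              nrow(x$bins), x$min_count,
              sum(x$bins$p_value <= 0.05, na.rm = TRUE)))
  invisible(x)
}

#' Shared-bin matched comparison of two forest classes
#'
#' Bins both classes on the same climate grid, keeps only bins covered by
#' both, and draws equal-size per-bin samples (seeded random subsampling
#' of the larger class), so the two returned samples are bin-matched and
#' of equal length — removing the climate-coverage confounder before
#' comparing classes (e.g. managed versus intact forests).
#'
#' @param values_a,values_b Per-pixel statistics of the two classes.
#' @param temp_a,precip_a,temp_b,precip_b Class climates.
#' @param nbins Bins per axis (default 50).
#' @param min_count Minimum records per class per shared bin (default 1).
#' @param seed Integer seed for the subsampling.
#' @return List with matched samples `a` and `b` (equal length), and
#'   `n_shared_bins`.
#' @export
match_forest_classes <- function(values_a, temp_a, precip_a,
                                 values_b, temp_b, precip_b,
                                 nbins = 50L, min_count = 1L, seed = 1L) {
  ok_a <- !is.na(values_a) & !is.na(temp_a) & !is.na(precip_a)
  ok_b <- !is.na(values_b) & !is.na(temp_b) & !is.na(precip_b)
  temp_edges <- .bin_edges(c(temp_a[ok_a], temp_b[ok_b]), nbins)
  precip_edges <- .bin_edges(c(precip_a[ok_a], precip_b[ok_b]), nbins)
  key <- function(tt, pp) {
    bt <- .bin_index(tt, temp_edges); bp <- .bin_index(pp, precip_edges)
    ifelse(is.na(bt) | is.na(bp), NA_integer_, (bt - 1L) * nbins + bp)
  }
  ka <- key(temp_a[ok_a], precip_a[ok_a])
  kb <- key(temp_b[ok_b], precip_b[ok_b])
  va <- values_a[ok_a]; vb <- values_b[ok_b]
  ta <- table(ka); tb <- table(kb)
  shared <- intersect(names(ta)[ta >= min_count], names(tb)[tb >= min_count])
  if (!length(shared))
    stop("the two classes share no climate bins", call. = FALSE)
  set.seed(seed)
  out_a <- out_b <- numeric(0)
  for (s in shared) {
    ia <- which(ka == as.integer(s)); ib <- which(kb == as.integer(s))
    m <- min(length(ia), length(ib))
    if (length(ia) > m) ia <- sample(ia, m)
    if (length(ib) > m) ib <- sample(ib, m)
    out_a <- c(out_a, va[ia]); out_b <- c(out_b, vb[ib])
  }
  list(a = out_a, b = out_b, n_shared_bins = length(shared))
}

#' Welch two-sample t-test
#'
#' Two-sided Welch test of the difference in means, as used for the
#' matched managed-versus-intact comparisons. Degenerate samples (both
#' zero-variance) give p = 1 when the means are equal and p = 0
#' otherwise.
#'
#' @param a,b Numeric samples (NA dropped), each with n >= 2.
#' @return List with `mean_diff` (= mean(a) - mean(b)), `p_value`, `n_a`,
#'   `n_b`.
#' @export
two_sample_ttest <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2)
    stop("each sample needs at least 2 values", call. = FALSE)
  d <- mean(a) - mean(b)
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    return(list(mean_diff = d, p_value = if (d == 0) 1 else 0,
                n_a = length(a), n_b = length(b)))
  }
  ht <- stats::t.test(a, b)
  list(mean_diff = d, p_value = ht$p.value, n_a = length(a),
       n_b = length(b))
}

#' Bin a statistic along an aridity gradient
#'
#' Aridity index computed as De Martonne `P / (T + 10)` (mm per degree C,
#' with annual precipitation in mm and temperature in degrees C); values
#' are binned on fixed edges (default 0-500 in steps of 100) and
#' summarized by mean and normal-approximation 95 percent confidence
#' interval.
#'
#' @param values Per-pixel statistic (e.g. tolerance).
#' @param precip Mean annual precipitation (mm).
#' @param temp Mean annual temperature (degrees C).
#' @param edges Aridity bin edges (default `seq(0, 500, 100)`).
#' @return Data frame with `bin_lo`, `bin_hi`, `mean`, `ci_lo`, `ci_hi`,
#'   `n` (empty bins reported with n = 0).
#' @export
bin_aridity <- function(values, precip, temp, edges = seq(0, 500, 100)) {
  aridity <- precip / (temp + 10)
  b <- .bin_index(aridity, edges)
  out <- lapply(seq_len(length(edges) - 1L), function(i) {
    v <- values[!is.na(b) & b == i & !is.na(values)]
    n <- length(v)
    if (n == 0)
      return(data.frame(bin_lo = edges[i], bin_hi = edges[i + 1L],
                        mean = NA_real_, ci_lo = NA_real_,
                        ci_hi = NA_real_, n = 0L))
    m <- mean(v)
    se <- if (n > 1) stats::sd(v) / sqrt(n) else 0
    data.frame(bin_lo = edges[i], bin_hi = edges[i + 1L], mean = m,
               ci_lo = m - 1.96 * se, ci_hi = m + 1.96 * se, n = n)
  })
  do.call(rbind, out)
}
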