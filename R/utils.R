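# Internal vectorized numerics shared across the package. All row-wise
# helpers treat rows as pixels and columns as time, with NA = invalid.

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

.as_row_matrix <- function(x) {
  if (is.matrix(x)) x else matrix(x, nrow = 1L)
}

# Row-wise OLS of y (n_row x n_col, NA allowed) on a shared abscissa x.
# Returns list(intercept, slope, n). Rows with fewer than min_n valid
# observations get NA.
.row_ols <- function(y, x, min_n = 2L) {
  y <- .as_row_matrix(y)
  stopifnot(length(x) == ncol(y))
  w <- !is.na(y)
  y0 <- y
  y0[!w] <- 0
  xm <- matrix(x, nrow(y), ncol(y), byrow = TRUE)
  n <- rowSums(w)
  sx <- rowSums(xm * w)
  sy <- rowSums(y0)
  sxx <- rowSums(xm * xm * w)
  sxy <- rowSums(xm * y0)
  denom <- sxx - sx * sx / n
  slope <- (sxy - sx * sy / n) / denom
  bad <- n < min_n | !is.finite(denom) | denom <= .Machine$double.eps * pmax(sxx, 1)
  slope[bad] <- NA_real_
  intercept <- sy / n - slope * sx / n
  intercept[bad] <- NA_real_
  list(intercept = intercept, slope = slope, n = n)
}

# Row-wise Pearson correlation between consecutive columns: cor(x_t, x_{t+1})
# over pairs where both members are non-NA. Zero-variance rows and rows with
# fewer than min_pairs valid pairs return NA.
.row_lag1 <- function(m, min_pairs = 20L) {
  m <- .as_row_matrix(m)
  if (ncol(m) < 2L) return(rep(NA_real_, nrow(m)))
  a <- m[, -ncol(m), drop = FALSE]
  b <- m[, -1L, drop = FALSE]
  v <- !is.na(a) & !is.na(b)
  a[!v] <- 0
  b[!v] <- 0
  n <- rowSums(v)
  ma <- rowSums(a) / n
  mb <- rowSums(b) / n
  cov <- rowSums(a * b) / n - ma * mb
  va <- rowSums(a * a) / n - ma * ma
  vb <- rowSums(b * b) / n - mb * mb
  r <- cov / sqrt(va * vb)
  eps <- .Machine$double.eps * 100
  r[n < min_pairs | !is.finite(r) | va <= eps | vb <= eps] <- NA_real_
  pmin(pmax(r, -1), 1)
}

# Map a 16-day composite period (1..23, day-of-year 1, 17, ..., 353) to its
# calendar month in a non-leap year.
.period_month <- function(period) {
  month_starts <- c(1, 32, 60, 91, 121, 152, 182, 213, 244, 274, 305, 335)
  doy <- 16L * (as.integer(period) - 1L) + 1L
  findInterval(doy, month_starts)
}

#' Build the 16-day composite calendar for a run of years
#'
#' Each year carries 23 composites anchored at day-of-year 1, 17, ..., 353,
#' mirroring the cadence of 16-day vegetation-index products.
#'
#' @param years Integer vector of calendar years (consecutive).
#' @return A data frame with one row per observation and columns `year`,
#'   `period` (1-23), `doy`, `month` and `frac_year` (fractional year used as
#'   the detrending abscissa).
#' @export
make_calendar <- function(years) {
  years <- as.integer(years)
  n <- length(years)
  period <- rep(1:23, times = n)
  year <- rep(years, each = 23L)
  doy <- 16L * (period - 1L) + 1L
  data.frame(
    year = year, period = period, doy = doy,
    month = .period_month(period),
    frac_year = year + (doy - 1) / 365
  )
}

.check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                          strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  ok <- if (strict) x > lower && x < upper else x >= lower && x <= upper
  if (!ok)
    stop(sprintf("`%s` = %g is outside [%g, %g]%s", name, x, lower, upper,
                 if (strict) " (exclusive)" else ""), call. = FALSE)
  invisible(x)
}
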