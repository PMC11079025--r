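#' Pixel-wise monotone trend detection
#'
#' Annual raster stacks (NDVI, groundwater table depth, soil organic carbon
#' stock) are screened for monotone trends with the nonparametric
#' Mann-Kendall test and the Sen's slope estimator. The MK statistic is
#' S = sum over pairs i < j of sign(x_j - x_i); its variance uses the
#' standard tie correction and the normal deviate Z applies the +/-1
#' continuity correction. Sen's slope is the median of all pairwise slopes
#' (x_j - x_i)/(j - i). The normal approximation is used at every series
#' length handled here (the analysis windows are 10-21 years); an exact
#' permutation oracle for short series lives in the test suite, not in the
#' package.
#'
#' @name trends
NULL

#' Mann-Kendall trend test for one annual series
#'
#' @param x numeric series ordered by year; `NA` gaps are dropped (their
#'   year indices are preserved for Sen's slope but MK uses ranks only).
#' @return A list with `S` (integer statistic), `var_S` (tie-corrected
#'   variance), `Z` (continuity-corrected normal deviate), `p` (two-sided
#'   p-value) and `n` (series length after gap removal), or `NULL`-like
#'   `NA` fields when fewer than 3 values remain.
#' @examples
#' mk_test(c(1, 2, 3, 4, 5))$S  # 10 = choose(5, 2)
#' @export
mk_test <- function(x) {
  keep <- !is.na(x)
  v <- x[keep]
  n <- length(v)
  if (n < 3L)
    return(list(S = NA_integer_, var_S = NA_real_, Z = NA_real_,
                p = NA_real_, n = n))
  d <- outer(v, v, "-")
  S <- sum(sign(d[lower.tri(d)]))        # lower.tri: rows j > cols i
  ties <- table(v)
  ties <- ties[ties > 1L]
  var_S <- (n * (n - 1) * (2 * n + 5) -
              sum(ties * (ties - 1) * (2 * ties + 5))) / 18
  Z <- if (var_S <= 0) 0
       else if (S > 0) (S - 1) / sqrt(var_S)
       else if (S < 0) (S + 1) / sqrt(var_S)
       else 0
  p <- 2 * stats::pnorm(-abs(Z))
  list(S = as.integer(S), var_S = var_S, Z = Z, p = min(p, 1), n = n)
}

#' Sen's slope estimator
#'
#' Median of all pairwise slopes (x_j - x_i) / (t_j - t_i) with time taken
#' as the integer year index, so gaps widen the denominator rather than
#' being ignored.
#'
#' @param x numeric series ordered by year; `NA` allowed.
#' @return The slope in units per year, or `NA` with fewer than 2 values.
#' @examples
#' sen_slope(c(0, 1, 2, 3))  # 1
#' @export
sen_slope <- function(x) {
  t <- seq_along(x)
  keep <- !is.na(x)
  v <- x[keep]; t <- t[keep]
  n <- length(v)
  if (n < 2L) return(NA_real_)
  dv <- outer(v, v, "-")
  dt <- outer(t, t, "-")
  stats::median(dv[lower.tri(dv)] / dt[lower.tri(dt)])
}

#' Mann-Kendall + Sen over many series at once
#'
#' Vectorised core used by [trend_raster()] and the uncertainty machinery:
#' series are the rows of a matrix with one column per year. Gap handling:
#' rows with fewer than `min_frac` of years present are returned as `NA`.
#' Tie-corrected variance is computed per row from pairwise and triple-wise
#' equality counts (sum over tie groups of t(t-1)(2t+5) expressed through
#' the number of equal pairs and equal triples).
#'
#' @param m numeric matrix, rows = series, cols = years.
#' @param min_frac minimum fraction of non-missing years (default 0.7).
#' @return list of vectors `S`, `var_S`, `Z`, `p`, `slope` (one per row).
#' @export
mk_sen_matrix <- function(m, min_frac = 0.7) {
  stopifnot(is.matrix(m))
  nr <- nrow(m); nyr <- ncol(m)
  if (nyr < 3L) stop("need at least 3 years")
  pairs <- utils::combn(nyr, 2L)
  npair <- ncol(pairs)
  S <- numeric(nr); P2 <- numeric(nr)
  slopes <- matrix(NA_real_, nr, npair)
  for (k in seq_len(npair)) {
    i <- pairs[1L, k]; j <- pairs[2L, k]
    d <- m[, j] - m[, i]
    S <- S + sign(ifelse(is.na(d), 0, d))
    P2 <- P2 + as.numeric(!is.na(d) & d == 0)
    slopes[, k] <- d / (j - i)
  }
  # equal triples for the tie correction
  P3 <- numeric(nr)
  if (nyr >= 3L) {
    trips <- utils::combn(nyr, 3L)
    for (k in seq_len(ncol(trips))) {
      a <- m[, trips[1L, k]]; b <- m[, trips[2L, k]]; c <- m[, trips[3L, k]]
      eq <- !is.na(a) & !is.na(b) & !is.na(c) & a == b & b == c
      P3 <- P3 + as.numeric(eq)
    }
  }
  nvalid <- rowSums(!is.na(m))
  # sum over tie groups of t(t-1)(2t+5) = 2*S3 + 3*S2 - 5*S1 with
  # S1 = n, S2 = n + 2*P2, S3 = 6*P3 + 3*S2 - 2*n
  S2 <- nvalid + 2 * P2
  S3 <- 6 * P3 + 3 * S2 - 2 * nvalid
  tie_term <- 2 * S3 + 3 * S2 - 5 * nvalid
  var_S <- (nvalid * (nvalid - 1) * (2 * nvalid + 5) - tie_term) / 18
  Z <- ifelse(var_S > 0,
              ifelse(S > 0, (S - 1) / sqrt(var_S),
                     ifelse(S < 0, (S + 1) / sqrt(var_S), 0)), 0)
  p <- pmin(2 * stats::pnorm(-abs(Z)), 1)
  slope <- apply(slopes, 1L, stats::median, na.rm = TRUE)
  slope[apply(slopes, 1L, function(r) all(is.na(r)))] <- NA_real_
  bad <- nvalid < max(3, ceiling(min_frac * nyr))
  S[bad] <- NA; var_S[bad] <- NA; Z[bad] <- NA; p[bad] <- NA; slope[bad] <- NA
  list(S = S, var_S = var_S, Z = Z, p = p, slope = slope)
}

#' Per-pixel trend grids from an annual stack
#'
#' @param stack multi-band [grid_create()] object, bands ordered by year.
#' @param min_frac minimum fraction of years a pixel must have (pixels
#'   below it get nodata).
#' @return list with `slope` and `p` single-band grids.
#' @export
trend_raster <- function(stack, min_frac = 0.7) {
  nb <- grid_nbands(stack)
  if (nb < 3L) stop("trend_raster needs at least 3 bands")
  d <- dim(stack$values)
  m <- matrix(stack$values, d[1] * d[2], d[3])  # column-major pixels x years
  res <- mk_sen_matrix(m, min_frac = min_frac)
  list(slope = grid_like(stack, matrix(res$slope, d[1], d[2])),
       p     = grid_like(stack, matrix(res$p, d[1], d[2])))
}
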