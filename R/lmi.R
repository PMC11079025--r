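#' Land Multi-degradation Index
#'
#' The LMI of a pixel is the number of degradation processes whose
#' criticality rule fires there: the pixel-wise sum of the binary Critical
#' layers over the land-use stratum of interest. It is interpreted through
#' five classes: very low (1 process), low (2), medium (3), high (4) and
#' very high (>= 5), with 0 meaning no degradation.
#'
#' @name lmi
NULL

#' Build a land-use mask object
#'
#' Emulates a CORINE-style nomenclature: agricultural codes cover arable
#' land (211, 212, 213), permanent crops (221, 222, 223), pastures (231)
#' and heterogeneous agricultural areas (241, 242, 243, 244); arable codes
#' are a subset.
#'
#' @param codes grid of integer land-cover codes.
#' @param agricultural_codes integer codes making up the agricultural
#'   stratum.
#' @param arable_codes subset of `agricultural_codes`.
#' @return list of class `lmdi_landmask`.
#' @export
land_mask <- function(codes,
                      agricultural_codes = c(211, 212, 213, 221, 222, 223,
                                             231, 241, 242, 243, 244),
                      arable_codes = c(211, 212, 213)) {
  if (!all(arable_codes %in% agricultural_codes))
    stop("arable_codes must be a subset of agricultural_codes")
  structure(list(codes = codes,
                 agricultural_codes = agricultural_codes,
                 arable_codes = arable_codes),
            class = "lmdi_landmask")
}

#' 0/1 grid of one land-use stratum
#' @param land a [land_mask()] object.
#' @param stratum `"agricultural"` or `"arable"`.
#' @export
stratum_mask <- function(land, stratum = c("agricultural", "arable")) {
  stratum <- match.arg(stratum)
  codes <- if (stratum == "agricultural") land$agricultural_codes
           else land$arable_codes
  v <- land$codes$values
  grid_like(land$codes, ifelse(is.na(v), NA_real_,
                               as.numeric(v %in% codes)), nodata = 255)
}

#' Compute the Land Multi-degradation Index
#'
#' Per-pixel sum of Critical masks over a land-use stratum. Pixels outside
#' the stratum are nodata. Within the stratum, layers that are nodata at a
#' pixel are skipped and the number of layers actually summed is returned
#' alongside, so downstream reporting can flag reduced completeness.
#'
#' @param masks named list of 0/1/NA grids (canonical order).
#' @param land a [land_mask()] object.
#' @param stratum `"agricultural"` or `"arable"`.
#' @return list of class `lmdi_index`: `counts` grid (integer LMI),
#'   `n_layers` grid (layers summed per pixel), `n_available` (number of
#'   masks supplied), `stratum`.
#' @export
compute_lmi <- function(masks, land, stratum = c("agricultural", "arable")) {
  stratum <- match.arg(stratum)
  if (length(masks) == 0L) stop("no critical masks supplied")
  grid_check_aligned(c(masks, list(land$codes)))
  sm <- stratum_mask(land, stratum)
  d <- dim(sm$values)
  counts <- matrix(0, d[1], d[2])
  nlay <- matrix(0, d[1], d[2])
  for (m in masks) {
    v <- m$values
    ok <- !is.na(v)
    counts[ok] <- counts[ok] + v[ok]
    nlay <- nlay + ok
  }
  inside <- !is.na(sm$values) & sm$values == 1
  counts[!inside] <- NA_real_
  nlay[!inside] <- NA_real_
  structure(list(counts = grid_like(sm, counts, nodata = 255),
                 n_layers = grid_like(sm, nlay, nodata = 255),
                 n_available = length(masks), stratum = stratum),
            class = "lmdi_index")
}

#' Bin LMI counts into the five degradation classes
#'
#' Mapping: 0 -> 0 (no degradation), 1 -> 1 (very low), 2 -> 2 (low),
#' 3 -> 3 (medium), 4 -> 4 (high), >= 5 -> 5 (very high).
#'
#' @param lmi an `lmdi_index` from [compute_lmi()] (or a bare counts grid).
#' @return grid of class codes 0..5 (nodata 255).
#' @export
classify_lmi <- function(lmi) {
  counts <- if (inherits(lmi, "lmdi_index")) lmi$counts else lmi
  v <- counts$values
  if (any(v < 0, na.rm = TRUE)) stop("negative LMI counts")
  grid_like(counts, pmin(v, 5), nodata = 255)
}

#' Descriptive labels of the LMI classes
#' @export
lmi_class_labels <- function() {
  c(`0` = "No degradation", `1` = "Very low", `2` = "Low",
    `3` = "Medium", `4` = "High", `5` = "Very high")
}

#' Histogram of LMI values
#'
#' Exact integer tallies of the LMI counts plus the share of nonzero
#' pixels falling in the 1..5 interval (the concentration statistic used
#' when fixing the class bins).
#'
#' @param lmi an `lmdi_index`.
#' @return list: `counts` (named integer vector over observed values 0..max),
#'   `share_1_5` (fraction of nonzero-LMI pixels with 1 <= LMI <= 5),
#'   `mean` (arithmetic mean LMI over valid pixels).
#' @export
lmi_histogram <- function(lmi) {
  v <- lmi$counts$values
  v <- v[!is.na(v)]
  mx <- if (length(v)) max(v) else 0
  tab <- tabulate(factor(v, levels = 0:mx), nbins = mx + 1)
  names(tab) <- 0:mx
  nz <- v[v > 0]
  list(counts = tab,
       share_1_5 = if (length(nz)) mean(nz >= 1 & nz <= 5) else NA_real_,
       mean = if (length(v)) mean(v) else NA_real_)
}

#' Zone partition object
#'
#' @param zones grid of integer zone (country) ids >= 1.
#' @param completeness named integer vector: layers available per zone
#'   (9..12); defaults to 12 everywhere.
#' @export
zone_partition <- function(zones, completeness = NULL) {
  ids <- sort(unique(zones$values[!is.na(zones$values)]))
  if (is.null(completeness))
    completeness <- stats::setNames(rep(12L, length(ids)), ids)
  if (!all(as.character(ids) %in% names(completeness)))
    stop("completeness missing for some zones")
  if (!all(completeness %in% 9:12))
    stop("completeness must be between 9 and 12 layers")
  structure(list(zones = zones, completeness = completeness),
            class = "lmdi_zones")
}

#' Zone- and stratum-level LMI area report
#'
#' For every zone: the area (km^2) and share of the stratum in each LMI
#' class, plus the area-weighted mean number of co-occurring processes.
#' Aggregate rows (`zone = "ALL"`) are computed over zones with complete
#' data only; zones integrating fewer than `n_complete` layers are flagged
#' `incomplete` and excluded from the aggregate, mirroring the reporting
#' convention for countries with 9-10 input layers.
#'
#' @param classes LMI class grid from [classify_lmi()].
#' @param lmi `lmdi_index` (supplies counts for the mean).
#' @param zones an `lmdi_zones` partition.
#' @param land a [land_mask()] object.
#' @param stratum stratum name used for labelling.
#' @param include_class0_in_mean include class-0 pixels in the mean
#'   co-occurrence (default TRUE; they are agricultural land).
#' @param n_complete layer count regarded as complete (default 12).
#' @return data.frame: `zone`, `stratum`, `class`, `label`, `area_km2`,
#'   `percent`, `mean_processes`, `incomplete`.
#' @export
zonal_stats <- function(classes, lmi, zones, land,
                        stratum = lmi$stratum,
                        include_class0_in_mean = TRUE,
                        n_complete = 12L) {
  grid_check_aligned(classes, lmi$counts, zones$zones, land$codes)
  cellkm2 <- (classes$cell_size / 1000)^2
  zv <- zones$zones$values
  cv <- classes$values
  nv <- lmi$counts$values
  valid <- !is.na(cv) & !is.na(zv)
  zid <- zv[valid]; cls <- cv[valid]; cnt <- nv[valid]
  ids <- sort(unique(zv[!is.na(zv)]))
  mk_rows <- function(zname, sel, flag) {
    if (!any(sel)) {
      return(data.frame(zone = zname, stratum = stratum, class = 0:5,
                        label = unname(lmi_class_labels()), area_km2 = 0,
                        percent = 0, mean_processes = NA_real_,
                        incomplete = flag, stringsAsFactors = FALSE))
    }
    tot <- sum(sel)
    per_class <- vapply(0:5, function(k) sum(cls[sel] == k), numeric(1))
    mean_sel <- if (include_class0_in_mean) sel else sel & cnt > 0
    data.frame(zone = zname, stratum = stratum, class = 0:5,
               label = unname(lmi_class_labels()),
               area_km2 = per_class * cellkm2,
               percent = 100 * per_class / tot,
               mean_processes = if (any(mean_sel)) mean(cnt[mean_sel])
                                else NA_real_,
               incomplete = flag, stringsAsFactors = FALSE)
  }
  rows <- list()
  complete_sel <- rep(FALSE, length(zid))
  for (z in ids) {
    comp <- zones$completeness[[as.character(z)]]
    flag <- comp < n_complete
    sel <- zid == z
    rows[[length(rows) + 1L]] <- mk_rows(as.character(z), sel, flag)
    if (!flag) complete_sel <- complete_sel | sel
  }
  rows[[length(rows) + 1L]] <- mk_rows("ALL", complete_sel, FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Jenks natural-breaks classification (exact)
#'
#' Optimal 1-D partition into `k` classes minimising the within-class sum
#' of squared deviations, by dynamic programming over the sorted values
#' (Fisher's method). Used as a cross-check on the fixed LMI class bins,
#' not as the binning path.
#'
#' @param values numeric vector.
#' @param k number of classes (>= 2).
#' @return numeric vector of `k - 1` break points; a value v belongs to the
#'   lowest class whose break is >= v (breaks are the class maxima of the
#'   lower classes).
#' @export
natural_breaks <- function(values, k) {
  values <- values[!is.na(values)]
  if (k < 2) stop("k must be >= 2")
  if (length(unique(values)) < k)
    stop("k exceeds the number of distinct values")
  x <- sort(values)
  n <- length(x)
  cs <- cumsum(x); cs2 <- cumsum(x^2)
  ssd <- function(i, j) {   # within-class SSD of x[i..j]
    s <- cs[j] - if (i > 1) cs[i - 1] else 0
    s2 <- cs2[j] - if (i > 1) cs2[i - 1] else 0
    s2 - s^2 / (j - i + 1)
  }
  cost <- matrix(Inf, k, n)
  back <- matrix(0L, k, n)
  for (j in 1:n) cost[1, j] <- ssd(1, j)
  if (k > 1) for (m in 2:k) for (j in m:n) {
    for (i in m:j) {
      val <- cost[m - 1, i - 1] + ssd(i, j)
      if (val < cost[m, j]) { cost[m, j] <- val; back[m, j] <- i }
    }
  }
  cuts <- integer(k - 1)
  j <- n
  for (m in k:2) {
    i <- back[m, j]
    cuts[m - 1] <- i - 1L   # index of the last element of the class below
    j <- i - 1L
  }
  x[cuts]
}
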