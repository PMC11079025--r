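#' Dominant combinations of co-occurring degradation processes
#'
#' Every stratum pixel carries the set of processes that are Critical there,
#' encoded as a bitset over the canonical 12-process order (bit 1 = WaE,
#' bit 2 = WiE, ... bit 12 = A). Within each LMI class the combinations are
#' tabulated by area, ranked, and the dominant ones selected; for display
#' the combination grid can be coarsened by modal aggregation, while all
#' quantification stays at the native resolution.
#'
#' @name combinations
NULL

#' Human-readable name of a combination bitset
#' @param key integer bitset value(s).
#' @param process_ids canonical process order.
#' @export
combo_label <- function(key, process_ids = registry_process_ids(default_registry())) {
  vapply(key, function(k) {
    if (is.na(k)) return(NA_character_)
    if (k == 0) return("(none)")
    on <- which(bitwAnd(k, bitwShiftL(1L, seq_along(process_ids) - 1L)) != 0L)
    paste(process_ids[on], collapse = " + ")
  }, character(1))
}

#' Per-pixel combination grid
#'
#' @param masks named list of 0/1/NA Critical grids in canonical order.
#' @return grid of integer bitset keys (`NA` where any mask is nodata).
#' @export
combo_grid <- function(masks) {
  grid_check_aligned(masks)
  ref <- masks[[1]]
  key <- matrix(0, nrow(ref$values), ncol(ref$values))
  for (i in seq_along(masks)) {
    v <- masks[[i]]$values
    key <- key + ifelse(is.na(v), NA_real_, v) * 2^(i - 1)
  }
  grid_like(ref, key, nodata = -1)
}

#' Tabulate process combinations within each LMI class
#'
#' @param masks named list of Critical grids (canonical order).
#' @param classes LMI class grid from [classify_lmi()]; pixels outside the
#'   stratum (nodata) are skipped.
#' @param counts optional LMI counts grid for the internal popcount
#'   consistency check (recomputed from the masks when omitted).
#' @return data.frame `lmdi_combos`: `class`, `key`, `combo`, `pixels`,
#'   `area_km2`, `percent_of_stratum`, `percent_of_class`, sorted by class
#'   then descending area (ties by ascending key).
#' @export
enumerate_combos <- function(masks, classes, counts = NULL) {
  grid_check_aligned(c(masks, list(classes)))
  kg <- combo_grid(masks)
  cellkm2 <- (classes$cell_size / 1000)^2
  cls <- as.vector(classes$values)
  key <- as.vector(kg$values)
  keep <- !is.na(cls) & !is.na(key)
  cls <- cls[keep]; key <- key[keep]
  pc <- vapply(key, function(k) sum(bitwAnd(as.integer(k),
                 bitwShiftL(1L, 0:(length(masks) - 1L))) != 0L), numeric(1))
  # class code 5 covers counts >= 5; all other codes equal the popcount
  if (!all(ifelse(cls < 5, pc == cls, pc >= 5)))
    stop("internal inconsistency: combination popcount does not match class")
  total <- length(cls)
  agg <- stats::aggregate(list(pixels = rep(1L, total)),
                          by = list(class = cls, key = key), FUN = sum)
  class_tot <- stats::aggregate(list(class_pixels = agg$pixels),
                                by = list(class = agg$class), FUN = sum)
  agg <- merge(agg, class_tot, by = "class")
  agg$area_km2 <- agg$pixels * cellkm2
  agg$percent_of_stratum <- 100 * agg$pixels / total
  agg$percent_of_class <- 100 * agg$pixels / agg$class_pixels
  agg$combo <- combo_label(agg$key, names(masks))
  agg <- agg[order(agg$class, -agg$area_km2, agg$key),
             c("class", "key", "combo", "pixels", "area_km2",
               "percent_of_stratum", "percent_of_class")]
  rownames(agg) <- NULL
  class(agg) <- c("lmdi_combos", "data.frame")
  agg
}

#' Select the dominant combinations of one LMI class
#'
#' Ranks a class's combinations by area (ties broken by ascending bitset
#' key) and returns the top `k`, their cumulative coverage of the class
#' area, and whether the selection reaches the coverage criterion
#' (>= 50% by default).
#'
#' @param table an `lmdi_combos` table.
#' @param class LMI class code (1..5).
#' @param k number of combinations to keep (default 12).
#' @param coverage_target fraction of class area the selection should
#'   reach (default 0.5).
#' @return data.frame with `rank` and `cumulative_percent` columns added,
#'   plus attributes `coverage_met` (logical) and `coverage_percent`.
#' @export
top_combinations <- function(table, class, k = 12, coverage_target = 0.5) {
  sub <- table[table$class == class, , drop = FALSE]
  if (nrow(sub) == 0L) {
    warning("no combinations recorded for class ", class)
    out <- sub
    out$rank <- integer(0); out$cumulative_percent <- numeric(0)
    attr(out, "coverage_met") <- NA
    attr(out, "coverage_percent") <- NA_real_
    return(out)
  }
  sub <- sub[order(-sub$area_km2, sub$key), , drop = FALSE]
  sub <- utils::head(sub, k)
  sub$rank <- seq_len(nrow(sub))
  sub$cumulative_percent <- cumsum(sub$percent_of_class)
  rownames(sub) <- NULL
  cov <- sub$cumulative_percent[nrow(sub)]
  attr(sub, "coverage_percent") <- cov
  attr(sub, "coverage_met") <- cov >= 100 * coverage_target
  sub
}

#' Coarsen a combination grid for display
#'
#' Majority (modal) label per `factor` x `factor` block, ties broken by the
#' lowest bitset value. Display-only: areas and tables must always be
#' computed from the native-resolution grid.
#'
#' @param g combination (or any categorical) grid.
#' @param factor integer block size (default 10, e.g. 500 m -> 5 km).
#' @return coarse grid with cell size multiplied by `factor`.
#' @export
coarsen_display <- function(g, factor = 10) {
  factor <- as.integer(factor)
  if (factor < 1L) stop("factor must be >= 1")
  if (factor == 1L) return(g)
  d <- dim(g$values)
  nr <- ceiling(d[1] / factor); nc <- ceiling(d[2] / factor)
  out <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) {
    rows <- ((i - 1L) * factor + 1L):min(i * factor, d[1])
    for (j in seq_len(nc)) {
      colsel <- ((j - 1L) * factor + 1L):min(j * factor, d[2])
      blk <- g$values[rows, colsel]
      blk <- blk[!is.na(blk)]
      if (length(blk) == 0L) next
      tab <- table(blk)
      best <- names(tab)[tab == max(tab)]
      out[i, j] <- min(as.numeric(best))
    }
  }
  grid_create(out, cell_size = g$cell_size * factor, xmin = g$xmin,
              ymax = g$ymax, crs = g$crs, nodata = g$nodata)
}
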