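#' Georeferenced grid (raster) objects
#'
#' A `grid` is the package's universal raster carrier: a 2-D matrix of values
#' (or a 3-D array for multi-band annual stacks) plus an affine geotransform
#' restricted to north-up, square-cell geometry, an equal-area CRS identifier
#' and a nodata sentinel. Row 1 of the matrix is the northernmost row
#' (top-left origin, row-major, cell-centre registration). In memory, missing
#' cells are `NA`; the `nodata` field is the sentinel written to disk.
#'
#' @param values numeric matrix (rows x cols) or 3-D array (rows x cols x
#'   bands) of cell values; `NA` marks nodata cells.
#' @param cell_size cell edge length in metres (strictly positive).
#' @param xmin x coordinate of the left edge of the western cell column.
#' @param ymax y coordinate of the top edge of the northern cell row.
#' @param crs identifier of an equal-area projected CRS (free-form string;
#'   the package treats it as an opaque compatibility token).
#' @param nodata numeric sentinel used when the grid is written to file.
#'
#' @return An object of class `lmdi_grid`.
#' @examples
#' g <- grid_create(matrix(1:12, 3, 4), cell_size = 500)
#' grid_dim(g)
#' @export
grid_create <- function(values, cell_size = 500, xmin = 0, ymax = NULL,
                        crs = "EPSG:3035", nodata = -9999) {
  if (is.vector(values)) values <- matrix(values, nrow = 1)
  stopifnot(is.numeric(values) || is.logical(values))
  if (!(length(dim(values)) %in% c(2L, 3L)))
    stop("values must be a matrix or a 3-D array")
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0)
    stop("cell_size must be a single strictly positive number")
  if (is.null(ymax)) ymax <- dim(values)[1] * cell_size
  storage.mode(values) <- "double"
  structure(
    list(values = values, cell_size = as.numeric(cell_size),
         xmin = as.numeric(xmin), ymax = as.numeric(ymax),
         crs = as.character(crs), nodata = as.numeric(nodata)),
    class = "lmdi_grid")
}

#' @export
print.lmdi_grid <- function(x, ...) {
  d <- dim(x$values)
  nb <- if (length(d) == 3L) d[3] else 1L
  cat(sprintf("<lmdi_grid> %d x %d cells, %d band(s), cell %g m, crs %s\n",
              d[1], d[2], nb, x$cell_size, x$crs))
  v <- x$values[is.finite(x$values)]
  if (length(v))
    cat(sprintf("  values: [%g, %g], %d NA\n", min(v), max(v),
                sum(is.na(x$values))))
  invisible(x)
}

#' @rdname grid_create
#' @param g a `lmdi_grid`.
#' @export
grid_dim <- function(g) {
  d <- dim(g$values)
  c(rows = d[1], cols = d[2], bands = if (length(d) == 3L) d[3] else 1L)
}

#' Number of bands in a grid
#' @param g a `lmdi_grid`.
#' @export
grid_nbands <- function(g) unname(grid_dim(g)[3])

#' Extract one band of a multi-band grid as a single-band grid
#' @param g a `lmdi_grid`.
#' @param i band index (1-based).
#' @export
grid_band <- function(g, i) {
  nb <- grid_nbands(g)
  if (i < 1L || i > nb) stop("band index out of range")
  v <- if (nb == 1L) g$values else g$values[, , i]
  grid_create(v, cell_size = g$cell_size, xmin = g$xmin, ymax = g$ymax,
              crs = g$crs, nodata = g$nodata)
}

#' Replace the value matrix of a grid, keeping its georeferencing
#' @param g a `lmdi_grid` template.
#' @param values replacement matrix/array with the same spatial shape.
#' @param nodata optional new nodata sentinel.
#' @export
grid_like <- function(g, values, nodata = g$nodata) {
  if (is.vector(values)) values <- matrix(values, dim(g$values)[1], dim(g$values)[2])
  if (!all(dim(values)[1:2] == dim(g$values)[1:2]))
    stop("replacement values do not match the template shape")
  grid_create(values, cell_size = g$cell_size, xmin = g$xmin, ymax = g$ymax,
              crs = g$crs, nodata = nodata)
}

#' Test that grids share shape, transform and CRS
#'
#' All grids entering one analysis must live on a common analysis grid; this
#' is the gatekeeper used by every multi-layer operation.
#' @param ... two or more `lmdi_grid` objects.
#' @return `TRUE` invisibly, or an error describing the first mismatch.
#' @export
grid_check_aligned <- function(...) {
  gs <- list(...)
  if (length(gs) == 1L && is.list(gs[[1]]) && !inherits(gs[[1]], "lmdi_grid"))
    gs <- gs[[1]]
  ref <- gs[[1]]
  for (g in gs[-1]) {
    if (!all(dim(g$values)[1:2] == dim(ref$values)[1:2]))
      stop("grids differ in shape")
    if (abs(g$cell_size - ref$cell_size) > 1e-9 ||
        abs(g$xmin - ref$xmin) > 1e-6 || abs(g$ymax - ref$ymax) > 1e-6)
      stop("grids differ in geotransform")
    if (!identical(g$crs, ref$crs)) stop("grids differ in CRS")
  }
  invisible(TRUE)
}

#' Align a grid to a template geometry
#'
#' Resamples `g` onto the geometry of `template`. `"nearest"` picks the
#' source cell whose centre is nearest to each target cell centre and is the
#' only method permitted for categorical layers; `"bilinear"` interpolates
#' the four surrounding source cell centres (edge cells are clamped) and is
#' meant for continuous fields. Aligning a grid already on the template
#' geometry is the identity.
#'
#' @param g source `lmdi_grid` (single-band).
#' @param template `lmdi_grid` supplying the target geometry.
#' @param method `"nearest"` or `"bilinear"`.
#' @param categorical logical; declaring a layer categorical forbids
#'   bilinear resampling.
#' @return A `lmdi_grid` on the template geometry.
#' @export
align_to_template <- function(g, template, method = c("nearest", "bilinear"),
                              categorical = FALSE) {
  method <- match.arg(method)
  if (categorical && method == "bilinear")
    stop("bilinear resampling is not allowed for categorical layers")
  if (!identical(g$crs, template$crs))
    stop("cannot align across different CRSs")
  dg <- dim(g$values); dt <- dim(template$values)
  same <- all(dg[1:2] == dt[1:2]) &&
    abs(g$cell_size - template$cell_size) < 1e-9 &&
    abs(g$xmin - template$xmin) < 1e-6 && abs(g$ymax - template$ymax) < 1e-6
  if (same) {
    out <- g
    out$nodata <- template$nodata
    return(out)
  }
  if (length(dg) == 3L) stop("align_to_template expects a single-band grid")
  # target cell-centre coordinates
  tx <- template$xmin + (seq_len(dt[2]) - 0.5) * template$cell_size
  ty <- template$ymax - (seq_len(dt[1]) - 0.5) * template$cell_size
  # fractional source indices of those centres (1-based, centre registration)
  fx <- (tx - g$xmin) / g$cell_size + 0.5
  fy <- (g$ymax - ty) / g$cell_size + 0.5
  out <- matrix(NA_real_, dt[1], dt[2])
  if (method == "nearest") {
    ix <- pmin(pmax(round(fx), 1L), dg[2])
    iy <- pmin(pmax(round(fy), 1L), dg[1])
    oob_x <- fx < 0.5 | fx > dg[2] + 0.5
    oob_y <- fy < 0.5 | fy > dg[1] + 0.5
    out <- matrix(g$values[cbind(rep(iy, times = dt[2]),
                                 rep(ix, each = dt[1]))], dt[1], dt[2])
    if (any(oob_x)) out[, oob_x] <- NA_real_
    if (any(oob_y)) out[oob_y, ] <- NA_real_
  } else {
    x0 <- pmin(pmax(floor(fx), 1L), dg[2] - 1L); x1 <- x0 + 1L
    y0 <- pmin(pmax(floor(fy), 1L), dg[1] - 1L); y1 <- y0 + 1L
    wx <- pmin(pmax(fx - x0, 0), 1); wy <- pmin(pmax(fy - y0, 0), 1)
    for (r in seq_len(dt[1])) {
      v00 <- g$values[y0[r], x0]; v01 <- g$values[y0[r], x1]
      v10 <- g$values[y1[r], x0]; v11 <- g$values[y1[r], x1]
      top <- v00 * (1 - wx) + v01 * wx
      bot <- v10 * (1 - wx) + v11 * wx
      out[r, ] <- top * (1 - wy[r]) + bot * wy[r]
    }
    oob_x <- fx < 0.5 | fx > dg[2] + 0.5
    oob_y <- fy < 0.5 | fy > dg[1] + 0.5
    if (any(oob_x)) out[, oob_x] <- NA_real_
    if (any(oob_y)) out[oob_y, ] <- NA_real_
  }
  grid_create(out, cell_size = template$cell_size, xmin = template$xmin,
              ymax = template$ymax, crs = template$crs,
              nodata = template$nodata)
}

#' Area of a binary mask in square kilometres
#'
#' Area accounting is pixel count times cell area, valid because the package
#' requires an equal-area CRS. Nodata (`NA`) cells are ignored; any value
#' other than 0, 1 or `NA` is an error.
#'
#' @param mask a `lmdi_grid` with values in \{0, 1, NA\} or such a matrix.
#' @param cell_size_m cell edge in metres; defaults to the grid's own.
#' @return Area in km^2 (a single number).
#' @examples
#' m <- grid_create(matrix(c(1, 1, 1, 1), 2, 2), cell_size = 500)
#' area_km2(m)  # 4 pixels x 0.25 km2 = 1
#' @export
area_km2 <- function(mask, cell_size_m = NULL) {
  if (inherits(mask, "lmdi_grid")) {
    if (is.null(cell_size_m)) cell_size_m <- mask$cell_size
    mask <- mask$values
  }
  if (is.null(cell_size_m)) stop("cell_size_m required for bare matrices")
  v <- mask[!is.na(mask)]
  if (length(v) && !all(v %in% c(0, 1)))
    stop("mask is not binary: found values other than 0/1")
  sum(v == 1) * (cell_size_m / 1000)^2
}
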