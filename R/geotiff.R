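#' Minimal GeoTIFF input/output
#'
#' The package carries its rasters as uncompressed baseline TIFF with the
#' standard GeoTIFF georeferencing tags (ModelPixelScale, ModelTiepoint,
#' GeoKeyDirectory) plus the GDAL nodata tag. The reader handles little- and
#' big-endian files, strip layout, 8/16/32-bit integer and 32/64-bit float
#' samples and pixel-interleaved multi-band images, which covers everything
#' this pipeline writes and what mainstream writers emit for such data. No
#' compression codecs are implemented: this is an analysis package, not a
#' general raster library.
#'
#' @name geotiff
NULL

.tiff_type_size <- c(`1` = 1L, `2` = 1L, `3` = 2L, `4` = 4L, `5` = 8L,
                     `6` = 1L, `7` = 1L, `8` = 2L, `9` = 4L, `10` = 8L,
                     `11` = 4L, `12` = 8L, `16` = 8L, `17` = 8L)

.read_tag_values <- function(con, type, count, order) {
  n <- as.integer(count)
  if (type == 2L) {                       # ASCII
    raw <- readBin(con, "raw", n = n)
    return(rawToChar(raw[raw != as.raw(0)]))
  }
  if (type == 3L)                         # SHORT
    return(readBin(con, "integer", n = n, size = 2, signed = FALSE,
                   endian = order))
  if (type == 4L) {                       # LONG (unsigned 32)
    v <- readBin(con, "integer", n = n, size = 4, endian = order)
    v <- as.numeric(v); v[v < 0] <- v[v < 0] + 2^32
    return(v)
  }
  if (type == 12L)                        # DOUBLE
    return(readBin(con, "double", n = n, size = 8, endian = order))
  if (type %in% c(1L, 6L, 7L))            # BYTE / SBYTE / UNDEFINED
    return(readBin(con, "integer", n = n, size = 1,
                   signed = type == 6L))
  if (type == 8L)                         # SSHORT
    return(readBin(con, "integer", n = n, size = 2, signed = TRUE,
                   endian = order))
  if (type == 9L)                         # SLONG
    return(readBin(con, "integer", n = n, size = 4, endian = order))
  if (type == 11L)                        # FLOAT
    return(readBin(con, "double", n = n, size = 4, endian = order))
  if (type %in% c(5L, 10L)) {             # (S)RATIONAL pairs
    v <- readBin(con, "integer", n = 2L * n, size = 4, endian = order)
    return(v[c(TRUE, FALSE)] / v[c(FALSE, TRUE)])
  }
  NULL                                    # unknown type: ignore the tag
}

.read_ifd <- function(con, offset, order) {
  seek(con, offset)
  n_entries <- readBin(con, "integer", size = 2, signed = FALSE, endian = order)
  tags <- list()
  for (i in seq_len(n_entries)) {
    seek(con, offset + 2 + (i - 1) * 12)
    code  <- readBin(con, "integer", size = 2, signed = FALSE, endian = order)
    type  <- readBin(con, "integer", size = 2, signed = FALSE, endian = order)
    count <- readBin(con, "integer", size = 4, endian = order)
    sz <- .tiff_type_size[as.character(type)]
    if (is.na(sz)) next                   # unknown tag type: skip entry
    nbytes <- sz * count
    if (nbytes > 4) {
      voff <- readBin(con, "integer", size = 4, endian = order)
      voff <- as.numeric(voff); if (voff < 0) voff <- voff + 2^32
      seek(con, voff)
    }
    tags[[as.character(code)]] <- .read_tag_values(con, type, count, order)
  }
  seek(con, offset + 2 + n_entries * 12)
  nxt <- readBin(con, "integer", size = 4, endian = order)
  list(tags = tags, next_ifd = nxt)
}

#' Read a (Geo)TIFF raster
#'
#' @param path path to an uncompressed single- or multi-band GeoTIFF.
#' @return A [grid_create()] object; multi-band files yield a 3-D value
#'   array whose bands share one geotransform.
#' @export
read_raster <- function(path) {
  if (!file.exists(path)) stop("raster file not found: ", path)
  con <- file(path, "rb"); on.exit(close(con))
  magic <- readBin(con, "raw", n = 2)
  order <- if (identical(rawToChar(magic), "II")) "little"
           else if (identical(rawToChar(magic), "MM")) "big"
           else stop("not a TIFF file: ", path)
  if (readBin(con, "integer", size = 2, signed = FALSE, endian = order) != 42L)
    stop("not a TIFF file: ", path)
  ifd_off <- readBin(con, "integer", size = 4, endian = order)
  ifd <- .read_ifd(con, ifd_off, order)
  tg <- ifd$tags
  need <- function(code, default = NULL) {
    v <- tg[[as.character(code)]]
    if (is.null(v)) {
      if (is.null(default)) stop("TIFF missing required tag ", code)
      default
    } else v
  }
  w   <- as.integer(need(256)); h <- as.integer(need(257))
  bps <- need(258, 1); spp <- as.integer(need(277, 1))
  if (length(unique(bps)) != 1L) stop("mixed bits-per-sample unsupported")
  bps <- as.integer(bps[1])
  if (as.integer(need(259, 1)) != 1L) stop("compressed TIFF unsupported")
  if (as.integer(need(284, 1)) != 1L) stop("planar configuration 2 unsupported")
  sfmt <- as.integer(need(339, 1))[1]
  offs <- need(273); cnts <- need(279)
  rps  <- as.integer(need(278, h))
  scale <- tg[["33550"]]; tie <- tg[["33922"]]
  if (is.null(scale) || is.null(tie))
    stop("ungeoreferenced raster: ", path,
         " (no ModelPixelScale/ModelTiepoint)")
  crs <- tg[["34737"]]
  if (!is.null(crs)) crs <- sub("\\|+$", "", crs) else crs <- "unknown"
  nodata <- tg[["42113"]]
  nodata <- if (is.null(nodata)) NA_real_ else suppressWarnings(as.numeric(nodata))

  ssz <- bps %/% 8L
  vals <- numeric(0)
  for (k in seq_along(offs)) {
    seek(con, offs[k])
    n <- cnts[k] %/% ssz
    v <- if (sfmt == 3L) {
      readBin(con, "double", n = n, size = ssz, endian = order)
    } else if (sfmt == 2L) {
      readBin(con, "integer", n = n, size = ssz, endian = order)
    } else {
      if (ssz == 4L) {
        x <- as.numeric(readBin(con, "integer", n = n, size = 4, endian = order))
        x[x < 0] <- x[x < 0] + 2^32; x
      } else {
        readBin(con, "integer", n = n, size = ssz, signed = FALSE,
                endian = order)
      }
    }
    vals <- c(vals, as.numeric(v))
  }
  if (length(vals) != as.numeric(w) * h * spp)
    stop("TIFF strip data size mismatch")
  if (spp == 1L) {
    values <- matrix(vals, h, w, byrow = TRUE)
  } else {
    values <- array(NA_real_, c(h, w, spp))
    for (b in seq_len(spp))
      values[, , b] <- matrix(vals[seq(b, length(vals), by = spp)],
                              h, w, byrow = TRUE)
  }
  if (!is.na(nodata)) values[values == nodata] <- NA_real_
  xmin <- tie[4] - tie[1] * scale[1]
  ymax <- tie[5] + tie[2] * scale[2]
  if (abs(scale[1] - scale[2]) > 1e-6)
    stop("non-square cells unsupported")
  grid_create(values, cell_size = scale[1], xmin = xmin, ymax = ymax,
              crs = crs, nodata = if (is.na(nodata)) -9999 else nodata)
}

.tag_entry <- function(code, type, values) {
  list(code = as.integer(code), type = as.integer(type), values = values)
}

.serialize_values <- function(type, values) {
  con <- rawConnection(raw(0), "wb")
  on.exit(close(con))
  if (type == 2L) {
    writeBin(c(charToRaw(values), as.raw(0)), con)
  } else if (type == 3L) {
    v <- as.integer(values); v[v > 32767] <- v[v > 32767] - 65536L
    writeBin(v, con, size = 2, endian = "little")
  } else if (type == 4L) {
    writeBin(as.integer(values), con, size = 4, endian = "little")
  } else if (type == 12L) {
    writeBin(as.numeric(values), con, size = 8, endian = "little")
  } else stop("unsupported tag type for writing")
  rawConnectionValue(con)
}

#' Write a grid as GeoTIFF
#'
#' @param g a [grid_create()] object (single- or multi-band).
#' @param path output path.
#' @param datatype one of `"FLT8S"`, `"FLT4S"`, `"INT4S"`, `"INT2S"`,
#'   `"INT1U"`: on-disk sample format. Integer types round values; `NA`
#'   cells are written as the grid's nodata sentinel.
#' @param georeference write the GeoTIFF tags (default). `FALSE` produces a
#'   plain ungeoreferenced TIFF (used to exercise the reader's error path).
#' @return `path`, invisibly.
#' @export
write_raster <- function(g, path,
                         datatype = c("FLT8S", "FLT4S", "INT4S", "INT2S",
                                      "INT1U"),
                         georeference = TRUE) {
  stopifnot(inherits(g, "lmdi_grid"))
  datatype <- match.arg(datatype)
  d <- dim(g$values); h <- d[1]; w <- d[2]
  spp <- if (length(d) == 3L) d[3] else 1L
  spec <- switch(datatype,
    FLT8S = list(bits = 64L, fmt = 3L),
    FLT4S = list(bits = 32L, fmt = 3L),
    INT4S = list(bits = 32L, fmt = 2L),
    INT2S = list(bits = 16L, fmt = 2L),
    INT1U = list(bits = 8L,  fmt = 1L))
  ssz <- spec$bits %/% 8L

  vals <- g$values
  vals[is.na(vals)] <- g$nodata
  # pixel-interleaved row-major scanlines
  flat <- if (spp == 1L) as.vector(t(vals))
          else as.vector(aperm(vals, c(3L, 2L, 1L)))

  data_con <- rawConnection(raw(0), "wb")
  if (spec$fmt == 3L) {
    writeBin(as.numeric(flat), data_con, size = ssz, endian = "little")
  } else {
    iv <- as.integer(round(flat))
    if (datatype == "INT1U") {
      writeBin(iv, data_con, size = 1, endian = "little")
    } else {
      writeBin(iv, data_con, size = ssz, endian = "little")
    }
  }
  img <- rawConnectionValue(data_con); close(data_con)
  if (length(img) %% 2L) img <- c(img, as.raw(0))  # word-align the IFD

  tags <- list(
    .tag_entry(256, 4, w), .tag_entry(257, 4, h),
    .tag_entry(258, 3, rep(spec$bits, spp)),
    .tag_entry(259, 3, 1), .tag_entry(262, 3, 1),
    .tag_entry(273, 4, 8), .tag_entry(277, 3, spp),
    .tag_entry(278, 4, h), .tag_entry(279, 4, length(img)),
    .tag_entry(284, 3, 1),
    .tag_entry(339, 3, rep(spec$fmt, spp)))
  if (georeference) {
    crs_ascii <- paste0(g$crs, "|")
    geokeys <- c(1, 1, 0, 3,
                 1024, 0, 1, 1,                    # projected model
                 1025, 0, 1, 1,                    # pixel-is-area raster
                 1026, 34737, nchar(crs_ascii) + 1, 0)
    tags <- c(tags, list(
      .tag_entry(33550, 12, c(g$cell_size, g$cell_size, 0)),
      .tag_entry(33922, 12, c(0, 0, 0, g$xmin, g$ymax, 0)),
      .tag_entry(34735, 3, geokeys),
      .tag_entry(34737, 2, crs_ascii),
      .tag_entry(42113, 2, format(g$nodata, scientific = FALSE))))
  }
  tags <- tags[order(vapply(tags, function(t) t$code, integer(1)))]

  ifd_off <- 8L + length(img)
  n <- length(tags)
  overflow_off <- ifd_off + 2L + n * 12L + 4L
  entries <- raw(0); overflow <- raw(0)
  for (tg in tags) {
    ser <- .serialize_values(tg$type, tg$values)
    count <- if (tg$type == 2L) length(ser)
             else length(tg$values)
    e <- rawConnection(raw(0), "wb")
    writeBin(as.integer(tg$code), e, size = 2, endian = "little")
    writeBin(as.integer(tg$type), e, size = 2, endian = "little")
    writeBin(as.integer(count), e, size = 4, endian = "little")
    if (length(ser) <= 4L) {
      pad <- c(ser, raw(4L - length(ser)))
      writeBin(pad, e)
    } else {
      if (length(ser) %% 2L) ser <- c(ser, as.raw(0))
      writeBin(as.integer(overflow_off + length(overflow)), e, size = 4,
               endian = "little")
      overflow <- c(overflow, ser)
    }
    entries <- c(entries, rawConnectionValue(e)); close(e)
  }

  out <- file(path, "wb"); on.exit(close(out))
  writeBin(charToRaw("II"), out)
  writeBin(42L, out, size = 2, endian = "little")
  writeBin(as.integer(ifd_off), out, size = 4, endian = "little")
  writeBin(img, out)
  writeBin(as.integer(n), out, size = 2, endian = "little")
  writeBin(entries, out)
  writeBin(0L, out, size = 4, endian = "little")   # no further IFDs
  writeBin(overflow, out)
  invisible(path)
}
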