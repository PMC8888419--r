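# Minimal GeoTIFF codec: uncompressed, single-band, strip-organized TIFF
# with the GeoTIFF georeferencing tags (ModelPixelScale, ModelTiepoint),
# the GDAL nodata tag, and a citation geokey carrying the CRS tag string.
# Scope is deliberately narrow -- exactly what the pipeline's own writer
# emits plus the common single-band variants (uint8/16/32, int16/32,
# float32/64, either byte order, one or many strips). Anything outside
# that raises a named error rather than guessing.

TIFF_TYPE_SIZE <- c(`1` = 1L, `2` = 1L, `3` = 2L, `4` = 4L, `5` = 8L,
                    `6` = 1L, `8` = 2L, `9` = 4L, `10` = 8L, `11` = 4L,
                    `12` = 8L)

read_geotiff <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 8L)
    stop(sprintf("read_raster: unreadable file: %s", path), call. = FALSE)
  endian <- if (identical(raw[1:2], as.raw(c(0x49, 0x49)))) "little"
            else if (identical(raw[1:2], as.raw(c(0x4d, 0x4d)))) "big"
            else stop(sprintf("read_raster: unreadable file: %s", path),
                      call. = FALSE)
  rd_int <- function(off, size, n = 1L, signed = FALSE) {
    readBin(raw[(off + 1L):(off + size * n)], "integer", n = n, size = size,
            signed = signed || size == 4L, endian = endian)
  }
  magic <- rd_int(2L, 2L)
  if (magic != 42L)
    stop(sprintf("read_raster: unreadable file (not a baseline TIFF): %s",
                 path), call. = FALSE)
  ifd_off <- rd_int(4L, 4L)
  n_entries <- rd_int(ifd_off, 2L)
  tags <- list()
  for (k in seq_len(n_entries)) {
    e <- ifd_off + 2L + (k - 1L) * 12L
    tag <- rd_int(e, 2L)
    type <- rd_int(e + 2L, 2L)
    count <- rd_int(e + 4L, 4L)
    tsz <- TIFF_TYPE_SIZE[as.character(type)]
    if (is.na(tsz)) next
    nbytes <- tsz * count
    voff <- if (nbytes <= 4L) e + 8L else rd_int(e + 8L, 4L)
    val <- switch(as.character(type),
      `1` = rd_int(voff, 1L, count),
      `2` = {
        rb <- raw[(voff + 1L):(voff + count)]
        rawToChar(rb[rb != as.raw(0L)])  # strip NUL terminators
      },
      `3` = rd_int(voff, 2L, count),
      `4` = rd_int(voff, 4L, count),
      `8` = rd_int(voff, 2L, count, signed = TRUE),
      `9` = rd_int(voff, 4L, count, signed = TRUE),
      `11` = readBin(raw[(voff + 1L):(voff + 4L * count)], "double",
                     n = count, size = 4L, endian = endian),
      `12` = readBin(raw[(voff + 1L):(voff + 8L * count)], "double",
                     n = count, size = 8L, endian = endian),
      NULL)
    if (!is.null(val)) tags[[as.character(tag)]] <- val
  }
  need <- function(id, default = NULL) {
    v <- tags[[as.character(id)]]
    if (is.null(v)) {
      if (is.null(default))
        stop(sprintf("read_raster: missing TIFF tag %d in %s", id, path),
             call. = FALSE)
      default
    } else v
  }
  width <- need(256L); height <- need(257L)
  bits <- need(258L, 1L)
  compression <- need(259L, 1L)
  spp <- need(277L, 1L)
  sample_format <- need(339L, 1L)[1]
  if (spp != 1L || length(bits) > 1L)
    stop(sprintf("read_raster: multi-band raster not supported: %s", path),
         call. = FALSE)
  if (compression != 1L)
    stop(sprintf("read_raster: compressed TIFF not supported: %s", path),
         call. = FALSE)
  pixel_scale <- need(33550L)
  if (abs(pixel_scale[1] - pixel_scale[2]) >
      1e-9 * max(abs(pixel_scale[1:2])))
    stop("read_raster: non-square cells", call. = FALSE)
  tiepoint <- need(33922L)
  # tiepoint maps raster point (i, j) -> model (x, y); writer anchors (0, 0)
  x_origin <- tiepoint[4] - tiepoint[1] * pixel_scale[1]
  y_origin <- tiepoint[5] + tiepoint[2] * pixel_scale[2]
  strip_offsets <- need(273L)
  strip_counts <- need(279L)
  rows_per_strip <- need(278L, height)
  bpp <- bits / 8L
  buf <- raw(width * height * bpp)
  pos <- 0L
  for (s in seq_along(strip_offsets)) {
    n <- strip_counts[s]
    buf[(pos + 1L):(pos + n)] <-
      raw[(strip_offsets[s] + 1L):(strip_offsets[s] + n)]
    pos <- pos + n
  }
  vals <- if (sample_format == 3L) {
    if (!bits %in% c(32L, 64L))
      stop(sprintf("read_raster: unsupported float depth %d in %s", bits,
                   path), call. = FALSE)
    readBin(buf, "double", n = width * height, size = bpp, endian = endian)
  } else if (sample_format %in% c(1L, 2L)) {
    if (!bits %in% c(8L, 16L, 32L))
      stop(sprintf("read_raster: unsupported integer depth %d in %s", bits,
                   path), call. = FALSE)
    readBin(buf, "integer", n = width * height, size = bpp,
            signed = sample_format == 2L || bits == 32L, endian = endian)
  } else
    stop(sprintf("read_raster: unsupported sample format %d in %s",
                 sample_format, path), call. = FALSE)
  m <- matrix(as.numeric(vals), nrow = height, ncol = width, byrow = TRUE)
  nodata <- -9999
  nd_tag <- tags[["42113"]]
  if (!is.null(nd_tag)) {
    nd <- suppressWarnings(as.numeric(nd_tag))
    if (is.finite(nd)) nodata <- nd
  }
  m[m == nodata] <- NA_real_
  crs <- ""
  cit <- tags[["34737"]]
  if (!is.null(cit)) crs <- gsub("\\|+$", "", cit)
  if (crs == "unspecified") crs <- ""
  spec <- grid_spec(height, width, x_origin, y_origin, pixel_scale[1],
                    crs = crs)
  grid_new(spec, m, nodata = nodata)
}

write_geotiff <- function(grid, path) {
  sp <- grid$spec
  v <- t(grid$values)  # column-major transpose -> row-major pixel order
  v[is.na(v)] <- grid$nodata
  pixel_bytes <- writeBin(as.numeric(v), raw(), size = 8L,
                          endian = "little")
  # ASCII tag payloads carried as raw vectors so NUL terminators survive
  nodata_raw <- c(charToRaw(sprintf("%.10g", grid$nodata)), as.raw(0L))
  crs_raw <- c(charToRaw(paste0(if (nzchar(sp$crs)) sp$crs else "unspecified",
                                "|")), as.raw(0L))
  # GeoKeyDirectory: version 1.1.0; ModelType=1 (projected),
  # RasterType=1 (pixel-is-area), citation in GeoAsciiParams
  geokeys <- as.integer(c(1, 1, 0, 3,
                          1024, 0, 1, 1,
                          1025, 0, 1, 1,
                          1026, 34737, length(crs_raw), 0))
  entries <- list(  # tag, type, values (already encoded semantics)
    list(256L, 3L, sp$n_cols),
    list(257L, 3L, sp$n_rows),
    list(258L, 3L, 64L),
    list(259L, 3L, 1L),
    list(262L, 3L, 1L),
    list(273L, 4L, NA),   # strip offset patched below
    list(277L, 3L, 1L),
    list(278L, 3L, sp$n_rows),
    list(279L, 4L, length(pixel_bytes)),
    list(284L, 3L, 1L),
    list(339L, 3L, 3L),
    list(33550L, 12L, c(sp$cell_size, sp$cell_size, 0)),
    list(33922L, 12L, c(0, 0, 0, sp$x_origin, sp$y_origin, 0)),
    list(34735L, 3L, geokeys),
    list(34737L, 2L, crs_raw),
    list(42113L, 2L, nodata_raw))
  n_ent <- length(entries)
  ifd_off <- 8L
  ifd_size <- 2L + 12L * n_ent + 4L
  ext_off <- ifd_off + ifd_size   # overflow area for values > 4 bytes
  enc_value <- function(type, value) {
    switch(as.character(type),
      `2` = value,  # already raw
      `3` = writeBin(as.integer(value), raw(), size = 2L, endian = "little"),
      `4` = writeBin(as.integer(value), raw(), size = 4L, endian = "little"),
      `12` = writeBin(as.numeric(value), raw(), size = 8L,
                      endian = "little"))
  }
  ext <- raw(0)
  entry_raw <- raw(0)
  for (en in entries) {
    tag <- en[[1]]; type <- en[[2]]; value <- en[[3]]
    count <- length(value)
    if (tag == 273L) { value <- 0L }  # placeholder, patched after layout
    vb <- enc_value(type, value)
    hdr <- c(writeBin(as.integer(tag), raw(), size = 2L, endian = "little"),
             writeBin(as.integer(type), raw(), size = 2L, endian = "little"),
             writeBin(as.integer(count), raw(), size = 4L,
                      endian = "little"))
    if (length(vb) <= 4L) {
      field <- c(vb, raw(4L - length(vb)))
    } else {
      field <- writeBin(as.integer(ext_off + length(ext)), raw(), size = 4L,
                        endian = "little")
      ext <- c(ext, vb)
    }
    entry_raw <- c(entry_raw, hdr, field)
  }
  data_off <- ext_off + length(ext)
  # patch strip offset (entry for tag 273): locate its field in entry_raw
  idx <- which(vapply(entries, function(e) e[[1]], 0L) == 273L)
  patch_at <- (idx - 1L) * 12L + 8L
  entry_raw[(patch_at + 1L):(patch_at + 4L)] <-
    writeBin(as.integer(data_off), raw(), size = 4L, endian = "little")
  out <- c(as.raw(c(0x49, 0x49)),
           writeBin(42L, raw(), size = 2L, endian = "little"),
           writeBin(8L, raw(), size = 4L, endian = "little"),
           writeBin(n_ent, raw(), size = 2L, endian = "little"),
           entry_raw,
           writeBin(0L, raw(), size = 4L, endian = "little"),
           ext,
           pixel_bytes)
  writeBin(out, path)
  invisible(path)
}
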