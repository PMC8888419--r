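#' Read a raster file into a grid
#'
#' Dispatches on content: TIFF magic bytes select the GeoTIFF reader,
#' anything else is parsed as an ESRI ASCII grid
#' (`NCOLS/NROWS/XLLCORNER/YLLCORNER/CELLSIZE/NODATA_value` header).
#' Only single-band rasters with square cells are supported; cells equal to
#' the file's nodata sentinel come back as `NA`.
#'
#' @param path path to a single-band GeoTIFF or ESRI ASCII grid.
#' @return a [grid_new()] object.
#' @export
read_raster <- function(path) {
  if (!file.exists(path))
    stop(sprintf("read_raster: file not found: %s", path), call. = FALSE)
  magic <- readBin(path, "raw", n = 4L)
  is_tiff <- length(magic) == 4L &&
    (identical(magic[1:2], as.raw(c(0x49, 0x49))) ||
     identical(magic[1:2], as.raw(c(0x4d, 0x4d))))
  if (is_tiff) read_geotiff(path) else read_ascii_grid(path)
}

#' Write a grid to a raster file
#'
#' @param grid a [grid_new()] object.
#' @param path output path.
#' @param format `"ascii"` (ESRI ASCII grid) or `"geotiff"` (uncompressed
#'   single-band float64 GeoTIFF).
#' @return `path`, invisibly.
#' @export
write_raster <- function(grid, path, format = c("ascii", "geotiff")) {
  stopifnot(inherits(grid, "phyl_grid"))
  format <- match.arg(format)
  dir <- dirname(path)
  if (!dir.exists(dir) || file.access(dir, 2L) != 0L)
    stop(sprintf("write_raster: path not writable: %s", path), call. = FALSE)
  if (format == "ascii") write_ascii_grid(grid, path) else
    write_geotiff(grid, path)
  invisible(path)
}

read_ascii_grid <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 2L)
    stop(sprintf("read_raster: unreadable ASCII grid: %s", path), call. = FALSE)
  hdr <- list(); i <- 1L
  repeat {
    tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    key <- toupper(tok[1])
    if (length(tok) == 2L && key %in%
        c("NCOLS", "NROWS", "XLLCORNER", "YLLCORNER", "XLLCENTER",
          "YLLCENTER", "CELLSIZE", "DX", "DY", "NODATA_VALUE")) {
      hdr[[key]] <- as.numeric(tok[2]); i <- i + 1L
    } else break
  }
  if (!is.null(hdr$DX) || !is.null(hdr$DY)) {
    if (is.null(hdr$DX) || is.null(hdr$DY) || hdr$DX != hdr$DY)
      stop("read_raster: non-square cells", call. = FALSE)
    hdr$CELLSIZE <- hdr$DX
  }
  need <- c("NCOLS", "NROWS", "CELLSIZE")
  if (!all(need %in% names(hdr)))
    stop(sprintf("read_raster: unreadable ASCII grid header in %s", path),
         call. = FALSE)
  nc <- as.integer(hdr$NCOLS); nr <- as.integer(hdr$NROWS)
  cs <- hdr$CELLSIZE
  if (!is.null(hdr$XLLCORNER)) x0 <- hdr$XLLCORNER
  else if (!is.null(hdr$XLLCENTER)) x0 <- hdr$XLLCENTER - cs / 2
  else stop("read_raster: missing x origin in ASCII header", call. = FALSE)
  if (!is.null(hdr$YLLCORNER)) yll <- hdr$YLLCORNER
  else if (!is.null(hdr$YLLCENTER)) yll <- hdr$YLLCENTER - cs / 2
  else stop("read_raster: missing y origin in ASCII header", call. = FALSE)
  nodata <- if (is.null(hdr$NODATA_VALUE)) -9999 else hdr$NODATA_VALUE
  prj <- prj_sidecar_path(path)
  crs <- if (file.exists(prj)) trimws(readLines(prj, n = 1L, warn = FALSE))
    else ""
  body <- paste(lines[seq.int(i, length(lines))], collapse = " ")
  vals <- suppressWarnings(as.numeric(strsplit(trimws(body), "\\s+")[[1]]))
  if (length(vals) != nr * nc)
    stop(sprintf("read_raster: expected %d values, found %d in %s",
                 nr * nc, length(vals), path), call. = FALSE)
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == nodata] <- NA_real_
  spec <- grid_spec(nr, nc, x0, yll + nr * cs, cs, crs = crs)
  grid_new(spec, m, nodata = nodata)
}

# ESRI ASCII grids cannot carry a CRS in-band; the conventional companion
# is a .prj file next to the raster (here holding the opaque CRS tag)
prj_sidecar_path <- function(path) {
  if (grepl("\\.[^./]+$", path)) sub("\\.[^./]+$", ".prj", path)
  else paste0(path, ".prj")
}

write_ascii_grid <- function(grid, path) {
  sp <- grid$spec
  v <- grid$values
  v[is.na(v)] <- grid$nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("NCOLS %d", sp$n_cols),
    sprintf("NROWS %d", sp$n_rows),
    sprintf("XLLCORNER %.10g", sp$x_origin),
    sprintf("YLLCORNER %.10g", sp$y_origin - sp$n_rows * sp$cell_size),
    sprintf("CELLSIZE %.10g", sp$cell_size),
    sprintf("NODATA_value %.10g", grid$nodata)), con)
  writeLines(apply(v, 1L, function(r) paste(format(r, digits = 10,
                                                   trim = TRUE,
                                                   scientific = FALSE),
                                            collapse = " ")), con)
  if (nzchar(sp$crs)) writeLines(sp$crs, prj_sidecar_path(path))
  invisible(path)
}
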