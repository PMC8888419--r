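#' Georeferenced grid specification
#'
#' A `grid_spec` describes the geometry of a north-up raster with square
#' cells in a projected coordinate reference system with meter units: the
#' number of rows and columns, the north-west corner of the grid, the cell
#' size, and an opaque CRS tag. Row indices increase southward, column
#' indices eastward. The pipeline never reprojects: all grids, polygons and
#' points entering one analysis must share the same CRS, which is checked by
#' tag equality only.
#'
#' @param n_rows,n_cols positive integers, the raster dimensions.
#' @param x_origin x coordinate (m) of the west edge.
#' @param y_origin y coordinate (m) of the north edge.
#' @param cell_size cell edge length in meters (> 0); cells are square.
#' @param crs opaque CRS identifier string (e.g. "EPSG:32610"); compared
#'   verbatim, never interpreted.
#' @return an object of class `grid_spec`.
#' @export
grid_spec <- function(n_rows, n_cols, x_origin, y_origin, cell_size,
                      crs = "") {
  n_rows <- as.integer(n_rows)
  n_cols <- as.integer(n_cols)
  if (is.na(n_rows) || n_rows < 1L || is.na(n_cols) || n_cols < 1L)
    stop("grid_spec: n_rows and n_cols must be positive integers")
  if (!is.finite(cell_size) || cell_size <= 0)
    stop("grid_spec: cell_size must be a positive number")
  if (!is.finite(x_origin) || !is.finite(y_origin))
    stop("grid_spec: origin coordinates must be finite")
  structure(
    list(n_rows = n_rows, n_cols = n_cols,
         x_origin = as.numeric(x_origin), y_origin = as.numeric(y_origin),
         cell_size = as.numeric(cell_size), crs = as.character(crs)),
    class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid_spec: %d x %d cells of %g m, NW corner (%g, %g)%s\n",
              x$n_rows, x$n_cols, x$cell_size, x$x_origin, x$y_origin,
              if (nzchar(x$crs)) paste0(", CRS ", x$crs) else ""))
  invisible(x)
}

#' Test whether two grid specs are compatible
#'
#' Two specs are compatible iff all fields agree: dimensions and CRS tag
#' exactly, coordinates and cell size to within a relative tolerance of
#' 1e-9 (guards against round-trip representation noise in file headers).
#'
#' @param a,b `grid_spec` objects.
#' @return logical scalar.
#' @export
specs_equal <- function(a, b) {
  stopifnot(inherits(a, "grid_spec"), inherits(b, "grid_spec"))
  num_eq <- function(u, v) isTRUE(all.equal(u, v, tolerance = 1e-9))
  a$n_rows == b$n_rows && a$n_cols == b$n_cols && a$crs == b$crs &&
    num_eq(a$x_origin, b$x_origin) && num_eq(a$y_origin, b$y_origin) &&
    num_eq(a$cell_size, b$cell_size)
}

#' Construct a raster grid
#'
#' The universal carrier between pipeline stages: a value matrix bound to a
#' [grid_spec()]. Cells with no valid measurement are held as `NA`
#' internally; the `nodata` sentinel is only materialized on file output and
#' translated back to `NA` on input, so a sentinel can never collide with a
#' legitimate data value in memory.
#'
#' @param spec a [grid_spec()].
#' @param values numeric matrix of dimension `n_rows x n_cols` (row 1 is the
#'   northernmost row), or a scalar which is recycled. `NA` marks nodata.
#' @param nodata sentinel written to files for `NA` cells (default -9999).
#' @return an object of class `phyl_grid` with fields `spec`, `values`,
#'   `nodata`.
#' @export
grid_new <- function(spec, values, nodata = -9999) {
  stopifnot(inherits(spec, "grid_spec"))
  if (length(values) == 1L)
    values <- matrix(as.numeric(values), spec$n_rows, spec$n_cols)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) != spec$n_rows || ncol(values) != spec$n_cols)
    stop("grid_new: values matrix shape does not match spec")
  if (!is.finite(nodata)) stop("grid_new: nodata sentinel must be finite")
  if (any(values == nodata, na.rm = TRUE))
    stop("grid_new: nodata sentinel occurs as a data value; pass it as NA")
  structure(list(spec = spec, values = values, nodata = as.numeric(nodata)),
            class = "phyl_grid")
}

#' @export
print.phyl_grid <- function(x, ...) {
  v <- x$values
  nd <- sum(is.na(v))
  cat(sprintf("phyl_grid: %d x %d @ %g m; %d nodata cell%s (%.1f%%)\n",
              x$spec$n_rows, x$spec$n_cols, x$spec$cell_size, nd,
              if (nd == 1L) "" else "s", 100 * nd / length(v)))
  if (nd < length(v))
    cat(sprintf("  values: min %.4g, mean %.4g, max %.4g\n",
                min(v, na.rm = TRUE), mean(v, na.rm = TRUE),
                max(v, na.rm = TRUE)))
  print(x$spec)
  invisible(x)
}

#' @export
summary.phyl_grid <- function(object, ...) {
  v <- as.vector(object$values)
  c(n_cells = length(v), n_nodata = sum(is.na(v)),
    summary(v[!is.na(v)]))
}

# x coordinates of cell centers for each column (length n_cols)
cell_center_x <- function(spec) {
  spec$x_origin + (seq_len(spec$n_cols) - 0.5) * spec$cell_size
}

# y coordinates of cell centers for each row (length n_rows), northmost first
cell_center_y <- function(spec) {
  spec$y_origin - (seq_len(spec$n_rows) - 0.5) * spec$cell_size
}

# extent as (xmin, xmax, ymin, ymax)
grid_extent <- function(spec) {
  c(xmin = spec$x_origin,
    xmax = spec$x_origin + spec$n_cols * spec$cell_size,
    ymin = spec$y_origin - spec$n_rows * spec$cell_size,
    ymax = spec$y_origin)
}

#' Sample a grid at a point
#'
#' Returns the value of the cell whose center is nearest to the query
#' point; no interpolation is performed, because downstream users sample
#' categorical risk rasters. A point equidistant between centers resolves
#' to the smaller row index, then the smaller column index, so lookups are
#' deterministic.
#'
#' @param grid a [grid_new()] object.
#' @param x,y projected point coordinates (m) in the grid's CRS.
#' @return the cell value, or `NA` if the nearest cell is nodata.
#' @export
sample_at_point <- function(grid, x, y) {
  stopifnot(inherits(grid, "phyl_grid"))
  sp <- grid$spec
  ext <- grid_extent(sp)
  if (!is.finite(x) || !is.finite(y))
    stop("sample_at_point: point coordinates must be finite")
  if (x < ext["xmin"] || x > ext["xmax"] || y < ext["ymin"] || y > ext["ymax"])
    stop(sprintf(
      "sample_at_point: point (%g, %g) outside grid extent [%g, %g] x [%g, %g]",
      x, y, ext["xmin"], ext["xmax"], ext["ymin"], ext["ymax"]),
      call. = FALSE)
  # fractional row/col measured from the NW corner; a point on the boundary
  # between cells has an integer fraction, and floor() + the clamp below
  # gives the smaller row/column index, the documented tie rule
  fc <- (x - sp$x_origin) / sp$cell_size
  fr <- (sp$y_origin - y) / sp$cell_size
  col <- min(max(1L, as.integer(floor(fc)) + (fc %% 1 != 0)), sp$n_cols)
  row <- min(max(1L, as.integer(floor(fr)) + (fr %% 1 != 0)), sp$n_rows)
  grid$values[row, col]
}

#' Resample a grid to a new cell size
#'
#' The output covers the same extent as the input, with
#' `round(extent / target_cell_size)` rows and columns (at least one).
#' `nearest` assigns each output cell the value of the input cell containing
#' its center; `bilinear` interpolates between the four surrounding input
#' cell centers (clamped at the outermost centers, so output values never
#' leave the input's range). Bilinear treats nodata conservatively: if any
#' of the four contributing neighbors is nodata, the output cell is nodata —
#' interpolation must not fabricate soil values at survey-gap edges; filling
#' such gaps is the job of a dedicated gap-fill step.
#'
#' @param grid a [grid_new()] object.
#' @param target_cell_size new cell edge length in meters (> 0).
#' @param method `"nearest"` or `"bilinear"`.
#' @return a resampled `phyl_grid`.
#' @export
resample <- function(grid, target_cell_size, method = c("nearest", "bilinear")) {
  stopifnot(inherits(grid, "phyl_grid"))
  method <- match.arg(method)
  if (!is.finite(target_cell_size) || target_cell_size <= 0)
    stop("resample: target_cell_size must be positive")
  sp <- grid$spec
  nr <- max(1L, as.integer(round(sp$n_rows * sp$cell_size / target_cell_size)))
  nc <- max(1L, as.integer(round(sp$n_cols * sp$cell_size / target_cell_size)))
  out_spec <- grid_spec(nr, nc, sp$x_origin, sp$y_origin, target_cell_size,
                        crs = sp$crs)
  xs <- cell_center_x(out_spec)
  ys <- cell_center_y(out_spec)
  v <- grid$values
  if (method == "nearest") {
    ci <- pmin(pmax(1L, floor((xs - sp$x_origin) / sp$cell_size) + 1L), sp$n_cols)
    ri <- pmin(pmax(1L, floor((sp$y_origin - ys) / sp$cell_size) + 1L), sp$n_rows)
    out <- v[ri, ci, drop = FALSE]
  } else {
    # positions in input cell-center coordinates
    gx <- (xs - sp$x_origin) / sp$cell_size - 0.5  # 0 at first center
    gy <- (sp$y_origin - ys) / sp$cell_size - 0.5
    gx <- pmin(pmax(gx, 0), sp$n_cols - 1L)
    gy <- pmin(pmax(gy, 0), sp$n_rows - 1L)
    c0 <- pmin(floor(gx) + 1L, sp$n_cols); c1 <- pmin(c0 + 1L, sp$n_cols)
    r0 <- pmin(floor(gy) + 1L, sp$n_rows); r1 <- pmin(r0 + 1L, sp$n_rows)
    tx <- gx - (c0 - 1L)  # in [0, 1]
    ty <- gy - (r0 - 1L)
    out <- matrix(NA_real_, nr, nc)
    for (i in seq_len(nr)) {
      a <- v[r0[i], c0]; b <- v[r0[i], c1]
      d <- v[r1[i], c0]; e <- v[r1[i], c1]
      top <- a * (1 - tx) + b * tx
      bot <- d * (1 - tx) + e * tx
      out[i, ] <- top * (1 - ty[i]) + bot * ty[i]
    }
  }
  grid_new(out_spec, out, nodata = grid$nodata)
}
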