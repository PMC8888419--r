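#' Read a polygon from a GeoJSON file
#'
#' Accepts a GeoJSON `Polygon` or `MultiPolygon` geometry, a `Feature`
#' wrapping one, or a `FeatureCollection` whose first feature wraps one.
#' Coordinates are taken verbatim (the pipeline is single-CRS; GeoJSON
#' files here carry projected coordinates, not longitude/latitude).
#'
#' @param path path to a GeoJSON file.
#' @return a polygon object: a list of rings, each a two-column matrix of
#'   vertices; exterior rings and holes are treated alike under the
#'   even-odd rule, so no winding-order bookkeeping is needed.
#' @export
read_polygon <- function(path) {
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  geom <- switch(gj$type %||% "",
    FeatureCollection = gj$features[[1]]$geometry,
    Feature = gj$geometry,
    Polygon = gj, MultiPolygon = gj,
    stop(sprintf("read_polygon: unsupported GeoJSON type in %s", path),
         call. = FALSE))
  rings <- switch(geom$type,
    Polygon = geom$coordinates,
    MultiPolygon = do.call(c, geom$coordinates),
    stop(sprintf("read_polygon: geometry must be Polygon or MultiPolygon, got %s",
                 geom$type), call. = FALSE))
  poly <- lapply(rings, function(r) {
    m <- do.call(rbind, lapply(r, function(p) c(p[[1]], p[[2]])))
    storage.mode(m) <- "double"
    m
  })
  validate_polygon(poly)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build a polygon from coordinate rings
#'
#' @param rings a list of two-column vertex matrices (closed or open; a
#'   closing vertex equal to the first is tolerated and dropped), or a
#'   single matrix for a one-ring polygon.
#' @return a validated polygon (list of rings).
#' @export
polygon_rings <- function(rings) {
  if (is.matrix(rings)) rings <- list(rings)
  validate_polygon(lapply(rings, function(m) {
    m <- as.matrix(m); storage.mode(m) <- "double"; m
  }))
}

validate_polygon <- function(poly) {
  if (length(poly) == 0L) stop("polygon: no rings", call. = FALSE)
  poly <- lapply(poly, function(m) {
    if (ncol(m) < 2L) stop("polygon: ring needs x and y columns",
                           call. = FALSE)
    m <- m[, 1:2, drop = FALSE]
    n <- nrow(m)
    if (n >= 2L && all(m[1, ] == m[n, ])) m <- m[-n, , drop = FALSE]
    if (nrow(m) < 3L)
      stop("polygon: degenerate ring with fewer than 3 distinct vertices",
           call. = FALSE)
    if (!all(is.finite(m))) stop("polygon: non-finite vertex", call. = FALSE)
    m
  })
  structure(poly, class = "phyl_polygon")
}

# Even-odd point-in-polygon over all rings. px, py are vectors; returns a
# logical vector. Half-open ray casting: boundary points resolve
# deterministically (cell centers of real grids essentially never sit
# exactly on polygon edges).
points_in_polygon <- function(poly, px, py) {
  inside <- logical(length(px))
  for (ring in poly) {
    xs <- ring[, 1]; ys <- ring[, 2]
    n <- length(xs)
    j <- c(n, seq_len(n - 1L))
    for (k in seq_len(n)) {
      x1 <- xs[j[k]]; y1 <- ys[j[k]]; x2 <- xs[k]; y2 <- ys[k]
      crosses <- ((y1 > py) != (y2 > py)) &
        (px < (x2 - x1) * (py - y1) / (y2 - y1) + x1)
      inside <- xor(inside, crosses)
    }
  }
  inside
}

#' Clip a grid to a polygon
#'
#' Cells whose centers fall outside the polygon are set to nodata; cell
#' values inside are untouched and the grid geometry is unchanged (this is
#' a mask, not a crop).
#'
#' @param grid a [grid_new()] object.
#' @param polygon a polygon from [read_polygon()] or [polygon_rings()].
#' @return the masked `phyl_grid`.
#' @export
clip_to_polygon <- function(grid, polygon) {
  stopifnot(inherits(grid, "phyl_grid"))
  if (!inherits(polygon, "phyl_polygon")) polygon <- polygon_rings(polygon)
  sp <- grid$spec
  xs <- cell_center_x(sp)
  ys <- cell_center_y(sp)
  px <- rep(xs, each = sp$n_rows)        # column-major order
  py <- rep(ys, times = sp$n_cols)
  keep <- points_in_polygon(polygon, px, py)
  v <- grid$values
  v[!keep] <- NA_real_
  grid_new(sp, matrix(v, sp$n_rows, sp$n_cols), nodata = grid$nodata)
}
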