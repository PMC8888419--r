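#' Annotate a grid with its soil depth interval
#'
#' Soil-survey sand rasters come as one layer per depth interval (the
#' standard set is 0-5, 5-20, 20-50 and 50-100 cm). A `depth_layer` binds a
#' percent-sand grid (g sand per 100 g soil) to its interval so the profile
#' aggregate can weight it by thickness.
#'
#' @param grid a [grid_new()] object with values in `[0, 100]` (percent
#'   sand by weight); `NA` where unsurveyed or bedrock.
#' @param top_cm,bottom_cm interval bounds in cm, `0 <= top < bottom`.
#' @return an object of class `depth_layer`.
#' @export
depth_layer <- function(grid, top_cm, bottom_cm) {
  stopifnot(inherits(grid, "phyl_grid"))
  if (!is.finite(top_cm) || !is.finite(bottom_cm) || top_cm < 0 ||
      top_cm >= bottom_cm)
    stop("depth_layer: need 0 <= top_cm < bottom_cm")
  rng <- suppressWarnings(range(grid$values, na.rm = TRUE))  # all-NA ok
  if (all(is.finite(rng)) && (rng[1] < 0 || rng[2] > 100))
    stop("depth_layer: percent-sand values must lie in [0, 100]")
  structure(list(grid = grid, top_cm = as.numeric(top_cm),
                 bottom_cm = as.numeric(bottom_cm)),
            class = "depth_layer")
}

#' Depth-weighted average of layered sand rasters
#'
#' Aggregates per-depth sand layers into a single profile raster using the
#' interval thicknesses as weights (5, 15, 30 and 50 cm for the standard
#' 0-100 cm set). At each pixel only the layers with data participate and
#' the weights renormalize over them, so a pixel surveyed only near the
#' surface still gets a (shallow-profile) estimate; a pixel with no data in
#' any layer is nodata. This mirrors how profile aggregates handle bedrock
#' and partial surveys: absent depths carry no weight rather than dragging
#' the average toward an imputed value.
#'
#' @param layers list of [depth_layer()] objects on one common grid
#'   geometry, with non-overlapping depth intervals.
#' @return a `phyl_grid` of 0-100 style profile percent sand.
#' @export
depth_weighted_average <- function(layers) {
  if (length(layers) < 1L)
    stop("depth_weighted_average: need at least one layer")
  stopifnot(all(vapply(layers, inherits, TRUE, "depth_layer")))
  spec <- layers[[1]]$grid$spec
  for (l in layers[-1])
    if (!specs_equal(l$grid$spec, spec))
      stop("depth_weighted_average: layers have mismatched grid specs")
  iv <- cbind(vapply(layers, `[[`, 0, "top_cm"),
              vapply(layers, `[[`, 0, "bottom_cm"))
  o <- order(iv[, 1])
  if (any(iv[o, 2][-length(o)] > iv[o, 1][-1] + 1e-9))
    stop("depth_weighted_average: overlapping depth intervals")
  wsum <- matrix(0, spec$n_rows, spec$n_cols)
  vsum <- matrix(0, spec$n_rows, spec$n_cols)
  for (l in layers) {
    w <- l$bottom_cm - l$top_cm
    v <- l$grid$values
    has <- !is.na(v)
    vsum[has] <- vsum[has] + w * v[has]
    wsum[has] <- wsum[has] + w
  }
  out <- vsum / wsum
  out[wsum == 0] <- NA_real_
  grid_new(spec, out, nodata = layers[[1]]$grid$nodata)
}

#' Fill nodata gaps from a secondary raster
#'
#' Where the primary raster has data it wins; where it is nodata the
#' secondary value is used (the secondary must already be resampled onto
#' the primary's geometry, see [resample()]). Output is nodata only where
#' both sources are.
#'
#' @param primary,secondary `phyl_grid` objects with identical specs.
#' @return the gap-filled `phyl_grid`.
#' @export
fill_gaps <- function(primary, secondary) {
  stopifnot(inherits(primary, "phyl_grid"), inherits(secondary, "phyl_grid"))
  if (!specs_equal(primary$spec, secondary$spec))
    stop("fill_gaps: primary and secondary grid specs differ")
  v <- primary$values
  gap <- is.na(v)
  v[gap] <- secondary$values[gap]
  grid_new(primary$spec, v, nodata = primary$nodata)
}
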