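# Ordinary kriging: best linear unbiased prediction under intrinsic
# stationarity. The augmented system for n data points is
#
#   [ G  1 ] [ w  ]   [ g0 ]        G[i,j] = gamma(d_ij),  g0[i] = gamma(d_i0)
#   [ 1' 0 ] [ mu ] = [ 1  ]
#
# with Lagrange multiplier mu enforcing sum(w) = 1; the prediction is w'z
# and the kriging variance w'g0 + mu. All stations enter every system
# (global kriging): at a couple hundred stations the dense solve is cheap
# and avoids search-neighborhood artifacts.

build_ok_matrix <- function(x, y, vm) {
  d <- as.matrix(stats::dist(cbind(x, y)))
  n <- length(x)
  G <- matrix(semivariance(vm, d), n, n)
  diag(G) <- 0
  A <- rbind(cbind(G, 1), c(rep(1, n), 0))
  A
}

solve_ok <- function(A, B) {
  tryCatch(solve(A, B), error = function(e)
    stop(sprintf("krige: singular kriging system (%s)", conditionMessage(e)),
         call. = FALSE))
}

#' Ordinary kriging prediction at one target point
#'
#' Solves the augmented ordinary-kriging system for a single target. With
#' zero nugget the predictor is exact at data locations; weights always sum
#' to one, so a constant field is reproduced everywhere.
#'
#' @param x,y data point coordinates (m); at least 2 distinct locations.
#' @param values observed values at the data points.
#' @param vm a [variogram_model()].
#' @param x0,y0 target coordinates (m).
#' @return a list with `prediction`, `variance` (kriging variance, clamped
#'   at zero against roundoff), `weights`, and the Lagrange multiplier
#'   `lagrange`.
#' @export
krige_point <- function(x, y, values, vm, x0, y0) {
  n <- length(x)
  stopifnot(length(y) == n, length(values) == n, n >= 2L)
  if (anyDuplicated(cbind(x, y)))
    stop("krige_point: duplicate data locations", call. = FALSE)
  A <- build_ok_matrix(x, y, vm)
  d0 <- sqrt((x - x0)^2 + (y - y0)^2)
  b <- c(semivariance(vm, d0), 1)
  sol <- solve_ok(A, b)
  w <- sol[seq_len(n)]
  mu <- sol[n + 1L]
  list(prediction = sum(w * values),
       variance = max(0, sum(w * b[seq_len(n)]) + mu),
       weights = w, lagrange = mu)
}

# average data values at near-coincident locations (within `tol` meters);
# protects the kriging matrix from near-singularity
merge_close_points <- function(x, y, values, tol) {
  n <- length(x)
  group <- seq_len(n)
  d <- as.matrix(stats::dist(cbind(x, y)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j > i && d[i, j] < tol) group[group == group[j]] <- group[i]
  }
  idx <- split(seq_len(n), group)
  list(x = vapply(idx, function(i) mean(x[i]), 0),
       y = vapply(idx, function(i) mean(y[i]), 0),
       values = vapply(idx, function(i) mean(values[i]), 0),
       n_merged = n - length(idx))
}

#' Krige station summaries onto a grid
#'
#' Evaluates the ordinary-kriging predictor at every cell center of the
#' target geometry. The factorization of the (station-only) system matrix
#' is shared across all cells, so the cost is one dense solve with as many
#' right-hand sides as cells. Stations closer together than one cell are
#' averaged into a single point first. The output has no nodata; clip it
#' afterwards if a boundary mask is wanted.
#'
#' @param summaries station summary table with columns `x`, `y` and a value
#'   column (default `mean_daily_max_c`).
#' @param vm a [variogram_model()].
#' @param spec target [grid_spec()].
#' @param value_col name of the value column in `summaries`.
#' @return a `phyl_grid` of predictions.
#' @export
krige_grid <- function(summaries, vm, spec,
                       value_col = "mean_daily_max_c") {
  stopifnot(inherits(spec, "grid_spec"))
  if (!all(c("x", "y", value_col) %in% names(summaries)))
    stop(sprintf("krige_grid: summaries needs columns x, y, %s", value_col))
  if (nrow(summaries) < 2L)
    stop("krige_grid: need at least 2 stations", call. = FALSE)
  m <- merge_close_points(summaries$x, summaries$y, summaries[[value_col]],
                          tol = spec$cell_size)
  if (m$n_merged > 0L)
    message(sprintf("krige_grid: averaged %d near-duplicate station(s)",
                    m$n_merged))
  x <- m$x; y <- m$y; z <- m$values
  n <- length(x)
  A <- build_ok_matrix(x, y, vm)
  xs <- cell_center_x(spec)
  ys <- cell_center_y(spec)
  # right-hand sides for all cells, column-major over the grid
  px <- rep(xs, each = spec$n_rows)
  py <- rep(ys, times = spec$n_cols)
  B <- rbind(semivariance(vm, sqrt(outer(x, px, `-`)^2 +
                                   outer(y, py, `-`)^2)),
             1)
  W <- solve_ok(A, B)
  pred <- as.vector(crossprod(W[seq_len(n), , drop = FALSE], z))
  grid_new(spec, matrix(pred, spec$n_rows, spec$n_cols))
}

#' Leave-one-out cross-validation of a kriging configuration
#'
#' Re-predicts each station from the others under the supplied variogram
#' model; a quick sanity report for manual model comparison.
#'
#' @inheritParams krige_grid
#' @return a data frame with per-station `observed`, `predicted`,
#'   `residual`, plus attributes `rmse` and `mean_error`.
#' @export
krige_loo <- function(summaries, vm, value_col = "mean_daily_max_c") {
  x <- summaries$x; y <- summaries$y; z <- summaries[[value_col]]
  n <- length(x)
  if (n < 3L) stop("krige_loo: need at least 3 stations")
  pred <- vapply(seq_len(n), function(i) {
    krige_point(x[-i], y[-i], z[-i], vm, x[i], y[i])$prediction
  }, 0)
  out <- data.frame(station_id = summaries$station_id %||% seq_len(n),
                    observed = z, predicted = pred, residual = pred - z)
  attr(out, "rmse") <- sqrt(mean(out$residual^2))
  attr(out, "mean_error") <- mean(out$residual)
  out
}
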