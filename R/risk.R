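# Risk classes and their integer raster codes. Codes order the combined
# classes so that larger = riskier; categorical rasters carry their legend
# as an attribute and writers emit it as a JSON sidecar.

SAND_LEVELS <- c("LOW", "MODERATE", "HIGH")
TEMP_LEVELS <- c("LOW", "HIGH")
COMBINED_LEVELS <- c("LOW", "MODERATE_LOW", "MODERATE", "HIGH_MODERATE",
                     "HIGH")

#' Risk class levels
#'
#' The ordered class labels for each risk factor; the integer raster code
#' of a class is its position in the vector (1 = least risk). Temperature
#' has no moderate class: the literature thresholds split it into an
#' optimal band and everything else.
#'
#' @param which `"sand"`, `"temp"` or `"combined"`.
#' @return character vector of labels, least to most risky.
#' @export
risk_levels <- function(which = c("sand", "temp", "combined")) {
  switch(match.arg(which), sand = SAND_LEVELS, temp = TEMP_LEVELS,
         combined = COMBINED_LEVELS)
}

#' Classify soil sand content into phylloxera risk
#'
#' Sandy soils impede phylloxera movement and survival, so risk falls as
#' sand content rises: below 65 percent sand is high risk, 65 to 80
#' moderate, above 80 low. The boundary values 65 and 80 belong to the
#' moderate class (the break points are written as strict bounds on the
#' outer classes).
#'
#' @param sand_pct percent sand by weight in `[0, 100]`; `NA` allowed.
#' @param breaks two ascending break points, default `c(65, 80)`.
#' @return character vector of `"HIGH"`, `"MODERATE"`, `"LOW"`, `NA`.
#' @export
classify_sand <- function(sand_pct, breaks = c(65, 80)) {
  stopifnot(length(breaks) == 2L, breaks[1] < breaks[2])
  bad <- !is.na(sand_pct) & (sand_pct < 0 | sand_pct > 100)
  if (any(bad))
    stop(sprintf("classify_sand: %d value(s) outside [0, 100]", sum(bad)),
         call. = FALSE)
  out <- rep(NA_character_, length(sand_pct))
  out[!is.na(sand_pct) & sand_pct < breaks[1]] <- "HIGH"
  out[!is.na(sand_pct) & sand_pct >= breaks[1] & sand_pct <= breaks[2]] <-
    "MODERATE"
  out[!is.na(sand_pct) & sand_pct > breaks[2]] <- "LOW"
  out
}

#' Classify soil temperature into phylloxera risk
#'
#' Temperatures between 18 and 27 deg C (inclusive) are optimal for
#' phylloxera development and classify as high risk; cooler or hotter
#' soils are low risk (heat above the band raises mortality). There is no
#' moderate temperature class.
#'
#' @param temp_c soil temperature in deg C; `NA` allowed.
#' @param band optimal band `c(low, high)`, default `c(18, 27)`, inclusive.
#' @return character vector of `"HIGH"`, `"LOW"`, `NA`.
#' @export
classify_temp <- function(temp_c, band = c(18, 27)) {
  stopifnot(length(band) == 2L, band[1] <= band[2])
  out <- rep(NA_character_, length(temp_c))
  hot_ok <- !is.na(temp_c)
  out[hot_ok & temp_c >= band[1] & temp_c <= band[2]] <- "HIGH"
  out[hot_ok & (temp_c < band[1] | temp_c > band[2])] <- "LOW"
  out
}

#' Combine sand-based and temperature-based risk
#'
#' The five-class combination treats sand as the dominant factor and
#' temperature as a modifier: low-sand-risk sites stay low risk whatever
#' the temperature, while high and moderate sand risk are downgraded one
#' notch when the temperature is outside the optimal band.
#'
#' \tabular{lll}{
#'   sand \tab temperature \tab combined \cr
#'   LOW \tab LOW \tab LOW \cr
#'   LOW \tab HIGH \tab LOW \cr
#'   MODERATE \tab LOW \tab MODERATE_LOW \cr
#'   MODERATE \tab HIGH \tab MODERATE \cr
#'   HIGH \tab LOW \tab HIGH_MODERATE \cr
#'   HIGH \tab HIGH \tab HIGH
#' }
#'
#' A missing sand class yields `NA` regardless of temperature (the combined
#' map is a modification of the sand map). A missing temperature with
#' valid sand follows `temp_nodata_policy`: `"nodata"` (default) yields
#' `NA`; `"passthrough_sand"` keeps the unmodified sand class.
#'
#' @param sand character vector of sand risk labels.
#' @param temp character vector of temperature risk labels.
#' @param temp_nodata_policy `"nodata"` or `"passthrough_sand"`.
#' @return character vector of combined risk labels.
#' @export
combine_risk <- function(sand, temp,
                         temp_nodata_policy = c("nodata",
                                                "passthrough_sand")) {
  temp_nodata_policy <- match.arg(temp_nodata_policy)
  stopifnot(length(sand) == length(temp))
  ok_s <- is.na(sand) | sand %in% SAND_LEVELS
  ok_t <- is.na(temp) | temp %in% TEMP_LEVELS
  if (!all(ok_s)) stop("combine_risk: invalid sand label(s)")
  if (!all(ok_t)) stop("combine_risk: invalid temperature label(s)")
  key <- paste(sand, temp, sep = ".")
  map <- c(LOW.LOW = "LOW", LOW.HIGH = "LOW",
           MODERATE.LOW = "MODERATE_LOW", MODERATE.HIGH = "MODERATE",
           HIGH.LOW = "HIGH_MODERATE", HIGH.HIGH = "HIGH")
  out <- unname(map[key])
  tna <- !is.na(sand) & is.na(temp)
  if (temp_nodata_policy == "passthrough_sand") out[tna] <- sand[tna]
  out[is.na(sand)] <- NA_character_
  out
}

#' Apply a scalar risk classifier to a whole grid
#'
#' Per-pixel classification; nodata pixels stay nodata. The result is an
#' integer-coded categorical grid whose legend (label per code) is attached
#' as attribute `"legend"` and respected by [area_summary()],
#' [combine_grids()] and the pipeline's sidecar writer.
#'
#' @param grid a numeric `phyl_grid`.
#' @param classifier a vectorized scalar classifier such as
#'   [classify_sand()] or [classify_temp()] (or a partial application with
#'   custom thresholds).
#' @param levels class labels in code order; inferred for the two built-in
#'   classifiers, required for custom ones.
#' @return an integer-coded `phyl_grid` with a `"legend"` attribute.
#' @export
classify_grid <- function(grid, classifier, levels = NULL) {
  stopifnot(inherits(grid, "phyl_grid"), is.function(classifier))
  if (is.null(levels)) {
    levels <- if (identical(classifier, classify_sand)) SAND_LEVELS
      else if (identical(classifier, classify_temp)) TEMP_LEVELS
      else stop("classify_grid: supply `levels` for a custom classifier")
  }
  lab <- classifier(as.vector(grid$values))
  unknown <- !is.na(lab) & !(lab %in% levels)
  if (any(unknown))
    stop("classify_grid: classifier produced labels outside `levels`")
  code <- match(lab, levels)
  out <- grid_new(grid$spec, matrix(as.numeric(code), grid$spec$n_rows,
                                    grid$spec$n_cols),
                  nodata = grid$nodata)
  attr(out, "legend") <- stats::setNames(seq_along(levels), levels)
  out
}

grid_legend <- function(grid) {
  lg <- attr(grid, "legend")
  if (is.null(lg)) stop("expected a categorical grid with a legend attribute")
  lg
}

decode_classes <- function(grid) {
  lg <- grid_legend(grid)
  names(lg)[match(as.vector(grid$values), lg)]
}

#' Combine sand-risk and temperature-risk rasters
#'
#' Per-pixel [combine_risk()] over two categorical grids on the same
#' geometry.
#'
#' @param sand_risk categorical grid from `classify_grid(, classify_sand)`.
#' @param temp_risk categorical grid from `classify_grid(, classify_temp)`.
#' @param temp_nodata_policy see [combine_risk()].
#' @return an integer-coded combined-risk `phyl_grid` (codes 1-5, legend
#'   attached).
#' @export
combine_grids <- function(sand_risk, temp_risk,
                          temp_nodata_policy = c("nodata",
                                                 "passthrough_sand")) {
  stopifnot(inherits(sand_risk, "phyl_grid"), inherits(temp_risk, "phyl_grid"))
  if (!specs_equal(sand_risk$spec, temp_risk$spec))
    stop("combine_grids: grid specs differ")
  lab <- combine_risk(decode_classes(sand_risk), decode_classes(temp_risk),
                      temp_nodata_policy = temp_nodata_policy)
  code <- match(lab, COMBINED_LEVELS)
  sp <- sand_risk$spec
  out <- grid_new(sp, matrix(as.numeric(code), sp$n_rows, sp$n_cols),
                  nodata = sand_risk$nodata)
  attr(out, "legend") <- stats::setNames(seq_along(COMBINED_LEVELS),
                                         COMBINED_LEVELS)
  out
}

#' Area fractions by risk class
#'
#' Cell-count fractions per class over the classified (non-nodata) area,
#' plus the nodata fraction of the total extent. Cells are equal-area in a
#' projected CRS, so counts are areas.
#'
#' @param class_grid a categorical grid with a legend.
#' @return an object of class `area_summary`: list with `fractions` (named,
#'   sums to 1 over classified cells), `counts`, `n_classified`,
#'   `nodata_fraction`.
#' @export
area_summary <- function(class_grid) {
  lab <- decode_classes(class_grid)
  lg <- grid_legend(class_grid)
  n_tot <- length(lab)
  n_cls <- sum(!is.na(lab))
  if (n_cls == 0L)
    stop("area_summary: no classified cells", call. = FALSE)
  counts <- vapply(names(lg), function(l) sum(lab == l, na.rm = TRUE), 0L)
  structure(list(fractions = counts / n_cls, counts = counts,
                 n_classified = n_cls,
                 nodata_fraction = 1 - n_cls / n_tot),
            class = "area_summary")
}

#' @export
print.area_summary <- function(x, ...) {
  cat("area by risk class (fraction of classified cells):\n")
  for (l in rev(names(x$fractions)))
    cat(sprintf("  %-14s %6.1f%%  (%d cells)\n", l, 100 * x$fractions[[l]],
                x$counts[[l]]))
  cat(sprintf("  nodata: %.1f%% of the full extent\n",
              100 * x$nodata_fraction))
  invisible(x)
}
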