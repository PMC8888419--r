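#' Read validation sites
#'
#' Sites of confirmed infestation (or synthetic truth) as either a
#' delimited text table with columns `site_id`, `x`, `y` and optionally
#' `known_label`, or a GeoJSON FeatureCollection of Points with a
#' `site_id` property.
#'
#' @param path path to a CSV or GeoJSON file.
#' @return data frame with columns `site_id`, `x`, `y` and (possibly
#'   all-`NA`) `known_label`; site ids must be unique.
#' @export
read_sites <- function(path) {
  first <- readChar(path, min(file.size(path), 512L))
  sites <- if (grepl("FeatureCollection|\"type\"", first)) {
    gj <- jsonlite::read_json(path, simplifyVector = FALSE)
    if (!identical(gj$type, "FeatureCollection"))
      stop("read_sites: GeoJSON must be a FeatureCollection of Points")
    rows <- lapply(seq_along(gj$features), function(i) {
      f <- gj$features[[i]]
      if (!identical(f$geometry$type, "Point"))
        stop("read_sites: all features must be Points")
      data.frame(
        site_id = as.character(f$properties$site_id %||% i),
        x = f$geometry$coordinates[[1]], y = f$geometry$coordinates[[2]],
        known_label = as.character(f$properties$known_label %||% NA),
        stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  } else {
    d <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (!all(c("site_id", "x", "y") %in% names(d)))
      stop("read_sites: need columns site_id, x, y", call. = FALSE)
    d$site_id <- as.character(d$site_id)
    if (is.null(d$known_label)) d$known_label <- NA_character_
    d[c("site_id", "x", "y", "known_label")]
  }
  if (anyDuplicated(sites$site_id))
    stop("read_sites: duplicate site_id values", call. = FALSE)
  sites
}

#' Assign risk classes to validation sites
#'
#' Looks up each site in the categorical risk raster via nearest-cell-center
#' sampling. Sites falling in nodata cells get `NA` and are reported via
#' [message()]; sites outside the raster extent are an error naming the
#' offenders.
#'
#' @param class_grid a categorical grid with a legend (see
#'   [classify_grid()]).
#' @param sites data frame with `site_id`, `x`, `y` (see [read_sites()]).
#' @return named character vector: risk label per `site_id`.
#' @export
assign_site_risk <- function(class_grid, sites) {
  lg <- grid_legend(class_grid)
  ext <- grid_extent(class_grid$spec)
  out_of <- sites$x < ext["xmin"] | sites$x > ext["xmax"] |
    sites$y < ext["ymin"] | sites$y > ext["ymax"]
  if (any(out_of))
    stop(sprintf("assign_site_risk: site(s) outside grid extent: %s",
                 paste(sites$site_id[out_of], collapse = ", ")),
         call. = FALSE)
  code <- vapply(seq_len(nrow(sites)), function(i)
    sample_at_point(class_grid, sites$x[i], sites$y[i]), 0)
  lab <- names(lg)[match(code, lg)]
  if (anyNA(lab))
    message(sprintf("assign_site_risk: %d site(s) fall in nodata cells: %s",
                    sum(is.na(lab)),
                    paste(sites$site_id[is.na(lab)], collapse = ", ")))
  stats::setNames(lab, sites$site_id)
}

#' Tally site risk labels
#'
#' Counts and percentages per risk class over the labelled sites, as used
#' to validate a risk map against confirmed infestations. Sites with `NA`
#' labels (nodata cells) are counted separately and excluded from the
#' percentage denominator.
#'
#' @param labels named character vector from [assign_site_risk()] (or any
#'   site -> class map).
#' @param levels class labels in code order; defaults to the combined-risk
#'   classes, with sand/temp classes accepted automatically.
#' @return an object of class `risk_tally`: list with `counts`,
#'   `percentages` (unrounded), `n_sites`, `n_nodata`.
#' @export
tally <- function(labels, levels = NULL) {
  if (length(labels) == 0L) stop("tally: empty label map", call. = FALSE)
  if (is.null(levels)) {
    seen <- unique(labels[!is.na(labels)])
    levels <- if (all(seen %in% COMBINED_LEVELS)) COMBINED_LEVELS
      else if (all(seen %in% SAND_LEVELS)) SAND_LEVELS
      else stop("tally: cannot infer levels; pass them explicitly")
  }
  ok <- !is.na(labels)
  n <- sum(ok)
  if (n == 0L) stop("tally: all sites unlabelled (nodata)", call. = FALSE)
  counts <- vapply(levels, function(l) sum(labels[ok] == l), 0L)
  structure(list(counts = counts, percentages = 100 * counts / n,
                 n_sites = n, n_nodata = sum(!ok)),
            class = "risk_tally")
}

#' @export
print.risk_tally <- function(x, ...) {
  cat(sprintf("site risk tally (%d labelled site%s%s):\n", x$n_sites,
              if (x$n_sites == 1L) "" else "s",
              if (x$n_nodata) sprintf(", %d in nodata", x$n_nodata) else ""))
  for (l in rev(names(x$counts)))
    if (x$counts[[l]] > 0 || length(x$counts) <= 5L)
      cat(sprintf("  %-14s %3d  (%.1f%%)\n", l, x$counts[[l]],
                  x$percentages[[l]]))
  invisible(x)
}
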