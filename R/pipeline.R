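# Stage orchestration. Stages communicate only through files so every
# intermediate product is inspectable and re-runs are reproducible; a run
# manifest (config hash + input checksums) is written next to the outputs.

PIPELINE_KEYS <- c("seed", "grid", "soil", "temperature", "kriging",
                   "boundary", "thresholds", "temp_nodata_policy", "sites",
                   "output_dir", "simulate")

#' Load and validate a pipeline configuration
#'
#' Reads the YAML configuration driving [run_stage()]. Unknown top-level
#' keys are rejected (typos must not silently disable options). Relative
#' paths are resolved against the config file's directory. A documented
#' template ships with the package:
#' `system.file("extdata", "config_template.yaml", package = "phylrisk")`.
#'
#' @param path path to a YAML file, or a list with the same structure.
#' @param base_dir directory against which relative paths resolve;
#'   defaults to the config file's directory.
#' @return a validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(path, base_dir = NULL) {
  cfg <- if (is.character(path)) {
    if (is.null(base_dir)) base_dir <- dirname(normalizePath(path))
    yaml::read_yaml(path)
  } else {
    if (is.null(base_dir)) base_dir <- getwd()
    path
  }
  unknown <- setdiff(names(cfg), PIPELINE_KEYS)
  if (length(unknown))
    stop(sprintf("pipeline_config: unknown key(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  defaults <- list(
    seed = 42L,
    kriging = list(family = "spherical", n_lags = 12L, max_dist = NULL),
    thresholds = list(sand_breaks = c(65, 80), temp_band = c(18, 27)),
    temp_nodata_policy = "nodata",
    output_dir = "out")
  for (k in names(defaults)) {
    if (is.null(cfg[[k]])) cfg[[k]] <- defaults[[k]]
    else if (is.list(defaults[[k]]))
      for (kk in names(defaults[[k]]))
        if (is.null(cfg[[k]][[kk]])) cfg[[k]][[kk]] <- defaults[[k]][[kk]]
  }
  if (!is.null(cfg$temperature$min_records_per_day)) {
    if (cfg$temperature$min_records_per_day < 1)
      stop("pipeline_config: min_records_per_day must be >= 1")
  } else cfg$temperature$min_records_per_day <- 48L
  if (!cfg$temp_nodata_policy %in% c("nodata", "passthrough_sand"))
    stop("pipeline_config: temp_nodata_policy must be 'nodata' or 'passthrough_sand'")
  cfg$base_dir <- base_dir
  class(cfg) <- "pipeline_config"
  cfg
}

cfg_path <- function(cfg, p) {
  if (is.null(p)) return(NULL)
  if (grepl("^(/|[A-Za-z]:)", p)) p else file.path(cfg$base_dir, p)
}

out_path <- function(cfg, ...) {
  d <- cfg_path(cfg, cfg$output_dir)
  dir.create(d, showWarnings = FALSE, recursive = TRUE)
  file.path(d, ...)
}

cfg_grid_spec <- function(cfg) {
  g <- cfg$grid
  if (is.null(g)) stop("pipeline: config has no `grid` block", call. = FALSE)
  grid_spec(g$n_rows, g$n_cols, g$x_origin, g$y_origin, g$cell_size,
            crs = g$crs %||% "")
}

cfg_window <- function(cfg) {
  w <- cfg$temperature$window
  if (is.null(w)) stop("pipeline: config has no temperature window")
  season_window(unlist(w$start), unlist(w$end), unlist(w$years))
}

write_legend_sidecar <- function(grid, raster_path) {
  lg <- attr(grid, "legend")
  if (is.null(lg)) return(invisible(NULL))
  jsonlite::write_json(as.list(lg), paste0(raster_path, ".legend.json"),
                       auto_unbox = TRUE)
}

read_classified <- function(path, levels) {
  g <- read_raster(path)
  attr(g, "legend") <- stats::setNames(seq_along(levels), levels)
  g
}

# atomically write via a temp file in the same directory
atomic_write <- function(write_fn, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = paste0(".tmp_",
                                                           basename(path)))
  write_fn(tmp)
  file.rename(tmp, path)
  invisible(path)
}

write_manifest <- function(cfg, stage, inputs, outputs) {
  inputs <- inputs[file.exists(inputs)]
  manifest <- list(
    stage = stage,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    package_version = as.character(utils::packageVersion("phylrisk")),
    config_hash = digest_config(cfg),
    input_checksums = as.list(tools::md5sum(inputs)),
    outputs = outputs)
  jsonlite::write_json(manifest, out_path(cfg, sprintf("manifest_%s.json",
                                                       stage)),
                       auto_unbox = TRUE, pretty = TRUE)
}

digest_config <- function(cfg) {
  c2 <- unclass(cfg); c2$base_dir <- NULL
  tmp <- tempfile(); on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(c2), tmp)
  unname(tools::md5sum(tmp))
}

#' Run one pipeline stage (or all of them)
#'
#' Stages, in flowchart order:
#' \describe{
#'   \item{simulate}{write a synthetic input bundle into the config's
#'     directory layout (requires a `simulate` block with [sim_config()]
#'     overrides).}
#'   \item{aggregate-soil}{depth-weighted sand aggregation + gap fill ->
#'     `sand_weighted.asc`.}
#'   \item{aggregate-temp}{station QC and summarization ->
#'     `station_summaries.csv`.}
#'   \item{krige}{variogram fit + ordinary kriging of station summaries ->
#'     `temp_kriged.asc`, `variogram.json`.}
#'   \item{classify}{threshold classification of both rasters (clipped to
#'     the boundary polygon if one is configured) -> `sand_risk.asc`,
#'     `temp_risk.asc` + legend sidecars.}
#'   \item{combine}{five-class combination -> `combined_risk.asc`.}
#'   \item{summarize}{area fractions per class -> `area_summary.json`.}
#'   \item{validate}{site risk assignment and tally ->
#'     `validation_tally.json`.}
#'   \item{run-all}{all of the above in order (simulate only if
#'     configured).}
#' }
#'
#' @param name stage name (see above).
#' @param cfg a [pipeline_config()].
#' @return invisibly, the paths written by the stage.
#' @export
run_stage <- function(name, cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  stages <- c("simulate", "aggregate-soil", "aggregate-temp", "krige",
              "classify", "combine", "summarize", "validate")
  if (identical(name, "run-all")) {
    todo <- if (is.null(cfg$simulate)) stages[-1] else stages
    return(invisible(lapply(todo, run_stage, cfg = cfg)))
  }
  name <- match.arg(name, stages)
  switch(name,
    `simulate` = stage_simulate(cfg),
    `aggregate-soil` = stage_aggregate_soil(cfg),
    `aggregate-temp` = stage_aggregate_temp(cfg),
    `krige` = stage_krige(cfg),
    `classify` = stage_classify(cfg),
    `combine` = stage_combine(cfg),
    `summarize` = stage_summarize(cfg),
    `validate` = stage_validate(cfg))
}

#' @rdname run_stage
#' @export
run_pipeline <- function(cfg) run_stage("run-all", cfg)

stage_simulate <- function(cfg) {
  sim <- cfg$simulate %||% list()
  args <- sim
  args$spec <- cfg_grid_spec(cfg)
  args$seed <- as.integer(sim$seed %||% cfg$seed)
  if (!is.null(cfg$temperature$window)) args$window <- cfg_window(cfg)
  sc <- do.call(sim_config, args)
  paths <- simulate_world(sc, cfg$base_dir)
  write_manifest(cfg, "simulate", character(0), unlist(paths))
  invisible(paths)
}

stage_aggregate_soil <- function(cfg) {
  lys <- cfg$soil$layers
  if (is.null(lys)) stop("pipeline: config has no soil layers", call. = FALSE)
  layers <- lapply(lys, function(l)
    depth_layer(read_raster(cfg_path(cfg, l$path)), l$top_cm, l$bottom_cm))
  agg <- depth_weighted_average(layers)
  if (!is.null(cfg$soil$fill)) {
    fill <- read_raster(cfg_path(cfg, cfg$soil$fill$path))
    if (!specs_equal(fill$spec, agg$spec))
      fill <- resample(fill, agg$spec$cell_size,
                       method = cfg$soil$fill$resample_method %||% "bilinear")
    agg <- fill_gaps(agg, fill)
  }
  out <- out_path(cfg, "sand_weighted.asc")
  atomic_write(function(p) write_raster(agg, p, "ascii"), out)
  message(sprintf("aggregate-soil: %d/%d cells populated",
                  sum(!is.na(agg$values)), length(agg$values)))
  write_manifest(cfg, "aggregate-soil",
                 vapply(lys, function(l) cfg_path(cfg, l$path), ""), out)
  invisible(out)
}

stage_aggregate_temp <- function(cfg) {
  rec_path <- cfg_path(cfg, cfg$temperature$records)
  coord_path <- cfg_path(cfg, cfg$temperature$coords)
  records <- parse_station_records(rec_path)
  window <- cfg_window(cfg)
  daily <- daily_maxima(records, window,
                        min_records_per_day =
                          cfg$temperature$min_records_per_day)
  coords <- utils::read.csv(coord_path, stringsAsFactors = FALSE)
  summaries <- summarize_stations(daily, coords)
  out <- out_path(cfg, "station_summaries.csv")
  atomic_write(function(p) utils::write.csv(summaries, p,
                                            row.names = FALSE), out)
  message(sprintf("aggregate-temp: %d station(s), %d total station-days",
                  nrow(summaries), sum(summaries$n_days_used)))
  write_manifest(cfg, "aggregate-temp", c(rec_path, coord_path), out)
  invisible(out)
}

stage_krige <- function(cfg) {
  in_path <- out_path(cfg, "station_summaries.csv")
  summaries <- utils::read.csv(in_path, stringsAsFactors = FALSE)
  emp <- empirical_variogram(summaries$x, summaries$y,
                             summaries$mean_daily_max_c,
                             n_lags = cfg$kriging$n_lags,
                             max_dist = cfg$kriging$max_dist)
  vm <- fit_variogram(emp, family = cfg$kriging$family)
  message(sprintf(
    "krige: fitted %s variogram (nugget %.4g, psill %.4g, range %.4g m)",
    vm$family, vm$nugget, vm$psill, vm$range_m))
  spec <- cfg_grid_spec(cfg)
  kg <- krige_grid(summaries, vm, spec)
  out <- out_path(cfg, "temp_kriged.asc")
  atomic_write(function(p) write_raster(kg, p, "ascii"), out)
  jsonlite::write_json(list(family = vm$family, nugget = vm$nugget,
                            partial_sill = vm$psill, range_m = vm$range_m),
                       out_path(cfg, "variogram.json"), auto_unbox = TRUE,
                       digits = NA)
  write_manifest(cfg, "krige", in_path,
                 c(out, out_path(cfg, "variogram.json")))
  invisible(out)
}

stage_classify <- function(cfg) {
  sand <- read_raster(out_path(cfg, "sand_weighted.asc"))
  temp <- read_raster(out_path(cfg, "temp_kriged.asc"))
  if (!is.null(cfg$boundary)) {
    poly <- read_polygon(cfg_path(cfg, cfg$boundary))
    sand <- clip_to_polygon(sand, poly)
    temp <- clip_to_polygon(temp, poly)
  }
  br <- as.numeric(unlist(cfg$thresholds$sand_breaks))
  bd <- as.numeric(unlist(cfg$thresholds$temp_band))
  sand_risk <- classify_grid(sand, function(v) classify_sand(v, breaks = br),
                             levels = SAND_LEVELS)
  temp_risk <- classify_grid(temp, function(v) classify_temp(v, band = bd),
                             levels = TEMP_LEVELS)
  p1 <- out_path(cfg, "sand_risk.asc")
  p2 <- out_path(cfg, "temp_risk.asc")
  atomic_write(function(p) write_raster(sand_risk, p, "ascii"), p1)
  atomic_write(function(p) write_raster(temp_risk, p, "ascii"), p2)
  write_legend_sidecar(sand_risk, p1)
  write_legend_sidecar(temp_risk, p2)
  write_manifest(cfg, "classify",
                 c(out_path(cfg, "sand_weighted.asc"),
                   out_path(cfg, "temp_kriged.asc")), c(p1, p2))
  invisible(c(p1, p2))
}

stage_combine <- function(cfg) {
  sand_risk <- read_classified(out_path(cfg, "sand_risk.asc"), SAND_LEVELS)
  temp_risk <- read_classified(out_path(cfg, "temp_risk.asc"), TEMP_LEVELS)
  comb <- combine_grids(sand_risk, temp_risk,
                        temp_nodata_policy = cfg$temp_nodata_policy)
  out <- out_path(cfg, "combined_risk.asc")
  atomic_write(function(p) write_raster(comb, p, "ascii"), out)
  write_legend_sidecar(comb, out)
  write_manifest(cfg, "combine",
                 c(out_path(cfg, "sand_risk.asc"),
                   out_path(cfg, "temp_risk.asc")), out)
  invisible(out)
}

stage_summarize <- function(cfg) {
  res <- list()
  for (nm in c("sand_risk", "temp_risk", "combined_risk")) {
    lv <- switch(nm, sand_risk = SAND_LEVELS, temp_risk = TEMP_LEVELS,
                 combined_risk = COMBINED_LEVELS)
    g <- read_classified(out_path(cfg, paste0(nm, ".asc")), lv)
    a <- area_summary(g)
    res[[nm]] <- list(fractions = as.list(a$fractions),
                      percent = as.list(100 * a$fractions),
                      nodata_fraction = a$nodata_fraction)
  }
  out <- out_path(cfg, "area_summary.json")
  atomic_write(function(p) jsonlite::write_json(res, p, auto_unbox = TRUE,
                                                digits = NA, pretty = TRUE),
               out)
  write_manifest(cfg, "summarize",
                 out_path(cfg, paste0(c("sand_risk", "temp_risk",
                                        "combined_risk"), ".asc")), out)
  invisible(out)
}

stage_validate <- function(cfg) {
  if (is.null(cfg$sites))
    stop("pipeline: config has no `sites` entry", call. = FALSE)
  sites <- read_sites(cfg_path(cfg, cfg$sites))
  comb <- read_classified(out_path(cfg, "combined_risk.asc"),
                          COMBINED_LEVELS)
  labels <- assign_site_risk(comb, sites)
  tl <- tally(labels, levels = COMBINED_LEVELS)
  res <- list(n_sites = tl$n_sites, n_nodata = tl$n_nodata,
              counts = as.list(tl$counts),
              percentages = as.list(tl$percentages),
              labels = as.list(labels))
  if (!all(is.na(sites$known_label)))
    res$agreement <- mean(labels == sites$known_label, na.rm = TRUE)
  out <- out_path(cfg, "validation_tally.json")
  atomic_write(function(p) jsonlite::write_json(res, p, auto_unbox = TRUE,
                                                digits = NA, pretty = TRUE),
               out)
  write_manifest(cfg, "validate", out_path(cfg, "combined_risk.asc"), out)
  invisible(out)
}
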