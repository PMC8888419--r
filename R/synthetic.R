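# Synthetic world generator: spatially autocorrelated sand fields with
# survey gaps, multi-year 15-minute station soil-temperature series with
# diurnal structure, and validation sites of designed class. Everything is
# a pure function of (config, seed), so pipeline tests have exact ground
# truth.

# evaluate f() under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched
with_seed <- function(seed, f) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  f()
}

#' Simulation configuration
#'
#' Desk-scale defaults chosen to resemble an agricultural survey region: a
#' 40 x 40 grid at 14.5 m resolution (the working resolution of the risk
#' pipeline), a sand field with standard deviation around 11 percentage
#' points and a 120 m correlation length, roughly 10 percent survey gaps,
#' a dozen stations, a 5 deg C diurnal soil-temperature swing around
#' station-specific summer baselines near the low twenties, and two years
#' of June-August records at 15-minute cadence.
#'
#' @param seed integer master seed; every generator output is a pure
#'   function of the config including this seed.
#' @param spec target [grid_spec()].
#' @param layer_means mean percent sand per depth layer (standard four
#'   intervals).
#' @param sand_variance variance of the shared base sand field.
#' @param perturb_variance variance of each layer's independent
#'   perturbation.
#' @param correlation_length exponential-covariance correlation length (m).
#' @param nodata_hole_fraction expected fraction of cells punched out as
#'   survey gaps, independently per layer.
#' @param n_stations number of soil-temperature stations.
#' @param station_min_sep_cells minimum station separation in cell widths.
#' @param temp_base_c mean of the station baseline (seasonal mean daily
#'   maximum) field, deg C.
#' @param temp_spatial_amplitude_c half-range of the smooth east-west
#'   baseline trend, deg C.
#' @param diurnal_amplitude_c amplitude of the diurnal sinusoid, deg C.
#' @param noise_sd_c observation noise standard deviation, deg C.
#' @param window a [season_window()].
#' @param n_sites number of validation sites to place.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(seed = 42L,
                       spec = grid_spec(40L, 40L, 500000, 5200000, 14.5,
                                        crs = "EPSG:32610"),
                       layer_means = c(55, 58, 62, 64),
                       sand_variance = 120,
                       perturb_variance = 10,
                       correlation_length = 120,
                       nodata_hole_fraction = 0.1,
                       n_stations = 12L,
                       station_min_sep_cells = 2,
                       temp_base_c = 21,
                       temp_spatial_amplitude_c = 2.5,
                       diurnal_amplitude_c = 5,
                       noise_sd_c = 0.5,
                       window = season_window(years = 2019:2020),
                       n_sites = 23L) {
  stopifnot(inherits(spec, "grid_spec"), inherits(window, "season_window"),
            sand_variance >= 0, perturb_variance >= 0,
            nodata_hole_fraction >= 0, nodata_hole_fraction < 1,
            noise_sd_c >= 0, n_stations >= 2L)
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate a Gaussian random field on a grid
#'
#' Stationary isotropic field with exponential covariance
#' \eqn{C(h) = \sigma^2 e^{-h/L}}, generated by dense Cholesky
#' factorization of the cell-center covariance matrix — exact, simple, and
#' adequate below the cell cap (circulant embedding would lift the cap but
#' is not needed at desk scale).
#'
#' @param spec a [grid_spec()].
#' @param mean field mean.
#' @param variance marginal variance \eqn{\sigma^2 \ge 0}.
#' @param correlation_length \eqn{L > 0}, meters.
#' @param seed integer seed; same seed, same field.
#' @param cell_cap refuse grids larger than this many cells (dense method).
#' @return a `phyl_grid`.
#' @export
gaussian_random_field <- function(spec, mean, variance, correlation_length,
                                  seed, cell_cap = 12000L) {
  stopifnot(inherits(spec, "grid_spec"))
  if (variance < 0) stop("gaussian_random_field: variance must be >= 0")
  if (correlation_length <= 0)
    stop("gaussian_random_field: correlation_length must be > 0")
  n <- spec$n_rows * spec$n_cols
  if (n > cell_cap)
    stop(sprintf(
      "gaussian_random_field: %d cells exceeds the dense-method cap of %d; use a smaller grid",
      n, cell_cap), call. = FALSE)
  if (variance == 0) return(grid_new(spec, mean))
  xs <- cell_center_x(spec); ys <- cell_center_y(spec)
  pts <- cbind(rep(xs, each = spec$n_rows), rep(ys, times = spec$n_cols))
  C <- variance * exp(-as.matrix(stats::dist(pts)) / correlation_length)
  L <- chol(C + diag(1e-8 * variance, n))
  z <- with_seed(seed, function() stats::rnorm(n))
  grid_new(spec, matrix(mean + crossprod(L, z), spec$n_rows, spec$n_cols))
}

#' Generate correlated sand depth layers with survey gaps
#'
#' Four standard depth intervals sharing one base Gaussian random field,
#' each with its own mean, an independent perturbation field, and an
#' independent random nodata mask. Values are clipped to `[0, 100]`; the
#' clipping rate is reported via [message()] when nonzero so configs that
#' truncate heavily are visible.
#'
#' @param cfg a [sim_config()].
#' @return list of four [depth_layer()] objects (0-5, 5-20, 20-50,
#'   50-100 cm).
#' @export
make_soil_layers <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  sp <- cfg$spec
  intervals <- list(c(0, 5), c(5, 20), c(20, 50), c(50, 100))
  base <- gaussian_random_field(sp, 0, cfg$sand_variance,
                                cfg$correlation_length, seed = cfg$seed)
  n <- sp$n_rows * sp$n_cols
  n_clip <- 0L
  layers <- lapply(seq_along(intervals), function(i) {
    pert <- if (cfg$perturb_variance > 0)
      gaussian_random_field(sp, 0, cfg$perturb_variance,
                            cfg$correlation_length,
                            seed = cfg$seed + 1000L * i)$values
      else 0
    v <- cfg$layer_means[i] + base$values + pert
    n_clip <<- n_clip + sum(v < 0 | v > 100, na.rm = TRUE)
    v <- pmin(pmax(v, 0), 100)
    if (cfg$nodata_hole_fraction > 0) {
      holes <- with_seed(cfg$seed + 2000L * i, function()
        stats::runif(n) < cfg$nodata_hole_fraction)
      v[matrix(holes, sp$n_rows, sp$n_cols)] <- NA_real_
    }
    depth_layer(grid_new(sp, matrix(v, sp$n_rows, sp$n_cols)),
                intervals[[i]][1], intervals[[i]][2])
  })
  if (n_clip > 0L)
    message(sprintf("make_soil_layers: clipped %d of %d cell values to [0, 100]",
                    n_clip, 4L * n))
  layers
}

#' Generate sand depth layers around a designed spatial pattern
#'
#' Like [make_soil_layers()], but the expected value of every layer is a
#' caller-supplied design raster instead of a stationary mean — the tool
#' for building worlds with known class geography (e.g. blocks of high,
#' moderate and low sand) whose recovery an end-to-end test can score.
#' Each layer adds an independent Gaussian-random-field perturbation to the
#' design and punches independent nodata holes; values are clipped to
#' `[0, 100]`.
#'
#' @param design a `phyl_grid` of designed percent-sand values.
#' @param perturb_variance variance of each layer's perturbation field.
#' @param correlation_length perturbation correlation length (m).
#' @param nodata_hole_fraction expected per-layer fraction of nodata holes.
#' @param seed integer seed.
#' @return list of four [depth_layer()] objects.
#' @export
designed_sand_layers <- function(design, perturb_variance = 4,
                                 correlation_length = 120,
                                 nodata_hole_fraction = 0.1, seed = 1L) {
  stopifnot(inherits(design, "phyl_grid"))
  sp <- design$spec
  n <- sp$n_rows * sp$n_cols
  intervals <- list(c(0, 5), c(5, 20), c(20, 50), c(50, 100))
  lapply(seq_along(intervals), function(i) {
    pert <- if (perturb_variance > 0)
      gaussian_random_field(sp, 0, perturb_variance, correlation_length,
                            seed = seed + 1000L * i)$values
      else 0
    v <- pmin(pmax(design$values + pert, 0), 100)
    if (nodata_hole_fraction > 0) {
      holes <- with_seed(seed + 2000L * i, function()
        stats::runif(n) < nodata_hole_fraction)
      v[matrix(holes, sp$n_rows, sp$n_cols)] <- NA_real_
    }
    depth_layer(grid_new(sp, v), intervals[[i]][1], intervals[[i]][2])
  })
}

# station locations: uniform in the extent with rejection sampling to
# enforce a minimum separation
place_stations <- function(cfg) {
  sp <- cfg$spec
  ext <- grid_extent(sp)
  min_sep <- cfg$station_min_sep_cells * sp$cell_size
  with_seed(cfg$seed + 7L, function() {
    xs <- numeric(0); ys <- numeric(0)
    tries <- 0L
    while (length(xs) < cfg$n_stations && tries < 10000L) {
      tries <- tries + 1L
      px <- stats::runif(1, ext["xmin"], ext["xmax"])
      py <- stats::runif(1, ext["ymin"], ext["ymax"])
      if (!length(xs) || min(sqrt((xs - px)^2 + (ys - py)^2)) >= min_sep) {
        xs <- c(xs, px); ys <- c(ys, py)
      }
    }
    if (length(xs) < cfg$n_stations)
      stop("place_stations: could not satisfy the minimum separation")
    data.frame(station_id = sprintf("ST%03d", seq_along(xs)),
               x = xs, y = ys, stringsAsFactors = FALSE)
  })
}

#' Generate multi-year 15-minute station soil-temperature series
#'
#' Each station gets a baseline drawn from a smooth east-west spatial trend
#' (so interpolation has signal), a diurnal sinusoid peaking on a sampling
#' instant, and white observation noise:
#' \eqn{T(t) = base + A \sin(2\pi t_{min}/1440) + \epsilon}. The returned
#' truth map holds each station's noise-free seasonal mean daily maximum,
#' which equals `base + A` exactly because the peak lies on the 15-minute
#' sampling lattice.
#'
#' @param cfg a [sim_config()].
#' @return list with `records` (data frame: station_id, timestamp, temp_c),
#'   `coords` (station_id, x, y), and `truth` (named vector of noise-free
#'   mean daily maxima, deg C).
#' @export
make_station_series <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  coords <- place_stations(cfg)
  ext <- grid_extent(cfg$spec)
  rel_x <- (coords$x - ext["xmin"]) / (ext["xmax"] - ext["xmin"])
  base <- cfg$temp_base_c + cfg$temp_spatial_amplitude_c * (2 * rel_x - 1)
  days <- do.call(c, lapply(cfg$window$years, function(yr) {
    d0 <- as.Date(sprintf("%04d-%02d-%02d", yr, cfg$window$start[1],
                          cfg$window$start[2]))
    seq(d0, by = "day", length.out = window_days(cfg$window, yr))
  }))
  minutes <- seq(0, 1425, by = 15)
  stamps <- rep(as.POSIXct(as.character(days), tz = "UTC"),
                each = length(minutes)) + rep(minutes * 60, length(days))
  diurnal <- cfg$diurnal_amplitude_c *
    sin(2 * pi * rep(minutes, length(days)) / 1440)
  n_per_station <- length(stamps)
  records <- with_seed(cfg$seed + 11L, function() {
    do.call(rbind, lapply(seq_len(nrow(coords)), function(i) {
      noise <- if (cfg$noise_sd_c > 0)
        stats::rnorm(n_per_station, 0, cfg$noise_sd_c) else 0
      data.frame(station_id = coords$station_id[i], timestamp = stamps,
                 temp_c = base[i] + diurnal + noise,
                 stringsAsFactors = FALSE)
    }))
  })
  truth <- stats::setNames(base + cfg$diurnal_amplitude_c,
                           coords$station_id)
  list(records = records, coords = coords, truth = truth)
}

#' Place validation sites at cell centers of designed classes
#'
#' Samples, per requested class, distinct cells carrying that class and
#' puts one site at each cell center, so nearest-cell lookup must recover
#' the design exactly.
#'
#' @param class_grid a categorical grid with a legend.
#' @param class_mix named integer vector: sites wanted per class label.
#' @param seed integer seed.
#' @return data frame of sites: `site_id`, `x`, `y`, `known_label`.
#' @export
make_sites <- function(class_grid, class_mix, seed) {
  lab <- decode_classes(class_grid)
  sp <- class_grid$spec
  xs <- cell_center_x(sp); ys <- cell_center_y(sp)
  with_seed(seed, function() {
    rows <- lapply(names(class_mix), function(cl) {
      k <- class_mix[[cl]]
      cand <- which(lab == cl)  # column-major cell index
      if (length(cand) < k)
        stop(sprintf(
          "make_sites: only %d cell(s) of class %s available, %d requested",
          length(cand), cl, k), call. = FALSE)
      pick <- if (length(cand) == 1L) cand else sample(cand, k)
      ri <- (pick - 1L) %% sp$n_rows + 1L
      ci <- (pick - 1L) %/% sp$n_rows + 1L
      data.frame(x = xs[ci], y = ys[ri], known_label = cl,
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    out$site_id <- sprintf("S%03d", seq_len(nrow(out)))
    out[c("site_id", "x", "y", "known_label")]
  })
}

#' Write a complete synthetic input bundle to a directory
#'
#' Materializes everything the pipeline reads: the four depth-layer rasters
#' and a fully-populated gap-fill raster (ESRI ASCII), station records and
#' coordinates (CSV), a rectangular boundary polygon inset 5 percent from
#' the grid edge (GeoJSON), and the station truth values (JSON).
#' Validation sites are not written here — they require a classified map,
#' see [make_sites()].
#'
#' @param cfg a [sim_config()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, a named list of the file paths written.
#' @export
simulate_world <- function(cfg, out_dir) {
  stopifnot(inherits(cfg, "sim_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(out_dir, ...)
  layers <- make_soil_layers(cfg)
  iv <- list(c(0, 5), c(5, 20), c(20, 50), c(50, 100))
  layer_paths <- vapply(seq_along(layers), function(i) {
    fp <- p(sprintf("sand_%03d_%03d.asc", iv[[i]][1], iv[[i]][2]))
    write_raster(layers[[i]]$grid, fp, "ascii")
    fp
  }, "")
  # gap-fill source: an independent full-coverage field, as a coarser
  # survey product would provide
  fill <- gaussian_random_field(cfg$spec, mean(cfg$layer_means),
                                cfg$sand_variance, cfg$correlation_length,
                                seed = cfg$seed + 5000L)
  fill$values[] <- pmin(pmax(fill$values, 0), 100)
  write_raster(fill, p("sand_fill.asc"), "ascii")
  series <- make_station_series(cfg)
  utils::write.csv(data.frame(station_id = series$records$station_id,
                              timestamp = format(series$records$timestamp,
                                                 "%Y-%m-%dT%H:%M:%S"),
                              soil_temp_c = series$records$temp_c),
                   p("station_records.csv"), row.names = FALSE)
  utils::write.csv(series$coords, p("station_coords.csv"),
                   row.names = FALSE)
  ext <- grid_extent(cfg$spec)
  mx <- 0.05 * (ext["xmax"] - ext["xmin"])
  my <- 0.05 * (ext["ymax"] - ext["ymin"])
  ring <- rbind(c(ext["xmin"] + mx, ext["ymin"] + my),
                c(ext["xmax"] - mx, ext["ymin"] + my),
                c(ext["xmax"] - mx, ext["ymax"] - my),
                c(ext["xmin"] + mx, ext["ymax"] - my),
                c(ext["xmin"] + mx, ext["ymin"] + my))
  gj <- list(type = "Polygon",
             coordinates = list(lapply(seq_len(nrow(ring)),
                                       function(i) as.list(ring[i, ]))))
  jsonlite::write_json(gj, p("boundary.geojson"), auto_unbox = TRUE,
                       digits = NA)
  jsonlite::write_json(as.list(series$truth), p("station_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(layers = layer_paths, fill = p("sand_fill.asc"),
                 records = p("station_records.csv"),
                 coords = p("station_coords.csv"),
                 boundary = p("boundary.geojson"),
                 truth = p("station_truth.json")))
}
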