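test_that("random fields are deterministic, respect variance zero and caps", {
  spec <- mk_spec(12, 12, cell = 14.5)
  a <- gaussian_random_field(spec, 50, 100, 120, seed = 3)
  b <- gaussian_random_field(spec, 50, 100, 120, seed = 3)
  expect_identical(a$values, b$values)
  c <- gaussian_random_field(spec, 50, 100, 120, seed = 4)
  expect_false(identical(a$values, c$values))
  flat <- gaussian_random_field(spec, 42, 0, 120, seed = 3)
  expect_true(all(flat$values == 42))
  expect_error(gaussian_random_field(mk_spec(200, 200), 0, 1, 10, seed = 1,
                                     cell_cap = 10000L), "cap")
})

test_that("field simulation honors the exponential covariance at short lags", {
  # spatially flat comparison: mean empirical semivariance over 10 seeds
  # against the generating model's closed form, at lags within the
  # correlation length
  spec <- grid_spec(64L, 64L, 0, 640, 10)
  variance <- 4; L <- 120
  gammas <- NULL
  for (seed in 1:10) {
    f <- gaussian_random_field(spec, 0, variance, L, seed = seed)
    xs <- rep(cell_center_x(spec), each = 64)
    ys <- rep(cell_center_y(spec), times = 64)
    ev <- empirical_variogram(xs, ys, as.vector(f$values), n_lags = 8L,
                              max_dist = 120)
    gammas <- rbind(gammas, ev$gamma)
  }
  mean_gamma <- colMeans(gammas)
  lags <- empirical_variogram(rep(cell_center_x(spec), each = 64),
                              rep(cell_center_y(spec), times = 64),
                              rnorm(4096), n_lags = 8L, max_dist = 120)$lag
  truth <- variance * (1 - exp(-lags / L))
  expect_true(all(abs(mean_gamma - truth) / truth < 0.25))
})

test_that("soil layer generation controls holes, coupling and clipping", {
  cfg <- sim_config(seed = 9, spec = mk_spec(50, 50, cell = 14.5),
                    nodata_hole_fraction = 0.2)
  layers <- make_soil_layers(cfg)
  expect_length(layers, 4L)
  fr <- vapply(layers, function(l) mean(is.na(l$grid$values)), 0)
  expect_true(all(fr > 0.15 & fr < 0.25))
  # hole masks differ across layers
  expect_false(identical(is.na(layers[[1]]$grid$values),
                         is.na(layers[[2]]$grid$values)))
  cfg0 <- sim_config(seed = 9, spec = mk_spec(10, 10),
                     nodata_hole_fraction = 0, perturb_variance = 0,
                     layer_means = rep(60, 4))
  same <- make_soil_layers(cfg0)
  expect_identical(same[[1]]$grid$values, same[[4]]$grid$values)
  cfg_full <- sim_config(seed = 9, spec = mk_spec(10, 10),
                         nodata_hole_fraction = 0)
  expect_false(anyNA(make_soil_layers(cfg_full)[[1]]$grid$values))
})

test_that("station series have full cadence, spatial signal and exact truth", {
  cfg <- sim_config(seed = 13, spec = mk_spec(10, 10, cell = 14.5),
                    n_stations = 4L, noise_sd_c = 0,
                    window = season_window(years = 2019))
  ss <- make_station_series(cfg)
  expect_equal(nrow(ss$records), 4L * 92L * 96L)
  per_day <- table(format(ss$records$timestamp[
    ss$records$station_id == ss$coords$station_id[1]], "%Y-%m-%d"))
  expect_true(all(per_day == 96L))
  # noise-free: the pipeline summary equals the closed-form truth
  daily <- daily_maxima(ss$records, cfg$window, 96L)
  tab <- summarize_stations(daily, ss$coords)
  expect_equal(setNames(tab$mean_daily_max_c, tab$station_id),
               ss$truth[tab$station_id], tolerance = 1e-6)
  # determinism
  ss2 <- make_station_series(cfg)
  expect_identical(ss$records$temp_c, ss2$records$temp_c)
})

test_that("site placement respects the requested class mix or fails loudly", {
  cg <- classify_grid(mk_grid(matrix(10, 5, 5), cell = 10), classify_sand)
  s <- make_sites(cg, c(HIGH = 3L), seed = 1)
  expect_equal(nrow(s), 3L)
  expect_false(anyDuplicated(s[c("x", "y")]) > 0)
  expect_error(make_sites(cg, c(LOW = 1L), seed = 1), "only 0 cell")
  lab <- assign_site_risk(cg, s)
  expect_true(all(lab == s$known_label))
})

test_that("the simulate bundle is complete and readable by the pipeline", {
  d <- file.path(tempdir(), "bundle_test")
  unlink(d, recursive = TRUE)
  cfg <- sim_config(seed = 21, spec = mk_spec(8, 8, cell = 14.5),
                    n_stations = 3L, window = season_window(years = 2019))
  paths <- simulate_world(cfg, d)
  expect_true(all(file.exists(unlist(paths))))
  g <- read_raster(paths$layers[[1]])
  expect_true(specs_equal(g$spec, mk_spec(8, 8, cell = 14.5)))
  rec <- parse_station_records(paths$records)
  expect_gt(nrow(rec), 0L)
  truth <- jsonlite::read_json(paths$truth)
  expect_length(truth, 3L)
})
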