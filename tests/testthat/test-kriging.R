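test_that("kriging is exact at data points and honors symmetry", {
  vm <- variogram_model("spherical", nugget = 0, psill = 3, range_m = 50)
  x <- c(0, 10, 25); y <- c(0, 15, 5); z <- c(4, 9, 6)
  for (i in seq_along(x)) {
    k <- krige_point(x, y, z, vm, x[i], y[i])
    expect_equal(k$prediction, z[i], tolerance = 1e-10)
    expect_equal(k$variance, 0, tolerance = 1e-10)
  }
  # two stations symmetric about the target: weights 1/2, 1/2
  ks <- krige_point(c(-10, 10), c(0, 0), c(2, 8), vm, 0, 0)
  expect_equal(ks$weights, c(0.5, 0.5), tolerance = 1e-12)
  expect_equal(ks$prediction, 5)
})

test_that("constant fields reproduce and predictions are shift-equivariant", {
  vm <- variogram_model("exponential", nugget = 0.2, psill = 2, range_m = 30)
  set.seed(41)
  x <- runif(8, 0, 100); y <- runif(8, 0, 100); z <- rnorm(8, 10)
  kc <- krige_point(x, y, rep(7.5, 8), vm, 33, 61)
  expect_equal(kc$prediction, 7.5, tolerance = 1e-10)
  k1 <- krige_point(x, y, z, vm, 33, 61)
  k2 <- krige_point(x, y, z + 100, vm, 33, 61)
  expect_equal(k2$prediction, k1$prediction + 100, tolerance = 1e-8)
  expect_equal(k2$variance, k1$variance, tolerance = 1e-10)
  expect_equal(sum(k1$weights), 1, tolerance = 1e-10)
})

test_that("degenerate kriging systems raise named errors", {
  vm <- variogram_model("spherical", 0, 1, 10)
  expect_error(krige_point(c(0, 0), c(1, 1), c(1, 2), vm, 5, 5),
               "duplicate data locations")
  vm0 <- variogram_model("spherical", 0, 0, 10)  # gamma identically 0
  expect_error(krige_point(c(0, 10, 20), c(0, 0, 0), c(1, 2, 3), vm0, 5, 0),
               "singular")
})

test_that("grid kriging agrees with pointwise kriging and hits stations", {
  vm <- variogram_model("spherical", nugget = 0, psill = 2, range_m = 60)
  spec <- mk_spec(8, 8, cell = 10)
  # a station exactly on the center of cell (3, 4): x = 35, y = 55
  st <- data.frame(x = c(35, 11, 72), y = c(55, 70, 18),
                   mean_daily_max_c = c(21, 19, 24))
  kg <- krige_grid(st, vm, spec)
  expect_equal(kg$values[3, 4], 21, tolerance = 1e-9)
  for (cell in list(c(1, 1), c(5, 7), c(8, 2))) {
    x0 <- cell_center_x(spec)[cell[2]]; y0 <- cell_center_y(spec)[cell[1]]
    kp <- krige_point(st$x, st$y, st$mean_daily_max_c, vm, x0, y0)
    expect_equal(kg$values[cell[1], cell[2]], kp$prediction,
                 tolerance = 1e-10)
  }
  expect_false(anyNA(kg$values))
  # two stations, monotone model: grid bounded by the station values
  st2 <- st[1:2, ]
  kg2 <- krige_grid(st2, vm, spec)
  expect_gte(min(kg2$values), min(st2$mean_daily_max_c) - 1e-9)
  expect_lte(max(kg2$values), max(st2$mean_daily_max_c) + 1e-9)
})

test_that("near-duplicate stations are merged before kriging", {
  vm <- variogram_model("spherical", 0, 2, 60)
  spec <- mk_spec(4, 4, cell = 10)
  st <- data.frame(x = c(4.5, 5.5, 35), y = c(35, 35, 5),
                   mean_daily_max_c = c(20, 22, 24))
  expect_message(kg <- krige_grid(st, vm, spec), "averaged 1")
  # merged station lands exactly on the center of cell (1, 1): mean value 21
  expect_equal(kg$values[1, 1], 21, tolerance = 1e-9)
})

test_that("kriging beats the mean predictor on a simulated field", {
  spec <- mk_spec(30, 30, cell = 10)
  truth <- gaussian_random_field(spec, 20, 4, 80, seed = 99)
  set.seed(99)
  idx <- sample(900, 50)
  ri <- (idx - 1) %% 30 + 1; ci <- (idx - 1) %/% 30 + 1
  st <- data.frame(x = cell_center_x(spec)[ci], y = cell_center_y(spec)[ri],
                   mean_daily_max_c = truth$values[cbind(ri, ci)])
  emp <- empirical_variogram(st$x, st$y, st$mean_daily_max_c)
  vm <- fit_variogram(emp, "exponential")
  pred <- krige_grid(st, vm, spec)
  rmse <- sqrt(mean((pred$values - truth$values)^2))
  expect_lt(rmse, sd(truth$values))
})

test_that("leave-one-out cross-validation reports sane residuals", {
  spec <- mk_spec(10, 10, cell = 10)
  truth <- gaussian_random_field(spec, 20, 4, 100, seed = 7)
  st <- data.frame(station_id = sprintf("S%02d", 1:9),
                   x = rep(c(15, 50, 85), 3), y = rep(c(15, 50, 85), each = 3))
  st$mean_daily_max_c <- vapply(seq_len(9), function(i)
    sample_at_point(truth, st$x[i], st$y[i]), 0)
  vm <- variogram_model("exponential", 0.1, 4, 100)
  cv <- krige_loo(st, vm)
  expect_equal(nrow(cv), 9L)
  expect_true(is.finite(attr(cv, "rmse")))
  expect_lt(attr(cv, "rmse"), 3 * sd(st$mean_daily_max_c))
})
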