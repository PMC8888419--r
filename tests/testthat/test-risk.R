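test_that("sand thresholds classify with boundaries in the moderate class", {
  expect_equal(classify_sand(50), "HIGH")
  expect_equal(classify_sand(70), "MODERATE")
  expect_equal(classify_sand(90), "LOW")
  expect_equal(classify_sand(c(65, 80)), c("MODERATE", "MODERATE"))
  expect_equal(classify_sand(c(64.999, 80.001)), c("HIGH", "LOW"))
  expect_true(is.na(classify_sand(NA)))
  expect_error(classify_sand(101), "outside")
  expect_error(classify_sand(-1), "outside")
  # custom break points
  expect_equal(classify_sand(62, breaks = c(60, 80)), "MODERATE")
})

test_that("temperature band classifies inclusively with no moderate class", {
  expect_equal(classify_temp(22), "HIGH")
  expect_equal(classify_temp(30), "LOW")
  expect_equal(classify_temp(15), "LOW")
  expect_equal(classify_temp(c(18, 27)), c("HIGH", "HIGH"))
  expect_equal(classify_temp(c(17.999, 27.001)), c("LOW", "LOW"))
  expect_true(is.na(classify_temp(NA)))
  expect_setequal(risk_levels("temp"), c("HIGH", "LOW"))
})

test_that("the combination matrix reproduces all six rows exactly", {
  rows <- list(c("LOW", "LOW", "LOW"),
               c("LOW", "HIGH", "LOW"),
               c("MODERATE", "LOW", "MODERATE_LOW"),
               c("MODERATE", "HIGH", "MODERATE"),
               c("HIGH", "LOW", "HIGH_MODERATE"),
               c("HIGH", "HIGH", "HIGH"))
  for (r in rows)
    expect_equal(combine_risk(r[1], r[2]), r[3])
  # totality over the non-nodata input space
  grid <- expand.grid(s = risk_levels("sand"), t = risk_levels("temp"),
                      stringsAsFactors = FALSE)
  expect_false(anyNA(combine_risk(grid$s, grid$t)))
})

test_that("combined risk is monotone and sand-dominant", {
  ord <- function(l) match(l, risk_levels("combined"))
  for (t in c("LOW", "HIGH")) {
    cs <- combine_risk(c("LOW", "MODERATE", "HIGH"), rep(t, 3))
    expect_true(all(diff(ord(cs)) > 0))
  }
  for (s in c("MODERATE", "HIGH"))
    expect_gt(ord(combine_risk(s, "HIGH")), ord(combine_risk(s, "LOW")))
  expect_equal(combine_risk("LOW", "HIGH"), combine_risk("LOW", "LOW"))
})

test_that("nodata policy controls combination with missing inputs", {
  expect_true(is.na(combine_risk(NA, "HIGH")))
  expect_true(is.na(combine_risk(NA, "HIGH", "passthrough_sand")))
  expect_true(is.na(combine_risk("HIGH", NA)))
  expect_equal(combine_risk("HIGH", NA, "passthrough_sand"), "HIGH")
  expect_equal(combine_risk("MODERATE", NA, "passthrough_sand"), "MODERATE")
})

test_that("grid classification applies per pixel and preserves nodata", {
  g <- mk_grid(matrix(c(50, 90, 70, NA), 2, 2))
  cg <- classify_grid(g, classify_sand)
  lg <- attr(cg, "legend")
  expect_equal(names(lg)[cg$values[1, 1]], "HIGH")
  expect_equal(names(lg)[cg$values[1, 2]], "MODERATE")
  expect_equal(names(lg)[cg$values[2, 1]], "LOW")
  expect_true(is.na(cg$values[2, 2]))
  allna <- classify_grid(mk_grid(matrix(NA_real_, 2, 2)), classify_sand)
  expect_true(all(is.na(allna$values)))
  const <- classify_grid(mk_grid(matrix(10, 3, 3)), classify_sand)
  expect_true(all(const$values == lg[["HIGH"]]))
})

test_that("grid combination enumerates the matrix and respects nodata", {
  sand <- classify_grid(mk_grid(matrix(c(50, 50, 70, 90), 2, 2)),
                        classify_sand)
  temp <- classify_grid(mk_grid(matrix(c(22, 30, 22, 30), 2, 2)),
                        classify_temp)
  comb <- combine_grids(sand, temp)
  lg <- attr(comb, "legend")
  expect_equal(names(lg)[comb$values[1, 1]], "HIGH")
  expect_equal(names(lg)[comb$values[2, 1]], "HIGH_MODERATE")
  expect_equal(names(lg)[comb$values[1, 2]], "MODERATE")
  expect_equal(names(lg)[comb$values[2, 2]], "LOW")
  # sand nodata dominates irrespective of temperature
  sand_na <- classify_grid(mk_grid(matrix(NA_real_, 2, 2)), classify_sand)
  comb_na <- combine_grids(sand_na, temp)
  expect_true(all(is.na(comb_na$values)))
  expect_error(combine_grids(sand, classify_grid(mk_grid(matrix(20, 3, 3)),
                                                 classify_temp)),
               "specs differ")
})

test_that("classification commutes with polygon clipping", {
  set.seed(51)
  g <- mk_grid(matrix(runif(36, 0, 100), 6, 6), cell = 10)
  half <- rbind(c(0, 0), c(30, 0), c(30, 60), c(0, 60), c(0, 0))
  a <- classify_grid(clip_to_polygon(g, half), classify_sand)
  b <- clip_to_polygon(classify_grid(g, classify_sand), half)
  expect_identical(a$values, b$values)
})

test_that("area summaries count cells and normalize over classified area", {
  cg <- classify_grid(mk_grid(matrix(c(10, 10, 10, 90), 2, 2)),
                      classify_sand)
  a <- area_summary(cg)
  expect_equal(unname(a$fractions[["HIGH"]]), 0.75)
  expect_equal(unname(a$fractions[["LOW"]]), 0.25)
  expect_equal(sum(a$fractions), 1)
  one <- area_summary(classify_grid(mk_grid(matrix(90, 2, 2)),
                                    classify_sand))
  expect_equal(unname(one$fractions[["LOW"]]), 1)
  set.seed(52)
  rg <- classify_grid(mk_grid(matrix(runif(100, 0, 100), 10, 10)),
                      classify_sand)
  expect_equal(sum(area_summary(rg)$fractions), 1, tolerance = 1e-9)
  # fractions are invariant under translating the grid origin
  shifted <- grid_new(grid_spec(10, 10, 5000, 9000, 10), rg$values)
  attr(shifted, "legend") <- attr(rg, "legend")
  expect_equal(area_summary(shifted)$fractions, area_summary(rg)$fractions)
  expect_error(area_summary(classify_grid(mk_grid(matrix(NA_real_, 2, 2)),
                                          classify_sand)),
               "no classified cells")
})
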