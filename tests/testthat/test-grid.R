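test_that("ASCII and GeoTIFF round trips preserve spec, values and nodata", {
  set.seed(101)
  m <- matrix(rnorm(9, 50, 10), 3, 3)
  m[2, 2] <- NA
  g <- mk_grid(m, cell = 14.5)  # CRS tag survives both formats
                                # (ASCII via the .prj sidecar)
  for (fmt in c("ascii", "geotiff")) {
    p <- tempfile(fileext = if (fmt == "ascii") ".asc" else ".tif")
    write_raster(g, p, fmt)
    g2 <- read_raster(p)
    expect_true(specs_equal(g$spec, g2$spec))
    expect_identical(is.na(g$values), is.na(g2$values))
    expect_lt(max(abs(g$values - g2$values), na.rm = TRUE), 1e-6)
    expect_equal(g2$nodata, g$nodata)
  }
})

test_that("integer rasters round trip bit-exact and all-nodata survives", {
  gi <- mk_grid(matrix(c(1, 2, 3, 4000), 2, 2))
  for (fmt in c("ascii", "geotiff")) {
    p <- tempfile()
    write_raster(gi, p, fmt)
    expect_identical(read_raster(p)$values, gi$values)
  }
  gn <- mk_grid(matrix(NA_real_, 2, 2))
  p <- tempfile()
  write_raster(gn, p, "ascii")
  expect_true(all(is.na(read_raster(p)$values)))
})

test_that("ASCII nodata sentinel maps to NA and headers parse", {
  p <- tempfile(fileext = ".asc")
  writeLines(c("NCOLS 2", "NROWS 2", "XLLCORNER 100", "YLLCORNER 200",
               "CELLSIZE 5", "NODATA_value -9999",
               "1 -9999", "3 4"), p)
  g <- read_raster(p)
  expect_true(is.na(g$values[1, 2]))
  expect_equal(g$values[2, 2], 4)
  expect_equal(g$spec$x_origin, 100)
  expect_equal(g$spec$y_origin, 200 + 2 * 5)  # north edge
})

test_that("malformed rasters raise named errors", {
  p <- tempfile(fileext = ".asc")
  writeLines(c("NCOLS 2", "NROWS 1", "XLLCORNER 0", "YLLCORNER 0",
               "DX 10", "DY 5", "1 2"), p)
  expect_error(read_raster(p), "non-square cells")
  expect_error(read_raster(tempfile()), "not found")
  # corrupt a valid GeoTIFF into a 2-band file: patch SamplesPerPixel (277)
  p2 <- tempfile(fileext = ".tif")
  write_raster(mk_grid(matrix(1:4, 2, 2)), p2, "geotiff")
  raw <- readBin(p2, "raw", file.size(p2))
  tag <- as.raw(c(0x15, 0x01, 0x03, 0x00))  # tag 277, type SHORT, LE
  hit <- which(vapply(seq_len(length(raw) - 3L), function(i)
    identical(raw[i:(i + 3L)], tag), TRUE))[1]
  raw[hit + 8L] <- as.raw(2L)  # count stays 1, value field -> 2
  writeBin(raw, p2)
  expect_error(read_raster(p2), "multi-band")
  # non-square pixel scale
  p3 <- tempfile(fileext = ".tif")
  write_raster(mk_grid(matrix(1:4, 2, 2), cell = 10), p3, "geotiff")
  raw3 <- readBin(p3, "raw", file.size(p3))
  # ModelPixelScale doubles live in the overflow area; scale y (2nd double)
  sc <- writeBin(10, raw(), size = 8L, endian = "little")
  hits <- which(vapply(seq_len(length(raw3) - 7L), function(i)
    identical(raw3[i:(i + 7L)], sc), TRUE))
  raw3[hits[2]:(hits[2] + 7L)] <- writeBin(5, raw(), size = 8L,
                                           endian = "little")
  writeBin(raw3, p3)
  expect_error(read_raster(p3), "non-square cells")
})

test_that("nearest resampling honors constants, refinement and idempotence", {
  g <- mk_grid(matrix(40, 3, 3), cell = 29)
  r <- resample(g, 14.5, "nearest")
  expect_equal(r$spec$n_rows, 6L)
  expect_true(all(r$values == 40))
  g1 <- mk_grid(matrix(7, 1, 1), cell = 10)
  r1 <- resample(g1, 5, "nearest")
  expect_equal(dim(r1$values), c(2L, 2L))
  expect_true(all(r1$values == 7))
  set.seed(7)
  g2 <- mk_grid(matrix(runif(25), 5, 5))
  expect_equal(resample(g2, g2$spec$cell_size, "nearest")$values, g2$values)
})

test_that("bilinear resampling interpolates linearly and stays in range", {
  # two cells valued 0 and 10; output cell centered midway between centers
  g <- mk_grid(matrix(c(0, 10), 1, 2), cell = 10)
  r <- resample(g, 5, "bilinear")  # 1x2 -> 2x4; centers at 2.5,7.5,12.5,17.5
  # input centers at x=5 and 15; output center x=7.5 is 1/4 of the way
  expect_equal(r$values[1, 2], 0 + 10 * 0.25)
  mid <- resample(g, 4, "bilinear")  # center x=10 lands midway
  expect_equal(mid$values[1, 3], 5, tolerance = 1e-12)
  set.seed(8)
  g2 <- mk_grid(matrix(runif(36, 20, 60), 6, 6))
  r2 <- resample(g2, 3.7, "bilinear")
  expect_gte(min(r2$values), min(g2$values))
  expect_lte(max(r2$values), max(g2$values))
})

test_that("bilinear resampling propagates nodata conservatively", {
  m <- matrix(50, 4, 4); m[2, 2] <- NA
  g <- mk_grid(m, cell = 10)
  r <- resample(g, 5, "bilinear")
  # any output cell drawing on the nodata center must be nodata
  expect_true(any(is.na(r$values)))
  # cells far from the hole are untouched
  expect_equal(r$values[8, 8], 50)
  # and nowhere does interpolation invent a value where all inputs were NA
  gnn <- resample(mk_grid(matrix(NA_real_, 2, 2)), 5, "bilinear")
  expect_true(all(is.na(gnn$values)))
})

test_that("point sampling uses nearest center with deterministic ties", {
  m <- matrix(1:16, 4, 4)
  g <- mk_grid(m, cell = 10)  # centers at 5,15,25,35; y0 = 40
  expect_equal(sample_at_point(g, 5, 35), m[1, 1])
  expect_equal(sample_at_point(g, 5 + 4, 35), m[1, 1])  # 0.4 cell east
  m2 <- m; m2[2, 2] <- NA
  g2 <- mk_grid(m2, cell = 10)
  expect_true(is.na(sample_at_point(g2, 15, 25)))
  expect_error(sample_at_point(g, 1000, 35), "outside grid extent")
  # tie on the vertical boundary between cols 1 and 2 -> smaller column
  expect_equal(sample_at_point(g, 10, 35), m[1, 1])
  # tie on the horizontal boundary between rows 1 and 2 -> smaller row
  expect_equal(sample_at_point(g, 5, 30), m[1, 1])
})
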