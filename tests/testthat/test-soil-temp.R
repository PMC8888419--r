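write_records <- function(df) {
  p <- tempfile(fileext = ".csv")
  write.csv(df, p, row.names = FALSE)
  p
}

test_that("station record parsing drops bad rows and requires columns", {
  p <- write_records(data.frame(
    station_id = c("A", "A", "A", "B"),
    timestamp = c("2019-06-01T00:00:00", "2019-06-01T00:15:00",
                  "not-a-time", "2019-06-01T00:00:00"),
    soil_temp_c = c("20.1", "NA", "21.0", "19.5")))
  expect_message(r <- parse_station_records(p), "dropped 2")
  expect_equal(nrow(r), 2L)
  expect_equal(attr(r, "n_dropped"), 2L)
  expect_s3_class(r$timestamp, "POSIXct")
  p2 <- write_records(data.frame(station_id = "A", soil_temp_c = 20))
  expect_error(parse_station_records(p2), "timestamp")
})

test_that("window day counts follow the calendar", {
  w <- season_window(c(6, 1), c(8, 31), years = 2010:2021)
  expect_true(all(vapply(2010:2021, function(y) window_days(w, y), 0L) == 92L))
  w1 <- season_window(c(6, 1), c(6, 1), years = 2015)
  expect_equal(window_days(w1, 2015), 1L)
  wf <- season_window(c(2, 1), c(2, 28), years = 2021)
  expect_equal(window_days(wf, 2021), 28L)
  expect_error(season_window(c(9, 1), c(8, 31), years = 2020), "start")
  expect_error(window_days(w1, 2016), "not in window")
})

mk_day <- function(station, date, temps, step_min = 15) {
  n <- length(temps)
  data.frame(station_id = station,
             timestamp = as.POSIXct(date, tz = "UTC") +
               seq(0, by = step_min * 60, length.out = n),
             temp_c = temps)
}

test_that("daily maxima respect the window and completeness rule", {
  w <- season_window(years = 2019)
  rec <- rbind(mk_day("A", "2019-06-10", c(10, 12, 15, 11)),
               mk_day("A", "2019-09-01", c(30, 31, 32, 30)))
  d <- daily_maxima(rec, w, min_records_per_day = 1L)
  expect_equal(nrow(d), 1L)
  expect_equal(d$max_c, 15)
  expect_equal(as.character(d$date), "2019-06-10")
  # 40 of 96 readings with a 48-reading floor -> omitted
  rec2 <- mk_day("A", "2019-06-11", rnorm(40, 20))
  expect_message(d2 <- daily_maxima(rec2, w, min_records_per_day = 48L),
                 "omitted 1")
  expect_equal(nrow(d2), 0L)
})

test_that("station summaries average daily maxima and flag empty stations", {
  w <- season_window(years = 2019)
  rec <- rbind(mk_day("A", "2019-06-10", c(8, 10)),
               mk_day("A", "2019-06-11", c(25, 30)))
  d <- daily_maxima(rec, w, min_records_per_day = 1L)
  s <- summarize_station(d, "A", 10, 20)
  expect_equal(s$mean_daily_max_c, 20)  # mean(10, 30)
  expect_equal(s$n_days_used, 2L)
  expect_error(summarize_station(d, "B", 0, 0), "insufficient data")
  coords <- data.frame(station_id = c("A", "B"), x = c(10, 99), y = c(20, 99))
  expect_message(tab <- summarize_stations(d, coords), "excluded 1")
  expect_equal(nrow(tab), 1L)
})

test_that("records outside the window never change a summary", {
  w <- season_window(years = 2019)
  rec <- mk_day("A", "2019-07-01", c(18, 22, 19))
  base <- summarize_station(daily_maxima(rec, w, 1L), "A", 0, 0)
  noisy <- rbind(rec,
                 mk_day("A", "2019-05-31", c(99, 99)),
                 mk_day("A", "2020-07-01", c(99, 99)),  # year not in window
                 mk_day("A", "2019-09-01", c(99, 99)))
  with_extra <- summarize_station(daily_maxima(noisy, w, 1L), "A", 0, 0)
  expect_equal(with_extra, base)
})

test_that("a noise-free diurnal sinusoid yields mean daily max m + a", {
  m <- 21; a <- 5
  w <- season_window(years = 2019)
  days <- seq(as.Date("2019-06-01"), as.Date("2019-06-07"), by = "day")
  rec <- do.call(rbind, lapply(as.character(days), function(d) {
    minutes <- seq(0, 1425, by = 15)
    mk_day("A", d, m + a * sin(2 * pi * minutes / 1440))
  }))
  s <- summarize_station(daily_maxima(rec, w, 96L), "A", 0, 0)
  expect_equal(s$mean_daily_max_c, m + a, tolerance = 1e-6)
  expect_equal(s$n_days_used, 7L)
  # the summary is bounded by the extreme daily maxima
  d <- daily_maxima(rec, w, 1L)
  expect_gte(s$mean_daily_max_c, min(d$max_c))
  expect_lte(s$mean_daily_max_c, max(d$max_c))
})
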