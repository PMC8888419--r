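#' Define a seasonal analysis window
#'
#' The season over which station soil temperatures are summarized: a
#' month-day range applied to each listed calendar year. The default is
#' June 1 through August 31 — the period when soil temperature most
#' influences phylloxera development rate.
#'
#' @param start_month_day,end_month_day integer vectors `c(month, day)`;
#'   start must not follow end within a year.
#' @param years calendar years to include (non-empty).
#' @return an object of class `season_window`.
#' @export
season_window <- function(start_month_day = c(6L, 1L),
                          end_month_day = c(8L, 31L),
                          years) {
  if (length(years) < 1L) stop("season_window: years must be non-empty")
  s <- as.integer(start_month_day); e <- as.integer(end_month_day)
  if (length(s) != 2L || length(e) != 2L)
    stop("season_window: month-day bounds must be c(month, day)")
  if (s[1] > e[1] || (s[1] == e[1] && s[2] > e[2]))
    stop("season_window: start must not follow end within a year")
  structure(list(start = s, end = e, years = as.integer(sort(years))),
            class = "season_window")
}

#' Count the days in one year's window
#'
#' Inclusive day count from the window start to the window end in the
#' given year; June 1 to August 31 gives 92 in every year.
#'
#' @param window a [season_window()].
#' @param year a calendar year listed in the window.
#' @return integer day count.
#' @export
window_days <- function(window, year) {
  stopifnot(inherits(window, "season_window"))
  if (!year %in% window$years)
    stop(sprintf("window_days: year %d not in window", year))
  d0 <- as.Date(sprintf("%04d-%02d-%02d", year, window$start[1],
                        window$start[2]))
  d1 <- as.Date(sprintf("%04d-%02d-%02d", year, window$end[1],
                        window$end[2]))
  as.integer(d1 - d0) + 1L
}

#' Parse a station soil-temperature record file
#'
#' Reads a comma-delimited file with header columns `station_id`,
#' `timestamp` (ISO-8601, local standard time taken at face value) and
#' `soil_temp_c` (deg C at 20.32 cm depth, 15-minute cadence). Rows with an
#' unparseable timestamp or a non-numeric temperature are dropped; the
#' number dropped is reported via [message()] and attached as attribute
#' `n_dropped`.
#'
#' @param path path to the delimited file.
#' @return a data frame with columns `station_id` (character), `timestamp`
#'   (POSIXct, UTC-tagged clock time) and `temp_c` (numeric).
#' @export
parse_station_records <- function(path) {
  raw <- utils::read.csv(path, colClasses = "character")
  need <- c("station_id", "timestamp", "soil_temp_c")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop(sprintf("parse_station_records: missing required column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  ts <- as.POSIXct(rep(NA_real_, nrow(raw)), origin = "1970-01-01",
                   tz = "UTC")
  for (fmt in c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S", "%Y-%m-%dT%H:%M",
                "%Y-%m-%d %H:%M", "%Y-%m-%d")) {
    miss <- is.na(ts)
    if (!any(miss)) break
    ts[miss] <- as.POSIXct(strptime(raw$timestamp[miss], fmt, tz = "UTC"))
  }
  temp <- suppressWarnings(as.numeric(raw$soil_temp_c))
  ok <- !is.na(ts) & !is.na(temp)
  n_dropped <- sum(!ok)
  if (n_dropped > 0L)
    message(sprintf("parse_station_records: dropped %d of %d row(s) with %s",
                    n_dropped, nrow(raw),
                    "unparseable timestamp or non-numeric temperature"))
  out <- data.frame(station_id = raw$station_id[ok], timestamp = ts[ok],
                    temp_c = temp[ok], stringsAsFactors = FALSE)
  attr(out, "n_dropped") <- n_dropped
  out
}

# month-day inside window test for a Date vector
in_window <- function(dates, window) {
  y <- as.integer(format(dates, "%Y"))
  md <- 100L * as.integer(format(dates, "%m")) + as.integer(format(dates, "%d"))
  s <- 100L * window$start[1] + window$start[2]
  e <- 100L * window$end[1] + window$end[2]
  (y %in% window$years) & md >= s & md <= e
}

#' Daily maximum temperatures inside a season window
#'
#' For each station-day falling inside the window, the maximum of that
#' day's readings — provided the day has at least `min_records_per_day`
#' readings. The daily maximum (rather than the daily mean) is the summary
#' of record because stations over irrigated surfaces run intermittently
#' cool, and means would understate the temperatures vineyard soils reach.
#' Days failing the completeness check are omitted and counted in a
#' message. Day boundaries are local midnight, timestamps at face value.
#'
#' @param records data frame from [parse_station_records()].
#' @param window a [season_window()].
#' @param min_records_per_day completeness threshold; the default 48 is
#'   half the 96 readings a full day of 15-minute logging yields.
#' @return data frame with columns `station_id`, `date`, `max_c`,
#'   `n_records`, one row per retained station-day.
#' @export
daily_maxima <- function(records, window, min_records_per_day = 48L) {
  stopifnot(inherits(window, "season_window"))
  if (min_records_per_day < 1L)
    stop("daily_maxima: min_records_per_day must be >= 1")
  dates <- as.Date(records$timestamp, tz = "UTC")
  keep <- in_window(dates, window)
  r <- records[keep, , drop = FALSE]
  if (nrow(r) == 0L)
    return(data.frame(station_id = character(), date = as.Date(character()),
                      max_c = numeric(), n_records = integer()))
  key <- interaction(r$station_id, dates[keep], drop = TRUE)
  agg <- data.frame(
    station_id = tapply(r$station_id, key, `[`, 1L),
    date = as.Date(tapply(as.character(dates[keep]), key, `[`, 1L)),
    max_c = as.numeric(tapply(r$temp_c, key, max)),
    n_records = as.integer(tapply(r$temp_c, key, length)),
    row.names = NULL, stringsAsFactors = FALSE)
  incomplete <- agg$n_records < min_records_per_day
  if (any(incomplete))
    message(sprintf(
      "daily_maxima: omitted %d station-day(s) with < %d records",
      sum(incomplete), min_records_per_day))
  agg[!incomplete, , drop = FALSE]
}

#' Summarize one station's daily maxima to a seasonal mean
#'
#' The station's scalar kriging input: the arithmetic mean of its daily
#' maximum temperatures pooled across every window day of every year (no
#' per-year balancing — years with fewer retained days simply contribute
#' fewer terms).
#'
#' @param daily data frame from [daily_maxima()].
#' @param station_id the station to summarize.
#' @param x,y station coordinates (m, projected).
#' @return a one-row data frame with `station_id`, `x`, `y`,
#'   `mean_daily_max_c`, `n_days_used`.
#' @export
summarize_station <- function(daily, station_id, x, y) {
  d <- daily[daily$station_id == station_id, , drop = FALSE]
  if (nrow(d) == 0L)
    stop(sprintf(
      "summarize_station: insufficient data: station '%s' has no retained days",
      station_id), call. = FALSE)
  data.frame(station_id = station_id, x = as.numeric(x), y = as.numeric(y),
             mean_daily_max_c = mean(d$max_c), n_days_used = nrow(d),
             stringsAsFactors = FALSE)
}

#' Summarize all stations with coordinates
#'
#' Applies [summarize_station()] to every station present in both the
#' daily-maxima table and the coordinate table. Stations with zero retained
#' days are excluded (not imputed) and reported via [message()].
#'
#' @param daily data frame from [daily_maxima()].
#' @param coords data frame with columns `station_id`, `x`, `y`.
#' @return station summary table, one row per retained station.
#' @export
summarize_stations <- function(daily, coords) {
  need <- c("station_id", "x", "y")
  if (!all(need %in% names(coords)))
    stop("summarize_stations: coords needs columns station_id, x, y")
  have <- intersect(coords$station_id, unique(daily$station_id))
  lost <- setdiff(coords$station_id, have)
  if (length(lost))
    message(sprintf("summarize_stations: excluded %d station(s) with no retained days: %s",
                    length(lost), paste(lost, collapse = ", ")))
  if (length(have) == 0L)
    stop("summarize_stations: no station has retained days", call. = FALSE)
  out <- do.call(rbind, lapply(have, function(s) {
    i <- match(s, coords$station_id)
    summarize_station(daily, s, coords$x[i], coords$y[i])
  }))
  rownames(out) <- NULL
  out
}
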