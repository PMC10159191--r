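# Diel, tidal, lunar, seasonal and environmental annotation of detections
# and visits.

#' Diel window
#'
#' Local clock times delimiting day and night. The default (07:00 / 19:00)
#' is the rounded mean sunrise/sunset over the 2017-2019 study window at
#' Sebastian, FL; regenerate with [derive_diel_window()] for other sites.
#'
#' @param day_start,night_start Local clock times, `"HH:MM:SS"` strings.
#' @param tz Olson timezone the clock times refer to.
#' @return A `diel_window` list.
#' @export
diel_window <- function(day_start = "07:00:00", night_start = "19:00:00",
                        tz = "America/New_York") {
  stopifnot(day_start != night_start)
  structure(list(day_start = day_start, night_start = night_start, tz = tz),
            class = "diel_window")
}

clock_seconds <- function(hms) {
  p <- as.numeric(strsplit(hms, ":", fixed = TRUE)[[1]])
  sum(p * c(3600, 60, 1)[seq_along(p)])
}

#' Classify instants as day or night
#'
#' Day is the half-open local-clock interval `[day_start, night_start)`;
#' everything else is night. With the defaults this reproduces the
#' 0700-1859 day / 1900-0659 night split.
#'
#' @param t `POSIXct` vector.
#' @param w A [diel_window()].
#' @return Character vector, `"day"` or `"night"`.
#' @export
classify_diel <- function(t, w = diel_window()) {
  stopifnot(inherits(t, "POSIXct"))
  lt <- lubridate::with_tz(t, w$tz)
  secs <- lubridate::hour(lt) * 3600 + lubridate::minute(lt) * 60 +
    lubridate::second(lt)
  d0 <- clock_seconds(w$day_start)
  n0 <- clock_seconds(w$night_start)
  if (d0 < n0) {
    ifelse(secs >= d0 & secs < n0, "day", "night")
  } else {
    ifelse(secs >= d0 | secs < n0, "day", "night")
  }
}

#' Derive a diel window from mean sunrise and sunset
#'
#' Averages local-clock sunrise and sunset over a date range and rounds
#' each to the nearest hour, mirroring how fixed day/night windows are set
#' from mean sun times over a study period.
#'
#' @param lat,lon Location in decimal degrees.
#' @param dates `Date` vector (e.g. `seq(start, end, by = "day")`).
#' @param tz Local timezone for the clock times.
#' @return A [diel_window()].
#' @export
derive_diel_window <- function(lat, lon, dates, tz = "America/New_York") {
  stopifnot(length(dates) >= 1)
  st <- sun_times(dates, lat, lon)
  local_hour <- function(t) {
    lt <- lubridate::with_tz(t, tz)
    lubridate::hour(lt) + lubridate::minute(lt) / 60 + lubridate::second(lt) / 3600
  }
  rise <- round(mean(local_hour(st$sunrise))) %% 24
  set <- round(mean(local_hour(st$sunset))) %% 24
  diel_window(sprintf("%02d:00:00", rise), sprintf("%02d:00:00", set), tz = tz)
}

#' Tidal rate of movement
#'
#' Speed at which the tidal phase propagates between two locations:
#' `TRM = d / delta_t`. The study defaults (d = 3698 m between the inlet
#' and river-mouth stations, delta_t = 2 h 20 min) give 0.4402 m/s.
#'
#' @param d_m Distance between the two tide stations, metres.
#' @param delta_t_s Tidal lag between them, seconds.
#' @return Metres per second.
#' @export
compute_trm <- function(d_m = 3698, delta_t_s = 8400) {
  stopifnot(d_m >= 0)
  if (delta_t_s <= 0) stop("delta_t_s must be positive")
  d_m / delta_t_s
}

#' Tide lag offset for a receiver
#'
#' Time for the tidal phase to cover `distance_m` at the given tidal rate
#' of movement; a receiver's tide series is the reference prediction
#' shifted by this lag.
#'
#' @param distance_m Distance from the reference tide station, metres.
#' @param trm Tidal rate of movement, m/s (see [compute_trm()]).
#' @return Seconds.
#' @export
tide_offset <- function(distance_m, trm) {
  if (any(trm <= 0)) stop("trm must be positive")
  stopifnot(all(distance_m >= 0))
  distance_m / trm
}

#' Per-receiver tide lags from array geometry
#'
#' Great-circle distance from each receiver to the reference station,
#' converted to a lag via the tidal rate of movement.
#'
#' @param receivers Receiver tibble with `latitude`, `longitude`.
#' @param reference_id `receiver_id` of the reference tide station.
#' @param trm Tidal rate of movement, m/s.
#' @return `receivers` with `distance_to_reference_m` and `tide_lag_s` added.
#' @export
receiver_tide_lags <- function(receivers, reference_id = "SINJ",
                               trm = compute_trm()) {
  ref <- receivers[receivers$receiver_id == reference_id, ]
  if (nrow(ref) != 1) stop("reference receiver not found: ", reference_id)
  d <- geosphere::distGeo(
    cbind(receivers$longitude, receivers$latitude),
    c(ref$longitude, ref$latitude)
  )
  receivers$distance_to_reference_m <- d
  receivers$tide_lag_s <- tide_offset(d, trm)
  receivers
}

#' Assign tide state from predicted extrema
#'
#' Shifts each instant back by the receiver's tide lag, locates it between
#' the bracketing predicted extrema, and discretizes with a symmetric
#' slack-band rule: within 1/8 of a full tidal cycle of a high (low)
#' extremum the state is `High` (`Low`); otherwise the rising limb is
#' `Incoming` and the falling limb `Outgoing`. Over a uniform cycle the
#' four states each occupy a quarter of the time.
#'
#' @param t `POSIXct` vector.
#' @param extrema Tibble of tide predictions: `timestamp` (`POSIXct`),
#'   `type` (`"H"` or `"L"`, strictly alternating).
#' @param lag_s Tide lag to subtract from `t`, seconds (scalar or vector).
#' @param band Slack-band half-width as a fraction of the full cycle
#'   (default 1/8).
#' @return Character vector: `"High"`, `"Incoming"`, `"Low"`, `"Outgoing"`.
#' @export
assign_tide_state <- function(t, extrema, lag_s = 0, band = 1 / 8) {
  stopifnot(inherits(t, "POSIXct"), all(extrema$type %in% c("H", "L")))
  ord <- order(extrema$timestamp)
  ex_t <- as.numeric(extrema$timestamp)[ord]
  ex_k <- extrema$type[ord]
  if (any(ex_k[-1] == ex_k[-length(ex_k)])) {
    stop("tide extrema must alternate between H and L")
  }
  tp <- as.numeric(t) - lag_s
  i <- findInterval(tp, ex_t)
  at_last <- tp == ex_t[length(ex_t)]
  i[at_last] <- length(ex_t) - 1
  if (any(i < 1 | i >= length(ex_t))) {
    stop("instant (after lag) falls outside tide extrema coverage")
  }
  t1 <- ex_t[i]; t2 <- ex_t[i + 1]
  half <- t2 - t1                      # half tidal cycle
  slack <- 2 * half * band             # band half-width in seconds
  k1 <- ex_k[i]; k2 <- ex_k[i + 1]
  state <- ifelse(tp - t1 <= slack, ifelse(k1 == "H", "High", "Low"),
           ifelse(t2 - tp <= slack, ifelse(k2 == "H", "High", "Low"),
           ifelse(k2 == "H", "Incoming", "Outgoing")))
  state
}

# Astronomical season boundaries (UTC dates): vernal equinox, summer
# solstice, autumnal equinox, winter solstice.
season_boundaries <- function() {
  b <- rbind(
    c(2016, "2016-03-20", "2016-06-20", "2016-09-22", "2016-12-21"),
    c(2017, "2017-03-20", "2017-06-21", "2017-09-22", "2017-12-21"),
    c(2018, "2018-03-20", "2018-06-21", "2018-09-23", "2018-12-21"),
    c(2019, "2019-03-20", "2019-06-21", "2019-09-23", "2019-12-22"),
    c(2020, "2020-03-20", "2020-06-20", "2020-09-22", "2020-12-21")
  )
  tibble::tibble(
    date = as.Date(as.vector(t(b[, 2:5]))),
    season = rep(c("spring", "summer", "fall", "winter"), nrow(b))
  )
}

#' Assign astronomical season
#'
#' Seasons run between the tabulated equinoxes and solstices (2016-2020):
#' spring starts at the vernal equinox, summer at the summer solstice,
#' fall at the autumnal equinox, winter at the winter solstice.
#'
#' @param d `Date` vector.
#' @return Character vector of seasons.
#' @export
assign_season <- function(d) {
  d <- as.Date(d)
  sb <- season_boundaries()
  i <- findInterval(d, sb$date)
  if (any(i < 1)) stop("date precedes tabulated season boundaries")
  sb$season[i]
}

#' Assign study year
#'
#' Study years run June through May: with the defaults, Y1 spans
#' 2017-06-01 to 2018-05-31 and Y2 spans 2018-06-01 to 2019-05-31.
#'
#' @param d `Date` vector.
#' @param start First day of study year 1.
#' @param years Number of study years.
#' @return Character vector (`"Y1"`, `"Y2"`, ...).
#' @export
assign_study_year <- function(d, start = as.Date("2017-06-01"), years = 2) {
  d <- as.Date(d)
  starts <- seq(start, by = "year", length.out = years + 1)
  i <- findInterval(d, starts)
  if (any(i < 1 | i > years)) stop("date outside the study years")
  paste0("Y", i)
}

#' Read tide-prediction extrema
#'
#' CSV with columns `timestamp` (ISO-8601 UTC) and `type` (`H`/`L`).
#'
#' @param path CSV path.
#' @return Tibble sorted by time.
#' @export
read_tides <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("timestamp", "type") %in% names(x)))
  x$timestamp <- lubridate::ymd_hms(x$timestamp, tz = "UTC")
  dplyr::arrange(tibble::as_tibble(x), .data$timestamp)
}

#' Read an environmental time series
#'
#' CSV with `timestamp` (ISO-8601 UTC) and water-quality columns
#' (`water_temp_c`, `salinity`, `do_mg_l`, `o2_sat_pct`).
#'
#' @param path CSV path.
#' @return Tibble sorted by time.
#' @export
read_env <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot("timestamp" %in% names(x))
  x$timestamp <- lubridate::ymd_hms(x$timestamp, tz = "UTC")
  dplyr::arrange(tibble::as_tibble(x), .data$timestamp)
}

# nearest-timestamp join of env values onto times, NA beyond tolerance
nearest_env <- function(times, env, tolerance_s) {
  et <- as.numeric(env$timestamp)
  tt <- as.numeric(times)
  i <- findInterval(tt, et)
  lo <- pmax(i, 1)
  hi <- pmin(i + 1, length(et))
  pick <- ifelse(abs(tt - et[lo]) <= abs(et[hi] - tt), lo, hi)
  ok <- abs(tt - et[pick]) <= tolerance_s
  out <- env[pick, setdiff(names(env), "timestamp"), drop = FALSE]
  out[!ok, ] <- NA
  out
}

#' Local decimal hour of day
#'
#' @param t `POSIXct` vector.
#' @param tz Local timezone.
#' @return Numeric in `[0, 24)`.
#' @export
decimal_hour <- function(t, tz = "America/New_York") {
  lt <- lubridate::with_tz(t, tz)
  lubridate::hour(lt) + lubridate::minute(lt) / 60 + lubridate::second(lt) / 3600
}

#' Annotate visits with diel, tidal, lunar and environmental covariates
#'
#' Joins each visit (at its start time) to: diel class and decimal hour in
#' the local timezone, illuminated moon fraction, tide state (via the
#' receiver's tide lag), season, study year, receiver `general_location`,
#' and the nearest environmental record within `env_tolerance_min` minutes.
#' Visits with no environmental match keep `NA` covariates; the number is
#' reported via a message so the caller can track modelling exclusions.
#'
#' @param visits Visit tibble (see [extract_visits()]).
#' @param receivers Receiver tibble, ideally from [receiver_tide_lags()];
#'   a missing `tide_lag_s` column is treated as zero lag.
#' @param env Environmental series from [read_env()], or `NULL` to skip.
#' @param tides Tide extrema from [read_tides()], or `NULL` to skip.
#' @param w Diel window.
#' @param env_tolerance_min Nearest-join tolerance, minutes.
#' @param study_start,study_years Passed to [assign_study_year()].
#' @return The visit tibble with annotation columns added.
#' @export
annotate_visits <- function(visits, receivers, env = NULL, tides = NULL,
                            w = diel_window(), env_tolerance_min = 30,
                            study_start = as.Date("2017-06-01"),
                            study_years = 2) {
  v <- visits
  v$diel <- classify_diel(v$start, w)
  v$decimal_hour <- decimal_hour(v$start, w$tz)
  v$moon_fraction <- moon_fraction(v$start)
  local_date <- as.Date(lubridate::with_tz(v$start, w$tz))
  v$season <- assign_season(local_date)
  v$study_year <- assign_study_year(local_date, study_start, study_years)
  ri <- match(v$receiver_id, receivers$receiver_id)
  if (anyNA(ri)) stop("visit at receiver missing from metadata")
  v$general_location <- receivers$general_location[ri]
  if (!is.null(tides)) {
    lag <- if (!is.null(receivers$tide_lag_s)) receivers$tide_lag_s[ri] else 0
    v$tide_state <- assign_tide_state(v$start, tides, lag_s = lag)
  }
  if (!is.null(env)) {
    env <- env[, c("timestamp", setdiff(names(env), names(v))), drop = FALSE]
    ev <- nearest_env(v$start, env, env_tolerance_min * 60)
    v <- dplyr::bind_cols(v, ev)
    n_miss <- sum(!stats::complete.cases(ev))
    if (n_miss > 0) {
      message(n_miss, " visit(s) had no environmental record within ",
              env_tolerance_min, " min; covariates set to NA")
    }
  }
  v
}

#' Annotate detections with diel class
#'
#' Adds `diel` and the local calendar `date` used for per-tag-per-day
#' aggregation.
#'
#' @param dets Detection tibble.
#' @param w Diel window.
#' @return Detections with `diel` and `date` columns.
#' @export
annotate_detections <- function(dets, w = diel_window()) {
  dets$diel <- classify_diel(dets$timestamp, w)
  dets$date <- as.Date(lubridate::with_tz(dets$timestamp, w$tz))
  dets
}
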