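# Residence-event ("visit") extraction from filtered detection logs.

#' Movement-derived time-out period
#'
#' Time for an animal travelling at `rom_km_h` to cross the average
#' receiver detection diameter, in minutes, reported to one decimal. The
#' defaults (400 m diameter, 1.4 km/h eagle-ray rate of movement) give the
#' 17.1-minute time-out used throughout.
#'
#' @param detection_diameter_m Detection diameter, metres.
#' @param rom_km_h Rate of movement, km/h.
#' @return Minutes, rounded to one decimal.
#' @export
compute_timeout <- function(detection_diameter_m = 400, rom_km_h = 1.4) {
  if (rom_km_h <= 0) stop("rom_km_h must be positive")
  stopifnot(detection_diameter_m >= 0)
  round((detection_diameter_m / 1000) / rom_km_h * 60, 1)
}

#' Visit-extraction parameters
#'
#' @param detection_diameter_m Detection diameter, metres.
#' @param rom_km_h Rate of movement, km/h.
#' @param timeout_min Maximum within-visit gap, minutes. Defaults to the
#'   movement-derived time-out of [compute_timeout()].
#' @param min_detections Minimum detections per visit (at least 2).
#' @param long_visit_threshold_min Duration strictly above which a visit is
#'   classed `long`; defaults to the time-out.
#' @return A `visit_params` list.
#' @export
visit_params <- function(detection_diameter_m = 400, rom_km_h = 1.4,
                         timeout_min = compute_timeout(detection_diameter_m, rom_km_h),
                         min_detections = 2,
                         long_visit_threshold_min = timeout_min) {
  stopifnot(min_detections >= 2, timeout_min >= 0)
  structure(list(
    detection_diameter_m = detection_diameter_m, rom_km_h = rom_km_h,
    timeout_min = timeout_min, min_detections = min_detections,
    long_visit_threshold_min = long_visit_threshold_min
  ), class = "visit_params")
}

#' Extract visits from a detection log
#'
#' Scans each transmitter's detections chronologically across all
#' receivers. A run accumulates while the receiver is unchanged and the gap
#' to the previous detection is at most the time-out (inclusive: the visit
#' terminates only on a gap strictly greater than the time-out, or on a
#' detection at a different receiver). Runs with at least `min_detections`
#' become visits whose duration is last minus first detection. Simultaneous
#' detections on two receivers are processed in receiver-ID lexical order,
#' which deterministically splits both runs.
#'
#' @param dets Detection tibble sorted by `(transmitter_id, timestamp)`
#'   and deduplicated (as returned by [read_detections()]).
#' @param p [visit_params()].
#' @return Tibble of visits: `transmitter_id`, `receiver_id`, `start`,
#'   `end`, `duration_min`, `n_detections`, `class`; sorted by
#'   `(transmitter_id, start)`. No detection belongs to two visits.
#' @export
extract_visits <- function(dets, p = visit_params()) {
  empty <- tibble::tibble(
    transmitter_id = character(), receiver_id = character(),
    start = lubridate::as_datetime(numeric(), tz = "UTC"),
    end = lubridate::as_datetime(numeric(), tz = "UTC"),
    duration_min = numeric(), n_detections = integer(), class = character()
  )
  if (nrow(dets) == 0) return(empty)
  ts <- as.numeric(dets$timestamp)
  o <- order(dets$transmitter_id, ts, dets$receiver_id)
  if (!identical(o, seq_len(nrow(dets)))) {
    chron <- order(dets$transmitter_id, ts)
    if (!identical(dets$transmitter_id[chron], dets$transmitter_id) ||
        !identical(ts[chron], ts)) {
      stop("detections must be sorted by (transmitter_id, timestamp)")
    }
    # same chronology; re-order only to fix lexical ties across receivers
    dets <- dets[o, , drop = FALSE]
    ts <- ts[o]
  }
  timeout_s <- p$timeout_min * 60
  new_tag <- dets$transmitter_id != dplyr::lag(dets$transmitter_id,
                                               default = "\x01")
  new_rec <- dets$receiver_id != dplyr::lag(dets$receiver_id, default = "\x01")
  gap <- ts - dplyr::lag(ts, default = -Inf)
  run <- cumsum(new_tag | new_rec | gap > timeout_s)
  v <- dets |>
    dplyr::mutate(.run = run) |>
    dplyr::group_by(.data$.run) |>
    dplyr::summarise(
      transmitter_id = .data$transmitter_id[1],
      receiver_id = .data$receiver_id[1],
      start = min(.data$timestamp),
      end = max(.data$timestamp),
      n_detections = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$n_detections >= p$min_detections) |>
    dplyr::mutate(duration_min = as.numeric(.data$end - .data$start,
                                            units = "mins")) |>
    dplyr::arrange(.data$transmitter_id, .data$start) |>
    dplyr::select(-".run")
  v$class <- classify_visit(v$duration_min, p$long_visit_threshold_min)
  v[, names(empty)]
}

#' Classify visit durations as short or long
#'
#' A visit is `long` only when its duration strictly exceeds the threshold
#' (a visit of exactly 17.1 min is `short` under the default).
#'
#' @param duration_min Numeric durations in minutes (or a visit tibble,
#'   in which case its `duration_min` column is used).
#' @param threshold_min Threshold in minutes.
#' @return Character vector, `"short"` or `"long"`.
#' @export
classify_visit <- function(duration_min, threshold_min = compute_timeout()) {
  stopifnot(threshold_min >= 0)
  if (is.data.frame(duration_min)) duration_min <- duration_min$duration_min
  ifelse(duration_min > threshold_min, "long", "short")
}

#' Write a visit table
#'
#' @param visits Visit tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_visits <- function(visits, path) {
  out <- visits
  out$start <- format(out$start, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  out$end <- format(out$end, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
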