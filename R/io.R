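# Detection-log and metadata I/O plus record-level filtering.

#' Default CSV dialect for detection logs
#'
#' Column mapping and datetime format for receiver-download style exports.
#' Extra columns are ignored on read.
#'
#' @param timestamp,receiver,transmitter Column names in the CSV.
#' @param datetime_format Format string understood by [lubridate::fast_strptime()];
#'   timestamps are interpreted as UTC.
#' @param unknown_receiver What to do with detections at receivers absent
#'   from the supplied receiver metadata: `"warn"` (keep, warn) or `"fail"`.
#' @return A named list used by [read_detections()].
#' @export
detection_dialect <- function(timestamp = "datetime",
                              receiver = "receiver",
                              transmitter = "transmitter",
                              datetime_format = "%Y-%m-%dT%H:%M:%SZ",
                              unknown_receiver = c("warn", "fail")) {
  list(
    timestamp = timestamp, receiver = receiver, transmitter = transmitter,
    datetime_format = datetime_format,
    unknown_receiver = match.arg(unknown_receiver)
  )
}

#' Read a detection log
#'
#' Reads a CSV of transmitter detections, parses timestamps as UTC,
#' optionally deduplicates exact `(timestamp, transmitter, receiver)`
#' repeats, and returns records sorted by `(transmitter_id, timestamp)`.
#'
#' @param path Path to a CSV file.
#' @param dialect Column mapping from [detection_dialect()].
#' @param receivers Optional receiver metadata (see [read_receivers()]);
#'   used to check for unknown receiver IDs.
#' @param dedup Drop exact duplicate rows (default `TRUE`).
#' @return A tibble with columns `timestamp` (POSIXct UTC), `transmitter_id`,
#'   `receiver_id`.
#' @export
read_detections <- function(path, dialect = detection_dialect(),
                            receivers = NULL, dedup = TRUE) {
  stopifnot(file.exists(path))
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c(dialect$timestamp, dialect$receiver, dialect$transmitter)
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols)) {
    stop("detection file lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  ts <- lubridate::fast_strptime(raw[[dialect$timestamp]],
                                 format = dialect$datetime_format,
                                 tz = "UTC", lt = FALSE)
  if (anyNA(ts)) {
    bad <- which(is.na(ts))
    stop("unparseable timestamp(s) at data line(s): ",
         paste(utils::head(bad, 5), collapse = ", "),
         if (length(bad) > 5) sprintf(" (and %d more)", length(bad) - 5) else "")
  }
  dets <- tibble::tibble(
    timestamp = ts,
    transmitter_id = as.character(raw[[dialect$transmitter]]),
    receiver_id = as.character(raw[[dialect$receiver]])
  )
  if (dedup) dets <- dedup_detections(dets)
  if (!is.null(receivers)) {
    unknown <- setdiff(unique(dets$receiver_id), receivers$receiver_id)
    if (length(unknown)) {
      msg <- paste("detections at unknown receiver(s):",
                   paste(unknown, collapse = ", "))
      if (dialect$unknown_receiver == "fail") stop(msg) else warning(msg)
    }
  }
  sort_detections(dets)
}

#' Sort detections into processing order
#'
#' Visit extraction requires `(transmitter_id, timestamp)` order with
#' same-second ties broken by receiver ID.
#'
#' @param dets Detection tibble.
#' @return Sorted detection tibble.
#' @export
sort_detections <- function(dets) {
  dplyr::arrange(dets, .data$transmitter_id, .data$timestamp, .data$receiver_id)
}

#' Remove exact duplicate detections
#'
#' Duplicates (identical timestamp, transmitter and receiver) arise when
#' overlapping receiver downloads are concatenated. Idempotent.
#'
#' @param dets Detection tibble.
#' @return Deduplicated detection tibble, input order otherwise preserved.
#' @export
dedup_detections <- function(dets) {
  dplyr::distinct(dets, .data$timestamp, .data$transmitter_id,
                  .data$receiver_id, .keep_all = TRUE)
}

#' Write a detection log
#'
#' RFC 4180 CSV with ISO-8601 UTC timestamps at second resolution; a
#' read/write round trip reproduces the detection set exactly.
#'
#' @param dets Detection tibble.
#' @param path Output path.
#' @param dialect Column naming from [detection_dialect()].
#' @return `path`, invisibly.
#' @export
write_detections <- function(dets, path, dialect = detection_dialect()) {
  out <- data.frame(
    format(dets$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    dets$receiver_id, dets$transmitter_id,
    check.names = FALSE
  )
  names(out) <- c(dialect$timestamp, dialect$receiver, dialect$transmitter)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Flag isolated detections as probable false positives
#'
#' Tag-collision artifacts tend to appear as isolated pings. A detection is
#' removed when fewer than `min_hits` detections of the same transmitter
#' (counting itself, anywhere in the array) fall within `window_min` minutes
#' either side of it. With the defaults, a detection survives only if some
#' other detection of its tag occurs within an hour.
#'
#' @param dets Detection tibble (any order; sorted internally per tag).
#' @param min_hits Minimum detections of the tag inside the window,
#'   including the detection itself (default 2).
#' @param window_min Half-window in minutes (default 60).
#' @return A list with tibbles `kept` and `removed`; their union is the
#'   input and they are disjoint.
#' @export
filter_false_detections <- function(dets, min_hits = 2, window_min = 60) {
  stopifnot(min_hits >= 1, window_min >= 0)
  if (nrow(dets) == 0) {
    return(list(kept = dets, removed = dets))
  }
  w <- window_min * 60
  keep <- logical(nrow(dets))
  idx <- split(seq_len(nrow(dets)), dets$transmitter_id)
  for (ii in idx) {
    tt <- as.numeric(dets$timestamp[ii])
    o <- order(tt)
    ts <- tt[o]
    # detections of this tag in [t - w, t + w], self included
    n_in <- findInterval(ts + w, ts) - findInterval(ts - w, ts, left.open = TRUE)
    keep[ii[o]] <- n_in >= min_hits
  }
  list(kept = dets[keep, , drop = FALSE], removed = dets[!keep, , drop = FALSE])
}

#' Clip detections to the study window
#'
#' Keeps detections with `start <= timestamp < end + 1 day`, i.e. both end
#' dates are included in full.
#'
#' @param dets Detection tibble.
#' @param start,end Study start and end `Date`s (inclusive).
#' @return Filtered detection tibble.
#' @export
study_window_clip <- function(dets, start, end) {
  start <- as.Date(start); end <- as.Date(end)
  if (start > end) stop("study window start is after end")
  lo <- lubridate::as_datetime(start, tz = "UTC")
  hi <- lubridate::as_datetime(end + 1, tz = "UTC")
  dets[dets$timestamp >= lo & dets$timestamp < hi, , drop = FALSE]
}

#' Read receiver metadata
#'
#' Expects columns `receiver_id`, `latitude`, `longitude`, `depth_m`,
#' `habitat` (one of `clam_lease`, `inlet`, `lagoon`) and optionally
#' `detection_radius_m` (default 200). Derives `general_location`
#' (`clam_lease` vs `other`) from habitat.
#'
#' @param path CSV path.
#' @param detection_radius_m Default detection radius when the column is
#'   absent, metres.
#' @return Receiver tibble.
#' @export
read_receivers <- function(path, detection_radius_m = 200) {
  r <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("receiver_id", "latitude", "longitude", "depth_m", "habitat")
  missing_cols <- setdiff(need, names(r))
  if (length(missing_cols)) {
    stop("receiver file lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (is.null(r$detection_radius_m)) r$detection_radius_m <- detection_radius_m
  as_receiver_table(tibble::as_tibble(r))
}

#' Validate and complete a receiver table
#'
#' @param r Data frame of receiver metadata.
#' @return Receiver tibble with `general_location` filled in.
#' @export
as_receiver_table <- function(r) {
  stopifnot(all(r$detection_radius_m > 0))
  bad <- setdiff(unique(r$habitat), c("clam_lease", "inlet", "lagoon"))
  if (length(bad)) stop("unknown habitat class(es): ", paste(bad, collapse = ", "))
  r$general_location <- ifelse(r$habitat == "clam_lease", "clam_lease", "other")
  tibble::as_tibble(r)
}

#' Read tag-deployment metadata
#'
#' Expects columns `transmitter_id`, `species`, `sex` (`F`/`M`),
#' `disc_width_cm`, `release_date`, `tag_model` (`V13`/`V16`); `weight_kg`
#' optional. Ping-interval bounds are attached per tag model: V13 transmits
#' at uniform 60-180 s intervals, V16 at 30-90 s.
#'
#' @param path CSV path.
#' @return Tag tibble with `ping_lo_s`, `ping_hi_s` columns added.
#' @export
read_tags <- function(path) {
  tg <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("transmitter_id", "species", "sex", "disc_width_cm",
            "release_date", "tag_model")
  missing_cols <- setdiff(need, names(tg))
  if (length(missing_cols)) {
    stop("tag file lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  tg$transmitter_id <- as.character(tg$transmitter_id)
  tg$release_date <- as.Date(tg$release_date)
  as_tag_table(tibble::as_tibble(tg))
}

ping_intervals <- function(tag_model) {
  lo <- c(V13 = 60, V16 = 30)[tag_model]
  hi <- c(V13 = 180, V16 = 90)[tag_model]
  list(lo = unname(lo), hi = unname(hi))
}

#' Validate a tag table
#'
#' @param tg Data frame of tag deployments.
#' @return Tag tibble with ping-interval bounds.
#' @export
as_tag_table <- function(tg) {
  stopifnot(all(tg$disc_width_cm > 0), all(tg$sex %in% c("F", "M")),
            all(tg$tag_model %in% c("V13", "V16")))
  pi <- ping_intervals(tg$tag_model)
  tg$ping_lo_s <- pi$lo
  tg$ping_hi_s <- pi$hi
  stopifnot(all(tg$ping_lo_s > 0), all(tg$ping_lo_s <= tg$ping_hi_s))
  tibble::as_tibble(tg)
}
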