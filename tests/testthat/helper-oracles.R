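# Shared builders and independent brute-force oracles used across tests.

utc <- function(x) as.POSIXct(x, tz = "UTC")

# detection tibble from minutes-offset vectors
dets_at <- function(min_offsets, tag = "T1", rec = "R1",
                    origin = utc("2017-06-15 12:00:00")) {
  tibble::tibble(
    timestamp = origin + min_offsets * 60,
    transmitter_id = rep_len(tag, length(min_offsets)),
    receiver_id = rep_len(rec, length(min_offsets))
  )
}

# O(n^2) all-pairs window check: keep a detection iff >= min_hits
# detections of its transmitter (itself included) lie within +/- window
bf_filter <- function(dets, min_hits = 2, window_min = 60) {
  n <- nrow(dets)
  keep <- logical(n)
  for (i in seq_len(n)) {
    same <- dets$transmitter_id == dets$transmitter_id[i]
    close <- abs(as.numeric(dets$timestamp) - as.numeric(dets$timestamp[i])) <=
      window_min * 60
    keep[i] <- sum(same & close) >= min_hits
  }
  list(kept = dets[keep, , drop = FALSE], removed = dets[!keep, , drop = FALSE])
}

# explicit per-tag segmentation oracle for visit extraction
bf_visits <- function(dets, timeout_min, min_detections = 2) {
  out <- list()
  for (tag in sort(unique(dets$transmitter_id))) {
    d <- dets[dets$transmitter_id == tag, , drop = FALSE]
    d <- d[order(d$timestamp, d$receiver_id), , drop = FALSE]
    i <- 1
    while (i <= nrow(d)) {
      j <- i
      while (j + 1 <= nrow(d) &&
             d$receiver_id[j + 1] == d$receiver_id[i] &&
             as.numeric(d$timestamp[j + 1]) - as.numeric(d$timestamp[j]) <=
               timeout_min * 60) {
        j <- j + 1
      }
      if (j - i + 1 >= min_detections) {
        out[[length(out) + 1]] <- tibble::tibble(
          transmitter_id = tag, receiver_id = d$receiver_id[i],
          start = d$timestamp[i], end = d$timestamp[j],
          n_detections = j - i + 1L
        )
      }
      i <- j + 1
    }
  }
  if (!length(out)) {
    return(tibble::tibble(transmitter_id = character(),
                          receiver_id = character(),
                          start = utc(character()), end = utc(character()),
                          n_detections = integer()))
  }
  res <- dplyr::bind_rows(out)
  dplyr::arrange(res, transmitter_id, start)
}

# random detection log across tags/receivers for property tests
random_dets <- function(n, n_tags = 3, n_recs = 3, span_min = 600) {
  tibble::tibble(
    timestamp = utc("2018-01-10 00:00:00") +
      round(runif(n, 0, span_min * 60)),
    transmitter_id = sample(paste0("T", seq_len(n_tags)), n, replace = TRUE),
    receiver_id = sample(paste0("R", seq_len(n_recs)), n, replace = TRUE)
  ) |>
    dplyr::distinct(timestamp, transmitter_id, receiver_id, .keep_all = TRUE) |>
    (\(d) d[order(d$transmitter_id, d$timestamp, d$receiver_id), ])()
}

fixture <- function(name) {
  path <- system.file("extdata", name, package = "rayvisits")
  if (path == "") path <- file.path("..", "..", "inst", "extdata", name)
  read.csv(path, stringsAsFactors = FALSE)
}

# small fast simulation config shared by pipeline tests
small_sim_config <- function(seed = 42, days = 30, n_eagle = 3, n_cow = 3,
                             detection_prob = 0.95, fp_per_day = 2) {
  sp <- default_species()
  sp$A_narinari$n_tags <- n_eagle
  sp$R_bonasus$n_tags <- n_cow
  sp$R_brasiliensis <- NULL
  sim_config(
    seed = seed, start = as.Date("2017-06-01"),
    end = as.Date("2017-06-01") + days - 1,
    species = sp, detection_prob = detection_prob,
    false_positive_per_day = fp_per_day
  )
}
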