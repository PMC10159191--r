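# Aggregation of detections and visits into per-species / per-receiver
# summary tables (counts, proportions, means +/- SE, totals).

#' Round half away from zero
#'
#' Printed-table convention: 64.45 -> 64.5 (not banker's rounding).
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded vector.
#' @export
round_half_out <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

se_or_zero <- function(x) {
  if (length(x) <= 1) 0 else stats::sd(x) / sqrt(length(x))
}

join_species <- function(x, tags, orphan = c("warn", "fail")) {
  orphan <- match.arg(orphan)
  i <- match(x$transmitter_id, tags$transmitter_id)
  if (anyNA(i)) {
    msg <- paste("transmitter(s) without tag metadata:",
                 paste(unique(x$transmitter_id[is.na(i)]), collapse = ", "))
    if (orphan == "fail") stop(msg) else warning(msg)
  }
  x$species <- tags$species[i]
  x
}

#' Per-species detection proportions from cell counts
#'
#' Core aggregation behind the detection summary: given per
#' `(species, receiver_id)` counts, computes each cell's share of its
#' species total and appends per-species `Total` margin rows. Shares are
#' also reported as percentages rounded half-away-from-zero to one
#' decimal, matching the printed-table convention.
#'
#' @param cells Tibble with `species`, `receiver_id`, `n_detections` and
#'   optionally `unique_tags`.
#' @return Tibble with `prop_of_species_total` and `pct` columns plus
#'   margin rows (`receiver_id == "Total"`).
#' @export
detection_summary_from_counts <- function(cells) {
  stopifnot(all(c("species", "receiver_id", "n_detections") %in% names(cells)))
  out <- cells |>
    dplyr::group_by(.data$species) |>
    dplyr::mutate(prop_of_species_total =
                    .data$n_detections / sum(.data$n_detections)) |>
    dplyr::ungroup()
  margins <- out |>
    dplyr::group_by(.data$species) |>
    dplyr::summarise(
      receiver_id = "Total",
      n_detections = sum(.data$n_detections),
      prop_of_species_total = 1,
      .groups = "drop"
    )
  out <- dplyr::bind_rows(out, margins)
  out$pct <- round_half_out(100 * out$prop_of_species_total, 1)
  out
}

#' Summarise detections by species and receiver
#'
#' Counts, per-species proportions of total detections, and unique-tag
#' counts per `(species, receiver)` cell, with per-species margin rows.
#'
#' @param dets Detection tibble.
#' @param tags Tag metadata (species lookup).
#' @param receivers Optional receiver tibble; cells are restricted to its
#'   receivers when given.
#' @param orphan Behaviour for transmitters with no tag metadata.
#' @return Detection summary tibble (see [detection_summary_from_counts()]).
#' @export
summarize_detections <- function(dets, tags, receivers = NULL,
                                 orphan = c("warn", "fail")) {
  d <- join_species(dets, tags, orphan)
  if (!is.null(receivers)) {
    d <- d[d$receiver_id %in% receivers$receiver_id, , drop = FALSE]
  }
  cells <- d |>
    dplyr::group_by(.data$species, .data$receiver_id) |>
    dplyr::summarise(
      n_detections = dplyr::n(),
      unique_tags = dplyr::n_distinct(.data$transmitter_id),
      .groups = "drop"
    )
  tag_margin <- d |>
    dplyr::group_by(.data$species) |>
    dplyr::summarise(unique_tags = dplyr::n_distinct(.data$transmitter_id),
                     .groups = "drop")
  out <- detection_summary_from_counts(cells)
  i <- match(out$species[out$receiver_id == "Total"], tag_margin$species)
  out$unique_tags[out$receiver_id == "Total"] <- tag_margin$unique_tags[i]
  out
}

#' Pooled detection shares over receiver groups
#'
#' Computes, for each (optionally pooled) species, the share of its
#' detections falling in each receiver group -- e.g. the fraction of all
#' cownose-ray detections logged at the clam-lease receivers.
#'
#' @param cells Per `(species, receiver_id)` counts (margin rows with
#'   `receiver_id == "Total"` are ignored).
#' @param receiver_groups Named character vector mapping `receiver_id` to
#'   a group label; receivers absent from the map keep their own ID.
#' @param species_groups Optional named character vector pooling species
#'   (e.g. both cownose-ray species into `"cownose"`).
#' @return Tibble `species`, `group`, `n_detections`, `prop`, `pct`.
#' @export
detection_proportions <- function(cells, receiver_groups,
                                  species_groups = NULL) {
  cells <- cells[cells$receiver_id != "Total", , drop = FALSE]
  grp <- receiver_groups[cells$receiver_id]
  grp[is.na(grp)] <- cells$receiver_id[is.na(grp)]
  sp <- cells$species
  if (!is.null(species_groups)) {
    pooled <- species_groups[sp]
    sp[!is.na(pooled)] <- pooled[!is.na(pooled)]
  }
  tibble::tibble(species = sp, group = unname(grp),
                 n_detections = cells$n_detections) |>
    dplyr::group_by(.data$species, .data$group) |>
    dplyr::summarise(n_detections = sum(.data$n_detections),
                     .groups = "drop_last") |>
    dplyr::mutate(prop = .data$n_detections / sum(.data$n_detections),
                  pct = round_half_out(100 * .data$prop, 1)) |>
    dplyr::ungroup()
}

#' Summarise detections by time of day
#'
#' For each `(species, receiver, diel)` cell: the mean (+/- SE) number of
#' detections per tag-day (each tag's count on each local calendar date it
#' was detected) and the raw total. Day and night totals sum to the
#' receiver total by construction.
#'
#' @param dets Annotated detections from [annotate_detections()] (needs
#'   `diel` and `date` columns).
#' @param tags Tag metadata.
#' @param unit Averaging unit: `"tag_date"` (default) averages over
#'   per-tag-per-date counts; `"tag"` averages over per-tag totals.
#' @param orphan Behaviour for unknown transmitters.
#' @return Tibble `species`, `receiver_id`, `diel`, `mean`, `se`, `total`.
#' @export
summarize_diel <- function(dets, tags, unit = c("tag_date", "tag"),
                           orphan = c("warn", "fail")) {
  unit <- match.arg(unit)
  stopifnot(all(c("diel", "date") %in% names(dets)))
  d <- join_species(dets, tags, orphan)
  keys <- if (unit == "tag_date") {
    c("species", "receiver_id", "diel", "transmitter_id", "date")
  } else {
    c("species", "receiver_id", "diel", "transmitter_id")
  }
  d |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(n = dplyr::n(), .groups = "drop") |>
    dplyr::group_by(.data$species, .data$receiver_id, .data$diel) |>
    dplyr::summarise(
      mean = mean(.data$n),
      se = se_or_zero(.data$n),
      total = sum(.data$n),
      .groups = "drop"
    )
}

#' Summarise visits by species and receiver
#'
#' Per `(species, receiver)` cell: number of unique tags, duration range,
#' mean +/- SE (SE reported as 0 for single-visit cells), visit count and
#' total visit time, with per-species margin rows (`receiver_id ==
#' "Total"`).
#'
#' @param visits Visit tibble.
#' @param tags Tag metadata.
#' @param orphan Behaviour for unknown transmitters.
#' @return Visit summary tibble.
#' @export
summarize_visits <- function(visits, tags, orphan = c("warn", "fail")) {
  v <- join_species(visits, tags, orphan)
  cell_stats <- function(x) {
    tibble::tibble(
      unique_tags = dplyr::n_distinct(x$transmitter_id),
      range_min_lo = min(x$duration_min),
      range_min_hi = max(x$duration_min),
      mean_min = mean(x$duration_min),
      se_min = se_or_zero(x$duration_min),
      n_visits = nrow(x),
      total_time_min = sum(x$duration_min)
    )
  }
  cells <- v |>
    dplyr::group_by(.data$species, .data$receiver_id) |>
    dplyr::group_modify(~cell_stats(.x)) |>
    dplyr::ungroup()
  margins <- v |>
    dplyr::group_by(.data$species) |>
    dplyr::group_modify(~cell_stats(.x)) |>
    dplyr::ungroup() |>
    dplyr::mutate(receiver_id = "Total")
  dplyr::bind_rows(cells, margins)
}

#' Share of visit time by receiver group
#'
#' Fraction of each species' total visit time spent in each receiver
#' group (e.g. inlet vs clam lease vs river mouth), as proportions and
#' one-decimal percentages.
#'
#' @param vs Visit summary from [summarize_visits()] (or a compatible
#'   tibble with `species`, `receiver_id`, `total_time_min`); margin rows
#'   are ignored.
#' @param receiver_groups Named character vector mapping `receiver_id` to
#'   group labels; unmapped receivers keep their own ID.
#' @return Tibble `species`, `group`, `total_time_min`, `prop`, `pct`.
#' @export
proportion_visit_time <- function(vs, receiver_groups) {
  cells <- vs[vs$receiver_id != "Total", , drop = FALSE]
  grp <- receiver_groups[cells$receiver_id]
  grp[is.na(grp)] <- cells$receiver_id[is.na(grp)]
  tibble::tibble(species = cells$species, group = unname(grp),
                 total_time_min = cells$total_time_min) |>
    dplyr::group_by(.data$species, .data$group) |>
    dplyr::summarise(total_time_min = sum(.data$total_time_min),
                     .groups = "drop_last") |>
    dplyr::mutate(prop = .data$total_time_min / sum(.data$total_time_min),
                  pct = round_half_out(100 * .data$prop, 1)) |>
    dplyr::ungroup()
}

#' Count long visits by species and receiver group
#'
#' Strict-threshold counting: a visit counts as long only when its
#' duration strictly exceeds `threshold_min`.
#'
#' @param visits Visit tibble.
#' @param tags Tag metadata (species lookup), or `NULL` to count overall.
#' @param threshold_min Long-visit threshold, minutes.
#' @param receiver_groups Optional receiver -> group map; unmapped
#'   receivers keep their own ID.
#' @return Tibble of long-visit counts `n_long` (and `n_visits`).
#' @export
count_long_visits <- function(visits, tags = NULL,
                              threshold_min = compute_timeout(),
                              receiver_groups = NULL) {
  v <- visits
  v$long <- v$duration_min > threshold_min
  v$group <- if (is.null(receiver_groups)) {
    v$receiver_id
  } else {
    g <- receiver_groups[v$receiver_id]
    ifelse(is.na(g), v$receiver_id, g)
  }
  keys <- "group"
  if (!is.null(tags)) {
    v <- join_species(v, tags)
    keys <- c("species", "group")
  }
  v |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(n_visits = dplyr::n(), n_long = sum(.data$long),
                     .groups = "drop")
}
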