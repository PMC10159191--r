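test_that("detection proportions reproduce the printed per-receiver shares", {
  cells <- fixture("detection_summary_cells.csv")
  s <- detection_summary_from_counts(cells)
  pick <- function(sp, rec) s$pct[s$species == sp & s$receiver_id == rec]
  expect_equal(pick("A_narinari", "SINJ"), 64.5)
  expect_equal(pick("A_narinari", "SISO"), 17.6)
  expect_equal(pick("A_narinari", "IR16"), 8.5)
  expect_equal(pick("R_bonasus", "SCLN"), 26.8)
  expect_equal(pick("R_brasiliensis", "IR16"), 99.0)
  # margins equal cell sums, per-species proportions sum to 1
  tot <- s[s$receiver_id == "Total", ]
  expect_equal(tot$n_detections[tot$species == "A_narinari"], 187016)
  expect_equal(tot$n_detections[tot$species == "R_bonasus"], 13477)
  expect_equal(tot$n_detections[tot$species == "R_brasiliensis"], 35965)
  by_sp <- split(s[s$receiver_id != "Total", ], s$species[s$receiver_id != "Total"])
  for (b in by_sp) expect_equal(sum(b$prop_of_species_total), 1, tolerance = 1e-9)
})

test_that("pooled cownose clam-lease detection share matches the printed 11.3%", {
  cells <- fixture("detection_summary_cells.csv")
  pr <- detection_proportions(
    cells,
    receiver_groups = c(SCLN = "clam_lease", SCLS = "clam_lease",
                        IR16 = "other", SINJ = "other", SISO = "other",
                        SIWP = "other"),
    species_groups = c(R_bonasus = "cownose", R_brasiliensis = "cownose")
  )
  expect_equal(pr$pct[pr$species == "cownose" & pr$group == "clam_lease"], 11.3)
  # degenerate single group -> 100%
  all_one <- detection_proportions(
    cells, receiver_groups = setNames(rep("all", 6), unique(cells$receiver_id)))
  expect_true(all(all_one$pct == 100.0))
})

test_that("summarize_detections counts all-at-one-receiver as 100%", {
  d <- dets_at(0:9, tag = "SER-01", rec = "SINJ")
  tg <- tibble::tibble(transmitter_id = "SER-01", species = "A_narinari",
                       sex = "F", disc_width_cm = 150,
                       release_date = as.Date("2017-06-01"), tag_model = "V13")
  s <- summarize_detections(d, as_tag_table(tg))
  expect_equal(s$pct[s$receiver_id == "SINJ"], 100.0)
  expect_equal(s$unique_tags[s$receiver_id == "Total"], 1)
})

test_that("diel summary means are per tag-day and totals are conserved", {
  # 10 day detections on each of 2 days, none at night
  d <- dplyr::bind_rows(
    dets_at(seq(0, 45, by = 5), origin = utc("2018-06-15 16:00:00")),
    dets_at(seq(0, 45, by = 5), origin = utc("2018-06-16 16:00:00"))
  )
  d <- annotate_detections(d)
  tg <- as_tag_table(tibble::tibble(
    transmitter_id = "T1", species = "A_narinari", sex = "F",
    disc_width_cm = 150, release_date = as.Date("2017-06-01"),
    tag_model = "V13"
  ))
  s <- summarize_diel(d, tg)
  expect_equal(nrow(s), 1)
  expect_equal(s$diel, "day")
  expect_equal(s$mean, 10)
  expect_equal(s$se, 0)
  expect_equal(s$total, 20)
  # conservation on a mixed random log
  set.seed(5)
  d2 <- annotate_detections(random_dets(500, n_tags = 1, span_min = 5000))
  s2 <- summarize_diel(d2, tg)
  expect_equal(sum(s2$total), nrow(d2))
})

test_that("printed diel totals are consistent with the detection table", {
  diel <- fixture("diel_summary_cells.csv")
  cells <- fixture("detection_summary_cells.csv")
  joint <- aggregate(total ~ species + receiver_id, diel, sum)
  m <- merge(joint, cells, by = c("species", "receiver_id"))
  expect_equal(m$total, m$n_detections)
})

test_that("visit summary margins and SE conventions are as printed", {
  vcells <- fixture("visit_summary_cells.csv")
  # margins from the printed cells: totals across receivers
  eagle <- vcells[vcells$species == "A_narinari", ]
  expect_equal(sum(eagle$total_time_min), 413583.3)
  expect_equal(sum(eagle$n_visits), 14317)
  expect_equal(sum(vcells$n_visits), 17014)
  # computed summary on raw visits: single visit gets SE 0
  v <- tibble::tibble(transmitter_id = "T1", receiver_id = "R1",
                      duration_min = 10)
  tg <- as_tag_table(tibble::tibble(
    transmitter_id = "T1", species = "A_narinari", sex = "M",
    disc_width_cm = 120, release_date = as.Date("2017-06-01"),
    tag_model = "V13"
  ))
  s <- summarize_visits(v, tg)
  cell <- s[s$receiver_id == "R1", ]
  expect_equal(cell$n_visits, 1)
  expect_equal(cell$mean_min, 10)
  expect_equal(cell$se_min, 0)
  expect_equal(cell$range_min_lo, 10)
  expect_equal(cell$range_min_hi, 10)
  # mean between min and max, margins equal cell sums, on random data
  set.seed(9)
  v2 <- tibble::tibble(
    transmitter_id = sample(c("T1", "T2"), 50, TRUE),
    receiver_id = sample(c("R1", "R2"), 50, TRUE),
    duration_min = rgamma(50, 2, 0.1)
  )
  tg2 <- as_tag_table(tibble::tibble(
    transmitter_id = c("T1", "T2"), species = "A_narinari", sex = "M",
    disc_width_cm = 120, release_date = as.Date("2017-06-01"),
    tag_model = "V13"
  ))
  s2 <- summarize_visits(v2, tg2)
  cells2 <- s2[s2$receiver_id != "Total", ]
  marg <- s2[s2$receiver_id == "Total", ]
  expect_true(all(cells2$range_min_lo <= cells2$mean_min &
                  cells2$mean_min <= cells2$range_min_hi))
  expect_equal(sum(cells2$total_time_min), marg$total_time_min)
  expect_equal(sum(cells2$n_visits), marg$n_visits)
})

test_that("visit-time shares reproduce the printed proportions", {
  vcells <- fixture("visit_summary_cells.csv")
  groups <- c(SINJ = "inlet", SISO = "inlet", SIWP = "inlet",
              SCLN = "clam_lease", SCLS = "clam_lease", IR16 = "river_mouth")
  pr <- proportion_visit_time(vcells, groups)
  expect_equal(pr$pct[pr$species == "A_narinari" & pr$group == "inlet"], 85.3)
  expect_equal(pr$pct[pr$species == "R_bonasus" & pr$group == "clam_lease"], 41.6)
  # shares sum to 100 within rounding
  sums <- tapply(pr$pct, pr$species, sum)
  expect_true(all(abs(sums - 100) <= 0.1 * 3))
})

test_that("long-visit counting is strictly greater than the threshold", {
  v <- tibble::tibble(
    transmitter_id = "T1", receiver_id = "R1",
    duration_min = c(5, 18, 17.1, 400)
  )
  out <- count_long_visits(v, threshold_min = 17.1)
  expect_equal(out$n_long, 2)
  empty <- count_long_visits(v[0, ], threshold_min = 17.1)
  expect_equal(nrow(empty), 0)
})
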