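test_that("the generator is fully deterministic under a seed", {
  cfg <- small_sim_config(days = 7)
  s1 <- simulate_telemetry(cfg)
  s2 <- simulate_telemetry(cfg)
  expect_identical(s1$detections, s2$detections)
  expect_identical(s1$env, s2$env)
  expect_identical(s1$truth, s2$truth)
  # and written CSVs are byte-identical
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_simulation(s1, d1); write_simulation(s2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  # a different seed changes the data
  s3 <- simulate_telemetry(small_sim_config(seed = 43, days = 7))
  expect_false(identical(s1$detections, s3$detections))
})

test_that("tide extrema alternate strictly and env is collinear by design", {
  cfg <- small_sim_config(days = 60)
  e <- simulate_environment(cfg)
  expect_true(all(e$tides$type[-1] != e$tides$type[-nrow(e$tides)]))
  expect_gt(cor(e$env$water_temp_c, e$env$o2_sat_pct), 0.9)
  expect_true(all(e$env$moon_fraction >= 0 & e$env$moon_fraction <= 1))
  # roughly semidiurnal spacing
  gaps <- diff(as.numeric(e$tides$timestamp))
  expect_true(all(abs(gaps / 3600 - 6.21) < 1))
})

test_that("bout durations follow the configured Gamma mean at large n", {
  cfg <- small_sim_config(days = 60, n_eagle = 1, n_cow = 0)
  sc <- cfg$species$A_narinari
  # neutralise covariate effects so the mean is exp(b0)
  sc$hour_amp <- 0; sc$b_moon <- 0; sc$b_clam <- 0
  sc$b_tide <- c(High = 0, Incoming = 0, Low = 0, Outgoing = 0)
  sc$mean_absent_min <- 5; sc$p_direct <- 0
  cfg$species <- list(A_narinari = sc)
  truth <- simulate_movement(cfg)
  # exclude bouts truncated by the window end
  ok <- truth$departure < max(truth$departure)
  expect_gt(sum(ok), 2000)
  expect_lt(abs(mean(truth$duration_min[ok]) - exp(sc$b0)) / exp(sc$b0), 0.05)
  # bouts are chronological and non-overlapping per tag
  expect_true(all(diff(as.numeric(truth$arrival)) > 0))
  expect_true(all(truth$departure >= truth$arrival))
})

test_that("diel site preference shows up in day-time occupancy", {
  cfg <- small_sim_config(days = 90, n_eagle = 4, n_cow = 0)
  # force a hard day-inlet / night-lagoon preference
  sc <- cfg$species$A_narinari
  inlet <- cfg$sites$receiver_id[cfg$sites$habitat == "inlet"]
  sc$day_weights[] <- ifelse(names(sc$day_weights) %in% inlet, 10, 0.5)
  sc$night_weights[] <- ifelse(names(sc$night_weights) %in% inlet, 0.5, 10)
  cfg$species <- list(A_narinari = sc)
  truth <- simulate_movement(cfg)
  day <- truth[truth$diel == "day", ]
  frac_inlet <- sum(day$duration_min[day$receiver_id %in% inlet]) /
    sum(day$duration_min)
  expect_gt(frac_inlet, 0.7)
})

test_that("detection counts follow the thinned renewal process", {
  cfg <- small_sim_config(days = 40, n_eagle = 2, n_cow = 0,
                          detection_prob = 0.5, fp_per_day = 0)
  sim <- simulate_telemetry(cfg)
  tags <- sim$tags
  mean_gap <- (tags$ping_lo_s[1] + tags$ping_hi_s[1]) / 2
  expected <- sum(sim$truth$duration_min * 60) / mean_gap * cfg$detection_prob
  expect_lt(abs(nrow(sim$detections) - expected) / expected, 0.05)
  # detection_prob = 0 gives an empty log
  cfg0 <- small_sim_config(days = 10, n_eagle = 1, n_cow = 0,
                           detection_prob = 0, fp_per_day = 0)
  sim0 <- simulate_telemetry(cfg0)
  expect_equal(nrow(sim0$detections), 0)
  # fixed 60 s gaps give detections exactly every 60 s within a bout
  cfg1 <- small_sim_config(days = 5, n_eagle = 1, n_cow = 0,
                           detection_prob = 1, fp_per_day = 0)
  cfg1$species$A_narinari$tag_model <- "V13"
  sim1 <- simulate_telemetry(cfg1)
  tg <- sim1$tags; tg$ping_lo_s <- 60; tg$ping_hi_s <- 60
  dets <- simulate_detections(sim1$truth, cfg1, tg)
  one_bout <- sim1$truth[which.max(sim1$truth$duration_min), ]
  inb <- dets[dets$timestamp >= one_bout$arrival &
                dets$timestamp <= one_bout$departure &
                dets$receiver_id == one_bout$receiver_id, ]
  expect_true(all(diff(as.numeric(inb$timestamp)) == 60))
})

test_that("truth visit table excludes bouts too short to yield two pings", {
  cfg <- small_sim_config(days = 20, n_eagle = 2, n_cow = 2)
  truth <- simulate_movement(cfg)
  tv <- truth_visit_table(truth, cfg)
  tags <- simulate_tags(cfg)
  mean_gap <- (tags$ping_lo_s + tags$ping_hi_s)[match(tv$transmitter_id,
                                                      tags$transmitter_id)] / 2
  expect_true(all(tv$n_expected >= 2))
  expect_true(all(tv$duration_min * 60 >= mean_gap))
  expect_lte(nrow(tv), nrow(truth))
})
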