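test_that("collinearity screen drops the constructed temperature/O2 pair", {
  set.seed(21)
  n <- 200
  temp <- runif(n, 15, 32)
  cov <- tibble::tibble(
    water_temp_c = temp,
    salinity = runif(n, 20, 36),
    do_mg_l = runif(n, 4, 10),
    o2_sat_pct = 2 * temp + rnorm(n, 0, 0.05)
  )
  sc <- collinearity_screen(cov)
  expect_true("o2_sat_pct" %in% sc$dropped)
  expect_false("water_temp_c" %in% sc$dropped)
  expect_setequal(sc$kept, c("water_temp_c", "salinity", "do_mg_l"))
  expect_gt(sc$correlation["water_temp_c", "o2_sat_pct"], 0.99)
})

test_that("orthogonal covariates all have VIF near 1 and none are dropped", {
  set.seed(22)
  cov <- as.data.frame(matrix(rnorm(400), ncol = 4))
  sc <- collinearity_screen(cov)
  expect_true(all(sc$vif < 1.2))
  expect_length(sc$dropped, 0)
})

test_that("degenerate columns are flagged, duplicates get infinite VIF", {
  set.seed(23)
  x <- rnorm(50)
  cov <- data.frame(a = x, b = x, c = rnorm(50), k = rep(1, 50))
  sc <- collinearity_screen(cov)
  expect_true(is.infinite(sc$vif["a"]) || is.infinite(sc$vif["b"]))
  expect_true(is.na(sc$vif["k"]))
  expect_true("k" %in% sc$flagged)
})

test_that("AICc equals AIC plus the small-sample correction, vanishing at large n", {
  set.seed(24)
  d <- data.frame(x = rnorm(50))
  d$y <- 1 + 2 * d$x + rnorm(50)
  fit <- lm(y ~ x, data = d)
  k <- attr(logLik(fit), "df")
  expect_equal(aicc(fit), AIC(fit) + 2 * k * (k + 1) / (50 - k - 1))
  big <- data.frame(x = rnorm(1e6))
  big$y <- big$x + rnorm(1e6)
  fitb <- lm(y ~ x, data = big)
  expect_lt(aicc(fitb) - AIC(fitb), 0.01)
  # boundary guard: n <= k + 1 gives infinite AICc
  tiny <- data.frame(x = rnorm(3), y = rnorm(3))
  expect_equal(aicc(lm(y ~ x, data = tiny)), Inf)
})

test_that("GLMM with negligible random-effect variance matches plain GLM", {
  set.seed(25)
  cells <- sim_count_cells(n_tags = 15, n_days = 20, re_sd = 0)
  fit <- fit_detection_glmm(cells, glmm_spec(fixed = ~ diel))
  glm_fit <- glm(count ~ diel, data = cells, family = poisson())
  expect_lt(max(abs(fit$coefficients$estimate - coef(glm_fit))), 1e-3)
  expect_true(fit$converged)
})

test_that("contrast count is choose(k,2) and Tukey p >= unadjusted p", {
  set.seed(26)
  cells <- sim_count_cells(n_tags = 12, n_days = 8)
  cells$receiver_id <- sample(c("R1", "R2", "R3"), nrow(cells), replace = TRUE)
  fit <- fit_detection_glmm(cells, glmm_spec(fixed = ~ receiver_id))
  ctr <- pairwise_contrasts(fit, "receiver_id")
  expect_equal(nrow(ctr), choose(3, 2))
  raw <- summary(emmeans::contrast(
    emmeans::emmeans(fit$model, ~receiver_id), method = "pairwise",
    adjust = "none"))
  expect_true(all(ctr$p.value >= raw$p.value - 1e-12))
  # two identical receivers: their contrast is non-significant
  set.seed(27)
  cells2 <- sim_count_cells(n_tags = 15, n_days = 15)
  cells2$receiver_id <- sample(c("R1", "R2"), nrow(cells2), replace = TRUE)
  fit2 <- fit_detection_glmm(cells2, glmm_spec(fixed = ~ receiver_id))
  ctr2 <- pairwise_contrasts(fit2, "receiver_id")
  expect_gt(ctr2$p.value, 0.05)
})

test_that("a strong simulated receiver effect is detected with tiny adjusted p", {
  set.seed(28)
  cells <- sim_count_cells(n_tags = 20, n_days = 15)
  cells$receiver_id <- sample(c("R1", "R2"), nrow(cells), replace = TRUE)
  cells$count <- rpois(nrow(cells), exp(log(5) + log(5) * (cells$receiver_id == "R2")))
  fit <- fit_detection_glmm(cells, glmm_spec(fixed = ~ receiver_id))
  ctr <- pairwise_contrasts(fit, "receiver_id")
  expect_lt(ctr$p.value, 0.001)
})

test_that("GAMM recovers a sinusoidal hour effect and the location contrast", {
  set.seed(29)
  v <- sim_gamma_visits(2000, hour_amp = 0.4, hour_peak = 10, b_moon = 0.5,
                        b_clam = log(1.3))
  spec <- gamm_spec(smooths = c("decimal_hour", "moon_fraction"),
                    parametric = "general_location")
  fit <- fit_visit_gamm(v, spec)
  expect_true(fit$converged)
  expect_true(all(fit$smooths$edf >= 0))
  expect_true(is.finite(fit$AICc))
  prof <- hour_profile(fit, v)
  peak <- prof$hour[which.max(prof$mu)]
  expect_lt(min(abs(peak - 10), 24 - abs(peak - 10)), 1.5)
  # clam-lease visits are predicted longer (response scale, link-agnostic)
  grid <- tibble::tibble(decimal_hour = 12, moon_fraction = 0.5,
                         general_location = c("clam_lease", "other"),
                         transmitter_id = v$transmitter_id[1])
  mu <- predict(fit$model, grid, type = "response")
  expect_gt(mu[1], mu[2])
  loc_p <- fit$coefficients$p[grepl("general_location", fit$coefficients$term)]
  expect_lt(loc_p, 0.05)
})

test_that("log-link fallback engages when the inverse link cannot be fit", {
  set.seed(30)
  # near-degenerate single-tag data with huge spread defeats the inverse link
  v <- sim_gamma_visits(60, hour_amp = 0, n_tags = 2, re_sd = 0,
                        shape = 0.05, base_mean = 2)
  spec <- gamm_spec(smooths = "moon_fraction", parametric = character(0))
  fit <- suppressWarnings(
    tryCatch(fit_visit_gamm(v, spec), error = function(e) NULL)
  )
  if (!is.null(fit) && fit$link_fallback) {
    expect_match(fit$family, "log")
  } else {
    # the inverse link happened to fit; the explicit log spec must also work
    fit2 <- suppressWarnings(
      fit_visit_gamm(v, gamm_spec(smooths = "moon_fraction",
                                  parametric = character(0), link = "log"))
    )
    expect_match(fit2$family, "log")
  }
})

test_that("model selection ranks the parsimonious model first on null data", {
  set.seed(31)
  wins <- 0
  for (r in 1:9) {
    v <- sim_gamma_visits(250, hour_amp = 0, b_moon = 0, re_sd = 0)
    tab <- aicc_model_selection(
      gamm_spec(smooths = c("moon_fraction", "water_temp_c"),
                parametric = character(0), link = "log"), v)
    if (tab$terms[1] == "") wins <- wins + 1
  }
  expect_gt(wins, 9 / 2)
})
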