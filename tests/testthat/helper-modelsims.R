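# Generators with known truth for model-recovery tests.

# Per-cell Poisson detection counts: n_tags x n_days x 2 diel cells with a
# lognormal random intercept per tag.
sim_count_cells <- function(n_tags = 20, n_days = 10, rate_ratio_day = 2,
                            base_rate = 5, sex_effect = 0, re_sd = 0.3) {
  tags <- sprintf("T%02d", seq_len(n_tags))
  sex <- sample(c("F", "M"), n_tags, replace = TRUE)
  b <- rnorm(n_tags, 0, re_sd)
  g <- expand.grid(transmitter_id = tags, date = seq_len(n_days),
                   diel = c("day", "night"), stringsAsFactors = FALSE)
  i <- match(g$transmitter_id, tags)
  mu <- exp(log(base_rate) + log(rate_ratio_day) * (g$diel == "day") +
              sex_effect * (sex[i] == "M") + b[i])
  g$count <- rpois(nrow(g), mu)
  g$sex <- sex[i]
  g$receiver_id <- "R1"
  tibble::as_tibble(g)
}

# Gamma visit durations with log-linear hour/moon/location effects.
sim_gamma_visits <- function(n, hour_amp = 0.4, hour_peak = 10, b_moon = 0,
                             b_clam = 0, n_tags = 15, shape = 2,
                             re_sd = 0.2, base_mean = 25) {
  tags <- sprintf("T%02d", seq_len(n_tags))
  b <- rnorm(n_tags, 0, re_sd)
  i <- sample(n_tags, n, replace = TRUE)
  h <- runif(n, 0, 24)
  m <- runif(n)
  loc <- sample(c("clam_lease", "other"), n, replace = TRUE)
  mu <- exp(log(base_mean) + hour_amp * cos(2 * pi * (h - hour_peak) / 24) +
              b_moon * (m - 0.5) + b_clam * (loc == "clam_lease") + b[i])
  tibble::tibble(
    duration_min = rgamma(n, shape, scale = mu / shape),
    decimal_hour = h, moon_fraction = m,
    water_temp_c = runif(n, 18, 31),
    general_location = loc, transmitter_id = tags[i],
    true_mean_min = mu
  )
}

# predicted response-scale hour profile with other covariates held fixed
hour_profile <- function(fit, data, by = 0.1) {
  grid <- tibble::tibble(
    decimal_hour = seq(0, 24 - by, by = by),
    moon_fraction = 0.5, water_temp_c = 25,
    general_location = "other",
    transmitter_id = data$transmitter_id[1]
  )
  list(hour = grid$decimal_hour,
       mu = as.numeric(predict(fit$model, grid, type = "response")))
}
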