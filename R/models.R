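# Mixed-model inference: Poisson GLMM for detection counts, Gamma GAMM for
# visit durations, collinearity screening and AICc subset selection.

#' Collinearity screen for model covariates
#'
#' Pairwise Pearson correlations and variance inflation factors (each
#' covariate regressed on all the others). Covariates are dropped
#' iteratively: while any VIF exceeds the threshold, the worst offender is
#' removed (ties broken toward the later-listed column, so of a collinear
#' pair the first-listed covariate is kept) and VIFs are recomputed.
#' Constant columns get an `NA` VIF and a flag; perfectly duplicated
#' columns get an infinite VIF.
#'
#' @param covariates Data frame of numeric covariates (>= 2 columns,
#'   >= 10 rows).
#' @param vif_threshold Drop threshold (default 3).
#' @return List: `correlation` matrix, `vif` named vector (for the full
#'   set), `dropped` character vector, `kept` character vector, `flagged`
#'   (constant/degenerate columns).
#' @export
collinearity_screen <- function(covariates, vif_threshold = 3) {
  x <- as.data.frame(covariates)
  stopifnot(ncol(x) >= 2, nrow(x) >= 10)
  if (!all(vapply(x, is.numeric, logical(1)))) {
    stop("all covariates must be numeric")
  }
  constant <- vapply(x, function(v) stats::var(v, na.rm = TRUE) == 0, logical(1))
  corr <- suppressWarnings(stats::cor(x, use = "pairwise.complete.obs"))
  vif_of <- function(dat) {
    vapply(names(dat), function(j) {
      if (stats::var(dat[[j]], na.rm = TRUE) == 0) return(NA_real_)
      fit <- stats::lm(dat[[j]] ~ ., data = dat[setdiff(names(dat), j)])
      r2 <- suppressWarnings(summary(fit)$r.squared)
      if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
    }, numeric(1))
  }
  vif_full <- vif_of(x)
  keep <- setdiff(names(x), names(x)[constant])
  dropped <- character(0)
  repeat {
    if (length(keep) < 2) break
    v <- vif_of(x[keep])
    bad <- which(!is.na(v) & v > vif_threshold)
    if (!length(bad)) break
    # drop the later-listed offender, so the first-listed of a collinear
    # pair is the one retained
    worst <- max(bad)
    dropped <- c(dropped, keep[worst])
    keep <- keep[-worst]
  }
  list(
    correlation = corr, vif = vif_full, dropped = dropped, kept = keep,
    flagged = names(x)[constant | !is.finite(vif_full)]
  )
}

#' Second-order corrected AIC
#'
#' `AICc = AIC + 2k(k+1)/(n-k-1)` with `k` the number of estimated
#' parameters. Returns `Inf` when `n <= k + 1` (the correction blows up at
#' the boundary).
#'
#' @param fit A fitted model with `logLik` and `AIC` methods.
#' @return AICc value.
#' @export
aicc <- function(fit) {
  ll <- stats::logLik(fit)
  k <- attr(ll, "df")
  n <- stats::nobs(fit)
  if (n - k - 1 <= 0) return(Inf)
  stats::AIC(fit) + 2 * k * (k + 1) / (n - k - 1)
}

#' Detection-count GLMM specification
#'
#' @param fixed One-sided formula for the fixed effects; the default is
#'   the full time-of-day x receiver x sex interaction.
#' @param random Grouping variable for the random intercept.
#' @return A `glmm_spec` list.
#' @export
glmm_spec <- function(fixed = ~ diel * receiver_id * sex,
                      random = "transmitter_id") {
  structure(list(fixed = fixed, random = random), class = "glmm_spec")
}

#' Aggregate detections to model cells
#'
#' The detection-count modelling unit: one row per tag x local date x
#' receiver x diel cell. With `fill_zeros = TRUE` (default) the grid is
#' completed with zero counts over each tag's detected date span and all
#' supplied receivers, so absences inform the model.
#'
#' @param dets Annotated detections (from [annotate_detections()]).
#' @param tags Tag metadata (adds `sex`, `species`).
#' @param receivers Receiver tibble (grid of receivers for zero fill).
#' @param fill_zeros Complete the per-tag grid with zero cells.
#' @return Tibble with `transmitter_id`, `date`, `receiver_id`, `diel`,
#'   `sex`, `species`, `count`.
#' @export
detection_cells <- function(dets, tags, receivers, fill_zeros = TRUE) {
  stopifnot(all(c("diel", "date") %in% names(dets)))
  d <- join_species(dets, tags)
  cells <- d |>
    dplyr::group_by(.data$transmitter_id, .data$species, .data$date,
                    .data$receiver_id, .data$diel) |>
    dplyr::summarise(count = dplyr::n(), .groups = "drop")
  if (fill_zeros) {
    span <- cells |>
      dplyr::group_by(.data$transmitter_id, .data$species) |>
      dplyr::summarise(first = min(.data$date), last = max(.data$date),
                       .groups = "drop")
    grid <- span |>
      dplyr::rowwise() |>
      dplyr::reframe(
        transmitter_id = .data$transmitter_id, species = .data$species,
        date = seq(.data$first, .data$last, by = "day")
      ) |>
      tidyr::crossing(receiver_id = receivers$receiver_id,
                      diel = c("day", "night"))
    cells <- dplyr::left_join(
      grid, cells,
      by = c("transmitter_id", "species", "date", "receiver_id", "diel")
    )
    cells$count[is.na(cells$count)] <- 0L
  }
  cells$sex <- tags$sex[match(cells$transmitter_id, tags$transmitter_id)]
  cells
}

glmm_formula <- function(spec) {
  rhs <- paste(deparse(spec$fixed[[2]]), collapse = " ")
  stats::as.formula(paste0("count ~ ", rhs, " + (1 | ", spec$random, ")"))
}

#' Fit the detection-count GLMM
#'
#' Poisson GLMM (log link, Laplace approximation via [lme4::glmer()]) of
#' per-cell detection counts with a random intercept per transmitter.
#' Convergence problems are recorded in the result, never silently
#' ignored.
#'
#' @param cells Model cells from [detection_cells()] (or any tibble with a
#'   `count` column and the spec's covariates).
#' @param spec A [glmm_spec()].
#' @return A `rayvisits_fit` list: `model`, `coefficients` tibble
#'   (estimate, SE, z, p), `converged`, `messages`, `AICc`,
#'   `variance_components`.
#' @export
fit_detection_glmm <- function(cells, spec = glmm_spec()) {
  fvars <- all.vars(spec$fixed)
  for (v in fvars) {
    if (is.character(cells[[v]])) cells[[v]] <- factor(cells[[v]])
    if (is.factor(cells[[v]]) && nlevels(droplevels(cells[[v]])) < 2) {
      stop("fixed-effect factor '", v, "' has fewer than 2 levels")
    }
  }
  cells[[spec$random]] <- factor(cells[[spec$random]])
  msgs <- character(0)
  fit <- withCallingHandlers(
    lme4::glmer(glmm_formula(spec), data = cells, family = stats::poisson()),
    warning = function(w) {
      msgs <<- c(msgs, conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )
  # a singular (boundary) fit is a zero variance estimate, not a failure
  lme4_msgs <- unlist(fit@optinfo$conv$lme4)
  real_problem <- function(m) {
    length(m) > 0 && !all(grepl("boundary|singular", m, ignore.case = TRUE))
  }
  conv <- !real_problem(lme4_msgs) &&
    !any(grepl("converge", msgs, ignore.case = TRUE))
  co <- summary(fit)$coefficients
  structure(list(
    model = fit,
    coefficients = tibble::tibble(
      term = rownames(co), estimate = co[, 1], se = co[, 2],
      z = co[, 3], p = co[, 4]
    ),
    variance_components = as.data.frame(lme4::VarCorr(fit)),
    converged = conv, messages = msgs, AICc = aicc(fit),
    family = "poisson(log)"
  ), class = "rayvisits_fit")
}

#' Tukey-adjusted pairwise contrasts
#'
#' Estimated marginal means on the link scale for a factor of the fit,
#' with all pairwise differences adjusted by the Tukey studentized-range
#' method via [emmeans::emmeans()].
#'
#' @param fit A `rayvisits_fit` from [fit_detection_glmm()] (or any model
#'   emmeans understands).
#' @param factor emmeans specification: a factor name like
#'   `"receiver_id"`, or e.g. `"diel | receiver_id"` for within-receiver
#'   day/night contrasts.
#' @return Tibble of contrasts with Tukey-adjusted p-values.
#' @export
pairwise_contrasts <- function(fit, factor = "receiver_id") {
  model <- if (inherits(fit, "rayvisits_fit")) fit$model else fit
  if (inherits(fit, "rayvisits_fit") && !fit$converged) {
    warning("model did not converge cleanly; contrasts may be unreliable")
  }
  spec <- stats::as.formula(paste("~", factor))
  emm <- emmeans::emmeans(model, spec)
  ctr <- emmeans::contrast(emm, method = "pairwise", adjust = "tukey")
  tibble::as_tibble(summary(ctr))
}

#' Visit-duration GAMM specification
#'
#' @param smooths Covariates entering as penalized smooths. `decimal_hour`
#'   always gets a cyclic basis (0 h and 24 h are the same instant).
#' @param parametric Parametric (factor) terms.
#' @param random Grouping variable for the random intercept (penalized
#'   `"re"` smooth).
#' @param k Basis dimension per smooth (default 9: reference df 8 plus
#'   the identifiability constraint).
#' @param link Gamma link: `"inverse"` (attempted first) or `"log"`.
#' @return A `gamm_spec` list.
#' @export
gamm_spec <- function(smooths = c("decimal_hour", "moon_fraction",
                                  "water_temp_c", "salinity", "do_mg_l"),
                      parametric = c("tide_state", "general_location"),
                      random = "transmitter_id", k = 9,
                      link = c("inverse", "log")) {
  structure(list(smooths = smooths, parametric = parametric,
                 random = random, k = k, link = match.arg(link)),
            class = "gamm_spec")
}

gamm_formula <- function(spec, smooths = spec$smooths,
                         parametric = spec$parametric) {
  sm <- vapply(smooths, function(v) {
    if (v == "decimal_hour") {
      sprintf("s(%s, bs = \"cc\", k = %d)", v, spec$k)
    } else {
      sprintf("s(%s, k = %d)", v, spec$k)
    }
  }, character(1))
  terms <- c(sm, parametric,
             sprintf("s(%s, bs = \"re\")", spec$random))
  stats::as.formula(paste("duration_min ~", paste(terms, collapse = " + ")))
}

fit_gam_once <- function(formula, data, link, spec) {
  knots <- if ("decimal_hour" %in% all.vars(formula)) {
    list(decimal_hour = c(0, 24))
  }
  mgcv::gam(formula, data = data, family = stats::Gamma(link = link),
            method = "REML", knots = knots)
}

#' Fit the visit-duration GAMM
#'
#' Gamma GAMM of visit duration with penalized smooths (REML smoothing
#' selection), a cyclic basis for decimal hour, parametric tide-state and
#' location terms, and a penalized random intercept per animal. The
#' inverse link is attempted first; if fitting fails or does not converge,
#' the model is refitted with a log link and flagged (`link_fallback`).
#'
#' @param visits Annotated visit tibble from [annotate_visits()] with
#'   strictly positive `duration_min`. Rows with missing covariates are
#'   dropped with a message.
#' @param spec A [gamm_spec()].
#' @param min_visits Minimum rows required (default 50).
#' @return A `rayvisits_fit` list: `model`, `smooths` tibble (edf, Ref.df,
#'   F, p), `coefficients` (parametric terms), `converged`,
#'   `link_fallback`, `AICc`, `family`.
#' @export
fit_visit_gamm <- function(visits, spec = gamm_spec(), min_visits = 50) {
  f <- gamm_formula(spec)
  vars <- unique(c("duration_min", spec$smooths, spec$parametric, spec$random))
  dat <- visits[, intersect(vars, names(visits)), drop = FALSE]
  missing_vars <- setdiff(vars, names(dat))
  if (length(missing_vars)) {
    stop("visits lack model column(s): ", paste(missing_vars, collapse = ", "))
  }
  cc <- stats::complete.cases(dat)
  if (any(!cc)) {
    message(sum(!cc), " visit(s) dropped for missing covariates")
    dat <- dat[cc, , drop = FALSE]
  }
  stopifnot(all(dat$duration_min > 0))
  if (nrow(dat) < min_visits) stop("fewer than ", min_visits, " usable visits")
  for (v in spec$parametric) dat[[v]] <- factor(dat[[v]])
  dat[[spec$random]] <- factor(dat[[spec$random]])
  fallback <- FALSE
  fit <- NULL
  if (spec$link == "inverse") {
    fit <- tryCatch(fit_gam_once(f, dat, "inverse", spec),
                    error = function(e) NULL)
    if (is.null(fit) || !fit$converged) {
      fallback <- TRUE
      fit <- fit_gam_once(f, dat, "log", spec)
    }
  } else {
    fit <- fit_gam_once(f, dat, "log", spec)
  }
  s <- summary(fit)
  structure(list(
    model = fit,
    smooths = tibble::tibble(
      term = rownames(s$s.table), edf = s$s.table[, "edf"],
      ref_df = s$s.table[, "Ref.df"], statistic = s$s.table[, 3],
      p = s$s.table[, 4]
    ),
    coefficients = tibble::tibble(
      term = rownames(s$p.table), estimate = s$p.table[, 1],
      se = s$p.table[, 2], statistic = s$p.table[, 3], p = s$p.table[, 4]
    ),
    r_sq_adj = s$r.sq,
    converged = fit$converged, link_fallback = fallback,
    AICc = aicc(fit),
    family = paste0("Gamma(", if (fallback) "log" else spec$link, ")")
  ), class = "rayvisits_fit")
}

#' @export
print.rayvisits_fit <- function(x, ...) {
  cat("rayvisits model fit:", x$family,
      if (isTRUE(x$link_fallback)) "[link fallback]" else "", "\n")
  cat("converged:", x$converged, "  AICc:", round(x$AICc, 2), "\n")
  if (!is.null(x$smooths) && nrow(x$smooths)) {
    cat("\nSmooth terms:\n")
    print(as.data.frame(x$smooths), digits = 3)
  }
  cat("\nParametric coefficients:\n")
  print(as.data.frame(x$coefficients), digits = 3)
  invisible(x)
}

#' AICc subset selection over GAMM terms
#'
#' Fits every subset of the specification's smooth and parametric terms
#' (the random intercept is always retained, as is the intercept-only
#' model) and ranks them by AICc. Ties within `tie_tol` are broken toward
#' fewer terms. Subsets that fail to fit are recorded and excluded from
#' the ranking.
#'
#' @param spec Full [gamm_spec()].
#' @param visits Annotated visit data.
#' @param tie_tol AICc difference treated as a tie (default 0.01).
#' @return Tibble ranked by AICc: `terms` (comma-joined), `n_terms`,
#'   `AICc`, `delta_AICc`, `weight`, `converged`, `note`.
#' @export
aicc_model_selection <- function(spec, visits, tie_tol = 0.01) {
  all_terms <- c(spec$smooths, spec$parametric)
  n <- length(all_terms)
  subsets <- lapply(0:(2^n - 1), function(m) all_terms[bitwAnd(m, 2^(0:(n - 1))) > 0])
  rows <- lapply(subsets, function(tt) {
    sm <- intersect(spec$smooths, tt)
    pa <- intersect(spec$parametric, tt)
    sub_spec <- spec
    sub_spec$smooths <- sm
    sub_spec$parametric <- pa
    res <- tryCatch(
      suppressMessages(fit_visit_gamm(visits, sub_spec)),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      tibble::tibble(terms = paste(tt, collapse = ","),
                     n_terms = length(tt), AICc = NA_real_,
                     converged = FALSE, note = conditionMessage(res))
    } else {
      tibble::tibble(terms = paste(tt, collapse = ","),
                     n_terms = length(tt), AICc = res$AICc,
                     converged = res$converged,
                     note = if (res$link_fallback) "link fallback" else "")
    }
  })
  tab <- dplyr::bind_rows(rows)
  ok <- tab[!is.na(tab$AICc) & tab$converged, , drop = FALSE]
  failed <- tab[is.na(tab$AICc) | !tab$converged, , drop = FALSE]
  ok <- ok[order(ok$AICc, ok$n_terms), , drop = FALSE]
  # tie-break: within tie_tol of the best, prefer fewer terms
  best_val <- ok$AICc[1]
  tied <- which(ok$AICc - best_val < tie_tol)
  if (length(tied) > 1) {
    lead <- tied[order(ok$n_terms[tied], ok$AICc[tied])]
    ok <- rbind(ok[lead, ], ok[-lead, ])
  }
  ok$delta_AICc <- ok$AICc - min(ok$AICc)
  ok$weight <- exp(-ok$delta_AICc / 2) / sum(exp(-ok$delta_AICc / 2))
  if (nrow(failed)) {
    failed$delta_AICc <- NA_real_
    failed$weight <- NA_real_
  }
  dplyr::bind_rows(ok, failed)
}
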