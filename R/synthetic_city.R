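#' Intervention effect specification
#'
#' Describes the planted causal response of health outcomes to added path
#' mileage: a saturating dose-response gated by the tract's demographic (DBC)
#' factor score, realized after a fixed lag. A tract whose true DBC score lies
#' below `dbc_gate` receives no benefit regardless of mileage; above the gate
#' the reference outcome's prevalence drop is
#' `max_drop * delta / (delta + half_sat)` percentage points for `delta`
#' added miles, reaching half of `max_drop` at `delta = half_sat`. Outcomes
#' respond proportionally to their cross-sectional dispersion: the drop for
#' outcome `o` is scaled by `scale_o / scale_ref`, where the reference is the
#' first health outcome in the catalog, so a low-variability outcome (e.g.
#' stroke prevalence) moves less in absolute terms than a high-variability
#' one (e.g. high blood pressure).
#'
#' @param max_drop Maximum prevalence drop in percentage points (>= 0).
#' @param half_sat Added miles at which half of `max_drop` is realized (> 0).
#' @param dbc_gate True-DBC-score threshold below which the effect is zero.
#' @param lag Years between the intervention and the realized outcome change.
#' @param noise_sd SD of the tract-by-outcome noise added to a nonzero drop,
#'   in percentage points.
#' @return An object of class `effect_spec`.
#' @export
effect_spec <- function(max_drop = 3, half_sat = 0.5, dbc_gate = -0.75,
                        lag = 5, noise_sd = 0.15) {
  stopifnot(max_drop >= 0, half_sat > 0, lag >= 0, noise_sd >= 0)
  structure(list(max_drop = max_drop, half_sat = half_sat,
                 dbc_gate = dbc_gate, lag = lag, noise_sd = noise_sd),
            class = "effect_spec")
}

#' Default signal-variable table for the synthetic city
#'
#' Twelve variables, four per factor, with loadings 0.80-0.95. The CDC
#' prevalence loadings are highest because real small-area estimates are
#' model-based predictions from demographics and carry little
#' tract-idiosyncratic variance.
#'
#' @return Data frame with columns `name`, `category`, `units`, `factor`,
#'   `loading`, `base`, `scale`.
#' @export
default_signal_vars <- function() {
  data.frame(
    name = c("pct_college", "median_income_k", "pct_employed",
             "pct_owner_occupied",
             "diabetes_pct", "high_blood_pressure_pct",
             "poor_physical_health_pct", "stroke_pct",
             "bpp_miles", "strava_use_count", "counter_daily_avg",
             "pct_active_commute"),
    category = c(rep("ACS_demographic", 4), rep("CDC_health_outcome", 4),
                 "path_mileage", rep("path_use", 3)),
    units = c("%", "thousand USD", "%", "%", "%", "%", "%", "%",
              "miles", "trips/year", "crossings/day", "%"),
    factor = c(rep("DBC", 4), rep("health", 4), rep("BPH", 4)),
    # CDC prevalences are model-based small-area estimates, largely driven by
    # tract demographics, hence near-deterministic given the factors
    loading = c(0.90, 0.85, 0.80, 0.90, 0.95, 0.95, 0.95, 0.95,
                0.80, 0.90, 0.85, 0.80),
    base = c(30, 55, 60, 55, 11, 32, 13, 4, 4, 1800, 120, 8),
    scale = c(10, 12, 8, 15, 2.5, 5, 3, 1.2, 1.5, 600, 40, 3),
    stringsAsFactors = FALSE
  )
}

#' Default distractor variables for the synthetic city
#'
#' Two variables cross-loading 0.45/0.45, designed to fail the 0.5 loading
#' rule and be discarded by the iterative EFA filter. Both sit on the
#' DBC/BPH pair — the factor pair whose dependence is linear throughout — so
#' their planted sub-threshold pattern loadings are exactly interpretable
#' (the gated health factor would confound the margin with model misfit).
#'
#' @return Data frame with columns `name`, `category`, `units`, `factor_a`,
#'   `factor_b`, `loading_a`, `loading_b`, `base`, `scale`. Subset to zero
#'   rows for a distractor-free panel.
#' @export
default_distractors <- function() {
  data.frame(
    name = c("pct_broadband", "pct_new_housing"),
    category = c("ACS_demographic", "ACS_demographic"),
    units = c("%", "%"),
    factor_a = c("DBC", "DBC"),
    factor_b = c("BPH", "BPH"),
    loading_a = c(0.45, 0.45),
    loading_b = c(0.45, 0.45),
    base = c(70, 6),
    scale = c(8, 2.5),
    stringsAsFactors = FALSE
  )
}

#' Synthetic city configuration
#'
#' Defines the generative world for a multi-year census-tract panel whose
#' observed variables load on three correlated latent factors: DBC
#' (demographics and background characteristics), health (adverse-outcome
#' burden), and BPH (bicycling and pedestrian habits, including the path
#' mileage variable). Distractor variables cross-load weakly on two factors
#' and are expected to fail the communality filter. Health outcomes are
#' prevalence percentages; they additionally carry an AR(1) drift and a small
#' secular improvement trend proportional to the tract's BPH score, active
#' only above the DBC gate of `effect`.
#'
#' @param n_tracts Number of census tracts.
#' @param years Contiguous integer vector of panel years.
#' @param factor_corr 3x3 positive-definite correlation matrix for
#'   (DBC, health, BPH). High DBC means more background advantage, high health
#'   means a higher adverse-outcome burden, high BPH means more active-path
#'   habits; the defaults encode an advantaged-healthier-more-active city.
#' @param signal_vars Data frame describing signal variables (see
#'   `default_signal_vars()` for the required columns).
#' @param distractors Data frame of cross-loading distractors (possibly
#'   zero-row), columns as in `default_distractors()`.
#' @param noise_sd SD of measurement noise added on the standardized scale on
#'   top of each variable's intrinsic uniqueness.
#' @param drift_sd Yearly SD, in percentage points, of the AR(1) drift on
#'   health outcomes.
#' @param drift_phi AR(1) coefficient of the drift.
#' @param trend_rate Secular improvement trend on health outcomes, in variable
#'   SD units per year per BPH factor SD, applied only above the DBC gate.
#' @param effect An [effect_spec] controlling the gate and the intervention
#'   response.
#' @param seed Integer seed.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_tracts = 195,
                         years = 2011:2021,
                         factor_corr = matrix(c(1, -0.80, 0.30,
                                                -0.80, 1, -0.60,
                                                0.30, -0.60, 1), 3, 3,
                                              dimnames = list(
                                                c("DBC", "health", "BPH"),
                                                c("DBC", "health", "BPH"))),
                         signal_vars = default_signal_vars(),
                         distractors = default_distractors(),
                         noise_sd = 0.3,
                         drift_sd = 0.3,
                         drift_phi = 0.7,
                         trend_rate = 0.08,
                         effect = effect_spec(),
                         seed = 1) {
  stopifnot(n_tracts >= 2, length(years) >= 1,
            identical(dim(factor_corr), c(3L, 3L)),
            noise_sd >= 0, drift_sd >= 0, inherits(effect, "effect_spec"))
  if (inherits(try(chol(factor_corr), silent = TRUE), "try-error")) {
    stop("factor_corr must be positive-definite", call. = FALSE)
  }
  if (is.null(dimnames(factor_corr))) {
    dimnames(factor_corr) <- list(c("DBC", "health", "BPH"),
                                  c("DBC", "health", "BPH"))
  }
  if (sum(signal_vars$category == "path_mileage") != 1) {
    stop("signal_vars must contain exactly one path_mileage variable",
         call. = FALSE)
  }
  per_factor <- table(signal_vars$factor)
  if (any(per_factor < 3)) {
    stop("each factor needs at least 3 signal variables", call. = FALSE)
  }
  structure(list(n_tracts = n_tracts, years = as.integer(years),
                 factor_corr = factor_corr, signal_vars = signal_vars,
                 distractors = distractors, noise_sd = noise_sd,
                 drift_sd = drift_sd, drift_phi = drift_phi,
                 trend_rate = trend_rate, effect = effect, seed = seed),
            class = "synth_config")
}

# Draw the true tract-level factor scores. DBC and BPH come from their
# bivariate normal margin; health is built structurally so that the
# BPH -> health channel is severed below the DBC gate (the planted "critical
# threshold"). Coefficients are solved so the ungated marginal correlations
# match factor_corr.
draw_factors <- function(n, factor_corr, dbc_gate) {
  r_db <- factor_corr["DBC", "BPH"]
  r_dh <- factor_corr["DBC", "health"]
  r_hb <- factor_corr["health", "BPH"]
  db <- MASS::mvrnorm(n, mu = c(0, 0),
                      Sigma = matrix(c(1, r_db, r_db, 1), 2, 2))
  f_dbc <- db[, 1]
  f_bph <- db[, 2]
  ab <- solve(matrix(c(1, r_db, r_db, 1), 2, 2), c(r_dh, r_hb))
  a <- ab[1]; b <- ab[2]
  resid_var <- 1 - (a^2 + b^2 + 2 * a * b * r_db)
  if (resid_var < 0) stop("factor_corr implies negative health residual variance")
  gate <- as.numeric(f_dbc >= dbc_gate)
  f_health <- a * f_dbc + b * gate * f_bph + rnorm(n, sd = sqrt(resid_var))
  cbind(DBC = f_dbc, health = f_health, BPH = f_bph)
}

# Loading matrix (variables x 3 factors) implied by a config.
config_loadings <- function(config) {
  sv <- config$signal_vars
  dv <- config$distractors
  vars <- c(sv$name, if (nrow(dv)) dv$name)
  L <- matrix(0, length(vars), 3,
              dimnames = list(vars, c("DBC", "health", "BPH")))
  for (i in seq_len(nrow(sv))) L[sv$name[i], sv$factor[i]] <- sv$loading[i]
  if (nrow(dv)) {
    for (i in seq_len(nrow(dv))) {
      L[dv$name[i], dv$factor_a[i]] <- dv$loading_a[i]
      L[dv$name[i], dv$factor_b[i]] <- dv$loading_b[i]
    }
  }
  L
}

#' Generate a synthetic city panel with planted factor structure
#'
#' Each standardized observed value is `loading x factor score` (plus
#' cross-loading terms for distractors), plus an intrinsic uniqueness term
#' with variance `1 - communal variance` (so a variable with a unit loading on
#' a single factor reproduces its factor score exactly when `noise_sd = 0`),
#' plus measurement noise with SD `noise_sd`. The standardized value is then
#' mapped affinely to the variable's base/scale. Health outcomes additionally
#' receive the AR(1) drift and gated trend, and are clipped to \[0, 100\];
#' path mileage is constant across years within a tract (paths persist) and
#' clipped at 0.
#'
#' @param config A [synth_config].
#' @return A list with elements `panel` (a [city_panel]) and `truth` (class
#'   `ground_truth`: true factor scores, true variable-to-factor assignment
#'   with `NA` for distractors, and empty intervention bookkeeping).
#' @export
generate_city <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  with_seed(config$seed, function() generate_city_impl(config))
}

generate_city_impl <- function(config) {
  n <- config$n_tracts
  years <- config$years
  ny <- length(years)
  tracts <- sprintf("51710%06d", seq_len(n))  # 11-char synthetic FIPS codes

  F <- draw_factors(n, config$factor_corr, config$effect$dbc_gate)
  L <- config_loadings(config)
  communal <- rowSums((L %*% config$factor_corr) * L)
  psi <- pmax(1 - communal, 0)  # keeps variable names (pmax copies arg-1 attrs)

  meta <- rbind(
    config$signal_vars[, c("name", "category", "units", "base", "scale")],
    if (nrow(config$distractors)) {
      config$distractors[, c("name", "category", "units", "base", "scale")]
    }
  )
  vars <- meta$name
  outcome_vars <- meta$name[meta$category %in% prevalence_categories()]
  mil_var <- meta$name[meta$category == "path_mileage"]
  gate <- as.numeric(F[, "DBC"] >= config$effect$dbc_gate)

  data <- data.frame(
    tract_id = rep(tracts, each = ny),
    year = rep(years, times = n),
    stringsAsFactors = FALSE
  )
  signal <- F %*% t(L)  # tracts x vars, standardized common part

  for (j in seq_along(vars)) {
    v <- vars[j]
    if (v %in% mil_var) {
      # one draw per tract: mileage is a persistent built attribute
      z <- signal[, v] + rnorm(n, sd = sqrt(psi[v])) +
        rnorm(n, sd = config$noise_sd)
      val <- pmax(0, meta$base[j] + meta$scale[j] * z)
      data[[v]] <- rep(val, each = ny)
    } else {
      z <- rep(signal[, v], each = ny) +
        rnorm(n * ny, sd = sqrt(psi[v])) +
        rnorm(n * ny, sd = config$noise_sd)
      data[[v]] <- meta$base[j] + meta$scale[j] * z
    }
  }

  # AR(1) drift and gated secular trend on health outcomes
  for (v in outcome_vars) {
    sc <- meta$scale[meta$name == v]
    drift <- matrix(0, n, ny)
    if (config$drift_sd > 0 && ny > 1) {
      eps <- matrix(rnorm(n * ny, sd = config$drift_sd), n, ny)
      for (t in 2:ny) drift[, t] <- config$drift_phi * drift[, t - 1] + eps[, t]
    }
    trend <- -config$trend_rate * sc * outer(gate * F[, "BPH"],
                                             seq_len(ny) - 1)
    adj <- as.vector(t(drift + trend))  # row-major: matches rep(each = ny)
    data[[v]] <- data[[v]] + adj
  }
  for (v in intersect(vars, meta$name[meta$category %in%
                                        prevalence_categories()])) {
    data[[v]] <- pmin(100, pmax(0, data[[v]]))
  }

  catalog <- meta[, c("name", "category", "units")]
  assignment_true <- setNames(
    c(config$signal_vars$factor,
      rep(NA_character_, nrow(config$distractors))),
    vars)
  out_idx <- meta$category == "CDC_health_outcome"
  truth <- structure(list(
    factor_scores_true = data.frame(tract_id = tracts,
                                    DBC = F[, "DBC"], health = F[, "health"],
                                    BPH = F[, "BPH"],
                                    stringsAsFactors = FALSE),
    assignment_true = assignment_true,
    outcome_scales = setNames(meta$scale[out_idx], meta$name[out_idx]),
    effect_applied = NULL,
    added_miles = NULL,
    intervention_year = NULL,
    effect = config$effect
  ), class = "ground_truth")

  list(panel = city_panel(data, catalog), truth = truth)
}

#' Apply a mileage intervention with a lagged, gated outcome response
#'
#' Increases the path-mileage variable of the selected tracts from
#' `intervention_year` onward, and reduces every health-outcome variable from
#' `intervention_year + lag` onward by
#' `max_drop * delta / (delta + half_sat)` percentage points (zero below the
#' DBC gate), plus tract-by-outcome noise, clamped to `[0, max_drop]`. A tract
#' with `delta = 0` or a true DBC score below the gate records a drop of
#' exactly zero. Applied drops are recorded in the returned ground truth.
#'
#' @param panel A [city_panel] produced by [generate_city()].
#' @param truth The matching `ground_truth`.
#' @param tracts Character vector of tract IDs to intervene on.
#' @param added_miles Numeric vector of added miles, recycled to `tracts`.
#' @param intervention_year Year the mileage is added.
#' @param effect An [effect_spec]; defaults to the one stored in `truth`.
#' @param seed Integer seed for the effect noise.
#' @return List with updated `panel` and `truth` (gains `effect_applied`,
#'   `added_miles`, `intervention_year`).
#' @export
apply_intervention <- function(panel, truth, tracts, added_miles,
                               intervention_year, effect = truth$effect,
                               seed = 1) {
  stopifnot(inherits(panel, "city_panel"), inherits(truth, "ground_truth"),
            inherits(effect, "effect_spec"))
  all_tracts <- unique(panel$data$tract_id)
  unknown <- setdiff(tracts, all_tracts)
  if (length(unknown) > 0) {
    stop("tract(s) not in panel: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  added_miles <- rep_len(added_miles, length(tracts))
  names(added_miles) <- tracts
  if (any(added_miles < 0)) stop("added_miles must be >= 0", call. = FALSE)
  years <- unique(panel$data$year)
  if (intervention_year + effect$lag > max(years)) {
    stop("intervention_year + lag must lie within the panel years",
         call. = FALSE)
  }

  mil <- mileage_var(panel)
  outcome_vars <- panel$catalog$name[panel$catalog$category ==
                                       "CDC_health_outcome"]
  ts <- truth$factor_scores_true
  dbc_true <- setNames(ts$DBC, ts$tract_id)
  # dispersion-proportional scaling relative to the first (reference) outcome
  rel <- if (!is.null(truth$outcome_scales)) {
    truth$outcome_scales[outcome_vars] / truth$outcome_scales[[1]]
  } else {
    setNames(rep(1, length(outcome_vars)), outcome_vars)
  }

  drops <- with_seed(seed, function() {
    m <- matrix(0, length(tracts), length(outcome_vars),
                dimnames = list(tracts, outcome_vars))
    for (i in seq_along(tracts)) {
      delta <- added_miles[i]
      gate_open <- dbc_true[tracts[i]] >= effect$dbc_gate
      base <- effect$max_drop * delta / (delta + effect$half_sat)
      if (delta > 0 && gate_open && base > 0) {
        m[i, ] <- pmin(effect$max_drop * rel,
                       pmax(0, base * rel +
                              rel * rnorm(length(outcome_vars),
                                          sd = effect$noise_sd)))
      }
    }
    m
  })

  d <- panel$data
  for (i in seq_along(tracts)) {
    sel_mil <- d$tract_id == tracts[i] & d$year >= intervention_year
    d[[mil]][sel_mil] <- d[[mil]][sel_mil] + added_miles[i]
    sel_out <- d$tract_id == tracts[i] &
      d$year >= intervention_year + effect$lag
    for (v in outcome_vars) {
      d[[v]][sel_out] <- pmax(0, d[[v]][sel_out] - drops[tracts[i], v])
    }
  }

  truth$effect_applied <- drops
  truth$added_miles <- added_miles
  truth$intervention_year <- intervention_year
  truth$effect <- effect
  list(panel = city_panel(d, panel$catalog), truth = truth)
}
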