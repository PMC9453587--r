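# Small panels and hand-built models used across test files. Everything is
# generated in code; no fixture files.

# A tiny valid panel: n tracts x years, deterministic values.
tiny_panel <- function(n_tracts = 3, years = 2011:2012) {
  tracts <- sprintf("51710%06d", seq_len(n_tracts))
  grid <- expand.grid(tract_id = tracts, year = years,
                      stringsAsFactors = FALSE)
  grid <- grid[order(grid$tract_id, grid$year), ]
  k <- nrow(grid)
  data <- data.frame(
    tract_id = grid$tract_id, year = grid$year,
    diabetes_pct = 10 + seq_len(k) * sqrt(2) / 10,
    bpp_miles = 2 + seq_len(k) / 7,
    pct_college = 30 + seq_len(k) * pi / 10,
    stringsAsFactors = FALSE
  )
  catalog <- data.frame(
    name = c("diabetes_pct", "bpp_miles", "pct_college"),
    category = c("CDC_health_outcome", "path_mileage", "ACS_demographic"),
    units = c("%", "miles", "%"),
    stringsAsFactors = FALSE
  )
  city_panel(data, catalog)
}

# Hand-built factor model with identity scoring: each factor score equals the
# raw value of its indicator variable (centers 0, scales 1), so neighbor sets
# can be enumerated by hand. Factors: F1 = DBC (dbc_var), F2 = health
# (diabetes_pct), F3 = BPH (bpp_miles, the mileage variable).
toy_model <- function(outcomes = "diabetes_pct") {
  vars <- c("dbc_var", outcomes, "bpp_miles")
  m <- 3
  catalog <- data.frame(
    name = vars,
    category = c("ACS_demographic", rep("CDC_health_outcome",
                                        length(outcomes)), "path_mileage"),
    units = c("%", rep("%", length(outcomes)), "miles"),
    stringsAsFactors = FALSE
  )
  assignment <- setNames(c(1L, rep(2L, length(outcomes)), 3L), vars)
  L <- matrix(0, length(vars), m, dimnames = list(vars, NULL))
  L[cbind(seq_along(vars), assignment)] <- 0.9
  W <- matrix(0, length(vars), m, dimnames = list(vars, NULL))
  W["dbc_var", 1] <- 1
  W[outcomes[1], 2] <- 1
  W["bpp_miles", 3] <- 1
  structure(list(
    retained_vars = vars,
    n_factors = m,
    loadings = L,
    assignment = assignment,
    labels = c("DBC", "health", "BPH"),
    label_index = c(DBC = 1L, health = 2L, BPH = 3L),
    factor_correlations = diag(m),
    scoring_weights = W,
    var_center = setNames(rep(0, length(vars)), vars),
    var_scale = setNames(rep(1, length(vars)), vars),
    score_center = rep(0, m),
    score_scale = rep(1, m),
    threshold = 0.5,
    catalog = catalog
  ), class = "factor_model")
}

# Panel for the toy model: values given per variable as named lists of
# per-tract vectors, one year.
toy_panel <- function(dbc, bph, outcomes, year = 2015,
                      tracts = LETTERS[seq_along(dbc)]) {
  data <- data.frame(tract_id = tracts, year = year, dbc_var = dbc,
                     bpp_miles = bph, stringsAsFactors = FALSE)
  for (v in names(outcomes)) data[[v]] <- outcomes[[v]]
  catalog <- data.frame(
    name = c("dbc_var", names(outcomes), "bpp_miles"),
    category = c("ACS_demographic",
                 rep("CDC_health_outcome", length(outcomes)), "path_mileage"),
    units = c("%", rep("%", length(outcomes)), "miles"),
    stringsAsFactors = FALSE
  )
  city_panel(data, catalog)
}

# Independent brute-force oracle for the prediction algorithm: a plain double
# loop over tracts and outcomes, recomputing the query's post-addition scores
# from first principles for the identity-scoring toy model.
brute_force_predict <- function(panel, tract_id, added_miles, x,
                                outcomes, year = 2015) {
  d <- panel$data[panel$data$year == year, ]
  q <- d[d$tract_id == tract_id, ]
  q_dbc <- q$dbc_var
  q_bph <- q$bpp_miles + added_miles
  res <- list()
  for (v in outcomes) {
    imps <- numeric(0)
    for (i in seq_len(nrow(d))) {
      if (d$tract_id[i] == tract_id) next
      in_dbc <- abs(d$dbc_var[i] - q_dbc) <= x
      in_bph <- abs(d$bpp_miles[i] - q_bph) <= x
      if (in_dbc && in_bph) {
        diff <- q[[v]] - d[[v]][i]
        if (diff >= 0) imps <- c(imps, diff)
      }
    }
    empty <- length(imps) == 0
    res[[v]] <- list(
      n = length(imps),
      min = if (empty) 0 else min(imps),
      mean = if (empty) 0 else mean(imps),
      median = if (empty) 0 else median(imps),
      max = if (empty) 0 else max(imps),
      empty = empty
    )
  }
  res
}

# Planted-structure city at the scale used by the recovery checks.
recovery_config <- function(seed, n_tracts = 200, loading = 0.9) {
  cfg <- synth_config(n_tracts = n_tracts, years = 2011:2015, seed = seed)
  cfg$signal_vars$loading <- rep(loading, nrow(cfg$signal_vars))
  cfg
}

# Fit + evaluate one seeded replicate of the planted-intervention design.
# Returns the per-approach mean MAE across outcomes and the below-gate
# regression overprediction (improvement credited to the addition).
evaluate_replicate <- function(seed, n_tracts = 195, n_intervened = 40,
                               n_boot = 50) {
  cfg <- synth_config(n_tracts = n_tracts, seed = seed)
  sim <- generate_city(cfg)
  tracts <- unique(sim$panel$data$tract_id)
  picks <- local({
    set.seed(seed + 1000L)
    list(tracts = sample(tracts, n_intervened),
         miles = round(runif(n_intervened, 0.3, 2.0), 2))
  })
  si <- apply_intervention(sim$panel, sim$truth, picks$tracts, picks$miles,
                           intervention_year = 2016, seed = seed + 2000L)
  fit <- suppressWarnings(bpp_model(si$panel, fit_years = 2011:2015,
                                    seed = seed))
  ev <- run_evaluation(fit$model, si$panel, si$truth, n_boot = n_boot,
                       seed = seed)
  agg <- aggregate(mae ~ approach, ev$moes, mean)
  mae <- setNames(agg$mae, agg$approach)

  # regression-credited improvement for below-gate tracts (true effect 0)
  lr <- linreg_baseline(fit$model, si$panel, 2011:2015)
  co <- attr(lr, "coefficients")
  ts <- si$truth$factor_scores_true
  below <- ts$tract_id[ts$DBC < cfg$effect$dbc_gate]
  bg <- intersect(picks$tracts, below)
  pre <- bpphealth:::panel_subset(si$panel, years = 2011:2015)
  lab <- bpphealth:::factor_colnames(fit$model)
  bph_col <- lab[fit$model$label_index["BPH"]]
  add_imp <- vapply(bg, function(tr) {
    q1 <- bpphealth:::score_modified_tract(fit$model, pre, tr,
                                           si$truth$added_miles[[tr]], 2015)
    q0 <- bpphealth:::score_modified_tract(fit$model, pre, tr, 0, 2015)
    mean(-co["BPH", ] * (q1[bph_col] - q0[bph_col]) * 5 / 4)
  }, numeric(1))
  list(mae = mae, below_gate_overprediction = add_imp)
}
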