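test_that("iterative EFA recovers planted structure and discards distractors", {
  cfg <- recovery_config(seed = 1)
  sim <- generate_city(cfg)
  sp <- split_halves(sim$panel, 1)
  half <- bpphealth:::panel_subset(sim$panel, tracts = sp$efa_tracts)
  fit <- run_efa(half)
  model <- label_factors(fit$model)

  truth <- sim$truth$assignment_true
  signal <- names(truth)[!is.na(truth)]
  distractors <- names(truth)[is.na(truth)]

  expect_equal(model$n_factors, 3)
  expect_true(all(signal %in% model$retained_vars))
  expect_false(any(distractors %in% model$retained_vars))
  recovered <- model$labels[model$assignment[signal]]
  expect_equal(unname(recovered), unname(truth[signal]))

  # the filter's own postcondition, asserted on the returned matrix
  L <- model$loadings
  for (i in seq_along(model$retained_vars)) {
    k <- model$assignment[[i]]
    expect_gt(abs(L[i, k]), model$threshold)
    expect_true(all(abs(L[i, -k]) < model$threshold))
  }
  # discards grow monotonically across iterations
  d <- fit$report$discarded
  expect_true(all(diff(d$iteration) >= 0))
  expect_false(any(duplicated(d$variable)))
})

test_that("data already satisfying thresholds converges in one iteration", {
  cfg <- synth_config(n_tracts = 200, years = 2011:2015,
                      distractors = default_distractors()[0, ], seed = 2)
  sim <- generate_city(cfg)
  fit <- run_efa(sim$panel)
  expect_equal(fit$report$iterations, 1L)
  expect_equal(nrow(fit$report$discarded), 0)
})

test_that("pure-noise panels raise a requirements-unmet error", {
  for (s in c(3, 17)) {
    set.seed(s)
    tracts <- sprintf("51710%06d", 1:90)
    cfg <- synth_config(n_tracts = 2, seed = 1)  # borrow the catalog layout
    vars <- c(cfg$signal_vars$name)
    data <- data.frame(tract_id = tracts, year = 2015,
                       stringsAsFactors = FALSE)
    for (v in vars) data[[v]] <- rnorm(90)
    catalog <- cfg$signal_vars[, c("name", "category", "units")]
    panel <- city_panel(data, catalog)
    expect_error(run_efa(panel), "requirements unmet")
  }
})

test_that("candidate preconditions are enforced", {
  cfg <- synth_config(n_tracts = 60, years = 2011:2015, seed = 4)
  sim <- generate_city(cfg)
  expect_error(run_efa(sim$panel, candidate_vars = c("pct_college",
                                                     "diabetes_pct")),
               "mileage")
  expect_error(run_efa(sim$panel,
                       candidate_vars = c("pct_college", "bpp_miles")),
               "health outcome")
})

test_that("orthogonally planted factors yield near-zero factor correlations", {
  for (s in c(5, 6)) {
    cfg <- synth_config(n_tracts = 500, years = 2011:2015,
                        factor_corr = diag(3), trend_rate = 0,
                        distractors = default_distractors()[0, ], seed = s)
    sim <- generate_city(cfg)
    fit <- run_efa(sim$panel)
    off <- fit$model$factor_correlations[upper.tri(diag(3))]
    expect_lt(max(abs(off)), 0.15)
  }
})

test_that("factors are labeled by majority category with the stated tie-break", {
  model <- toy_model()
  # unanimous majority: 4 ACS variables -> DBC
  vars <- c(paste0("acs", 1:4), "diabetes_pct", "poor_physical_health_pct",
            "stroke_pct", "bpp_miles", "strava", "counter")
  catalog <- data.frame(
    name = vars,
    category = c(rep("ACS_demographic", 4), rep("CDC_health_outcome", 3),
                 "path_mileage", rep("path_use", 2)),
    units = "x", stringsAsFactors = FALSE)
  assignment <- setNames(c(1L, 1L, 1L, 1L, 2L, 2L, 2L, 3L, 3L, 3L), vars)
  L <- matrix(0, length(vars), 3, dimnames = list(vars, NULL))
  L[cbind(seq_along(vars), assignment)] <- 0.8
  m <- model
  m$retained_vars <- vars
  m$assignment <- assignment
  m$loadings <- L
  m$catalog <- catalog
  m$labels <- rep(NA_character_, 3)
  m$label_index <- NULL
  out <- label_factors(m)
  expect_equal(out$labels, c("DBC", "health", "BPH"))
  expect_equal(unname(out$label_index), 1:3)

  # tie: 2 CDC + 2 ACS on one factor, CDC mean |loading| higher -> health
  vars2 <- c("acs1", "acs2", "cdc1", "cdc2",
             paste0("acs", 3:5), "bpp_miles", "strava", "counter")
  catalog2 <- data.frame(
    name = vars2,
    category = c("ACS_demographic", "ACS_demographic", "CDC_health_outcome",
                 "CDC_health_outcome", rep("ACS_demographic", 3),
                 "path_mileage", rep("path_use", 2)),
    units = "x", stringsAsFactors = FALSE)
  assignment2 <- setNames(c(1L, 1L, 1L, 1L, 2L, 2L, 2L, 3L, 3L, 3L), vars2)
  L2 <- matrix(0, length(vars2), 3, dimnames = list(vars2, NULL))
  L2[cbind(seq_along(vars2), assignment2)] <-
    c(0.6, 0.6, 0.9, 0.9, 0.8, 0.8, 0.8, 0.8, 0.8, 0.8)
  m2 <- m
  m2$retained_vars <- vars2
  m2$assignment <- assignment2
  m2$loadings <- L2
  m2$catalog <- catalog2
  out2 <- label_factors(m2)
  expect_equal(out2$labels[1], "health")

  # BPH-labeled factor without the mileage variable is rejected
  m3 <- m
  m3$retained_vars <- setdiff(vars, "bpp_miles")
  m3$assignment <- assignment[m3$retained_vars]
  m3$loadings <- L[m3$retained_vars, ]
  expect_error(label_factors(m3), "mileage")
})

test_that("CFA confirms planted structure and rejects destroyed structure", {
  cfg <- recovery_config(seed = 7)
  sim <- generate_city(cfg)
  sp <- split_halves(sim$panel, 7)
  efa_half <- bpphealth:::panel_subset(sim$panel, tracts = sp$efa_tracts)
  cfa_half <- bpphealth:::panel_subset(sim$panel, tracts = sp$cfa_tracts)
  model <- label_factors(run_efa(efa_half)$model)

  rep_ok <- run_cfa(model, cfa_half)
  expect_true(rep_ok$confirmed)
  expect_named(rep_ok$fit_indices, c("CFI", "TLI", "RMSEA", "SRMR"))
  expect_true(all(abs(rep_ok$cfa_loadings[
    cbind(seq_along(model$retained_vars),
          model$assignment[model$retained_vars])]) > model$threshold))

  # self-consistency: thresholds hold when CFA reuses the EFA half
  rep_self <- run_cfa(model, efa_half)
  expect_true(rep_self$thresholds_pass)

  # independently permuting each column destroys the correlation structure
  d <- cfa_half$data
  set.seed(7)
  for (v in model$retained_vars) d[[v]] <- sample(d[[v]])
  scrambled <- city_panel(d, cfa_half$catalog)
  rep_bad <- run_cfa(model, scrambled)
  expect_false(rep_bad$confirmed)
})
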