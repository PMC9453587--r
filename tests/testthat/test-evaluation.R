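test_that("predict-no-change is the fit-window mean", {
  panel <- toy_panel(dbc = c(0, 1), bph = c(0, 1),
                     outcomes = list(diabetes_pct = c(10, 10)), year = 2011,
                     tracts = c("A", "B"))
  d <- do.call(rbind, lapply(2011:2015, function(y) {
    dd <- panel$data
    dd$year <- y
    dd$diabetes_pct <- c(8, 10) + (y - 2011)  # A: 8..12, B: constant-ish
    dd
  }))
  d$diabetes_pct[d$tract_id == "B"] <- 10
  p5 <- city_panel(d, panel$catalog)
  expect_equal(predict_no_change(p5, 2011:2015, "A", "diabetes_pct"), 10)
  expect_equal(predict_no_change(p5, 2011:2015, "B", "diabetes_pct"), 10)
  expect_error(predict_no_change(p5, 2001:2005, "A", "diabetes_pct"),
               "fit window")
})

make_linreg_panel <- function(n = 30, slope_dbc = 2, slope_bph = 0,
                              noise = 0, seed = 51) {
  set.seed(seed)
  dbc <- rnorm(n)
  bph <- rnorm(n)
  base <- runif(n, 20, 40)
  rows <- lapply(2011:2015, function(y) {
    data.frame(tract_id = sprintf("T%02d", 1:n), year = y,
               dbc_var = dbc, bpp_miles = bph,
               diabetes_pct = base + (y - 2011) / 4 *
                 (slope_dbc * dbc + slope_bph * bph) +
                 rnorm(n, sd = noise),
               stringsAsFactors = FALSE)
  })
  catalog <- data.frame(
    name = c("dbc_var", "diabetes_pct", "bpp_miles"),
    category = c("ACS_demographic", "CDC_health_outcome", "path_mileage"),
    units = c("%", "%", "miles"), stringsAsFactors = FALSE)
  city_panel(do.call(rbind, rows), catalog)
}

test_that("the regression baseline recovers a noiseless linear change", {
  model <- toy_model()
  panel <- make_linreg_panel(slope_dbc = 2, slope_bph = 0)
  f <- linreg_baseline(model, panel, 2011:2015, horizon_years = 5)
  co <- attr(f, "coefficients")[, "diabetes_pct"]
  expect_equal(unname(co), c(0, 2, 0), tolerance = 1e-6)
  # prediction = last + fitted change * horizon / span, clipped
  expect_equal(unname(f("diabetes_pct", 30, dbc = 1, bph = 0)),
               30 + 2 * 5 / 4, tolerance = 1e-6)
  expect_equal(unname(f("diabetes_pct", 99.9, dbc = 10, bph = 0)), 100)
})

test_that("zero change everywhere predicts no change for every tract", {
  model <- toy_model()
  panel <- make_linreg_panel(slope_dbc = 0, slope_bph = 0)
  f <- linreg_baseline(model, panel, 2011:2015)
  expect_equal(unname(f("diabetes_pct", 25, dbc = 1.7, bph = -2)), 25,
               tolerance = 1e-8)
})

test_that("a collinear design is rejected", {
  model <- toy_model()
  panel <- make_linreg_panel()
  d <- panel$data
  d$dbc_var <- 1  # constant DBC score
  expect_error(linreg_baseline(model, city_panel(d, panel$catalog),
                               2011:2015), "rank-deficient")
})

test_that("MAE and RMSE match closed forms with deterministic bootstrap SDs", {
  preds <- data.frame(
    tract_id = sprintf("T%d", 1:3), outcome = "diabetes_pct",
    approach = "ours", predicted = c(11, 12, 13), actual = c(10, 10, 10),
    stringsAsFactors = FALSE)
  m <- compute_moes(preds, n_boot = 500, seed = 3)
  expect_equal(m$mae, 2)
  expect_equal(m$rmse, sqrt(14 / 3), tolerance = 1e-12)
  expect_gte(m$rmse, m$mae)

  m2 <- compute_moes(preds, n_boot = 500, seed = 3)
  expect_identical(m, m2)

  const <- preds
  const$predicted <- const$actual - 1.5  # every error exactly -1.5
  mc <- compute_moes(const, n_boot = 200, seed = 1)
  expect_equal(mc$mae, 1.5)
  expect_equal(mc$rmse, 1.5)
  expect_equal(mc$mae_sd, 0)
  expect_equal(mc$rmse_sd, 0)
  expect_error(compute_moes(preds[0, ]), "empty")
})

test_that("the one-tailed paired t test matches closed forms and flags degeneracy", {
  r <- paired_one_tailed_t(c(0, 2), c(1, 1))  # d = (-1, 1)
  expect_equal(r$t, 0)
  expect_equal(r$p, 0.5)

  # d = (-2, -1, -3, -2): t = mean(d)/(sd(d)/2) = -4.899 with 3 df; the
  # expected p comes from the closed-form t CDF
  r2 <- paired_one_tailed_t(c(0, 1, 0, 1), c(2, 2, 3, 3))
  t_exp <- -2 / (sqrt(2 / 3) / 2)
  expect_equal(r2$t, t_exp, tolerance = 1e-10)
  expect_equal(r2$t, -4.8990, tolerance = 1e-4)
  expect_equal(r2$p, pt(t_exp, 3), tolerance = 1e-10)
  expect_equal(r2$df, 3)

  same <- c(1.2, 3.4, 2.2)
  r3 <- paired_one_tailed_t(same, same)
  expect_true(r3$degenerate)
  expect_equal(r3$p, 1)

  r4 <- paired_one_tailed_t(c(1, 1, 1), c(2, 2, 2))  # constant negative d
  expect_true(r4$degenerate)
  expect_equal(r4$p, 0)
})

test_that("the t test is calibrated under an exchangeable null", {
  set.seed(61)
  n_rep <- 400
  rejections <- 0
  for (i in seq_len(n_rep)) {
    ours <- abs(rnorm(31))
    alt <- abs(rnorm(31))
    rejections <- rejections + (paired_one_tailed_t(ours, alt)$p < 0.05)
  }
  expect_lt(abs(rejections / n_rep - 0.05), 0.03)
})

test_that("the full evaluation satisfies its structural invariants", {
  rep1 <- evaluate_replicate(seed = 1, n_tracts = 100, n_intervened = 20,
                             n_boot = 50)
  expect_named(rep1$mae, c("linreg", "no_change", "ours"))

  cfg <- synth_config(n_tracts = 100, seed = 1)
  sim <- generate_city(cfg)
  tracts <- unique(sim$panel$data$tract_id)
  set.seed(1001)
  si <- apply_intervention(sim$panel, sim$truth, sample(tracts, 20),
                           round(runif(20, 0.3, 2), 2), 2016, seed = 2001)
  fit <- suppressWarnings(bpp_model(si$panel, fit_years = 2011:2015,
                                    seed = 1))
  ev <- run_evaluation(fit$model, si$panel, si$truth, n_boot = 50, seed = 1)
  expect_true(all(ev$moes$rmse >= ev$moes$mae - 1e-12))
  expect_true(all(ev$tests$p >= 0 & ev$tests$p <= 1))
  expect_true(all(ev$predictions$predicted >= 0 &
                    ev$predictions$predicted <= 100))
  expect_equal(nrow(ev$moes),
               3 * length(unique(ev$predictions$outcome)))
  # bootstrap determinism
  ev2 <- run_evaluation(fit$model, si$panel, si$truth, n_boot = 50, seed = 1)
  expect_identical(ev$moes, ev2$moes)
  # csv export mirrors the MOE table
  tmp <- tempfile(fileext = ".csv")
  out <- write_evaluation_csv(ev, tmp)
  expect_true(file.exists(tmp))
  expect_equal(nrow(out), nrow(ev$moes))
})
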