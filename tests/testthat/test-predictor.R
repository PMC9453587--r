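test_that("neighbor matching and the discard rule follow the hand enumeration", {
  # DBC scores A=0, B=0.2, C=0.4, D=1.0; BPH scores A=0, B=0.3, C=0.8, D=0.1
  # (identity scoring, zero added miles); x=0.5. DBC ball around A: {B, C};
  # BPH ball: {B, D}; intersection {B}. diabetes A=12, B=10 -> improvement 2.
  model <- toy_model()
  panel <- toy_panel(dbc = c(0, 0.2, 0.4, 1.0), bph = c(0, 0.3, 0.8, 0.1),
                     outcomes = list(diabetes_pct = c(12, 10, 9, 8)))
  scores <- compute_scores(model, panel, year = 2015)
  pred <- predict_improvements(model, panel, scores, "A", added_miles = 0,
                               x = 0.5)
  expect_equal(pred$neighbors, "B")
  s <- pred$summary
  expect_equal(s$n_improvements, 1)
  expect_equal(c(s$min, s$mean, s$median, s$max), rep(2, 4))
  expect_false(s$empty_flag)

  # same setup but B's diabetes = 15: the only difference is -3, discarded
  panel2 <- toy_panel(dbc = c(0, 0.2, 0.4, 1.0), bph = c(0, 0.3, 0.8, 0.1),
                      outcomes = list(diabetes_pct = c(12, 15, 9, 8)))
  pred2 <- predict_improvements(model, panel2, scores, "A", added_miles = 0,
                                x = 0.5)
  s2 <- pred2$summary
  expect_true(s2$empty_flag)
  expect_equal(c(s2$min, s2$mean, s2$median, s2$max), rep(0, 4))

  # a huge radius never binds: every other tract is a neighbor
  pred3 <- predict_improvements(model, panel, scores, "A", added_miles = 0,
                                x = 10)
  expect_setequal(pred3$neighbors, c("B", "C", "D"))

  # closed ball: a tract at exactly distance x is included
  pred4 <- predict_improvements(model, panel, scores, "A", added_miles = 0,
                                x = 0.4)
  expect_true("C" %in% c(pred4$neighbors,
                         scores$tract_id[abs(scores$DBC - 0) <= 0.4]))
  expect_error(predict_improvements(model, panel, scores, "ZZ", 0, 0.5),
               "unknown tract")
})

test_that("adding zero miles reproduces the neighbor set of current scores", {
  model <- toy_model()
  set.seed(41)
  n <- 12
  panel <- toy_panel(dbc = rnorm(n), bph = rnorm(n),
                     outcomes = list(diabetes_pct = runif(n, 5, 20)),
                     tracts = sprintf("T%02d", 1:n))
  scores <- compute_scores(model, panel, year = 2015)
  pred <- predict_improvements(model, panel, scores, "T01", added_miles = 0,
                               x = 0.7)
  q <- scores[scores$tract_id == "T01", ]
  manual <- scores$tract_id[scores$tract_id != "T01" &
                              abs(scores$DBC - q$DBC) <= 0.7 &
                              abs(scores$BPH - q$BPH) <= 0.7]
  expect_setequal(pred$neighbors, manual)
})

test_that("predict_improvements matches a brute-force oracle on random instances", {
  model <- toy_model(outcomes = c("diabetes_pct", "stroke_pct"))
  set.seed(99)
  for (rep in 1:100) {
    n <- 20
    panel <- toy_panel(dbc = rnorm(n), bph = rnorm(n),
                       outcomes = list(diabetes_pct = runif(n, 5, 25),
                                       stroke_pct = runif(n, 1, 8)),
                       tracts = sprintf("T%02d", 1:n))
    scores <- compute_scores(model, panel, year = 2015)
    tract <- sample(panel$data$tract_id, 1)
    x <- runif(1, 0.1, 1.5)
    miles <- runif(1, 0, 2)
    pred <- predict_improvements(model, panel, scores, tract,
                                 added_miles = miles, x = x)
    oracle <- brute_force_predict(panel, tract, miles, x,
                                  outcomes = c("diabetes_pct", "stroke_pct"))
    for (v in names(oracle)) {
      s <- pred$summary[pred$summary$outcome == v, ]
      o <- oracle[[v]]
      expect_equal(s$n_improvements, o$n)
      expect_equal(s$min, o$min, tolerance = 1e-12)
      expect_equal(s$mean, o$mean, tolerance = 1e-12)
      expect_equal(s$median, o$median, tolerance = 1e-12)
      expect_equal(s$max, o$max, tolerance = 1e-12)
      expect_equal(s$empty_flag, o$empty)
    }
  }
})

test_that("the sweep grid always covers the full requested mileage", {
  model <- toy_model()
  set.seed(13)
  n <- 15
  panel <- toy_panel(dbc = rnorm(n), bph = rnorm(n),
                     outcomes = list(diabetes_pct = runif(n, 5, 25)),
                     tracts = sprintf("T%02d", 1:n))
  scores <- compute_scores(model, panel, year = 2015)
  sw <- sweep_increments(model, panel, scores, "T01", total_miles = 0.25,
                         x = 0.5, step = 0.1)
  expect_equal(sw$grid, c(0.10, 0.20, 0.25))
  expect_equal(nrow(sw$trace), 3)
  expect_error(sweep_increments(model, panel, scores, "T01",
                                total_miles = 0), "> 0")
})

test_that("best median is the max of the trace and grows under refinement", {
  model <- toy_model()
  set.seed(14)
  n <- 25
  panel <- toy_panel(dbc = rnorm(n), bph = rnorm(n),
                     outcomes = list(diabetes_pct = runif(n, 5, 25)),
                     tracts = sprintf("T%02d", 1:n))
  scores <- compute_scores(model, panel, year = 2015)
  sw <- sweep_increments(model, panel, scores, "T03", total_miles = 1.5,
                         x = 0.8, step = 0.25)
  expect_equal(unname(sw$best_median["diabetes_pct"]),
               max(sw$trace$median[sw$trace$outcome == "diabetes_pct"]))
  fine <- sweep_increments(model, panel, scores, "T03", total_miles = 1.5,
                           x = 0.8, step = 0.05)
  expect_true(all(sw$grid %in% fine$grid))
  expect_gte(fine$best_median["diabetes_pct"],
             sw$best_median["diabetes_pct"])
})

test_that("a zero matching radius leaves no neighbors under continuous scores", {
  model <- toy_model()
  set.seed(15)
  n <- 10
  panel <- toy_panel(dbc = rnorm(n), bph = rnorm(n),
                     outcomes = list(diabetes_pct = runif(n, 5, 25)),
                     tracts = sprintf("T%02d", 1:n))
  scores <- compute_scores(model, panel, year = 2015)
  pred <- predict_improvements(model, panel, scores, "T02", added_miles = 0.5,
                               x = 0)
  expect_equal(pred$neighbor_count, 0)
  expect_true(all(pred$summary$empty_flag))
  expect_true(all(pred$summary$median == 0))
})
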