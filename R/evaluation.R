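#' Predict-no-change baseline
#'
#' Forecasts a tract's future health outcome as its arithmetic mean over the
#' fitting window — the analogue of predicting tomorrow's temperature as the
#' average of the last five days.
#'
#' @param panel A [city_panel].
#' @param fit_years Years to average over.
#' @param tract Tract ID.
#' @param outcome Outcome variable name.
#' @return The mean prevalence (%) over the window.
#' @export
predict_no_change <- function(panel, fit_years, tract, outcome) {
  d <- panel$data[panel$data$tract_id == tract &
                    panel$data$year %in% fit_years, , drop = FALSE]
  vals <- d[[outcome]][!is.na(d[[outcome]])]
  if (length(vals) == 0) {
    stop("no ", outcome, " data for tract ", tract, " in the fit window",
         call. = FALSE)
  }
  mean(vals)
}

#' Linear-regression baseline
#'
#' Regresses each outcome's change over the fitting window (last fit year
#' minus first) on an intercept and the tract's DBC and BPH factor scores,
#' by ordinary least squares. The returned predictor extrapolates: prediction
#' at the horizon = last observed outcome + fitted change evaluated at the
#' (post-addition) scores, rescaled by `horizon_years / window length`, and
#' clipped to \[0, 100\].
#'
#' @param model A labeled `factor_model` with frozen standardization.
#' @param panel A [city_panel] spanning `fit_years`.
#' @param fit_years Fitting window (the change is last year minus first).
#' @param horizon_years Forecast horizon in years (default 5).
#' @return A function `f(outcome, last_value, dbc, bph)` returning the
#'   predicted prevalence; its `"coefficients"` attribute holds the per-
#'   outcome OLS coefficients (intercept, DBC, BPH).
#' @export
linreg_baseline <- function(model, panel, fit_years, horizon_years = 5) {
  stopifnot(inherits(model, "factor_model"))
  if (is.null(model$label_index)) {
    stop("model has no DBC/health/BPH labels; run label_factors() first",
         call. = FALSE)
  }
  y0 <- min(fit_years); y1 <- max(fit_years)
  span <- y1 - y0
  if (span <= 0) stop("fit_years must span more than one year", call. = FALSE)

  scores <- compute_scores(model, panel, year = y1,
                           refit_standardization = FALSE)
  lab_cols <- factor_colnames(model)
  dbc_col <- lab_cols[model$label_index["DBC"]]
  bph_col <- lab_cols[model$label_index["BPH"]]

  d0 <- panel$data[panel$data$year == y0, , drop = FALSE]
  d1 <- panel$data[panel$data$year == y1, , drop = FALSE]
  common <- intersect(intersect(d0$tract_id, d1$tract_id), scores$tract_id)
  if (length(common) < 3) stop("need at least 3 tracts", call. = FALSE)
  d0 <- d0[match(common, d0$tract_id), ]
  d1 <- d1[match(common, d1$tract_id), ]
  sc <- scores[match(common, scores$tract_id), ]

  X <- cbind(1, sc[[dbc_col]], sc[[bph_col]])
  if (qr(X)$rank < 3) {
    stop("rank-deficient design: DBC and BPH scores are collinear",
         call. = FALSE)
  }
  outcomes <- health_outcome_vars(model)
  coefs <- sapply(outcomes, function(v) {
    qr.solve(X, d1[[v]] - d0[[v]])
  })
  rownames(coefs) <- c("(Intercept)", "DBC", "BPH")

  f <- function(outcome, last_value, dbc, bph) {
    ch <- coefs["(Intercept)", outcome] + coefs["DBC", outcome] * dbc +
      coefs["BPH", outcome] * bph
    pmin(100, pmax(0, last_value + ch * horizon_years / span))
  }
  attr(f, "coefficients") <- coefs
  attr(f, "horizon_years") <- horizon_years
  attr(f, "span") <- span
  f
}

#' Mean absolute and root mean squared error with bootstrap SDs
#'
#' For each (approach, outcome) cell: MAE = mean |error| and
#' RMSE = sqrt(mean error^2) over tracts, with standard deviations from a
#' nonparametric bootstrap over tracts.
#'
#' @param predictions Data frame with columns `tract_id`, `outcome`,
#'   `approach`, `predicted`, `actual` (`error = predicted - actual` is
#'   derived if absent).
#' @param n_boot Bootstrap resamples (default 1000).
#' @param seed Seed for the bootstrap, making the SDs deterministic.
#' @return Data frame with one row per (approach, outcome): `mae`, `mae_sd`,
#'   `rmse`, `rmse_sd`, `n_tracts`.
#' @export
compute_moes <- function(predictions, n_boot = 1000, seed = 1) {
  stopifnot(is.data.frame(predictions))
  if (is.null(predictions$error)) {
    predictions$error <- predictions$predicted - predictions$actual
  }
  if (nrow(predictions) == 0) stop("empty prediction set", call. = FALSE)
  cells <- unique(predictions[, c("approach", "outcome")])
  out <- with_seed(seed, function() {
    rows <- lapply(seq_len(nrow(cells)), function(i) {
      sel <- predictions$approach == cells$approach[i] &
        predictions$outcome == cells$outcome[i]
      e <- predictions$error[sel]
      n <- length(e)
      if (n < 2) stop("need >= 2 tracts per (approach, outcome) cell",
                      call. = FALSE)
      boots <- matrix(e[sample.int(n, n * n_boot, replace = TRUE)],
                      n_boot, n)
      mae_b <- rowMeans(abs(boots))
      rmse_b <- sqrt(rowMeans(boots^2))
      data.frame(approach = cells$approach[i], outcome = cells$outcome[i],
                 mae = mean(abs(e)), mae_sd = sd(mae_b),
                 rmse = sqrt(mean(e^2)), rmse_sd = sd(rmse_b),
                 n_tracts = n, stringsAsFactors = FALSE)
    })
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  })
  out
}

#' One-tailed paired t test on per-tract measures of effectiveness
#'
#' Tests whether the mean paired difference `ours - alt` is below zero, i.e.
#' whether our approach's per-tract errors are systematically smaller. The
#' per-tract MOE is `|error|` for the MAE comparison and `error^2` for the
#' RMSE comparison. Degenerate inputs (zero-variance differences) cannot
#' support a t statistic: the p value is reported as 0 or 1 by the sign of
#' the mean difference (1 when all differences are zero, so no significance
#' is claimed) and flagged.
#'
#' @param ours_moe_per_tract,alt_moe_per_tract Equal-length numeric vectors
#'   (length >= 2) of per-tract MOEs.
#' @return List with `t`, `p`, `df`, `degenerate`.
#' @export
paired_one_tailed_t <- function(ours_moe_per_tract, alt_moe_per_tract) {
  stopifnot(length(ours_moe_per_tract) == length(alt_moe_per_tract),
            length(ours_moe_per_tract) >= 2)
  d <- ours_moe_per_tract - alt_moe_per_tract
  n <- length(d)
  if (sd(d) == 0) {
    md <- mean(d)
    p <- if (md < 0) 0 else 1
    return(list(t = NA_real_, p = p, df = n - 1, degenerate = TRUE))
  }
  tt <- t.test(ours_moe_per_tract, alt_moe_per_tract, paired = TRUE,
               alternative = "less")
  list(t = unname(tt$statistic), p = unname(tt$p.value),
       df = unname(tt$parameter), degenerate = FALSE)
}

#' Evaluate the approach against both baselines on intervened tracts
#'
#' For every intervened tract (recorded in `truth`) and every health outcome
#' in the model's health factor, builds three forecasts of the outcome at
#' `intervention_year + horizon_years`:
#' \describe{
#'   \item{ours}{intervention-year observed outcome minus the best median
#'     improvement from [sweep_increments()] over the tract's actual added
#'     mileage (matching performed on the last pre-intervention year),
#'     clipped to \[0, 100\].}
#'   \item{no_change}{the tract's mean outcome over `fit_years`.}
#'   \item{linreg}{the [linreg_baseline()] forecast at the tract's
#'     post-addition DBC/BPH scores.}
#' }
#' then computes MAE/RMSE with bootstrap SDs and one-tailed paired t tests of
#' ours against the better alternative per (outcome, MOE).
#'
#' @param model A labeled, frozen `factor_model`.
#' @param panel The post-intervention [city_panel].
#' @param truth `ground_truth` with intervention bookkeeping.
#' @param intervention_year Year mileage was added.
#' @param horizon_years Years ahead to evaluate (default 5).
#' @param x Matching radius (default 0.50).
#' @param step Sweep increment in miles (default 0.10).
#' @param fit_years Fitting window for the baselines.
#' @param n_boot Bootstrap resamples for MOE SDs.
#' @param seed Seed for the bootstrap.
#' @return An object of class `bpp_evaluation`: `predictions` (per tract,
#'   outcome, approach), `moes`, `tests` (per outcome and MOE: the better
#'   alternative, t, p, degeneracy flag), and the configuration used.
#' @export
run_evaluation <- function(model, panel, truth,
                           intervention_year = 2016, horizon_years = 5,
                           x = 0.5, step = 0.1, fit_years = 2011:2015,
                           n_boot = 1000, seed = 1) {
  stopifnot(inherits(model, "factor_model"), inherits(panel, "city_panel"),
            inherits(truth, "ground_truth"))
  if (is.null(truth$added_miles)) {
    stop("truth carries no intervention; run apply_intervention() first",
         call. = FALSE)
  }
  added <- truth$added_miles[truth$added_miles > 0]
  tracts <- names(added)
  pre_year <- intervention_year - 1
  eval_year <- intervention_year + horizon_years
  if (!(eval_year %in% panel$data$year)) {
    stop("panel does not reach the evaluation year ", eval_year, call. = FALSE)
  }
  outcomes <- health_outcome_vars(model)

  # neighbor matching operates on the last pre-intervention state
  pre_panel <- panel_subset(panel, years = min(panel$data$year):pre_year)
  scores_pre <- compute_scores(model, pre_panel, year = pre_year,
                               refit_standardization = FALSE)
  linreg <- linreg_baseline(model, panel, fit_years,
                            horizon_years = horizon_years)
  lab_cols <- factor_colnames(model)
  dbc_col <- lab_cols[model$label_index["DBC"]]
  bph_col <- lab_cols[model$label_index["BPH"]]

  d_int <- panel$data[panel$data$year == intervention_year, , drop = FALSE]
  d_fit_end <- panel$data[panel$data$year == max(fit_years), , drop = FALSE]
  d_eval <- panel$data[panel$data$year == eval_year, , drop = FALSE]

  rows <- list()
  for (tr in tracts) {
    sw <- sweep_increments(model, pre_panel, scores_pre, tr,
                           total_miles = added[[tr]], x = x, step = step,
                           year = pre_year)
    q_post <- score_modified_tract(model, pre_panel, tr, added[[tr]],
                                   pre_year)
    for (v in outcomes) {
      actual <- d_eval[[v]][d_eval$tract_id == tr]
      base_int <- d_int[[v]][d_int$tract_id == tr]
      base_fit <- d_fit_end[[v]][d_fit_end$tract_id == tr]
      preds <- c(
        ours = min(100, max(0, base_int - sw$best_median[[v]])),
        no_change = predict_no_change(panel, fit_years, tr, v),
        linreg = unname(linreg(v, base_fit, q_post[dbc_col],
                               q_post[bph_col]))
      )
      for (ap in names(preds)) {
        rows[[length(rows) + 1]] <- data.frame(
          tract_id = tr, outcome = v, approach = ap,
          predicted = preds[[ap]], actual = actual,
          error = preds[[ap]] - actual, stringsAsFactors = FALSE)
      }
    }
  }
  predictions <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  moes <- compute_moes(predictions, n_boot = n_boot, seed = seed)

  tests <- list()
  for (v in outcomes) {
    ours_e <- predictions$error[predictions$approach == "ours" &
                                  predictions$outcome == v]
    for (moe in c("MAE", "RMSE")) {
      alt_stats <- vapply(c("no_change", "linreg"), function(ap) {
        r <- moes[moes$approach == ap & moes$outcome == v, ]
        if (moe == "MAE") r$mae else r$rmse
      }, numeric(1))
      best_alt <- names(alt_stats)[which.min(alt_stats)]
      alt_e <- predictions$error[predictions$approach == best_alt &
                                   predictions$outcome == v]
      per_tract <- if (moe == "MAE") abs else function(e) e^2
      tt <- paired_one_tailed_t(per_tract(ours_e), per_tract(alt_e))
      tests[[length(tests) + 1]] <- data.frame(
        outcome = v, moe = moe, alternative = best_alt,
        t = tt$t, p = tt$p, df = tt$df, degenerate = tt$degenerate,
        stringsAsFactors = FALSE)
    }
  }
  tests <- do.call(rbind, c(tests, list(make.row.names = FALSE)))

  structure(list(
    predictions = predictions,
    moes = moes,
    tests = tests,
    config = list(intervention_year = intervention_year,
                  horizon_years = horizon_years, x = x, step = step,
                  fit_years = fit_years, n_boot = n_boot, seed = seed)
  ), class = "bpp_evaluation")
}

#' @export
print.bpp_evaluation <- function(x, ...) {
  cat(sprintf("bpp_evaluation: %d tract(s), x = %.2f, horizon %d year(s)\n",
              length(unique(x$predictions$tract_id)), x$config$x,
              x$config$horizon_years))
  cat("\nMOEs, mean (bootstrap SD) over tracts:\n")
  m <- x$moes
  for (v in unique(m$outcome)) {
    cat(" ", v, "\n")
    for (ap in unique(m$approach)) {
      r <- m[m$approach == ap & m$outcome == v, ]
      cat(sprintf("    %-10s MAE %.2f (%.2f)  RMSE %.2f (%.2f)\n",
                  ap, r$mae, r$mae_sd, r$rmse, r$rmse_sd))
    }
  }
  cat("\nOne-tailed paired t tests (ours vs best alternative):\n")
  print(x$tests, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Write an evaluation report as a tidy CSV
#'
#' One row per (outcome, approach) with MAE/RMSE and their bootstrap SDs,
#' mirroring the usual layout of model-comparison tables, plus the paired-test
#' p values for ours vs the best alternative.
#'
#' @param evaluation A `bpp_evaluation`.
#' @param path Output CSV path.
#' @return The tidy data frame, invisibly.
#' @export
write_evaluation_csv <- function(evaluation, path) {
  stopifnot(inherits(evaluation, "bpp_evaluation"))
  m <- evaluation$moes
  t_mae <- evaluation$tests[evaluation$tests$moe == "MAE", ]
  t_rmse <- evaluation$tests[evaluation$tests$moe == "RMSE", ]
  m$p_mae_vs_best_alt <- ifelse(
    m$approach == "ours", t_mae$p[match(m$outcome, t_mae$outcome)], NA)
  m$p_rmse_vs_best_alt <- ifelse(
    m$approach == "ours", t_rmse$p[match(m$outcome, t_rmse$outcome)], NA)
  write.csv(m, path, row.names = FALSE)
  invisible(m)
}
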