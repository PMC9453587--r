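# Score a single tract's row after adding hypothetical mileage, under frozen
# standardization. Returns the standardized score vector (named by factor).
score_modified_tract <- function(model, panel, tract_id, added_miles, year) {
  d <- panel$data[panel$data$year == year & panel$data$tract_id == tract_id,
                  , drop = FALSE]
  if (nrow(d) != 1) {
    stop("tract ", tract_id, " has no row for year ", year, call. = FALSE)
  }
  mil <- mileage_var(model$catalog)
  d[[mil]] <- d[[mil]] + added_miles
  sub <- structure(list(data = d, catalog = model$catalog),
                   class = "city_panel")
  sc <- compute_scores(model, sub, year = year,
                       refit_standardization = FALSE)
  setNames(as.numeric(sc[1, factor_colnames(model)]), factor_colnames(model))
}

#' Predict health-outcome improvements from added path mileage
#'
#' The five-step neighbor-matching algorithm. (1) The requested mileage is
#' added to the query tract; (2) its factor scores are recomputed under the
#' frozen model; (3) all other tracts whose DBC score lies within `x` of the
#' query's are collected; (4) likewise for the BPH score, using the
#' post-addition query score; (5) for the tracts in both sets (demographically
#' similar AND similar in realized path habits), the difference
#' (query outcome − neighbor outcome) is computed for every health-outcome
#' variable in the health factor, negative differences are discarded, and the
#' remaining nonnegative values form the hypothesized-improvement
#' distribution. An empty neighbor set (or all-negative differences) yields
#' zero summaries with `empty_flag` set — operationally, a tract where added
#' paths are unlikely to be an effective intervention.
#'
#' @param model A labeled `factor_model` with frozen standardization.
#' @param panel The [city_panel] holding observed outcome values.
#' @param scores [compute_scores()] output for all tracts at `year` under the
#'   frozen model.
#' @param tract_id Query tract.
#' @param added_miles Hypothetical added path miles (>= 0).
#' @param x Factor-score matching radius in SD units (default 0.50); the
#'   comparison is a closed ball, so ties at exactly `x` are neighbors.
#' @param year Panel year to use; defaults to the scores' year.
#' @return An object of class `bpp_prediction`: per-outcome summary data frame
#'   (`min`, `mean`, `median`, `max`, `sd`, `n_improvements`, `empty_flag`,
#'   all in prevalence percentage points), the full improvement lists, the
#'   neighbor IDs, and the query's post-addition scores.
#' @export
predict_improvements <- function(model, panel, scores, tract_id, added_miles,
                                 x = 0.5, year = NULL) {
  stopifnot(inherits(model, "factor_model"), inherits(panel, "city_panel"))
  if (added_miles < 0) stop("added_miles must be >= 0", call. = FALSE)
  if (x < 0) stop("x must be >= 0", call. = FALSE)
  if (is.null(model$label_index)) {
    stop("model has no DBC/health/BPH labels; run label_factors() first",
         call. = FALSE)
  }
  if (is.null(year)) year <- attr(scores, "year")
  if (!(tract_id %in% scores$tract_id)) {
    stop("unknown tract: ", tract_id, call. = FALSE)
  }

  q_scores <- score_modified_tract(model, panel, tract_id, added_miles, year)
  others <- scores[scores$tract_id != tract_id, , drop = FALSE]
  lab_cols <- factor_colnames(model)
  dbc_col <- lab_cols[model$label_index["DBC"]]
  bph_col <- lab_cols[model$label_index["BPH"]]
  in_dbc <- abs(others[[dbc_col]] - q_scores[dbc_col]) <= x
  in_bph <- abs(others[[bph_col]] - q_scores[bph_col]) <= x
  neighbors <- others$tract_id[in_dbc & in_bph]

  outcomes <- health_outcome_vars(model)
  d <- panel$data[panel$data$year == year, , drop = FALSE]
  q_row <- d[d$tract_id == tract_id, , drop = FALSE]
  n_rows <- d[d$tract_id %in% neighbors, , drop = FALSE]

  improvements <- list()
  summary_rows <- list()
  for (v in outcomes) {
    diffs <- q_row[[v]] - n_rows[[v]]
    imp <- diffs[!is.na(diffs) & diffs >= 0]
    improvements[[v]] <- imp
    empty <- length(imp) == 0
    summary_rows[[v]] <- data.frame(
      outcome = v,
      n_improvements = length(imp),
      min = if (empty) 0 else min(imp),
      mean = if (empty) 0 else mean(imp),
      median = if (empty) 0 else median(imp),
      max = if (empty) 0 else max(imp),
      sd = if (length(imp) > 1) sd(imp) else 0,
      empty_flag = empty,
      stringsAsFactors = FALSE
    )
  }

  structure(list(
    tract_id = tract_id,
    added_miles = added_miles,
    x = x,
    year = year,
    query_scores = q_scores,
    neighbor_count = length(neighbors),
    neighbors = neighbors,
    summary = do.call(rbind, c(summary_rows, list(make.row.names = FALSE))),
    improvements = improvements
  ), class = "bpp_prediction")
}

#' @export
print.bpp_prediction <- function(x, ...) {
  cat(sprintf(
    "bpp_prediction: tract %s, +%.2f miles, x = %.2f, %d neighbor(s)\n",
    x$tract_id, x$added_miles, x$x, x$neighbor_count))
  print(x$summary, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Sweep mileage increments and report the best median improvement
#'
#' Runs [predict_improvements()] for every `step`-mile increment up to
#' `total_miles` (the final partial increment is always included so the full
#' requested mileage is covered), collects the median improvement per
#' outcome at each increment, and reports the largest median over the sweep —
#' the assumption being that adding more mileage is never detrimental to the
#' expected improvement.
#'
#' @inheritParams predict_improvements
#' @param total_miles Total path miles to sweep up to (> 0).
#' @param step Increment size in miles (default 0.10).
#' @return An object of class `bpp_sweep`: `best_median` (named vector, one
#'   entry per outcome, in percentage points) and `trace` (data frame with
#'   one row per increment and outcome).
#' @export
sweep_increments <- function(model, panel, scores, tract_id, total_miles,
                             x = 0.5, step = 0.1, year = NULL) {
  if (total_miles <= 0) stop("total_miles must be > 0", call. = FALSE)
  if (step <= 0) stop("step must be > 0", call. = FALSE)
  grid <- round(c(seq(step, total_miles + 1e-9, by = step), total_miles), 10)
  grid <- sort(unique(grid[grid <= total_miles + 1e-9]))

  trace <- list()
  for (g in grid) {
    pred <- predict_improvements(model, panel, scores, tract_id,
                                 added_miles = g, x = x, year = year)
    trace[[length(trace) + 1]] <- data.frame(
      miles = g,
      outcome = pred$summary$outcome,
      median = pred$summary$median,
      n_improvements = pred$summary$n_improvements,
      empty_flag = pred$summary$empty_flag,
      stringsAsFactors = FALSE
    )
  }
  trace <- do.call(rbind, c(trace, list(make.row.names = FALSE)))
  best <- tapply(trace$median, trace$outcome, max)
  best <- setNames(as.numeric(best), names(best))

  structure(list(
    tract_id = tract_id,
    total_miles = total_miles,
    step = step,
    x = x,
    grid = grid,
    best_median = best,
    trace = trace
  ), class = "bpp_sweep")
}

#' @export
print.bpp_sweep <- function(x, ...) {
  cat(sprintf("bpp_sweep: tract %s, up to %.2f miles in %d increment(s)\n",
              x$tract_id, x$total_miles, length(x$grid)))
  cat("  best median improvement (%-points):\n")
  for (nm in names(x$best_median)) {
    cat(sprintf("    %-28s %.3f\n", nm, x$best_median[[nm]]))
  }
  invisible(x)
}
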