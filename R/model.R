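#' Fit a city factor model for path-mileage health prediction
#'
#' The umbrella fitting chain: tracts are split at random into an EFA half
#' (ceiling) and a CFA half; an iterative exploratory factor analysis with the
#' 0.5 loading filter is fitted on the EFA half; factors are labeled DBC,
#' health, and BPH from the variable catalog; the structure is confirmed on
#' the CFA half (on confirmation the model's loadings are replaced by the CFA
#' estimates); and the scoring standardization is frozen over all tracts at
#' the last fitted year, so that hypothetical single-tract mileage additions
#' can be rescored without moving anyone else's scores.
#'
#' @param panel A [city_panel].
#' @param fit_years Years to fit on; defaults to all years in the panel.
#' @param seed Integer seed controlling the tract split.
#' @param x Default matching radius stored for [predict.bpp_model()].
#' @param max_factors,threshold,min_vars_per_factor Passed to [run_efa()].
#' @param cutoffs Fit-index cutoffs passed to [run_cfa()].
#' @return An object of class `bpp_model` wrapping the `factor_model`
#'   (element `model`), the EFA `report`, the CFA report (`cfa`), the
#'   `split`, and the call. If the CFA does not confirm the structure a
#'   warning is issued and `confirmed` is `FALSE`; downstream prediction is
#'   still possible but should be interpreted with care.
#' @examples
#' sim <- generate_city(synth_config(n_tracts = 60, years = 2011:2015,
#'                                   seed = 7))
#' fit <- bpp_model(sim$panel, seed = 7)
#' print(fit)
#' @export
bpp_model <- function(panel, fit_years = NULL, seed = 1, x = 0.5,
                      max_factors = 6, threshold = 0.5,
                      min_vars_per_factor = 3,
                      cutoffs = c(CFI = 0.90, TLI = 0.90,
                                  RMSEA = 0.08, SRMR = 0.08)) {
  stopifnot(inherits(panel, "city_panel"))
  if (is.null(fit_years)) fit_years <- sort(unique(panel$data$year))
  fit_panel <- panel_subset(panel, years = fit_years)
  split <- split_halves(fit_panel, seed)
  efa_half <- panel_subset(fit_panel, tracts = split$efa_tracts)
  cfa_half <- panel_subset(fit_panel, tracts = split$cfa_tracts)

  efa <- run_efa(efa_half, max_factors = max_factors, seed = seed,
                 threshold = threshold,
                 min_vars_per_factor = min_vars_per_factor)
  model <- label_factors(efa$model)
  cfa <- run_cfa(model, cfa_half, cutoffs = cutoffs)
  if (isTRUE(cfa$confirmed)) {
    model$loadings <- cfa$cfa_loadings
    model$factor_correlations <- cfa$cfa_phi
  } else {
    warning("CFA did not confirm the factor structure (see $cfa); ",
            "proceeding with the EFA estimates", call. = FALSE)
  }
  model <- freeze_scoring(model, fit_panel, year = max(fit_years))

  structure(list(
    model = model,
    report = efa$report,
    cfa = cfa,
    split = split,
    confirmed = isTRUE(cfa$confirmed),
    fit_years = fit_years,
    x = x,
    seed = seed,
    call = match.call()
  ), class = "bpp_model")
}

#' @export
print.bpp_model <- function(x, ...) {
  cat("Call: "); print(x$call)
  cat(sprintf("Fitted on years %d-%d; %d EFA / %d CFA tracts (seed %d)\n",
              min(x$fit_years), max(x$fit_years),
              length(x$split$efa_tracts), length(x$split$cfa_tracts),
              x$seed))
  print(x$model)
  cat(sprintf("CFA confirmed: %s\n", x$confirmed))
  invisible(x)
}

#' @export
summary.bpp_model <- function(object, ...) {
  m <- object$model
  cat(sprintf("Factor model with %d factors over %d retained variables\n",
              m$n_factors, length(m$retained_vars)))
  cat(sprintf("EFA: %d iteration(s); discarded: %s\n",
              object$report$iterations,
              if (nrow(object$report$discarded) == 0) "none" else
                paste(object$report$discarded$variable, collapse = ", ")))
  cat("\nLoadings (pattern matrix):\n")
  L <- m$loadings
  colnames(L) <- factor_colnames(m)
  print(round(L, 3))
  cat("\nFactor correlations:\n")
  phi <- m$factor_correlations
  dimnames(phi) <- list(factor_colnames(m), factor_colnames(m))
  print(round(phi, 3))
  cat("\nCFA fit indices:\n")
  print(round(object$cfa$fit_indices, 3))
  cat(sprintf("CFA confirmed: %s\n", object$confirmed))
  invisible(object)
}

#' Extract factor loadings
#'
#' @param object A `bpp_model`.
#' @param ... Unused.
#' @return The pattern loading matrix with factor labels as column names.
#' @export
coef.bpp_model <- function(object, ...) {
  L <- object$model$loadings
  colnames(L) <- factor_colnames(object$model)
  L
}

#' Predict health-outcome improvements for a tract
#'
#' Dispatches to [predict_improvements()] (single mileage addition) or, with
#' `sweep = TRUE`, to [sweep_increments()] (0.10-mile increment sweep
#' reporting the best median improvement).
#'
#' @param object A `bpp_model`.
#' @param panel The [city_panel] to predict on.
#' @param tract_id Query tract.
#' @param added_miles Path miles to add.
#' @param x Matching radius; defaults to the value stored at fit time.
#' @param year Panel year; defaults to the latest.
#' @param sweep Run the increment sweep instead of a single query.
#' @param step Sweep increment (miles).
#' @param ... Unused.
#' @return A `bpp_prediction` or `bpp_sweep`.
#' @export
predict.bpp_model <- function(object, panel, tract_id, added_miles,
                              x = object$x, year = NULL, sweep = FALSE,
                              step = 0.1, ...) {
  scores <- compute_scores(object$model, panel, year = year,
                           refit_standardization = FALSE)
  if (sweep) {
    sweep_increments(object$model, panel, scores, tract_id,
                     total_miles = added_miles, x = x, step = step,
                     year = year)
  } else {
    predict_improvements(object$model, panel, scores, tract_id,
                         added_miles = added_miles, x = x, year = year)
  }
}

#' Plot factor loadings of a fitted model
#'
#' Horizontal barplot of pattern loadings per factor, with the 0.5 retention
#' threshold marked.
#'
#' @param x A `bpp_model`.
#' @param ... Passed to [graphics::barplot()].
#' @export
plot.bpp_model <- function(x, ...) {
  L <- coef(x)
  m <- ncol(L)
  old <- graphics::par(mfrow = c(1, m), mar = c(4, 8, 2, 1))
  on.exit(graphics::par(old))
  for (k in seq_len(m)) {
    graphics::barplot(L[, k], horiz = TRUE, las = 1, xlim = c(-1, 1),
                      main = colnames(L)[k], xlab = "loading",
                      cex.names = 0.7, ...)
    graphics::abline(v = c(-x$model$threshold, x$model$threshold), lty = 2,
                     col = "grey40")
  }
  invisible(x)
}
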