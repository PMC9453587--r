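#' Compute standardized factor scores for every tract
#'
#' Applies the model's regression (Thurstone) scoring weights to
#' z-standardized observed variables and standardizes each factor's scores to
#' mean 0, SD 1. With `refit_standardization = TRUE` both the variable
#' centers/scales and the factor-score mean/SD are recomputed on the scored
#' tract set (and returned via the `"model"` attribute so they can be frozen);
#' with `FALSE` the constants stored in the model are applied unchanged, which
#' is the contract the prediction algorithm relies on when it rescores a
#' single tract with hypothetical extra mileage.
#'
#' @param model A `factor_model`.
#' @param panel A [city_panel] containing all retained variables.
#' @param year Panel year to score; defaults to the most recent year present.
#' @param refit_standardization Recompute standardization constants on this
#'   tract set (`TRUE`) or apply the frozen ones (`FALSE`, default).
#' @return A data frame of class `factor_scores` with column `tract_id` and
#'   one column per factor (named by label where labeled). Attributes:
#'   `year`, `refit`, and — when refitting — `model`, the updated model.
#' @export
compute_scores <- function(model, panel, year = NULL,
                           refit_standardization = FALSE) {
  stopifnot(inherits(model, "factor_model"), inherits(panel, "city_panel"))
  if (is.null(year)) year <- max(panel$data$year)
  d <- panel$data[panel$data$year == year, , drop = FALSE]
  if (nrow(d) == 0) stop("panel has no rows for year ", year, call. = FALSE)
  missing_vars <- setdiff(model$retained_vars, names(d))
  if (length(missing_vars) > 0) {
    stop("panel lacks retained variable(s): ",
         paste(missing_vars, collapse = ", "), call. = FALSE)
  }
  X <- as.matrix(d[, model$retained_vars, drop = FALSE])
  if (anyNA(X)) {
    for (v in colnames(X)) {
      idx <- is.na(X[, v])
      if (any(idx)) X[idx, v] <- mean(X[, v], na.rm = TRUE)
    }
  }

  if (refit_standardization) {
    v_center <- colMeans(X)
    v_scale <- apply(X, 2, sd)
    v_scale[v_scale == 0] <- 1
  } else {
    v_center <- model$var_center
    v_scale <- model$var_scale
  }
  Z <- sweep(sweep(X, 2, v_center), 2, v_scale, "/")
  raw <- Z %*% model$scoring_weights
  if (refit_standardization) {
    s_center <- colMeans(raw)
    s_scale <- apply(raw, 2, sd)
    s_scale[s_scale == 0] <- 1
  } else {
    s_center <- model$score_center
    s_scale <- model$score_scale
  }
  std <- sweep(sweep(raw, 2, s_center), 2, s_scale, "/")

  cols <- factor_colnames(model)
  scores <- data.frame(tract_id = d$tract_id, std, stringsAsFactors = FALSE)
  names(scores) <- c("tract_id", cols)
  class(scores) <- c("factor_scores", "data.frame")
  attr(scores, "year") <- year
  attr(scores, "refit") <- refit_standardization
  if (refit_standardization) {
    model$var_center <- v_center
    model$var_scale <- v_scale
    model$score_center <- s_center
    model$score_scale <- s_scale
    attr(scores, "model") <- model
  }
  scores
}

# Column names for score output: factor labels where available.
factor_colnames <- function(model) {
  if (all(is.na(model$labels))) {
    paste0("F", seq_len(model$n_factors))
  } else {
    model$labels
  }
}

#' Freeze a model's scoring standardization on a reference tract set
#'
#' Recomputes variable and factor-score standardization constants over the
#' given panel/year (typically the whole city at the last fitted year) and
#' stores them in the model, so that later single-tract rescoring — e.g. after
#' a hypothetical mileage addition — leaves every other tract's score
#' unchanged.
#'
#' @inheritParams compute_scores
#' @return The updated `factor_model`.
#' @export
freeze_scoring <- function(model, panel, year = NULL) {
  attr(compute_scores(model, panel, year, refit_standardization = TRUE),
       "model")
}
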