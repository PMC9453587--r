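# Build the analysis matrix for a panel half: select variables, drop the ones
# with excessive missingness or zero variance, mean-impute within year, and
# z-standardize. Returns the matrix plus the standardization constants.
prepare_matrix <- function(panel, vars, na_threshold = 0.2) {
  d <- panel$data
  keep <- character()
  for (v in vars) {
    frac_na <- mean(is.na(d[[v]]))
    if (frac_na > na_threshold) {
      warning(sprintf("variable %s missing in %.0f%% of tract-years; dropped",
                      v, 100 * frac_na), call. = FALSE)
      next
    }
    keep <- c(keep, v)
  }
  X <- as.matrix(d[, keep, drop = FALSE])
  # mean-impute within year
  if (anyNA(X)) {
    for (v in colnames(X)) {
      na_idx <- which(is.na(X[, v]))
      if (length(na_idx) == 0) next
      yr_means <- tapply(X[, v], d$year, mean, na.rm = TRUE)
      fill <- yr_means[as.character(d$year[na_idx])]
      fill[is.na(fill)] <- mean(X[, v], na.rm = TRUE)
      X[na_idx, v] <- fill
    }
  }
  sds <- apply(X, 2, sd)
  if (any(sds == 0)) {
    warning("zero-variance variable(s) dropped: ",
            paste(colnames(X)[sds == 0], collapse = ", "), call. = FALSE)
    X <- X[, sds > 0, drop = FALSE]
    sds <- sds[sds > 0]
  }
  center <- colMeans(X)
  Z <- sweep(sweep(X, 2, center), 2, sds, "/")
  list(Z = Z, center = center, scale = sds, vars = colnames(Z),
       tract_id = d$tract_id, year = d$year)
}

# One iterative fit-and-filter pass at a fixed number of factors m.
# Returns NULL if m is not viable (convergence failure, a factor dissolves
# below min_vars, or the candidate pool runs out); otherwise the final fit.
efa_filter_at_m <- function(Z, vars, m, threshold, min_vars) {
  discarded <- data.frame(variable = character(), iteration = integer(),
                          reason = character(), stringsAsFactors = FALSE)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    p <- length(vars)
    if (p < m * min_vars) return(NULL)
    if ((p - m)^2 < p + m) return(NULL)  # ML factor model not identified
    fa <- tryCatch(
      suppressWarnings(factanal(Z[, vars, drop = FALSE], factors = m,
                                rotation = "promax")),
      error = function(e) NULL)
    if (is.null(fa)) return(NULL)
    L <- matrix(loadings(fa), p, m, dimnames = list(vars, NULL))
    assigned <- apply(abs(L), 1, which.max)
    on_load <- abs(L[cbind(seq_len(p), assigned)])
    off_load <- vapply(seq_len(p), function(i) {
      if (m == 1) 0 else max(abs(L[i, -assigned[i]]))
    }, numeric(1))
    low <- on_load <= threshold
    high_off <- off_load >= threshold
    bad <- low | high_off
    if (!any(bad)) {
      if (any(tabulate(assigned, m) < min_vars)) return(NULL)
      return(list(fa = fa, L = L, assigned = assigned, vars = vars,
                  iterations = iter, discarded = discarded))
    }
    reason <- ifelse(low[bad] & high_off[bad], "low on-factor & high off-factor loading",
                     ifelse(low[bad], "on-factor loading below threshold",
                            "off-factor loading above threshold"))
    discarded <- rbind(discarded,
                       data.frame(variable = vars[bad], iteration = iter,
                                  reason = reason, stringsAsFactors = FALSE))
    vars <- vars[!bad]
  }
}

#' Iterative exploratory factor analysis with communality filtering
#'
#' Fits an oblique (promax-rotated, maximum-likelihood) factor model to the
#' z-standardized tract-year rows of a panel half and iteratively discards
#' every variable whose absolute pattern loading is not above `threshold` on
#' its assigned factor (the argmax of absolute loadings) and below `threshold`
#' on all others. The number of factors is the smallest `m` in
#' `3:max_factors` whose filtered solution converges and retains at least
#' `min_vars_per_factor` variables on every factor; if a factor falls below
#' that size the candidate pool re-enters at the next `m`.
#'
#' @param panel_half A [city_panel] (typically the EFA half from
#'   [split_halves()]).
#' @param candidate_vars Variables to analyze; defaults to the full catalog.
#'   Must include the mileage variable and at least one health outcome.
#' @param max_factors Largest number of factors to try.
#' @param seed Integer seed (kept for interface symmetry; the fit itself is
#'   deterministic given the data).
#' @param threshold Loading threshold (default 0.5): retained variables must
#'   load above it on their factor and below it elsewhere.
#' @param min_vars_per_factor Minimum retained variables per factor.
#' @return List with elements `model` (class `factor_model`) and `report`
#'   (class `fit_report`). The model's scoring weights are regression
#'   (Thurstone) weights computed from the fitting half, and its
#'   standardization constants (variable centers/scales and factor-score
#'   mean/SD) are frozen from the fitting half until re-frozen.
#' @export
run_efa <- function(panel_half, candidate_vars = NULL, max_factors = 6,
                    seed = 1, threshold = 0.5, min_vars_per_factor = 3) {
  stopifnot(inherits(panel_half, "city_panel"))
  catalog <- panel_half$catalog
  if (is.null(candidate_vars)) candidate_vars <- catalog$name
  mil <- mileage_var(panel_half)
  outcomes <- catalog$name[catalog$category == "CDC_health_outcome"]
  if (!(mil %in% candidate_vars)) {
    stop("candidate set must include the path mileage variable", call. = FALSE)
  }
  if (!any(outcomes %in% candidate_vars)) {
    stop("candidate set must include at least one health outcome",
         call. = FALSE)
  }

  prep <- prepare_matrix(panel_half, candidate_vars)
  if (nrow(prep$Z) < 5 * length(prep$vars)) {
    stop("too few tract-year rows: need at least 5 per candidate variable",
         call. = FALSE)
  }

  fit <- NULL
  for (m in 3:max_factors) {
    fit <- efa_filter_at_m(prep$Z, prep$vars, m, threshold,
                           min_vars_per_factor)
    if (!is.null(fit)) break
  }
  if (is.null(fit)) {
    stop("requirements unmet: no factor solution with >= 3 factors of >= ",
         min_vars_per_factor, " variables each survives the ", threshold,
         " loading filter", call. = FALSE)
  }

  m <- ncol(fit$L)
  vars <- fit$vars
  L <- fit$L
  assigned <- fit$assigned

  # canonical orientation: each factor's assigned variables load positively
  flip <- vapply(seq_len(m), function(k) {
    s <- sum(L[assigned == k, k])
    if (s < 0) -1 else 1
  }, numeric(1))
  L <- sweep(L, 2, flip, "*")

  Zr <- prep$Z[, vars, drop = FALSE]
  R <- cor(Zr)
  # Factor correlations by projecting the common part of R onto the pattern
  # matrix: Phi = (L'L)^-1 L' (R - Psi) L (L'L)^-1. (The promax rotation
  # matrix stored by factanal is not guaranteed to share the column order of
  # the stored loadings, so it is not used here.)
  Psi <- diag(fit$fa$uniquenesses[vars])
  proj <- solve(t(L) %*% L, t(L))
  phi_raw <- proj %*% (R - Psi) %*% t(proj)
  phi <- stats::cov2cor((phi_raw + t(phi_raw)) / 2)
  dimnames(phi) <- NULL
  W <- solve(R, L %*% phi)  # Thurstone regression weights
  raw <- Zr %*% W
  colnames(L) <- colnames(W) <- paste0("F", seq_len(m))

  model <- structure(list(
    retained_vars = vars,
    n_factors = m,
    loadings = L,
    assignment = setNames(assigned, vars),
    labels = rep(NA_character_, m),
    label_index = NULL,
    factor_correlations = phi,
    scoring_weights = W,
    var_center = prep$center[vars],
    var_scale = prep$scale[vars],
    score_center = colMeans(raw),
    score_scale = apply(raw, 2, sd),
    threshold = threshold,
    catalog = catalog
  ), class = "factor_model")

  report <- structure(list(
    iterations = fit$iterations,
    discarded = fit$discarded,
    n_factors = m,
    efa_stat = list(statistic = unname(fit$fa$STATISTIC),
                    dof = unname(fit$fa$dof),
                    p_value = unname(fit$fa$PVAL)),
    fit_indices = NULL,
    confirmed = NA
  ), class = "fit_report")

  list(model = model, report = report)
}

#' @export
print.factor_model <- function(x, ...) {
  cat(sprintf("factor_model: %d factors, %d retained variables (threshold %.2f)\n",
              x$n_factors, length(x$retained_vars), x$threshold))
  if (!all(is.na(x$labels))) {
    cat("  labels:", paste(x$labels, collapse = ", "), "\n")
  }
  for (k in seq_len(x$n_factors)) {
    vs <- names(x$assignment)[x$assignment == k]
    lab <- if (is.na(x$labels[k])) paste0("F", k) else x$labels[k]
    cat(sprintf("  %s: %s\n", lab, paste(vs, collapse = ", ")))
  }
  invisible(x)
}

#' @export
print.fit_report <- function(x, ...) {
  cat(sprintf("fit_report: %d iteration(s), %d variable(s) discarded\n",
              x$iterations, nrow(x$discarded)))
  if (!is.null(x$fit_indices)) {
    cat("  fit indices:",
        paste(sprintf("%s=%.3f", names(x$fit_indices), x$fit_indices),
              collapse = ", "), "\n")
    cat("  confirmed:", x$confirmed, "\n")
  }
  invisible(x)
}

# Category -> factor-label group.
category_group <- function(category) {
  ifelse(category == "ACS_demographic", "DBC",
         ifelse(category %in% prevalence_categories(), "health",
                ifelse(category %in% c("path_mileage", "path_use"), "BPH",
                       NA_character_)))
}

#' Label fitted factors as DBC, health, and BPH
#'
#' Each factor is labeled by the majority category group of its retained
#' variables (ACS demographics -> DBC, CDC prevalence variables -> health,
#' path mileage/use -> BPH); ties are broken in favour of the group with the
#' larger mean absolute loading on that factor. The method's restrictions are
#' then checked: all three labels must be present, the health factor must
#' retain at least one health-outcome variable, and the BPH factor must retain
#' the path-mileage variable.
#'
#' @param model A `factor_model` from [run_efa()].
#' @param catalog Variable catalog; defaults to the one stored in the model.
#' @return The model with `labels` filled in and `label_index` mapping each of
#'   DBC/health/BPH to its factor column.
#' @export
label_factors <- function(model, catalog = model$catalog) {
  stopifnot(inherits(model, "factor_model"))
  groups <- setNames(category_group(catalog$category), catalog$name)
  labels <- character(model$n_factors)
  for (k in seq_len(model$n_factors)) {
    vs <- names(model$assignment)[model$assignment == k]
    g <- groups[vs]
    tab <- table(g)
    top <- names(tab)[tab == max(tab)]
    if (length(top) > 1) {
      mean_load <- vapply(top, function(gr) {
        mean(abs(model$loadings[vs[g == gr], k]))
      }, numeric(1))
      top <- top[which.max(mean_load)]
    }
    labels[k] <- top
  }

  required <- c("DBC", "health", "BPH")
  missing_lab <- setdiff(required, labels)
  if (length(missing_lab) > 0) {
    stop("requirements unmet: no factor qualifies for label(s): ",
         paste(missing_lab, collapse = ", "), call. = FALSE)
  }

  # primary factor per label: BPH must contain the mileage variable; other
  # duplicated labels resolve to the factor with the most retained variables
  label_index <- integer(0)
  mil <- catalog$name[catalog$category == "path_mileage"]
  for (lab in required) {
    ks <- which(labels == lab)
    if (lab == "BPH") {
      has_mil <- ks[vapply(ks, function(k) {
        mil %in% names(model$assignment)[model$assignment == k]
      }, logical(1))]
      if (length(has_mil) == 0) {
        stop("requirements unmet: the BPH factor must include the path ",
             "mileage variable", call. = FALSE)
      }
      ks <- has_mil
    }
    if (length(ks) > 1) {
      ks <- ks[which.max(tabulate(model$assignment, model$n_factors)[ks])]
    }
    label_index[lab] <- ks
  }
  health_vars <- names(model$assignment)[model$assignment ==
                                           label_index["health"]]
  outcome_vars <- catalog$name[catalog$category == "CDC_health_outcome"]
  if (!any(health_vars %in% outcome_vars)) {
    stop("requirements unmet: the health factor must include at least one ",
         "health-outcome variable", call. = FALSE)
  }

  model$labels <- labels
  model$label_index <- label_index
  model
}

# Retained health-outcome variables assigned to the (primary) health factor.
health_outcome_vars <- function(model) {
  outcome_vars <- model$catalog$name[model$catalog$category ==
                                       "CDC_health_outcome"]
  hv <- names(model$assignment)[model$assignment == model$label_index["health"]]
  intersect(hv, outcome_vars)
}
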