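# Maximum-likelihood confirmatory factor analysis on a correlation matrix,
# with simple structure (each variable loads on exactly one factor), freely
# correlated factors, and diagonal uniquenesses. Written against the standard
# ML discrepancy F = log|Sigma| + tr(S Sigma^-1) - log|S| - p.

# Parameter vector layout: p loadings, m(m-1)/2 factor-correlation parameters
# (row-normalized Cholesky entries), p log-uniquenesses.
cfa_unpack <- function(theta, p, m, assigned) {
  lambda <- theta[seq_len(p)]
  t_par <- theta[p + seq_len(m * (m - 1) / 2)]
  log_psi <- theta[p + m * (m - 1) / 2 + seq_len(p)]
  Mlt <- diag(m)
  Mlt[lower.tri(Mlt)] <- t_par
  Lch <- Mlt / sqrt(rowSums(Mlt^2))
  phi <- Lch %*% t(Lch)
  L <- matrix(0, p, m)
  L[cbind(seq_len(p), assigned)] <- lambda
  list(L = L, phi = phi, psi = exp(log_psi))
}

cfa_discrepancy <- function(theta, S, assigned, m) {
  p <- nrow(S)
  par <- cfa_unpack(theta, p, m, assigned)
  Sigma <- par$L %*% par$phi %*% t(par$L) + diag(par$psi)
  ch <- tryCatch(chol(Sigma), error = function(e) NULL)
  if (is.null(ch)) return(1e10)
  log_det <- 2 * sum(log(diag(ch)))
  tr_term <- sum(diag(chol2inv(ch) %*% S))
  f <- log_det + tr_term - determinant(S, logarithm = TRUE)$modulus[1] - p
  if (!is.finite(f)) 1e10 else f
}

#' Confirmatory factor analysis on a held-out panel half
#'
#' Refits the loadings of a fitted factor model on independent data, keeping
#' the variable-to-factor assignment fixed (simple structure: every off-factor
#' loading is constrained to zero), with freely correlated factors and
#' diagonal uniquenesses, by maximum likelihood on the correlation matrix.
#' The model is confirmed when every refitted standardized loading exceeds
#' the model's loading threshold and the fit indices meet their cutoffs.
#'
#' @param model A labeled `factor_model` from [run_efa()]/[label_factors()].
#' @param panel_half A [city_panel] disjoint from the EFA half.
#' @param cutoffs Named numeric vector of fit-index cutoffs; CFI and TLI are
#'   lower bounds, RMSEA and SRMR upper bounds.
#' @return A `fit_report` with `fit_indices` (CFI, TLI, RMSEA, SRMR),
#'   `confirmed`, the CFA loading matrix (`cfa_loadings`), factor correlations
#'   (`cfa_phi`), and estimation diagnostics.
#' @export
run_cfa <- function(model, panel_half,
                    cutoffs = c(CFI = 0.90, TLI = 0.90,
                                RMSEA = 0.08, SRMR = 0.08)) {
  stopifnot(inherits(model, "factor_model"), inherits(panel_half, "city_panel"))
  vars <- model$retained_vars
  missing_vars <- setdiff(vars, names(panel_half$data))
  if (length(missing_vars) > 0) {
    stop("panel half lacks retained variable(s): ",
         paste(missing_vars, collapse = ", "), call. = FALSE)
  }
  prep <- prepare_matrix(panel_half, vars)
  if (!identical(prep$vars, vars)) {
    stop("CFA estimation failure: retained variable(s) unusable on this half",
         call. = FALSE)
  }
  Z <- prep$Z
  S <- cor(Z)
  n <- nrow(Z)
  p <- length(vars)
  m <- model$n_factors
  assigned <- unname(model$assignment[vars])

  # start from the EFA solution
  lam0 <- model$loadings[cbind(seq_len(p), assigned)]
  phi0 <- model$factor_correlations
  Lch0 <- tryCatch(t(chol(phi0)), error = function(e) t(chol(diag(m))))
  t0 <- (Lch0 / diag(Lch0))[lower.tri(Lch0)]
  psi0 <- pmax(0.05, 1 - lam0^2)
  theta0 <- c(lam0, t0, log(psi0))

  opt <- optim(theta0, cfa_discrepancy, S = S, assigned = assigned, m = m,
               method = "BFGS", control = list(maxit = 500, reltol = 1e-10))
  if (opt$value >= 1e9) {
    stop("CFA estimation failure: discrepancy did not evaluate on a ",
         "positive-definite covariance; check the panel half", call. = FALSE)
  }
  par <- cfa_unpack(opt$par, p, m, assigned)
  # canonical orientation, as in run_efa
  flip <- vapply(seq_len(m), function(k) {
    if (sum(par$L[assigned == k, k]) < 0) -1 else 1
  }, numeric(1))
  L_cfa <- sweep(par$L, 2, flip, "*")
  phi_cfa <- diag(flip) %*% par$phi %*% diag(flip)
  dimnames(L_cfa) <- list(vars, paste0("F", seq_len(m)))

  # test statistic and fit indices
  f_min <- opt$value
  stat <- (n - 1) * f_min
  df <- p * (p + 1) / 2 - (2 * p + m * (m - 1) / 2)
  f_base <- -determinant(S, logarithm = TRUE)$modulus[1]  # independence model
  stat_base <- (n - 1) * f_base
  df_base <- p * (p - 1) / 2
  cfi <- 1 - max(stat - df, 0) / max(stat - df, stat_base - df_base, 0)
  tli <- (stat_base / df_base - stat / df) / (stat_base / df_base - 1)
  rmsea <- sqrt(max(stat - df, 0) / (df * (n - 1)))
  Sigma <- L_cfa %*% phi_cfa %*% t(L_cfa) + diag(par$psi)
  resid <- (S - Sigma)[lower.tri(S, diag = TRUE)]
  srmr <- sqrt(mean(resid^2))
  indices <- c(CFI = cfi, TLI = min(tli, 1), RMSEA = rmsea, SRMR = srmr)

  on_load <- L_cfa[cbind(seq_len(p), assigned)]
  thresholds_pass <- all(abs(on_load) > model$threshold)
  indices_pass <- indices["CFI"] >= cutoffs["CFI"] &&
    indices["TLI"] >= cutoffs["TLI"] &&
    indices["RMSEA"] <= cutoffs["RMSEA"] &&
    indices["SRMR"] <= cutoffs["SRMR"]

  structure(list(
    iterations = 1L,
    discarded = data.frame(variable = character(), iteration = integer(),
                           reason = character(), stringsAsFactors = FALSE),
    n_factors = m,
    fit_indices = indices,
    confirmed = thresholds_pass && indices_pass,
    thresholds_pass = thresholds_pass,
    cfa_loadings = L_cfa,
    cfa_phi = phi_cfa,
    cfa_uniquenesses = setNames(par$psi, vars),
    statistic = stat,
    df = df,
    n_obs = n,
    convergence = opt$convergence,
    cutoffs = cutoffs
  ), class = "fit_report")
}
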