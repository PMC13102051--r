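#' Partial-dependence simulation for one covariate
#'
#' Generates synthetic participants that sweep one covariate across its
#' empirical percentile grid while holding every other covariate at a
#' central value (median for continuous, mode for binary), feeds them
#' through the fitted forest, and records how the simulated individual
#' treatment effect moves with the covariate. An increasing profile marks a
#' risk factor (the stress effect grows with the covariate), a decreasing
#' one a protective factor.
#'
#' @param forest a fitted `causal_forest` (typically a final model).
#' @param table reference `cohort_table` supplying the empirical quantiles
#'   and central values.
#' @param covariate covariate name to sweep.
#' @param n_points grid size for continuous covariates (default 100,
#'   quantiles at equispaced probabilities 0.5%..99.5%); binary covariates
#'   always use the 2-point grid {0, 1}.
#' @param trend_rho,trend_epsilon thresholds passed to [classify_trend()].
#' @return Object of class `pdp_curve`: data.frame-like list with `grid`
#'   (probability, covariate value), `simulated_ite`, `trend`
#'   (`"risk"`, `"protective"` or `"flat"`) and `trend_stat` (Spearman
#'   rank correlation).
#' @export
partial_dependence <- function(forest, table, covariate, n_points = 100L,
                               trend_rho = 0.5, trend_epsilon = 0.05) {
  validate_cohort_table(table)
  if (!covariate %in% forest$covariate_names)
    stopf("covariate '%s' is not in the forest's covariate space", covariate)
  covs <- forest$covariate_names
  kind <- table$covariate_kind[match(covs, table$covariate_names)]
  X <- table$X[, covs, drop = FALSE]

  center <- vapply(seq_along(covs), function(j) {
    if (kind[j] == "binary") {
      v <- X[, j]
      as.numeric(names(which.max(table(v))))  # mode
    } else median(X[, j])
  }, 0)

  j0 <- match(covariate, covs)
  if (kind[j0] == "binary") {
    probs <- c(0, 1)
    values <- sort(unique(c(0, 1)))
  } else {
    probs <- seq(0.005, 0.995, length.out = n_points)
    values <- unname(quantile(X[, j0], probs = probs, type = 7))
  }

  grid_X <- matrix(rep(center, each = length(values)), nrow = length(values),
                   dimnames = list(NULL, covs))
  grid_X[, j0] <- values
  ite <- predict(forest, newdata = grid_X)

  cls <- classify_trend(values, ite, rho = trend_rho, epsilon = trend_epsilon)
  structure(list(covariate = covariate,
                 grid = data.frame(probability = probs, value = values),
                 simulated_ite = ite,
                 trend = cls$trend, trend_stat = cls$rho),
            class = "pdp_curve")
}

#' Classify a partial-dependence profile as risk, protective, or flat
#'
#' The trend statistic is the Spearman rank correlation between the
#' simulated treatment effects and the covariate grid values. The profile
#' is `"risk"` when the correlation is at least `rho` and the effect range
#' exceeds `epsilon`, `"protective"` when the correlation is at most `-rho`
#' with the same range requirement, and `"flat"` otherwise (including any
#' profile whose total movement is within `epsilon`, whatever its shape).
#'
#' @param values covariate grid values (or a `pdp_curve`, in which case
#'   `ite` is ignored).
#' @param ite simulated treatment effects on the grid.
#' @param rho rank-correlation threshold (default 0.5).
#' @param epsilon minimum effect range on the standardized-outcome scale
#'   (default 0.05).
#' @return List with `trend` and `rho` (the observed rank correlation,
#'   `NA` for degenerate grids).
#' @export
classify_trend <- function(values, ite = NULL, rho = 0.5, epsilon = 0.05) {
  if (inherits(values, "pdp_curve")) {
    ite <- values$simulated_ite
    values <- values$grid$value
  }
  if (length(values) < 2L) stopf("need at least 2 grid points")
  rng <- diff(range(ite))
  obs_rho <- if (var(values) < 1e-24 || var(ite) < 1e-24) NA_real_ else
    suppressWarnings(cor(values, ite, method = "spearman"))
  trend <- if (!is.na(obs_rho) && rng > epsilon && obs_rho >= rho) "risk"
  else if (!is.na(obs_rho) && rng > epsilon && obs_rho <= -rho) "protective"
  else "flat"
  list(trend = trend, rho = obs_rho)
}

#' @export
print.pdp_curve <- function(x, ...) {
  cat(sprintf("partial dependence of tau-hat on %s: trend = %s (rho = %.2f, range %.3f)\n",
              x$covariate, x$trend,
              if (is.na(x$trend_stat)) NA else x$trend_stat,
              diff(range(x$simulated_ite))))
  invisible(x)
}

#' Tabulate partial-dependence curves for a set of covariates
#'
#' @param forest a fitted `causal_forest`.
#' @param table reference `cohort_table`.
#' @param covariates covariates to profile (default: all in the forest).
#' @param ... passed to [partial_dependence()].
#' @return Named list of `pdp_curve`s.
#' @export
partial_dependence_all <- function(forest, table,
                                   covariates = forest$covariate_names, ...) {
  setNames(lapply(covariates, function(cv)
    partial_dependence(forest, table, cv, ...)), covariates)
}
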