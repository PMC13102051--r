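#' Augmented inverse-propensity weighted (AIPW) scores
#'
#' Computes the per-participant doubly robust influence score
#' \deqn{\Gamma_i = \hat\tau^{-i}(X_i) + \frac{W_i - \hat e(X_i)}
#'   {\hat e(X_i)(1 - \hat e(X_i))}
#'   \left(Y_i - \hat m(X_i) - (W_i - \hat e(X_i))\,\hat\tau^{-i}(X_i)\right)}
#' whose mean estimates the average treatment effect, with consistency if
#' either the propensity or the outcome model is correct (double
#' robustness). \eqn{\hat\tau^{-i}} is the out-of-bag forest prediction.
#'
#' @param table a `cohort_table`.
#' @param nuisance a `nuisance_fits` aligned with `table` (propensities
#'   already clipped away from 0 and 1).
#' @param oob_tau n-vector of out-of-bag CATE predictions; no `NA` allowed.
#' @return Object of class `aipw_scores`: list with `gamma` (n-vector) and
#'   `cluster`.
#' @export
aipw_scores <- function(table, nuisance, oob_tau) {
  validate_cohort_table(table)
  n <- nrow(table$X)
  validate_nuisance(nuisance, n)
  if (length(oob_tau) != n) stopf("oob_tau has length %d; expected %d",
                                  length(oob_tau), n)
  bad <- which(!is.finite(oob_tau))
  if (length(bad))
    stopf("oob_tau is missing for row(s): %s%s",
          paste(utils::head(bad, 10L), collapse = ", "),
          if (length(bad) > 10L) sprintf(" (and %d more)", length(bad) - 10L) else "")
  e <- nuisance$e_hat
  w_res <- as.numeric(table$W) - e
  gamma <- oob_tau + w_res / (e * (1 - e)) *
    (table$Y - nuisance$m_hat - w_res * oob_tau)
  structure(list(gamma = gamma, cluster = table$cluster),
            class = "aipw_scores")
}

#' Average treatment effect with cluster-robust inference
#'
#' The ATE estimate is the mean AIPW score; its standard error treats sites
#' as the independent sampling units (influence contributions are summed
#' within site before squaring), and the p-value is two-sided normal.
#'
#' @param scores an `aipw_scores` object with at least 2 clusters.
#' @return Object of class `ate_result`: `estimate`, `se`, `p_value`, `n`,
#'   `n_clusters`, plus `degenerate = TRUE` when the scores are constant
#'   (se = 0).
#' @export
average_treatment_effect <- function(scores) {
  stopifnot(inherits(scores, "aipw_scores"))
  g <- scores$gamma
  n_clusters <- length(unique(scores$cluster))
  if (n_clusters < 2L)
    stopf(paste("only one cluster present; cluster-robust inference undefined",
                "(relabel rows into pseudo-clusters for an unclustered analysis)"))
  est <- mean(g)
  se <- cluster_se_mean(g, scores$cluster)
  degenerate <- se < 1e-12
  p <- if (degenerate) NA_real_ else 2 * pnorm(-abs(est / se))
  structure(list(estimate = est, se = se, p_value = p, n = length(g),
                 n_clusters = n_clusters, degenerate = degenerate),
            class = "ate_result")
}

#' @export
print.ate_result <- function(x, ...) {
  cat(sprintf("ATE = %.4f (cluster-robust SE %.4f, p = %.3g, n = %d, %d sites)%s\n",
              x$estimate, x$se, x$p_value, x$n, x$n_clusters,
              if (isTRUE(x$degenerate)) " [degenerate: constant scores]" else ""))
  invisible(x)
}

#' Calibration test for forest treatment-effect estimates
#'
#' Best-linear-predictor regression of the residualized outcome on the mean
#' forest prediction and the demeaned (differential) forest prediction:
#' \deqn{Y_i - \hat m_i = \alpha\,\bar\tau\,(W_i - \hat e_i) +
#'   \beta\,(\hat\tau^{-i}_i - \bar\tau)(W_i - \hat e_i) + \varepsilon_i}
#' with \eqn{\bar\tau} the mean out-of-bag prediction. \eqn{\alpha} near 1
#' ("model fit") says the forest's average effect is correctly scaled;
#' \eqn{\beta} near 1 ("heterogeneity index") says its *differential*
#' predictions track true effect variation, and a one-sided test of
#' \eqn{\beta > 0} is the heterogeneity test. Standard errors are
#' cluster-robust (CR1 via [sandwich::vcovCL()]); p-values are one-sided
#' normal for positive coefficients.
#'
#' @param table a `cohort_table`.
#' @param nuisance a `nuisance_fits`.
#' @param oob_tau out-of-bag CATE predictions.
#' @param clusters optional cluster labels (defaults to `table$cluster`).
#' @return Object of class `calibration_result`: `model_fit_coef`,
#'   `heterogeneity_index`, `se_alpha`, `se_beta`, `p_alpha`, `p_beta`,
#'   `degenerate` (`TRUE` when `var(oob_tau)` is 0, in which case the
#'   heterogeneity terms are `NA` rather than silently numeric).
#' @export
calibration_test <- function(table, nuisance, oob_tau,
                             clusters = table$cluster) {
  validate_cohort_table(table)
  n <- nrow(table$X)
  validate_nuisance(nuisance, n)
  if (length(oob_tau) != n || anyNA(oob_tau))
    stopf("oob_tau must be complete and aligned with the table")

  tau_bar <- mean(oob_tau)
  w_res <- as.numeric(table$W) - nuisance$e_hat
  y_res <- table$Y - nuisance$m_hat
  mean_pred <- tau_bar * w_res
  diff_pred <- (oob_tau - tau_bar) * w_res

  if (var(oob_tau) < 1e-12) {
    fit <- lm(y_res ~ mean_pred + 0)
    V <- sandwich::vcovCL(fit, cluster = clusters)
    a <- coef(fit)[["mean_pred"]]
    se_a <- sqrt(V[1, 1])
    return(structure(list(
      model_fit_coef = a, heterogeneity_index = NA_real_,
      se_alpha = se_a, se_beta = NA_real_,
      p_alpha = pnorm(a / se_a, lower.tail = FALSE),
      p_beta = NA_real_, degenerate = TRUE
    ), class = "calibration_result"))
  }

  fit <- lm(y_res ~ mean_pred + diff_pred + 0)
  V <- sandwich::vcovCL(fit, cluster = clusters)
  a <- coef(fit)[["mean_pred"]]
  b <- coef(fit)[["diff_pred"]]
  se_a <- sqrt(V["mean_pred", "mean_pred"])
  se_b <- sqrt(V["diff_pred", "diff_pred"])
  structure(list(
    model_fit_coef = a, heterogeneity_index = b,
    se_alpha = se_a, se_beta = se_b,
    p_alpha = pnorm(a / se_a, lower.tail = FALSE),
    p_beta = pnorm(b / se_b, lower.tail = FALSE),
    degenerate = FALSE
  ), class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  if (isTRUE(x$degenerate)) {
    cat(sprintf("calibration: model fit %.3f (p = %.3g); heterogeneity undefined (constant predictions)\n",
                x$model_fit_coef, x$p_alpha))
  } else {
    cat(sprintf("calibration: model fit %.3f (p = %.3g); heterogeneity index %.3f (p = %.3g)\n",
                x$model_fit_coef, x$p_alpha, x$heterogeneity_index, x$p_beta))
  }
  invisible(x)
}

#' Benjamini-Hochberg adjustment across a declared family of results
#'
#' Attaches FDR q-values across a family of test results collected in one
#' pipeline run (e.g. the ATE, model-fit and heterogeneity tests across
#' timepoints and outcomes). Membership in the family is explicit — the
#' caller passes the p-values — so every reported q traces to a declared
#' family.
#'
#' @param p numeric vector of p-values.
#' @return Vector of BH q-values, never smaller than the input p-values.
#' @export
fdr_adjust <- function(p) p.adjust(p, method = "BH")
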