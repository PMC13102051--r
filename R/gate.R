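#' Group average treatment effect (GATE) test
#'
#' Stratifies the sample into `n_groups` risk groups by ranking the
#' out-of-bag CATE predictions (ties broken by stable row index), computes
#' each group's ATE from its AIPW scores with cluster-robust standard
#' errors, and compares groups pairwise with Welch t-tests on the scores,
#' BH-FDR adjusted across the contrasts. A monotonic increase of the group
#' ATEs from the low-risk to the high-risk group is the qualitative
#' signature of real effect heterogeneity.
#'
#' @param scores an `aipw_scores` object.
#' @param oob_tau out-of-bag CATE predictions aligned with `scores`.
#' @param n_groups number of risk groups (default 3: tertiles Q1 low /
#'   Q2 middle / Q3 high).
#' @return Object of class `gate_result`: `group_assignment` (factor
#'   `Q1..Qk` in row order), `group_ates` (list of `ate_result`),
#'   `contrasts` (data.frame with difference, Welch t, p and BH q per
#'   pairwise contrast; `Q3 - Q1` is the headline contrast), `monotonic`,
#'   and `no_ranking_signal` (`TRUE` when `oob_tau` is constant and the
#'   grouping is arbitrary).
#' @export
gate_test <- function(scores, oob_tau, n_groups = 3L) {
  stopifnot(inherits(scores, "aipw_scores"))
  g <- scores$gamma
  n <- length(g)
  if (length(oob_tau) != n) stopf("oob_tau not aligned with scores")
  if (anyNA(oob_tau)) stopf("oob_tau contains missing values")
  n_groups <- as.integer(n_groups)
  if (n < 3L * n_groups)
    stopf("need at least %d rows for %d groups", 3L * n_groups, n_groups)

  no_signal <- var(oob_tau) < 1e-12
  ord <- order(oob_tau, seq_len(n))
  grp <- integer(n)
  grp[ord] <- ceiling(seq_len(n) * n_groups / n)
  labels <- paste0("Q", seq_len(n_groups))
  assignment <- factor(labels[grp], levels = labels)

  group_ates <- lapply(seq_len(n_groups), function(k) {
    idx <- grp == k
    sub <- structure(list(gamma = g[idx], cluster = scores$cluster[idx]),
                     class = "aipw_scores")
    average_treatment_effect(sub)
  })
  names(group_ates) <- labels

  contrasts <- NULL
  monotonic <- NA
  if (n_groups >= 2L) {
    pairs <- utils::combn(n_groups, 2L)
    rows <- lapply(seq_len(ncol(pairs)), function(c0) {
      i <- pairs[1L, c0]; j <- pairs[2L, c0]
      tt <- t.test(g[grp == j], g[grp == i])
      data.frame(contrast = sprintf("Q%d - Q%d", j, i),
                 difference = unname(diff(rev(tt$estimate))),
                 t = unname(tt$statistic), p = tt$p.value)
    })
    contrasts <- do.call(rbind, rows)
    contrasts$q <- fdr_adjust(contrasts$p)
    est <- vapply(group_ates, `[[`, 0, "estimate")
    monotonic <- all(diff(est) > 0)
  }

  structure(list(group_assignment = assignment, group_ates = group_ates,
                 contrasts = contrasts, monotonic = monotonic,
                 n_groups = n_groups, no_ranking_signal = no_signal),
            class = "gate_result")
}

#' @export
print.gate_result <- function(x, ...) {
  est <- vapply(x$group_ates, `[[`, 0, "estimate")
  se <- vapply(x$group_ates, `[[`, 0, "se")
  cat(sprintf("GATE (%d groups%s):\n", x$n_groups,
              if (x$no_ranking_signal) "; no ranking signal" else ""))
  for (k in seq_along(est))
    cat(sprintf("  %s: ATE = %.3f (SE %.3f)\n", names(est)[k], est[k], se[k]))
  if (!is.null(x$contrasts)) {
    cat(sprintf("  monotonic increase: %s\n", x$monotonic))
    for (r in seq_len(nrow(x$contrasts)))
      cat(sprintf("  %s: diff %.3f (q = %.3g)\n", x$contrasts$contrast[r],
                  x$contrasts$difference[r], x$contrasts$q[r]))
  }
  invisible(x)
}

#' Compare covariate values between the low- and high-risk groups
#'
#' Profiles the final model's covariates across the extreme GATE groups to
#' flag candidate risk and protective factors: each covariate is compared
#' between the lowest (Q1) and highest (Qk) risk group with a Welch t-test
#' (continuous) or a two-proportion test (binary), BH-FDR adjusted across
#' the covariate family.
#'
#' @param table the `cohort_table` the GATE groups refer to.
#' @param gate a `gate_result` with at least 2 groups.
#' @param final_covariates covariates to profile (the final model's set).
#' @return Object of class `group_profile`: data.frame with per-covariate
#'   group means, difference (Qk - Q1), test statistic, p and q.
#' @export
compare_risk_groups <- function(table, gate,
                                final_covariates = table$covariate_names) {
  validate_cohort_table(table)
  stopifnot(inherits(gate, "gate_result"))
  if (gate$n_groups < 2L) stopf("need at least 2 GATE groups")
  if (length(gate$group_assignment) != nrow(table$X))
    stopf("gate result not aligned with table")
  bad <- setdiff(final_covariates, table$covariate_names)
  if (length(bad)) stopf("unknown covariate(s): %s", paste(bad, collapse = ", "))

  lo <- gate$group_assignment == levels(gate$group_assignment)[1L]
  hi <- gate$group_assignment == levels(gate$group_assignment)[gate$n_groups]
  if (!any(lo) || !any(hi)) stopf("empty GATE group")

  kind <- table$covariate_kind[match(final_covariates, table$covariate_names)]
  rows <- lapply(seq_along(final_covariates), function(j) {
    x_lo <- table$X[lo, final_covariates[j]]
    x_hi <- table$X[hi, final_covariates[j]]
    m_lo <- mean(x_lo); m_hi <- mean(x_hi)
    if (isTRUE(all.equal(var(x_lo), 0)) && isTRUE(all.equal(var(x_hi), 0)) &&
        m_lo == m_hi) {
      stat <- 0; p <- 1
    } else if (kind[j] == "binary") {
      ht <- suppressWarnings(prop.test(c(sum(x_hi), sum(x_lo)),
                                       c(length(x_hi), length(x_lo))))
      stat <- unname(ht$statistic); p <- ht$p.value
    } else {
      ht <- t.test(x_hi, x_lo)
      stat <- unname(ht$statistic); p <- ht$p.value
    }
    data.frame(covariate = final_covariates[j], kind = kind[j],
               mean_low = m_lo, mean_high = m_hi,
               difference = m_hi - m_lo, statistic = stat, p = p)
  })
  out <- do.call(rbind, rows)
  out$q <- fdr_adjust(out$p)
  class(out) <- c("group_profile", "data.frame")
  out
}
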