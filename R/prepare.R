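#' Complete-case filter
#'
#' Removes every row with a missing covariate, treatment or outcome value
#' (no imputation), then drops any site left with fewer than 2 members so
#' cluster-robust inference stays defined. Removal counts are attached as
#' attributes for the run log.
#'
#' @param table a `cohort_table`, possibly with `NA` cells.
#' @return The filtered `cohort_table` with attributes `n_dropped_incomplete`
#'   and `n_dropped_small_cluster`.
#' @export
complete_case_filter <- function(table) {
  validate_cohort_table(table, require_complete = FALSE)
  keep <- complete.cases(table$X) & !is.na(table$W) & !is.na(table$Y) &
    !is.na(table$cluster)
  n_incomplete <- sum(!keep)
  out <- subset_cohort(table, rows = which(keep))
  sizes <- table(out$cluster)
  small <- names(sizes)[sizes < 2L]
  n_small <- 0L
  if (length(small)) {
    keep2 <- !(out$cluster %in% small)
    n_small <- sum(!keep2)
    out <- subset_cohort(out, rows = which(keep2))
  }
  if (nrow(out$X) == 0L) stopf("no complete cases remain")
  attr(out, "n_dropped_incomplete") <- n_incomplete
  attr(out, "n_dropped_small_cluster") <- n_small
  out
}

#' Drop near-zero-variance covariates
#'
#' A covariate is removed when its value distribution is too degenerate to
#' support splits: the ratio of the most to the second-most frequent value
#' exceeds `freq_ratio` *and* the fraction of distinct values is below
#' `unique_pct`. Constant columns are always dropped.
#'
#' @param table a `cohort_table`.
#' @param freq_ratio dominant/second value frequency-ratio cutoff
#'   (default 19, i.e. 95/5).
#' @param unique_pct maximum fraction of distinct values (default 0.1).
#' @return List with `table` (covariates trimmed) and `dropped` (names).
#' @export
drop_near_zero_variance <- function(table, freq_ratio = 19, unique_pct = 0.1) {
  validate_cohort_table(table, require_complete = FALSE)
  n <- nrow(table$X)
  nzv <- vapply(seq_len(ncol(table$X)), function(j) {
    v <- table$X[, j]
    v <- v[!is.na(v)]
    tab <- sort(table(v), decreasing = TRUE)
    if (length(tab) < 2L) return(TRUE)  # constant
    ratio <- tab[1L] / tab[2L]
    distinct_frac <- length(tab) / length(v)
    ratio > freq_ratio && distinct_frac < unique_pct
  }, NA)
  dropped <- table$covariate_names[nzv]
  out <- if (any(nzv)) subset_cohort(table, table$covariate_names[!nzv]) else table
  list(table = out, dropped = dropped)
}

#' Screen candidate features by adjusted association with the outcome
#'
#' For each candidate (e.g. each brain feature), fits an ordinary least
#' squares regression of the outcome on that candidate plus the adjustment
#' set (e.g. sociodemographic factors and polygenic scores), collects the
#' candidate coefficient's p-value, and applies BH-FDR across candidates.
#' Candidates with `q < alpha` are selected as covariates for the
#' treatment-effect models of that timepoint.
#'
#' @param table a `cohort_table`.
#' @param candidate_features covariate names to screen.
#' @param outcome outcome vector, or `NULL` to use `table$Y`.
#' @param adjustment_set covariate names held in every model; must be
#'   disjoint from the candidates and of full rank.
#' @param alpha FDR threshold (default 0.05).
#' @return Object of class `screen_result`: data.frame with per-candidate
#'   coefficient, p, q and `selected` flag.
#' @export
screen_features <- function(table, candidate_features, outcome = NULL,
                            adjustment_set = character(0), alpha = 0.05) {
  validate_cohort_table(table)
  if (alpha <= 0 || alpha >= 1) stopf("alpha must be in (0, 1)")
  overlap <- intersect(candidate_features, adjustment_set)
  if (length(overlap))
    stopf("candidates overlap the adjustment set: %s",
          paste(overlap, collapse = ", "))
  bad <- setdiff(c(candidate_features, adjustment_set), table$covariate_names)
  if (length(bad)) stopf("unknown covariate(s): %s", paste(bad, collapse = ", "))
  y <- outcome %||% table$Y

  A <- cbind(`(Intercept)` = 1, table$X[, adjustment_set, drop = FALSE])
  qrA <- qr(A)
  if (qrA$rank < ncol(A)) {
    dropped_cols <- colnames(A)[qrA$pivot[(qrA$rank + 1L):ncol(A)]]
    stopf("adjustment set is collinear; offending column(s): %s",
          paste(dropped_cols, collapse = ", "))
  }

  rows <- lapply(candidate_features, function(cand) {
    M <- cbind(A, cand = table$X[, cand])
    fit <- lm.fit(M, y)
    if (fit$rank < ncol(M)) {
      stopf("candidate '%s' is collinear with the adjustment set", cand)
    }
    res <- fit$residuals
    df <- length(y) - ncol(M)
    sigma2 <- sum(res^2) / df
    XtXinv <- chol2inv(chol(crossprod(M)))
    se <- sqrt(sigma2 * XtXinv[ncol(M), ncol(M)])
    b <- fit$coefficients[["cand"]]
    data.frame(feature = cand, coefficient = b, se = se,
               p = 2 * pt(-abs(b / se), df))
  })
  out <- do.call(rbind, rows)
  out$q <- fdr_adjust(out$p)
  out$selected <- out$q < alpha
  attr(out, "alpha") <- alpha
  class(out) <- c("screen_result", "data.frame")
  out
}
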