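#' Fit out-of-bag nuisance models for treatment and outcome
#'
#' Estimates the two nuisance functions the doubly robust machinery needs:
#' the propensity \eqn{e(x) = P(W = 1 | X = x)} and the conditional mean
#' outcome \eqn{m(x) = E[Y | X = x]}, both by regression forests whose
#' predictions for row *i* never use row *i* (out-of-bag). Propensity
#' estimates are clipped to `[clip, 1 - clip]` so inverse-propensity weights
#' stay bounded.
#'
#' An oracle mode short-circuits fitting: supplying `e_fn` and/or `m_fn`
#' evaluates the given functions row-wise on `table$X` instead, which is how
#' simulation studies inject known nuisances.
#'
#' @param table a `cohort_table` with both treatment arms present.
#' @param params list of forest settings: `num_trees` (default 500),
#'   `min_node_size` (5), `clip` (0.05).
#' @param seed integer seed.
#' @param e_fn,m_fn optional oracle functions mapping a covariate matrix (on
#'   the table's scale) to propensities / conditional means.
#' @return An object of class `nuisance_fits`: list with `e_hat`, `m_hat`
#'   (n-vectors) and the clipping bound used.
#' @export
fit_nuisance <- function(table, params = list(), seed = 1L,
                         e_fn = NULL, m_fn = NULL) {
  validate_cohort_table(table)
  if (length(unique(table$W)) < 2L && is.null(e_fn))
    stopf("no overlap: only one treatment arm present")
  num_trees <- params$num_trees %||% 500L
  min_node_size <- params$min_node_size %||% 5L
  clip <- params$clip %||% 0.05

  X <- table$X
  oob_regression <- function(y, which_seed) {
    fit <- ranger::ranger(
      x = X, y = y, num.trees = num_trees,
      min.node.size = min_node_size,
      seed = which_seed, num.threads = 1L
    )
    fit$predictions  # out-of-bag by construction in ranger
  }

  e_hat <- if (!is.null(e_fn)) as.numeric(e_fn(X)) else {
    oob_regression(as.numeric(table$W), derive_seed(seed, 1L))
  }
  m_hat <- if (!is.null(m_fn)) as.numeric(m_fn(X)) else {
    oob_regression(table$Y, derive_seed(seed, 2L))
  }
  if (length(e_hat) != nrow(X) || length(m_hat) != nrow(X))
    stopf("nuisance predictions have wrong length")
  # ranger leaves OOB predictions NaN for rows in every bag; back-fill with
  # the marginal mean (rare at practical tree counts)
  e_hat[!is.finite(e_hat)] <- mean(table$W)
  m_hat[!is.finite(m_hat)] <- mean(table$Y)
  e_hat <- pmin(pmax(e_hat, clip), 1 - clip)

  structure(list(e_hat = e_hat, m_hat = m_hat, clip = clip),
            class = "nuisance_fits")
}

validate_nuisance <- function(nuisance, n) {
  if (!inherits(nuisance, "nuisance_fits")) stopf("not a 'nuisance_fits'")
  if (length(nuisance$e_hat) != n || length(nuisance$m_hat) != n)
    stopf("nuisance fits not aligned with table (expected length %d)", n)
  invisible(nuisance)
}
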