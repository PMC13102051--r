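#' Specify a synthetic multi-site cohort
#'
#' Defines the generating model for an ABCD-like cohort: a multi-site sample
#' with covariates in three blocks (environment, polygenic scores, brain
#' features), a binary stress exposure whose assignment may be confounded by
#' covariates, and a continuous symptom outcome whose treatment effect
#' \eqn{\tau(x)} can be modified nonlinearly by a small covariate subset.
#'
#' The outcome model is \eqn{Y = \mu(X) + \tau(X) W + b_{site} + \epsilon}
#' with site intercepts \eqn{b_{site} \sim N(0, site\_sd^2)} and noise
#' \eqn{\epsilon \sim N(0, noise\_sd^2)}. Treatment follows
#' \eqn{W \sim Bernoulli(e(X))} with propensity
#' \eqn{e(X) = 0.05 + 0.9\,logistic(X\beta_e)}, bounded away from 0 and 1 so
#' overlap holds by construction.
#'
#' @param n_participants number of rows; must be at least `10 * n_sites`.
#' @param n_sites number of recruitment sites (clusters); default 21.
#' @param covariate_blocks list of blocks, each a list with `block` (one of
#'   `"environment"`, `"prs"`, `"brain"`), `count`, `kind`
#'   (`"continuous"` or `"binary"`), and optionally `loadings` (per-covariate
#'   loadings on a shared within-block factor; default a declining sequence
#'   from 0.9 to 0.1). Phenotype blocks — family environment scales,
#'   polygenic scores, regional brain features — are substantially and
#'   *unevenly* intercorrelated in real cohorts: covariate j and k within a
#'   block correlate at `loadings[j] * loadings[k]`, so early covariates
#'   have strong, stable surrogates while late ones are nearly independent.
#'   Continuous covariates have standard normal marginals and are z-scaled
#'   after generation; binary covariates are Bernoulli(0.3), independent,
#'   and left on the 0/1 scale.
#' @param propensity_coefs named numeric vector of log-odds coefficients on
#'   covariates in the treatment-assignment model (confounding strength).
#' @param baseline_coefs named numeric vector of main effects \eqn{\mu(x)}.
#' @param tau_intercept homogeneous treatment-effect component \eqn{\tau_0}.
#' @param modifier_terms list of effect-modifier terms, each a list with
#'   `covariate`, `form` (`"linear"`: \eqn{\gamma x}; `"threshold"`:
#'   \eqn{\gamma 1[x > 0]}; `"saturating"`: \eqn{\gamma \tanh(x)}), and
#'   `coefficient`.
#' @param noise_sd outcome noise standard deviation (> 0).
#' @param site_sd standard deviation of additive site intercepts (>= 0).
#' @param missing_rate MCAR cell-masking rate in `[0, 1)` applied by
#'   [apply_missingness()]; the generator itself returns complete data.
#' @param seed integer seed; generation is deterministic given the spec.
#'
#' @return An object of class `cohort_spec`.
#' @seealso [generate_cohort()]
#' @export
cohort_spec <- function(n_participants,
                        n_sites = 21L,
                        covariate_blocks = list(
                          list(block = "environment", count = 20L, kind = "continuous"),
                          list(block = "prs", count = 17L, kind = "continuous"),
                          list(block = "brain", count = 18L, kind = "continuous")
                        ),
                        propensity_coefs = numeric(0),
                        baseline_coefs = numeric(0),
                        tau_intercept = 0,
                        modifier_terms = list(),
                        noise_sd = 1,
                        site_sd = 0.25,
                        missing_rate = 0,
                        seed = 1L) {
  spec <- list(
    n_participants = as.integer(n_participants),
    n_sites = as.integer(n_sites),
    covariate_blocks = covariate_blocks,
    propensity_coefs = propensity_coefs,
    baseline_coefs = baseline_coefs,
    tau_intercept = tau_intercept,
    modifier_terms = modifier_terms,
    noise_sd = noise_sd,
    site_sd = site_sd,
    missing_rate = missing_rate,
    seed = as.integer(seed)
  )
  class(spec) <- "cohort_spec"
  validate_cohort_spec(spec)
  spec
}

covariate_names_from_blocks <- function(blocks) {
  unlist(lapply(blocks, function(b) {
    sprintf("%s__x%02d", b$block, seq_len(b$count))
  }), use.names = FALSE)
}

covariate_kinds_from_blocks <- function(blocks) {
  unlist(lapply(blocks, function(b) rep(b$kind, b$count)), use.names = FALSE)
}

validate_cohort_spec <- function(spec) {
  if (spec$n_participants < 1L) stopf("invalid 'n_participants': must be positive")
  if (spec$n_sites < 1L) stopf("invalid 'n_sites': must be positive")
  if (length(spec$covariate_blocks) == 0L)
    stopf("invalid 'covariate_blocks': at least one block required")
  for (b in spec$covariate_blocks) {
    if (!b$block %in% c("environment", "prs", "brain"))
      stopf("invalid 'covariate_blocks': unknown block '%s'", b$block)
    if (!b$kind %in% c("continuous", "binary"))
      stopf("invalid 'covariate_blocks': unknown kind '%s'", b$kind)
    if (b$count < 0L) stopf("invalid 'covariate_blocks': negative count")
    if (!is.null(b$loadings) &&
        (length(b$loadings) != b$count || any(b$loadings < 0) ||
         any(b$loadings >= 1)))
      stopf("invalid 'covariate_blocks': loadings must be %d values in [0, 1)",
            b$count)
  }
  nm <- covariate_names_from_blocks(spec$covariate_blocks)
  if (length(nm) < 1L) stopf("invalid 'covariate_blocks': total dimension must be >= 1")
  if (anyDuplicated(nm)) stopf("invalid 'covariate_blocks': duplicated covariate names")
  if (spec$n_participants < 10L * spec$n_sites)
    stopf("invalid 'n_participants': need at least 10 rows per site (n >= %d)",
          10L * spec$n_sites)
  for (field in c("propensity_coefs", "baseline_coefs")) {
    cf <- spec[[field]]
    if (length(cf) > 0L && (is.null(names(cf)) || !all(names(cf) %in% nm)))
      stopf("invalid '%s': names %s not among generated covariates", field,
            paste(setdiff(names(cf), nm), collapse = ", "))
  }
  for (term in spec$modifier_terms) {
    if (!term$covariate %in% nm)
      stopf("invalid 'modifier_terms': covariate '%s' not among generated covariates",
            term$covariate)
    if (!term$form %in% c("linear", "threshold", "saturating"))
      stopf("invalid 'modifier_terms': unknown form '%s'", term$form)
  }
  if (spec$noise_sd <= 0) stopf("invalid 'noise_sd': must be > 0")
  if (spec$site_sd < 0) stopf("invalid 'site_sd': must be >= 0")
  if (spec$missing_rate < 0 || spec$missing_rate >= 1)
    stopf("invalid 'missing_rate': must be in [0, 1)")
  invisible(spec)
}

modifier_value <- function(x, form) {
  switch(form,
    linear = x,
    threshold = as.numeric(x > 0),
    saturating = tanh(x),
    stopf("unknown modifier form '%s'", form)
  )
}

# tau(x) on the raw (pre-scaling) covariate scale
tau_raw_fn <- function(spec) {
  force(spec)
  function(X_raw) {
    tau <- rep(spec$tau_intercept, nrow(X_raw))
    for (term in spec$modifier_terms) {
      tau <- tau + term$coefficient *
        modifier_value(X_raw[, term$covariate], term$form)
    }
    tau
  }
}

#' Generate a synthetic cohort with known ground truth
#'
#' Draws a cohort from a [cohort_spec()] generating model and returns both
#' the observable data and a truth ledger (the true effect surface, true
#' average treatment effect, true propensity, and the effect-modifier set)
#' for recovery testing. Generation is bit-reproducible for a fixed spec.
#'
#' Continuous covariates are z-scaled after generation; the truth callables
#' accept rows on the *returned* (scaled) covariate scale and undo the
#' scaling internally, so `mean(truth$true_tau(table$X))` equals
#' `truth$true_ate` exactly.
#'
#' @param spec a [cohort_spec()].
#' @return A list with elements `table` (class `cohort_table`: covariate
#'   matrix `X`, treatment `W`, outcome `Y`, site labels `cluster`,
#'   `covariate_names`, `covariate_kind`) and `truth` (class `ground_truth`:
#'   `true_ate`, `true_tau`, `propensity`, `modifier_names`).
#' @export
generate_cohort <- function(spec) {
  validate_cohort_spec(spec)
  n <- spec$n_participants
  nm <- covariate_names_from_blocks(spec$covariate_blocks)
  kind <- covariate_kinds_from_blocks(spec$covariate_blocks)
  p <- length(nm)

  with_seed(spec$seed, {
    # balanced-then-shuffled assignment guarantees >= 2 rows per site
    site <- sample(rep_len(seq_len(spec$n_sites), n))

    X_raw <- matrix(0, n, p, dimnames = list(NULL, nm))
    col <- 0L
    for (b in spec$covariate_blocks) {
      lambda <- b$loadings %||%
        (if (b$count > 1) seq(0.9, 0.1, length.out = b$count) else 0.9)
      shared <- rnorm(n)  # within-block factor; cor(j, k) = lambda_j lambda_k
      for (k in seq_len(b$count)) {
        col <- col + 1L
        X_raw[, col] <- if (b$kind == "binary") rbinom(n, 1L, 0.3) else
          lambda[k] * shared + sqrt(1 - lambda[k]^2) * rnorm(n)
      }
    }

    beta_e <- setNames(numeric(p), nm)
    beta_e[names(spec$propensity_coefs)] <- spec$propensity_coefs
    e_x <- 0.05 + 0.9 * stats::plogis(drop(X_raw %*% beta_e))
    W <- rbinom(n, 1L, e_x)

    beta_mu <- setNames(numeric(p), nm)
    beta_mu[names(spec$baseline_coefs)] <- spec$baseline_coefs
    mu <- drop(X_raw %*% beta_mu)

    tau_fn <- tau_raw_fn(spec)
    tau <- tau_fn(X_raw)

    site_eff <- rnorm(spec$n_sites, 0, spec$site_sd)[site]
    Y <- mu + tau * W + site_eff + rnorm(n, 0, spec$noise_sd)
  })

  # z-scale continuous columns only
  center <- setNames(numeric(p), nm)
  scale_ <- setNames(rep(1, p), nm)
  cont <- kind == "continuous"
  center[cont] <- colMeans(X_raw[, cont, drop = FALSE])
  scale_[cont] <- apply(X_raw[, cont, drop = FALSE], 2, sd)
  scale_[scale_ < 1e-12] <- 1
  X <- sweep(sweep(X_raw, 2, center, "-"), 2, scale_, "/")

  table <- new_cohort_table(X = X, W = W, Y = Y,
                            cluster = sprintf("site%02d", site),
                            covariate_names = nm, covariate_kind = kind)

  unscale <- function(Xs) {
    Xs <- rbind(Xs)  # accept a single row as a vector
    if (is.null(colnames(Xs))) colnames(Xs) <- nm
    sweep(sweep(Xs[, nm, drop = FALSE], 2, scale_[nm], "*"), 2, center[nm], "+")
  }
  truth <- structure(list(
    true_ate = mean(tau),
    true_tau = function(x) tau_fn(unscale(x)),
    propensity = function(x) {
      0.05 + 0.9 * stats::plogis(drop(unscale(x) %*% beta_e))
    },
    modifier_names = unique(vapply(spec$modifier_terms, `[[`, "", "covariate")),
    spec = spec
  ), class = "ground_truth")

  list(table = table, truth = truth)
}

new_cohort_table <- function(X, W, Y, cluster, covariate_names, covariate_kind) {
  structure(list(X = X, W = as.integer(W), Y = as.numeric(Y),
                 cluster = as.character(cluster),
                 covariate_names = covariate_names,
                 covariate_kind = covariate_kind),
            class = "cohort_table")
}

validate_cohort_table <- function(table, require_complete = TRUE) {
  if (!inherits(table, "cohort_table")) stopf("not a 'cohort_table'")
  n <- nrow(table$X)
  if (length(table$W) != n || length(table$Y) != n || length(table$cluster) != n)
    stopf("cohort_table components have inconsistent lengths")
  if (require_complete && (anyNA(table$X) || anyNA(table$W) || anyNA(table$Y)))
    stopf("cohort_table contains missing values; apply complete_case_filter() first")
  invisible(table)
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf("cohort_table: %d participants, %d covariates, %d sites\n",
              nrow(x$X), ncol(x$X), length(unique(x$cluster))))
  cat(sprintf("  treated: %d (%.1f%%); outcome mean %.3f (sd %.3f)\n",
              sum(x$W == 1L, na.rm = TRUE),
              100 * mean(x$W == 1L, na.rm = TRUE),
              mean(x$Y, na.rm = TRUE), sd(x$Y, na.rm = TRUE)))
  invisible(x)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("ground_truth: true ATE %.4f; modifiers: %s\n", x$true_ate,
              if (length(x$modifier_names)) paste(x$modifier_names, collapse = ", ")
              else "(none; homogeneous effect)"))
  invisible(x)
}

#' Mask covariate cells completely at random
#'
#' Introduces MCAR gaps into the covariate matrix so the downstream
#' complete-case filter is exercised; treatment, outcome and cluster columns
#' are never masked.
#'
#' @param table a `cohort_table`.
#' @param rate cell-masking probability in `[0, 1)`.
#' @param seed integer seed.
#' @return The table with `NA` covariate cells; `rate = 0` returns the input
#'   unchanged.
#' @export
apply_missingness <- function(table, rate, seed = 1L) {
  validate_cohort_table(table, require_complete = FALSE)
  if (rate < 0 || rate >= 1) stopf("invalid 'rate': must be in [0, 1)")
  if (rate == 0) return(table)
  with_seed(seed, {
    mask <- matrix(runif(length(table$X)) < rate, nrow(table$X))
  })
  table$X[mask] <- NA_real_
  table
}

#' Write / read a cohort table as CSV
#'
#' The on-disk layout is one row per participant with columns `W`, `Y`,
#' `cluster` (string site labels) followed by the covariates under their
#' `<block>__<name>` names. A JSON truth sidecar (written alongside when a
#' `ground_truth` is supplied) records the true ATE, the modifier set and
#' the generating parameters; the effect-surface callables themselves are
#' reconstructed by regenerating from the stored spec, not deserialized.
#'
#' @param table a `cohort_table`.
#' @param path CSV output path.
#' @param truth optional `ground_truth` to record as `<path>.truth.json`.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(table, path, truth = NULL) {
  validate_cohort_table(table, require_complete = FALSE)
  df <- data.frame(W = table$W, Y = table$Y, cluster = table$cluster,
                   table$X, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  if (!is.null(truth)) {
    side <- list(true_ate = truth$true_ate,
                 modifier_names = as.list(truth$modifier_names),
                 spec = truth$spec[setdiff(names(truth$spec), "covariate_blocks")],
                 covariate_blocks = truth$spec$covariate_blocks)
    jsonlite::write_json(side, paste0(path, ".truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' @rdname write_cohort
#' @param treatment,outcome,cluster column names in the CSV.
#' @export
read_cohort <- function(path, treatment = "W", outcome = "Y",
                        cluster = "cluster") {
  df <- utils::read.csv(path, check.names = FALSE,
                        colClasses = setNames("character", cluster))
  need <- c(treatment, outcome, cluster)
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stopf("cohort file lacks column(s): %s", paste(missing_cols, collapse = ", "))
  covs <- setdiff(names(df), need)
  X <- as.matrix(df[covs])
  kind <- vapply(covs, function(j) {
    v <- X[, j]
    if (all(v %in% c(0, 1) | is.na(v))) "binary" else "continuous"
  }, "")
  new_cohort_table(X = X, W = df[[treatment]], Y = df[[outcome]],
                   cluster = df[[cluster]], covariate_names = covs,
                   covariate_kind = unname(kind))
}

#' Restrict a cohort table to a subset of covariate columns or rows
#'
#' @param table a `cohort_table`.
#' @param covariates character vector of covariate names to keep.
#' @param rows optional integer/logical row index.
#' @return The subset `cohort_table`.
#' @export
subset_cohort <- function(table, covariates = table$covariate_names,
                          rows = NULL) {
  validate_cohort_table(table, require_complete = FALSE)
  bad <- setdiff(covariates, table$covariate_names)
  if (length(bad)) stopf("unknown covariate(s): %s", paste(bad, collapse = ", "))
  keep <- match(covariates, table$covariate_names)
  if (is.null(rows)) rows <- seq_len(nrow(table$X))
  new_cohort_table(X = table$X[rows, keep, drop = FALSE],
                   W = table$W[rows], Y = table$Y[rows],
                   cluster = table$cluster[rows],
                   covariate_names = table$covariate_names[keep],
                   covariate_kind = table$covariate_kind[keep])
}
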