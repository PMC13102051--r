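#' Fit an honest causal forest
#'
#' Grows an ensemble of honest trees estimating the conditional average
#' treatment effect \eqn{\tau(x)}. Each tree is grown on a cluster-level
#' subsample (whole sites in or out, so out-of-bag predictions respect the
#' multi-site design); the subsample is split into an honest pair of halves —
#' splits are searched on one half and leaf effects estimated on the other.
#' Splitting is gradient-style: within a node the local effect is the
#' no-intercept regression slope of the centered outcome on the centered
#' treatment, and candidate splits maximize between-child heterogeneity of
#' that slope via the standard CART criterion on the pseudo-outcome
#' \eqn{\rho_i = (W_i - \hat e_i)\,(Y_i - \hat m_i - (W_i - \hat e_i)\,
#' \tau_{parent})}. Ties in split gain resolve to the lowest covariate index,
#' then the lowest threshold, so refits under fixed seeds are reproducible.
#'
#' @param table a `cohort_table`.
#' @param nuisance a `nuisance_fits` aligned with `table`.
#' @param params list of forest settings: `num_trees` (default 500),
#'   `honesty_fraction` (0.5), `subsample_rate` (0.5, fraction of *sites*
#'   per tree), `min_node_size` (5), `mtry` (default
#'   `min(p, ceiling(sqrt(p)) + 20)`).
#' @param seed integer seed; one forest per seed, see [merge_forests()] for
#'   seed ensembles.
#' @return An object of class `causal_forest`: trees, per-tree subsample
#'   bookkeeping, `oob_tau` (out-of-bag CATE predictions; `NA` where no tree
#'   left the row out), split-frequency counts, the training data, and the
#'   resolved parameters.
#' @export
fit_causal_forest <- function(table, nuisance, params = list(), seed = 1L) {
  validate_cohort_table(table)
  n <- nrow(table$X)
  p <- ncol(table$X)
  validate_nuisance(nuisance, n)

  par <- resolve_forest_params(params, p)
  cluster_f <- factor(table$cluster)
  n_clusters <- nlevels(cluster_f)
  subsample_n <- floor(par$subsample_rate * n)
  if (par$min_node_size > subsample_n)
    stopf("min_node_size (%d) exceeds the expected subsample size (%d)",
          par$min_node_size, subsample_n)

  Wc <- as.numeric(table$W) - nuisance$e_hat
  Yc <- table$Y - nuisance$m_hat
  grown <- .grow_causal_forest_cpp(
    table$X, Wc, Yc, as.integer(cluster_f) - 1L, n_clusters,
    as.integer(par$num_trees), par$subsample_rate, par$honesty_fraction,
    as.integer(par$mtry), as.integer(par$min_node_size), as.numeric(seed)
  )

  forest <- structure(list(
    trees = grown$trees,
    split_counts = trim_split_counts(grown$split_counts, table$covariate_names),
    params = par,
    seeds = as.integer(seed),
    X = table$X, W = table$W, Y = table$Y,
    cluster = table$cluster,
    covariate_names = table$covariate_names,
    e_hat = nuisance$e_hat, m_hat = nuisance$m_hat
  ), class = "causal_forest")
  forest$oob_tau <- predict(forest, oob = TRUE)
  forest
}

resolve_forest_params <- function(params, p) {
  par <- list(
    num_trees = as.integer(params$num_trees %||% 500L),
    honesty_fraction = params$honesty_fraction %||% 0.5,
    subsample_rate = params$subsample_rate %||% 0.5,
    min_node_size = as.integer(params$min_node_size %||% 5L),
    mtry = as.integer(params$mtry %||% min(p, ceiling(sqrt(p)) + 20L))
  )
  if (par$num_trees < 1L) stopf("num_trees must be >= 1")
  if (par$honesty_fraction <= 0 || par$honesty_fraction >= 1)
    stopf("honesty_fraction must be in (0, 1)")
  if (par$subsample_rate <= 0 || par$subsample_rate > 1)
    stopf("subsample_rate must be in (0, 1]")
  par
}

trim_split_counts <- function(counts, covariate_names) {
  used <- which(colSums(counts) > 0)
  depth <- if (length(used)) max(used) else 1L
  counts <- counts[, seq_len(depth), drop = FALSE]
  rownames(counts) <- covariate_names
  colnames(counts) <- paste0("depth", seq_len(depth))
  counts
}

#' Predict conditional treatment effects from a causal forest
#'
#' @param object a `causal_forest`.
#' @param newdata optional covariate matrix (columns matching the training
#'   covariates); defaults to the training matrix.
#' @param oob if `TRUE` (training data only), row *i* is predicted using only
#'   trees whose site subsample excluded row *i*'s site; rows covered by no
#'   tree are `NA`.
#' @param ... unused.
#' @return Numeric vector of \eqn{\hat\tau(x)}.
#' @export
predict.causal_forest <- function(object, newdata = NULL, oob = FALSE, ...) {
  if (oob && !is.null(newdata))
    stopf("out-of-bag prediction is only defined on the training data")
  X <- if (is.null(newdata)) object$X else {
    newdata <- rbind(newdata)
    if (!is.null(colnames(newdata))) {
      bad <- setdiff(object$covariate_names, colnames(newdata))
      if (length(bad)) stopf("newdata lacks covariate(s): %s",
                             paste(bad, collapse = ", "))
      newdata <- newdata[, object$covariate_names, drop = FALSE]
    } else if (ncol(newdata) != ncol(object$X)) {
      stopf("newdata has %d columns; forest expects %d", ncol(newdata),
            ncol(object$X))
    }
    newdata
  }
  cl <- if (oob) as.integer(factor(object$cluster)) - 1L else integer(nrow(X))
  .predict_trees_cpp(object$trees, X, oob, cl)
}

#' Merge causal forests fitted with different seeds into one ensemble
#'
#' Implements the seed-ensemble step: several forests grown on the same data
#' with identical parameters but different seeds are pooled into one large
#' forest, and out-of-bag predictions are recomputed over the pooled trees.
#'
#' @param forests list of `causal_forest` objects fitted on the identical
#'   table with identical parameters (seeds may differ).
#' @return A single merged `causal_forest`.
#' @export
merge_forests <- function(forests) {
  if (!length(forests)) stopf("no forests to merge")
  if (length(forests) == 1L) return(forests[[1L]])
  ref <- forests[[1L]]
  for (f in forests[-1L]) {
    if (!inherits(f, "causal_forest")) stopf("all elements must be causal forests")
    if (!identical(dim(f$X), dim(ref$X)) || !identical(f$X, ref$X) ||
        !identical(f$W, ref$W) || !identical(f$Y, ref$Y) ||
        !identical(f$cluster, ref$cluster))
      stopf("forests were not fitted on the identical table")
    if (!identical(f$params, ref$params))
      stopf("forests were not fitted with identical parameters")
  }
  merged <- ref
  merged$trees <- do.call(c, lapply(forests, `[[`, "trees"))
  merged$seeds <- unlist(lapply(forests, `[[`, "seeds"))
  merged$params$num_trees <- length(merged$trees)
  counts <- lapply(forests, `[[`, "split_counts")
  depth <- max(vapply(counts, ncol, 0L))
  pad <- function(m) {
    if (ncol(m) < depth)
      m <- cbind(m, matrix(0L, nrow(m), depth - ncol(m)))
    m
  }
  merged$split_counts <- Reduce(`+`, lapply(counts, pad))
  colnames(merged$split_counts) <- paste0("depth", seq_len(depth))
  merged$oob_tau <- predict(merged, oob = TRUE)
  merged
}

#' Split-frequency variable importance
#'
#' Importance of covariate *j* is the depth-weighted count of splits on *j*
#' across all trees, \eqn{\sum_d d^{-decay}\, counts_{jd}} over depths
#' `1..depth_cap`, normalized to sum to one. Early (shallow) splits carry
#' more weight; splits deeper than `depth_cap` are ignored.
#'
#' @param forest a `causal_forest`.
#' @param decay depth-decay exponent (default 2).
#' @param depth_cap deepest split level counted (default 4).
#' @return Named numeric vector of importances summing to 1 (all zero, with
#'   a warning, for a forest of stumps).
#' @export
variable_importance <- function(forest, decay = 2, depth_cap = 4L) {
  counts <- forest$split_counts
  d <- seq_len(min(ncol(counts), depth_cap))
  w <- d^(-decay)
  imp <- drop(counts[, d, drop = FALSE] %*% w)
  total <- sum(imp)
  if (total <= 0) {
    warning("forest has no internal nodes; importance is the zero vector")
    return(setNames(numeric(nrow(counts)), rownames(counts)))
  }
  imp / total
}

#' @export
print.causal_forest <- function(x, ...) {
  cat(sprintf("causal_forest: %d trees (seeds: %s), n = %d, p = %d, %d sites\n",
              length(x$trees), paste(x$seeds, collapse = ","), nrow(x$X),
              ncol(x$X), length(unique(x$cluster))))
  ok <- is.finite(x$oob_tau)
  cat(sprintf("  oob tau: mean %.4f, sd %.4f (%d/%d rows covered)\n",
              mean(x$oob_tau[ok]), sd(x$oob_tau[ok]), sum(ok), length(ok)))
  invisible(x)
}

#' Serialize a causal forest to a JSON bundle
#'
#' Writes parameters, seeds, tree structures and out-of-bag predictions so
#' a fitted forest can be cached between pipeline stages. The training data
#' itself is not stored; [read_forest()] needs the identical `cohort_table`
#' back and verifies it against stored fingerprints before attaching it.
#'
#' @param forest a `causal_forest`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_forest <- function(forest, path) {
  stopifnot(inherits(forest, "causal_forest"))
  payload <- list(
    params = forest$params, seeds = forest$seeds,
    covariate_names = forest$covariate_names,
    n = nrow(forest$X),
    fingerprint = c(sum(forest$X), sum(forest$W), sum(forest$Y)),
    split_counts = forest$split_counts,
    oob_tau = forest$oob_tau,
    trees = lapply(forest$trees, function(tr)
      tr[c("split_var", "threshold", "left", "right", "depth", "leaf_tau",
           "sites", "split_idx", "est_idx", "est_leaf")])
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       null = "null", na = "null")
  invisible(path)
}

#' @rdname write_forest
#' @param table the `cohort_table` the forest was fitted on.
#' @export
read_forest <- function(path, table) {
  validate_cohort_table(table)
  payload <- jsonlite::read_json(path, simplifyVector = FALSE)
  num <- function(x) vapply(x, function(v) if (is.null(v)) NA_real_ else
    as.numeric(v), 0)
  int <- function(x) as.integer(num(x))
  if (payload$n != nrow(table$X) ||
      !isTRUE(all.equal(num(payload$fingerprint),
                        c(sum(table$X), sum(table$W), sum(table$Y)))) ||
      !identical(vapply(payload$covariate_names, as.character, ""),
                 table$covariate_names))
    stopf("stored forest does not match the supplied table")
  trees <- lapply(payload$trees, function(tr) {
    list(split_var = int(tr$split_var), threshold = num(tr$threshold),
         left = int(tr$left), right = int(tr$right), depth = int(tr$depth),
         leaf_tau = num(tr$leaf_tau), sites = int(tr$sites),
         split_idx = int(tr$split_idx), est_idx = int(tr$est_idx),
         est_leaf = int(tr$est_leaf))
  })
  counts <- do.call(rbind, lapply(payload$split_counts, int))
  rownames(counts) <- table$covariate_names
  colnames(counts) <- paste0("depth", seq_len(ncol(counts)))
  params <- lapply(payload$params, function(v) v)
  params$num_trees <- as.integer(params$num_trees)
  params$min_node_size <- as.integer(params$min_node_size)
  params$mtry <- as.integer(params$mtry)
  structure(list(
    trees = trees, split_counts = counts,
    params = params, seeds = int(payload$seeds),
    X = table$X, W = table$W, Y = table$Y, cluster = table$cluster,
    covariate_names = table$covariate_names,
    oob_tau = num(payload$oob_tau)
  ), class = "causal_forest")
}
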