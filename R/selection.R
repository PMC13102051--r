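#' Default configuration for the three-step selection procedure
#'
#' @param order_seeds one seed per random iteration (the covariate-order
#'   shuffles); default `c(1, 2, 3)` gives the three random iterations.
#' @param forest_seeds list (one element per iteration) of three seeds each
#'   for the seed-ensemble forests.
#' @param forest_params,nuisance_params passed to [fit_causal_forest()] and
#'   [fit_nuisance()].
#' @param ate_alpha,het_alpha stage-gate thresholds: a stage must show a
#'   significant ATE (two-sided `p < ate_alpha`) and significant
#'   heterogeneity (one-sided `p_beta < het_alpha`) to justify further
#'   model reduction.
#' @param gate_rule how the per-iteration gates aggregate into a stage
#'   decision: `"majority"` (default; at least 2 of 3 iterations pass),
#'   `"any"`, `"all"`, or `"first"` (iteration 1 decides).
#' @param empty_intersection policy when the retained sets share no
#'   covariate: `"stop"` (default; the trace records the diagnostic) or
#'   `"top_k"` (fall back to the `top_k` covariates by mean importance rank).
#' @param top_k fallback set size under `empty_intersection = "top_k"`.
#' @return A config list for [three_step_select()].
#' @export
selection_config <- function(order_seeds = c(1L, 2L, 3L),
                             forest_seeds = list(c(11L, 12L, 13L),
                                                 c(21L, 22L, 23L),
                                                 c(31L, 32L, 33L)),
                             forest_params = list(),
                             nuisance_params = list(),
                             ate_alpha = 0.05,
                             het_alpha = 0.05,
                             gate_rule = c("majority", "any", "all", "first"),
                             empty_intersection = c("stop", "top_k"),
                             top_k = 10L) {
  if (length(forest_seeds) != length(order_seeds))
    stopf("need one forest-seed triple per order seed")
  list(order_seeds = order_seeds, forest_seeds = forest_seeds,
       forest_params = forest_params, nuisance_params = nuisance_params,
       ate_alpha = ate_alpha, het_alpha = het_alpha,
       gate_rule = match.arg(gate_rule),
       empty_intersection = match.arg(empty_intersection),
       top_k = as.integer(top_k))
}

#' Run one random iteration: shuffle, seed-ensemble, importance, retain
#'
#' One iteration of the selection procedure: the covariate columns are
#' shuffled into a random order, nuisances are fitted on the current
#' covariate set, three forests with different seeds are grown and merged
#' into one ensemble, split-frequency importance is computed on the merged
#' forest, and covariates with importance strictly above the mean importance
#' are retained.
#'
#' @param table a `cohort_table`.
#' @param covariates covariate names in play for this stage.
#' @param order_seed seed for the column shuffle.
#' @param forest_seeds three seeds for the ensemble members (duplicates give
#'   a warning: the ensemble degenerates toward a single forest).
#' @param config a [selection_config()] (forest/nuisance params and gates).
#' @param iteration_id integer label stored in the result.
#' @param keep_forest keep the merged forest (and nuisance fits) in the
#'   result; needed when the iteration's model is used downstream.
#' @return Object of class `iteration_result`: the shuffled order, the
#'   importance vector (in shuffled-column order), the retained set, and the
#'   iteration's `ate_result` and `calibration_result`.
#' @export
run_random_iteration <- function(table, covariates, order_seed, forest_seeds,
                                 config = selection_config(),
                                 iteration_id = 1L, keep_forest = FALSE) {
  validate_cohort_table(table)
  if (length(forest_seeds) != 3L)
    stopf("forest_seeds must contain exactly 3 seeds")
  if (anyDuplicated(forest_seeds))
    warning("duplicate forest seeds: the seed ensemble degenerates")

  order_idx <- with_seed(order_seed, sample(length(covariates)))
  shuffled <- covariates[order_idx]
  sub <- subset_cohort(table, shuffled)

  nuisance <- fit_nuisance(sub, params = config$nuisance_params,
                           seed = derive_seed(order_seed, 97L))
  forests <- lapply(forest_seeds, function(s)
    fit_causal_forest(sub, nuisance, params = config$forest_params, seed = s))
  merged <- merge_forests(forests)

  importance <- variable_importance(merged)
  retained <- names(importance)[importance > mean(importance)]

  scores <- aipw_scores(sub, nuisance, merged$oob_tau)
  ate <- average_treatment_effect(scores)
  calibration <- calibration_test(sub, nuisance, merged$oob_tau)

  res <- list(iteration_id = iteration_id, order_seed = order_seed,
              forest_seeds = forest_seeds, covariate_order = shuffled,
              importance = importance, retained = retained,
              ate = ate, calibration = calibration,
              scores = scores)
  if (keep_forest) {
    res$forest <- merged
    res$nuisance <- nuisance
    res$table <- sub
  }
  class(res) <- "iteration_result"
  res
}

#' Intersect the retained covariate sets across random iterations
#'
#' @param results list of `iteration_result`s (or plain character vectors)
#'   from the same stage.
#' @return Character vector: covariates retained in *every* iteration,
#'   reported in a stable (sorted) order.
#' @export
intersect_retained <- function(results) {
  sets <- lapply(results, function(r)
    if (inherits(r, "iteration_result")) r$retained else as.character(r))
  sort(Reduce(intersect, sets))
}

stage_gate <- function(iterations, config) {
  ate_ok <- vapply(iterations, function(it)
    !is.na(it$ate$p_value) && it$ate$p_value < config$ate_alpha, NA)
  het_ok <- vapply(iterations, function(it)
    !isTRUE(it$calibration$degenerate) && !is.na(it$calibration$p_beta) &&
      it$calibration$p_beta < config$het_alpha, NA)
  pass <- ate_ok & het_ok
  passed <- switch(config$gate_rule,
    majority = sum(pass) >= ceiling(length(pass) / 2),
    any = any(pass),
    all = all(pass),
    first = pass[1L]
  )
  reason <- if (passed) NA_character_ else {
    parts <- character(0)
    if (sum(ate_ok) < ceiling(length(pass) / 2)) parts <- c(parts, "ATE not significant")
    if (sum(het_ok) < ceiling(length(pass) / 2)) parts <- c(parts, "heterogeneity not significant")
    if (!length(parts)) parts <- "stage gates not jointly met"
    paste(parts, collapse = "; ")
  }
  list(per_iteration = pass, passed = passed, reason = reason)
}

#' Three-step covariate selection with seed-ensembled random iterations
#'
#' The full iterative model-reduction procedure: a *first model* on all
#' covariates is fitted in several random iterations (shuffled covariate
#' order, three-seed forest ensembles); each iteration retains the
#' covariates with above-mean split-frequency importance, and the
#' intersection across iterations forms the *second model*'s covariate set.
#' The same procedure on the second model yields the *final model*'s set,
#' and final models are then fitted (one per iteration) on that set. The
#' procedure only advances past a stage whose ATE and heterogeneity gates
#' pass — with no significant effect-size variation among individuals there
#' is nothing for further reduction to find, and the trace stops with the
#' recorded reason rather than an error.
#'
#' @param table a `cohort_table`.
#' @param covariates covariates in play (>= 4).
#' @param config a [selection_config()].
#' @return Object of class `selection_trace`: per-stage iteration results,
#'   retained sets and intersections, the final covariate set, the final
#'   models (with forests kept for downstream GATE / partial-dependence
#'   analysis), and `stop_reason` (`NA` when the procedure completed).
#' @export
three_step_select <- function(table, covariates = table$covariate_names,
                              config = selection_config()) {
  validate_cohort_table(table)
  if (length(covariates) < 4L)
    stopf("three-step selection needs at least 4 covariates")

  n_iter <- length(config$order_seeds)
  run_stage <- function(covs, stage_name, keep_forest) {
    iterations <- lapply(seq_len(n_iter), function(i)
      run_random_iteration(table, covs,
                           order_seed = config$order_seeds[[i]],
                           forest_seeds = config$forest_seeds[[i]],
                           config = config, iteration_id = i,
                           keep_forest = keep_forest))
    gate <- stage_gate(iterations, config)
    list(name = stage_name, covariates = covs, iterations = iterations,
         gate = gate,
         intersection = intersect_retained(iterations))
  }

  fallback_set <- function(stage) {
    # mean importance rank across iterations, best (lowest) first
    ranks <- sapply(stage$iterations, function(it) {
      imp <- it$importance[stage$covariates]
      rank(-imp, ties.method = "min")
    })
    mean_rank <- rowMeans(ranks)
    stage$covariates[order(mean_rank)][seq_len(min(config$top_k,
                                                   length(stage$covariates)))]
  }

  trace <- list(stages = list(), final_covariates = character(0),
                final_models = list(), stop_reason = NA_character_,
                config = config)
  class(trace) <- "selection_trace"

  stage_names <- c("first", "second")
  covs <- covariates
  for (s in seq_along(stage_names)) {
    stage <- run_stage(covs, stage_names[s], keep_forest = FALSE)
    trace$stages[[stage_names[s]]] <- stage
    if (!stage$gate$passed) {
      trace$stop_reason <- sprintf("halted at stage '%s': %s",
                                   stage_names[s], stage$gate$reason)
      return(trace)
    }
    next_set <- stage$intersection
    if (!length(next_set) && length(covs) == 1L) {
      # a singleton set cannot clear the strictly-above-mean rule; it is
      # irreducible, so carry it forward rather than halting
      next_set <- covs
      trace$stages[[stage_names[s]]]$irreducible <- TRUE
    }
    if (!length(next_set)) {
      if (config$empty_intersection == "stop") {
        trace$stop_reason <- sprintf(
          "halted at stage '%s': empty intersection of retained sets",
          stage_names[s])
        return(trace)
      }
      next_set <- fallback_set(stage)
      trace$stages[[stage_names[s]]]$fallback_used <- TRUE
    }
    covs <- next_set
  }

  final <- run_stage(covs, "final", keep_forest = TRUE)
  trace$stages$final <- final
  trace$final_covariates <- covs
  trace$final_models <- final$iterations
  if (!final$gate$passed)
    trace$stop_reason <- sprintf("final model gates failed: %s",
                                 final$gate$reason)
  trace
}

#' @export
print.selection_trace <- function(x, ...) {
  for (nm in names(x$stages)) {
    st <- x$stages[[nm]]
    cat(sprintf("stage '%s': %d covariates -> intersection of %d\n",
                nm, length(st$covariates), length(st$intersection)))
  }
  if (!is.na(x$stop_reason)) cat(sprintf("  %s\n", x$stop_reason))
  else cat(sprintf("  final set (%d): %s\n", length(x$final_covariates),
                   paste(x$final_covariates, collapse = ", ")))
  invisible(x)
}

#' Per-stage importance tables from a selection trace
#'
#' @param trace a `selection_trace`.
#' @return A data.frame with one row per (stage, iteration, covariate):
#'   importance and whether the covariate was retained.
#' @export
selection_importance_table <- function(trace) {
  rows <- list()
  for (nm in names(trace$stages)) {
    for (it in trace$stages[[nm]]$iterations) {
      rows[[length(rows) + 1L]] <- data.frame(
        stage = nm, iteration = it$iteration_id,
        covariate = names(it$importance),
        importance = unname(it$importance),
        retained = names(it$importance) %in% it$retained)
    }
  }
  do.call(rbind, rows)
}
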