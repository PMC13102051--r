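#' Configure an end-to-end analysis run
#'
#' A run is a grid of analysis cells: one cohort per (timepoint x outcome)
#' combination, optionally crossed with strata (row subsets, e.g. sex
#' groups). Every cell is processed identically: complete-case filtering,
#' near-zero-variance removal, adjusted feature screening, three-step
#' covariate selection, and — when the selection gates pass — GATE,
#' risk-group profiling and partial-dependence simulation. All randomness
#' is controlled by the seeds recorded in the config, so a rerun reproduces
#' the report byte for byte.
#'
#' @param cohorts named list of analysis cells; each element is a
#'   `cohort_table`, a [cohort_spec()] (generated on the fly), or a CSV path
#'   for [read_cohort()].
#' @param strata named list of stratum definitions (`NULL` for the full
#'   sample, or a function `table -> logical rows`); default one unstratified
#'   stratum `"all"`.
#' @param screening `NULL` to skip, or a list with `candidate_prefix`
#'   (default `"brain__"`; candidates are the covariates with this prefix),
#'   and `alpha` (default 0.05). The adjustment set is all non-candidate
#'   covariates.
#' @param selection a [selection_config()].
#' @param nzv list with `freq_ratio` and `unique_pct` for
#'   [drop_near_zero_variance()].
#' @param gate_groups number of GATE groups (default 3).
#' @param pdp list with `n_points`, `trend_rho`, `trend_epsilon`.
#' @param min_stratum_n strata smaller than this are skipped with a logged
#'   reason (default 210, ten rows per site in the reference design).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(cohorts,
                            strata = list(all = NULL),
                            screening = list(candidate_prefix = "brain__",
                                             alpha = 0.05),
                            selection = selection_config(),
                            nzv = list(freq_ratio = 19, unique_pct = 0.1),
                            gate_groups = 3L,
                            pdp = list(n_points = 100L, trend_rho = 0.5,
                                       trend_epsilon = 0.05),
                            min_stratum_n = 210L) {
  if (is.null(names(cohorts)) || any(!nzchar(names(cohorts))))
    stopf("every cohort cell must be named")
  if (is.null(names(strata)) || any(!nzchar(names(strata))))
    stopf("every stratum must be named")
  structure(list(cohorts = cohorts, strata = strata, screening = screening,
                 selection = selection, nzv = nzv,
                 gate_groups = as.integer(gate_groups), pdp = pdp,
                 min_stratum_n = as.integer(min_stratum_n)),
            class = "pipeline_config")
}

resolve_cohort <- function(cell) {
  if (inherits(cell, "cohort_table")) list(table = cell, truth = NULL)
  else if (inherits(cell, "cohort_spec")) generate_cohort(cell)
  else if (is.character(cell) && length(cell) == 1L)
    list(table = read_cohort(cell), truth = NULL)
  else stopf("cohort cell must be a cohort_table, cohort_spec, or CSV path")
}

run_pipeline_cell <- function(table, config, log) {
  cell <- list()
  log("complete_case_filter", n_before = nrow(table$X))
  table <- complete_case_filter(table)
  cell$n <- nrow(table$X)
  cell$n_dropped_incomplete <- attr(table, "n_dropped_incomplete")

  nz <- drop_near_zero_variance(table, config$nzv$freq_ratio,
                                config$nzv$unique_pct)
  table <- nz$table
  cell$nzv_dropped <- nz$dropped
  log("drop_near_zero_variance", dropped = length(nz$dropped))

  covariates <- table$covariate_names
  if (!is.null(config$screening)) {
    cands <- grep(paste0("^", config$screening$candidate_prefix),
                  covariates, value = TRUE)
    if (length(cands)) {
      adj <- setdiff(covariates, cands)
      scr <- screen_features(table, cands, adjustment_set = adj,
                             alpha = config$screening$alpha %||% 0.05)
      cell$screening <- as.data.frame(scr)
      covariates <- c(adj, scr$feature[scr$selected])
      log("screen_features", candidates = length(cands),
          selected = sum(scr$selected))
    }
  }

  trace <- three_step_select(table, covariates, config$selection)
  cell$trace <- trace
  log("three_step_select", final_size = length(trace$final_covariates),
      stop_reason = trace$stop_reason)

  headline <- NULL
  if (is.na(trace$stop_reason)) {
    # Random Iteration 1 of the final model is the headline model
    headline <- trace$final_models[[1L]]
    gate <- gate_test(headline$scores, headline$forest$oob_tau,
                      n_groups = config$gate_groups)
    profile <- compare_risk_groups(headline$table, gate,
                                   trace$final_covariates)
    pdps <- partial_dependence_all(
      headline$forest, headline$table, trace$final_covariates,
      n_points = config$pdp$n_points %||% 100L,
      trend_rho = config$pdp$trend_rho %||% 0.5,
      trend_epsilon = config$pdp$trend_epsilon %||% 0.05)
    q3q1 <- gate$contrasts$q[gate$contrasts$contrast ==
                               sprintf("Q%d - Q1", config$gate_groups)]
    cell$gate <- gate
    cell$profile <- profile
    cell$pdp <- pdps
    cell$specific_pattern_failed <- (length(q3q1) && q3q1 >= 0.05) ||
      !isTRUE(gate$monotonic)
    log("gate_test", monotonic = gate$monotonic,
        q3_q1_q = if (length(q3q1)) q3q1 else NA)
  } else {
    # halted: the pattern an outcome must show for specificity is absent
    cell$specific_pattern_failed <- TRUE
  }
  cell$ate <- if (!is.null(headline)) headline$ate else
    trace$stages$first$iterations[[1L]]$ate
  cell$calibration <- if (!is.null(headline)) headline$calibration else
    trace$stages$first$iterations[[1L]]$calibration
  cell
}

#' Run the full analysis pipeline over all cells
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory; when given, writes
#'   `report.json`, `summary.md`, per-cell CSV tables and a JSON-lines run
#'   log underneath it.
#' @return Object of class `run_report`: per-(cell x stratum) results plus
#'   a specificity summary flagging outcomes whose GATE pattern failed.
#' @export
run_full_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  log_lines <- character(0)
  cells <- list()

  for (cohort_name in names(config$cohorts)) {
    resolved <- resolve_cohort(config$cohorts[[cohort_name]])
    for (stratum_name in names(config$strata)) {
      key <- paste(cohort_name, stratum_name, sep = ".")
      log <- function(stage, ...) {
        rec <- list(cell = key, stage = stage, ...)
        log_lines[[length(log_lines) + 1L]] <<-
          jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA, null = "null")
      }
      table <- resolved$table
      sel <- config$strata[[stratum_name]]
      if (!is.null(sel)) {
        rows <- which(sel(table))
        if (length(rows) < config$min_stratum_n) {
          log("skip", reason = sprintf("stratum has %d rows (< %d)",
                                       length(rows), config$min_stratum_n))
          cells[[key]] <- list(skipped = TRUE,
                               reason = "stratum below minimum size")
          next
        }
        table <- subset_cohort(table, rows = rows)
      }
      cells[[key]] <- tryCatch(
        run_pipeline_cell(table, config, log),
        error = function(e) {
          log("error", message = conditionMessage(e))
          list(failed = TRUE, reason = conditionMessage(e))
        })
      cells[[key]]$truth <- resolved$truth
    }
  }

  specificity <- data.frame(
    cell = names(cells),
    skipped = vapply(cells, function(x) isTRUE(x$skipped), NA),
    failed = vapply(cells, function(x) isTRUE(x$failed), NA),
    specific_pattern_failed = vapply(cells, function(x)
      if (is.null(x$specific_pattern_failed)) NA else x$specific_pattern_failed, NA),
    row.names = NULL)

  report <- structure(list(cells = cells, specificity = specificity,
                           config = config, log = log_lines),
                      class = "run_report")
  if (!is.null(out_dir)) write_run_report(report, out_dir)
  report
}

serialize_ate <- function(a) {
  if (is.null(a)) return(NULL)
  a[c("estimate", "se", "p_value", "n", "n_clusters")]
}
serialize_calibration <- function(cal) {
  if (is.null(cal)) return(NULL)
  cal[c("model_fit_coef", "heterogeneity_index", "se_alpha", "se_beta",
        "p_alpha", "p_beta", "degenerate")]
}

serialize_cell <- function(cell) {
  out <- list(
    skipped = isTRUE(cell$skipped), failed = isTRUE(cell$failed),
    reason = cell$reason, n = cell$n,
    ate = serialize_ate(cell$ate),
    calibration = serialize_calibration(cell$calibration),
    specific_pattern_failed = cell$specific_pattern_failed)
  if (!is.null(cell$trace)) {
    out$final_covariates <- cell$trace$final_covariates
    out$stop_reason <- cell$trace$stop_reason
    out$stage_sizes <- lapply(cell$trace$stages, function(s)
      length(s$covariates))
    out$seeds <- list(order = cell$trace$config$order_seeds,
                      forest = cell$trace$config$forest_seeds)
  }
  if (!is.null(cell$gate)) {
    out$gate <- list(
      group_ates = lapply(cell$gate$group_ates, serialize_ate),
      contrasts = cell$gate$contrasts,
      monotonic = cell$gate$monotonic)
  }
  if (!is.null(cell$profile)) out$profile <- as.data.frame(cell$profile)
  if (!is.null(cell$pdp))
    out$pdp_trends <- lapply(cell$pdp, function(p)
      list(trend = p$trend, rho = p$trend_stat))
  out
}

#' Write a run report to disk
#'
#' Writes `report.json` (the full serialized report, deterministic: no
#' timestamps), `summary.md`, `log.jsonl`, and per-cell CSVs (GATE table,
#' group profile, importance tables, PDP curves).
#'
#' @param report a `run_report`.
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_run_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  payload <- list(cells = lapply(report$cells, serialize_cell),
                  specificity = report$specificity)
  jsonlite::write_json(payload, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null", dataframe = "rows")
  writeLines(unlist(report$log), file.path(out_dir, "log.jsonl"))

  md <- c("# Run summary", "")
  for (key in names(report$cells)) {
    cell <- report$cells[[key]]
    md <- c(md, sprintf("## %s", key))
    if (isTRUE(cell$skipped) || isTRUE(cell$failed)) {
      md <- c(md, sprintf("- skipped/failed: %s", cell$reason), "")
      next
    }
    md <- c(md, sprintf("- n = %d", cell$n),
            sprintf("- ATE = %.3f (SE %.3f, p = %.3g)", cell$ate$estimate,
                    cell$ate$se, cell$ate$p_value))
    if (!is.null(cell$calibration) && !isTRUE(cell$calibration$degenerate))
      md <- c(md, sprintf("- model fit = %.3f, heterogeneity index = %.3f (p = %.3g)",
                          cell$calibration$model_fit_coef,
                          cell$calibration$heterogeneity_index,
                          cell$calibration$p_beta))
    if (!is.null(cell$trace)) {
      if (!is.na(cell$trace$stop_reason))
        md <- c(md, sprintf("- %s", cell$trace$stop_reason))
      else
        md <- c(md, sprintf("- final covariates: %s",
                            paste(cell$trace$final_covariates, collapse = ", ")))
    }
    if (!is.null(cell$gate))
      md <- c(md, sprintf("- GATE monotonic: %s", cell$gate$monotonic))
    md <- c(md, sprintf("- specific pattern failed: %s",
                        cell$specific_pattern_failed), "")

    safe <- gsub("[^A-Za-z0-9_.-]", "_", key)
    if (!is.null(cell$trace) && length(cell$trace$stages))
      utils::write.csv(selection_importance_table(cell$trace),
                       file.path(out_dir, sprintf("%s_importance.csv", safe)),
                       row.names = FALSE)
    if (!is.null(cell$gate))
      utils::write.csv(cell$gate$contrasts,
                       file.path(out_dir, sprintf("%s_gate.csv", safe)),
                       row.names = FALSE)
    if (!is.null(cell$profile))
      utils::write.csv(as.data.frame(cell$profile),
                       file.path(out_dir, sprintf("%s_profile.csv", safe)),
                       row.names = FALSE)
    if (!is.null(cell$pdp)) {
      pdp_df <- do.call(rbind, lapply(cell$pdp, function(p)
        data.frame(covariate = p$covariate, p$grid,
                   simulated_ite = p$simulated_ite, trend = p$trend)))
      utils::write.csv(pdp_df,
                       file.path(out_dir, sprintf("%s_pdp.csv", safe)),
                       row.names = FALSE)
    }
  }
  writeLines(md, file.path(out_dir, "summary.md"))
  invisible(out_dir)
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("run_report: %d cell(s)\n", length(x$cells)))
  print(x$specificity)
  invisible(x)
}
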