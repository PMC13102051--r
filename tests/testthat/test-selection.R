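fast_sel_config <- function(...) {
  selection_config(forest_params = list(num_trees = 40),
                   nuisance_params = list(num_trees = 50), ...)
}

test_that("iterations are deterministic in their seeds", {
  gen <- generate_cohort(quick_spec(n = 800, modifier_coef = 1, seed = 51))
  it1 <- run_random_iteration(gen$table, gen$table$covariate_names,
                              order_seed = 3, forest_seeds = c(11, 12, 13),
                              config = fast_sel_config())
  it2 <- run_random_iteration(gen$table, gen$table$covariate_names,
                              order_seed = 3, forest_seeds = c(11, 12, 13),
                              config = fast_sel_config())
  expect_identical(it1$retained, it2$retained)
  expect_identical(it1$importance, it2$importance)
  expect_warning(run_random_iteration(gen$table, gen$table$covariate_names,
                                      order_seed = 3,
                                      forest_seeds = c(11, 11, 13),
                                      config = fast_sel_config()),
                 "duplicate")
})

test_that("the retained set is exactly the strictly-above-mean importance set", {
  gen <- generate_cohort(quick_spec(n = 800, modifier_coef = 1, seed = 52))
  it <- run_random_iteration(gen$table, gen$table$covariate_names,
                             order_seed = 1, forest_seeds = c(11, 12, 13),
                             config = fast_sel_config())
  expect_setequal(it$retained,
                  names(it$importance)[it$importance > mean(it$importance)])
})

test_that("intersection of retained sets follows set algebra", {
  expect_identical(intersect_retained(list(c("A", "B", "C"),
                                           c("B", "C", "D"),
                                           c("B", "E"))), "B")
  expect_identical(intersect_retained(list(c("A", "B"), c("A", "B"))),
                   c("A", "B"))
  expect_identical(intersect_retained(list(c("A"), c("B"), c("C"))),
                   character(0))
})

test_that("CATE rankings are stable across covariate orderings under strong signal", {
  gen <- generate_cohort(quick_spec(n = 2000, modifier_coef = 1.5, seed = 53))
  cfg <- fast_sel_config()
  its <- lapply(1:2, function(k)
    run_random_iteration(gen$table, gen$table$covariate_names,
                         order_seed = k, forest_seeds = c(11, 12, 13),
                         config = cfg, keep_forest = TRUE))
  expect_gt(cor(its[[1]]$forest$oob_tau, its[[2]]$forest$oob_tau,
                use = "complete.obs"), 0.9)
})

test_that("a strong single modifier survives iteration-level retention", {
  spec <- cohort_spec(1500, covariate_blocks = simple_blocks(20),
                      tau_intercept = 1,
                      modifier_terms = list(list(covariate = "environment__x03",
                                                 form = "linear",
                                                 coefficient = 1.2)),
                      seed = 54)
  gen <- generate_cohort(spec)
  hits <- vapply(1:3, function(k) {
    it <- run_random_iteration(gen$table, gen$table$covariate_names,
                               order_seed = k, forest_seeds = 10 * k + 1:3,
                               config = fast_sel_config())
    "environment__x03" %in% it$retained
  }, NA)
  expect_gte(sum(hits), 2)
})

test_that("the three-step trace shrinks monotonically and keeps stage records", {
  spec <- cohort_spec(1500, covariate_blocks = simple_blocks(12),
                      tau_intercept = 1,
                      modifier_terms = list(list(covariate = "environment__x02",
                                                 form = "linear",
                                                 coefficient = 1.2)),
                      seed = 55)
  gen <- generate_cohort(spec)
  trace <- three_step_select(gen$table, config = fast_sel_config())
  sizes <- vapply(trace$stages, function(s) length(s$covariates), 0L)
  expect_true(all(diff(sizes) <= 0))
  if (is.na(trace$stop_reason)) {
    # the final set is the second-stage intersection, except that an
    # irreducible singleton set is carried forward unchanged
    if (length(trace$stages$second$intersection))
      expect_identical(trace$final_covariates,
                       trace$stages$second$intersection)
    else
      expect_identical(trace$final_covariates,
                       trace$stages$second$covariates)
    expect_length(trace$final_models, 3)
    expect_s3_class(trace$final_models[[1]]$ate, "ate_result")
    expect_s3_class(trace$final_models[[1]]$calibration, "calibration_result")
  }
})

test_that("a single-iteration config reduces to plain above-mean pruning", {
  gen <- generate_cohort(quick_spec(n = 800, modifier_coef = 1.2, seed = 56))
  cfg <- selection_config(order_seeds = 1L, forest_seeds = list(c(11, 12, 13)),
                          forest_params = list(num_trees = 40),
                          nuisance_params = list(num_trees = 50))
  trace <- three_step_select(gen$table, config = cfg)
  it <- trace$stages$first$iterations[[1]]
  expect_setequal(trace$stages$first$intersection, it$retained)
})

test_that("relabeling covariates relabels every set in the trace identically", {
  gen <- generate_cohort(quick_spec(n = 800, p = 6, modifier_coef = 1.2, seed = 57))
  cfg <- fast_sel_config()
  trace1 <- three_step_select(gen$table, config = cfg)
  relabeled <- gen$table
  map <- setNames(sprintf("environment__z%02d", 1:6), relabeled$covariate_names)
  colnames(relabeled$X) <- unname(map[relabeled$covariate_names])
  relabeled$covariate_names <- unname(map[relabeled$covariate_names])
  trace2 <- three_step_select(relabeled, config = cfg)
  expect_identical(unname(map[trace1$stages$first$intersection]),
                   trace2$stages$first$intersection)
  expect_identical(unname(map[trace1$final_covariates]),
                   trace2$final_covariates)
})

test_that("fewer than four covariates are rejected", {
  gen <- generate_cohort(quick_spec(n = 800, p = 3, seed = 58))
  expect_error(three_step_select(gen$table, config = fast_sel_config()),
               "at least 4")
})
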