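test_that("a null effect surface yields oob predictions centered at zero", {
  gen <- generate_cohort(quick_spec(n = 2000, tau0 = 0, seed = 12))
  fit <- fit_quick(gen, num_trees = 100, seed = 3)
  tau <- fit$forest$oob_tau
  expect_lt(abs(mean(tau)), 3 * sd(tau) / sqrt(length(tau)) + 0.05)
})

test_that("a strong threshold modifier is recovered in the CATE ranking", {
  spec <- cohort_spec(4000, covariate_blocks = simple_blocks(10),
                      tau_intercept = 0,
                      modifier_terms = list(list(covariate = "environment__x01",
                                                 form = "threshold",
                                                 coefficient = 2)),
                      site_sd = 0, seed = 13)
  gen <- generate_cohort(spec)
  fit <- fit_quick(gen, num_trees = 150, seed = 5)
  true_tau <- gen$truth$true_tau(gen$table$X)
  expect_gt(cor(fit$forest$oob_tau, true_tau), 0.5)
})

test_that("single-tree forests define oob predictions only off the subsample", {
  gen <- generate_cohort(quick_spec(n = 400, seed = 14))
  nuis <- fit_nuisance(gen$table, params = quick_nuisance_params, seed = 1)
  f <- fit_causal_forest(gen$table, nuis, params = list(num_trees = 1), seed = 2)
  tree <- f$trees[[1]]
  in_bag_sites <- levels(factor(gen$table$cluster))[tree$sites + 1L]
  expect_true(all(is.na(f$oob_tau[gen$table$cluster %in% in_bag_sites])))
  expect_false(anyNA(f$oob_tau[!gen$table$cluster %in% in_bag_sites]))
})

test_that("honest structure ignores estimation-half outcomes", {
  gen <- generate_cohort(quick_spec(n = 600, seed = 15))
  # oracle nuisances so a single-row outcome change only moves that row's
  # centered outcome
  nuis <- oracle_nuisance_randomized(gen$table, tau_vec = 1)
  f1 <- fit_causal_forest(gen$table, nuis, params = list(num_trees = 5), seed = 9)
  row <- f1$trees[[1]]$est_idx[1] + 1L  # 0-based in the tree record
  gen$table$Y[row] <- gen$table$Y[row] + 50
  f2 <- fit_causal_forest(gen$table, nuis, params = list(num_trees = 5), seed = 9)
  expect_identical(f1$trees[[1]]$split_var, f2$trees[[1]]$split_var)
  expect_identical(f1$trees[[1]]$threshold, f2$trees[[1]]$threshold)
  # but the leaf estimates (honest half) do change
  expect_false(identical(f1$trees[[1]]$leaf_tau, f2$trees[[1]]$leaf_tau))
})

test_that("merging forests concatenates trees and reproduces single-forest predictions", {
  gen <- generate_cohort(quick_spec(n = 600, seed = 16))
  nuis <- fit_nuisance(gen$table, params = quick_nuisance_params, seed = 1)
  f1 <- fit_causal_forest(gen$table, nuis, params = list(num_trees = 40), seed = 1)
  f2 <- fit_causal_forest(gen$table, nuis, params = list(num_trees = 40), seed = 2)
  f3 <- fit_causal_forest(gen$table, nuis, params = list(num_trees = 40), seed = 3)
  m1 <- merge_forests(list(f1))
  expect_identical(m1$oob_tau, f1$oob_tau)
  m <- merge_forests(list(f1, f2, f3))
  expect_equal(length(m$trees), 120)
  expect_identical(m$seeds, c(1L, 2L, 3L))
  expect_equal(sum(m$split_counts), sum(f1$split_counts) +
                 sum(f2$split_counts) + sum(f3$split_counts))
  # merged oob averages over all trees excluding the row's site
  pred_manual <- rowMeans(cbind(f1$oob_tau, f2$oob_tau, f3$oob_tau))
  expect_gt(cor(m$oob_tau, pred_manual, use = "complete.obs"), 0.97)
})

test_that("merging rejects forests from different tables or parameters", {
  gen1 <- generate_cohort(quick_spec(n = 400, seed = 17))
  gen2 <- generate_cohort(quick_spec(n = 400, seed = 18))
  nuis1 <- fit_nuisance(gen1$table, params = quick_nuisance_params, seed = 1)
  nuis2 <- fit_nuisance(gen2$table, params = quick_nuisance_params, seed = 1)
  fa <- fit_causal_forest(gen1$table, nuis1, params = list(num_trees = 10), seed = 1)
  fb <- fit_causal_forest(gen2$table, nuis2, params = list(num_trees = 10), seed = 2)
  fc <- fit_causal_forest(gen1$table, nuis1,
                          params = list(num_trees = 10, min_node_size = 10), seed = 2)
  expect_error(merge_forests(list(fa, fb)), "identical table")
  expect_error(merge_forests(list(fa, fc)), "identical parameters")
})

test_that("seed ensembles reduce the variance of the mean CATE", {
  gen <- generate_cohort(quick_spec(n = 600, seed = 19))
  nuis <- fit_nuisance(gen$table, params = quick_nuisance_params, seed = 1)
  single_means <- ensemble_means <- numeric(10)
  for (r in 1:10) {
    fs <- lapply(1:3, function(k)
      fit_causal_forest(gen$table, nuis, params = list(num_trees = 25),
                        seed = 100 * r + k))
    single_means[r] <- mean(fs[[1]]$oob_tau, na.rm = TRUE)
    ensemble_means[r] <- mean(merge_forests(fs)$oob_tau, na.rm = TRUE)
  }
  expect_lte(var(ensemble_means), var(single_means))
})

test_that("oob noise shrinks as the forest grows on fixed data", {
  gen <- generate_cohort(quick_spec(n = 800, tau0 = 1, seed = 20))
  nuis <- fit_nuisance(gen$table, params = quick_nuisance_params, seed = 1)
  f_small <- fit_causal_forest(gen$table, nuis, params = list(num_trees = 50), seed = 4)
  f_big <- fit_causal_forest(gen$table, nuis, params = list(num_trees = 400), seed = 4)
  expect_lt(sd(f_big$oob_tau, na.rm = TRUE), sd(f_small$oob_tau, na.rm = TRUE))
})

test_that("split counts total the internal nodes and importance normalizes", {
  gen <- generate_cohort(quick_spec(n = 600, modifier_coef = 1, seed = 21))
  fit <- fit_quick(gen, num_trees = 50, seed = 6)
  n_internal <- sum(vapply(fit$forest$trees, function(tr)
    sum(tr$split_var >= 0), 0L))
  expect_equal(sum(fit$forest$split_counts), n_internal)
  imp <- variable_importance(fit$forest)
  expect_equal(sum(imp), 1)
  expect_true(all(imp >= 0))
})

test_that("a forest that can only split on one covariate is one-hot important", {
  gen <- generate_cohort(quick_spec(n = 600, p = 2, modifier_coef = 1.5, seed = 22))
  gen$table$X[, 2] <- 0  # degenerate second covariate: unsplittable
  nuis <- oracle_nuisance_randomized(gen$table,
                                     gen$truth$true_tau(gen$table$X))
  f <- fit_causal_forest(gen$table, nuis, params = list(num_trees = 30), seed = 2)
  imp <- variable_importance(f)
  expect_equal(unname(imp), c(1, 0))
})

test_that("stump-only forests give a zero importance vector with a warning", {
  gen <- generate_cohort(quick_spec(n = 300, seed = 23))
  nuis <- fit_nuisance(gen$table, params = quick_nuisance_params, seed = 1)
  f <- fit_causal_forest(gen$table, nuis,
                         params = list(num_trees = 10, min_node_size = 100),
                         seed = 2)
  expect_warning(imp <- variable_importance(f), "no internal nodes")
  expect_true(all(imp == 0))
})

test_that("min_node_size larger than the subsample is rejected", {
  gen <- generate_cohort(quick_spec(n = 300, seed = 24))
  nuis <- fit_nuisance(gen$table, params = quick_nuisance_params, seed = 1)
  expect_error(fit_causal_forest(gen$table, nuis,
                                 params = list(num_trees = 5, min_node_size = 400),
                                 seed = 1), "min_node_size")
})

test_that("a forest round-trips through its JSON bundle", {
  gen <- generate_cohort(quick_spec(n = 400, modifier_coef = 1, seed = 25))
  nuis <- fit_nuisance(gen$table, params = quick_nuisance_params, seed = 1)
  f <- fit_causal_forest(gen$table, nuis, params = list(num_trees = 15), seed = 4)
  path <- tempfile(fileext = ".json")
  write_forest(f, path)
  back <- read_forest(path, gen$table)
  expect_equal(back$oob_tau, f$oob_tau, tolerance = 1e-12)
  expect_identical(back$split_counts, f$split_counts)
  expect_equal(predict(back), predict(f), tolerance = 1e-12)
  wrong <- gen$table
  wrong$Y <- wrong$Y + 1
  expect_error(read_forest(path, wrong), "does not match")
})
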