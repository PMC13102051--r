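test_that("invalid specs fail with the offending field named", {
  expect_error(quick_spec(n = 100, n_sites = 21), "n_participants")
  expect_error(cohort_spec(500, covariate_blocks = list(
    list(block = "imaging", count = 3, kind = "continuous"))), "block")
  expect_error(cohort_spec(500, propensity_coefs = c(nope = 1)),
               "propensity_coefs")
  expect_error(cohort_spec(500, modifier_terms = list(
    list(covariate = "environment__x01", form = "quadratic", coefficient = 1))),
    "modifier_terms")
  expect_error(cohort_spec(500, noise_sd = 0), "noise_sd")
  expect_error(cohort_spec(500, missing_rate = 1), "missing_rate")
})

test_that("no modifiers forces a constant effect surface with true_ate = tau0", {
  gen <- generate_cohort(quick_spec(n = 500, tau0 = 1.0))
  expect_equal(gen$truth$true_ate, 1.0)
  tau <- gen$truth$true_tau(gen$table$X)
  expect_true(all(tau == 1.0))
  expect_identical(gen$truth$modifier_names, character(0))
})

test_that("zero propensity coefficients give an unconfounded Bernoulli(0.5) exposure", {
  n <- 2000
  gen <- generate_cohort(quick_spec(n = n, seed = 11))
  expect_lt(abs(mean(gen$table$W) - 0.5), 3 * sqrt(0.25 / n))
})

test_that("empirical mean of a linear modifier surface matches its analytic mean", {
  # tau(x) = 1 + 0.8 x1 with x1 ~ N(0,1): E[tau] = 1, MC sd = 0.8/sqrt(n)
  n <- 4000
  gen <- generate_cohort(quick_spec(n = n, modifier_coef = 0.8, seed = 21))
  expect_lt(abs(mean(gen$truth$true_tau(gen$table$X)) - 1.0),
            3 * 0.8 / sqrt(n))
})

test_that("generated tables satisfy the scaling and design invariants", {
  spec <- cohort_spec(2100, n_sites = 21,
                      covariate_blocks = c(simple_blocks(5),
                                           simple_blocks(0, 3, 0, kind = "binary")),
                      tau_intercept = 1, seed = 5)
  gen <- generate_cohort(spec)
  tab <- gen$table
  cont <- tab$covariate_kind == "continuous"
  expect_true(all(abs(colMeans(tab$X[, cont])) < 0.1))
  expect_true(all(abs(apply(tab$X[, cont], 2, sd) - 1) < 0.1))
  expect_true(all(tab$X[, !cont] %in% c(0, 1)))
  expect_gt(sum(tab$W == 1), 0)
  expect_gt(sum(tab$W == 0), 0)
  expect_true(all(table(tab$cluster) >= 2))
  expect_equal(length(unique(tab$cluster)), 21)
  # truth ledger consistency: computed, not assumed
  expect_lt(abs(mean(gen$truth$true_tau(tab$X)) - gen$truth$true_ate), 1e-12)
})

test_that("generation is bit-identical under one seed and differs across seeds", {
  g1 <- generate_cohort(quick_spec(n = 400, seed = 9))
  g2 <- generate_cohort(quick_spec(n = 400, seed = 9))
  g3 <- generate_cohort(quick_spec(n = 400, seed = 10))
  expect_identical(g1$table$X, g2$table$X)
  expect_identical(g1$table$W, g2$table$W)
  expect_identical(g1$table$Y, g2$table$Y)
  expect_false(identical(g1$table$Y, g3$table$Y))
})

test_that("regressing Y - tau(X) W on X recovers the baseline coefficients", {
  spec <- cohort_spec(4000, covariate_blocks = simple_blocks(6),
                      baseline_coefs = c(environment__x01 = 0.7,
                                         environment__x03 = -0.4),
                      tau_intercept = 1,
                      modifier_terms = list(list(covariate = "environment__x02",
                                                 form = "saturating",
                                                 coefficient = 0.8)),
                      site_sd = 0, seed = 31)
  gen <- generate_cohort(spec)
  tau <- gen$truth$true_tau(gen$table$X)
  resid_y <- gen$table$Y - tau * gen$table$W
  fit <- summary(lm(resid_y ~ gen$table$X))
  cf <- fit$coefficients
  # coefficients on the z-scale; x1, x3 were generated ~ N(0,1) so the scale
  # factor is the sample sd, close to 1
  expect_lt(abs(cf["gen$table$Xenvironment__x01", 1] - 0.7), 3 * cf["gen$table$Xenvironment__x01", 2] + 0.02)
  expect_lt(abs(cf["gen$table$Xenvironment__x03", 1] + 0.4), 3 * cf["gen$table$Xenvironment__x03", 2] + 0.02)
})

test_that("treated fraction is monotone in a propensity coefficient", {
  # a binary covariate has nonzero mean, so E[e(X)] strictly increases in
  # its log-odds coefficient (a symmetric continuous covariate would not)
  frac <- vapply(c(-1, 0, 1), function(b) {
    spec <- cohort_spec(3000, covariate_blocks = c(
      simple_blocks(2), simple_blocks(0, 1, 0, kind = "binary")),
      propensity_coefs = c(prs__x01 = b), tau_intercept = 1, seed = 17)
    mean(generate_cohort(spec)$table$W)
  }, 0)
  expect_true(frac[1] < frac[2] && frac[2] < frac[3])
})

test_that("MCAR masking hits the expected cell count and is filterable", {
  gen <- generate_cohort(quick_spec(n = 1000, p = 20, seed = 3))
  expect_identical(apply_missingness(gen$table, 0), gen$table)
  expect_error(apply_missingness(gen$table, 1), "rate")
  gapped <- apply_missingness(gen$table, 0.05, seed = 8)
  n_cells <- length(gapped$X)
  n_masked <- sum(is.na(gapped$X))
  expect_lt(abs(n_masked - 0.05 * n_cells), 3 * sqrt(n_cells * 0.05 * 0.95))
  filtered <- complete_case_filter(gapped)
  expect_false(anyNA(filtered$X))
})

test_that("cohort CSV round-trips with covariate kinds and site labels intact", {
  spec <- cohort_spec(300, n_sites = 7,
                      covariate_blocks = c(simple_blocks(3),
                                           simple_blocks(0, 2, 0, kind = "binary")),
                      tau_intercept = 0.5, seed = 2)
  gen <- generate_cohort(spec)
  path <- tempfile(fileext = ".csv")
  write_cohort(gen$table, path, truth = gen$truth)
  back <- read_cohort(path)
  expect_equal(back$X, gen$table$X, tolerance = 1e-12)
  expect_identical(back$W, gen$table$W)
  expect_identical(back$cluster, gen$table$cluster)
  expect_identical(back$covariate_kind, gen$table$covariate_kind)
  truth_json <- jsonlite::read_json(paste0(path, ".truth.json"))
  expect_equal(truth_json$true_ate, gen$truth$true_ate, tolerance = 1e-12)
})
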