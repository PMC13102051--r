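#!/usr/bin/env Rscript
# Step 5 — specificity and stratified reruns.
#
# Reruns the identical pipeline on outcomes that should NOT carry the
# effect-heterogeneity pattern (a homogeneous-effect outcome standing in
# for the non-ADHD symptom scales) and on sex-like strata, and flags
# outcomes whose GATE pattern fails (non-significant Q3 - Q1 contrast or a
# non-monotone group ordering).

library(hteforest)

modifiers <- c("environment__x01", "prs__x01", "brain__x01")
adhd <- cohort_spec(
  4000, tau_intercept = 1,
  modifier_terms = lapply(modifiers, function(v)
    list(covariate = v, form = "linear", coefficient = 0.6)),
  propensity_coefs = c(environment__x02 = 0.4),
  baseline_coefs = c(environment__x02 = 0.5), seed = 20260102)
# same exposure, a real but homogeneous average effect: nothing to rank on
somatic <- cohort_spec(
  4000, tau_intercept = 0.6,
  propensity_coefs = c(environment__x02 = 0.4),
  baseline_coefs = c(environment__x02 = 0.5), seed = 20260103)

cfg <- pipeline_config(
  cohorts = list(adhd_1y = adhd, somatic_1y = somatic),
  strata = list(all = NULL,
                # a covariate-defined split standing in for sex strata
                grpA = function(tab) tab$X[, "environment__x10"] > 0,
                grpB = function(tab) tab$X[, "environment__x10"] <= 0),
  screening = list(candidate_prefix = "brain__", alpha = 0.05),
  selection = selection_config(forest_params = list(num_trees = 100),
                               nuisance_params = list(num_trees = 100)))

report <- run_full_pipeline(cfg, out_dir = "results/specificity")
print(report)
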