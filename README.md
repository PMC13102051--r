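# hteforest

Who is harmed most by early-life stress? In multi-site developmental
cohorts (thousands of children recruited across ~20 sites, with family
environment measures, polygenic scores and brain features as baseline
covariates), exposure to stressful life events raises ADHD-type symptom
scores on average — but the effect varies widely between children.
`hteforest` implements the complete analysis chain for estimating and
validating that variation:

* an **honest causal forest** for the conditional treatment effect
  τ(x) = E[Y(1) − Y(0) | X = x], grown on centered data with
  gradient-style splits that maximize between-child effect heterogeneity,
  cluster-aware (whole-site) subsampling, and seed-ensemble merging;
* **doubly robust inference**: per-participant AIPW scores
  Γᵢ = τ̂⁻ⁱ(Xᵢ) + (Wᵢ − ê)/(ê(1−ê)) · (Yᵢ − m̂ − (Wᵢ − ê) τ̂⁻ⁱ(Xᵢ)),
  whose mean estimates the ATE with cluster-robust standard errors;
* the **calibration test** (best-linear-predictor regression): a "model
  fit" coefficient α ≈ 1 and a "heterogeneity index" β ≈ 1 with one-sided
  β > 0 as the test for real individual differences;
* the **three-step covariate selection**: random covariate orders ×
  three-seed forest ensembles, retention of covariates with strictly
  above-mean split-frequency importance, intersection across iterations,
  repeated once, final models fitted on the surviving set — gated at each
  stage on significant ATE and heterogeneity;
* the **GATE test** (risk tertiles Q1/Q2/Q3 ranked by predicted effect,
  group ATEs from AIPW scores, Welch contrasts with BH-FDR, monotonicity
  check), **risk-group covariate profiles**, and **partial-dependence
  simulation** classifying each covariate as risk / protective / flat;
* a **synthetic multi-site cohort generator** with a full ground-truth
  ledger (true τ(·), true propensity, true ATE) so every stage above is
  validated against known truth.

## Worked example

```r
library(hteforest)

# a 4,000-child, 21-site cohort; stress raises symptoms by 1 SD on average,
# modified by one covariate in each of the three blocks
modifiers <- c("environment__x01", "prs__x01", "brain__x01")
spec <- cohort_spec(4000, tau_intercept = 1,
                    modifier_terms = lapply(modifiers, function(v)
                      list(covariate = v, form = "linear", coefficient = 0.6)),
                    propensity_coefs = c(environment__x02 = 0.4),
                    baseline_coefs  = c(environment__x02 = 0.5),
                    seed = 364)
gen <- generate_cohort(spec)
gen$truth
#> ground_truth: true ATE 0.9710; modifiers: environment__x01, prs__x01, brain__x01

cfg <- selection_config(forest_params = list(num_trees = 50),
                        nuisance_params = list(num_trees = 50))
trace <- three_step_select(gen$table, config = cfg)
trace
#> stage 'first': 55 covariates -> intersection of 6
#> stage 'second': 6 covariates -> intersection of 3
#> stage 'final': 3 covariates -> intersection of 2
#>   final set (3): brain__x01, environment__x01, prs__x01

final <- trace$final_models[[1]]
final$ate
#> ATE = 1.0214 (cluster-robust SE 0.0421, p = 3.97e-130, n = 4000, 21 sites)
final$calibration
#> calibration: model fit 0.989 (p = 2.02e-243); heterogeneity index 1.073 (p = 5.31e-107)

gate <- gate_test(final$scores, final$forest$oob_tau)
gate
#> GATE (3 groups):
#>   Q1: ATE = -0.088 (SE 0.084)
#>   Q2: ATE = 1.044 (SE 0.076)
#>   Q3: ATE = 2.107 (SE 0.087)
#>   monotonic increase: TRUE
#>   Q2 - Q1: diff 1.133 (q = 3.62e-21)
#>   Q3 - Q1: diff 2.196 (q = 6.11e-72)
#>   Q3 - Q2: diff 1.063 (q = 1.49e-18)

partial_dependence(final$forest, final$table, "environment__x01")
#> partial dependence of tau-hat on environment__x01: trend = risk (rho = 0.97, range 2.110)
```

Read: the selection procedure reduced 55 covariates to exactly the three
true modifiers; the final model's ATE (1.02 ± 0.04) matches the true
value 0.97 within about one standard error; both calibration
coefficients sit at their ideal value 1; the high-risk tertile's stress
effect (2.11) dwarfs the low-risk tertile's (−0.09, indistinguishable
from zero) with a significant Q3 − Q1 contrast; and the
partial-dependence sweep classifies the positive modifier as a risk
factor.

The `analysis/` directory holds the same workflow as numbered scripts
(simulate → screen → select → heterogeneity → specificity), each writing
its tables under `results/`.

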