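---
title: "Estimating heterogeneous effects of early-life stress with honest causal forests"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating heterogeneous effects of early-life stress with honest causal forests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hteforest)
```

## The scientific problem

Children exposed to stressful life events develop attention problems at
very different rates, and the clinically interesting question is not only
whether stress raises symptom scores *on average* but *for whom* the
effect is largest. `hteforest` implements the full analysis chain for this
question in a multi-site observational cohort: a binary exposure $W$
(e.g. lifetime exposure to indirect-threat events), a continuous symptom
outcome $Y$ (e.g. a CBCL DSM-oriented scale), a site label used as a
clustering factor, and a large block of standardized baseline covariates
$X$ — family environment, polygenic scores, and brain features.

The estimands are the average treatment effect
$\mathrm{ATE} = E[Y(1) - Y(0)]$ and the conditional (individual) effect
$\tau(x) = E[Y(1) - Y(0) \mid X = x]$, together with validation machinery:
a calibration test of the fitted effect surface, a group-ATE (GATE)
stratification test of whether predicted individual differences are real,
and partial-dependence profiling of which covariates push the effect up
(risk factors) or down (protective factors).

## The honest causal forest

`fit_causal_forest()` estimates $\tau(x)$ with an ensemble of honest
trees grown on centered data
$W^c_i = W_i - \hat e(X_i)$, $Y^c_i = Y_i - \hat m(X_i)$, where the
nuisances $\hat e(x) = P(W{=}1 \mid x)$ and $\hat m(x) = E[Y \mid x]$ come
from out-of-bag regression forests (`fit_nuisance()`, backed by `ranger`;
row $i$'s prediction never uses row $i$). Within any node the local effect
is the no-intercept least-squares slope
$\hat\tau = \sum W^c_i Y^c_i / \sum (W^c_i)^2$, and a candidate split is
scored by the standard CART criterion on the gradient pseudo-outcome
$\rho_i = W^c_i\,(Y^c_i - W^c_i\,\hat\tau_{parent})$, i.e. splits maximize
the between-child heterogeneity of the local effect estimate.

Three structural choices matter:

* **Honesty.** Each tree's subsample is split in half: structure (splits)
  is learned on one half, leaf effects are estimated on the other. A leaf
  whose estimation half is too small or has no treatment variation falls
  back to its nearest valid ancestor. Unit tests verify that perturbing an
  estimation-half outcome changes leaf values but no split thresholds.
* **Cluster-aware subsampling.** Trees subsample whole *sites*, not rows,
  so out-of-bag predictions for a row use only trees that excluded the
  row's entire site. This respects the multi-site design and keeps the
  downstream cluster-robust inference coherent.
* **Determinism.** Trees use a dedicated RNG keyed by the forest seed and
  tree index; split-gain ties resolve to the lowest covariate index and
  then the lowest threshold, so a fit is bit-reproducible for fixed seeds.

Defaults (config-exposed, reference-engine conventions): 500 trees per
seed, honesty fraction 0.5, site subsample rate 0.5, `min_node_size` 5,
`mtry` $\lceil\sqrt p\rceil + 20$ capped at $p$. `merge_forests()` pools
forests grown with different seeds into one ensemble (the seed-ensemble
step) and recomputes out-of-bag predictions over the pooled trees.

## Doubly robust estimands and inference

`aipw_scores()` computes the augmented inverse-propensity weighted score
$$\Gamma_i = \hat\tau^{-i}(X_i) +
\frac{W_i - \hat e_i}{\hat e_i (1 - \hat e_i)}
\bigl(Y_i - \hat m_i - (W_i - \hat e_i)\,\hat\tau^{-i}(X_i)\bigr),$$
whose mean is the ATE (`average_treatment_effect()`). The standard error
treats sites as sampling units: influence contributions are summed within
site before squaring. The acceptance suite verifies the classic double
robustness: the estimator stays unbiased with an oracle propensity and a
badly wrong outcome model, and vice versa.

`calibration_test()` fits the best-linear-predictor regression of
$Y - \hat m$ on $\bar\tau\,(W - \hat e)$ and
$(\hat\tau^{-i} - \bar\tau)(W - \hat e)$ without intercept. The first
coefficient ("model fit", $\alpha$) is 1 when the average prediction is
correctly scaled; the second ("heterogeneity index", $\beta$) is 1 when
differential predictions track real effect variation, and a one-sided
test of $\beta > 0$ is the heterogeneity test. Standard errors are
cluster-robust (`sandwich::vcovCL`), p-values one-sided normal for the
calibration coefficients and two-sided for the ATE. With constant
predictions $\beta$ is undefined; the result is flagged degenerate rather
than returned as a silent number. BH-FDR (`fdr_adjust()`) is applied
across an explicitly declared family — in the pipeline, the ATE /
model-fit / heterogeneity tests across all cells of one run — because the
appropriate family is a reporting decision, not a property of any single
model.

## Three-step covariate selection

`three_step_select()` implements the iterative reduction: each *random
iteration* shuffles the covariate order, fits three forests with
different seeds, merges them, and retains the covariates with
split-frequency importance strictly above the mean importance
(importance is the depth-weighted split count, weights $d^{-2}$ over the
first four levels, normalized to sum to one). The intersection of the
retained sets across iterations defines the next stage's covariates;
after two reduction rounds the final models are fitted per iteration on
the surviving set. A stage must show a significant ATE *and* a
significant heterogeneity index (both $p < .05$ by default, majority rule
across the three iterations) before the procedure continues — with no
credible individual differences there is nothing for reduction to find,
and the trace stops with a recorded reason instead of an error.

Two policies are explicit because the mathematics forces them:

* **Empty intersections** stop the procedure by default (`"stop"`), with
  an optional `"top_k"` fallback by mean importance rank.
* **Singleton sets are irreducible**: at most $k-1$ of $k$ values can
  exceed their own mean, so a single covariate can never retain itself;
  a singleton set is carried forward unchanged rather than treated as a
  failure.

Nuisances are refit at every stage on the reduced covariate set, since
the final model's covariate space differs from the initial one; the
refits are recorded in the trace seeds.

## GATE, risk-group profiles, and partial dependence

`gate_test()` ranks participants by out-of-bag predicted effect (stable
row-index tie-breaking), cuts tertiles Q1/Q2/Q3, computes each group's
ATE from its AIPW scores with cluster-robust standard errors, and
compares groups with Welch t-tests on the scores, BH-adjusted across the
three contrasts; Q3 − Q1 is the headline contrast, and a monotone
increase of group ATEs is the qualitative signature of real
heterogeneity. Group ATEs come from the AIPW scores, not raw outcome
differences, so the GATE test stays consistent with the doubly robust
ATE machinery.

`compare_risk_groups()` contrasts each final-model covariate between Q1
and Q3 (Welch for continuous, two-proportion for binary, BH across the
covariate family). `partial_dependence()` sweeps one covariate across
100 empirical quantiles at equispaced probabilities (0.5%–99.5%; a
two-point grid for binary covariates) with all other covariates held at
their median (continuous) or mode (binary), pushes the synthetic rows
through the final forest, and `classify_trend()` labels the profile by
Spearman rank correlation: *risk* if $\rho \ge 0.5$, *protective* if
$\rho \le -0.5$, *flat* otherwise — and always flat when the profile's
total movement is below $\varepsilon = 0.05$ on the standardized-outcome
scale. Both thresholds are config-exposed; the qualitative rule
(increasing = risk, decreasing = protective) is the substantive content,
the numeric cutoffs are reporting conventions.

## The synthetic cohort generator

`cohort_spec()` / `generate_cohort()` define the study conditions under
which everything above is validated, with a full truth ledger (the true
effect surface $\tau(\cdot)$, the true propensity, the true ATE computed
as the empirical mean of $\tau$ over the generated rows). The generating
model is
$$Y = \mu(X) + \tau(X)\,W + b_{site} + \varepsilon,\qquad
W \sim \mathrm{Bernoulli}\bigl(0.05 + 0.9\,\mathrm{logistic}(X\beta_e)\bigr),$$
so overlap holds by construction. Site effects are additive Gaussian
intercepts on $Y$ (not on $\tau$): the simplest structure that makes
cluster-robust standard errors consequential. Effect modifiers come in
three forms — linear $\gamma x$, threshold $\gamma\,1[x>0]$, saturating
$\gamma\tanh(x)$ — emulating the nonlinear conditioning a forest is
supposed to capture. Continuous covariates are z-scaled after generation
(the truth callables undo the scaling internally); binary covariates are
Bernoulli(0.3) and never scaled.

Covariates within a block follow a one-factor model with *declining
loadings* (default 0.9 down to 0.1), so covariate $j$ and $k$ correlate
at $\lambda_j \lambda_k$. This unevenness is deliberate and load-bearing.
Real phenotype blocks are strongly but heterogeneously intercorrelated
(bilateral brain homologues and related-trait polygenic scores correlate
around 0.6–0.8; family-environment scales overlap), and it is exactly
this structure that makes covariate selection *gradual*: strong
covariates have informative surrogates that survive the first reduction
and dilute the importance mean at the second. With independent
covariates the above-mean rule degenerates — the first intersection
collapses to the modifiers alone, after which no balanced set of three
can keep all members above its own mean. Independent blocks remain
available (`loadings = rep(0, count)`) and are used in tests that need
genuinely inert bystanders.

What the generator does **not** emulate: longitudinal correlation between
timepoints (each outcome is generated independently), missingness that is
informative (gaps are MCAR via `apply_missingness()`, matching a
complete-case analysis), measurement floor/ceiling effects of symptom
scales, and real LD-driven PRS structure. Passing recovery tests on these
cohorts therefore shows the machinery is correct and well-calibrated
under a faithful stylization of the design — not that any particular real
cohort satisfies its assumptions.

## Numerical choices and degenerate inputs

* Propensities are clipped to $[0.05, 0.95]$ everywhere (config-exposed);
  the generator also bounds the true propensity to the same range.
* Constant AIPW scores give `se = 0` and are flagged degenerate instead
  of producing a p-value.
* One cluster is an error (cluster-robust inference is undefined); the
  message suggests relabeling into pseudo-clusters when an unclustered
  analysis is genuinely wanted.
* `gate_test()` with constant predictions flags `no_ranking_signal`; the
  grouping is then arbitrary by construction.
* Cluster-robust variances carry the standard $G/(G-1)$ small-sample
  factor ($G$ = number of sites; `sandwich::vcovCL` applies its analogous
  correction in the calibration regression).
* Normal (not t) reference distributions are used for ATE and calibration
  tests; with 21 clusters the difference is immaterial next to forest
  noise, and it keeps one convention across all tests.
* AIPW bias scales with the variance of the propensity estimates, so
  nuisance forests should not be starved: the package default is 500
  trees, and in near-randomized designs larger nuisance leaves
  (`min_node_size` 50–150) reduce both bias and cost.
* Tertile splits differ in size by at most one row; ties in predicted
  effect break by row index so reruns are stable.

## Simulation sizes

The validation suite mirrors the reference design where it matters —
cohorts of $n = 4000$ across 21 sites with 55 covariates in three blocks
for recovery and power checks, 100–200 replicates for coverage and size
checks — while per-replicate forests use 50–150 trees per seed. Tree
count affects the variance of $\hat\tau$, not the validity of the AIPW /
calibration / GATE machinery around it, so the replication dimension is
spent where the statistical claims live. The package defaults (500 trees
per seed, three seeds) are what an applied analysis should use.

## Known limitations

* The forest is a faithful implementation of gradient-style honest
  splitting, not a bit-level replica of any particular engine; absolute
  importance values and CATE estimates differ from other implementations
  even at equal settings.
* Split-frequency importance inherits the usual biases (it favors
  covariates offering many distinct cut points); the three-step
  procedure's randomized orders and ensembles mitigate order effects but
  not that structural preference.
* The GATE grouping reuses the same data that trained the forest
  (out-of-bag, but not sample-split); with few sites this can be mildly
  optimistic.
* Partial dependence extrapolates into sparse covariate corners, where
  small honest leaves are noise-dominated: with the default 5-row leaves
  even an inert covariate can show a spurious profile range above the
  flat threshold. Profiling is best done on a forest with larger leaves
  (`min_node_size` around 50) and several hundred trees.
* Weak, unbalanced modifiers can be dropped at the second reduction even
  when real — the strictly-above-mean rule is aggressive by design, and
  the trace keeps every stage's importance table so such cases are
  visible.
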