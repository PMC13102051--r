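# Shared fixture builders: small, fast generating models used across tests.

simple_blocks <- function(p_env = 10L, p_prs = 0L, p_brain = 0L,
                          kind = "continuous") {
  blocks <- list()
  if (p_env > 0) blocks <- c(blocks, list(list(block = "environment",
                                               count = p_env, kind = kind)))
  if (p_prs > 0) blocks <- c(blocks, list(list(block = "prs",
                                               count = p_prs, kind = kind)))
  if (p_brain > 0) blocks <- c(blocks, list(list(block = "brain",
                                                 count = p_brain, kind = kind)))
  blocks
}

# randomized treatment, homogeneous or linearly modified effect
quick_spec <- function(n = 1000L, p = 10L, tau0 = 1, modifier_coef = 0,
                       propensity = numeric(0), site_sd = 0.25, seed = 1L,
                       n_sites = 21L, noise_sd = 1) {
  mods <- if (modifier_coef != 0)
    list(list(covariate = "environment__x01", form = "linear",
              coefficient = modifier_coef))
  else list()
  cohort_spec(n_participants = n, n_sites = n_sites,
              covariate_blocks = simple_blocks(p),
              propensity_coefs = propensity,
              baseline_coefs = c(environment__x02 = 0.5),
              tau_intercept = tau0, modifier_terms = mods,
              noise_sd = noise_sd, site_sd = site_sd, seed = seed)
}

# small forests for unit tests: enough trees for stable oob coverage
quick_forest_params <- list(num_trees = 80L)
quick_nuisance_params <- list(num_trees = 60L)

fit_quick <- function(gen, num_trees = 80L, seed = 1L) {
  nuis <- fit_nuisance(gen$table, params = quick_nuisance_params,
                       seed = derive_seed_for_tests(seed))
  forest <- fit_causal_forest(gen$table, nuis,
                              params = list(num_trees = num_trees), seed = seed)
  list(nuisance = nuis, forest = forest)
}

derive_seed_for_tests <- function(seed) as.integer(seed) + 5000L

# oracle nuisance helpers for randomized designs
oracle_nuisance_randomized <- function(table, tau_vec, mu_vec = 0) {
  n <- nrow(table$X)
  structure(list(e_hat = rep(0.5, n),
                 m_hat = rep_len(mu_vec + 0.5 * tau_vec, n), clip = 0.05),
            class = "nuisance_fits")
}
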