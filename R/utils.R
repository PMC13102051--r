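# Internal helpers shared across modules.

# Run code under a temporary RNG state so exported functions are
# deterministic in their seed argument without disturbing the caller's RNG.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
  }
  force(code)
}

# Derive a child seed from a base seed and a stream label; keeps all
# randomness traceable to one user-facing seed while decorrelating stages.
derive_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 7919 + stream * 104729) %% 2147483647L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Cluster-robust standard error of a mean of influence scores, with the
# standard G/(G-1) small-sample factor:
# se^2 = G/(G-1) * sum_c (sum_{i in c} (g_i - mean(g)))^2 / n^2.
cluster_se_mean <- function(g, cluster) {
  n <- length(g)
  psi <- g - mean(g)
  cl_sums <- tapply(psi, cluster, sum)
  G <- length(cl_sums)
  correction <- if (G > 1) G / (G - 1) else 1
  sqrt(correction * sum(cl_sums^2)) / n
}
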