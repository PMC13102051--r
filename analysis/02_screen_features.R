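#!/usr/bin/env Rscript
# Step 2 — screen brain features against the outcome.
#
# Mirrors the data-preparation stage of the workflow: brain features are
# kept as model covariates only if they are associated with the outcome
# after adjusting for the sociodemographic and polygenic blocks
# (OLS per candidate, BH-FDR across candidates at q < .05). Degenerate
# near-zero-variance covariates are removed first.

library(hteforest)
dir.create("results", showWarnings = FALSE)

tab <- read_cohort("results/data/cohort_complete.csv")

nzv <- drop_near_zero_variance(tab)
tab <- nzv$table
message(sprintf("near-zero variance: dropped %d covariate(s)%s",
                length(nzv$dropped),
                if (length(nzv$dropped))
                  paste0(" (", paste(nzv$dropped, collapse = ", "), ")")
                else ""))

cands <- grep("^brain__", tab$covariate_names, value = TRUE)
adjust <- setdiff(tab$covariate_names, cands)
scr <- screen_features(tab, cands, adjustment_set = adjust)
write.csv(as.data.frame(scr), "results/screening.csv", row.names = FALSE)
message(sprintf("screening: %d of %d brain features selected (q < .05)",
                sum(scr$selected), length(cands)))
print(head(as.data.frame(scr)[order(scr$q), ], 8))
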