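#!/usr/bin/env Rscript
# Step 1 — generate the synthetic study inputs.
#
# Builds (a) a 3-case / 6-control cfDNA cohort with the group structure the
# downstream analyses probe — cases carry a higher short-fragment proportion
# and hypermethylated panel regions — and (b) reference beta matrices
# (tumor / normal / blood) with planted differential positions, standing in
# for the external methylation arrays a panel would be designed from.

suppressPackageStartupMessages(library(cfdnaLN))

out <- "scratch/cohort"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cfg <- sim_config(seed = 20260923, n_fragments_per_sample = 10000)
cohort <- generate_cohort(cfg)
print(cohort)
write_cohort(cohort, out)

bm <- generate_beta_matrix(n_tumor = 20, n_normal = 20, n_blood = 20,
                           n_cpg = 3000, n_planted_dmp = 150, delta = 0.5,
                           seed = 20260923, n_correlated_blocks = 40)
write_beta(bm$beta, bm$info, file.path(out, "beta.tsv"))
writeLines(bm$planted, file.path(out, "planted_dmps.txt"))

cat(sprintf("wrote cohort (%d fragments) and beta matrix (%d CpGs x %d samples) to %s\n",
            nrow(cohort$fragments), nrow(bm$beta), ncol(bm$beta), out))
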