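#!/usr/bin/env Rscript
# Step 3 — design the methylation panel from the reference beta matrix.
#
# Moderated t-test (tumor vs blood) per CpG -> DMP selection both ways
# (top-5000 by |delta beta| and the delta > 0.3 / FDR < 0.05 threshold
# rule) -> 250 bp merging into DMRs -> methylation-correlated blocks
# (>= 3 CpGs, <= 100 bp adjacent spacing, adjacent Pearson r >= 0.95).

suppressPackageStartupMessages(library(cfdnaLN))

bm <- read_beta("scratch/cohort/beta.tsv")
groups <- sub("[0-9]+$", "", colnames(bm$beta))
planted <- readLines("scratch/cohort/planted_dmps.txt")

st <- moderated_t_test(bm$beta,
                       colnames(bm$beta)[groups == "tumor"],
                       colnames(bm$beta)[groups == "blood"])
cat(sprintf("moderated t-test: %d CpGs, prior df = %.2f\n",
            nrow(st), attr(st, "prior_df")))

top <- select_dmps(st, mode = "topN", top_n = 5000)
thr <- select_dmps(st, mode = "threshold", delta_min = 0.3, fdr_max = 0.05)
recall <- mean(planted %in% thr$cpg_id)
fdp <- mean(!thr$cpg_id %in% planted)
cat(sprintf("DMPs: %d (topN cap 5000), %d (threshold rule); planted recall %.2f, false-discovery proportion %.3f\n",
            nrow(top), nrow(thr), recall, fdp))

pos <- bm$info[match(thr$cpg_id, bm$info$cpg_id), ]
dmrs <- merge_dmps_to_dmrs(cbind(thr["cpg_id"], pos[c("chrom", "pos")]))
cat(sprintf("DMRs after 250 bp merging: %d (median %d CpGs per DMR)\n",
            nrow(dmrs), as.integer(median(dmrs$n_cpg))))

mcbs <- suppressMessages(build_mcbs(bm$beta, bm$info))
cat(sprintf("MCBs (>=3 CpGs, <=100 bp, r>=0.95): %d\n", nrow(mcbs)))

dir.create("results", showWarnings = FALSE)
write.table(thr, "results/dmps_selected.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write_bed(dmrs, "results/dmrs.bed")
write_bed(mcbs, "results/mcbs.bed")
cat("wrote results/dmps_selected.tsv, results/dmrs.bed, results/mcbs.bed\n")
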