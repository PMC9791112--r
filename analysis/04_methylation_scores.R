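#!/usr/bin/env Rscript
# Step 4 — region-level methylation metrics and the weighted Fisher score.
#
# Fragments are filtered (>= 3 CpGs covered, conversion rate >= 95%),
# summarised per region and sample into the methylated fragment ratio
# (MFR) and a fragment-based mean beta, and differential features are
# selected at p < 0.05 and p < 0.01 for each metric. Each sample is then
# scored against the control (non-LN-like) baseline: per-feature z-score,
# upper-tail p, combined as sum(-2 c_i log p_i) / sum(c_i) with the
# sample's fragment counts as weights.

suppressPackageStartupMessages(library(cfdnaLN))

data_dir <- "scratch/cohort"
methcalls <- read_methcalls(file.path(data_dir, "methcalls.tsv"))
regions <- read_regions_bed(file.path(data_dir, "regions.bed"))
labels <- read_labels(file.path(data_dir, "labels.tsv"))

metrics <- region_metrics(methcalls, region_ids = regions$name,
                          sample_ids = labels$sample_id)
write.table(metrics, "results/metrics.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

feature_sets <- list()
for (metric in c("mfr", "mean_beta")) for (alpha in c(0.05, 0.01)) {
  f <- suppressMessages(select_features(metrics, labels, metric = metric,
                                        alpha = alpha))
  feature_sets[[sprintf("%s_p%s", metric, alpha)]] <- f
  cat(sprintf("features (%s, p < %.2f): %d of %d regions\n",
              metric, alpha, length(f), nrow(regions)))
}

feats <- feature_sets[["mfr_p0.05"]]
scores <- suppressWarnings(score_cohort(metrics, labels, feats,
                                        value = "mfr", side = "upper"))
write.table(scores, "results/scores.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

m <- tapply(scores$score, scores$group, mean)
r <- exact_rank_sum(scores$score[scores$group == "case"],
                    scores$score[scores$group == "control"])
cat(sprintf("methylation score (MFR features): mean %.3f vs %.3f, p = %.4f (%s)\n",
            m["case"], m["control"], r$p_two_sided, r$method))
cat("wrote results/metrics.tsv, results/scores.tsv\n")
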