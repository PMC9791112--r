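#!/usr/bin/env Rscript
# Step 5 — leave-one-out cross-validated classification.
#
# The selected MFR features feed four classifiers (logistic regression,
# entropy decision tree, 30-tree random forest, RBF support-vector
# classifier) with their reference decision thresholds (0.63 / 0 / 0.23 /
# 0.24 for MFR features). Each sample is predicted by a model trained on
# the other eight; cross-model concordance is reported.

suppressPackageStartupMessages(library(cfdnaLN))

data_dir <- "scratch/cohort"
methcalls <- read_methcalls(file.path(data_dir, "methcalls.tsv"))
regions <- read_regions_bed(file.path(data_dir, "regions.bed"))
labels <- read_labels(file.path(data_dir, "labels.tsv"))

metrics <- region_metrics(methcalls, region_ids = regions$name,
                          sample_ids = labels$sample_id)
feats <- suppressMessages(select_features(metrics, labels, metric = "mfr",
                                          alpha = 0.05))
fm <- t(sapply(labels$sample_id, function(sid) {
  m <- metrics[metrics$sample_id == sid, ]
  m$mfr[match(feats, m$region_id)]
}))
colnames(fm) <- feats

specs <- list(model_spec("logistic"),
              model_spec("decision_tree"),
              model_spec("random_forest"),
              model_spec("svc", threshold = 0.24))  # MFR-feature preset
results <- lapply(specs, function(sp)
  loocv_predict(fm, labels, sp, seed = 20260923))
names(results) <- vapply(specs, `[[`, "", "kind")

for (k in names(results)) {
  r <- results[[k]]
  cat(sprintf("%-14s accuracy %d/%d  (threshold %.2f)\n", k,
              sum(r$predicted == r$true, na.rm = TRUE), nrow(r),
              attr(r, "threshold")))
}
cc <- concordance(results)
cat(sprintf("cross-model concordance: %.3f\n", cc$concordance))

dir.create("results", showWarnings = FALSE)
pred <- cc$per_sample
pred$true <- labels$group[match(pred$sample_id, labels$sample_id)]
write.table(pred, "results/loocv_predictions.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("wrote results/loocv_predictions.tsv\n")
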