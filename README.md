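# cfdnaLN

Cell-free DNA (cfDNA) fragmentomics and methylation scoring for lupus
nephritis (LN) cohorts.

Patients with systemic lupus erythematosus shed nucleosome-protected DNA
fragments into plasma; in patients with renal involvement the fragment
population skews short and targeted panel regions shift in methylation.
`cfdnaLN` implements the full analysis layer for characterizing such
cohorts from post-alignment artifacts — no raw sequencing required — and a
synthetic-data module that generates every input with known ground truth,
so the whole pipeline is testable end to end.

For a 3-case vs 6-control sequencing cohort the package provides:

* **Fragmentomics** — fragmentation index (electropherogram peaks merged
  within the instrument's 10%/20% sizing resolution), 5' end-motif
  frequencies (motif score = CCCA frequency at MAPQ ≥ 30), and the
  DELFI-style score: per-region short (100–150 bp) / long (151–220 bp)
  coverage ratio, LOESS-corrected for GC
  (`corrected = raw − fit(GC) + mean(raw)`), averaged over regions.
* **Panel design** — empirical-Bayes moderated t-tests per CpG,
  Benjamini–Hochberg FDR, DMP selection (top-5000 by |Δβ| or Δβ > 0.3 &
  FDR < 0.05), merging of DMPs < 250 bp apart into DMRs, and
  methylation-correlated blocks (runs of ≥ 3 CpGs, ≤ 100 bp apart,
  adjacent Pearson r ≥ 0.95).
* **Methylation scoring** — fragment filters (≥ 3 CpGs covered,
  conversion ≥ 95%), methylated fragment ratio (MFR) and mean beta per
  region × sample, feature selection at p < 0.05 / 0.01, per-feature
  z-scores against the non-LN baseline `z_i = (x_i − μ_i)/σ_i`, and the
  weighted Fisher methylation score

      score = Σ −2·c_i·ln(p_i) / Σ c_i

  with the sample's qualifying fragment counts `c_i` as weights.
* **Exact small-sample statistics** — Wilcoxon rank-sum by full
  enumeration of all C(9,3) = 84 rank assignments (two-sided by tail
  doubling), Spearman correlation, 2×2 chi-square.
* **Classification** — leave-one-out cross-validation with logistic
  regression, entropy decision tree, 30-tree random forest and an RBF
  SVC, thresholded at 0.63 / 0 / 0.23 / 0.2 (0.24 for MFR features), and
  cross-model concordance.

See `vignettes/cfdna-ln-methods.Rmd` for the model, the design decisions
and the generator's assumptions.

## Worked example

The `analysis/` directory is a numbered workflow over the package
(simulate → fragmentomics → panel design → methylation scores →
classification). Running it

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_fragmentomics.R
Rscript analysis/03_panel_design.R
Rscript analysis/04_methylation_scores.R
Rscript analysis/05_classification.R
```

prints, for the default synthetic cohort (seed 20260923, 10,000 fragments
per sample, cases with short-fragment weight 0.47 vs 0.43 and a +0.3
methylation shift):

```
Fragmentation profile, case vs control:
  DELFI score:         0.9711 vs 0.8275, p = 0.0238 (exact)
  motif score (CCCA):  0.0189 vs 0.0197, p = 0.5476 (exact)
  fragmentation index: 4.3 vs 4.7, p = 0.6788 (normal-approximation)

DMPs: 156 (topN cap 5000), 150 (threshold rule); planted recall 1.00, ...
DMRs after 250 bp merging: 148 (median 1 CpGs per DMR)
MCBs (>=3 CpGs, <=100 bp, r>=0.95): 40

methylation score (MFR features): mean 348.543 vs 1.910, p = 0.0238 (exact)

logistic       accuracy 9/9  (threshold 0.63)
decision_tree  accuracy 9/9  (threshold 0.00)
random_forest  accuracy 9/9  (threshold 0.23)
svc            accuracy 9/9  (threshold 0.24)
cross-model concordance: 1.000
```

Read: the planted short-fragment excess drives the DELFI score apart at
the smallest p an exact 3-vs-6 rank-sum test can produce (2/84 = 0.0238),
while the motif score and fragmentation index — generated without group
differences — stay null. The planted hypermethylation separates the
weighted Fisher scores completely (controls sit near the −2·ln(p) null
level, cases far above), the 150 planted DMPs are recovered exactly, and
all four LOOCV models classify every sample correctly and concordantly.
Summary tables land in `results/`, bulky simulated inputs in `scratch/`.

Interactive use mirrors the scripts:

```r
library(cfdnaLN)
coh <- generate_cohort(sim_config(seed = 1))
d   <- delfi_score(subset(coh$fragments, sample_id == "case01"),
                   coh$regions)
d$score
exact_rank_sum(c(10, 11, 12), c(1, 2, 3, 4, 5, 6))$p_two_sided  # 0.0238
```

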