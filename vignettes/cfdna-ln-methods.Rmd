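---
title: "Methods: cfDNA fragmentomics and methylation scoring for lupus nephritis"
author: "cfdnaLN authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cfDNA fragmentomics and methylation scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cfdnaLN)
```

## Scope and model

`cfdnaLN` implements the analysis layer of a plasma cell-free DNA (cfDNA)
characterization study in systemic lupus erythematosus, contrasting a small
group of patients with renal involvement (lupus nephritis, LN; n = 3 in the
sequencing cohort) against patients without it (non-LN, n = 6). Dying cells
release nucleosome-protected DNA fragments into plasma; both the *size
profile* of those fragments and the *methylation state* of targeted panel
regions carry signal about tissue damage. The package computes three
fragmentomic statistics, designs a methylation panel from reference beta
matrices, summarises per-fragment methylation calls into region-level
metrics, combines them into a per-sample methylation score, and classifies
samples by leave-one-out cross-validation — all on inputs that a
synthetic-data module can generate with known ground truth, so every stage
is testable without any sequencing download.

The package consumes post-alignment artifacts only: fragment tables
(coordinates, mapping quality, 5' 4-mer, GC fraction), per-fragment
methylation-call tables, electropherogram peak tables, CpG beta matrices and
BED region files. Read processing (trimming, bisulfite alignment,
deduplication) is out of scope; the only sequencing-level filter retained is
the mapping-quality floor (MAPQ >= 20 for coverage statistics, >= 30 for
end-motif counting).

## Fragmentomic statistics

**Fragmentation index.** On-chip electrophoresis reports peaks with a sizing
resolution of 10% below 600 bp and 20% above. Peaks closer than the
resolution cannot be distinguished, so sorted peak sizes are swept left to
right and a peak joins the current cluster when `(larger - smaller) /
smaller` is below the resolution of the smaller peak's band; the index is
the number of clusters. Single-linkage chaining was chosen because the
instrument cannot resolve *any* adjacent pair within resolution; the rule is
monotone — a coarser resolution can only reduce the index. Sizes below
50 bp use the 10% band; the instrument markers bound valid sizes to
35–10380 bp.

**End-motif (motif) score.** The frequency of a given 5'-terminal 4-mer
among fragments with mapping quality >= 30; the conventional summary motif
is CCCA. "Quality" is interpreted as mapping quality, the only per-read
quality field surviving alignment. Fragments whose motif contains an
ambiguous base are excluded from numerator and denominator alike, which
keeps the 256 motif frequencies summing to exactly 1 and makes the
single-motif and all-motif code paths consistent.

**DELFI-style score.** Per targeted region, the coverage ratio of short
(100–150 bp) to long (151–220 bp) fragments, GC-corrected by a LOESS
regression (span 0.75, default degree 2) of the raw ratio on the region's
mean fragment GC: `corrected = raw - fit(GC) + mean(raw)`. The sample score
is the mean corrected ratio over regions with at least one long fragment.
Open choices resolved here: fragments are assigned to regions by midpoint
containment (unambiguous at region edges); region GC is the mean of
assigned fragments' GC (a reference-genome GC is equally defensible but the
fragment tables already carry GC); the sample score averages per-region
ratios rather than pooling counts (pooled mode is available via
`aggregate = "pooled"`). With fewer than 5 usable regions, or a degenerate
(constant-GC) fit, the correction is skipped with a warning rather than
extrapolated.

## Panel design

**Moderated t-test.** Differential methylation between reference groups
(tumor vs peripheral blood) is tested per CpG with an empirical-Bayes
moderated t: pooled two-sample variances are shrunk towards a prior
estimated by moment matching of `log s^2` through the trigamma function,
and the statistic is referred to `d0 + d` degrees of freedom. This is the
standard limma model, implemented directly so that the prior df can be
pinned (`prior_df = 0` recovers the ordinary t-test, used in tests as a
limiting-case oracle); the test suite also cross-checks statistics and
p-values against `limma::eBayes` itself. When the moment match finds no
excess dispersion the prior df is infinite and the prior variance is the
arithmetic mean of the observed variances, matching the limma convention.

**DMP selection.** Either the top-5000 CpGs by |mean beta difference| among
those with FDR < 0.05 (Benjamini–Hochberg; the FDR procedure is not further
specified upstream, so the limma default was adopted), or the threshold
rule |difference| > 0.3 and FDR < 0.05. Boundary ties in top-N mode break
by larger |difference|, then smaller p, then CpG id, making output
deterministic.

**DMR merging.** DMPs closer than 250 bp (strict, on probe coordinates)
chain into one region by single linkage; regions are reported 0-based
half-open. **MCB construction** chains CpGs while the next site is within
100 bp (inclusive) of the previous *and* their beta values correlate at
Pearson r >= 0.95 across samples; runs of >= 3 sites become blocks.
Zero-variance CpGs have undefined correlation and break the chain. Both
constructions are verified against brute-force oracles (transitive-closure
components; enumeration of maximal qualifying runs).

## Methylation scoring

Fragments qualify for the methylated fragment ratio (MFR) when they cover
>= 3 CpGs in the region and have conversion rate >= 0.95 (both inclusive).
For region *i* and a sample, `c_i` is the qualifying fragment count and MFR
is the fraction of those fragments that are fully methylated
(`n_meth == n_cpg`). The fragment-based mean beta (total methylated CpGs /
total covered CpGs) is the second supported metric. Features are selected
by the moderated t-test on the chosen metric between groups at unadjusted
p < 0.05 (or 0.01).

Scoring standardises each sample's feature value against the control
(non-LN) baseline, `z_i = (x_i - mu_i) / sigma_i`. The upstream printed
formula for this z omits the test value; the standardised difference is the
only reading consistent with its stated purpose and is what is implemented.
`z_i` maps to an upper-tail normal p-value by default — the panel targets
hypermethylated regions, and disease is expected to push MFR upward — with
a two-sided option. Per sample, the weighted Fisher combination

\[ \mathrm{score} = \frac{\sum_i -2\,c_i \ln p_i}{\sum_i c_i} \]

uses the sample's own fragment counts as weights, so deeply covered
features dominate. The score is invariant to rescaling all weights, monotone
decreasing in each p, and zero when every p is 1. Exact zeros (from extreme
z) are clamped to 1e-300 before the logarithm. A control sample's own value
stays in the baseline by default — the upstream description does not state
leave-one-out, and with 6 controls the inclusive baseline is what the
printed design implies — `loo_baseline = TRUE` provides the alternative.
Features with zero baseline spread carry no usable information and are
dropped for all samples; features without qualifying fragments in a sample
are dropped for that sample only. Feature selection and scoring use the
same nine samples, replicating the original design; with n = 9 this is
circular by construction and the resulting scores are descriptive, not an
unbiased classifier evaluation — the LOOCV layer exists for that.

## Exact small-sample statistics

With 3 vs 6 samples, asymptotic rank tests are meaningless; the rank-sum
test enumerates all `choose(9, 3) = 84` rank assignments and doubles the
smaller tail (capped at 1). Complete separation gives the floor value
2/84 = 0.0238, and the interleaved configuration with U = 8 gives
76/84 = 0.9048 — the two analytically reproducible anchors of the original
cohort analysis (`scripts/acceptance.R` recomputes both). Tail doubling was
chosen over the deviation-summing convention because it reproduces those
printed values; the alternative is available via `two_sided = "deviation"`.
Ties or combined n > 12 fall back to the tie-corrected normal approximation
with continuity correction (exact tie permutation is out of scope). The
Spearman p uses the t-approximation; the chi-square test is the Pearson
2x2 form without continuity correction.

## Classification

Four models — logistic regression, decision tree (entropy splits), random
forest (30 trees), RBF support-vector classifier — are evaluated by
leave-one-out cross-validation, with held-out case probabilities thresholded
at 0.63 / 0 / 0.23 / 0.2 (0.24 for MFR features) respectively.
Hyperparameters stay at defaults; with nine samples any tuning would
overfit. Where R and Python library defaults diverge, the defaults of the
reference implementation stack were emulated: the tree grows to pure leaves
(`minsplit = 2`, `cp = 0`); the SVC uses bandwidth
`1 / (n_features * var(X))` and no internal rescaling; and logistic
regression switches to its L2-regularised (ridge) form with
`lambda = 1/n_train` when features outnumber training samples, where
maximum likelihood is degenerate. The decision-tree threshold of 0 is
degenerate as printed (any positive held-out probability yields a case
call); it is replicated as specified. Per-fold seeding makes the stochastic
models reproducible.

## Synthetic data: what it emulates, and what it does not

The generator produces cohorts under the study conditions: 3 cases vs 6
controls, fragment lengths from a two-component truncated-normal mixture
(short: mean 135 sd 10 on 100–150 bp; long: mean 166 sd 15 on 151–220 bp —
the upstream description fixes only the windows, so the component shapes
are plausible stand-ins, not estimates), group-specific short-fragment
weights defaulting to 0.47 (case) and 0.43 (control), which place the
expected short/long ratios near the reported 0.897 and 0.763 magnitudes; a
per-region GC level coupled to short-fragment coverage on the log-odds
scale (`gc_trend_strength`, default 2), planting the artifact the LOESS
correction removes; per-region methylation probabilities uniform on
0.2–0.5 for controls, shifted by `meth_shift` (default +0.3, +0.4 in the
recovery experiments) for cases; CpGs per fragment Poisson(4) truncated to
>= 1; conversion rates Beta-distributed around 0.99 so a realistic few
percent of fragments fail the 0.95 filter; and a 4-mer end-motif
distribution that is uniform except for a five-fold CCCA enrichment,
putting the motif score near the ~0.02 seen in plasma. Electropherograms
are nucleosome ladders (multiples of 166 bp) with 2% sizing jitter.

What the generator does **not** emulate: genomic sequence (one synthetic
chromosome, uniform region coverage), nucleosome-positioned cleavage and
its 10 bp periodicity, sample-to-sample depth variation, batch effects,
correlated methylation errors, or immune-complex-driven fragment loss.
Passing recovery tests therefore demonstrates that the *statistics recover
planted effects of realistic size under the stated sampling model* — not
that the pipeline's biological conclusions transfer to real plasma.

## Problem sizes and numerical choices

The test-suite simulations use cohorts of 2,000–10,000 fragments per
sample over 40–50 regions, 50-seed replications for the recovery and
GC-correction properties, and 20–30 seeds for calibration checks; the
analysis scripts use 10,000 fragments per sample and a 3,000-CpG reference
matrix — sizes at which every planted effect is comfortably detectable and
a full run stays in the minutes range on one core. Other numerical
decisions: fragment-region assignment by midpoint; MFR undefined (not 0)
at zero coverage; p-value floor 1e-300; trigamma inversion by Newton
iteration to 1e-8 relative tolerance; all generated numeric columns
rounded to 4 decimals so emitted files round-trip bit-identically.

## Known limitations

* The exact rank-sum path requires tie-free data; tied observations fall
  back to the normal approximation even at n = 9.
* The LOESS correction extrapolates poorly outside the observed GC range;
  the package refuses to correct with < 5 usable regions rather than
  guess.
* Feature selection reuses the scored samples (see above); with n = 9 a
  proper nested design is not possible and is not attempted.
* Reproducing the original cohort-level counts (e.g. DMR or MCB totals)
  requires the external array and sequencing data and is out of scope; the
  analysis scripts report the corresponding quantities on synthetic
  inputs instead.
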