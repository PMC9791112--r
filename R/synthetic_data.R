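#' Simulation configuration for a synthetic cfDNA cohort
#'
#' Bundles and validates the parameters controlling [generate_cohort()].
#' Defaults emulate the study conditions of a small methylation-sequencing
#' cohort: 3 case (lupus-nephritis-like) and 6 control samples, cases with a
#' mildly elevated short-fragment proportion and hypermethylated panel
#' regions.
#'
#' @param seed Integer seed; the same seed yields byte-identical cohorts.
#' @param n_case,n_control Number of case / control samples.
#' @param n_regions Number of targeted panel regions on the synthetic
#'   chromosome `chrS`.
#' @param n_fragments_per_sample Fragments drawn per sample; must be at
#'   least `n_regions` so every region can expect coverage.
#' @param short_frac_case,short_frac_control Weight of the short
#'   (100-150 bp) fragment-length mixture component per group. Defaults
#'   0.47 / 0.43 put the expected short/long coverage ratios near 0.89 and
#'   0.76, the magnitudes reported for LN and non-LN plasma.
#' @param meth_shift Added to the per-region methylation probability of
#'   case samples (clipped to \[0, 1\]).
#' @param conversion_rate_mean Mean of the per-fragment bisulfite/enzymatic
#'   conversion rate (Beta-distributed around this mean).
#' @param gc_trend_strength Slope (on the log-odds scale) linking a
#'   region's GC content to its short-fragment coverage bias; positive
#'   values make GC-rich regions short-fragment-rich, the artifact the
#'   LOESS GC correction removes.
#' @param len_range Overall truncation bounds of fragment lengths (bp).
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_case = 3L, n_control = 6L,
                       n_regions = 50L,
                       n_fragments_per_sample = 5000L,
                       short_frac_case = 0.47,
                       short_frac_control = 0.43,
                       meth_shift = 0.3,
                       conversion_rate_mean = 0.99,
                       gc_trend_strength = 2,
                       len_range = c(100L, 220L)) {
  cfg <- list(seed = as.integer(seed),
              n_case = as.integer(n_case), n_control = as.integer(n_control),
              n_regions = as.integer(n_regions),
              n_fragments_per_sample = as.integer(n_fragments_per_sample),
              short_frac_case = short_frac_case,
              short_frac_control = short_frac_control,
              meth_shift = meth_shift,
              conversion_rate_mean = conversion_rate_mean,
              gc_trend_strength = gc_trend_strength,
              len_range = as.integer(len_range))
  counts <- c(cfg$n_case, cfg$n_control, cfg$n_regions,
              cfg$n_fragments_per_sample)
  if (any(counts <= 0L)) stop("all counts must be positive")
  props <- c(cfg$short_frac_case, cfg$short_frac_control,
             cfg$conversion_rate_mean)
  if (any(props < 0 | props > 1)) stop("proportions must lie in [0, 1]")
  if (abs(cfg$meth_shift) > 1) stop("meth_shift must lie in [-1, 1]")
  if (cfg$n_fragments_per_sample < cfg$n_regions)
    stop("n_fragments_per_sample must be >= n_regions (zero expected ",
         "fragments per region)")
  structure(cfg, class = "sim_config")
}

## truncated-normal draw via inverse-CDF; vectorised over mean
rtnorm <- function(n, mean, sd, lo, hi) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

## fixed 5' 4-mer end-motif distribution: near-uniform with CCCA enriched
## about five-fold, so the default motif score sits near the ~0.02 seen in
## plasma
motif_universe <- function() {
  bases <- c("A", "C", "G", "T")
  g <- expand.grid(b4 = bases, b3 = bases, b2 = bases, b1 = bases,
                   stringsAsFactors = FALSE)
  sort(paste0(g$b1, g$b2, g$b3, g$b4))
}

motif_weights <- function() {
  m <- motif_universe()
  w <- rep(1, length(m))
  names(w) <- m
  w["CCCA"] <- 5
  w / sum(w)
}

#' Generate a synthetic cfDNA cohort
#'
#' Simulates per-sample fragment tables, per-fragment methylation-call
#' tables, a region (panel) file, group labels and one electropherogram per
#' sample, with the group structure the downstream analysis assumes:
#'
#' * fragment lengths come from a two-component truncated-normal mixture,
#'   short (mean 135, sd 10, truncated to 100-150 bp) with group-specific
#'   weight, long (mean 166, sd 15, truncated to 151-220 bp) otherwise;
#' * each region carries a GC level; a region's short-fragment weight is
#'   shifted on the log-odds scale by `gc_trend_strength * (GC - 0.5)`,
#'   planting the GC-coverage artifact that the DELFI LOESS correction is
#'   meant to remove;
#' * per-region methylation probability of cases equals the control
#'   probability plus `meth_shift` (clipped to \[0, 1\]); per fragment, the
#'   number of covered CpGs is Poisson(4) truncated to >= 1 and each CpG is
#'   methylated independently with the region probability.
#'
#' @param config A [sim_config()].
#' @return A list of class `synthetic_cohort` with elements `fragments`,
#'   `methcalls`, `regions`, `labels`, `peaks` (data frames) and `truth`
#'   (the per-region parameters actually used).
#' @examples
#' coh <- generate_cohort(sim_config(seed = 1, n_fragments_per_sample = 200))
#' table(coh$labels$group)
#' @export
generate_cohort <- function(config = sim_config()) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  set.seed(config$seed)
  nr <- config$n_regions

  ## panel regions on one synthetic chromosome, 1 kb wide, 1 kb apart
  region_width <- 1000L
  regions <- data.frame(
    chrom = "chrS",
    start = (seq_len(nr) - 1L) * 2L * region_width,
    end = (seq_len(nr) - 1L) * 2L * region_width + region_width,
    name = sprintf("R%03d", seq_len(nr)),
    stringsAsFactors = FALSE)

  gc_region <- round(stats::runif(nr, 0.30, 0.70), 4)
  p_meth_control <- round(stats::runif(nr, 0.20, 0.50), 4)
  p_meth_case <- pmin(1, pmax(0, p_meth_control + config$meth_shift))

  samples <- c(sprintf("case%02d", seq_len(config$n_case)),
               sprintf("ctrl%02d", seq_len(config$n_control)))
  groups <- rep(c("case", "control"), c(config$n_case, config$n_control))
  labels <- data.frame(sample_id = samples, group = groups,
                       stringsAsFactors = FALSE)

  mw <- motif_weights()
  frag_list <- vector("list", length(samples))
  meth_list <- vector("list", length(samples))
  peak_list <- vector("list", length(samples))

  for (s in seq_along(samples)) {
    n <- config$n_fragments_per_sample
    is_case <- groups[s] == "case"
    sf <- if (is_case) config$short_frac_case else config$short_frac_control

    ridx <- sample.int(nr, n, replace = TRUE)
    sf_region <- stats::plogis(stats::qlogis(pmin(pmax(sf, 1e-6), 1 - 1e-6)) +
                               config$gc_trend_strength * (gc_region - 0.5))
    short <- stats::runif(n) < sf_region[ridx]
    len <- integer(n)
    lo <- config$len_range[1]; hi <- config$len_range[2]
    len[short] <- round(rtnorm(sum(short), 135, 10, max(lo, 100), 150))
    len[!short] <- round(rtnorm(sum(!short), 166, 15, 151, min(hi, 220)))

    rstart <- regions$start[ridx]
    offset <- floor(stats::runif(n) * (region_width - len))
    start <- rstart + as.integer(offset)
    end <- start + len

    mapq <- sample(c(60L, 42L, 27L, 12L), n, replace = TRUE,
                   prob = c(0.85, 0.08, 0.04, 0.03))
    motif <- sample(names(mw), n, replace = TRUE, prob = mw)
    gc <- round(pmin(1, pmax(0,
            gc_region[ridx] +
              0.01 * config$gc_trend_strength * (166 - len) / 31 +
              stats::rnorm(n, 0, 0.02))), 4)

    fid <- sprintf("%s_f%05d", samples[s], seq_len(n))
    frag_list[[s]] <- data.frame(
      sample_id = samples[s], fragment_id = fid,
      chrom = "chrS", start = start, end = end,
      mapq = mapq, motif4 = motif, gc = gc, stringsAsFactors = FALSE)

    p_meth <- if (is_case) p_meth_case else p_meth_control
    n_cpg <- stats::qpois(stats::runif(n, stats::ppois(0, 4), 1), 4)
    n_meth <- stats::rbinom(n, n_cpg, p_meth[ridx])
    k <- 200
    conv <- round(stats::rbeta(n, config$conversion_rate_mean * k,
                               (1 - config$conversion_rate_mean) * k), 4)
    meth_list[[s]] <- data.frame(
      sample_id = samples[s], fragment_id = fid,
      region_id = regions$name[ridx],
      n_cpg = n_cpg, n_meth = n_meth, conversion_rate = conv,
      stringsAsFactors = FALSE)

    ## electropherogram: mono- to multi-nucleosomal ladder of 166 bp
    n_peaks <- sample(3:8, 1)
    ep <- generate_electropherogram(166 * seq_len(n_peaks), jitter = 0.02,
                                    seed = NULL)
    ep$sample_id <- samples[s]
    peak_list[[s]] <- ep[, c("sample_id", "size_bp", "intensity")]
  }

  structure(list(
    fragments = do.call(rbind, frag_list),
    methcalls = do.call(rbind, meth_list),
    regions = regions,
    labels = labels,
    peaks = do.call(rbind, peak_list),
    truth = list(gc_region = gc_region,
                 p_meth_control = p_meth_control,
                 p_meth_case = p_meth_case,
                 config = config)),
    class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(paste0("synthetic cfDNA cohort: %d samples (%d case / %d ",
                     "control), %d regions, %d fragments\n"),
              nrow(x$labels), sum(x$labels$group == "case"),
              sum(x$labels$group == "control"), nrow(x$regions),
              nrow(x$fragments)))
  invisible(x)
}

#' Generate a CpG-by-sample beta matrix with planted DMPs
#'
#' Emulates reference methylation arrays (tumor, adjacent-normal and
#' peripheral-blood groups) used to design a methylation panel. A chosen
#' subset of CpGs is "planted": their tumor-group mean beta is shifted by
#' `delta` relative to blood/normal; the rest share one mean across groups.
#' CpG positions are laid out on a synthetic chromosome with irregular
#' spacing so that 250 bp DMR merging and 100 bp MCB chaining both split
#' and join sites.
#'
#' @param n_tumor,n_normal,n_blood Samples per group.
#' @param n_cpg Number of CpG sites.
#' @param n_planted_dmp Number of planted differential positions
#'   (<= `n_cpg`).
#' @param delta Mean tumor-minus-blood beta difference at planted CpGs
#'   (<= 1).
#' @param seed Integer seed.
#' @param n_correlated_blocks Optionally, number of 3-CpG runs whose
#'   members share a per-sample latent beta (adjacent correlation near 1,
#'   gaps <= 100 bp), for exercising methylation-correlated-block
#'   construction. Default 0.
#' @return List with `beta` (matrix, rows = CpGs, columns = samples),
#'   `info` (cpg_id, chrom, pos), `groups` (per-column group), `planted`
#'   (planted CpG ids) and `delta`.
#' @export
generate_beta_matrix <- function(n_tumor, n_normal, n_blood, n_cpg,
                                 n_planted_dmp, delta, seed = 1L,
                                 n_correlated_blocks = 0L) {
  if (delta > 1) stop("delta must be <= 1")
  if (n_planted_dmp > n_cpg) stop("n_planted_dmp must be <= n_cpg")
  set.seed(seed)

  gaps <- sample(c(20:90, 150:400), n_cpg, replace = TRUE)
  pos <- cumsum(gaps) + 1000L
  info <- data.frame(cpg_id = sprintf("cg%05d", seq_len(n_cpg)),
                     chrom = "chrS", pos = as.integer(pos),
                     stringsAsFactors = FALSE)

  groups <- rep(c("tumor", "normal", "blood"),
                c(n_tumor, n_normal, n_blood))
  samp <- sprintf("%s%02d", groups,
                  unlist(lapply(c(n_tumor, n_normal, n_blood), seq_len)))

  base_mean <- stats::runif(n_cpg, 0.05, max(0.05, 0.95 - max(0, delta)))
  planted <- sort(sample.int(n_cpg, n_planted_dmp))
  mean_mat <- matrix(base_mean, n_cpg, length(samp))
  mean_mat[planted, groups == "tumor"] <-
    pmin(0.98, pmax(0.02, base_mean[planted] + delta))

  prec <- 50
  beta <- matrix(stats::rbeta(length(mean_mat),
                              c(mean_mat) * prec, (1 - c(mean_mat)) * prec),
                 n_cpg, length(samp))

  planted_ids <- info$cpg_id[planted]
  if (n_correlated_blocks > 0L) {
    free <- setdiff(seq_len(n_cpg - 2L), c(planted, planted - 1L, planted - 2L))
    anchors <- sort(sample(free, min(n_correlated_blocks, length(free))))
    ## keep anchors non-overlapping
    anchors <- anchors[c(TRUE, diff(anchors) >= 3)]
    for (a in anchors) {
      for (j in 1:2) {
        beta[a + j, ] <- beta[a, ] + stats::rnorm(length(samp), 0, 0.005)
        info$pos[a + j] <- info$pos[a] + j * 40L
      }
    }
    ord <- order(info$pos)
    info <- info[ord, ]
    beta <- beta[ord, , drop = FALSE]
    rownames(info) <- NULL
  }

  beta <- round(pmin(pmax(beta, 0), 1), 4)
  dimnames(beta) <- list(info$cpg_id, samp)
  list(beta = beta, info = info, groups = groups,
       planted = planted_ids, delta = delta)
}

#' Generate a synthetic electropherogram peak table
#'
#' Emulates microfluidic on-chip electrophoresis sizing: each true peak is
#' reported with at most `jitter` relative sizing error and an arbitrary
#' intensity. Peak sizes must lie within the 35-10380 bp marker range.
#'
#' @param true_peak_sizes Numeric vector of true fragment sizes (bp); may
#'   be empty.
#' @param jitter Maximum relative sizing error (proportion).
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @return Data frame with columns `size_bp`, `intensity`, sorted by size.
#' @export
generate_electropherogram <- function(true_peak_sizes, jitter = 0.02,
                                      seed = 1L) {
  if (length(true_peak_sizes) == 0L)
    return(data.frame(size_bp = numeric(0), intensity = numeric(0)))
  if (any(true_peak_sizes < 35 | true_peak_sizes > 10380))
    stop("peak sizes must lie within the 35-10380 bp marker range")
  if (!is.null(seed)) set.seed(seed)
  n <- length(true_peak_sizes)
  size <- true_peak_sizes * (1 + stats::runif(n, -jitter, jitter))
  df <- data.frame(size_bp = round(size, 2),
                   intensity = round(stats::rlnorm(n, 5, 0.5), 2))
  df[order(df$size_bp), , drop = FALSE]
}
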