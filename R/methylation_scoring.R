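#' Filter fragment methylation records
#'
#' Keeps fragments usable for the methylated-fragment-ratio metric:
#' at least `min_cpg` CpG sites covered in the region (inclusive) and a
#' conversion rate of at least `min_conversion` (inclusive).
#'
#' @param records Data frame with columns `n_cpg`, `n_meth`,
#'   `conversion_rate` (e.g. from [read_methcalls()]).
#' @param min_cpg Minimum CpGs covered (default 3).
#' @param min_conversion Minimum conversion rate (default 0.95).
#' @return The qualifying rows, original order preserved.
#' @export
filter_fragments <- function(records, min_cpg = 3L, min_conversion = 0.95) {
  records[records$n_cpg >= min_cpg &
            records$conversion_rate >= min_conversion, , drop = FALSE]
}

#' Methylated fragment ratio for one region and sample
#'
#' @param records Already-filtered records of one region in one sample.
#' @return List with `mfr` (fraction of fragments fully methylated,
#'   `n_meth == n_cpg`; `NA` when no fragment qualifies) and `c` (the
#'   fragment count, used downstream as the Fisher weight).
#' @export
region_mfr <- function(records) {
  cc <- nrow(records)
  if (cc == 0L) return(list(mfr = NA_real_, c = 0L))
  list(mfr = mean(records$n_meth == records$n_cpg), c = cc)
}

#' Mean beta value over the CpGs of a region
#'
#' @param betas Numeric vector of per-CpG beta values (NAs dropped).
#' @return Arithmetic mean, or `NA` when no CpG has a defined beta.
#' @export
region_mean_beta <- function(betas) {
  betas <- betas[!is.na(betas)]
  if (length(betas) == 0L) return(NA_real_)
  mean(betas)
}

#' Region-by-sample methylation metrics
#'
#' Applies the fragment filters, then summarises each (region, sample)
#' pair: `c` = qualifying fragment count, `mfr` = methylated fragment
#' ratio, and `mean_beta` = total methylated CpGs over total covered CpGs
#' (the fragment-based estimate of the region's average methylation
#' level). Pairs with no qualifying fragment get `c = 0` and undefined
#' metrics.
#'
#' @param methcalls Data frame with `sample_id`, `region_id`, `n_cpg`,
#'   `n_meth`, `conversion_rate`.
#' @param region_ids Region ids to tabulate (default: those present).
#' @param sample_ids Sample ids to tabulate (default: those present).
#' @inheritParams filter_fragments
#' @return Data frame: `region_id`, `sample_id`, `mean_beta`, `mfr`, `c`.
#' @export
region_metrics <- function(methcalls, region_ids = NULL, sample_ids = NULL,
                           min_cpg = 3L, min_conversion = 0.95) {
  if (is.null(region_ids)) region_ids <- sort(unique(methcalls$region_id))
  if (is.null(sample_ids)) sample_ids <- sort(unique(methcalls$sample_id))
  f <- filter_fragments(methcalls, min_cpg, min_conversion)
  rg <- factor(f$region_id, levels = region_ids)
  sm <- factor(f$sample_id, levels = sample_ids)
  cnt <- table(rg, sm)
  full <- table(rg[f$n_meth == f$n_cpg], sm[f$n_meth == f$n_cpg])
  meth <- tapply(f$n_meth, list(rg, sm), sum)
  covd <- tapply(f$n_cpg, list(rg, sm), sum)
  grid <- expand.grid(region_id = region_ids, sample_id = sample_ids,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  i <- cbind(match(grid$region_id, region_ids),
             match(grid$sample_id, sample_ids))
  grid$c <- as.integer(cnt[i])
  grid$mfr <- ifelse(grid$c > 0, as.vector(full[i]) / grid$c, NA_real_)
  grid$mean_beta <- ifelse(grid$c > 0, meth[i] / covd[i], NA_real_)
  grid[, c("region_id", "sample_id", "mean_beta", "mfr", "c")]
}

## region x sample matrix of one metric from a region_metrics data frame
metrics_matrix <- function(metrics, value = c("mfr", "mean_beta", "c")) {
  value <- match.arg(value)
  rid <- sort(unique(metrics$region_id))
  sid <- sort(unique(metrics$sample_id))
  m <- matrix(NA_real_, length(rid), length(sid),
              dimnames = list(rid, sid))
  m[cbind(match(metrics$region_id, rid), match(metrics$sample_id, sid))] <-
    metrics[[value]]
  m
}

#' Select differential methylation features between groups
#'
#' Per region, runs the moderated t-test on the chosen region-level metric
#' between the case and control samples and keeps regions with unadjusted
#' p below `alpha`. Regions whose metric is undefined in any sample are
#' excluded (reported via a message).
#'
#' @param metrics Data frame from [region_metrics()].
#' @param labels Data frame with `sample_id`, `group` (values `"case"` /
#'   `"control"`).
#' @param metric `"mfr"` (default) or `"mean_beta"`.
#' @param alpha Unadjusted p-value cutoff (0.05 or 0.01 in the reference
#'   design; any value accepted).
#' @return Character vector of selected region ids; the per-region test
#'   table is attached as attribute `"stats"`.
#' @export
select_features <- function(metrics, labels, metric = c("mfr", "mean_beta"),
                            alpha = 0.05) {
  metric <- match.arg(metric)
  m <- metrics_matrix(metrics, metric)
  m <- m[, labels$sample_id, drop = FALSE]
  complete <- stats::complete.cases(m)
  if (any(!complete))
    message(sum(!complete),
            " region(s) with undefined metric in some sample excluded")
  m <- m[complete, , drop = FALSE]
  if (nrow(m) == 0L) return(character(0))
  st <- moderated_t_test(m,
                         labels$sample_id[labels$group == "case"],
                         labels$sample_id[labels$group == "control"])
  sel <- st$cpg_id[st$p < alpha]
  attr(sel, "stats") <- st
  sel
}

#' Baseline mean and standard deviation of a feature metric
#'
#' @param metrics Data frame from [region_metrics()].
#' @param baseline_ids Sample ids forming the baseline (reference) group.
#' @param features Region ids to summarise.
#' @param value Metric column (default `"mfr"`).
#' @return Data frame: `region_id`, `mu`, `sigma`.
#' @export
baseline_stats <- function(metrics, baseline_ids, features,
                           value = "mfr") {
  if (length(baseline_ids) < 2L)
    stop("need at least 2 baseline samples")
  m <- metrics_matrix(metrics, value)[features, baseline_ids, drop = FALSE]
  data.frame(region_id = features,
             mu = rowMeans(m),
             sigma = apply(m, 1L, stats::sd),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Z-score of a test value against baseline statistics
#'
#' `z = (x - mu) / sigma`, the standardised departure of a test sample's
#' feature value from the baseline distribution.
#'
#' @param x Test-sample value(s).
#' @param mu,sigma Baseline mean and standard deviation (recycled).
#' @return Numeric z; `NA` with a warning where `sigma <= 0`.
#' @export
zscore_vs_baseline <- function(x, mu, sigma) {
  bad <- sigma <= 0
  if (any(bad, na.rm = TRUE))
    warning("feature(s) with zero baseline sigma dropped")
  ifelse(bad, NA_real_, (x - mu) / sigma)
}

#' Transform z-scores to p-values
#'
#' @param z Numeric z-score(s).
#' @param side `"upper"` (default; upper-tail standard-normal probability,
#'   appropriate for a hypermethylation panel) or `"two"` (two-sided).
#' @return Probability in (0, 1\].
#' @export
z_to_p <- function(z, side = c("upper", "two")) {
  side <- match.arg(side)
  if (side == "upper") stats::pnorm(z, lower.tail = FALSE)
  else 2 * stats::pnorm(-abs(z))
}

#' Weighted Fisher combination of feature p-values
#'
#' The sample-level methylation score
#' `sum(-2 c_i log p_i) / sum(c_i)`, where `c_i` is the qualifying
#' fragment count of feature i (so deeply covered features carry more
#' weight). Invariant to rescaling all weights and monotone decreasing in
#' every p.
#'
#' @param p Feature p-values in (0, 1\]; exact zeros are clamped to
#'   `p_floor` (with a message).
#' @param c Positive feature weights (fragment counts).
#' @param p_floor Clamp for zero p-values (default 1e-300).
#' @return Non-negative score.
#' @examples
#' methylation_score(c(0.05, 0.5), c(10, 30))  # 2.5376
#' @export
methylation_score <- function(p, c, p_floor = 1e-300) {
  if (length(p) != length(c)) stop("p and c must have equal length")
  if (length(p) == 0L) stop("no features to combine")
  if (any(c <= 0)) stop("weights must be positive")
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  if (any(p == 0)) {
    message(sum(p == 0), " zero p-value(s) clamped to ", p_floor)
    p <- pmax(p, p_floor)
  }
  sum(-2 * c * log(p)) / sum(c)
}

#' Score every sample of a cohort against the control baseline
#'
#' For each selected feature, baseline mean and sd of the MFR (or mean
#' beta) are computed from the control samples; each sample's feature
#' value is standardised (z), converted to a p-value, and the p-values are
#' combined into the weighted Fisher methylation score with the sample's
#' own fragment counts as weights. Control samples are scored too; by
#' default a control sample's own value stays in the baseline
#' (`loo_baseline = TRUE` removes it for its own score). Features with
#' zero baseline sigma are dropped for all samples; features with no
#' qualifying fragment in a given sample are dropped for that sample.
#'
#' @param metrics Data frame from [region_metrics()].
#' @param labels Data frame with `sample_id`, `group` (`"case"` /
#'   `"control"`); controls form the baseline.
#' @param features Region ids to score (e.g. from [select_features()]).
#' @param value Metric used (default `"mfr"`).
#' @param side Tail for [z_to_p()] (default `"upper"`).
#' @param loo_baseline Leave each control sample out of its own baseline.
#' @param p_floor Passed to [methylation_score()].
#' @return Data frame: `sample_id`, `group`, `score`, `n_features`; the
#'   per-sample feature detail is attached as attribute `"details"`.
#' @export
score_cohort <- function(metrics, labels, features, value = "mfr",
                         side = "upper", loo_baseline = FALSE,
                         p_floor = 1e-300) {
  if (length(features) == 0L) stop("no features to score")
  controls <- labels$sample_id[labels$group == "control"]
  if (length(controls) < 2L) stop("need at least 2 baseline samples")
  vmat <- metrics_matrix(metrics, value)[features, , drop = FALSE]
  cmat <- metrics_matrix(metrics, "c")[features, , drop = FALSE]

  base_all <- baseline_stats(metrics, controls, features, value)
  if (any(base_all$sigma == 0, na.rm = TRUE))
    warning(sum(base_all$sigma == 0, na.rm = TRUE),
            " feature(s) with zero baseline sigma dropped")

  details <- list()
  out <- labels[, c("sample_id", "group")]
  out$score <- NA_real_
  out$n_features <- 0L
  for (i in seq_len(nrow(out))) {
    sid <- out$sample_id[i]
    bs <- if (loo_baseline && out$group[i] == "control") {
      baseline_stats(metrics, setdiff(controls, sid), features, value)
    } else base_all
    x <- vmat[features, sid]
    w <- cmat[features, sid]
    ok <- !is.na(x) & w > 0 & !is.na(bs$sigma) & bs$sigma > 0
    if (!any(ok)) next
    z <- (x[ok] - bs$mu[ok]) / bs$sigma[ok]
    p <- z_to_p(z, side)
    details[[sid]] <- data.frame(region_id = features[ok], z = z, p = p,
                                 c = w[ok], stringsAsFactors = FALSE,
                                 row.names = NULL)
    out$score[i] <- suppressMessages(
      methylation_score(p, w[ok], p_floor = p_floor))
    out$n_features[i] <- sum(ok)
  }
  attr(out, "details") <- details
  out
}
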