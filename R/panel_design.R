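#' Moderated two-group t-test across CpGs
#'
#' Row-wise two-sample comparison of a beta-value matrix with
#' empirical-Bayes variance shrinkage. Per CpG the pooled residual
#' variance `s^2` (df `d = n_a + n_b - 2`) is shrunk towards a prior
#' variance `s0^2` with prior df `d0`, both estimated by moment matching
#' of `log s^2` across CpGs (mean/variance of the log-scaled chi-square,
#' inverted through the trigamma function). The moderated statistic
#'
#'   `t = (mean_a - mean_b) / sqrt(s_mod^2 (1/n_a + 1/n_b))`,
#'   `s_mod^2 = (d0 s0^2 + d s^2) / (d0 + d)`
#'
#' is referred to a t-distribution with `d0 + d` degrees of freedom;
#' `d0 = Inf` (all variances equal) falls back to the normal reference.
#' Setting `prior_df = 0` recovers the ordinary pooled-variance t-test.
#'
#' @param beta Numeric matrix, rows = CpGs (rownames used as ids),
#'   columns = samples.
#' @param group_a,group_b Column names or indices of the two groups
#'   (>= 2 samples each). The reported difference is
#'   `mean(group_a) - mean(group_b)`.
#' @param prior_df `NULL` (estimate by moment matching), `0` (ordinary
#'   t-test), or a fixed positive prior df.
#' @return Data frame with columns `cpg_id`, `delta_beta`, `t`, `p`,
#'   `fdr` (Benjamini-Hochberg), plus attributes `prior_df` and
#'   `prior_var`.
#' @export
moderated_t_test <- function(beta, group_a, group_b, prior_df = NULL) {
  beta <- as.matrix(beta)
  a <- beta[, group_a, drop = FALSE]
  b <- beta[, group_b, drop = FALSE]
  na <- ncol(a); nb <- ncol(b)
  if (na < 2L || nb < 2L) stop("need at least 2 samples per group")
  d <- na + nb - 2L
  if (d < 1L) stop("zero residual degrees of freedom")

  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- apply(a, 1L, stats::var)
  vb <- apply(b, 1L, stats::var)
  s2 <- ((na - 1L) * va + (nb - 1L) * vb) / d
  diff <- ma - mb

  if (!is.null(prior_df) && prior_df == 0) {
    d0 <- 0; s02 <- 0
  } else {
    ok <- s2 > 0
    if (!any(ok)) stop("all CpGs have zero variance")
    e <- log(s2[ok]) - digamma(d / 2) + log(d / 2)
    if (is.null(prior_df)) {
      evar <- stats::var(e) - trigamma(d / 2)
      d0 <- if (is.na(evar) || evar <= 0) Inf else 2 * trigamma_inverse(evar)
    } else {
      d0 <- prior_df
    }
    s02 <- if (is.finite(d0))
      exp(mean(e) + digamma(d0 / 2) - log(d0 / 2)) else mean(s2)
  }

  s2mod <- if (is.infinite(d0)) rep(s02, length(s2))
           else (d0 * s02 + d * s2) / (d0 + d)
  se <- sqrt(s2mod * (1 / na + 1 / nb))
  tstat <- ifelse(se > 0, diff / se, ifelse(diff == 0, 0, sign(diff) * Inf))
  df_total <- d0 + d
  p <- if (is.infinite(df_total)) 2 * stats::pnorm(-abs(tstat))
       else 2 * stats::pt(-abs(tstat), df = df_total)
  p[tstat == 0] <- 1

  ids <- rownames(beta)
  if (is.null(ids)) ids <- sprintf("cpg_%d", seq_len(nrow(beta)))
  out <- data.frame(cpg_id = ids, delta_beta = diff, t = tstat, p = p,
                    fdr = bh_fdr(p), stringsAsFactors = FALSE,
                    row.names = NULL)
  attr(out, "prior_df") <- d0
  attr(out, "prior_var") <- s02
  out
}

## Newton solve of trigamma(x) = y, as used for the prior-df moment match
trigamma_inverse <- function(y) {
  if (y <= 0) return(Inf)
  if (y > 1e7) return(1 / sqrt(y))
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, 2L)
    x <- x + dif
    if (abs(dif / x) < 1e-8) break
  }
  x
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment (wraps
#' `p.adjust(method = "BH")`).
#'
#' @param p Vector of p-values in \[0, 1\].
#' @return Adjusted values, capped at 1.
#' @export
bh_fdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Select differentially methylated positions
#'
#' Two selection modes over the output of [moderated_t_test()]:
#' `"topN"` keeps, among CpGs with `fdr < fdr_max`, the `top_n` with the
#' largest absolute mean beta difference (ties broken by larger
#' `|delta_beta|`, then smaller p, then CpG id, so output is
#' deterministic); `"threshold"` keeps all CpGs with
#' `|delta_beta| > delta_min` and `fdr < fdr_max`.
#'
#' @param stats Data frame from [moderated_t_test()].
#' @param mode `"topN"` or `"threshold"`.
#' @param top_n Number kept in topN mode (default 5000).
#' @param delta_min Minimum absolute beta difference in threshold mode
#'   (default 0.3, strict).
#' @param fdr_max FDR ceiling (default 0.05, strict).
#' @return The selected rows (possibly none), ordered by decreasing
#'   `|delta_beta|`.
#' @export
select_dmps <- function(stats, mode = c("topN", "threshold"),
                        top_n = 5000L, delta_min = 0.3, fdr_max = 0.05) {
  mode <- match.arg(mode)
  keep <- stats[stats$fdr < fdr_max, , drop = FALSE]
  if (mode == "threshold")
    keep <- keep[abs(keep$delta_beta) > delta_min, , drop = FALSE]
  ord <- order(-abs(keep$delta_beta), keep$p, keep$cpg_id)
  keep <- keep[ord, , drop = FALSE]
  if (mode == "topN") keep <- utils::head(keep, top_n)
  row.names(keep) <- NULL
  keep
}

#' Merge differentially methylated positions into regions
#'
#' Single-linkage chaining along each chromosome: consecutive DMPs whose
#' positions differ by less than `max_gap` join one region; a chain of one
#' becomes a width-1 region. Output coordinates are 0-based half-open
#' (`start = min pos - 1`, `end = max pos` for 1-based probe positions).
#'
#' @param dmps Data frame with columns `cpg_id`, `chrom`, `pos` (1-based).
#' @param max_gap Maximum merge distance in bp (default 250, strict `<`).
#' @return Data frame of regions: `name`, `chrom`, `start`, `end`,
#'   `n_cpg`, `cpg_ids` (comma-separated), `kind = "DMR"`.
#' @export
merge_dmps_to_dmrs <- function(dmps, max_gap = 250L) {
  if (nrow(dmps) == 0L)
    return(data.frame(name = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      n_cpg = integer(0), cpg_ids = character(0),
                      kind = character(0), stringsAsFactors = FALSE))
  dmps <- dmps[order(dmps$chrom, dmps$pos), , drop = FALSE]
  new_run <- c(TRUE, diff(dmps$pos) >= max_gap |
                 dmps$chrom[-1L] != dmps$chrom[-nrow(dmps)])
  run <- cumsum(new_run)
  out <- do.call(rbind, lapply(split(dmps, run), function(g) {
    data.frame(chrom = g$chrom[1L],
               start = min(g$pos) - 1L, end = max(g$pos),
               n_cpg = nrow(g), cpg_ids = paste(g$cpg_id, collapse = ","),
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  out$name <- sprintf("DMR%04d", seq_len(nrow(out)))
  out$kind <- "DMR"
  row.names(out) <- NULL
  out[, c("name", "chrom", "start", "end", "n_cpg", "cpg_ids", "kind")]
}

#' Construct methylation-correlated blocks
#'
#' Scans CpGs in genomic order and extends the current block while the
#' next site lies within `max_gap` bp of the previous one AND the Pearson
#' correlation (across samples, complete cases) of their beta values is at
#' least `min_r`. Blocks with at least `min_cpgs` sites are emitted. A
#' zero-variance CpG makes the adjacent correlation undefined and breaks
#' the chain (reported via a message).
#'
#' @param beta Matrix, rows = CpGs in the order of `info`, columns =
#'   samples (>= 3 samples).
#' @param info Data frame with `cpg_id`, `chrom`, `pos` aligned to the
#'   rows of `beta`.
#' @param max_gap Maximum adjacent-site distance in bp (default 100,
#'   inclusive).
#' @param min_r Minimum adjacent-site Pearson correlation (default 0.95,
#'   inclusive).
#' @param min_cpgs Minimum sites per block (default 3).
#' @return Data frame of regions (`name`, `chrom`, `start`, `end`,
#'   `n_cpg`, `cpg_ids`, `kind = "MCB"`), 0-based half-open.
#' @export
build_mcbs <- function(beta, info, max_gap = 100L, min_r = 0.95,
                       min_cpgs = 3L) {
  beta <- as.matrix(beta)
  stopifnot(nrow(beta) == nrow(info))
  if (ncol(beta) < 3L) stop("need >= 3 samples to compute correlations")
  ord <- order(info$chrom, info$pos)
  info <- info[ord, , drop = FALSE]
  beta <- beta[ord, , drop = FALSE]
  n <- nrow(info)
  if (n == 0L) link <- logical(0)
  else {
    link <- logical(n - 1L)
    n_zero_var <- 0L
    for (i in seq_len(n - 1L)) {
      if (info$chrom[i + 1L] != info$chrom[i]) next
      if (info$pos[i + 1L] - info$pos[i] > max_gap) next
      x <- beta[i, ]; y <- beta[i + 1L, ]
      cc <- stats::complete.cases(x, y)
      if (sum(cc) < 3L) next
      if (stats::sd(x[cc]) == 0 || stats::sd(y[cc]) == 0) {
        n_zero_var <- n_zero_var + 1L
        next
      }
      link[i] <- stats::cor(x[cc], y[cc]) >= min_r
    }
    if (n_zero_var > 0L)
      message(n_zero_var,
              " adjacent pair(s) with a zero-variance CpG broke the chain")
  }
  run <- cumsum(c(TRUE, !link))
  blocks <- split(seq_len(n), run)
  blocks <- Filter(function(ix) length(ix) >= min_cpgs, blocks)
  if (length(blocks) == 0L)
    return(data.frame(name = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      n_cpg = integer(0), cpg_ids = character(0),
                      kind = character(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, lapply(blocks, function(ix) {
    data.frame(chrom = info$chrom[ix[1L]],
               start = min(info$pos[ix]) - 1L, end = max(info$pos[ix]),
               n_cpg = length(ix),
               cpg_ids = paste(info$cpg_id[ix], collapse = ","),
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  out$name <- sprintf("MCB%04d", seq_len(nrow(out)))
  out$kind <- "MCB"
  row.names(out) <- NULL
  out[, c("name", "chrom", "start", "end", "n_cpg", "cpg_ids", "kind")]
}
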