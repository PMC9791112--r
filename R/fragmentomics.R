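#' Fragmentation index from electropherogram peaks
#'
#' Counts the number of distinct cfDNA lengths represented by
#' electropherogram peaks, honouring the sizing resolution of on-chip
#' electrophoresis: two peaks are considered the same length when their
#' relative size difference, `(larger - smaller) / smaller`, falls below
#' the instrument resolution — `res_low` (default 10%) when the smaller
#' peak lies below 600 bp, `res_high` (default 20%) otherwise. Peaks are
#' merged by a single-linkage left-to-right sweep over sorted sizes; the
#' returned index is the number of resulting clusters. Intensities are
#' ignored.
#'
#' @param peaks Data frame with a `size_bp` column (e.g. from
#'   [read_peaks()]), or a numeric vector of peak sizes.
#' @param res_low,res_high Relative sizing resolution below / at-or-above
#'   `res_break` bp.
#' @param res_break Size (bp) at which the coarser resolution takes over.
#' @return Integer cluster count (0 for no peaks).
#' @examples
#' fragmentation_index(c(100, 105, 300))  # 105 merges into 100 -> 2
#' @export
fragmentation_index <- function(peaks, res_low = 0.10, res_high = 0.20,
                                res_break = 600) {
  sizes <- if (is.data.frame(peaks)) peaks$size_bp else as.numeric(peaks)
  if (length(sizes) == 0L) return(0L)
  if (any(sizes <= 0)) stop("peak sizes must be positive")
  sizes <- sort(sizes)
  thr <- ifelse(sizes < res_break, res_low, res_high)[-length(sizes)]
  if (length(sizes) == 1L) return(1L)
  new_cluster <- diff(sizes) / sizes[-length(sizes)] >= thr
  1L + sum(new_cluster)
}

## quality filter + ambiguous-motif drop shared by the motif statistics
motif_eligible <- function(fragments, min_quality) {
  keep <- fragments$mapq >= min_quality
  motifs <- toupper(fragments$motif4[keep])
  motifs[!grepl("N", motifs, fixed = TRUE)]
}

#' Frequency of one 5' end motif
#'
#' Fraction of quality-passing fragments whose 5'-terminal 4-mer equals
#' `motif`. Fragments with mapping quality below `min_quality` are
#' discarded first, as are fragments whose motif contains an ambiguous
#' base (N) — these enter neither numerator nor denominator. The default
#' motif, CCCA, gives the conventional plasma "motif score".
#'
#' @param fragments Data frame with columns `mapq` and `motif4`.
#' @param motif A 4-character DNA string.
#' @param min_quality Minimum mapping quality (default 30).
#' @return A proportion, or `NA` (with a warning) when no fragment passes
#'   the quality filter.
#' @export
end_motif_frequency <- function(fragments, motif = "CCCA",
                                min_quality = 30L) {
  if (nchar(motif) != 4L) stop("motif must be a 4-mer")
  motifs <- motif_eligible(fragments, min_quality)
  if (length(motifs) == 0L) {
    warning("no quality-passing fragments; motif frequency undefined")
    return(NA_real_)
  }
  mean(motifs == toupper(motif))
}

#' Frequencies of all 256 end motifs
#'
#' @inheritParams end_motif_frequency
#' @return Named numeric vector over the 256 4-mers, summing to 1, or
#'   all-`NA` (with a warning) when no fragment passes the filter.
#' @export
all_motif_frequencies <- function(fragments, min_quality = 30L) {
  universe <- motif_universe()
  motifs <- motif_eligible(fragments, min_quality)
  if (length(motifs) == 0L) {
    warning("no quality-passing fragments; motif frequencies undefined")
    return(stats::setNames(rep(NA_real_, length(universe)), universe))
  }
  counts <- table(factor(motifs, levels = universe))
  stats::setNames(as.vector(counts) / length(motifs), universe)
}

## midpoint-containment assignment of fragments to non-overlapping regions;
## returns the region name per fragment (NA when the midpoint is outside
## every region)
assign_regions <- function(fragments, regions) {
  out <- rep(NA_character_, nrow(fragments))
  mid <- floor((fragments$start + fragments$end) / 2)
  for (chr in unique(regions$chrom)) {
    r <- regions[regions$chrom == chr, , drop = FALSE]
    r <- r[order(r$start), , drop = FALSE]
    sel <- which(fragments$chrom == chr)
    if (length(sel) == 0L) next
    idx <- findInterval(mid[sel], r$start)
    ok <- idx >= 1L & mid[sel] < r$end[pmax(idx, 1L)]
    out[sel[ok]] <- r$name[idx[ok]]
  }
  out
}

#' GC-corrected short/long fragment ratio (DELFI-style score)
#'
#' Per targeted region, counts short (100-150 bp) and long (151-220 bp)
#' fragments assigned by midpoint containment, forms the raw coverage
#' ratio short/long, and removes the GC trend by locally weighted
#' regression (LOESS) of the raw ratio on the region's mean fragment GC:
#' `corrected = raw - loess_fit(GC) + mean(raw)`. The sample score is the
#' mean corrected ratio over regions with at least one long fragment.
#'
#' Regions without long fragments are excluded (reported via a message).
#' With fewer than 5 usable regions the LOESS fit is unreliable and the
#' correction is skipped with a warning, leaving raw ratios.
#'
#' @param fragments Data frame of fragment records (`chrom`, `start`,
#'   `end`, `mapq`, `gc`).
#' @param regions Data frame of non-overlapping regions (`chrom`, `start`,
#'   `end`, `name`), 0-based half-open.
#' @param loess_span LOESS span (default 0.75).
#' @param min_mapq Mapping-quality floor applied before counting
#'   (default 20).
#' @param aggregate `"mean"` (default) averages corrected per-region
#'   ratios; `"pooled"` instead reports the uncorrected pooled-count ratio
#'   `sum(short) / sum(long)` over usable regions.
#' @return Object of class `delfi_result`: list with `regions` (per-region
#'   table: region, short, long, ratio, gc, corrected, usable), `score`
#'   and `corrected` (logical, whether LOESS was applied).
#' @export
delfi_score <- function(fragments, regions, loess_span = 0.75,
                        min_mapq = 20L, aggregate = c("mean", "pooled")) {
  aggregate <- match.arg(aggregate)
  frag <- fragments[fragments$mapq >= min_mapq, , drop = FALSE]
  frag$region <- assign_regions(frag, regions)
  frag <- frag[!is.na(frag$region), , drop = FALSE]
  len <- frag$end - frag$start

  tab <- data.frame(region = regions$name, stringsAsFactors = FALSE)
  cnt <- function(sel) {
    t0 <- table(factor(frag$region[sel], levels = regions$name))
    as.vector(t0)
  }
  tab$short <- cnt(len >= 100 & len <= 150)
  tab$long <- cnt(len >= 151 & len <= 220)
  gc_means <- tapply(frag$gc, factor(frag$region, levels = regions$name),
                     mean)
  tab$gc <- as.vector(gc_means)
  tab$ratio <- ifelse(tab$long > 0, tab$short / tab$long, NA_real_)
  tab$usable <- tab$long > 0
  if (any(!tab$usable))
    message(sum(!tab$usable), " region(s) without long fragments excluded")

  u <- tab$usable
  corrected_applied <- FALSE
  tab$corrected <- tab$ratio
  if (sum(u) < 5L) {
    warning("fewer than 5 usable regions; GC correction skipped, ",
            "raw ratios used")
  } else {
    fit <- tryCatch(
      stats::loess(ratio ~ gc, data = tab[u, ], span = loess_span,
                   degree = 2),
      error = function(e) NULL)
    fitted_vals <- if (is.null(fit)) NULL else stats::fitted(fit)
    if (is.null(fitted_vals) || any(!is.finite(fitted_vals))) {
      # constant or near-constant GC leaves nothing to fit
      warning("LOESS fit failed; raw ratios used")
    } else {
      tab$corrected[u] <- tab$ratio[u] - fitted_vals + mean(tab$ratio[u])
      corrected_applied <- TRUE
    }
  }

  score <- if (aggregate == "mean") mean(tab$corrected[u])
           else sum(tab$short[u]) / sum(tab$long[u])
  structure(list(regions = tab, score = score,
                 corrected = corrected_applied, aggregate = aggregate),
            class = "delfi_result")
}

#' @export
print.delfi_result <- function(x, ...) {
  cat(sprintf("DELFI score = %.4f (%s over %d usable regions%s)\n",
              x$score, x$aggregate, sum(x$regions$usable),
              if (x$corrected) ", GC-corrected" else ", uncorrected"))
  invisible(x)
}

#' Fragment-length histogram
#'
#' @param fragments Data frame with `start` and `end` columns.
#' @param bin_width Bin width in bp (default 1).
#' @return Data frame with columns `length` (bin lower bound), `count`,
#'   `proportion` (summing to 1); zero rows for no fragments.
#' @export
size_histogram <- function(fragments, bin_width = 1L) {
  len <- fragments$end - fragments$start
  if (length(len) == 0L)
    return(data.frame(length = integer(0), count = integer(0),
                      proportion = numeric(0)))
  bin <- floor(len / bin_width) * bin_width
  tb <- table(bin)
  data.frame(length = as.integer(names(tb)),
             count = as.vector(tb),
             proportion = as.vector(tb) / length(len))
}
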