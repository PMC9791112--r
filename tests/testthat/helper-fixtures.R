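# In-code fixtures shared across test files.

# minimal fragment table; motif/gc/mapq recycled to length n
make_fragments <- function(lengths, motif = "ACGT", mapq = 60L, gc = 0.5,
                           chrom = "chrS", start = 0L) {
  n <- length(lengths)
  start <- rep_len(start, n)
  data.frame(sample_id = "s1",
             fragment_id = sprintf("f%03d", seq_len(n)),
             chrom = chrom, start = start, end = start + lengths,
             mapq = rep_len(mapq, n), motif4 = rep_len(motif, n),
             gc = rep_len(gc, n), stringsAsFactors = FALSE)
}

make_methcalls <- function(n_cpg, n_meth, conversion_rate = 0.99,
                           sample_id = "s1", region_id = "R001") {
  n <- length(n_cpg)
  data.frame(sample_id = rep_len(sample_id, n),
             fragment_id = sprintf("f%03d", seq_len(n)),
             region_id = rep_len(region_id, n),
             n_cpg = n_cpg, n_meth = n_meth,
             conversion_rate = rep_len(conversion_rate, n),
             stringsAsFactors = FALSE)
}

# independent rank-sum oracle: enumerate every way of choosing which
# pooled observations came from group 1, recomputing U by pair counting
# from the raw values (no rank arithmetic shared with the implementation)
oracle_rank_sum_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  u_obs <- sum(outer(x, y, ">"))
  combos <- utils::combn(length(pooled), n1)
  u_all <- apply(combos, 2L, function(ix) {
    sum(outer(pooled[ix], pooled[-ix], ">"))
  })
  min(1, 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs)))
}

# transitive-closure oracle for DMR merging: connected components of the
# "closer than max_gap on the same chromosome, by position rank" graph
oracle_merge_components <- function(chrom, pos, max_gap) {
  ord <- order(chrom, pos)
  chrom <- chrom[ord]; pos <- pos[ord]
  n <- length(pos)
  adj <- outer(seq_len(n), seq_len(n), function(i, j)
    chrom[i] == chrom[j] & abs(pos[i] - pos[j]) < max_gap)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (adj[i, j] && comp[j] != comp[i]) {
        comp[comp == comp[j]] <- comp[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  # return the member position sets, ordered
  unname(lapply(split(pos, comp), sort))
}

# maximal-run oracle for MCB construction: every window [i, j] whose
# consecutive links all qualify, kept if maximal and long enough
oracle_mcb_runs <- function(beta, info, max_gap, min_r, min_cpgs) {
  ord <- order(info$chrom, info$pos)
  info <- info[ord, , drop = FALSE]
  beta <- beta[ord, , drop = FALSE]
  n <- nrow(info)
  qual <- function(i) {
    if (info$chrom[i + 1] != info$chrom[i]) return(FALSE)
    if (info$pos[i + 1] - info$pos[i] > max_gap) return(FALSE)
    if (sd(beta[i, ]) == 0 || sd(beta[i + 1, ]) == 0) return(FALSE)
    cor(beta[i, ], beta[i + 1, ]) >= min_r
  }
  runs <- list()
  for (i in seq_len(n)) {
    j <- i
    while (j < n && qual(j)) j <- j + 1
    maximal <- (i == 1 || !qual(i - 1)) && (j - i + 1) >= min_cpgs
    if (maximal) runs[[length(runs) + 1L]] <- info$cpg_id[i:j]
  }
  runs
}
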