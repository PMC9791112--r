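test_that("moderated t-test handles degenerate and limiting cases", {
  set.seed(1)
  beta <- matrix(rnorm(100 * 10, 0.5, 0.1), 100,
                 dimnames = list(sprintf("cg%03d", 1:100),
                                 sprintf("s%02d", 1:10)))
  ga <- sprintf("s%02d", 1:5); gb <- sprintf("s%02d", 6:10)

  # identical group values at a CpG -> t = 0, p = 1
  beta2 <- beta
  beta2[1, ] <- rep(c(0.1, 0.2, 0.3, 0.4, 0.5), 2)
  st <- moderated_t_test(beta2, ga, gb)
  expect_equal(st$t[1], 0)
  expect_equal(st$p[1], 1)
  expect_true(all(st$fdr >= st$p))

  # prior df forced to 0 recovers the ordinary pooled t-test
  st0 <- moderated_t_test(beta, ga, gb, prior_df = 0)
  ref <- apply(beta, 1, function(v)
    t.test(v[1:5], v[6:10], var.equal = TRUE)$p.value)
  expect_equal(st0$p, unname(ref), tolerance = 1e-12)

  expect_error(moderated_t_test(beta[, 1:3], "s01", c("s02", "s03")),
               "2 samples")
})

test_that("moderated t-test agrees with the limma reference", {
  skip_if_not_installed("limma")
  set.seed(2)
  n <- 400
  row_sd <- runif(n, 0.02, 0.2)  # heteroscedastic, so the prior df is finite
  beta <- matrix(rnorm(n * 12, 0.4, row_sd), n,
                 dimnames = list(sprintf("cg%04d", 1:n),
                                 sprintf("s%02d", 1:12)))
  beta[1:40, 1:6] <- beta[1:40, 1:6] + 0.3
  st <- moderated_t_test(beta, sprintf("s%02d", 1:6),
                         sprintf("s%02d", 7:12))
  design <- cbind(1, rep(c(1, 0), each = 6))
  fit <- limma::eBayes(limma::lmFit(beta, design))
  expect_true(is.finite(attr(st, "prior_df")))
  expect_equal(attr(st, "prior_df"), fit$df.prior, tolerance = 1e-6)
  expect_equal(attr(st, "prior_var"), fit$s2.prior, tolerance = 1e-6)
  expect_equal(st$t, unname(fit$t[, 2]), tolerance = 1e-8)
  expect_equal(st$p, unname(fit$p.value[, 2]), tolerance = 1e-8)
})

test_that("null p-values from the moderated t-test are uniform", {
  ks <- sapply(1:20, function(s) {
    set.seed(300 + s)
    beta <- matrix(rnorm(2000 * 8, 0.5, 0.1), 2000,
                   dimnames = list(sprintf("cg%04d", 1:2000),
                                   sprintf("s%d", 1:8)))
    st <- moderated_t_test(beta, sprintf("s%d", 1:4), sprintf("s%d", 5:8))
    suppressWarnings(ks.test(st$p, "punif")$p.value)
  })
  expect_gt(median(ks), 0.01)
})

test_that("BH adjustment matches the hand-computed step-up", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(rep(0.07, 5)), rep(0.07, 5))
  # re-adjusting never decreases any value
  set.seed(4)
  p <- runif(50)
  expect_true(all(bh_fdr(bh_fdr(p)) >= bh_fdr(p)))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("DMP selection applies thresholds and deterministic ties", {
  st <- data.frame(cpg_id = c("a", "b", "c", "d"),
                   delta_beta = c(0.5, 0.35, 0.31, 0.8),
                   t = 1, p = c(0.001, 0.1, 0.002, 0.02),
                   fdr = c(0.01, 0.2, 0.01, 0.04),
                   stringsAsFactors = FALSE)
  sel <- select_dmps(st, mode = "threshold")
  expect_setequal(sel$cpg_id, c("a", "c", "d"))  # b fails the FDR gate
  # nothing passes fdr -> empty
  st2 <- st; st2$fdr <- 0.5
  expect_equal(nrow(select_dmps(st2, mode = "threshold")), 0L)
  # topN keeps the largest |delta| among FDR-passing CpGs
  sel2 <- select_dmps(st, mode = "topN", top_n = 2)
  expect_equal(sel2$cpg_id, c("d", "a"))
  # boundary ties break by |delta|, then p, then id
  st3 <- data.frame(cpg_id = c("z", "y"), delta_beta = c(0.4, 0.4),
                    t = 1, p = c(0.01, 0.01), fdr = c(0.01, 0.01),
                    stringsAsFactors = FALSE)
  expect_equal(select_dmps(st3, mode = "topN", top_n = 1)$cpg_id, "y")
})

test_that("planted DMPs are recovered by selection", {
  recalls <- sapply(1:20, function(s) {
    bm <- generate_beta_matrix(20, 20, 20, n_cpg = 2000,
                               n_planted_dmp = 100, delta = 0.5, seed = s)
    st <- moderated_t_test(bm$beta, colnames(bm$beta)[bm$groups == "tumor"],
                           colnames(bm$beta)[bm$groups == "blood"])
    sel <- select_dmps(st, mode = "threshold")
    c(recall = mean(bm$planted %in% sel$cpg_id),
      fdp = mean(!sel$cpg_id %in% bm$planted))
  })
  expect_gte(median(recalls["recall", ]), 0.90)
  expect_lte(median(recalls["fdp", ]), 0.05)
})

test_that("DMR merging follows the worked examples", {
  mk <- function(pos) data.frame(cpg_id = sprintf("c%d", seq_along(pos)),
                                 chrom = "chr1", pos = pos,
                                 stringsAsFactors = FALSE)
  # a single DMP becomes a width-1 region in 0-based coordinates
  r1 <- merge_dmps_to_dmrs(mk(100))
  expect_equal(r1$start, 99L)
  expect_equal(r1$end, 100L)
  # gap 200 merges, gap 400 splits
  r2 <- merge_dmps_to_dmrs(mk(c(100, 300, 700)))
  expect_equal(nrow(r2), 2L)
  expect_equal(r2$n_cpg, c(2L, 1L))
  # chaining is transitive: consecutive 240 bp gaps form one region
  r3 <- merge_dmps_to_dmrs(mk(c(100, 340, 580)))
  expect_equal(nrow(r3), 1L)
  expect_equal(r3$n_cpg, 3L)
  # the threshold is strict: exactly 250 bp does not merge
  expect_equal(nrow(merge_dmps_to_dmrs(mk(c(100, 350)))), 2L)
  # chromosomes never merge
  d <- mk(c(100, 200)); d$chrom <- c("chr1", "chr2")
  expect_equal(nrow(merge_dmps_to_dmrs(d)), 2L)
})

test_that("DMR merging matches the transitive-closure oracle", {
  set.seed(6)
  for (i in 1:25) {
    n <- sample(2:50, 1)
    pos <- sort(sample(1:5000, n))
    chrom <- sample(c("chr1", "chr2"), n, TRUE)
    dmps <- data.frame(cpg_id = sprintf("c%02d", seq_len(n)),
                       chrom = chrom, pos = pos, stringsAsFactors = FALSE)
    dmrs <- merge_dmps_to_dmrs(dmps, max_gap = 250)
    got <- lapply(seq_len(nrow(dmrs)), function(k) {
      ids <- strsplit(dmrs$cpg_ids[k], ",")[[1]]
      sort(dmps$pos[match(ids, dmps$cpg_id)])
    })
    want <- oracle_merge_components(chrom, pos, 250)
    expect_setequal(got, want)
    # regions cover every DMP exactly once
    expect_equal(sum(dmrs$n_cpg), n)
    # and are disjoint per chromosome
    for (ch in unique(dmrs$chrom)) {
      r <- dmrs[dmrs$chrom == ch, ]
      r <- r[order(r$start), ]
      if (nrow(r) > 1) expect_true(all(r$start[-1] >= r$end[-nrow(r)]))
    }
  }
})

test_that("MCB construction follows the worked examples", {
  mk_beta <- function(n, r_target) {
    # build rows with controlled adjacent correlation by mixing a shared
    # latent vector with noise
    base <- rnorm(10)
    out <- matrix(NA_real_, n, 10)
    out[1, ] <- base
    for (i in 2:n) out[i, ] <- r_target[i - 1] * scale(out[i - 1, ]) +
        sqrt(1 - r_target[i - 1]^2) * rnorm(10)
    out
  }
  set.seed(9)
  info <- data.frame(cpg_id = sprintf("c%d", 1:4), chrom = "chr1",
                     pos = c(1L, 50L, 120L, 400L),
                     stringsAsFactors = FALSE)
  beta <- mk_beta(4, c(0.999, 0.999, 0.999))
  rownames(beta) <- info$cpg_id
  m <- build_mcbs(beta, info)
  expect_equal(nrow(m), 1L)
  expect_equal(m$cpg_ids, "c1,c2,c3")  # 280 bp gap to c4 breaks the chain

  # two qualifying sites are not enough
  m2 <- build_mcbs(beta[1:2, ], info[1:2, ])
  expect_equal(nrow(m2), 0L)

  # a sub-threshold correlation splits a 4-run into fragments too short
  beta3 <- mk_beta(4, c(0.999, 0.5, 0.999))
  info3 <- info; info3$pos <- c(1L, 50L, 120L, 200L)
  rownames(beta3) <- info3$cpg_id
  expect_equal(nrow(build_mcbs(beta3, info3)), 0L)

  # zero-variance CpG breaks the chain with a message
  beta4 <- mk_beta(3, c(0.999, 0.999))
  beta4[2, ] <- 0.5
  info4 <- info[1:3, ]
  rownames(beta4) <- info4$cpg_id
  expect_message(m4 <- build_mcbs(beta4, info4), "zero-variance")
  expect_equal(nrow(m4), 0L)

  expect_error(build_mcbs(beta[, 1:2], info), "3 samples")
})

test_that("MCB construction matches the maximal-run oracle", {
  set.seed(10)
  for (i in 1:20) {
    n <- sample(4:30, 1)
    info <- data.frame(cpg_id = sprintf("c%02d", seq_len(n)),
                       chrom = "chr1",
                       pos = cumsum(sample(c(30:90, 120:200), n, TRUE)),
                       stringsAsFactors = FALSE)
    # block-structured betas: shared latent per run of ~4 with noise
    latent <- rnorm(12)
    beta <- t(sapply(seq_len(n), function(j) {
      if (runif(1) < 0.5) latent + rnorm(12, 0, 0.02)
      else rnorm(12)
    }))
    rownames(beta) <- info$cpg_id
    got <- suppressMessages(build_mcbs(beta, info))
    got_sets <- if (nrow(got)) strsplit(got$cpg_ids, ",") else list()
    want <- oracle_mcb_runs(beta, info, max_gap = 100, min_r = 0.95,
                            min_cpgs = 3)
    expect_setequal(got_sets, want)
  }
})
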