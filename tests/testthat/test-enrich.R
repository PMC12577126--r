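test_that("query equal to universe gives fold exactly 1", {
  u <- gr("chr1", seq(1000, 20000, by = 1000),
          seq(1000, 20000, by = 1000) + 300)
  tes <- gr("chr1", c(1100, 5100), c(1200, 5200), te_class = "DNA/hAT")
  r <- te_enrichment(u, u, tes, n_perm = 100, seed = 1L)
  expect_equal(r$fold, 1)
  expect_true(all(r$null == r$observed))
})

test_that("an empty TE annotation yields zero overlap and p = 1", {
  u <- gr("chr1", seq(1000, 20000, by = 1000),
          seq(1000, 20000, by = 1000) + 300)
  r <- te_enrichment(u[1:5], u, gr("chr1", 1, 2)[0], n_perm = 100,
                     seed = 1L)
  expect_equal(r$observed, 0)
  expect_equal(r$p, 1)
  expect_error(te_enrichment(u, u[1:3], u, n_perm = 100), "universe")
})

test_that("injected TE enrichment of the query is recovered", {
  set.seed(12)
  n <- 400
  start <- seq(1e4, by = 5e3, length.out = n)
  u <- gr("chr1", start, start + round(runif(n, 200, 600)))
  # TEs placed on a random 20% of universe regions
  on <- sample(n, 80)
  tes <- gr("chr1", start[on] + 10, start[on] + 50, te_class = "DNA/hAT")
  # query: 60 regions, 2x odds of TE overlap
  w <- ifelse(seq_len(n) %in% on, 2, 1)
  q_idx <- sample(n, 60, prob = w)
  r <- te_enrichment(u[q_idx], u, tes, n_perm = 500, seed = 3L)
  expect_gt(r$fold, 1.2)
  expect_lt(r$fold, 3)
})

test_that("SV-promoter enrichment is calibrated and detects placement bias", {
  set.seed(9)
  n <- 300
  start <- seq(1e4, by = 4e3, length.out = n)
  prom <- gr("chr1", start, start + 999,
             gene_id = sprintf("g%03d", 1:n))
  has_del <- rbinom(n, 1, 0.15) == 1
  dels <- gr("chr1", start[has_del] + 100, start[has_del] + 200)
  # null: ASE genes chosen independently of deletions
  ids <- prom$gene_id
  ps <- vapply(1:50, function(i) {
    set.seed(200 + i)
    sv_promoter_enrichment(sample(ids, 40), ids, prom, dels,
                           n_perm = 199, seed = i)$p
  }, 0)
  expect_gt(mean(ps > 0.05), 0.85)
  # enriched: ASE genes preferentially deletion-bearing
  set.seed(77)
  ase <- c(sample(ids[has_del], 25), sample(ids[!has_del], 15))
  r <- sv_promoter_enrichment(ase, ids, prom, dels, n_perm = 499,
                              seed = 5L)
  expect_lt(r$p, 0.01)
  expect_gt(r$fold, 2)
})

test_that("trait-SNP enrichment recovers arithmetic on a fixed layout", {
  # all significant SNPs inside ACRs, background fraction 2%
  n_bg <- 2000
  gwas <- data.frame(
    chrom = "chr1",
    pos = c(seq(1e6, 1e6 + 49, by = 1), round(runif(n_bg, 1, 9e5))),
    p = c(rep(1e-10, 50), runif(n_bg, 0.1, 1)),
    maf = 0.25)
  acr_bg <- round(runif(40, 1, 9e5))
  acrs <- gr("chr1", c(1e6, acr_bg), c(1e6 + 100, acr_bg + 400))
  genes <- gr("chr1", seq(1e5, 9e5, by = 1e5),
              seq(1e5, 9e5, by = 1e5) + 5000)
  r <- trait_snp_acr_enrichment(gwas, acrs, genes, n_perm = 300,
                                seed = 2L, maf_bins = 1, dist_bins = 1)
  expect_equal(r$observed, 1)
  bg_frac <- mean(r$null)
  expect_equal(r$fold, 1 / bg_frac)
  expect_lt(r$p, 0.01)
})

test_that("no significant SNPs gives a typed no-query result", {
  gwas <- data.frame(chrom = "chr1", pos = 1:100 * 1000,
                     p = runif(100, 0.5, 1), maf = 0.2)
  acrs <- gr("chr1", 5000, 6000)
  genes <- gr("chr1", 50000, 60000)
  r <- trait_snp_acr_enrichment(gwas, acrs, genes, n_perm = 100, seed = 1L)
  expect_true(r$no_query)
  expect_true(is.na(r$fold))
  expect_output(print(r), "no query")
})

test_that("LD blocks follow dosage correlation", {
  set.seed(6)
  n_acc <- 154
  pos <- data.frame(snp_id = sprintf("s%02d", 1:20), chrom = "chr1",
                    pos = 1:20 * 1e4)
  lead <- rbinom(n_acc, 2, 0.4)
  G <- rbind(
    matrix(rep(lead, 5), nrow = 5, byrow = TRUE),      # perfect LD
    matrix(rbinom(15 * n_acc, 2, 0.4), nrow = 15))
  rownames(G) <- pos$snp_id
  bl <- ld_blocks(G, pos, "s01")
  expect_equal(bl$start, 1e4)
  expect_equal(bl$end, 5e4)
  expect_equal(bl$n_snps, 5)
  # monomorphic lead is reported as undefined
  G2 <- G; G2[1, ] <- 1
  expect_true(is.na(ld_blocks(G2, pos, "s01")$start))
  # independent dosages: mean r2 near 1/(n-1)
  r2 <- vapply(6:20, function(j) cor(lead, G[j, ])^2, 0)
  expect_lt(abs(mean(r2) - 1 / (n_acc - 1)), 0.015)
})

test_that("SV genotyping from allele frequency follows the bands", {
  expect_equal(genotype_sv_from_af(c(0.5, 0.96, 0.8, 0.1, 0.25, NA)),
               c("+/SV", "SV/SV", "no-call", "+/+", "+/SV", "no-call"))
  expect_error(genotype_sv_from_af(1.2), "\\[0, 1\\]")
})

test_that("length-matched resampling preserves total queried length", {
  set.seed(14)
  uw <- round(rlnorm(500, log(400), 0.6))
  qw <- sample(uw, 80)
  for (i in 1:5) {
    idx <- haplocis:::sample_length_matched(qw, uw)
    expect_lt(abs(sum(uw[idx]) - sum(qw)) / sum(qw), 0.05)
    expect_false(anyDuplicated(idx) > 0)
  }
})
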