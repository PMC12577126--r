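test_that("Hedges g matches the closed form and is antisymmetric", {
  expect_equal(hedges_g(c(2, 3, 4), c(0, 1, 2)), 1.6, tolerance = 1e-12)
  expect_equal(hedges_g(c(1, 2, 3), c(1, 2, 3)), 0)
  a <- rnorm(20); b <- rnorm(15)
  expect_equal(hedges_g(a, b), -hedges_g(b, a), tolerance = 1e-12)
  expect_true(is.na(hedges_g(c(1, 1), c(1, 1))))  # zero pooled variance
  expect_error(hedges_g(1, c(1, 2)), "at least 2")
})

test_that("deletion:gene pairs respect blocks, promoters and re-keying", {
  blocks <- data.frame(block_id = c(1, 2), chrom = "chr1",
                       start = c(1, 50000), end = c(40000, 90000))
  genes <- gr("chr1", c(10001, 60001), c(12000, 62000), strand = "+",
              gene_id = c("gA", "gB"),
              maternal_sum = c(90, 10), paternal_sum = c(10, 90))
  dels <- gr("chr1", c(9500, 30000), c(9600, 30100),
             sv_id = c("svP", "svFar"),
             ancestry = c("maternal", "paternal"))
  pairs <- pair_deletion_gene(genes, dels, blocks)
  # gB's nearest deletion is in block 1, gB in block 2: dropped
  expect_equal(pairs$gene_id, "gA")
  expect_true(pairs$sv_in_promoter)
  # maternal deletion: numerator is the maternal count
  expect_equal(pairs$del_ratio, log2(91 / 11), tolerance = 1e-12)

  # flip deletion haplotype: ratio re-keys to the paternal count
  dels$ancestry <- c("paternal", "paternal")
  pairs2 <- pair_deletion_gene(genes, dels, blocks)
  expect_equal(pairs2$del_ratio, log2(11 / 91), tolerance = 1e-12)
})

test_that("global maternal/paternal swap leaves deletion-keyed ratios fixed", {
  blocks <- data.frame(block_id = 1, chrom = "chr1", start = 1, end = 1e5)
  genes <- gr("chr1", 10001, 12000, strand = "+", gene_id = "g",
              maternal_sum = 70, paternal_sum = 30)
  dels <- gr("chr1", 9500, 9600, sv_id = "s", ancestry = "maternal")
  p1 <- pair_deletion_gene(genes, dels, blocks)
  # swap labels globally: counts and deletion ancestry both flip
  genes$maternal_sum <- 30; genes$paternal_sum <- 70
  dels$ancestry <- "paternal"
  p2 <- pair_deletion_gene(genes, dels, blocks)
  expect_equal(p1$del_ratio, p2$del_ratio, tolerance = 1e-12)
})

test_that("label permutation test is valid and deterministic", {
  set.seed(15)
  vals <- rnorm(80)
  grp <- rep(c(TRUE, FALSE), c(20, 60))
  r1 <- permute_group_labels(vals, grp, n_perm = 300, seed = 2L)
  r2 <- permute_group_labels(vals, grp, n_perm = 300, seed = 2L)
  expect_identical(r1$p, r2$p)
  expect_error(permute_group_labels(vals, grp, n_perm = 50), "100")
  # under independence, p is roughly uniform over repeated simulations
  ps <- vapply(1:60, function(i) {
    set.seed(100 + i)
    v <- rnorm(40)
    g <- sample(rep(c(TRUE, FALSE), c(10, 30)))
    permute_group_labels(v, g, n_perm = 199, seed = i)$p
  }, 0)
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("an injected promoter-deletion boost is detected", {
  set.seed(8)
  n_prom <- 104; n_other <- 1550
  vals <- c(rnorm(n_prom, 0.5), rnorm(n_other, 0))
  grp <- rep(c(TRUE, FALSE), c(n_prom, n_other))
  r <- permute_group_labels(vals, grp, n_perm = 999, seed = 3L)
  expect_gt(r$g_obs, 0.25)
  expect_lt(r$p, 0.01)
})

test_that("ACR:gene pairing enforces separation, block and intervening genes", {
  blocks <- data.frame(block_id = 1, chrom = "chr1", start = 1, end = 1e5)
  genes <- gr("chr1", c(10001, 14000), c(12000, 14500), strand = "+",
              gene_id = c("g1", "gMid"),
              maternal_sum = c(60, 5), paternal_sum = c(20, 5))
  acr_in <- gr("chr1", 10500, 10800, acr_id = "aIn",
               maternal_sum = 40, paternal_sum = 10)
  acr_far <- gr("chr1", 40000, 40300, acr_id = "aFar",
                maternal_sum = 8, paternal_sum = 9)
  acr_blocked <- gr("chr1", 15000, 15300, acr_id = "aBlk",
                    maternal_sum = 3, paternal_sum = 9)
  res <- pair_acr_gene(c(acr_in, acr_far, acr_blocked), genes[1], blocks,
                       genes = genes)
  # inside the gene: separation 0, kept; far: excluded by max_sep;
  # aBlk: gMid intervenes between it and g1
  expect_equal(res$pairs$acr_id, "aIn")
  expect_equal(res$pairs$separation, 0)
  expect_true(is.na(res$correlation))  # < 3 pairs
})

test_that("coupled allelic accessibility and expression correlate", {
  set.seed(33)
  blocks <- data.frame(block_id = 1, chrom = "chr1", start = 1, end = 1e7)
  n <- 30
  start <- seq(2e4, by = 3e5, length.out = n)
  driver <- rnorm(n, 0, 1)
  gm <- round(100 * 2^(driver / 2)); gp <- round(100 * 2^(-driver / 2))
  am <- round(50 * 2^(driver / 2 + rnorm(n, 0, 0.2)))
  ap <- round(50 * 2^(-driver / 2 + rnorm(n, 0, 0.2)))
  genes <- gr("chr1", start, start + 2000, strand = "+",
              gene_id = sprintf("g%02d", 1:n),
              maternal_sum = gm, paternal_sum = gp)
  acrs <- gr("chr1", start - 3000, start - 2500,
             acr_id = sprintf("a%02d", 1:n),
             maternal_sum = am, paternal_sum = ap)
  res <- pair_acr_gene(acrs, genes, blocks, genes = genes)
  expect_equal(res$n, n)
  expect_gt(res$correlation, 0.8)
  expect_lt(res$p_value, 1e-5)
})
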