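test_that("factor registry has 56 + 3 columns", {
  reg <- factor_registry()
  expect_equal(nrow(reg), 59)
  expect_equal(sum(reg$kind == "overall"), 28)
  expect_equal(sum(reg$kind == "allelic"), 28)
  expect_equal(sum(reg$kind == "covariate"), 3)
})

test_that("promoter geometry follows the strand", {
  genes <- gr("chr1", c(10001, 50000), c(12000, 52000),
              strand = c("+", "-"), gene_id = c("gp", "gm"))
  acrs <- gr("chr1", 1, 2, acr_id = "a0")  # far away: no reg regions
  rg <- assign_regions(genes, acrs)
  # plus strand, TSS at 10001: promoter covers the kb before it
  p <- rg$promoter[rg$promoter$gene_id == "gp"]
  expect_equal(GenomicRanges::start(p), 9001)
  expect_equal(GenomicRanges::end(p), 10000)
  # minus strand, TSS at 52000: promoter is downstream in genome coords
  m <- rg$promoter[rg$promoter$gene_id == "gm"]
  expect_equal(GenomicRanges::start(m), 52001)
  expect_equal(GenomicRanges::end(m), 53000)
  expect_equal(length(rg$upstream_reg), 0)
  expect_equal(length(rg$downstream_reg), 0)
})

test_that("regulatory regions exist only where an ACR is present", {
  genes <- gr("chr1", 10001, 12000, strand = "+", gene_id = "g1")
  acr_up <- gr("chr1", 5500, 5900, acr_id = "aU")    # in 5 kb upstream win
  rg <- assign_regions(genes, acr_up)
  expect_equal(length(rg$upstream_reg), 1)
  expect_equal(length(rg$downstream_reg), 0)
  acr_dn <- gr("chr1", 13000, 13400, acr_id = "aD")
  rg2 <- assign_regions(genes, acr_dn)
  expect_equal(length(rg2$upstream_reg), 0)
  expect_equal(length(rg2$downstream_reg), 1)
})

test_that("regions are clipped at chromosome edges", {
  si <- GenomeInfoDb::Seqinfo(seqnames = "chr1", seqlengths = 3000)
  genes <- GenomicRanges::GRanges("chr1", IRanges::IRanges(501, 1500),
                                  strand = "+", seqinfo = si)
  genes$gene_id <- "edge"
  acrs <- gr("chr1", 100, 200, acr_id = "a1")
  rg <- assign_regions(genes, acrs)
  # the upstream window lies wholly off the chromosome and is dropped
  expect_equal(length(rg$upstream_reg), 0)
  p <- rg$promoter
  expect_equal(GenomicRanges::start(p), 1)  # promoter truncated at chr start
})

test_that("ACR proximity classes use overlap then 2 kb gap", {
  genes <- gr("chr1", 10000, 20000, gene_id = "g")
  acrs <- gr("chr1", c(15000, 21500, 22501, 8000),
             c(15400, 21900, 22901, 8400))
  cls <- classify_acr(acrs, genes)
  expect_equal(cls, c("genic", "proximal", "distal", "proximal"))
  expect_warning(out <- classify_acr(acrs, genes[0]), "empty")
  expect_true(all(out == "distal"))
})

test_that("factor matrix applies NA rules and the WGS outlier filter", {
  # 8 genes: g1..g7 balanced WGS with comparable depth, g8 a gross
  # outlier; g_empty has no phased SNP at all
  starts <- seq(10001, by = 20000, length.out = 9)
  ids <- c(sprintf("g%d", 1:8), "g_empty")
  genes <- gr("chr1", starts, starts + 1999, strand = "+", gene_id = ids)
  acrs <- gr("chr1", 1, 2, acr_id = "a0")
  rg <- assign_regions(genes, acrs)
  pos <- as.vector(vapply(starts[1:8], function(s) s + c(500, 900), c(0, 0)))
  m <- rep(c(30, 31), 8); p <- rep(c(30, 29), 8)
  m[15:16] <- c(300, 310); p[15:16] <- c(3, 2)  # g8 outlier
  counts <- list(
    WGS = data.frame(chrom = "chr1", pos = pos,
                     maternal_count = m, paternal_count = p),
    ATAC = data.frame(chrom = "chr1", pos = starts[1:8] + 700,
                      maternal_count = 12, paternal_count = 10))
  sig <- data.frame(gene_id = ids, factor_type = "ATAC",
                    region = "genic", signal = seq(-1, 1, length.out = 9))
  fm <- build_factor_matrix(genes, rg, sig, counts, iqr_mult = 1.5,
                            pct_filter = 10)
  expect_false("g8" %in% fm$gene_id)         # outlier dropped
  expect_equal(attr(fm, "n_outliers"), 1)
  ge <- fm[fm$gene_id == "g_empty", ]
  expect_true(is.na(ge$WGS_genic_allelic))   # no phased SNP
  expect_true(is.na(ge$ATAC_promoter_allelic))
  g2r <- fm[fm$gene_id == "g2", ]
  expect_equal(g2r$ATAC_genic_overall, sig$signal[2])
  expect_false(is.na(g2r$WGS_genic_allelic))
  expect_equal(g2r$WGS_genic_allelic, log2(62 / 60), tolerance = 1e-12)
})

test_that("promoter deletion indicators are per ancestry", {
  genes <- gr("chr1", 10001, 12000, strand = "+", gene_id = "g1")
  acrs <- gr("chr1", 1, 2, acr_id = "a0")
  rg <- assign_regions(genes, acrs)
  svs <- gr("chr1", c(9500, 9600), c(9550, 9700),
            sv_id = c("s1", "s2"), ancestry = c("maternal", NA))
  fm <- build_factor_matrix(genes, rg, NULL, list(), svs = svs)
  expect_equal(fm$maternal_promoter_deletion, 1)
  expect_equal(fm$paternal_promoter_deletion, 0)
})
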