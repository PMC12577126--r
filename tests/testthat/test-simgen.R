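test_that("configuration invariants are enforced", {
  expect_error(sim_config(rho = 1), "rho")
  expect_error(sim_config(pi_ref = 0), "pi_ref")
  expect_error(sim_config(trait_snp_acr_fold = -1), "trait_snp_acr_fold")
  expect_error(sim_config(coupling_coefficients = c(not_a_factor = 1)),
               "registry")
  expect_output(print(sim_config()), "Synthetic study")
})

test_that("generators are deterministic for a fixed seed", {
  cfg <- small_config()
  g1 <- simulate_genome(cfg)
  g2 <- simulate_genome(cfg)
  expect_identical(as.data.frame(g1$genes), as.data.frame(g2$genes))
  p1 <- simulate_phased_variants(g1, cfg)
  p2 <- simulate_phased_variants(g2, cfg)
  expect_identical(p1$variants, p2$variants)
  a1 <- simulate_allelic_counts(p1, g1, cfg)
  a2 <- simulate_allelic_counts(p2, g2, cfg)
  expect_identical(a1$counts$WGS, a2$counts$WGS)
})

test_that("a zero-gene genome is a valid empty bundle", {
  cfg <- small_config(n_genes = 0L, n_acrs = 0L, n_svs = 0L)
  g <- simulate_genome(cfg)
  expect_equal(length(g$genes), 0)
  expect_equal(length(g$acrs), 0)
})

test_that("an overcrowded chromosome raises a sizing error", {
  expect_error(
    simulate_genome(sim_config(n_genes = 5000L, chrom_length = 1e5)),
    "too short")
})

test_that("genes never overlap on a chromosome", {
  g <- get_small_study()$genome$genes
  for (ch in unique(as.character(GenomicRanges::seqnames(g)))) {
    gc <- g[GenomicRanges::seqnames(g) == ch]
    hits <- GenomicRanges::findOverlaps(gc, gc,
                                        ignore.strand = TRUE)
    expect_equal(length(hits), length(gc))  # only self-hits
  }
})

test_that("SV lengths match the target log-normal mean", {
  cfg <- sim_config(n_svs = 2481L, n_genes = 50L, n_acrs = 50L,
                    chrom_length = 5e6, seed = 5L)
  g <- simulate_genome(cfg)
  expect_equal(mean(GenomicRanges::width(g$svs)), 332, tolerance = 0.1)
})

test_that("simulated switch errors hit the requested rate", {
  cfg <- small_config(switch_error_rate = 0.03, seed = 6L)
  g <- simulate_genome(cfg)
  ph <- simulate_phased_variants(g, cfg)
  # toggles of the switch state per block are Bernoulli(rate)
  flips <- 0L; trans <- 0L
  for (b in unique(ph$variants$block_id)) {
    s <- ph$truth$switch_state[ph$variants$block_id == b]
    if (length(s) < 2) next
    flips <- flips + sum(s[-1] != s[-length(s)])
    trans <- trans + length(s) - 1L
  }
  rate <- flips / trans
  expect_lt(abs(rate - 0.03), 1.96 * sqrt(0.03 * 0.97 / trans) + 1e-6)

  cfg0 <- small_config(switch_error_rate = 0)
  ph0 <- simulate_phased_variants(simulate_genome(cfg0), cfg0)
  expect_false(any(ph0$truth$switch_state))
})

test_that("recombinant truth blocks change ancestry within a haplotype", {
  st <- get_small_study()
  cls <- st$phased$truth$block_class
  for (b in names(cls)[cls == "recombinant"]) {
    anc <- st$phased$truth$phys_hap1_ancestry[
      st$phased$variants$block_id == as.integer(b)]
    expect_gte(length(unique(anc)), 2)
  }
})

test_that("allelic counts follow the configured imbalance", {
  cfg <- small_config(ase_fraction = 1, ase_log2fc_range = c(2, 2),
                      rho = 0.05, seed = 12L)
  g <- simulate_genome(cfg)
  ph <- simulate_phased_variants(g, cfg)
  ac <- simulate_allelic_counts(ph, g, cfg)
  rna <- ac$counts$RNA_rep1
  # orient to maternal using truth and check the mean maternal fraction
  mat_is_h1 <- ph$truth$hap1_ancestry == "maternal"
  m <- ifelse(mat_is_h1, rna$hap1_count, rna$hap2_count)
  tot <- rna$hap1_count + rna$hap2_count
  vg <- GenomicRanges::GRanges(rna$chrom, IRanges::IRanges(rna$pos, width = 1))
  in_gene <- GenomicRanges::countOverlaps(vg, g$genes) > 0
  sel <- in_gene & tot > 20
  frac <- sum(m[sel]) / sum(tot[sel])
  # genes are an even +2/-2 log2FC mixture: E[pi] = (0.8 + 0.2)/2 = 0.5,
  # so test per-gene |fraction - 0.8| after keying to the gene's sign
  fc <- ac$truth$gene_log2fc
  ov <- GenomicRanges::findOverlaps(vg, g$genes, select = "first")
  keyed <- ifelse(!is.na(ov) & fc[ifelse(is.na(ov), 1, ov)] < 0,
                  tot - m, m)
  frac_keyed <- sum(keyed[sel]) / sum(tot[sel])
  expect_equal(frac_keyed, 0.8, tolerance = 0.03)
  # WGS never carries signal
  wgs <- ac$counts$WGS
  mw <- ifelse(mat_is_h1, wgs$hap1_count, wgs$hap2_count)
  expect_equal(sum(mw) / sum(wgs$hap1_count + wgs$hap2_count), 0.5,
               tolerance = 0.01)
})

test_that("WGS allelic overdispersion matches rho by method of moments", {
  cfg <- sim_config(n_chromosomes = 2L, chrom_length = 2e6, n_genes = 100L,
                    n_acrs = 100L, snp_density = 4, rho = 0.1, seed = 9L)
  g <- simulate_genome(cfg)
  ph <- simulate_phased_variants(g, cfg)
  ac <- simulate_allelic_counts(ph, g, cfg)
  wgs <- ac$counts$WGS
  tot <- wgs$hap1_count + wgs$hap2_count
  sel <- tot >= 10
  expect_gt(sum(sel), 10000)
  fit <- fit_betabin_null(wgs$hap1_count[sel], tot[sel])
  expect_equal(fit$rho_mom, 0.1, tolerance = 0.01)
})

test_that("methylation table straddles the coverage filter", {
  st <- get_small_study()
  cov <- st$methylation$sites$hap1_total + st$methylation$sites$hap2_total
  expect_gt(sum(cov < 10), 10)
  expect_gt(sum(cov >= 10), 10)
  # zero injected gap leaves the caller at its nominal false-positive rate
  cfg <- small_config(diff_meth_rate = 0, n_cytosines = 3000L, seed = 21L)
  ph <- get_small_study()$phased
  meth <- simulate_methylation(ph, cfg)
  calls <- call_diff_methylation(meth$sites)
  fp <- mean(calls$is_differential[calls$evaluated])
  # one-sided Fisher at 1 - p >= 0.7 admits at most 30% by construction
  expect_lt(fp, 0.3 + 0.03)
})

test_that("GWAS tables encode significance and MAF contracts", {
  st <- get_small_study()
  gw <- st$gwas$gwas
  bonf <- 0.05 / nrow(gw)
  expect_identical(gw$significant, gw$p < bonf)
  expect_true(all(gw$maf >= 0.03))
  expect_equal(sum(gw$significant), 150)
  expect_equal(dim(st$gwas$genotypes), c(nrow(gw), 154L))
})

test_that("written study files carry no ground-truth columns", {
  dir <- tempfile("study")
  cfg <- small_config(n_cytosines = 200L)
  simulate_study(cfg, out_dir = dir)
  for (f in list.files(dir, pattern = "\\.tsv$", full.names = TRUE)) {
    if (grepl("truth", f)) next
    h <- names(utils::read.delim(f, nrows = 1))
    expect_false(any(grepl("truth|log2fc_true|ancestry_true", h)),
                 info = f)
  }
  # variants.tsv keeps phasing but not ancestry truth
  v <- utils::read.delim(file.path(dir, "variants.tsv"), nrows = 5)
  expect_false("hap1_ancestry" %in% names(v))
  unlink(dir, recursive = TRUE)
})

test_that("study writing is byte-identical under one seed", {
  d1 <- tempfile("s1"); d2 <- tempfile("s2")
  cfg <- small_config(n_cytosines = 200L)
  simulate_study(cfg, out_dir = d1)
  simulate_study(cfg, out_dir = d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))), info = f)
  }
  unlink(c(d1, d2), recursive = TRUE)
})
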