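# End-to-end orchestration: simulate -> ancestry -> allelic -> ase ->
# features -> model -> link -> enrich, file-based between stages, with a
# hashed manifest for reproducibility. Each stage derives its RNG stream
# from the master seed and the stage name, so adding or skipping a stage
# never perturbs the randomness of the others.

pipeline_stages <- function() {
  c("simulate", "ancestry", "allelic", "ase", "features", "model",
    "link", "enrich")
}

stage_requirements <- function() {
  list(
    simulate = character(0),
    ancestry = c("variants.tsv", "parents.tsv"),
    allelic = c("counts_WGS.tsv", "ancestry.tsv", "genes.gff3", "acrs.bed",
                "methylation.tsv"),
    ase = c("counts_oriented_RNA_rep1.tsv", "counts_oriented_WGS.tsv",
            "genes.gff3", "acrs.bed"),
    features = c("ase_genes.tsv", "region_signal.tsv", "svs.bed",
                 "blocks.tsv", "dnds.tsv"),
    model = c("factor_matrix.tsv", "expression.tsv"),
    link = c("ase_genes.tsv", "as_acrs.tsv", "svs.bed", "blocks.tsv"),
    enrich = c("as_acrs.tsv", "acrs.bed", "tes.bed", "gwas.tsv")
  )
}

read_genes_gff3 <- function(dir) {
  g <- read_intervals(file.path(dir, "genes.gff3"), "GFF3")
  g <- g[g$type == "gene"]
  g$gene_id <- g$ID
  g
}

read_svs_bed <- function(dir) {
  s <- read_intervals(file.path(dir, "svs.bed"), "BED")
  parts <- strsplit(s$name, "|", fixed = TRUE)
  s$sv_id <- vapply(parts, `[`, "", 1)
  s$haplotype <- vapply(parts, `[`, "", 2)
  s
}

# ancestry for every SV: non-recombinant block -> block haplotype
# ancestry (flipped for hap2 SVs); recombinant -> nearest-5-SNPs vote on
# the SV's haplotype; otherwise unknown
impute_all_sv_ancestry <- function(svs, variants, ancestry, blocks) {
  mid <- (GenomicRanges::start(svs) + GenomicRanges::end(svs)) %/% 2
  chrom <- as.character(GenomicRanges::seqnames(svs))
  blk <- block_at(chrom, mid, blocks)
  anc <- ancestry$hap1_ancestry[match(variants$snp_id, ancestry$snp_id)]
  out <- rep(NA_character_, length(svs))
  flip <- function(a) ifelse(a == "maternal", "paternal", "maternal")
  for (i in seq_along(svs)) {
    b <- blk[i]
    if (is.na(b)) next
    cls <- blocks$class[match(b, blocks$block_id)]
    if (is.na(cls)) next
    idx <- which(variants$block_id == b & !is.na(anc))
    hap1_anc <- anc[idx]
    sv_anc <- if (svs$haplotype[i] == "hap1") hap1_anc else flip(hap1_anc)
    blk_anc1 <- blocks$block_hap1_ancestry[match(b, blocks$block_id)]
    block_ancestry <- if (!is.na(blk_anc1)) {
      if (svs$haplotype[i] == "hap1") blk_anc1 else flip(blk_anc1)
    } else NULL
    out[i] <- impute_sv_ancestry(mid[i], variants$pos[idx], sv_anc,
                                 cls, block_ancestry)
  }
  out
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in dependency order inside
#' \code{out_dir}; every stage reads its inputs from and writes its
#' outputs to that directory, and a JSON manifest of MD5 hashes is
#' written at the end. Re-running with the same configuration and seed
#' reproduces identical hashes.
#'
#' @param config A \code{\link{sim_config}} (also carries the
#'   simulation seed) describing the synthetic study, plus analysis
#'   thresholds via \code{thresholds}.
#' @param out_dir Run directory (created if needed).
#' @param stages Character vector of stages to run, a subset of
#'   \code{simulate, ancestry, allelic, ase, features, model, link,
#'   enrich}.
#' @param seed Master seed; overrides \code{config$seed} when given.
#' @param thresholds Named list of analysis thresholds; defaults:
#'   \code{ase_alpha} 0.05, \code{snp_coverage} 10, \code{min_snps} 2,
#'   \code{promoter} 1000, \code{proximal} 2000, \code{reg_window} 5000,
#'   \code{link_max_sep} 5000, \code{meth_coverage} 10,
#'   \code{meth_prob} 0.7, \code{wgs_iqr} 1.5, \code{pct_filter} 10,
#'   \code{n_sims} 4000, \code{n_perm} 1000.
#' @return Invisibly, the manifest (named vector of MD5 hashes).
#' @export
run_pipeline <- function(config = sim_config(), out_dir,
                         stages = pipeline_stages(), seed = NULL,
                         thresholds = list()) {
  stopifnot(inherits(config, "sim_config"))
  stages <- match.arg(stages, pipeline_stages(), several.ok = TRUE)
  stages <- pipeline_stages()[pipeline_stages() %in% stages]
  if (!is.null(seed)) config$seed <- as.integer(seed)
  th <- utils::modifyList(list(
    ase_alpha = 0.05, snp_coverage = 10, min_snps = 2, promoter = 1000,
    proximal = 2000, reg_window = 5000, link_max_sep = 5000,
    meth_coverage = 10, meth_prob = 0.7, wgs_iqr = 1.5, pct_filter = 10,
    n_sims = 4000, n_perm = 1000), thresholds)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  req <- stage_requirements()
  log <- file.path(out_dir, "run.log")
  note <- function(...) cat(format(Sys.time(), "%H:%M:%S "),
                            sprintf(...), "\n", sep = "",
                            file = log, append = TRUE)

  for (st in stages) {
    missing <- req[[st]][!file.exists(file.path(out_dir, req[[st]]))]
    if (length(missing))
      stop(sprintf("stage '%s' requires upstream output '%s' (run the %s)",
                   st, missing[1],
                   "producing stage first"), call. = FALSE)
    note("stage %s", st)
    switch(st,
      simulate = stage_simulate(config, out_dir),
      ancestry = stage_ancestry(config, out_dir),
      allelic = stage_allelic(config, out_dir, th),
      ase = stage_ase(config, out_dir, th),
      features = stage_features(config, out_dir, th),
      model = stage_model(config, out_dir, th),
      link = stage_link(config, out_dir, th),
      enrich = stage_enrich(config, out_dir, th)
    )
  }

  cfg <- config
  attributes(cfg) <- list(names = names(cfg))
  cfg_ser <- lapply(cfg, function(v)
    if (is.numeric(v) && !is.null(names(v))) as.list(v) else v)
  yaml::write_yaml(c(cfg_ser, list(thresholds = th)),
                   file.path(out_dir, "config.yaml"))
  files <- setdiff(list.files(out_dir),
                   c("manifest.json", "run.log"))
  manifest <- tools::md5sum(file.path(out_dir, sort(files)))
  names(manifest) <- sort(files)
  jsonlite::write_json(as.list(manifest),
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(manifest)
}

stage_simulate <- function(config, dir) {
  simulate_study(config, out_dir = dir)
  invisible(NULL)
}

stage_ancestry <- function(config, dir) {
  variants <- read_tsv(file.path(dir, "variants.tsv"))
  parents <- read_tsv(file.path(dir, "parents.tsv"))
  res <- assign_ancestry(variants, parents)
  write_tsv(res$ancestry, file.path(dir, "ancestry.tsv"))
  write_tsv(res$blocks, file.path(dir, "blocks.tsv"))
  invisible(NULL)
}

stage_allelic <- function(config, dir, th) {
  ancestry <- read_tsv(file.path(dir, "ancestry.tsv"))
  genes <- read_genes_gff3(dir)
  genes$feature_id <- genes$gene_id
  acrs <- read_intervals(file.path(dir, "acrs.bed"), "BED")
  acrs$feature_id <- acrs$name
  agg <- list()
  for (assay in assay_registry()) {
    f <- file.path(dir, paste0("counts_", assay, ".tsv"))
    if (!file.exists(f)) next
    ct <- validate_counts(f, assay)
    ct <- filter_snp_counts(ct, th$snp_coverage)
    ct <- orient_counts(ct, ancestry)
    write_tsv(ct, file.path(dir, paste0("counts_oriented_", assay, ".tsv")))
    ga <- aggregate_feature(ct, genes, th$min_snps)
    ga$type <- "gene"; ga$assay <- assay
    aa <- aggregate_feature(ct, acrs, th$min_snps)
    aa$type <- "acr"; aa$assay <- assay
    agg[[assay]] <- rbind(ga, aa)
  }
  write_tsv(do.call(rbind, agg), file.path(dir, "feature_allelic.tsv"))
  meth <- read_tsv(file.path(dir, "methylation.tsv"))
  calls <- call_diff_methylation(meth, th$meth_coverage, th$meth_prob)
  write_tsv(calls, file.path(dir, "methyl_calls.tsv"))
  invisible(NULL)
}

stage_ase <- function(config, dir, th) {
  genes <- read_genes_gff3(dir)
  genes$feature_id <- genes$gene_id
  acrs <- read_intervals(file.path(dir, "acrs.bed"), "BED")
  acrs$feature_id <- acrs$name
  wgs <- read_tsv(file.path(dir, "counts_oriented_WGS.tsv"))
  wgr <- GenomicRanges::GRanges(wgs$chrom,
                                IRanges::IRanges(wgs$pos, width = 1))
  in_gene <- GenomicRanges::countOverlaps(wgr, genes) > 0
  in_acr <- GenomicRanges::countOverlaps(wgr, acrs) > 0
  null_gene <- fit_betabin_null(wgs$maternal_count[in_gene],
                                wgs$maternal_count[in_gene] +
                                  wgs$paternal_count[in_gene])
  null_acr <- fit_betabin_null(wgs$maternal_count[in_acr],
                               wgs$maternal_count[in_acr] +
                                 wgs$paternal_count[in_acr])

  reps <- list()
  for (assay in c("RNA_rep1", "RNA_rep2")) {
    ct <- read_tsv(file.path(dir, paste0("counts_oriented_", assay, ".tsv")))
    reps[[assay]] <- ase_test(ct, genes, null_gene, n_sims = th$n_sims,
                              seed = derive_seed(config$seed, assay),
                              min_snps = th$min_snps)
  }
  calls <- call_ase(reps, alpha = th$ase_alpha)
  genes_out <- merge(reps$RNA_rep1, calls, by = "feature_id")
  write_tsv(genes_out, file.path(dir, "ase_genes.tsv"))

  atac <- read_tsv(file.path(dir, "counts_oriented_ATAC.tsv"))
  acr_res <- ase_test(atac, acrs, null_acr, n_sims = th$n_sims,
                      seed = derive_seed(config$seed, "ATAC"),
                      min_snps = th$min_snps)
  acr_calls <- call_ase(acr_res, alpha = th$ase_alpha)
  acr_out <- merge(acr_res, acr_calls, by = "feature_id")
  write_tsv(acr_out, file.path(dir, "as_acrs.tsv"))
  nulls <- list(
    gene = list(pi = null_gene$pi_hat, rho = null_gene$rho_hat,
                n = null_gene$n_obs, converged = null_gene$converged),
    acr = list(pi = null_acr$pi_hat, rho = null_acr$rho_hat,
               n = null_acr$n_obs, converged = null_acr$converged))
  jsonlite::write_json(nulls, file.path(dir, "betabin_nulls.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(NULL)
}

stage_features <- function(config, dir, th) {
  genes <- read_genes_gff3(dir)
  acrs <- read_intervals(file.path(dir, "acrs.bed"), "BED")
  regions <- assign_regions(genes, acrs, th$promoter, th$reg_window)
  region_signal <- read_tsv(file.path(dir, "region_signal.tsv"))
  counts <- list()
  for (assay in c("ATAC", "H3K4me3", "H3K36me3", "H3K56ac", "H3K27me3",
                  "WGS")) {
    f <- file.path(dir, paste0("counts_oriented_", assay, ".tsv"))
    if (file.exists(f)) counts[[assay]] <- read_tsv(f)
  }
  # methylation allelic input: methylated counts per haplotype need
  # ancestry orientation via the nearest phase block
  meth <- read_tsv(file.path(dir, "methyl_calls.tsv"))
  blocks <- read_tsv(file.path(dir, "blocks.tsv"))
  bsim <- read_tsv(file.path(dir, "blocks_sim.tsv"))
  blk <- block_at(meth$chrom, meth$pos, bsim)
  anc1 <- blocks$block_hap1_ancestry[match(blk, blocks$block_id)]
  known <- !is.na(anc1)
  counts$methylation <- data.frame(
    chrom = meth$chrom[known], pos = meth$pos[known],
    maternal_count = ifelse(anc1[known] == "maternal",
                            meth$hap1_meth[known], meth$hap2_meth[known]),
    paternal_count = ifelse(anc1[known] == "maternal",
                            meth$hap2_meth[known], meth$hap1_meth[known]))

  variants <- read_tsv(file.path(dir, "variants.tsv"))
  ancestry <- read_tsv(file.path(dir, "ancestry.tsv"))
  svs <- read_svs_bed(dir)
  svs$ancestry <- impute_all_sv_ancestry(svs, variants, ancestry, bsim_with_class(blocks, bsim))
  dnds <- read_tsv(file.path(dir, "dnds.tsv"))
  fm <- build_factor_matrix(genes, regions, region_signal, counts,
                            svs = svs, dnds = dnds,
                            pct_filter = th$pct_filter,
                            iqr_mult = th$wgs_iqr)
  write_tsv(fm, file.path(dir, "factor_matrix.tsv"))
  jsonlite::write_json(attr(fm, "registry"),
                       file.path(dir, "factor_registry.json"))
  invisible(NULL)
}

# merge the simulated block geometry with the classified block table
bsim_with_class <- function(blocks, bsim) {
  out <- bsim
  i <- match(out$block_id, blocks$block_id)
  out$class <- blocks$class[i]
  out$block_hap1_ancestry <- blocks$block_hap1_ancestry[i]
  out
}

stage_model <- function(config, dir, th) {
  fm <- read_tsv(file.path(dir, "factor_matrix.tsv"))
  expr <- read_tsv(file.path(dir, "expression.tsv"))
  y <- expr$log2_tpm[match(fm$gene_id, expr$gene_id)]
  fit <- fit_enet_cv(fm, y, nfolds = 5,
                     seed = derive_seed(config$seed, "enet_overall"))
  red <- reduce_1se(fit)
  write_tsv(enet_report(fit), file.path(dir, "enet_overall.tsv"))
  write_tsv(enet_report(red), file.path(dir, "enet_overall_1se.tsv"))

  ase <- read_tsv(file.path(dir, "ase_genes.tsv"))
  y2 <- ase$log2fc[match(fm$gene_id, ase$feature_id)]
  if (sum(!is.na(y2)) >= 10 * 5) {
    fit2 <- fit_enet_cv(fm[!is.na(y2), ], y2[!is.na(y2)], nfolds = 5,
                        seed = derive_seed(config$seed, "enet_allelic"))
    write_tsv(enet_report(fit2), file.path(dir, "enet_allelic.tsv"))
  }
  write_tsv(data.frame(lambda = fit$lambda, cvm = fit$cvm,
                       cvsd = fit$cvsd),
            file.path(dir, "cvcurve.tsv"))
  invisible(NULL)
}

stage_link <- function(config, dir, th) {
  genes <- read_genes_gff3(dir)
  ase <- read_tsv(file.path(dir, "ase_genes.tsv"))
  sig <- ase$feature_id[ase$significant]
  gsel <- genes[match(intersect(ase$feature_id, genes$gene_id),
                      genes$gene_id)]
  i <- match(gsel$gene_id, ase$feature_id)
  gsel$maternal_sum <- ase$maternal_sum[i]
  gsel$paternal_sum <- ase$paternal_sum[i]
  ase_gr <- gsel[gsel$gene_id %in% sig]

  blocks <- read_tsv(file.path(dir, "blocks_sim.tsv"))
  svs <- read_svs_bed(dir)
  variants <- read_tsv(file.path(dir, "variants.tsv"))
  ancestry <- read_tsv(file.path(dir, "ancestry.tsv"))
  bcls <- read_tsv(file.path(dir, "blocks.tsv"))
  svs$ancestry <- impute_all_sv_ancestry(svs, variants, ancestry,
                                         bsim_with_class(bcls, blocks))
  pairs <- pair_deletion_gene(ase_gr, svs, blocks, th$promoter)
  write_tsv(pairs, file.path(dir, "deletion_pairs.tsv"))
  stats <- list(n_pairs = nrow(pairs))
  if (nrow(pairs) > 0 && sum(pairs$sv_in_promoter) >= 2 &&
      sum(!pairs$sv_in_promoter) >= 2) {
    pt <- permute_group_labels(pairs$del_ratio, pairs$sv_in_promoter,
                               n_perm = th$n_perm,
                               seed = derive_seed(config$seed, "delperm"))
    stats$hedges_g <- pt$g_obs
    stats$p_promoter_effect <- pt$p
  }

  acr_tab <- read_tsv(file.path(dir, "as_acrs.tsv"))
  acrs <- read_intervals(file.path(dir, "acrs.bed"), "BED")
  acrs$acr_id <- acrs$name
  as_sel <- acrs[acrs$acr_id %in% acr_tab$feature_id[acr_tab$significant]]
  j <- match(as_sel$acr_id, acr_tab$feature_id)
  as_sel$maternal_sum <- acr_tab$maternal_sum[j]
  as_sel$paternal_sum <- acr_tab$paternal_sum[j]
  ag <- pair_acr_gene(as_sel, ase_gr, blocks, genes = genes,
                      max_sep = th$link_max_sep)
  write_tsv(ag$pairs, file.path(dir, "acr_gene_pairs.tsv"))
  stats$acr_gene_r <- ag$correlation
  stats$acr_gene_n <- ag$n
  jsonlite::write_json(stats, file.path(dir, "link_stats.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(NULL)
}

stage_enrich <- function(config, dir, th) {
  acrs <- read_intervals(file.path(dir, "acrs.bed"), "BED")
  acrs$acr_id <- acrs$name
  tes <- read_intervals(file.path(dir, "tes.bed"), "BED")
  tes$te_class <- tes$name
  acr_tab <- read_tsv(file.path(dir, "as_acrs.tsv"))
  asids <- acr_tab$feature_id[acr_tab$significant]
  te <- te_enrichment(acrs[acrs$acr_id %in% asids], acrs, tes,
                      n_perm = th$n_perm,
                      seed = derive_seed(config$seed, "te"))
  ser <- function(x) list(observed = x$observed, fold = x$fold, p = x$p,
                          n_perm = x$n_perm, n_query = x$n_query,
                          matching = x$matching, null = x$null)
  jsonlite::write_json(ser(te), file.path(dir, "enrichment_te.json"),
                       auto_unbox = TRUE, digits = NA)

  genes <- read_genes_gff3(dir)
  regions <- assign_regions(genes, acrs, th$promoter, th$reg_window)
  ase <- read_tsv(file.path(dir, "ase_genes.tsv"))
  svs <- read_svs_bed(dir)
  sv <- sv_promoter_enrichment(ase$feature_id[ase$significant],
                               ase$feature_id, regions$promoter, svs,
                               n_perm = th$n_perm,
                               seed = derive_seed(config$seed, "svprom"))
  jsonlite::write_json(ser(sv), file.path(dir, "enrichment_sv_promoter.json"),
                       auto_unbox = TRUE, digits = NA)

  gwas <- read_tsv(file.path(dir, "gwas.tsv"))
  tr <- trait_snp_acr_enrichment(gwas, acrs, genes, n_perm = th$n_perm,
                                 seed = derive_seed(config$seed, "gwas"))
  jsonlite::write_json(ser(tr), file.path(dir, "enrichment_trait_acr.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(NULL)
}
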