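# Synthetic-study generator: genome model, phased variants with ancestry
# truth, allelic count tables, methylation, GWAS summaries. The defaults
# define the study conditions the downstream statistics assume; ground
# truth is returned alongside, never mixed into analysis inputs.

#' Configuration for the synthetic study generator
#'
#' Defaults emulate a highly heterozygous hybrid genome at desk scale: a
#' few megabase-sized chromosomes, kilobase-scale genes, phase blocks
#' tiling each chromosome, beta-binomially overdispersed allelic counts
#' with configurable imbalance and reference-mapping bias, chromatin
#' signal linearly coupled to log-expression, TE-biased structural-variant
#' placement and trait-SNP enrichment in accessible chromatin.
#'
#' @param n_chromosomes Number of chromosomes.
#' @param chrom_length Chromosome length in bp.
#' @param n_genes Total genes.
#' @param n_acrs Total accessible chromatin regions.
#' @param n_svs Total structural variants (deletions).
#' @param n_phase_blocks Total phase blocks (tiled across chromosomes).
#' @param snp_density Heterozygous SNPs per kb.
#' @param rho Beta-binomial intra-class overdispersion in [0, 1).
#' @param pi_ref Expected reference-haplotype read fraction under no
#'   allelic signal (reference-mapping bias); 0.5 = unbiased.
#' @param ase_fraction Fraction of genes with true allelic imbalance.
#' @param ase_log2fc_range Interval of true |log2 maternal/paternal|
#'   effects.
#' @param coupling_coefficients Named vector of true linear coefficients
#'   linking chromatin factor signal to log2 expression; names must be
#'   factor-registry columns (see \code{\link{factor_registry}}).
#' @param snr Signal-to-noise ratio of the expression model (variance of
#'   the linear predictor over noise variance).
#' @param allelic_coupling Named per-assay multiplier translating a
#'   gene's true expression log2FC into the allelic imbalance of reads of
#'   that assay over the gene.
#' @param te_fraction Fraction of the genome tiled by TE intervals.
#' @param te_enrichment_sv Relative odds that an SV lands on a TE.
#' @param sv_promoter_fraction Fraction of SVs seeded into gene promoters.
#' @param trait_snp_acr_fold True fold-enrichment (odds multiplier) of
#'   significant trait SNPs in ACRs relative to matched background.
#' @param n_gwas_snps,n_trait_snps GWAS SNP counts (total, significant).
#' @param n_accessions Accessions in the simulated genotype matrix.
#' @param switch_error_rate Per-SNP probability that the phase flips
#'   (Markov switch process) within a block; must be < 0.5.
#' @param informative_fraction Fraction of SNPs homozygous-alternate
#'   between the simulated parents (ancestry-informative).
#' @param recombinant_fraction,unclassified_fraction Fractions of phase
#'   blocks made recombinant (one within-haplotype ancestry change) or
#'   unclassifiable (no informative SNPs).
#' @param depth_mean,depth_dispersion Negative-binomial read depth per
#'   SNP: mean and dispersion (variance = mu + dispersion * mu^2).
#' @param n_cytosines Cytosines in the methylation table.
#' @param diff_meth_rate Fraction of cytosines made differentially
#'   methylated between haplotypes.
#' @param meth_gap Methylation-fraction gap injected at differential
#'   sites.
#' @param seed RNG seed; identical seeds give bit-identical output.
#' @return An object of class \code{sim_config}.
#' @export
sim_config <- function(n_chromosomes = 3L,
                       chrom_length = 2e6,
                       n_genes = 240L,
                       n_acrs = 300L,
                       n_svs = 120L,
                       n_phase_blocks = 30L,
                       snp_density = 4,
                       rho = 0.1,
                       pi_ref = 0.5,
                       ase_fraction = 0.2,
                       ase_log2fc_range = c(0.5, 2),
                       coupling_coefficients = NULL,
                       snr = 2,
                       allelic_coupling = c(RNA_rep1 = 1, RNA_rep2 = 1,
                                            ATAC = 0.8, H3K4me3 = 0.5,
                                            H3K36me3 = 0.5, H3K56ac = 0.3,
                                            H3K27me3 = -0.3, WGS = 0),
                       te_fraction = 0.2,
                       te_enrichment_sv = 2,
                       sv_promoter_fraction = 0.1,
                       trait_snp_acr_fold = 2,
                       n_gwas_snps = 4000L,
                       n_trait_snps = 150L,
                       n_accessions = 154L,
                       switch_error_rate = 0.01,
                       informative_fraction = 0.1,
                       recombinant_fraction = 0.1,
                       unclassified_fraction = 0.07,
                       depth_mean = 60,
                       depth_dispersion = 0.3,
                       n_cytosines = 2000L,
                       diff_meth_rate = 0.1,
                       meth_gap = 0.6,
                       seed = 1L) {
  if (is.null(coupling_coefficients)) {
    coupling_coefficients <- c(
      ATAC_genic_overall = 0.8,
      H3K4me3_genic_overall = 0.6,
      H3K27me3_genic_overall = -0.5,
      H3K36me3_genic_overall = 0.4,
      ATAC_promoter_overall = 0.3
    )
  }
  cfg <- as.list(environment())
  for (nm in c("n_chromosomes", "chrom_length", "n_genes", "n_acrs",
               "n_svs", "n_phase_blocks", "n_gwas_snps", "n_accessions",
               "n_cytosines")) {
    if (cfg[[nm]] < 0) stop("'", nm, "' must be >= 0", call. = FALSE)
  }
  if (cfg$n_chromosomes < 1 || cfg$chrom_length < 1)
    stop("need at least one chromosome of positive length", call. = FALSE)
  if (rho < 0 || rho >= 1) stop("'rho' must lie in [0, 1)", call. = FALSE)
  stopifnot_scalar_prob(pi_ref, "pi_ref")
  if (trait_snp_acr_fold < 0)
    stop("'trait_snp_acr_fold' must be >= 0", call. = FALSE)
  if (switch_error_rate >= 0.5 || switch_error_rate < 0)
    stop("'switch_error_rate' must lie in [0, 0.5); at 0.5 the haplotype ",
         "labels carry no information", call. = FALSE)
  bad <- setdiff(names(cfg$coupling_coefficients), factor_registry()$name)
  if (length(bad))
    stop("coupling_coefficients name(s) not in the factor registry: ",
         paste(bad, collapse = ", "), call. = FALSE)
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic study configuration\n")
  cat(sprintf("  genome: %d x %.2g bp; %d genes, %d ACRs, %d SVs\n",
              x$n_chromosomes, x$chrom_length, x$n_genes, x$n_acrs, x$n_svs))
  cat(sprintf("  variants: %.3g SNP/kb in %d phase blocks; switch %.3g\n",
              x$snp_density, x$n_phase_blocks, x$switch_error_rate))
  cat(sprintf("  counts: depth NB(%g, %g), rho %.3g, pi_ref %.3g\n",
              x$depth_mean, x$depth_dispersion, x$rho, x$pi_ref))
  cat(sprintf("  ASE: fraction %.3g, |log2FC| in [%g, %g]\n",
              x$ase_fraction, x$ase_log2fc_range[1], x$ase_log2fc_range[2]))
  invisible(x)
}

# Structural-variant (deletion) length distribution: log-normal with mean
# 332 bp and sigma 0.8 on the log scale, reproducing the observed span
# from tens of bp to ~10 kb.
sv_length_params <- function() {
  sdlog <- 0.8
  c(meanlog = log(332) - sdlog^2 / 2, sdlog = sdlog)
}

#' Simulate the genome annotation bundle
#'
#' Places non-overlapping genes, ACRs spanning the genic / proximal /
#' distal classes, TE intervals tiling a configurable genome fraction,
#' and deletion SVs whose placement is TE-biased with odds
#' \code{te_enrichment_sv} and whose lengths follow a log-normal with
#' mean 332 bp.
#'
#' @param config A \code{\link{sim_config}}.
#' @return A list with \code{GRanges} elements \code{genes, acrs, tes,
#'   svs} and a named \code{chrom_sizes} vector.
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, "genome"))
  chroms <- paste0("chr", seq_len(config$n_chromosomes))
  sizes <- stats::setNames(rep(config$chrom_length, length(chroms)), chroms)
  si <- GenomeInfoDb::Seqinfo(seqnames = chroms, seqlengths = sizes)

  # genes: one per slot so they never overlap (hence never nest)
  n_per <- diff(round(seq(0, config$n_genes, length.out =
                            config$n_chromosomes + 1)))
  genes <- GenomicRanges::GRanges(seqinfo = si)
  gid <- 0L
  for (i in seq_along(chroms)) {
    n <- n_per[i]
    if (n == 0) next
    slot <- config$chrom_length / n
    if (slot < 1200)
      stop(sprintf(paste0("chromosome %s too short: %d genes need slots of ",
                          ">= 1200 bp but only %.0f bp each are available"),
                   chroms[i], n, slot), call. = FALSE)
    len <- pmin(round(stats::rlnorm(n, log(2000), 0.4)), slot - 400)
    len <- pmax(len, 300)
    start <- round((seq_len(n) - 1) * slot +
                     stats::runif(n, 200, slot - len - 200))
    g <- GenomicRanges::GRanges(chroms[i],
                                IRanges::IRanges(start, width = len),
                                strand = sample(c("+", "-"), n, TRUE),
                                seqinfo = si)
    g$gene_id <- sprintf("gene%05d", gid + seq_len(n))
    gid <- gid + n
    genes <- c(genes, g)
  }

  # ACRs: guarantee all three proximity classes occur
  acrs <- GenomicRanges::GRanges(seqinfo = si)
  if (config$n_acrs > 0 && length(genes) > 0) {
    cls <- sample(c("genic", "proximal", "distal"), config$n_acrs,
                  replace = TRUE, prob = c(0.40, 0.35, 0.25))
    w <- round(stats::runif(config$n_acrs, 200, 800))
    host <- sample(seq_along(genes), config$n_acrs, replace = TRUE)
    hs <- GenomicRanges::start(genes)[host]
    he <- GenomicRanges::end(genes)[host]
    hc <- as.character(GenomicRanges::seqnames(genes))[host]
    start <- integer(config$n_acrs)
    for (k in seq_len(config$n_acrs)) {
      start[k] <- switch(cls[k],
        genic = round(stats::runif(1, hs[k], max(hs[k], he[k] - w[k]))),
        proximal = he[k] + round(stats::runif(1, 50, 2000 - w[k])),
        distal = he[k] + round(stats::runif(1, 2500, 6000)))
    }
    start <- pmax(1L, pmin(start, config$chrom_length - w))
    acrs <- GenomicRanges::GRanges(hc, IRanges::IRanges(start, width = w),
                                   seqinfo = si)
    acrs$acr_id <- sprintf("acr%05d", seq_len(config$n_acrs))
    acrs <- GenomicRanges::sort(acrs)
    acrs$acr_id <- sprintf("acr%05d", seq_along(acrs))
  }

  # TEs tile te_fraction of the genome
  te_classes <- c("DNA/hAT", "DNA/MULE-MuDR", "DNA/CACTA",
                  "LTR/Gypsy", "LTR/Copia", "LINE/L1")
  target <- config$te_fraction * sum(sizes)
  n_te <- max(1L, round(target / 500))
  te_w <- round(stats::rlnorm(n_te, log(450), 0.5))
  te_chr <- sample(chroms, n_te, replace = TRUE,
                   prob = sizes / sum(sizes))
  te_start <- round(stats::runif(n_te, 1, config$chrom_length - te_w))
  tes <- GenomicRanges::GRanges(te_chr,
                                IRanges::IRanges(te_start, width = te_w),
                                seqinfo = si)
  tes$te_class <- sample(te_classes, n_te, replace = TRUE,
                         prob = c(0.2, 0.15, 0.1, 0.3, 0.2, 0.05))
  tes <- GenomicRanges::sort(tes)

  # SVs: log-normal lengths; TE-biased placement by rejection sampling
  svs <- GenomicRanges::GRanges(seqinfo = si)
  if (config$n_svs > 0) {
    lp <- sv_length_params()
    odds <- max(config$te_enrichment_sv, 1e-6)
    n_prom <- round(config$sv_promoter_fraction * config$n_svs)
    sv_list <- vector("list", config$n_svs)
    for (k in seq_len(config$n_svs)) {
      len <- max(20L, round(stats::rlnorm(1, lp["meanlog"], lp["sdlog"])))
      if (k <= n_prom && length(genes) > 0) {
        # seed into a promoter so deletion:gene linkage has signal
        g <- genes[sample(length(genes), 1)]
        tss <- if (as.character(GenomicRanges::strand(g)) == "+")
          GenomicRanges::start(g) else GenomicRanges::end(g)
        off <- round(stats::runif(1, 0, 900))
        st <- if (as.character(GenomicRanges::strand(g)) == "+")
          tss - off - len else tss + off
        sv <- GenomicRanges::GRanges(GenomicRanges::seqnames(g),
                IRanges::IRanges(max(1L, st), width = len), seqinfo = si)
      } else {
        repeat {
          chr <- sample(chroms, 1)
          st <- round(stats::runif(1, 1, sizes[chr] - len))
          sv <- GenomicRanges::GRanges(chr, IRanges::IRanges(st, width = len),
                                       seqinfo = si)
          on_te <- length(GenomicRanges::findOverlaps(sv, tes)) > 0
          if (on_te || stats::runif(1) < 1 / odds) break
        }
      }
      sv_list[[k]] <- sv
    }
    svs <- do.call(c, sv_list)
    svs$sv_id <- sprintf("sv%05d", seq_along(svs))
    svs$haplotype <- sample(c("hap1", "hap2"), length(svs), replace = TRUE)
    svs$sv_type <- "DEL"
  }

  list(genes = genes, acrs = acrs, tes = tes, svs = svs,
       chrom_sizes = sizes, seqinfo = si)
}

#' Simulate phased heterozygous variants with ancestry truth
#'
#' SNPs are placed at \code{snp_density} per kb and partitioned into
#' contiguous phase blocks. Each physical haplotype carries a parental
#' ancestry per block; recombinant blocks change ancestry once within the
#' block, unclassifiable blocks receive no ancestry-informative SNPs.
#' Phase (switch) errors follow a Markov switch process: with probability
#' \code{switch_error_rate} per SNP the observed haplotype labelling
#' toggles and stays toggled until the next switch.
#'
#' @param genome Output of \code{\link{simulate_genome}}.
#' @param config The \code{\link{sim_config}} used to build it.
#' @return A list: \code{variants} (data.frame, one row per SNP with
#'   observed phasing and the \code{informative} flag), \code{blocks}
#'   (block table), \code{parents} (parental genotype table), and
#'   \code{truth} (true ancestry of the observed hap1 label per SNP, true
#'   block classes, switch states).
#' @export
simulate_phased_variants <- function(genome, config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$switch_error_rate >= 0.5)
    stop("switch_error_rate >= 0.5: haplotype labels uninformative",
         call. = FALSE)
  set.seed(derive_seed(config$seed, "variants"))
  chroms <- names(genome$chrom_sizes)
  nb_per <- diff(round(seq(0, config$n_phase_blocks,
                           length.out = length(chroms) + 1)))
  bases <- c("A", "C", "G", "T")

  var_list <- list(); blk_list <- list()
  blk_i <- 0L
  for (ci in seq_along(chroms)) {
    L <- genome$chrom_sizes[ci]
    n_snp <- stats::rpois(1, config$snp_density * L / 1000)
    pos <- sort(sample.int(L, min(n_snp, L)))
    nb <- max(nb_per[ci], 1L)
    cuts <- sort(sample.int(L - 1L, nb - 1L))
    block_of <- findInterval(pos, c(0, cuts)) + blk_i
    for (b in unique(block_of)) {
      blk_i2 <- b
      bp <- pos[block_of == b]
      blk_list[[length(blk_list) + 1L]] <- data.frame(
        block_id = blk_i2, chrom = chroms[ci],
        start = min(bp), end = max(bp), n_snps = length(bp))
    }
    var_list[[ci]] <- data.frame(chrom = chroms[ci], pos = pos,
                                 block_id = block_of)
    blk_i <- blk_i + nb
  }
  v <- do.call(rbind, var_list)
  blocks <- do.call(rbind, blk_list)
  n <- nrow(v)

  v$ref <- sample(bases, n, replace = TRUE)
  v$alt <- vapply(v$ref, function(r) sample(setdiff(bases, r), 1), "")
  # physical haplotype 1 carries ref or alt at random
  h1_is_ref <- sample(c(TRUE, FALSE), n, replace = TRUE)

  # block classes (truth)
  ub <- unique(v$block_id)
  cls <- sample(c("non_recombinant", "recombinant", "unclassified"),
                length(ub), replace = TRUE,
                prob = c(1 - config$recombinant_fraction -
                           config$unclassified_fraction,
                         config$recombinant_fraction,
                         config$unclassified_fraction))
  names(cls) <- ub
  # ancestry of physical hap1 per block; recombinants flip once mid-block
  anc1_block <- sample(c("maternal", "paternal"), length(ub), replace = TRUE)
  names(anc1_block) <- ub

  anc1 <- anc1_block[as.character(v$block_id)]
  for (b in ub[cls[as.character(ub)] == "recombinant"]) {
    idx <- which(v$block_id == b)
    if (length(idx) >= 4) {
      bp <- sample(seq(2, length(idx) - 1), 1)
      flip <- idx[seq(bp, length(idx))]
      anc1[flip] <- ifelse(anc1[flip] == "maternal", "paternal", "maternal")
    } else cls[as.character(b)] <- "non_recombinant"
  }

  # informative SNPs (parents homozygous for alternate alleles)
  informative <- stats::runif(n) < config$informative_fraction
  informative[v$block_id %in% ub[cls[as.character(ub)] == "unclassified"]] <- FALSE

  # Markov switch process per block
  sw_state <- logical(n)
  for (b in ub) {
    idx <- which(v$block_id == b)
    tog <- stats::runif(length(idx)) < config$switch_error_rate
    sw_state[idx] <- as.logical(cumsum(tog) %% 2L)
  }

  h1_allele <- ifelse(h1_is_ref, v$ref, v$alt)
  h2_allele <- ifelse(h1_is_ref, v$alt, v$ref)
  v$hap1_allele <- ifelse(sw_state, h2_allele, h1_allele)
  v$hap2_allele <- ifelse(sw_state, h1_allele, h2_allele)
  v$informative <- informative
  v$snp_id <- sprintf("snp%07d", seq_len(n))

  # parental genotypes: informative -> mother hom(maternal allele),
  # father hom(paternal allele); otherwise both parents heterozygous
  maternal_allele <- ifelse(anc1 == "maternal", h1_allele, h2_allele)
  paternal_allele <- ifelse(anc1 == "maternal", h2_allele, h1_allele)
  gt_of <- function(allele) ifelse(allele == v$ref, "0/0", "1/1")
  parents <- data.frame(
    chrom = v$chrom, pos = v$pos, ref = v$ref, alt = v$alt,
    mother_gt = ifelse(informative, gt_of(maternal_allele), "0/1"),
    father_gt = ifelse(informative, gt_of(paternal_allele), "0/1"),
    stringsAsFactors = FALSE)

  anc2 <- ifelse(anc1 == "maternal", "paternal", "maternal")
  truth <- list(
    hap1_ancestry = ifelse(sw_state, anc2, anc1),  # ancestry behind label 1
    phys_hap1_ancestry = anc1,
    switch_state = sw_state,
    block_class = cls,
    maternal_allele = maternal_allele
  )
  list(variants = v, blocks = blocks, parents = parents, truth = truth)
}

#' Simulate per-assay allelic count tables and expression
#'
#' Per-SNP total depth is negative binomial; the maternal read count is
#' beta-binomial with \code{logit(pi) = logit(pi_ref) + ln(2) * log2FC *
#' coupling[assay]} for SNPs inside genes with true allelic imbalance.
#' WGS counts always use \code{pi = pi_ref} (mapping bias only, no
#' signal). Gene-level log2 expression is a linear function of the true
#' chromatin factor signal plus Gaussian noise at the configured
#' signal-to-noise ratio.
#'
#' @param variants Output of \code{\link{simulate_phased_variants}}.
#' @param genome Output of \code{\link{simulate_genome}}.
#' @param config The shared \code{\link{sim_config}}.
#' @return A list: \code{counts} (one data.frame per assay keyed by the
#'   observed hap1/hap2 labels), \code{region_signal} (gene x factor x
#'   region overall chromatin signal, log scale), \code{expression}
#'   (gene_id, log2_tpm), \code{dnds}, and \code{truth} (per-gene true
#'   log2FC, true coefficient vector, factor signal matrix).
#' @export
simulate_allelic_counts <- function(variants, genome, config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$rho < 0 || config$rho >= 1)
    stop("'rho' must lie in [0, 1)", call. = FALSE)
  set.seed(derive_seed(config$seed, "counts"))
  v <- variants$variants
  n <- nrow(v)
  genes <- genome$genes

  # true ASE effects per gene
  ng <- length(genes)
  is_ase <- stats::runif(ng) < config$ase_fraction
  mag <- stats::runif(ng, config$ase_log2fc_range[1],
                      config$ase_log2fc_range[2])
  gene_log2fc <- ifelse(is_ase, mag * sample(c(-1, 1), ng, TRUE), 0)

  # map SNPs to genes (first overlapping gene); SNPs in ACRs within 5 kb
  # of a gene share that gene's allelic driver (cis-coupling of
  # accessibility and expression)
  vg <- GenomicRanges::GRanges(v$chrom, IRanges::IRanges(v$pos, width = 1))
  ov <- GenomicRanges::findOverlaps(vg, genes, select = "first")
  snp_fc <- ifelse(is.na(ov), 0, gene_log2fc[ov])
  acr_fc <- rep(0, n)
  if (length(genome$acrs) > 0 && ng > 0) {
    dn <- GenomicRanges::distanceToNearest(genome$acrs, genes)
    acr_gene_fc <- rep(0, length(genome$acrs))
    near <- S4Vectors::mcols(dn)$distance <= 5000
    acr_gene_fc[S4Vectors::queryHits(dn)[near]] <-
      gene_log2fc[S4Vectors::subjectHits(dn)[near]]
    ova <- GenomicRanges::findOverlaps(vg, genome$acrs, select = "first")
    acr_fc <- ifelse(is.na(ova), 0, acr_gene_fc[ova])
  }
  snp_fc_chromatin <- ifelse(snp_fc != 0, snp_fc, acr_fc)

  maternal_is_hap1 <- variants$truth$hap1_ancestry == "maternal"
  size_nb <- 1 / config$depth_dispersion

  counts <- list()
  for (assay in assay_registry()) {
    coup <- config$allelic_coupling[[assay]] %||% 0
    if (assay == "WGS") coup <- 0
    fc_here <- if (assay %in% c("RNA_rep1", "RNA_rep2")) snp_fc else
      snp_fc_chromatin
    depth <- stats::rnbinom(n, mu = config$depth_mean, size = size_nb)
    pi_snp <- inv_logit(logit(config$pi_ref) + log(2) * fc_here * coup)
    if (config$rho == 0) {
      m <- stats::rbinom(n, depth, pi_snp)
    } else {
      a <- pi_snp * (1 - config$rho) / config$rho
      b <- (1 - pi_snp) * (1 - config$rho) / config$rho
      m <- stats::rbinom(n, depth, stats::rbeta(n, a, b))
    }
    p <- depth - m
    counts[[assay]] <- data.frame(
      snp_id = v$snp_id, chrom = v$chrom, pos = v$pos,
      block_id = v$block_id,
      hap1_count = ifelse(maternal_is_hap1, m, p),
      hap2_count = ifelse(maternal_is_hap1, p, m),
      assay = assay, stringsAsFactors = FALSE)
  }

  # overall chromatin signal per gene x factor (log scale, centred) and
  # the linear expression model on top of it
  reg <- factor_registry()
  overall_cols <- reg$name[reg$kind == "overall"]
  Z <- matrix(stats::rnorm(ng * length(overall_cols)), nrow = ng,
              dimnames = list(genes$gene_id, overall_cols))
  beta <- stats::setNames(numeric(length(overall_cols)), overall_cols)
  cc <- config$coupling_coefficients
  beta[names(cc)] <- cc
  lin <- as.vector(Z %*% beta)
  sd_noise <- if (sum(beta^2) > 0) sqrt(sum(beta^2) / config$snr) else 1
  log2_tpm <- 5 + lin + stats::rnorm(ng, 0, sd_noise)

  parts <- do.call(rbind, strsplit(colnames(Z),
                                   "_(?=(genic|promoter|upstream_reg|downstream_reg)_overall$)",
                                   perl = TRUE))
  ftype <- parts[, 1]
  fregion <- sub("_overall$", "", parts[, 2])
  region_signal <- data.frame(
    gene_id = rep(rownames(Z), times = ncol(Z)),
    factor_type = rep(ftype, each = nrow(Z)),
    region = rep(fregion, each = nrow(Z)),
    signal = round(as.vector(Z), 6),
    stringsAsFactors = FALSE)

  dnds <- data.frame(gene_id = genes$gene_id,
                     dnds = round(stats::rlnorm(ng, log(0.3), 0.5), 4))

  truth <- list(gene_log2fc = stats::setNames(gene_log2fc, genes$gene_id),
                beta = beta, factor_signal = Z,
                log2_tpm = stats::setNames(log2_tpm, genes$gene_id))
  list(counts = counts,
       region_signal = region_signal,
       expression = data.frame(gene_id = genes$gene_id,
                               log2_tpm = round(log2_tpm, 6)),
       dnds = dnds, truth = truth)
}

#' Simulate per-cytosine haplotype methylation counts
#'
#' Coverage straddles the downstream coverage filter; a configurable
#' fraction of sites receives a true methylation-fraction gap between
#' haplotypes.
#'
#' @param variants Output of \code{\link{simulate_phased_variants}} (used
#'   for chromosome naming only).
#' @param config The shared \code{\link{sim_config}}.
#' @return A list: \code{sites} data.frame (chrom, pos, context,
#'   hap1_meth, hap1_total, hap2_meth, hap2_total) and \code{truth}
#'   (logical vector of injected differential sites).
#' @export
simulate_methylation <- function(variants, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, "methylation"))
  nc <- config$n_cytosines
  chroms <- unique(variants$variants$chrom)
  chrom <- sample(chroms, nc, replace = TRUE)
  pos <- sample.int(config$chrom_length, nc, replace = TRUE)
  cov1 <- stats::rnbinom(nc, mu = 8, size = 2)
  cov2 <- stats::rnbinom(nc, mu = 8, size = 2)
  base <- stats::runif(nc, 0.2, 0.9)
  is_diff <- stats::runif(nc) < config$diff_meth_rate
  gap <- ifelse(is_diff, config$meth_gap * sample(c(-1, 1), nc, TRUE), 0)
  p1 <- pmin(pmax(base + gap / 2, 0.02), 0.98)
  p2 <- pmin(pmax(base - gap / 2, 0.02), 0.98)
  sites <- data.frame(
    chrom = chrom, pos = pos,
    context = sample(c("CpG", "CHG", "CHH"), nc, replace = TRUE),
    hap1_meth = stats::rbinom(nc, cov1, p1), hap1_total = cov1,
    hap2_meth = stats::rbinom(nc, cov2, p2), hap2_total = cov2,
    stringsAsFactors = FALSE)
  o <- order(sites$chrom, sites$pos)
  list(sites = sites[o, ], truth = is_diff[o])
}

#' Simulate GWAS summary statistics and a genotype matrix
#'
#' Non-significant SNP p-values are uniform; \code{n_trait_snps}
#' significant SNPs (below the Bonferroni threshold for the simulated SNP
#' count) are placed with ACR odds multiplied by
#' \code{trait_snp_acr_fold} relative to the uniform background process,
#' so a matched-background enrichment test should recover that fold. The
#' genotype matrix has blocks of correlated dosages for LD analysis.
#'
#' @param genome Output of \code{\link{simulate_genome}}.
#' @param config The shared \code{\link{sim_config}}.
#' @return A list: \code{gwas} data.frame (snp_id, chrom, pos, p, maf,
#'   significant), \code{genotypes} (SNP x accession dosage matrix), and
#'   \code{truth} (ids of the injected trait SNPs).
#' @export
simulate_gwas <- function(genome, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, "gwas"))
  ns <- config$n_gwas_snps
  nt <- min(config$n_trait_snps, ns)
  chroms <- names(genome$chrom_sizes)
  acrs <- genome$acrs
  fold <- config$trait_snp_acr_fold

  draw_pos <- function() {
    chr <- sample(chroms, 1, prob = genome$chrom_sizes /
                    sum(genome$chrom_sizes))
    c(chr = chr, pos = sample.int(genome$chrom_sizes[chr], 1))
  }
  in_acr <- function(chr, pos) {
    length(GenomicRanges::findOverlaps(
      GenomicRanges::GRanges(chr, IRanges::IRanges(pos, width = 1)),
      acrs)) > 0
  }

  # background SNPs: uniform over the genome
  n_bg <- ns - nt
  bg_chr <- sample(chroms, n_bg, replace = TRUE,
                   prob = genome$chrom_sizes / sum(genome$chrom_sizes))
  bg_pos <- vapply(bg_chr, function(ch)
    sample.int(genome$chrom_sizes[ch], 1), 1L)

  # trait SNPs: same spatial process, ACR odds multiplied by `fold`
  tr_chr <- character(nt); tr_pos <- integer(nt)
  for (k in seq_len(nt)) {
    repeat {
      d <- draw_pos()
      hit <- in_acr(d["chr"], as.integer(d["pos"]))
      acc <- if (fold >= 1) (hit || stats::runif(1) < 1 / max(fold, 1e-9))
             else (!hit || stats::runif(1) < fold)
      if (acc) { tr_chr[k] <- d["chr"]; tr_pos[k] <- as.integer(d["pos"]); break }
    }
  }

  bonf <- 0.05 / ns
  gwas <- data.frame(
    snp_id = sprintf("gwas%06d", seq_len(ns)),
    chrom = c(tr_chr, bg_chr),
    pos = c(tr_pos, bg_pos),
    p = c(10^stats::runif(nt, -20, log10(bonf) - 0.5),
          stats::runif(n_bg, bonf * 2, 1)),
    maf = round(stats::runif(ns, 0.03, 0.5), 4),
    stringsAsFactors = FALSE)
  gwas$significant <- gwas$p < bonf
  o <- order(gwas$chrom, gwas$pos)
  gwas <- gwas[o, ]

  # genotype matrix: LD groups of ~20 consecutive SNPs share a latent
  # dosage; 5% per-SNP mutation breaks the correlation slightly
  grp <- cumsum(stats::runif(ns) < 1 / 20)
  G <- matrix(0L, nrow = ns, ncol = config$n_accessions,
              dimnames = list(gwas$snp_id, NULL))
  for (g in unique(grp)) {
    idx <- which(grp == g)
    f <- stats::runif(1, 0.05, 0.5)
    lat <- stats::rbinom(config$n_accessions, 2, f)
    for (i in idx) {
      mut <- stats::runif(config$n_accessions) < 0.05
      G[i, ] <- ifelse(mut, stats::rbinom(config$n_accessions, 2, f), lat)
    }
  }
  list(gwas = gwas, genotypes = G,
       truth = list(trait_snp_ids = gwas$snp_id[gwas$significant]))
}

#' Generate and (optionally) write a complete synthetic study
#'
#' Runs every generator with sub-seeds derived from \code{config$seed}
#' and, when \code{out_dir} is given, writes the standard file bundle:
#' \code{genes.gff3, acrs.bed, tes.bed, svs.bed, variants.vcf,
#' parents.vcf, counts_<assay>.tsv, region_signal.tsv, expression.tsv,
#' dnds.tsv, methylation.tsv, gwas.tsv, genotypes.tsv, blocks.tsv,
#' truth.json}. Ground truth goes only to \code{truth.json}.
#'
#' @param config A \code{\link{sim_config}}.
#' @param out_dir Output directory, or \code{NULL} to skip writing.
#' @return Invisibly, a list with all in-memory pieces
#'   (\code{genome, phased, assays, methylation, gwas}).
#' @export
simulate_study <- function(config = sim_config(), out_dir = NULL) {
  genome <- simulate_genome(config)
  phased <- simulate_phased_variants(genome, config)
  assays <- simulate_allelic_counts(phased, genome, config)
  meth <- simulate_methylation(phased, config)
  gwas <- simulate_gwas(genome, config)
  study <- list(genome = genome, phased = phased, assays = assays,
                methylation = meth, gwas = gwas, config = config)
  if (!is.null(out_dir)) write_study(study, out_dir)
  invisible(study)
}

# Write the study bundle to disk (text formats only).
write_study <- function(study, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  gn <- study$genome
  g <- gn$genes; g$type <- "gene"; g$ID <- g$gene_id
  rtracklayer::export(g, file.path(out_dir, "genes.gff3"), format = "gff3")
  a <- gn$acrs; a$name <- a$acr_id
  rtracklayer::export(a, file.path(out_dir, "acrs.bed"), format = "bed")
  t <- gn$tes; t$name <- t$te_class
  rtracklayer::export(t, file.path(out_dir, "tes.bed"), format = "bed")
  s <- gn$svs; s$name <- paste(s$sv_id, s$haplotype, sep = "|")
  rtracklayer::export(s, file.path(out_dir, "svs.bed"), format = "bed")

  v <- study$phased$variants
  write_phased_vcf(v, file.path(out_dir, "variants.vcf"))
  write_parent_vcf(study$phased$parents, file.path(out_dir, "parents.vcf"))
  write_tsv(study$phased$parents, file.path(out_dir, "parents.tsv"))
  write_tsv(study$phased$blocks, file.path(out_dir, "blocks_sim.tsv"))
  write_tsv(v, file.path(out_dir, "variants.tsv"))

  for (assay in names(study$assays$counts))
    write_tsv(study$assays$counts[[assay]],
              file.path(out_dir, paste0("counts_", assay, ".tsv")))
  write_tsv(study$assays$region_signal,
            file.path(out_dir, "region_signal.tsv"))
  write_tsv(study$assays$expression, file.path(out_dir, "expression.tsv"))
  write_tsv(study$assays$dnds, file.path(out_dir, "dnds.tsv"))
  write_tsv(study$methylation$sites, file.path(out_dir, "methylation.tsv"))
  write_tsv(study$gwas$gwas, file.path(out_dir, "gwas.tsv"))
  utils::write.table(study$gwas$genotypes,
                     file.path(out_dir, "genotypes.tsv"),
                     sep = "\t", quote = FALSE, col.names = FALSE)

  truth <- list(
    hap1_ancestry = study$phased$truth$hap1_ancestry,
    block_class = as.list(study$phased$truth$block_class),
    gene_log2fc = as.list(study$assays$truth$gene_log2fc),
    beta = as.list(study$assays$truth$beta),
    diff_meth = study$methylation$truth,
    trait_snp_ids = study$gwas$truth$trait_snp_ids)
  jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
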