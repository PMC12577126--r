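# Permutation enrichment engines: TE overlap of AS-ACRs against
# length-matched draws from all ACRs, deletions in ASE promoters against
# draws from the ASE-testable gene set, and trait-associated SNPs in
# ACRs against MAF/gene-distance matched background SNPs. Plus LD-block
# definition from dosage correlation and SV genotyping from insertion
# allele frequency.

new_enrichment_result <- function(observed, null, matching, n_query,
                                  no_query = FALSE) {
  fold <- if (no_query || mean(null) == 0) NA_real_ else
    observed / mean(null)
  p <- if (no_query) NA_real_ else
    (sum(null >= observed) + 1) / (length(null) + 1)
  structure(list(observed = observed, null = null, fold = fold, p = p,
                 n_perm = length(null), n_query = n_query,
                 matching = matching, no_query = no_query),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  if (x$no_query) {
    cat("Enrichment test: no query elements (nothing to test)\n")
    return(invisible(x))
  }
  cat(sprintf(
    "Permutation enrichment: observed %.4g, null mean %.4g, fold %.3g, p = %.4g (%d permutations)\n",
    x$observed, mean(x$null), x$fold, x$p, x$n_perm))
  cat("  matching:", x$matching, "\n")
  invisible(x)
}

# sample |query| regions from the universe with lengths matched through
# decile bins of the universe length distribution, without replacement
sample_length_matched <- function(query_w, universe_w, nbins = 10) {
  edges <- unique(stats::quantile(universe_w,
                                  probs = seq(0, 1, length.out = nbins + 1)))
  bin_u <- findInterval(universe_w, edges, rightmost.closed = TRUE,
                        all.inside = TRUE)
  bin_q <- findInterval(query_w, edges, rightmost.closed = TRUE,
                        all.inside = TRUE)
  avail <- split(seq_along(universe_w), bin_u)
  used <- logical(length(universe_w))
  out <- integer(length(query_w))
  for (i in order(query_w)) {
    b <- as.character(bin_q[i])
    cand <- avail[[b]]
    cand <- cand[!used[cand]]
    if (length(cand) == 0) cand <- which(!used)
    # among available candidates, sample uniformly from the 10 nearest
    # in length, so lengths stay matched but draws vary across perms
    cand <- cand[order(abs(universe_w[cand] - query_w[i]))[
      seq_len(min(10L, length(cand)))]]
    pick <- cand[sample.int(length(cand), 1)]
    used[pick] <- TRUE
    out[i] <- pick
  }
  out
}

#' TE-overlap enrichment of a region set by permutation
#'
#' Compares the number of query regions intersecting at least one TE of
#' the requested class set to draws of equally many length-matched
#' regions from the universe (by construction AS-ACRs are a subset of
#' all ACRs).
#'
#' @param query \code{GRanges} of query regions (e.g. AS-ACRs).
#' @param universe \code{GRanges} containing the query (e.g. all ACRs).
#' @param tes \code{GRanges} of TEs with a \code{te_class} column.
#' @param n_perm Number of permutations.
#' @param seed RNG seed.
#' @param classes TE class filter: \code{"all"}, a regex such as
#'   \code{"^DNA/"} (class II) or \code{"^(LTR|LINE|SINE)/"} (class I).
#' @return An \code{enrichment_result}.
#' @export
te_enrichment <- function(query, universe, tes, n_perm = 1000, seed = 1L,
                          classes = "all") {
  if (length(universe) < length(query))
    stop("universe smaller than query", call. = FALSE)
  if (classes != "all" && !is.null(tes$te_class))
    tes <- tes[grepl(classes, tes$te_class)]
  obs <- sum(GenomicRanges::countOverlaps(query, tes) > 0)
  if (length(query) == 0)
    return(new_enrichment_result(0, numeric(n_perm), "length-matched",
                                 0L, no_query = TRUE))
  hit_u <- GenomicRanges::countOverlaps(universe, tes) > 0
  qw <- GenomicRanges::width(query)
  uw <- GenomicRanges::width(universe)
  set.seed(seed)
  null <- vapply(seq_len(n_perm), function(i) {
    idx <- sample_length_matched(qw, uw)
    sum(hit_u[idx])
  }, 0)
  new_enrichment_result(obs, null,
                        "length-decile matched sampling from universe",
                        length(query))
}

#' Deletion enrichment in ASE-gene promoters by permutation
#'
#' Observed statistic: number of ASE-gene promoters overlapping at least
#' one deletion. Null: equally many genes drawn from the ASE-testable
#' set each permutation.
#'
#' @param ase_ids Gene ids called ASE.
#' @param tested_ids Gene ids analysed for ASE (superset).
#' @param promoters \code{GRanges} of promoters with \code{gene_id}.
#' @param deletions \code{GRanges} of deletions.
#' @param n_perm,seed Permutation count and seed.
#' @return An \code{enrichment_result}.
#' @export
sv_promoter_enrichment <- function(ase_ids, tested_ids, promoters,
                                   deletions, n_perm = 1000, seed = 1L) {
  stopifnot(all(ase_ids %in% tested_ids))
  hit <- stats::setNames(
    GenomicRanges::countOverlaps(promoters, deletions) > 0,
    promoters$gene_id)
  obs <- sum(hit[ase_ids], na.rm = TRUE)
  if (length(ase_ids) == 0)
    return(new_enrichment_result(0, numeric(n_perm),
                                 "resampled from tested genes", 0L,
                                 no_query = TRUE))
  set.seed(seed)
  null <- vapply(seq_len(n_perm), function(i)
    sum(hit[sample(tested_ids, length(ase_ids))], na.rm = TRUE), 0)
  new_enrichment_result(obs, null, "resampled from ASE-tested gene set",
                        length(ase_ids))
}

#' Trait-SNP enrichment in ACRs with matched background
#'
#' Query SNPs are those below the Bonferroni threshold for the tested
#' SNP count. Background SNPs are binned by MAF deciles and
#' distance-to-nearest-gene quintiles (edges from the background
#' distribution); each permutation draws one background SNP per query
#' SNP from its bin. Statistic: fraction of SNPs inside ACRs; fold =
#' observed fraction / mean null fraction.
#'
#' @param gwas Data.frame with \code{chrom, pos, p, maf}.
#' @param acrs \code{GRanges} of ACRs.
#' @param genes \code{GRanges} of genes (for the distance matching).
#' @param n_perm,seed Permutation count and seed.
#' @param maf_bins,dist_bins Number of matching bins per axis.
#' @param alpha Family-wise level for the Bonferroni threshold.
#' @return An \code{enrichment_result} with an \code{unmatched} field;
#'   aborts when more than 20\% of query SNPs cannot be matched.
#' @export
trait_snp_acr_enrichment <- function(gwas, acrs, genes, n_perm = 1000,
                                     seed = 1L, maf_bins = 10,
                                     dist_bins = 5, alpha = 0.05) {
  thr <- alpha / nrow(gwas)
  snp_gr <- GenomicRanges::GRanges(gwas$chrom,
                                   IRanges::IRanges(gwas$pos, width = 1))
  in_acr <- GenomicRanges::countOverlaps(snp_gr, acrs) > 0
  dn <- GenomicRanges::distanceToNearest(snp_gr, genes)
  gene_dist <- rep(NA_real_, nrow(gwas))
  gene_dist[S4Vectors::queryHits(dn)] <- S4Vectors::mcols(dn)$distance

  sig <- gwas$p < thr
  if (sum(sig) == 0) {
    r <- new_enrichment_result(NA_real_, numeric(n_perm), "matched", 0L,
                               no_query = TRUE)
    r$unmatched <- character(0)
    return(r)
  }
  bg <- which(!sig)
  qu <- which(sig)

  maf_edges <- unique(stats::quantile(gwas$maf[bg],
                                      seq(0, 1, length.out = maf_bins + 1)))
  dist_edges <- unique(stats::quantile(gene_dist[bg],
                                       seq(0, 1, length.out = dist_bins + 1),
                                       na.rm = TRUE))
  bin_of <- function(i) paste(
    findInterval(gwas$maf[i], maf_edges, rightmost.closed = TRUE,
                 all.inside = TRUE),
    findInterval(gene_dist[i], dist_edges, rightmost.closed = TRUE,
                 all.inside = TRUE))
  bg_bins <- split(bg, bin_of(bg))
  q_bin <- bin_of(qu)
  matched <- q_bin %in% names(bg_bins)
  unmatched_ids <- if ("snp_id" %in% names(gwas))
    gwas$snp_id[qu[!matched]] else as.character(qu[!matched])
  if (mean(!matched) > 0.2)
    stop(sprintf(paste0("%d of %d query SNPs (%.0f%%) fall in empty ",
                        "background bins; matching infeasible"),
                 sum(!matched), length(qu), 100 * mean(!matched)),
         call. = FALSE)
  qu <- qu[matched]; q_bin <- q_bin[matched]
  obs <- mean(in_acr[qu])

  set.seed(seed)
  pools <- bg_bins[q_bin]
  # one matched background SNP per query per permutation
  draws <- vapply(pools, function(pl)
    pl[sample.int(length(pl), n_perm, replace = TRUE)],
    integer(n_perm))
  if (is.null(dim(draws))) draws <- matrix(draws, nrow = n_perm)
  null <- rowMeans(matrix(in_acr[draws], nrow = n_perm))
  r <- new_enrichment_result(obs, null,
    sprintf("MAF %d-iles x gene-distance %d-iles matched background",
            maf_bins, dist_bins), length(qu))
  r$unmatched <- unmatched_ids
  r
}

#' LD blocks around lead SNPs from dosage correlation
#'
#' r-squared is the squared Pearson correlation of 0/1/2 dosage vectors
#' within \code{window} bp of the lead; the block spans the minimum to
#' maximum position of SNPs with \code{r2 > r2_threshold} to the lead
#' (the lead alone when none pass).
#'
#' @param genotypes SNP x accession dosage matrix (rownames = SNP ids);
#'   missing values allowed.
#' @param positions Data.frame \code{snp_id, chrom, pos} aligned with
#'   the matrix rows.
#' @param lead_ids SNP ids of the leads.
#' @param window Half-window in bp.
#' @param r2_threshold Block membership threshold.
#' @return Data.frame: \code{lead_id, chrom, start, end, n_snps};
#'   monomorphic leads yield \code{NA} bounds.
#' @export
ld_blocks <- function(genotypes, positions, lead_ids, window = 1e6,
                      r2_threshold = 0.8) {
  res <- lapply(lead_ids, function(lid) {
    i <- match(lid, positions$snp_id)
    if (is.na(i)) stop("unknown lead SNP: ", lid, call. = FALSE)
    g0 <- genotypes[i, ]
    if (stats::sd(g0, na.rm = TRUE) == 0 || all(is.na(g0)))
      return(data.frame(lead_id = lid, chrom = positions$chrom[i],
                        start = NA_integer_, end = NA_integer_,
                        n_snps = NA_integer_))
    near <- which(positions$chrom == positions$chrom[i] &
                    abs(positions$pos - positions$pos[i]) <= window)
    r2 <- vapply(near, function(j) {
      r <- suppressWarnings(stats::cor(g0, genotypes[j, ],
                                       use = "pairwise.complete.obs"))
      if (is.na(r)) 0 else r^2
    }, 0)
    memb <- near[r2 > r2_threshold]
    memb <- union(memb, i)
    data.frame(lead_id = lid, chrom = positions$chrom[i],
               start = min(positions$pos[memb]),
               end = max(positions$pos[memb]), n_snps = length(memb))
  })
  do.call(rbind, res)
}

#' Genotype a structural variant from its insertion allele frequency
#'
#' Heterozygous when the insertion allele frequency lies in
#' [0.25, 0.75]; homozygous for the insertion above 0.95; homozygous
#' reference below 0.25; the gap (0.75, 0.95] and missing values are
#' no-calls.
#'
#' @param af Insertion allele frequency in [0, 1] (vectorised; NA
#'   allowed).
#' @return Character vector over \code{"+/+", "+/SV", "SV/SV",
#'   "no-call"}.
#' @export
genotype_sv_from_af <- function(af) {
  if (any(af < 0 | af > 1, na.rm = TRUE))
    stop("allele frequency outside [0, 1]", call. = FALSE)
  out <- rep("no-call", length(af))
  out[!is.na(af) & af < 0.25] <- "+/+"
  out[!is.na(af) & af >= 0.25 & af <= 0.75] <- "+/SV"
  out[!is.na(af) & af > 0.95] <- "SV/SV"
  out
}
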