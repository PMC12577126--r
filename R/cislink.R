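# Linking structural variants and allele-specific ACRs to ASE genes
# within phase blocks: deletion:gene pairing with deletion-keyed
# expression ratios, Hedges-g permutation testing of the
# promoter-deletion effect, and AS-ACR:gene allelic correlation.

#' Hedges' g standardized mean difference
#'
#' \code{g = (mean_a - mean_b) / s_pooled * J} with the pooled standard
#' deviation on \code{n_a + n_b - 2} degrees of freedom and the
#' small-sample correction \code{J = 1 - 3 / (4 (n_a + n_b) - 9)}.
#'
#' @param a,b Numeric vectors (each of length >= 2).
#' @return g, or \code{NA} when the pooled variance is zero.
#' @export
hedges_g <- function(a, b) {
  na <- length(a); nb <- length(b)
  if (na < 2 || nb < 2)
    stop("both groups need at least 2 observations", call. = FALSE)
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) /
    (na + nb - 2)
  if (sp2 == 0) return(NA_real_)
  J <- 1 - 3 / (4 * (na + nb) - 9)
  (mean(a) - mean(b)) / sqrt(sp2) * J
}

# block id at an interval midpoint, from the block table
block_at <- function(chrom, mid, blocks) {
  out <- rep(NA_integer_, length(chrom))
  for (i in seq_along(chrom)) {
    hit <- which(blocks$chrom == chrom[i] & blocks$start <= mid[i] &
                   blocks$end >= mid[i])
    if (length(hit)) out[i] <- blocks$block_id[hit[1]]
  }
  out
}

#' Pair ASE genes with their nearest deletion in the same phase block
#'
#' For each ASE gene the nearest deletion on its chromosome
#' (edge-to-edge gap; ties broken toward the smaller SV id) is found;
#' the pair is kept only when gene and deletion fall in the same phase
#' block. The expression ratio is re-keyed so the numerator is the
#' deletion-carrying haplotype:
#' \code{log2((count_del_hap + 1) / (count_alt_hap + 1))}.
#'
#' @param ase_genes \code{GRanges} of ASE genes with \code{gene_id},
#'   \code{maternal_sum}, \code{paternal_sum} (RNA read sums).
#' @param deletions \code{GRanges} with \code{sv_id} and
#'   \code{ancestry} (\code{"maternal"}/\code{"paternal"}).
#' @param blocks Block table (\code{block_id, chrom, start, end}).
#' @param promoter_size Promoter width upstream of the TSS.
#' @return Data.frame of pairs: \code{gene_id, sv_id, sv_in_promoter,
#'   del_ratio} (deletion-keyed log2 expression ratio).
#' @export
pair_deletion_gene <- function(ase_genes, deletions, blocks,
                               promoter_size = 1000) {
  if (length(ase_genes) == 0 || length(deletions) == 0)
    return(data.frame(gene_id = character(0), sv_id = character(0),
                      sv_in_promoter = logical(0), del_ratio = numeric(0)))
  # nearest by gap with deterministic tie-break toward smaller sv_id
  ord <- order(deletions$sv_id)
  deletions <- deletions[ord]
  d <- GenomicRanges::distanceToNearest(ase_genes, deletions,
                                        select = "all")
  qh <- S4Vectors::queryHits(d); sh <- S4Vectors::subjectHits(d)
  pick <- tapply(seq_along(qh), qh, function(i) i[which.min(sh[i])])
  qh <- qh[unlist(pick)]; sh <- sh[unlist(pick)]

  plus <- as.character(GenomicRanges::strand(ase_genes)) != "-"
  tss <- ifelse(plus, GenomicRanges::start(ase_genes),
                GenomicRanges::end(ase_genes))
  prom <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(ase_genes),
    IRanges::IRanges(pmax(ifelse(plus, tss - promoter_size, tss + 1), 1),
                     pmax(ifelse(plus, tss - 1, tss + promoter_size), 1)))

  gmid <- (GenomicRanges::start(ase_genes) +
             GenomicRanges::end(ase_genes)) %/% 2
  smid <- (GenomicRanges::start(deletions) +
             GenomicRanges::end(deletions)) %/% 2
  gblk <- block_at(as.character(GenomicRanges::seqnames(ase_genes)),
                   gmid, blocks)
  sblk <- block_at(as.character(GenomicRanges::seqnames(deletions)),
                   smid, blocks)

  res <- list()
  for (i in seq_along(qh)) {
    g <- qh[i]; s <- sh[i]
    if (is.na(gblk[g]) || is.na(sblk[s]) || gblk[g] != sblk[s]) next
    anc <- deletions$ancestry[s]
    if (is.na(anc)) next
    in_prom <- length(GenomicRanges::findOverlaps(deletions[s],
                                                  prom[g])) > 0
    m <- ase_genes$maternal_sum[g]; p <- ase_genes$paternal_sum[g]
    del_c <- if (anc == "maternal") m else p
    alt_c <- if (anc == "maternal") p else m
    res[[length(res) + 1]] <- data.frame(
      gene_id = ase_genes$gene_id[g], sv_id = deletions$sv_id[s],
      sv_in_promoter = in_prom,
      del_ratio = log2((del_c + 1) / (alt_c + 1)),
      stringsAsFactors = FALSE)
  }
  if (length(res)) do.call(rbind, res) else
    data.frame(gene_id = character(0), sv_id = character(0),
               sv_in_promoter = logical(0), del_ratio = numeric(0))
}

#' Permutation test of the promoter-deletion effect
#'
#' Permutes the promoter/non-promoter group labels (preserving group
#' sizes), recomputing Hedges' g each time;
#' \code{p = (#\{|g_perm| >= |g_obs|\} + 1) / (n_perm + 1)}.
#'
#' @param values Deletion-keyed expression ratios.
#' @param in_promoter Logical group label per pair.
#' @param n_perm Number of permutations (>= 100).
#' @param seed RNG seed.
#' @return List: \code{g_obs}, \code{p}, \code{null} (permuted g's).
#' @export
permute_group_labels <- function(values, in_promoter, n_perm = 1000,
                                 seed = 1L) {
  if (n_perm < 100) stop("n_perm must be at least 100", call. = FALSE)
  if (sum(in_promoter) < 2 || sum(!in_promoter) < 2)
    stop("need at least 2 pairs in each group", call. = FALSE)
  g_obs <- hedges_g(values[in_promoter], values[!in_promoter])
  set.seed(seed)
  n1 <- sum(in_promoter)
  null <- replicate(n_perm, {
    lab <- sample(in_promoter)
    hedges_g(values[lab], values[!lab])
  })
  p <- (sum(abs(null) >= abs(g_obs), na.rm = TRUE) + 1) / (n_perm + 1)
  list(g_obs = g_obs, p = p, null = null)
}

#' Pair allele-specific ACRs with ASE genes and correlate allelic ratios
#'
#' Each AS-ACR is paired with its nearest ASE gene; the pair is kept
#' when both fall in the same phase block, their edge-to-edge gap is at
#' most \code{max_sep}, and no other annotated gene intervenes. The
#' Pearson correlation of the allelic (maternal/paternal, pseudocount 1)
#' log2 ratios of accessibility and expression is computed over pairs.
#'
#' @param as_acrs \code{GRanges} with \code{acr_id, maternal_sum,
#'   paternal_sum} (ATAC read sums).
#' @param ase_genes \code{GRanges} with \code{gene_id, maternal_sum,
#'   paternal_sum} (RNA read sums).
#' @param blocks Block table.
#' @param genes All annotated genes (\code{GRanges}) for the
#'   no-intervening-gene rule; defaults to \code{ase_genes}.
#' @param max_sep Maximum separation in bp.
#' @return List: \code{pairs} data.frame (\code{acr_id, gene_id,
#'   separation, atac_log2fc, rna_log2fc}), \code{correlation},
#'   \code{p_value}, \code{n} (correlation is \code{NA} below 3 pairs).
#' @export
pair_acr_gene <- function(as_acrs, ase_genes, blocks, genes = NULL,
                          max_sep = 5000) {
  if (is.null(genes)) genes <- ase_genes
  empty <- data.frame(acr_id = character(0), gene_id = character(0),
                      separation = numeric(0), atac_log2fc = numeric(0),
                      rna_log2fc = numeric(0))
  if (length(as_acrs) == 0 || length(ase_genes) == 0)
    return(list(pairs = empty, correlation = NA_real_,
                p_value = NA_real_, n = 0L))
  d <- GenomicRanges::distanceToNearest(as_acrs, ase_genes)
  qh <- S4Vectors::queryHits(d); sh <- S4Vectors::subjectHits(d)
  sep <- S4Vectors::mcols(d)$distance

  amid <- (GenomicRanges::start(as_acrs) + GenomicRanges::end(as_acrs)) %/% 2
  gmid <- (GenomicRanges::start(ase_genes) +
             GenomicRanges::end(ase_genes)) %/% 2
  ablk <- block_at(as.character(GenomicRanges::seqnames(as_acrs)),
                   amid, blocks)
  gblk <- block_at(as.character(GenomicRanges::seqnames(ase_genes)),
                   gmid, blocks)

  res <- list()
  for (i in seq_along(qh)) {
    a <- qh[i]; g <- sh[i]
    if (sep[i] > max_sep) next
    if (is.na(ablk[a]) || is.na(gblk[g]) || ablk[a] != gblk[g]) next
    # no intervening gene: nothing strictly between the nearest edges
    lo <- min(GenomicRanges::end(as_acrs)[a],
              GenomicRanges::end(ase_genes)[g]) + 1
    hi <- max(GenomicRanges::start(as_acrs)[a],
              GenomicRanges::start(ase_genes)[g]) - 1
    if (lo <= hi) {
      gapr <- GenomicRanges::GRanges(
        GenomicRanges::seqnames(as_acrs)[a], IRanges::IRanges(lo, hi))
      others <- if (is.null(genes$gene_id)) genes else
        genes[genes$gene_id != ase_genes$gene_id[g]]
      if (length(GenomicRanges::findOverlaps(gapr, others)) > 0) next
    }
    res[[length(res) + 1]] <- data.frame(
      acr_id = as_acrs$acr_id[a], gene_id = ase_genes$gene_id[g],
      separation = sep[i],
      atac_log2fc = log2((as_acrs$maternal_sum[a] + 1) /
                           (as_acrs$paternal_sum[a] + 1)),
      rna_log2fc = log2((ase_genes$maternal_sum[g] + 1) /
                          (ase_genes$paternal_sum[g] + 1)),
      stringsAsFactors = FALSE)
  }
  pairs <- if (length(res)) do.call(rbind, res) else empty
  if (nrow(pairs) >= 3) {
    ct <- stats::cor.test(pairs$atac_log2fc, pairs$rna_log2fc)
    list(pairs = pairs, correlation = unname(ct$estimate),
         p_value = ct$p.value, n = nrow(pairs))
  } else {
    list(pairs = pairs, correlation = NA_real_, p_value = NA_real_,
         n = nrow(pairs))
  }
}
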