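# Per-SNP haplotype counts -> filtered, feature-aggregated allelic
# quantities, plus per-cytosine differential-methylation calls.

#' Remove SNPs covered by fewer than \code{min_total} reads
#'
#' The coverage filter is applied per assay independently; the boundary
#' is strict (total < 10 removed, total = 10 retained).
#'
#' @param counts Data.frame with \code{hap1_count}, \code{hap2_count}
#'   (or \code{maternal_count}/\code{paternal_count}) and \code{assay}.
#' @param min_total Minimum total reads per SNP.
#' @return The retained rows.
#' @export
filter_snp_counts <- function(counts, min_total = 10) {
  if (nrow(counts) == 0) return(counts)
  cols <- intersect(c("hap1_count", "hap2_count",
                      "maternal_count", "paternal_count"), names(counts))
  total <- Reduce(`+`, counts[cols[1:2]])
  counts[total >= min_total, , drop = FALSE]
}

#' Orient haplotype-labelled counts to maternal/paternal
#'
#' Joins a count table to per-SNP hap1 ancestry labels; SNPs of unknown
#' ancestry are dropped (counted in an attribute).
#'
#' @param counts Data.frame with \code{snp_id, hap1_count, hap2_count}.
#' @param ancestry Data.frame with \code{snp_id, hap1_ancestry}.
#' @return Counts with \code{maternal_count}/\code{paternal_count}
#'   columns; attribute \code{"n_unknown"} counts dropped SNPs.
#' @export
orient_counts <- function(counts, ancestry) {
  anc <- ancestry$hap1_ancestry[match(counts$snp_id, ancestry$snp_id)]
  known <- !is.na(anc)
  out <- counts[known, , drop = FALSE]
  a <- anc[known]
  out$maternal_count <- ifelse(a == "maternal", out$hap1_count,
                               out$hap2_count)
  out$paternal_count <- ifelse(a == "maternal", out$hap2_count,
                               out$hap1_count)
  attr(out, "n_unknown") <- sum(!known)
  out
}

#' Aggregate per-SNP allelic counts over features
#'
#' Assigns SNPs to every overlapping feature interval (full gene span or
#' ACR span), sums maternal/paternal counts, and computes the allelic
#' log2 fold change with a pseudocount of 1:
#' \code{log2((maternal + 1) / (paternal + 1))}. Features with fewer
#' than \code{min_snps} retained SNPs are flagged untestable.
#'
#' @param counts Data.frame with \code{chrom, pos, maternal_count,
#'   paternal_count} (already coverage-filtered and oriented).
#' @param features A \code{GRanges} with a \code{feature_id} metadata
#'   column (or \code{gene_id}/\code{acr_id}).
#' @param min_snps Minimum SNPs for a feature to be testable.
#' @return Data.frame: \code{feature_id, n_snps, maternal_sum,
#'   paternal_sum, log2fc, testable}, one row per feature.
#' @export
aggregate_feature <- function(counts, features, min_snps = 2) {
  fid <- features$feature_id %||% features$gene_id %||% features$acr_id
  if (is.null(fid)) stop("features need a feature_id column", call. = FALSE)
  if (nrow(counts) > 0) {
    gr <- GenomicRanges::GRanges(counts$chrom,
                                 IRanges::IRanges(counts$pos, width = 1))
    ov <- GenomicRanges::findOverlaps(gr, features)
    qi <- S4Vectors::queryHits(ov); si <- S4Vectors::subjectHits(ov)
    m <- tapply(counts$maternal_count[qi], fid[si], sum)
    p <- tapply(counts$paternal_count[qi], fid[si], sum)
    ns <- tapply(qi, fid[si], length)
  } else {
    m <- p <- ns <- numeric(0)
  }
  out <- data.frame(feature_id = fid, n_snps = 0L, maternal_sum = 0,
                    paternal_sum = 0, stringsAsFactors = FALSE)
  i <- match(names(ns), fid)
  out$n_snps[i] <- as.integer(ns)
  out$maternal_sum[i] <- as.numeric(m)
  out$paternal_sum[i] <- as.numeric(p)
  out$log2fc <- log2((out$maternal_sum + 1) / (out$paternal_sum + 1))
  out$testable <- out$n_snps >= min_snps
  out
}

#' Call differential methylation per cytosine
#'
#' One-sided Fisher's exact test on the 2x2 table (methylated /
#' unmethylated by haplotype), sided toward the observed difference. A
#' site is differential when combined coverage is at least
#' \code{min_coverage} and the probability of differential methylation
#' (1 - p) is at least \code{min_prob}. Sites with zero coverage on
#' either haplotype are skipped.
#'
#' @param sites Data.frame with \code{hap1_meth, hap1_total, hap2_meth,
#'   hap2_total}.
#' @param min_coverage Combined read-coverage threshold.
#' @param min_prob Probability threshold for a differential call.
#' @return \code{sites} with added \code{p_differential},
#'   \code{is_differential}, and \code{evaluated} columns; skipped and
#'   under-coverage sites have \code{evaluated = FALSE}.
#' @export
call_diff_methylation <- function(sites, min_coverage = 10,
                                  min_prob = 0.7) {
  n <- nrow(sites)
  p <- rep(NA_real_, n)
  cov <- sites$hap1_total + sites$hap2_total
  evaluated <- sites$hap1_total > 0 & sites$hap2_total > 0 &
    cov >= min_coverage
  for (i in which(evaluated)) {
    m1 <- sites$hap1_meth[i]; t1 <- sites$hap1_total[i]
    m2 <- sites$hap2_meth[i]; t2 <- sites$hap2_total[i]
    side <- if (m1 / t1 >= m2 / t2) "greater" else "less"
    tab <- matrix(c(m1, t1 - m1, m2, t2 - m2), nrow = 2)
    p[i] <- stats::fisher.test(tab, alternative = side)$p.value
  }
  sites$p_differential <- p
  sites$evaluated <- evaluated
  sites$is_differential <- evaluated & !is.na(p) & (1 - p) >= min_prob
  sites
}
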