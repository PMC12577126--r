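# Gene x factor matrix: overall and allelic chromatin quantities across
# four gene-relative regions, with explicit missingness rules, the
# per-factor 10th-percentile coverage filter, the WGS allelic-outlier
# gene filter, and SV-presence / dN/dS covariates.

#' The factor registry
#'
#' Seven chromatin data types (ATAC, four histone marks, methylation,
#' WGS coverage) by four gene-relative regions by \{overall, allelic\}
#' = 56 factors, plus three appended covariates: maternal and paternal
#' promoter-deletion indicators and dN/dS.
#'
#' @return Data.frame: \code{name, factor_type, region, kind}.
#' @export
factor_registry <- function() {
  types <- c("ATAC", "H3K4me3", "H3K36me3", "H3K56ac", "H3K27me3",
             "methylation", "WGS")
  regions <- c("genic", "promoter", "upstream_reg", "downstream_reg")
  kinds <- c("overall", "allelic")
  grid <- expand.grid(factor_type = types, region = regions,
                      kind = kinds, stringsAsFactors = FALSE)
  grid$name <- paste(grid$factor_type, grid$region, grid$kind, sep = "_")
  cov <- data.frame(
    factor_type = c("SV", "SV", "dnds"),
    region = c("promoter", "promoter", NA),
    kind = "covariate",
    name = c("maternal_promoter_deletion", "paternal_promoter_deletion",
             "dnds"))
  rbind(grid[, c("name", "factor_type", "region", "kind")],
        cov[, c("name", "factor_type", "region", "kind")])
}

#' Gene-relative analysis regions
#'
#' For each gene: \code{genic} is the full annotated span; the
#' \code{promoter} is the 1 kb strictly upstream of the TSS on the
#' gene's strand; \code{upstream_reg} and \code{downstream_reg} are the
#' ACR-bearing parts of the 5 kb windows beyond the promoter and beyond
#' the gene end, and are absent when no ACR overlaps the window.
#' Minus-strand genes mirror all geometry; regions are clipped to the
#' chromosome.
#'
#' @param genes \code{GRanges} with strand and \code{gene_id}.
#' @param acrs \code{GRanges} of accessible chromatin regions.
#' @param promoter_size Promoter width in bp.
#' @param window Regulatory-window width in bp.
#' @return A \code{GRangesList}-like list per region name; each element
#'   is a \code{GRanges} with \code{gene_id}, containing one range per
#'   gene (regulatory regions only for genes where they exist).
#' @export
assign_regions <- function(genes, acrs, promoter_size = 1000,
                           window = 5000) {
  plus <- as.character(GenomicRanges::strand(genes)) != "-"
  tss <- ifelse(plus, GenomicRanges::start(genes),
                GenomicRanges::end(genes))
  gend <- ifelse(plus, GenomicRanges::end(genes),
                 GenomicRanges::start(genes))
  chr <- as.character(GenomicRanges::seqnames(genes))
  si <- GenomicRanges::seqinfo(genes)

  clip_gr <- function(start, end) {
    start <- pmax(start, 1L)
    lim <- GenomeInfoDb::seqlengths(si)[chr]
    if (any(!is.na(lim))) end <- pmin(end, ifelse(is.na(lim), end, lim))
    ok <- start <= end
    gr <- GenomicRanges::GRanges(chr[ok],
                                 IRanges::IRanges(start[ok], end[ok]),
                                 seqinfo = si)
    gr$gene_id <- genes$gene_id[ok]
    gr
  }
  promoter <- clip_gr(ifelse(plus, tss - promoter_size, tss + 1),
                      ifelse(plus, tss - 1, tss + promoter_size))
  up_win <- clip_gr(ifelse(plus, tss - promoter_size - window,
                           tss + promoter_size + 1),
                    ifelse(plus, tss - promoter_size - 1,
                           tss + promoter_size + window))
  dn_win <- clip_gr(ifelse(plus, gend + 1, gend - window),
                    ifelse(plus, gend + window, gend - 1))
  has_acr <- function(w)
    GenomicRanges::countOverlaps(w, acrs) > 0
  genic <- GenomicRanges::granges(genes)
  genic$gene_id <- genes$gene_id
  list(genic = genic,
       promoter = promoter,
       upstream_reg = up_win[has_acr(up_win)],
       downstream_reg = dn_win[has_acr(dn_win)])
}

#' Classify ACRs by proximity to the nearest gene
#'
#' Overlapping any gene: \code{genic}; otherwise within
#' \code{proximal_dist} bp (gap distance) of the nearest gene:
#' \code{proximal}; otherwise \code{distal}.
#'
#' @param acrs \code{GRanges} of ACRs.
#' @param genes \code{GRanges} of genes.
#' @param proximal_dist Gap threshold in bp.
#' @return Character vector, one class per ACR.
#' @export
classify_acr <- function(acrs, genes, proximal_dist = 2000) {
  if (length(genes) == 0) {
    warning("empty gene set: all ACRs classified distal")
    return(rep("distal", length(acrs)))
  }
  d <- GenomicRanges::distanceToNearest(acrs, genes)
  dist <- rep(NA_real_, length(acrs))
  dist[S4Vectors::queryHits(d)] <- S4Vectors::mcols(d)$distance
  out <- rep("distal", length(acrs))
  out[!is.na(dist) & dist <= proximal_dist] <- "proximal"
  out[GenomicRanges::countOverlaps(acrs, genes) > 0] <- "genic"
  out
}

# sum maternal/paternal counts of one assay over one region set;
# returns per-gene sums aligned to gene_ids
region_allelic_sums <- function(counts, region_gr, gene_ids) {
  m <- stats::setNames(rep(NA_real_, length(gene_ids)), gene_ids)
  p <- m; tot <- m; nsnp <- stats::setNames(rep(0L, length(gene_ids)),
                                            gene_ids)
  if (is.null(counts) || nrow(counts) == 0 || length(region_gr) == 0)
    return(list(m = m, p = p, tot = tot, nsnp = nsnp))
  gr <- GenomicRanges::GRanges(counts$chrom,
                               IRanges::IRanges(counts$pos, width = 1))
  ov <- GenomicRanges::findOverlaps(gr, region_gr)
  qi <- S4Vectors::queryHits(ov)
  gid <- region_gr$gene_id[S4Vectors::subjectHits(ov)]
  if (length(qi)) {
    ms <- tapply(counts$maternal_count[qi], gid, sum)
    ps <- tapply(counts$paternal_count[qi], gid, sum)
    ns <- tapply(qi, gid, length)
    m[names(ms)] <- ms; p[names(ps)] <- ps
    tot[names(ms)] <- ms + ps
    nsnp[names(ns)] <- ns
  }
  list(m = m, p = p, tot = tot, nsnp = nsnp)
}

#' Build the gene-by-factor matrix
#'
#' Overall cells come from the supplied region-signal table; allelic
#' cells are \code{log2((maternal+1)/(paternal+1))} over the phased SNPs
#' of the region and assay, set to \code{NA} when the region has no
#' phased SNP or its total SNP-based read count falls below the 10th
#' percentile for that factor-by-region combination (computed over genes
#' with at least one SNP, after the per-SNP coverage filter). Genes
#' whose genic WGS allelic log-ratio lies beyond 1.5 IQR are dropped
#' entirely. Promoter-deletion indicators are per-haplotype-ancestry
#' overlap flags; dN/dS is passed through.
#'
#' @param genes \code{GRanges} with \code{gene_id}.
#' @param regions Output of \code{\link{assign_regions}}.
#' @param region_signal Long data.frame \code{gene_id, factor_type,
#'   region, signal} with overall quantities.
#' @param counts Named list of coverage-filtered oriented count tables
#'   (assays among ATAC/H3K*/WGS), plus optionally
#'   \code{methylation} with the same maternal/paternal column contract.
#' @param svs \code{GRanges} of deletions with an \code{ancestry} column
#'   (\code{"maternal"}/\code{"paternal"}).
#' @param dnds Data.frame \code{gene_id, dnds}.
#' @param pct_filter Percentile (0-100) below which allelic cells are
#'   masked.
#' @param iqr_mult IQR multiplier for the WGS outlier filter.
#' @return Data.frame, genes x (56 + 3) columns with \code{gene_id};
#'   attributes \code{"registry"} and \code{"n_outliers"}.
#' @export
build_factor_matrix <- function(genes, regions, region_signal, counts,
                                svs = NULL, dnds = NULL,
                                pct_filter = 10, iqr_mult = 1.5) {
  reg <- factor_registry()
  gene_ids <- genes$gene_id
  ng <- length(gene_ids)
  M <- matrix(NA_real_, nrow = ng, ncol = nrow(reg),
              dimnames = list(gene_ids, reg$name))

  # overall cells
  if (!is.null(region_signal) && nrow(region_signal)) {
    key <- paste(region_signal$factor_type, region_signal$region,
                 "overall", sep = "_")
    ok <- key %in% reg$name & region_signal$gene_id %in% gene_ids
    M[cbind(region_signal$gene_id[ok], key[ok])] <- region_signal$signal[ok]
  }

  # allelic cells with NA rules
  assay_of <- c(ATAC = "ATAC", H3K4me3 = "H3K4me3", H3K36me3 = "H3K36me3",
                H3K56ac = "H3K56ac", H3K27me3 = "H3K27me3",
                methylation = "methylation", WGS = "WGS")
  wgs_genic_fc <- rep(NA_real_, ng)
  for (ft in names(assay_of)) {
    ct <- counts[[ft]]
    for (rg in names(regions)) {
      s <- region_allelic_sums(ct, regions[[rg]], gene_ids)
      fc <- log2((s$m + 1) / (s$p + 1))
      fc[s$nsnp == 0] <- NA
      present <- s$nsnp > 0
      if (any(present)) {
        thr <- stats::quantile(s$tot[present], pct_filter / 100,
                               na.rm = TRUE, names = FALSE)
        fc[present & s$tot < thr] <- NA
      }
      M[, paste(ft, rg, "allelic", sep = "_")] <- fc
      if (ft == "WGS" && rg == "genic")
        wgs_genic_fc <- log2((s$m + 1) / (s$p + 1))
    }
  }

  # covariates
  if (!is.null(svs) && length(svs) > 0 && !is.null(svs$ancestry)) {
    prom <- regions$promoter
    for (side in c("maternal", "paternal")) {
      dels <- svs[!is.na(svs$ancestry) & svs$ancestry == side]
      hit <- GenomicRanges::countOverlaps(prom, dels) > 0
      col <- paste0(side, "_promoter_deletion")
      v <- stats::setNames(rep(0, ng), gene_ids)
      v[prom$gene_id[hit]] <- 1
      M[, col] <- v
    }
  } else {
    M[, c("maternal_promoter_deletion", "paternal_promoter_deletion")] <- 0
  }
  if (!is.null(dnds))
    M[, "dnds"] <- dnds$dnds[match(gene_ids, dnds$gene_id)]

  # WGS allelic outlier filter (1.5 x IQR on the genic log-ratio)
  keep <- rep(TRUE, ng)
  v <- wgs_genic_fc
  if (any(!is.na(v))) {
    q <- stats::quantile(v, c(0.25, 0.75), na.rm = TRUE)
    iqr <- q[2] - q[1]
    out_lo <- q[1] - iqr_mult * iqr
    out_hi <- q[2] + iqr_mult * iqr
    keep <- is.na(v) | (v >= out_lo & v <= out_hi)
  }
  out <- data.frame(gene_id = gene_ids[keep],
                    M[keep, , drop = FALSE],
                    check.names = FALSE, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "registry") <- reg
  attr(out, "n_outliers") <- sum(!keep)
  out
}
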