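# Parental ancestry over phase blocks: block classification, filtering of
# discordant SNPs, imputation for uninformative SNPs and for SVs, and
# switch-error estimation. Haplotype labels are arbitrary between blocks;
# ancestry-informative SNPs (parents homozygous for alternate alleles)
# anchor each block's labels to the parents.

count_runs <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0) return(0L)
  1L + sum(x[-1] != x[-length(x)])
}

#' Filter SNPs discordant with the block-haplotype majority
#'
#' Removes informative SNPs whose hap1 ancestry disagrees with the
#' majority over the block, but only when the majority reaches
#' \code{threshold}; an exact 50/50 split never filters (the block is
#' handled as recombinant rather than fabricating a majority).
#'
#' @param ancestry Character vector of hap1 ancestry
#'   (\code{"maternal"}/\code{"paternal"}) for the block's informative
#'   SNPs, in positional order.
#' @param threshold Majority fraction required before minority SNPs are
#'   treated as discordant and removed.
#' @return List: \code{keep} (logical vector), \code{n_removed},
#'   \code{tie} (logical).
#' @export
filter_discordant <- function(ancestry, threshold = 0.5) {
  n <- length(ancestry)
  if (n == 0) stop("no informative SNPs to filter", call. = FALSE)
  nm <- sum(ancestry == "maternal")
  np <- n - nm
  if (nm == np)
    return(list(keep = rep(TRUE, n), n_removed = 0L, tie = TRUE))
  major <- if (nm > np) "maternal" else "paternal"
  frac <- max(nm, np) / n
  if (frac >= threshold) {
    keep <- ancestry == major
    list(keep = keep, n_removed = sum(!keep), tie = FALSE)
  } else {
    list(keep = rep(TRUE, n), n_removed = 0L, tie = FALSE)
  }
}

#' Classify a phase block from its informative SNPs
#'
#' \code{unclassified} if the block contains no ancestry-informative
#' SNPs; after the discordance filter, \code{non_recombinant} if the
#' retained hap1 ancestries are unanimous, \code{recombinant} if the
#' ancestry changes once, and \code{excluded_switching} if it changes
#' repeatedly (three or more runs), mirroring the removal of blocks with
#' repeated haplotype switching.
#'
#' @param ancestry Hap1 ancestry of the block's informative SNPs in
#'   positional order (may be empty).
#' @param chrom Optional chromosome per SNP; mixed chromosomes in one
#'   block are a structural error.
#' @param threshold Passed to \code{\link{filter_discordant}}.
#' @return List: \code{class}, \code{keep} (filter mask over the
#'   informative SNPs), \code{n_removed}.
#' @export
classify_block <- function(ancestry, chrom = NULL, threshold = 0.5) {
  if (!is.null(chrom) && length(unique(chrom)) > 1)
    stop("phase block spans multiple chromosomes", call. = FALSE)
  if (length(ancestry) == 0)
    return(list(class = "unclassified", keep = logical(0), n_removed = 0L))
  f <- filter_discordant(ancestry, threshold)
  runs <- count_runs(ancestry[f$keep])
  cls <- if (runs <= 1) "non_recombinant"
         else if (runs == 2) "recombinant"
         else "excluded_switching"
  list(class = cls, keep = f$keep, n_removed = f$n_removed)
}

#' Impute SNP ancestry within a classified block
#'
#' Non-recombinant blocks propagate the haplotype's unanimous ancestry to
#' every member SNP; recombinant blocks retain only the informative SNPs
#' themselves; unclassified and excluded blocks yield unknowns.
#'
#' @param block_class Output of \code{\link{classify_block}}.
#' @param informative Logical vector over all block SNPs.
#' @param ancestry Hap1 ancestry for informative SNPs (NA elsewhere),
#'   over all block SNPs in positional order.
#' @return Character vector of hap1 ancestry per SNP
#'   (\code{"maternal"}, \code{"paternal"}, or \code{NA} = unknown),
#'   with attribute \code{"source"} (\code{informative}/\code{imputed}).
#' @export
impute_snp_ancestry <- function(block_class, informative, ancestry) {
  n <- length(informative)
  out <- rep(NA_character_, n)
  src <- rep(NA_character_, n)
  if (block_class$class == "non_recombinant") {
    kept <- which(informative)[block_class$keep]
    anc <- unique(ancestry[kept])
    stopifnot(length(anc) == 1)
    out[] <- anc
    src[] <- "imputed"
    src[kept] <- "informative"
  } else if (block_class$class == "recombinant") {
    kept <- which(informative)[block_class$keep]
    out[kept] <- ancestry[kept]
    src[kept] <- "informative"
  }
  attr(out, "source") <- src
  out
}

#' Impute the ancestry of a structural variant
#'
#' In a non-recombinant block the SV inherits the ancestry of its
#' haplotype for the whole block. In a recombinant block the SV takes the
#' majority ancestry of the nearest (up to) 5 labelled SNPs on each side
#' of its midpoint; an exact tie gives unknown.
#'
#' @param sv_mid SV midpoint position (bp).
#' @param snp_pos Positions of the block's ancestry-labelled SNPs.
#' @param snp_ancestry Hap1 ancestry at those SNPs, on the SV's
#'   haplotype scale (caller flips labels for hap2 SVs).
#' @param block_class Block class string.
#' @param block_ancestry Haplotype ancestry of the block when
#'   non-recombinant.
#' @return \code{"maternal"}, \code{"paternal"}, or \code{NA}.
#' @export
impute_sv_ancestry <- function(sv_mid, snp_pos, snp_ancestry,
                               block_class, block_ancestry = NULL) {
  if (block_class == "non_recombinant") {
    stopifnot(!is.null(block_ancestry))
    return(block_ancestry)
  }
  if (block_class != "recombinant") return(NA_character_)
  ok <- !is.na(snp_ancestry)
  snp_pos <- snp_pos[ok]; snp_ancestry <- snp_ancestry[ok]
  if (length(snp_pos) == 0) return(NA_character_)
  up <- which(snp_pos < sv_mid)
  up <- up[order(sv_mid - snp_pos[up])][seq_len(min(5, length(up)))]
  dn <- which(snp_pos >= sv_mid)
  dn <- dn[order(snp_pos[dn] - sv_mid)][seq_len(min(5, length(dn)))]
  votes <- snp_ancestry[c(up, dn)]
  nm <- sum(votes == "maternal"); np <- sum(votes == "paternal")
  if (nm > np) "maternal" else if (np > nm) "paternal" else NA_character_
}

#' Estimate the switch-error rate against an independent label source
#'
#' The rate is the fraction of adjacent within-block transitions at which
#' the agreement between observed and reference hap1 ancestry changes
#' state (a phase switch), evaluated per haplotype.
#'
#' @param observed Observed hap1 ancestry per SNP.
#' @param reference Reference hap1 ancestry (simulation truth or
#'   parental-SNP derived) per SNP.
#' @param block_id Phase-block id per SNP; transitions never cross
#'   blocks.
#' @return List with \code{rate_hap1}, \code{rate_hap2},
#'   \code{n_switches}, \code{n_transitions}; rates are \code{NA} when
#'   fewer than 2 evaluable SNPs exist.
#' @export
estimate_switch_error <- function(observed, reference, block_id) {
  ok <- !is.na(observed) & !is.na(reference)
  observed <- observed[ok]; reference <- reference[ok]
  block_id <- block_id[ok]
  disc <- observed != reference
  nsw <- 0L; ntr <- 0L
  for (b in unique(block_id)) {
    d <- disc[block_id == b]
    if (length(d) < 2) next
    nsw <- nsw + sum(d[-1] != d[-length(d)])
    ntr <- ntr + length(d) - 1L
  }
  rate <- if (ntr == 0) NA_real_ else nsw / ntr
  # hap2 labels are the complement of hap1, so its switch events coincide
  list(rate_hap1 = rate, rate_hap2 = rate,
       n_switches = nsw, n_transitions = ntr)
}

#' Assign ancestry to all phased SNPs of a study
#'
#' Driver over every phase block: derives informative-SNP ancestry from
#' parental homozygous-alternate genotypes, filters discordant SNPs,
#' classifies blocks, and imputes uninformative SNPs.
#'
#' @param variants Variant table (\code{chrom, pos, snp_id, block_id,
#'   hap1_allele, hap2_allele, ref, alt, informative}).
#' @param parents Parental genotype table (\code{chrom, pos, mother_gt,
#'   father_gt, ref, alt}) aligned row-wise with \code{variants}.
#' @param threshold Discordance-filter majority fraction.
#' @return List: \code{ancestry} (snp_id, block_id, hap1_ancestry,
#'   source), \code{blocks} (block_id, class, n_informative, n_removed,
#'   block_hap1_ancestry).
#' @export
assign_ancestry <- function(variants, parents, threshold = 0.5) {
  stopifnot(nrow(variants) == nrow(parents))
  # informative = both parents homozygous, for different alleles
  hom <- function(gt) gt %in% c("0/0", "1/1", "0|0", "1|1")
  informative <- hom(parents$mother_gt) & hom(parents$father_gt) &
    substr(parents$mother_gt, 1, 1) != substr(parents$father_gt, 1, 1)
  m_allele <- ifelse(substr(parents$mother_gt, 1, 1) == "0",
                     variants$ref, variants$alt)
  anc1 <- ifelse(informative,
                 ifelse(variants$hap1_allele == m_allele,
                        "maternal", "paternal"),
                 NA_character_)

  o <- order(variants$block_id, variants$pos)
  idx_by_block <- split(o, variants$block_id[o])
  n <- nrow(variants)
  hap1_anc <- rep(NA_character_, n)
  src <- rep(NA_character_, n)
  blk <- lapply(names(idx_by_block), function(b) {
    idx <- idx_by_block[[b]]
    inf <- informative[idx]
    cl <- classify_block(anc1[idx][inf], chrom = variants$chrom[idx],
                         threshold = threshold)
    imp <- impute_snp_ancestry(cl, inf, anc1[idx])
    hap1_anc[idx] <<- imp
    src[idx] <<- attr(imp, "source")
    anc_block <- if (cl$class == "non_recombinant")
      unique(imp[!is.na(imp)]) else NA_character_
    data.frame(block_id = b, class = cl$class,
               n_informative = sum(inf), n_removed = cl$n_removed,
               block_hap1_ancestry = anc_block %||% NA_character_,
               stringsAsFactors = FALSE)
  })
  blocks <- do.call(rbind, blk)
  list(
    ancestry = data.frame(
      snp_id = variants$snp_id, block_id = variants$block_id,
      hap1_ancestry = hap1_anc, source = src, stringsAsFactors = FALSE),
    blocks = blocks)
}
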