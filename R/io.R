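# Readers/writers for the interchange formats shared by every stage.
# In memory, intervals live in GenomicRanges objects (1-based closed, the
# Bioconductor convention); rtracklayer performs the conversion to BED
# (0-based half-open) and GFF3 (1-based closed) at file boundaries.

#' Read a phased VCF into a variant table
#'
#' Loads biallelic, phased heterozygous records for one sample. The GT
#' field must use the \code{|} phase separator and a \code{PS} (phase set)
#' FORMAT tag identifying the phase block. Records that are unphased,
#' homozygous, multi-allelic or missing PS are skipped and counted.
#'
#' @param path Path to a VCF (plain or gzipped).
#' @param sample Sample name; defaults to the first sample in the file.
#' @return A data.frame with columns \code{chrom, pos, ref, alt,
#'   hap1_allele, hap2_allele, block_id}, with attribute
#'   \code{"skipped"} giving per-reason skip counts.
#' @export
read_phased_vcf <- function(path, sample = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  ps <- suppressWarnings(vcfR::extract.gt(v, element = "PS"))
  if (is.null(sample)) sample <- colnames(gt)[1L]
  g <- gt[, sample]
  p <- if (is.null(ps)) rep(NA_character_, length(g)) else ps[, sample]

  multi <- grepl(",", fix$ALT, fixed = TRUE)
  phased <- grepl("|", g, fixed = TRUE) & !is.na(g)
  al <- matrix(NA_character_, nrow = length(g), ncol = 2)
  sp <- strsplit(ifelse(phased, g, "./."), "|", fixed = TRUE)
  al[phased, ] <- do.call(rbind, sp[phased])
  het <- phased & al[, 1] != al[, 2] & al[, 1] %in% c("0", "1") &
    al[, 2] %in% c("0", "1")
  has_ps <- !is.na(p) & p != "."
  keep <- !multi & het & has_ps

  skipped <- c(
    multiallelic = sum(multi),
    unphased_or_missing = sum(!phased & !multi),
    not_het = sum(phased & !het & !multi),
    no_phase_set = sum(het & !multi & !has_ps)
  )
  alleles <- cbind(fix$REF, fix$ALT)
  out <- data.frame(
    chrom = fix$CHROM[keep],
    pos = as.integer(fix$POS[keep]),
    ref = fix$REF[keep],
    alt = fix$ALT[keep],
    hap1_allele = alleles[cbind(which(keep), as.integer(al[keep, 1]) + 1L)],
    hap2_allele = alleles[cbind(which(keep), as.integer(al[keep, 2]) + 1L)],
    block_id = p[keep],
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  if (!anyNA(suppressWarnings(as.integer(out$block_id))))
    out$block_id <- as.integer(out$block_id)
  attr(out, "skipped") <- skipped
  out
}

#' Write a phased variant table as VCF
#'
#' Inverse of \code{\link{read_phased_vcf}}: one sample, GT phased with
#' \code{|}, PS carrying the phase-block identifier.
#'
#' @param variants Data.frame with the columns produced by
#'   \code{read_phased_vcf}.
#' @param path Output path.
#' @param sample Sample name written in the header.
#' @return \code{path}, invisibly.
#' @export
write_phased_vcf <- function(variants, path, sample = "sample1") {
  gt1 <- ifelse(variants$hap1_allele == variants$ref, "0", "1")
  gt2 <- ifelse(variants$hap2_allele == variants$ref, "0", "1")
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=PS,Number=1,Type=Integer,Description=\"Phase set\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample, sep = "\t")
  )
  rec <- paste(variants$chrom, variants$pos, ".", variants$ref,
               variants$alt, ".", "PASS", ".", "GT:PS",
               paste0(gt1, "|", gt2, ":", variants$block_id), sep = "\t")
  writeLines(c(hdr, rec), path)
  invisible(path)
}

# Write a simple diploid-genotype VCF for the two parents (GT only).
write_parent_vcf <- function(parents, path) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "mother", "father", sep = "\t")
  )
  rec <- paste(parents$chrom, parents$pos, ".", parents$ref, parents$alt,
               ".", "PASS", ".", "GT", parents$mother_gt, parents$father_gt,
               sep = "\t")
  writeLines(c(hdr, rec), path)
  invisible(path)
}

#' Read genomic intervals from BED or GFF3
#'
#' @param path File path.
#' @param dialect \code{"BED"} or \code{"GFF3"}; inferred from the
#'   extension when missing.
#' @return A \code{GRanges}; GFF3 attribute columns are kept as metadata.
#' @export
read_intervals <- function(path, dialect = c("auto", "BED", "GFF3")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.gff3?(\\.gz)?$", path, ignore.case = TRUE))
      "GFF3" else "BED"
  }
  gr <- if (dialect == "GFF3") rtracklayer::import(path, format = "gff3")
        else rtracklayer::import(path, format = "bed")
  if (any(GenomicRanges::width(gr) < 1L))
    stop("interval with start >= end in ", path, call. = FALSE)
  gr
}

#' Write genomic intervals to BED or GFF3
#'
#' @param gr A \code{GRanges}.
#' @param path Output path; extension selects the dialect.
#' @return \code{path}, invisibly.
#' @export
write_intervals <- function(gr, path) {
  fmt <- if (grepl("\\.gff3?$", path, ignore.case = TRUE)) "gff3" else "bed"
  rtracklayer::export(gr, path, format = fmt)
  invisible(path)
}

#' Validate and load an allelic-count table
#'
#' Checks a per-SNP haplotype-split count table against the assay
#' registry: integer non-negative counts and no duplicated
#' (chrom, pos, assay) keys.
#'
#' @param x Path to a TSV or a data.frame with columns
#'   \code{chrom, pos, block_id, hap1_count, hap2_count} and optionally
#'   \code{assay}.
#' @param assay Assay name to stamp on the table when it lacks an
#'   \code{assay} column; must belong to \code{\link{assay_registry}}.
#' @return The validated data.frame.
#' @export
validate_counts <- function(x, assay = NULL) {
  df <- if (is.character(x)) read_tsv(x) else x
  need <- c("chrom", "pos", "hap1_count", "hap2_count")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("count table missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!"assay" %in% names(df)) {
    if (is.null(assay)) stop("no 'assay' column and no assay given",
                             call. = FALSE)
    df$assay <- assay
  }
  bad_assay <- setdiff(unique(df$assay), assay_registry())
  if (length(bad_assay))
    stop("unknown assay(s): ", paste(bad_assay, collapse = ", "),
         call. = FALSE)
  for (cc in c("hap1_count", "hap2_count")) {
    v <- df[[cc]]
    if (any(is.na(v)) || any(v < 0) || any(v != round(v))) {
      bad <- which(is.na(v) | v < 0 | v != round(v))[1L]
      stop(sprintf("invalid count in '%s' at row %d", cc, bad),
           call. = FALSE)
    }
  }
  key <- paste(df$chrom, df$pos, df$assay)
  if (anyDuplicated(key)) {
    stop("duplicate (chrom, pos, assay) rows, first at row ",
         which(duplicated(key))[1L], call. = FALSE)
  }
  df
}
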