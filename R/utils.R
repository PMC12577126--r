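# internal helpers shared across modules

# Derive a reproducible child seed from a master seed and a label.
# Keeps results stable when stages are added/removed: each stage's stream
# depends only on (seed, label), never on execution order.
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(as.character(label)) * seq_along(utf8ToInt(as.character(label))))
  as.integer((as.numeric(seed) * 48271 + h) %% .Machine$integer.max)
}

logit <- function(p) log(p / (1 - p))
inv_logit <- function(x) 1 / (1 + exp(-x))

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar_prob <- function(x, name, open = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop(sprintf("'%s' must be a single number", name), call. = FALSE)
  lo_ok <- if (open) x > 0 else x >= 0
  hi_ok <- if (open) x < 1 else x <= 1
  if (!lo_ok || !hi_ok)
    stop(sprintf("'%s' must lie in %s", name,
                 if (open) "(0,1)" else "[0,1]"), call. = FALSE)
  invisible(x)
}

# write a data.frame as a TSV with NA tokens, no quoting
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Registry of allelic-count assays
#'
#' The fixed set of assays for which per-SNP haplotype-split read counts are
#' recognised: two RNA-seq replicates, ATAC-seq, four ChIP-seq histone
#' marks, and whole-genome sequencing (the mapping-bias calibration data).
#'
#' @return Character vector of assay names.
#' @export
assay_registry <- function() {
  c("RNA_rep1", "RNA_rep2", "ATAC",
    "H3K4me3", "H3K36me3", "H3K56ac", "H3K27me3", "WGS")
}
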