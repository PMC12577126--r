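# shared fixtures, built once per test run

.fixture_env <- new.env(parent = emptyenv())

# small but complete synthetic study, cached across test files
small_config <- function(...) {
  args <- utils::modifyList(
    list(n_chromosomes = 2L, chrom_length = 6e5, n_genes = 80L,
         n_acrs = 100L, n_svs = 40L, n_phase_blocks = 12L,
         snp_density = 4, seed = 101L),
    list(...))
  do.call(sim_config, args)
}

get_small_study <- function() {
  if (is.null(.fixture_env$study))
    .fixture_env$study <- simulate_study(small_config())
  .fixture_env$study
}

# GRanges helper for terse interval construction in tests
gr <- function(chrom, start, end, strand = "*", ...) {
  g <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end),
                              strand = strand)
  mc <- list(...)
  for (nm in names(mc)) S4Vectors::mcols(g)[[nm]] <- mc[[nm]]
  g
}
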