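---
title: "Methods: haplotype-resolved cis-regulatory analysis with haplocis"
author: "haplocis authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: haplotype-resolved cis-regulatory analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Overview

`haplocis` analyses cis-regulatory variation between the two haplotypes of
a highly heterozygous individual — the setting of an interspecific hybrid
plant whose variants have been phased into blocks and whose functional
genomics data (RNA-seq, ATAC-seq, ChIP-seq for four histone marks,
whole-genome and bisulfite sequencing) have been split into per-haplotype
read counts at heterozygous SNPs. The pipeline runs in eight stages:

1. **simulate** — generate a synthetic study with known ground truth;
2. **ancestry** — anchor haplotype labels to the two parents per phase
   block and impute ancestry for uninformative SNPs and SVs;
3. **allelic** — coverage-filter per-SNP counts, orient them to
   maternal/paternal, aggregate over genes and ACRs, call differential
   methylation;
4. **ase** — test genes and accessible chromatin regions (ACRs) for
   allele-specific signal under a WGS-calibrated beta-binomial null;
5. **features** — build a gene-by-factor matrix of chromatin quantities
   over four gene-relative regions;
6. **model** — elastic-net regression of expression on those factors;
7. **link** — pair deletions and allele-specific ACRs with
   allele-specifically expressed (ASE) genes within phase blocks;
8. **enrich** — permutation enrichment tests with matched backgrounds.

All of it is driven by `run_pipeline()`, which writes per-stage files and
a hashed manifest into one run directory; identical configuration and
seed reproduce identical bytes.

# The allele-specific calling model

At a heterozygous SNP covered by $n$ reads of which $m$ support the
maternal haplotype, the null model for $m$ is beta-binomial,

$$m \sim \mathrm{BetaBin}(n, \pi, \rho),$$

parameterised by the mean marginal probability of success $\pi$ and the
intra-class overdispersion $\rho \in [0,1)$; $\rho = 0$ recovers the
binomial. Both parameters are fitted by maximum likelihood to
**whole-genome sequencing** counts over the same feature class (genes or
ACRs) being tested. WGS carries no true allelic expression signal, so
$\hat\pi \ne 0.5$ measures reference-mapping bias and $\hat\rho$ absorbs
extra-binomial count noise; fitting the null on WGS therefore corrects
both at once. A method-of-moments estimate (Kleinman's weighted
estimator) is always computed as a cross-check and used as a fallback if
the optimiser fails (flagged in the output).

Each SNP's evidence is the two-sided beta-binomial tail probability of
the observed maternal count under $(\hat\pi, \hat\rho)$ — defined as
$2\min(P(X \le m), P(X \ge m))$ capped at 1, ties included — converted to
a signed z-score via the inverse normal, with the sign given by the
direction of the maternal deviation from $\hat\pi$. Per feature, SNP
z-scores are pooled with Stouffer's method, $Z = \sum_i z_i / \sqrt{k}$.
Significance comes from a parametric bootstrap: maternal counts are
redrawn from the fitted null at the feature's observed depths, the
pooled statistic recomputed, and
$p = (\#\{|Z^\ast| \ge |Z|\} + 1)/(B + 1)$. Benjamini–Hochberg FDR is
applied within each replicate; a gene is called ASE only when it passes
FDR 0.05 in **both** RNA replicates with agreeing fold-change signs,
while ACRs (one ATAC library) use the single-replicate rule. The
descriptive effect size is the allelic log2 ratio with a pseudocount of
1, $\log_2((m+1)/(p+1))$, used consistently wherever allelic ratios are
compared or correlated.

Two properties of this construction are verified by the test suite: with
all assays sharing a simulated mapping bias of $\pi = 0.55$, the
WGS-calibrated null keeps the false-positive rate at its nominal level
while a naive binomial(0.5) test is strongly anti-conservative; and
empirical p-values of null features pass a Kolmogorov–Smirnov uniformity
check.

## Per-SNP effect definition

The upstream literature reports unitless per-SNP "effect sizes" without
a printed formula. This package standardises on the signed z from the
two-sided beta-binomial tail as the inferential per-SNP statistic and
reports the allelic log2 ratio separately as the descriptive effect;
nothing downstream depends on the descriptive scale.

# Ancestry over phase blocks

Within a phase block, haplotype labels (1/2) are arbitrary but
consistent; between blocks they are not. SNPs where the two parents are
homozygous for alternate alleles ("informative", about 10% in the
default simulation, the sparsity typical of a hybrid cross) anchor the
labels: haplotype 1 is maternal at such a SNP iff it carries the
maternal parent's allele.

Blocks are classified from the informative-SNP ancestry sequence:

* **unclassified** — no informative SNPs; all SNPs stay unknown.
* SNPs discordant with the block majority are filtered when a strict
  majority exists (threshold parameter, default any majority > 50%;
  exact ties never filter — a majority is never fabricated).
* **non_recombinant** — unanimous after filtering; every SNP in the
  block inherits the haplotype's ancestry (source flagged
  `informative` vs `imputed`).
* **recombinant** — ancestry changes once; only informative SNPs keep
  labels.
* **excluded_switching** — three or more ancestry runs survive the
  filter (repeated haplotype switching); the block is dropped.

The majority threshold deserves comment, because phasing switch errors
interact with it. Switch errors are generated (and estimated) as a
Markov switch process: with probability $r$ per SNP the labelling flips
and stays flipped. Under that process a lenient (>50%) majority filter
absorbs switch-error tracts and classifies blocks the way a pedigree
block census typically looks (the vast majority non-recombinant); a strict
threshold (say 75%) instead leaves many blocks with several ancestry
runs and excludes them. The cost of the lenient default is that a
genuinely recombinant block whose informative SNPs happen to have a
majority on one side of the breakpoint is absorbed into
`non_recombinant` with the minority segment mislabelled; the
`threshold` argument exposes this trade-off for sensitivity analysis.

The switch-error rate is estimated as the fraction of adjacent
within-block transitions at which the discordance state between the
assigned labels and an independent reference (simulation truth, or
parental SNPs) changes. Under the Markov switch model this estimator
recovers the generating rate exactly in expectation, which the
acceptance suite checks against a binomial confidence interval at
$r = 0.03$ (the magnitude typical of linked-read phasing).

Structural variants take their block haplotype's ancestry in
non-recombinant blocks; in recombinant blocks they take the majority of
the nearest five labelled SNPs on each side of the SV midpoint (ties are
unknown). The midpoint anchor is a package choice; nothing in the data
dictates another.

# The factor matrix

For each gene, four regions are defined: **genic** (the annotated
span), **promoter** (1 kb strictly upstream of the TSS on the gene's
strand), and **upstream/downstream regulatory** (the ACR-bearing parts
of the 5 kb windows beyond the promoter and beyond the gene end, present
only when an ACR overlaps the window). Minus-strand genes mirror the
geometry; regions are clipped at chromosome edges.

Seven data types (ATAC, H3K4me3, H3K36me3, H3K56ac, H3K27me3,
methylation, WGS coverage) × four regions × {overall, allelic} give the
56 factors; indicators for a maternal or paternal deletion overlapping
the promoter and a dN/dS column are appended. Allelic cells are the
pseudocount log2 ratio over the region's phased SNPs and are set to NA
when the region has no phased SNP or when its total SNP-based read count
falls below the 10th percentile for that factor × region combination
(computed over genes with at least one SNP, after the per-SNP coverage
filter — the order is fixed and tested). Genes whose genic WGS allelic
log-ratio lies outside 1.5 × IQR are dropped entirely, removing
copy-number and collapsed-repeat artefacts. Missingness is explicit
(`NA`), never coded as zero.

# Elastic-net modelling

`fit_enet_cv()` grid-searches the L1/L2 mixing parameter
$\alpha \in \{0.1, \dots, 1.0\}$ and a 100-point lambda path with 5-fold
cross-validation, using glmnet for the path fits. Because the factor
matrix has structural missingness, missing cells are mean-imputed
**inside each training fold** and the fold means are applied to the
held-out fold — the imputation never sees test data. Fold membership is
derived from gene identifiers, not row order, so permuting the input
leaves the fit bit-identical. Both the in-sample and the
cross-validated Pearson correlation between predicted and observed
response are reported, since either convention appears in published
model fits. The reduced model takes the largest lambda whose CV
mean-squared error is within one standard error of the minimum
(`reduce_1se()`); its support provably shrinks. On simulated matrices
(1,900 genes, 5 true coefficients among 56, signal-to-noise 2) the
recovered coefficient vector correlates with truth above 0.9 with all
true signs correct.

# Linkage and enrichment

Deletion:gene pairs take, for each ASE gene, its nearest deletion
(edge-to-edge gap, ties to the smaller SV id) and are kept when both lie
in the same phase block. Expression ratios are re-keyed so the
numerator is the deletion-carrying haplotype, which makes the statistic
invariant to a global maternal/paternal relabelling. The
promoter-deletion effect is Hedges' g
($J = 1 - 3/(4N - 9)$ small-sample correction) with a label-permutation
p-value. ACR:gene pairs additionally require separation of at most 5 kb
and no intervening annotated gene, and yield the Pearson correlation of
the two allelic log2 ratios.

Enrichment engines share one contract: observed statistic, a permuted
null vector, fold = observed / mean(null), and the +1/+1 one-sided
p-value. TE enrichment resamples length-matched region sets from the
ACR universe: universe regions are binned by length decile and each
query picks uniformly among the ten nearest-length unused candidates in
its bin. (A deterministic nearest-length assignment would produce the
same draw every permutation and a degenerate null; the binned sampler
keeps total resampled length within 5% of the query set, which is
tested.) Trait-SNP enrichment in ACRs compares Bonferroni-significant
GWAS SNPs against background SNPs matched on MAF deciles × gene-distance
quintiles with bin edges from the background distribution; queries in
empty bins are reported, and more than 20% unmatched aborts with
diagnostics. SV genotypes from insertion allele frequency follow fixed
bands: [0.25, 0.75] heterozygous, > 0.95 homozygous insertion, < 0.25
homozygous reference, and the (0.75, 0.95] gap is a deliberate no-call.

# The synthetic-data generator

`simulate_study()` emulates the statistical structure the analyses
assume, not sequences: interval annotations (genes placed one per slot
so they never nest; ACRs spanning genic/proximal/distal classes; TEs
tiling 20% of the genome; deletion SVs with log-normal lengths of mean
332 bp and TE-biased placement at 2× odds), phased variants in blocks
with ancestry truth, switch errors, recombinant and unclassifiable
blocks, and per-assay allelic counts. Depth is negative binomial with
mean 60 and dispersion 0.3 — chosen so both sides of the 10-read
coverage filter occur; the maternal count is beta-binomial with
$\mathrm{logit}(\pi) = \mathrm{logit}(\pi_{\mathrm{ref}}) + \ln 2 \cdot
\beta_a \cdot \mathrm{log2FC}$, where the per-assay coupling $\beta_a$
is 1 for RNA, 0.8 for ATAC, positive for activating marks, negative for
H3K27me3, and 0 for WGS. SNPs inside ACRs within 5 kb of a gene share
the gene's allelic driver, so allele-specific accessibility and
expression are genuinely coupled in cis. Overall chromatin signal is a
standard-normal gene × factor matrix on the log scale, and log2
expression is a sparse linear function of it (five nonzero coefficients
by default) at signal-to-noise 2. Two RNA replicates share true effects
with independent counting noise, because the ASE call demands
cross-replicate consistency. GWAS trait SNPs are placed by rejection
sampling with ACR odds multiplied by the configured fold relative to
the uniform background process, so a matched-background test should
recover that fold — and does, within sampling error, in the acceptance
suite.

What the generator does **not** emulate: read-level artefacts
(alignment, duplicates, WASP filtering), linkage disequilibrium between
the phased SNPs themselves, genuine TE biology, dosage from real
populations, or any sequence content. Passing tests therefore
demonstrate the statistical machinery — calibration, recovery,
invariances — not robustness to upstream bioinformatics.

Default problem sizes (3 chromosomes × 2 Mb, 240 genes, 300 ACRs,
~24,000 SNPs, 4,000 bootstrap replicates per feature) are chosen so a
full pipeline run takes about a minute on one CPU while every analysis
stage still has enough features to exercise its statistics; all counts
scale through `sim_config()`.

# Numerical choices and edge cases

* Empirical p-values always use the $(+1)/(+1)$ estimator — never zero.
* Two-sided tails are floored at the smallest positive double before the
  inverse-normal map, so extreme counts give large finite z rather than
  infinities.
* Per-feature bootstrap streams derive from the master seed and the
  feature index, so results are independent of execution order.
* Degenerate cases return typed results rather than crashing: zero
  significant GWAS SNPs (a no-query result), zero pooled variance in
  Hedges' g (missing), monomorphic LD leads (missing bounds), features
  with fewer than 2 SNPs (untestable flag).
* Coordinates follow the Bioconductor convention in memory (GRanges,
  1-based closed); BED (0-based half-open) and GFF3 (1-based closed)
  conversions happen only at file boundaries via rtracklayer, and the
  round-trips are tested.
* The methylation "probability of differential methylation" is
  operationalised as $1 - p$ of the one-sided Fisher exact test, sided
  toward the observed difference; sites need combined coverage ≥ 10 and
  probability ≥ 0.7 to be called.

# Known limitations

* Recombinant-block detection is deliberately conservative under the
  lenient majority filter (see above); block-level ancestry errors
  propagate to oriented counts as sign flips for genes inside
  mislabelled segments, and the pipeline tests tolerate a small rate of
  such flips rather than pretending they cannot happen.
* The beta-binomial null is fitted per assay and feature class but not
  per feature; features with atypical local mapping bias are only
  partially corrected.
* Mean imputation in the elastic net is unbiased under ignorable
  missingness; the 10th-percentile masking rule is not ignorable in
  principle, and indicator columns for missingness are available but
  off by default.
* The trait-SNP matching uses fixed decile/quintile bins rather than
  continuous matching; very skewed background distributions can leave
  sparse bins.
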