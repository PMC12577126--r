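# Allele-specific expression / accessibility calling: beta-binomial null
# fitted to WGS allelic counts (absorbing reference-mapping bias),
# per-SNP two-sided tail probabilities converted to signed z-scores,
# Stouffer pooling over features, parametric-bootstrap empirical
# p-values, and BH FDR with cross-replicate consistency.

#' Fit the beta-binomial null to WGS allelic counts
#'
#' Maximum-likelihood fit of the mean marginal success probability
#' \code{pi} and overdispersion \code{rho} to maternal counts given
#' totals, on whole-genome sequencing reads over the tested feature
#' class. Because WGS carries no allelic signal, the fit captures
#' reference-mapping bias (\code{pi != 0.5}) and count overdispersion;
#' method-of-moments estimates are reported as a cross-check and used as
#' a fallback when the optimizer fails.
#'
#' @param maternal Maternal (or hap1) read counts.
#' @param total Total read counts per SNP.
#' @param min_obs Minimum observations required.
#' @return Object of class \code{betabin_null}: \code{pi_hat, rho_hat,
#'   n_obs, loglik, converged, pi_mom, rho_mom}.
#' @export
fit_betabin_null <- function(maternal, total, min_obs = 50) {
  ok <- !is.na(maternal) & !is.na(total) & total > 0
  m <- maternal[ok]; n <- total[ok]
  if (length(m) < min_obs)
    stop("need at least ", min_obs, " SNP observations to fit the null",
         call. = FALSE)

  # method of moments (Kleinman weighted estimator)
  w <- n
  pi_mom <- sum(m) / sum(n)
  f <- m / n
  s2 <- sum(w * (f - pi_mom)^2)
  N <- length(n)
  denom <- pi_mom * (1 - pi_mom) *
    (sum(w) - sum(w^2) / sum(w))
  # decompose: E[s2] = pi(1-pi) [ (N-1) + rho (sum w - N - ...) ] approx
  nbar <- sum(w) / N
  rho_mom <- if (denom > 0) {
    (s2 / (pi_mom * (1 - pi_mom)) - (N - 1)) /
      (sum(w) - N - (sum(w^2) / sum(w) - 1))
  } else 0
  rho_mom <- min(max(rho_mom, 0), 0.99)

  nll <- function(par) {
    pi <- inv_logit(par[1])
    rho <- inv_logit(par[2])
    if (rho < 1e-8) rho <- 1e-8
    a <- pi * (1 - rho) / rho
    b <- (1 - pi) * (1 - rho) / rho
    -sum(lchoose(n, m) + lbeta(m + a, n - m + b) - lbeta(a, b))
  }
  start <- c(logit(min(max(pi_mom, 1e-3), 1 - 1e-3)),
             logit(min(max(rho_mom, 1e-4), 0.9)))
  fit <- tryCatch(stats::optim(start, nll, method = "Nelder-Mead",
                               control = list(maxit = 2000)),
                  error = function(e) NULL)
  converged <- !is.null(fit) && fit$convergence == 0
  if (converged) {
    pi_hat <- inv_logit(fit$par[1])
    rho_hat <- inv_logit(fit$par[2])
    if (rho_hat <= 1.1e-8) rho_hat <- 0
    ll <- -fit$value
  } else {
    warning("beta-binomial MLE did not converge; using method of moments")
    pi_hat <- pi_mom; rho_hat <- rho_mom
    ll <- -nll(c(logit(pi_hat), logit(max(rho_hat, 1e-6))))
  }
  structure(list(pi_hat = pi_hat, rho_hat = rho_hat,
                 n_obs = length(m), loglik = ll, converged = converged,
                 pi_mom = pi_mom, rho_mom = rho_mom),
            class = "betabin_null")
}

#' @export
print.betabin_null <- function(x, ...) {
  cat(sprintf(
    "Beta-binomial null: pi = %.4f, rho = %.4f (n = %d SNPs%s)\n",
    x$pi_hat, x$rho_hat, x$n_obs,
    if (x$converged) "" else "; MoM fallback"))
  cat(sprintf("  method of moments: pi = %.4f, rho = %.4f\n",
              x$pi_mom, x$rho_mom))
  invisible(x)
}

# two-sided beta-binomial tail probability and signed z for a vector of
# (maternal, total) pairs under a fitted null; ties at the observed count
# are included in the tail, p = 2*min(lower, upper) capped at 1.
bb_two_sided <- function(m, n, pi, rho) {
  lower <- pbetabinom(m, n, pi, rho)
  upper <- 1 - pbetabinom(m - 1, n, pi, rho)
  pmin(2 * pmin(lower, upper), 1)
}

#' Per-SNP allelic effect statistic
#'
#' Two-sided beta-binomial tail probability of the observed maternal
#' count under the fitted null, converted to a signed z-score through the
#' inverse normal; the sign is the direction of the maternal deviation
#' from \code{pi_hat}.
#'
#' @param maternal,paternal Read counts at the SNP.
#' @param null A \code{\link{fit_betabin_null}} object (or a list with
#'   \code{pi_hat} and \code{rho_hat}).
#' @return Data.frame: \code{p_two_sided, z, effect} where \code{effect}
#'   is the descriptive allelic log2 ratio (pseudocount 1).
#' @export
snp_effect <- function(maternal, paternal, null) {
  if (is.null(null$pi_hat) || null$pi_hat <= 0 || null$pi_hat >= 1)
    stop("degenerate null: pi_hat must lie in (0, 1)", call. = FALSE)
  n <- maternal + paternal
  p2 <- pmax(bb_two_sided(maternal, n, null$pi_hat, null$rho_hat),
             .Machine$double.xmin)
  s <- sign(maternal / n - null$pi_hat)
  z <- s * stats::qnorm(p2 / 2, lower.tail = FALSE)
  data.frame(p_two_sided = p2, z = z,
             effect = log2((maternal + 1) / (paternal + 1)))
}

#' Pool per-SNP z-scores with Stouffer's method
#'
#' @param z Vector of per-SNP z-scores.
#' @return \code{sum(z) / sqrt(length(z))}.
#' @export
pool_stouffer <- function(z) {
  if (length(z) == 0) stop("empty z vector", call. = FALSE)
  if (any(!is.finite(z)))
    stop("non-finite z at SNP index ",
         paste(which(!is.finite(z)), collapse = ", "), call. = FALSE)
  sum(z) / sqrt(length(z))
}

# z lookup tables per distinct total, so bootstrap draws map to z by
# indexing rather than recomputing tail sums
build_z_tables <- function(totals, pi, rho) {
  ut <- sort(unique(totals))
  tabs <- vector("list", length(ut))
  names(tabs) <- as.character(ut)
  for (i in seq_along(ut)) {
    n <- ut[i]
    x <- 0:n
    if (rho == 0) {
      cdf <- stats::pbinom(x, n, pi)
      cdfm1 <- c(0, cdf[-length(cdf)])
    } else {
      d <- dbetabinom(x, n, pi, rho)
      cdf <- pmin(cumsum(d), 1)
      cdfm1 <- c(0, cdf[-length(cdf)])
    }
    p2 <- pmax(pmin(2 * pmin(cdf, 1 - cdfm1), 1), .Machine$double.xmin)
    z <- sign(x / n - pi) * stats::qnorm(p2 / 2, lower.tail = FALSE)
    z[p2 >= 1] <- 0
    tabs[[i]] <- z
  }
  tabs
}

#' Empirical p-value for one feature by parametric bootstrap
#'
#' Simulates maternal counts from the fitted null at the feature's
#' observed per-SNP depths, recomputes the pooled Stouffer statistic for
#' each replicate, and returns
#' \code{p = (#\{|z_null| >= |z_obs|\} + 1) / (n_sims + 1)}.
#'
#' @param totals Observed per-SNP total depths for the feature.
#' @param z_obs Observed pooled z.
#' @param null Fitted \code{\link{fit_betabin_null}}.
#' @param n_sims Bootstrap replicates (>= 100).
#' @param seed RNG seed.
#' @return Empirical p-value.
#' @export
empirical_null_p <- function(totals, z_obs, null, n_sims = 1000,
                             seed = 1L) {
  if (n_sims < 100) stop("n_sims must be at least 100", call. = FALSE)
  set.seed(seed)
  k <- length(totals)
  tabs <- build_z_tables(totals, null$pi_hat, null$rho_hat)
  draws <- rbetabinom(k * n_sims, rep(totals, n_sims),
                      null$pi_hat, null$rho_hat)
  zmat <- matrix(0, nrow = k, ncol = n_sims)
  tot_rep <- rep(totals, n_sims)
  zvals <- unlist(tabs, use.names = FALSE)
  off <- cumsum(c(0, sapply(tabs, length)))
  names(off) <- c(names(tabs), "end")
  zmat[] <- zvals[off[as.character(tot_rep)] + draws + 1]
  z_null <- colSums(zmat) / sqrt(k)
  (sum(abs(z_null) >= abs(z_obs)) + 1) / (n_sims + 1)
}

#' Test all features of one assay for allelic imbalance
#'
#' Batch driver: per-SNP z-scores under the WGS-calibrated null, Stouffer
#' pooling per feature, and a parametric-bootstrap empirical p per
#' feature. Each feature consumes its own RNG substream derived from
#' \code{seed} and the feature index, so results are reproducible under
#' any execution order.
#'
#' @param counts Coverage-filtered oriented counts (\code{chrom, pos,
#'   maternal_count, paternal_count}).
#' @param features \code{GRanges} of the tested features with a
#'   \code{feature_id} (or \code{gene_id}/\code{acr_id}) column.
#' @param null Fitted \code{\link{fit_betabin_null}} for this assay.
#' @param n_sims Bootstrap replicates per feature.
#' @param seed Master seed.
#' @param min_snps Minimum SNPs per testable feature.
#' @return Data.frame (class \code{ase_result}): \code{feature_id,
#'   n_snps, pooled_z, p_empirical, log2fc, maternal_sum, paternal_sum}.
#' @export
ase_test <- function(counts, features, null, n_sims = 1000, seed = 1L,
                     min_snps = 2) {
  fid <- features$feature_id %||% features$gene_id %||% features$acr_id
  gr <- GenomicRanges::GRanges(counts$chrom,
                               IRanges::IRanges(counts$pos, width = 1))
  ov <- GenomicRanges::findOverlaps(gr, features)
  qi <- S4Vectors::queryHits(ov); si <- S4Vectors::subjectHits(ov)
  eff <- snp_effect(counts$maternal_count[qi], counts$paternal_count[qi],
                    null)
  tot <- counts$maternal_count[qi] + counts$paternal_count[qi]

  split_idx <- split(seq_along(qi), si)
  keep <- names(split_idx)[lengths(split_idx) >= min_snps]
  res <- vector("list", length(keep))
  for (j in seq_along(keep)) {
    idx <- split_idx[[keep[j]]]
    fi <- as.integer(keep[j])
    zpool <- pool_stouffer(eff$z[idx])
    pe <- empirical_null_p(tot[idx], zpool, null, n_sims = n_sims,
                           seed = derive_seed(seed, paste0("feat", fi)))
    ms <- sum(counts$maternal_count[qi][idx])
    ps <- sum(counts$paternal_count[qi][idx])
    res[[j]] <- data.frame(
      feature_id = fid[fi], n_snps = length(idx), pooled_z = zpool,
      p_empirical = pe, maternal_sum = ms, paternal_sum = ps,
      log2fc = log2((ms + 1) / (ps + 1)), stringsAsFactors = FALSE)
  }
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(feature_id = character(0), n_snps = integer(0),
               pooled_z = numeric(0), p_empirical = numeric(0),
               maternal_sum = numeric(0), paternal_sum = numeric(0),
               log2fc = numeric(0))
  class(out) <- c("ase_result", class(out))
  out
}

#' Final allele-specific calls across replicates
#'
#' Benjamini-Hochberg adjustment within each replicate; a feature is
#' called allele-specific iff its FDR is below \code{alpha} in every
#' replicate and the allelic log2FC signs agree across replicates.
#' Single-replicate inputs (ATAC) use the one-replicate rule.
#'
#' @param replicates A list of \code{\link{ase_test}} results (one per
#'   replicate) or a single result.
#' @param alpha FDR threshold.
#' @return Data.frame over the intersection of feature sets:
#'   per-replicate \code{q} and \code{log2fc} columns, plus
#'   \code{significant}.
#' @export
call_ase <- function(replicates, alpha = 0.05) {
  if (inherits(replicates, "data.frame")) replicates <- list(replicates)
  stopifnot(length(replicates) >= 1)
  common <- Reduce(intersect, lapply(replicates, `[[`, "feature_id"))
  n_dropped <- sum(vapply(replicates,
                          function(r) sum(!r$feature_id %in% common), 0L))
  qs <- list(); fcs <- list()
  for (i in seq_along(replicates)) {
    r <- replicates[[i]]
    r <- r[match(common, r$feature_id), ]
    qs[[i]] <- stats::p.adjust(r$p_empirical, method = "BH")
    fcs[[i]] <- r$log2fc
  }
  sig <- Reduce(`&`, lapply(qs, function(q) q < alpha))
  if (length(replicates) > 1) {
    signs <- sapply(fcs, sign)
    agree <- apply(signs, 1, function(s) length(unique(s[s != 0])) <= 1)
    sig <- sig & agree
  }
  out <- data.frame(feature_id = common, stringsAsFactors = FALSE)
  for (i in seq_along(qs)) {
    out[[paste0("q_rep", i)]] <- qs[[i]]
    out[[paste0("log2fc_rep", i)]] <- fcs[[i]]
  }
  out$significant <- sig
  attr(out, "n_dropped") <- n_dropped
  out
}
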