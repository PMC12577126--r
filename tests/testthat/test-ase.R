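null0 <- list(pi_hat = 0.5, rho_hat = 0)

test_that("balanced counts give p = 1 and z = 0", {
  e <- snp_effect(10, 10, null0)
  expect_equal(e$p_two_sided, 1)
  expect_equal(e$z, 0)
})

test_that("extreme imbalance matches the exact binomial tail", {
  e <- snp_effect(20, 0, null0)
  expect_equal(e$p_two_sided, 2 * 0.5^20, tolerance = 1e-12)
  expect_equal(e$z, qnorm(1 - 0.5^20), tolerance = 1e-9)
})

test_that("swapping counts flips the sign of z only", {
  e1 <- snp_effect(30, 12, null0)
  e2 <- snp_effect(12, 30, null0)
  expect_equal(e1$z, -e2$z, tolerance = 1e-12)
  expect_equal(e1$p_two_sided, e2$p_two_sided, tolerance = 1e-12)
})

test_that("degenerate null is rejected", {
  expect_error(snp_effect(5, 5, list(pi_hat = 1, rho_hat = 0)),
               "degenerate")
})

test_that("Stouffer pooling matches the closed form", {
  expect_equal(pool_stouffer(c(1, 1)), sqrt(2), tolerance = 1e-12)
  expect_equal(pool_stouffer(c(1.96, -1.96)), 0, tolerance = 1e-12)
  set.seed(5)
  for (i in 1:100) {
    z <- rnorm(sample(2:20, 1))
    expect_equal(pool_stouffer(z), sum(z) / sqrt(length(z)),
                 tolerance = 1e-12)
  }
  expect_error(pool_stouffer(c(1, NA, 2)), "SNP index 2")
})

test_that("empirical p is deterministic and near 1 at z = 0", {
  null <- list(pi_hat = 0.5, rho_hat = 0.05)
  totals <- c(40, 55, 62)
  p1 <- empirical_null_p(totals, 0, null, n_sims = 500, seed = 9L)
  p2 <- empirical_null_p(totals, 0, null, n_sims = 500, seed = 9L)
  expect_identical(p1, p2)
  expect_gt(p1, 0.9)
  expect_error(empirical_null_p(totals, 0, null, n_sims = 50), "100")
})

test_that("empirical p-values are calibrated under the null", {
  # features drawn from the fitted null itself must give uniform p
  set.seed(21)
  null <- list(pi_hat = 0.55, rho_hat = 0.08)
  nfeat <- 300
  ps <- vapply(seq_len(nfeat), function(i) {
    k <- sample(2:6, 1)
    tot <- rnbinom(k, mu = 60, size = 5) + 10
    m <- rbetabinom(k, tot, null$pi_hat, null$rho_hat)
    z <- pool_stouffer(snp_effect(m, tot - m, null)$z)
    empirical_null_p(tot, z, null, n_sims = 300, seed = 1000L + i)
  }, 0)
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("the WGS-calibrated null absorbs mapping bias that breaks a naive test", {
  # all assays share pi = 0.55 mapping bias; the null fitted on WGS stays
  # calibrated, while assuming binomial(0.5) is anti-conservative
  set.seed(41)
  nfeat <- 200
  pi0 <- 0.55; rho0 <- 0.08
  fitted <- list(pi_hat = pi0, rho_hat = rho0)
  naive <- list(pi_hat = 0.5, rho_hat = 0)
  p_fit <- numeric(nfeat); p_naive <- numeric(nfeat)
  for (i in seq_len(nfeat)) {
    k <- sample(3:8, 1)
    tot <- rnbinom(k, mu = 60, size = 5) + 10
    m <- rbetabinom(k, tot, pi0, rho0)
    z_f <- pool_stouffer(snp_effect(m, tot - m, fitted)$z)
    z_n <- pool_stouffer(snp_effect(m, tot - m, naive)$z)
    p_fit[i] <- empirical_null_p(tot, z_f, fitted, n_sims = 300,
                                 seed = 5000L + i)
    p_naive[i] <- empirical_null_p(tot, z_n, naive, n_sims = 300,
                                   seed = 6000L + i)
  }
  expect_lte(mean(p_fit <= 0.05), 0.05 + 2 * sqrt(0.05 * 0.95 / nfeat))
  expect_gt(mean(p_naive <= 0.05), 0.15)
})

test_that("detection power rises with effect size and depth", {
  set.seed(51)
  null <- list(pi_hat = 0.5, rho_hat = 0.05)
  power_at <- function(fc, depth) {
    hits <- vapply(1:40, function(i) {
      k <- 4
      tot <- rep(depth, k)
      pi <- 1 / (1 + 2^(-fc)) # logit shift by fc log2 units
      m <- rbetabinom(k, tot, pi, null$rho_hat)
      z <- pool_stouffer(snp_effect(m, tot - m, null)$z)
      empirical_null_p(tot, z, null, n_sims = 200,
                       seed = i * 7L + depth + round(100 * fc)) < 0.05
    }, NA)
    mean(hits)
  }
  grid <- expand.grid(fc = c(0, 1, 2), depth = c(20, 60, 180))
  pw <- mapply(power_at, grid$fc, grid$depth)
  dim(pw) <- c(3, 3)
  # non-decreasing in effect size at every depth (small MC slack)
  expect_true(all(diff(pw[, 2]) >= -0.1))
  expect_true(all(diff(pw[, 3]) >= -0.1))
  # non-decreasing in depth at fc = 2
  expect_true(all(diff(pw[3, ]) >= -0.1))
  expect_gt(pw[3, 3], 0.9)  # strong effect at high depth is found
  expect_lt(pw[1, 1], 0.2)  # null stays near the nominal level
})

test_that("BH adjustment and replicate-consistency rule behave", {
  r1 <- data.frame(feature_id = letters[1:4], n_snps = 2,
                   pooled_z = c(3, 2.5, 2, 1),
                   p_empirical = c(0.01, 0.02, 0.03, 0.04),
                   maternal_sum = 10, paternal_sum = 5,
                   log2fc = c(1, 1, 1, 1))
  calls <- call_ase(r1, alpha = 0.05)
  expect_equal(calls$q_rep1, rep(0.04, 4), tolerance = 1e-12)
  expect_true(all(calls$significant))

  # second replicate with an opposite-sign feature is not called
  r2 <- r1
  r2$log2fc[1] <- -1
  both <- call_ase(list(r1, r2), alpha = 0.05)
  expect_false(both$significant[both$feature_id == "a"])
  expect_true(all(both$significant[both$feature_id != "a"]))
})

test_that("ase_test detects strong imbalance and skips sparse features", {
  set.seed(31)
  genes <- gr("chr1", c(1000, 5000, 9000), c(2000, 6000, 9100),
              feature_id = c("gA", "gB", "gC"))
  # gA: 4 strongly imbalanced SNPs; gB: 4 balanced; gC: one SNP only
  pos <- c(1100, 1300, 1500, 1700, 5100, 5300, 5500, 5700, 9050)
  m <- c(55, 60, 50, 58, 30, 28, 31, 33, 30)
  tot <- rep(60, 9)
  counts <- data.frame(chrom = "chr1", pos = pos,
                       maternal_count = m, paternal_count = tot - m)
  null <- list(pi_hat = 0.5, rho_hat = 0.02)
  res <- ase_test(counts, genes, null, n_sims = 500, seed = 4L)
  expect_setequal(res$feature_id, c("gA", "gB"))
  expect_lt(res$p_empirical[res$feature_id == "gA"], 0.01)
  expect_gt(res$p_empirical[res$feature_id == "gB"], 0.05)
  expect_gt(res$log2fc[res$feature_id == "gA"], 1.5)
})
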