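test_that("linear scan is calibrated on null SNPs and exact on signal", {
  set.seed(61)
  n <- 2000; m <- 5000
  y <- rnorm(n)
  D <- matrix(rbinom(n * m, 2, 0.3), n, m)
  g <- make_geno(D)
  names(y) <- rownames(D) <- as.character(seq_len(n))
  scan <- snp_scan_linear(y, g)
  # null p-values approximately uniform; type-I rate within +/- 0.01
  expect_lt(abs(mean(scan$p < 0.05) - 0.05), 0.01)
  expect_lt(abs(mean(scan$p < 0.5) - 0.5), 0.02)
  # residual exactly proportional to dosage
  y2 <- setNames(2.5 * D[, 1], rownames(D))
  scan2 <- snp_scan_linear(y2, g)
  expect_equal(scan2$beta[1], 2.5)
  expect_lt(scan2$p[1], 1e-300)
  # zero-variance SNP skipped
  D3 <- cbind(D[, 1:3], 1L)
  scan3 <- snp_scan_linear(y, make_geno(D3))
  expect_true(scan3$skipped[4])
  expect_true(is.na(scan3$p[4]))
  # missing dosages handled per SNP
  D4 <- D[, 1:50]
  D4[sample(length(D4), 500)] <- -1L
  scan4 <- snp_scan_linear(y, make_geno(D4))
  j <- which.max(colSums(D4 == -1L))
  ok <- D4[, j] >= 0
  ref <- summary(lm(y[ok] ~ D4[ok, j]))$coefficients[2, ]
  expect_equal(scan4$beta[j], unname(ref[1]), tolerance = 1e-10)
  expect_equal(scan4$p[j], unname(ref[4]), tolerance = 1e-8)
  expect_equal(scan4$n[j], sum(ok))
})

test_that("permutation threshold matches its definition and edge cases", {
  set.seed(62)
  n <- 300; m <- 150
  y <- setNames(rnorm(n), as.character(seq_len(n)))
  g <- make_geno(matrix(rbinom(n * m, 2, 0.4), n, m,
                        dimnames = list(as.character(seq_len(n)), NULL)))
  pn <- permutation_threshold(y, g, n_perm = 200, alpha = 0.05, seed = 1)
  expect_equal(pn$threshold,
               unname(quantile(pn$min_p, 0.05, type = 1)))
  expect_length(pn$min_p, 200)
  # alpha = 1: threshold 1, every SNP significant
  pn1 <- permutation_threshold(y, g, n_perm = 100, alpha = 1, seed = 1)
  expect_equal(pn1$threshold, 1)
  expect_length(pn1$significant, m)
  # independent SNPs: threshold close to the Bonferroni-implied quantile
  expect_lt(abs(log10(pn$threshold) - log10(0.05 / m)), 0.6)
  # reproducible under the same seed
  pn2 <- permutation_threshold(y, g, n_perm = 200, alpha = 0.05, seed = 1)
  expect_identical(pn$threshold, pn2$threshold)
})

test_that("stratification PCs separate simulated populations", {
  set.seed(63)
  # two founder populations with divergent allele frequencies
  n1 <- 60; n2 <- 60; m <- 300
  p1 <- runif(m, 0.1, 0.9)
  fst <- 0.15
  shift <- function(p) {
    a <- p * (1 - fst) / fst; b <- (1 - p) * (1 - fst) / fst
    rbeta(length(p), a, b)
  }
  # each population draws genotypes at its own drifted frequencies
  q1 <- shift(p1); q2 <- shift(p1)
  D <- rbind(t(replicate(n1, rbinom(m, 2, q1))),
             t(replicate(n2, rbinom(m, 2, q2))))
  g <- make_geno(D)
  pcs <- stratification_pcs(g, K = 4)
  pop <- rep(c(0, 1), c(n1, n2))
  expect_gt(abs(cor(pcs$scores[, 1], pop)), 0.9)
  # columns orthogonal, variance explained non-increasing
  cp <- crossprod(pcs$scores)
  expect_lt(max(abs(cp[upper.tri(cp)])) / max(diag(cp)), 1e-8)
  expect_true(all(diff(pcs$varexp) <= 1e-12))
  # K = n-1 on a small matrix: cumulative variance 100%
  gs <- make_geno(matrix(rbinom(20 * 50, 2, 0.5), 20, 50))
  ps <- stratification_pcs(gs, K = 19)
  expect_equal(sum(ps$varexp), 1, tolerance = 1e-8)
  # matches dense eigendecomposition of the normalized covariance
  g5 <- make_geno(matrix(rbinom(50 * 100, 2, 0.35), 50, 100))
  p5 <- stratification_pcs(g5, K = 5)
  D5 <- g5$dosage
  pf <- colMeans(D5) / 2
  keep <- pf > 0 & pf < 1
  Z <- sweep(sweep(D5[, keep], 2, 2 * pf[keep], "-"), 2,
             sqrt(2 * pf[keep] * (1 - pf[keep])), "/")
  ev <- eigen(tcrossprod(Z), symmetric = TRUE)
  for (k in 1:5) {
    sc <- p5$scores[, k] / sqrt(sum(p5$scores[, k]^2))
    expect_equal(abs(sum(sc * ev$vectors[, k])), 1, tolerance = 1e-6)
  }
})

test_that("logistic PC scan is calibrated and robust to confounding", {
  set.seed(64)
  n <- 800; m <- 600
  pop <- rep(0:1, each = n / 2)
  q1 <- runif(m, 0.15, 0.85)
  q2 <- pmin(pmax(q1 + rnorm(m, 0, 0.15), 0.05), 0.95)
  D <- matrix(0L, n, m)
  D[pop == 0, ] <- t(replicate(n / 2, rbinom(m, 2, q1)))
  D[pop == 1, ] <- t(replicate(n / 2, rbinom(m, 2, q2)))
  g <- make_geno(D)
  # case probability depends only on population
  y <- setNames(rbinom(n, 1, ifelse(pop == 1, 0.65, 0.35)),
                rownames(g$dosage))
  pcs <- stratification_pcs(g, K = 2)
  scan_adj <- snp_scan_logistic(y, g, pcs)
  scan_raw <- snp_scan_logistic(y, g, NULL)
  lam_adj <- genomic_inflation(scan_adj$p)
  lam_raw <- genomic_inflation(scan_raw$p)
  expect_gt(lam_raw, 1.1)             # confounded without adjustment
  expect_lt(abs(lam_adj - 1), 0.15)   # calibrated with PCs
  expect_lt(abs(mean(scan_adj$p < 0.05, na.rm = TRUE) - 0.05), 0.02)
  # zero-variance SNP skipped with flag
  g2 <- make_geno(cbind(D[, 1:3], 2L))
  s2 <- snp_scan_logistic(y, g2, NULL)
  expect_true(s2$skipped[4])
})

test_that("local FDR recovers a planted spike and stays monotone", {
  set.seed(65)
  # pure null: eta0 near 1, at most a stray handful significant (the
  # Grenander slope is noisy at the very smallest order statistics)
  p0 <- runif(2000)
  lf0 <- local_fdr(p0, cutoff = 0.2)
  expect_gt(lf0$eta0, 0.8)
  expect_lte(sum(lf0$significant), 10)
  # 5% Beta(0.1, 1) spike: recovery tracks the Bayes-oracle local fdr
  # for the known mixture, and the false discovery proportion is held
  n <- 10000
  spike <- rbeta(n * 0.05, 0.1, 1)
  p <- c(spike, runif(n * 0.95))
  lf <- local_fdr(p, cutoff = 0.2)
  found <- lf$significant
  spike_idx <- seq_along(spike)
  recovered <- mean(found[spike_idx])
  fdp <- sum(found[-spike_idx]) / max(sum(found), 1)
  # oracle: fdr*(p) = 0.95 / (0.95 + 0.005 p^-0.9); P_spike(fdr* <= 0.2)
  p_star <- (0.005 / (4 * 0.95))^(1 / 0.9)
  oracle_recovery <- p_star^0.1
  expect_lt(abs(recovered - oracle_recovery), 0.15)
  expect_lte(fdp, 0.25)
  # fdr monotone non-decreasing in p
  ord <- order(p)
  expect_true(all(diff(lf$fdr[ord]) >= -1e-12))
  expect_error(local_fdr(rep(0.5, 200)), "degenerate")
})
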