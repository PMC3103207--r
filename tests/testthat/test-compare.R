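test_that("measure correlations match pairs and flag degenerate input", {
  ld <- data.frame(Marker1 = c("A", "A", "B", "Z"),
                   Marker2 = c("B", "C", "C", "Q"),
                   D = c(0.1, 0.2, 0.05, 0.3),
                   CorrCoeff = c(0.5, 0.8, 0.3, 0.9),
                   Dprime = c(0.9, 0.95, 0.5, 1),
                   YulesQ = c(0.8, 0.9, 0.4, 1))
  # arcs listed with reversed pair order must still match
  arcs <- data.frame(parent = c("B", "C", "C"),
                     child = c("A", "A", "B"),
                     arc = c(0.5, 0.8, 0.3) * 100)
  mc <- correlate_measures(ld, arcs)
  expect_equal(mc$n_common, 3)
  expect_equal(mc$n_dropped, 1)
  # ARC proportional to CorrCoeff: correlation exactly 1
  expect_equal(mc$cor["ARC", "CorrCoeff"], 1)
  expect_true(all(diag(mc$cor) == 1))
  expect_true(isSymmetric(mc$cor))
  # constant measure flagged
  ld2 <- ld; ld2$D <- 0.5
  mc2 <- correlate_measures(ld2, arcs)
  expect_true("D" %in% mc2$constant)
  expect_error(correlate_measures(ld[1:2, ], arcs[1:2, ]), "at least 3")
})

test_that("forest arc strengths track r more closely than D-prime", {
  # panel of SNP pairs in complete LD (D' = 1) whose correlation varies
  # through allele-frequency mismatch, plus intermediate-LD pairs: a
  # forest learned on such data should have arc strengths correlating
  # more with r than with D'
  set.seed(121)
  n <- 600
  blocks <- list()
  freqs <- cbind(pA = c(0.5, 0.3, 0.15, 0.45, 0.25, 0.35),
                 extra = c(0, 0.2, 0.35, 0.03, 0.4, 0.1))
  D <- NULL
  for (b in seq_len(nrow(freqs))) {
    pA <- freqs[b, 1]
    # haplotypes: allele 1 at locus 2 wherever locus 1 has it, plus
    # `extra` mass of (0,1) haplotypes -> D' = 1, r < 1 when extra > 0
    h11 <- pA; h10 <- 0; h01 <- freqs[b, 2]
    h00 <- 1 - h11 - h01
    s <- sample_genotypes_from_haps(n, h11, h10, h01, h00)
    D <- cbind(D, s$g1, s$g2)
  }
  colnames(D) <- paste0("V", seq_len(ncol(D)))
  g <- make_geno(D, snp = colnames(D))
  ld <- ld_pairs(g, pairs = cbind(paste0("V", seq(1, 11, 2)),
                                  paste0("V", seq(2, 12, 2))))
  fo <- learn_forest(D + 1L, ess = 1)
  mc <- correlate_measures(ld, fo$arcs)
  expect_gt(mc$cor["ARC", "CorrCoeff"], mc$cor["ARC", "Dprime"])
})

test_that("mapping evaluation matches hand construction and brute force", {
  # QTL at 10 Mb; SNPs at 10.33 Mb and 40 Mb; window 1 Mb
  truth <- data.frame(chrom = 1, pos_bp = 10e6)
  sig <- data.frame(chrom = c(1, 1), pos_bp = c(10.33e6, 40e6))
  rep <- evaluate_mapping(sig, truth, window_mb = 1)
  expect_equal(rep$n_mapped, 1)
  expect_equal(rep$n_false_positive, 1)
  expect_equal(rep$mean_mapped_dist_mb, 0.33)
  expect_equal(rep$mean_fp_dist_mb, 30)
  # SNP exactly at the QTL: distance 0
  rep0 <- evaluate_mapping(data.frame(chrom = 1, pos_bp = 10e6), truth, 1)
  expect_equal(rep0$qtl$nearest_dist_mb, 0)
  expect_true(rep0$qtl$mapped)
  # empty significant set: zero report
  repe <- evaluate_mapping(sig[0, ], truth, 1)
  expect_equal(repe$n_mapped, 0)
  expect_equal(repe$n_significant, 0)
  # randomized layout equals brute-force nearest-neighbour scan
  set.seed(122)
  truth2 <- data.frame(chrom = sample(1:3, 6, TRUE),
                       pos_bp = runif(6, 1e6, 9e7))
  sig2 <- data.frame(chrom = sample(1:3, 25, TRUE),
                     pos_bp = runif(25, 1e6, 9e7))
  rep2 <- evaluate_mapping(sig2, truth2, window_mb = 2)
  bf_q <- sapply(seq_len(6), function(k) {
    d <- abs(sig2$pos_bp[sig2$chrom == truth2$chrom[k]] -
             truth2$pos_bp[k]) / 1e6
    if (length(d)) min(d) else Inf
  })
  expect_equal(rep2$n_mapped, sum(bf_q <= 2))
  bf_s <- sapply(seq_len(25), function(k) {
    d <- abs(truth2$pos_bp[truth2$chrom == sig2$chrom[k]] -
             sig2$pos_bp[k]) / 1e6
    if (length(d)) min(d) else Inf
  })
  expect_equal(rep2$n_false_positive, sum(bf_s > 2))
  # conservation: every QTL is mapped or unassigned
  expect_equal(sum(rep2$qtl$mapped) + sum(!rep2$qtl$mapped), 6)
})

test_that("variance explained behaves on constructed responses", {
  set.seed(123)
  d <- rbinom(500, 2, 0.4)
  # pure noise: ~0%
  expect_lt(snp_variance_explained(rnorm(500), d), 2)
  # exactly linear: 100%
  expect_equal(snp_variance_explained(2 * d - 1, d), 100)
  # affine invariance
  y <- 0.4 * d + rnorm(500)
  expect_equal(snp_variance_explained(y, d),
               snp_variance_explained(5 * y - 3, d))
  expect_error(snp_variance_explained(rep(1, 500), d), "zero-variance")
})

test_that("phenotype-based estimates exceed residual-based under structure", {
  # family structure inflates the naive estimate; GRAMMAR residuals
  # deflate it (the direction of the published 7.7% vs 2.9% contrast)
  des <- paper_design()
  cfg <- planted_cfg(seed = 401)
  g <- simulate_genotypes(cfg, des$ped)
  ph <- simulate_phenotypes(cfg, des$ped, g)
  fit <- run_reml_on(des, ph$phen)
  resid <- grammar_residuals(fit)
  qsnp <- g$qtl$info$snp[1]
  dos <- setNames(g$dosage[, match(qsnp, g$map$snp)],
                  rownames(g$dosage))
  ve <- variance_explained_both(ph$phen, resid, dos)
  expect_gt(ve$phenotype_pct, ve$residual_pct)
  expect_gt(ve$residual_pct, 0.5)   # the QTL is visible in residuals
})
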