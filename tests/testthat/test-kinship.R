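test_that("relationship matrix reproduces textbook closed forms", {
  # unrelated founders
  ped <- data.frame(id = 1:4, sire = 0, dam = 0, sex = c(1, 2, 1, 2))
  expect_equal(additive_relationship(ped), diag(4),
               ignore_attr = TRUE)
  # parent-offspring 0.5, full sibs 0.5, paternal half-sibs 0.25
  ped <- data.frame(id = 1:6,
                    sire = c(0, 0, 0, 1, 1, 1),
                    dam = c(0, 0, 0, 2, 2, 3),
                    sex = c(1, 2, 2, 1, 2, 1))
  A <- additive_relationship(ped)
  expect_equal(A[1, 4], 0.5)   # parent-offspring
  expect_equal(A[4, 5], 0.5)   # full sibs
  expect_equal(A[4, 6], 0.25)  # paternal half sibs
  expect_equal(unname(diag(A)), rep(1, 6))
  # offspring of full sibs is inbred: diagonal 1 + F
  ped2 <- rbind(ped, data.frame(id = 7, sire = 4, dam = 5, sex = 1))
  A2 <- additive_relationship(ped2)
  expect_equal(A2[7, 7], 1.25)
  # unsorted pedigree rejected
  expect_error(additive_relationship(
    data.frame(id = c(3, 1, 2), sire = c(1, 0, 0), dam = c(2, 0, 0))),
    "parents-first")
})

test_that("relationship matrix matches gene-dropping IBD Monte Carlo", {
  set.seed(501)
  cfg <- sim_config(n_sires = 4, n_dams_per_sire = 3,
                    n_offspring_per_dam = 2, n_generations = 2,
                    n_chromosomes = 1, snps_per_chromosome = 10,
                    qtl = NULL, seed = 13)
  ped <- simulate_pedigree(cfg)   # 64 members, two generations
  A <- additive_relationship(ped)
  pairs <- cbind(sample(nrow(ped), 40, replace = TRUE),
                 sample(nrow(ped), 40, replace = TRUE))
  est <- gene_drop_relationship(ped, pairs, R = 1e5)
  expect_lt(max(abs(est - A[pairs])), 0.02)
})

test_that("REML recovers variance components and respects invariances", {
  des <- paper_design()
  cfg <- planted_cfg(seed = 301)
  g <- simulate_genotypes(cfg, des$ped)
  ph <- simulate_phenotypes(cfg, des$ped, g)
  fit <- run_reml_on(des, ph$phen)
  expect_false(fit$boundary)
  expect_lt(abs(fit$h2 - 0.58), 3 * fit$se_h2)
  expect_true(fit$sigma2_a > 0 && fit$sigma2_e > 0)
  # rescaling the phenotype scales variances by c^2, leaves h2 unchanged
  ph2 <- ph$phen
  ph2$y_quant <- 3 * ph2$y_quant
  fit2 <- run_reml_on(des, ph2)
  expect_equal(fit2$h2, fit$h2, tolerance = 1e-4)
  expect_equal(fit2$sigma2_a, 9 * fit$sigma2_a, tolerance = 1e-3)

  # pure-noise phenotype: boundary estimate near zero
  set.seed(8)
  ph0 <- ph$phen
  ph0$y_quant <- rnorm(nrow(ph0))
  fit0 <- run_reml_on(des, ph0)
  expect_lt(fit0$h2, 0.05)
})

test_that("REML agrees with the classical sire-model ANOVA estimator", {
  # balanced paternal half-sib design: 60 sires x 40 offspring,
  # unrelated dams, offspring phenotyped
  set.seed(77)
  ns <- 50; no <- 30
  h2_true <- 0.4
  sire_id <- seq_len(ns)
  n <- ns * no
  ped <- data.frame(
    id = c(sire_id, ns + seq_len(n), ns + n + seq_len(n)),
    sire = c(rep(0, ns), rep(0, n), rep(sire_id, each = no)),
    dam = c(rep(0, ns), rep(0, n), ns + seq_len(n)),
    sex = c(rep(1, ns), rep(2, n), rep(1, n)))
  A <- additive_relationship(ped)
  s2a <- h2_true
  u_s <- rnorm(ns, 0, sqrt(s2a))
  u_d <- rnorm(n, 0, sqrt(s2a))
  off_sire <- rep(sire_id, each = no)
  u_o <- 0.5 * (u_s[off_sire] + u_d) + rnorm(n, 0, sqrt(s2a / 2))
  y <- rep(NA_real_, nrow(ped))
  y[ns + n + seq_len(n)] <- u_o + rnorm(n, 0, sqrt(1 - h2_true))
  fit <- reml_fit(y, rep(1, nrow(ped)), A)
  h2_aov <- anova_h2(y[ns + n + seq_len(n)], off_sire)
  expect_lt(abs(fit$h2 - h2_aov), 0.1)
  expect_lt(abs(fit$h2 - h2_true), 0.12)
})

test_that("GRAMMAR residuals match the dense mixed-model equations", {
  set.seed(9)
  cfg <- sim_config(n_sires = 3, n_dams_per_sire = 3,
                    n_offspring_per_dam = 2, n_chromosomes = 1,
                    snps_per_chromosome = 12, qtl = NULL,
                    h2_quant = 0.5, seed = 17)
  sim <- simulate_dataset(cfg)   # 30 individuals
  A <- additive_relationship(sim$ped)
  y <- setNames(sim$phen$y_quant, as.character(sim$phen$id))
  fit <- reml_fit(y, sim$phen$sex, A)
  e_pkg <- grammar_residuals(fit)
  X <- model.matrix(~factor(sim$phen$sex))
  mme <- mme_solve(unname(y), X, A, fit$sigma2_a, fit$sigma2_e)
  expect_equal(unname(e_pkg), unname(mme$e), tolerance = 1e-6)
  # residuals average zero with an intercept in the model
  expect_lt(abs(mean(e_pkg)), 1e-10)
  # sigma2_a -> 0 (pure-noise fit): residuals collapse to OLS on sex
  set.seed(11)
  yn <- setNames(rnorm(length(y)), names(y))
  fitn <- reml_fit(yn, sim$phen$sex, A)
  if (fitn$sigma2_a / fitn$sigma2_e < 1e-4) {
    e_lim <- grammar_residuals(fitn)
    e_ols <- residuals(lm(yn ~ factor(sim$phen$sex)))
    expect_equal(unname(e_lim), unname(e_ols), tolerance = 1e-3)
  }
})
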