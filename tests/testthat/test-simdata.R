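test_that("pedigree structure follows the mating design", {
  cfg <- sim_config(n_sires = 1, n_dams_per_sire = 1,
                    n_offspring_per_dam = 1, seed = 1)
  ped <- simulate_pedigree(cfg)
  expect_equal(nrow(ped), 3)
  off <- ped[ped$gen == 1, ]
  expect_true(off$sire > 0 && off$dam > 0)

  cfg <- sim_config(n_sires = 10, n_dams_per_sire = 5,
                    n_offspring_per_dam = 10, seed = 1)
  ped <- simulate_pedigree(cfg)
  expect_equal(nrow(ped), 10 + 50 + 500)
  # sires male, dams female, parents precede offspring
  expect_true(all(ped$sex[match(setdiff(ped$sire, 0), ped$id)] == 1))
  expect_true(all(ped$sex[match(setdiff(ped$dam, 0), ped$id)] == 2))
  nonf <- ped$sire != 0
  expect_true(all(match(ped$sire[nonf], ped$id) < which(nonf)))

  expect_error(sim_config(n_sires = 0), "positive")
})

test_that("simulation is bit-reproducible under a fixed seed", {
  s1 <- simulate_dataset(small_cfg(seed = 77))
  s2 <- simulate_dataset(small_cfg(seed = 77))
  expect_identical(s1$ped, s2$ped)
  expect_identical(s1$geno$dosage, s2$geno$dosage)
  expect_identical(s1$phen, s2$phen)
})

test_that("genotypes are Mendelian-consistent and in dosage range", {
  sim <- small_sim()
  D <- sim$geno$dosage
  expect_true(all(D %in% 0:2))
  ped <- sim$ped
  off <- which(ped$sire != 0)
  si <- match(ped$sire[off], ped$id)
  di <- match(ped$dam[off], ped$id)
  # a homozygous parent must transmit its allele: |d_off - d_par| <= 1 + het
  viol <- 0L
  for (k in seq_along(off)) {
    do <- D[off[k], ]; ds <- D[si[k], ]; dd <- D[di[k], ]
    # child allele count must lie within the transmissible range
    lo <- (ds == 2) + (dd == 2)
    hi <- 2 - ((ds == 0) + (dd == 0))
    viol <- viol + sum(do < lo | do > hi)
  }
  expect_identical(viol, 0L)
  # map positions strictly increasing within chromosome
  by_chr <- split(sim$geno$map$pos_bp, sim$geno$map$chrom)
  expect_true(all(vapply(by_chr, function(p) all(diff(p) > 0), logical(1))))
})

test_that("founder LD follows the haplotype copying chain", {
  # rho = 0: adjacent founder SNPs essentially uncorrelated
  cfg0 <- small_cfg(seed = 5, ld_decay_rho = 0)
  g0 <- simulate_genotypes(cfg0, simulate_pedigree(cfg0))
  f <- seq_len(8 + 32)  # founders
  r2 <- sapply(seq_len(39), function(j)
    cor(g0$dosage[f, j], g0$dosage[f, j + 1])^2)
  expect_lt(mean(r2, na.rm = TRUE), 0.05)

  # rho = 0.9 with many founders: matches an independent Monte-Carlo
  # simulation of the same two-locus copying chain
  cfg9 <- sim_config(n_sires = 500, n_dams_per_sire = 1,
                     n_offspring_per_dam = 1, n_chromosomes = 1,
                     snps_per_chromosome = 60, qtl = NULL,
                     ld_decay_rho = 0.9, seed = 11)
  ped9 <- simulate_pedigree(cfg9)
  g9 <- simulate_genotypes(cfg9, ped9)
  fo <- which(ped9$gen == 0)
  r2_sim <- mean(sapply(seq_len(59), function(j)
    cor(g9$dosage[fo, j], g9$dosage[fo, j + 1])^2), na.rm = TRUE)
  # oracle: simulate the chain for random frequency pairs directly
  set.seed(99)
  r2_mc <- replicate(200, {
    p <- runif(2, 0.1, 0.9)
    a1 <- rbinom(2000, 1, p[1])
    copy <- runif(2000) < 0.9
    a2 <- ifelse(copy, a1, rbinom(2000, 1, p[2]))
    g1 <- a1[1:1000] + a1[1001:2000]
    g2 <- a2[1:1000] + a2[1001:2000]
    cor(g1, g2)^2
  })
  expect_lt(abs(r2_sim - mean(r2_mc)), 0.05)
})

test_that("phenotype model hits its heritability and QTL targets", {
  # planted QTL records its configured variance fraction exactly
  sim <- small_sim()
  expect_equal(sim$truth$var_frac, 0.0449, tolerance = 1e-12)

  # h2 = 0, no QTL: offspring-parent regression slope ~ 0
  cfg0 <- sim_config(n_sires = 30, n_dams_per_sire = 10,
                     n_offspring_per_dam = 5, n_chromosomes = 1,
                     snps_per_chromosome = 20, qtl = NULL,
                     h2_quant = 0, seed = 3)
  d0 <- simulate_dataset(cfg0)
  off <- d0$ped[d0$ped$gen == 1, ]
  mid <- (d0$phen$y_quant[match(off$sire, d0$phen$id)] +
          d0$phen$y_quant[match(off$dam, d0$phen$id)]) / 2
  yo <- d0$phen$y_quant[match(off$id, d0$phen$id)]
  b0 <- coef(lm(yo ~ mid))[2]
  expect_lt(abs(b0), 0.06)

  # h2 = 0.5: offspring-midparent slope ~ 0.5
  cfg5 <- sim_config(n_sires = 100, n_dams_per_sire = 10,
                     n_offspring_per_dam = 5, n_chromosomes = 1,
                     snps_per_chromosome = 20, qtl = NULL,
                     h2_quant = 0.5, sex_effect = 0, seed = 4)
  d5 <- simulate_dataset(cfg5)
  off <- d5$ped[d5$ped$gen == 1, ]
  mid <- (d5$phen$y_quant[match(off$sire, d5$phen$id)] +
          d5$phen$y_quant[match(off$dam, d5$phen$id)]) / 2
  yo <- d5$phen$y_quant[match(off$id, d5$phen$id)]
  b5 <- coef(lm(yo ~ mid))[2]
  expect_lt(abs(b5 - 0.5), 0.05)

  # realized h2 within Monte-Carlo error of target at n >= 2000
  cfg <- sim_config(seed = 21)
  sim2 <- simulate_dataset(cfg)
  fitless_h2 <- var(sim2$phen$y_quant)  # used only for sanity
  expect_true(fitless_h2 > 0.8 && fitless_h2 < 1.5)

  # binary trait prevalence matches configuration
  expect_equal(mean(sim2$phen$y_binary), 0.5, tolerance = 0.01)

  # h2 = 1 is rejected
  expect_error(simulate_phenotypes(
    sim_config(h2_quant = 1, qtl = NULL, seed = 1),
    sim$ped, sim$geno), "residual")
})

test_that("hidden QTL are in LD with flanking SNPs", {
  sim <- small_sim()  # hidden mode, QTL on chromosome 1
  qd <- sim$geno$qtl$dosage[, 1]
  map <- sim$geno$map
  near <- which(map$chrom == 1 &
                abs(map$pos_bp - sim$truth$pos_bp[1]) < 3e6)
  r2 <- max(sapply(near, function(j) cor(qd, sim$geno$dosage[, j])^2))
  expect_gt(r2, 0.5)
})
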