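# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_cache[[name]]))
    assign(name, builder(), envir = .fixture_cache)
  .fixture_cache[[name]]
}

# small two-chromosome dataset for module tests
small_cfg <- function(seed = 101, ...) {
  sim_config(n_sires = 8, n_dams_per_sire = 4, n_offspring_per_dam = 6,
             n_chromosomes = 2, snps_per_chromosome = 40,
             qtl = data.frame(chrom = 1, pos_bp = 5.05e7,
                              frac = 0.0449, freq = 0.3),
             seed = seed, ...)
}

small_sim <- function() fixture("small_sim", function() {
  simulate_dataset(small_cfg())
})

# the paper-like study design: fixed pedigree, its relationship matrix
# and eigendecomposition, reused across replicate phenotype draws
paper_design <- function() fixture("paper_design", function() {
  cfg <- sim_config(seed = 1)
  ped <- simulate_pedigree(cfg)
  A <- additive_relationship(ped)
  eg <- eigen(A, symmetric = TRUE)
  list(cfg = cfg, ped = ped, A = A, eigen = eg)
})

# paper-like config with a single planted 4.49% QTL attached to a SNP
planted_cfg <- function(seed) {
  sim_config(qtl = data.frame(chrom = 3, pos_bp = 5.02e7,
                              frac = 0.0449, freq = 0.3),
             qtl_mode = "at_snp", seed = seed)
}

# structured-null config: polygenic half-sib structure, no QTL
null_cfg <- function(seed) sim_config(qtl = NULL, seed = seed)

run_reml_on <- function(design, phen) {
  reml_fit(setNames(phen$y_quant, as.character(phen$id)), phen$sex,
           design$A, eigen_A = design$eigen)
}
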