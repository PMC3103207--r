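# Shared study configuration for the analysis scripts.
#
# The synthetic study emulates a multi-generation half-sib association
# panel at desk scale: 20 sires x 10 dams x 10 offspring (2220
# individuals), 5 chromosomes x 200 SNPs with block LD, five additive
# QTL led by a 4.49%-variance locus, quantitative h2 = 0.58, liability
# h2 = 0.44, and a sex fixed effect.

library(grammarbn)

RESULTS_DIR <- file.path("results", "analysis")
dir.create(RESULTS_DIR, showWarnings = FALSE, recursive = TRUE)

study_cfg <- function(seed = 2010) sim_config(seed = seed)

# simulate + QC, deterministically reproducible from the seed
study_data <- function(seed = 2010) {
  sim <- simulate_dataset(study_cfg(seed))
  qc <- qc_pipeline(sim$geno, sim$phen)
  list(sim = sim, qc = qc)
}

study_reml <- function(sd) {
  A <- additive_relationship(sd$sim$ped)
  phen <- sd$qc$phen
  keep <- match(as.character(phen$id), as.character(sd$sim$ped$id))
  reml_fit(setNames(phen$y_quant, as.character(phen$id)),
           phen$sex, A[keep, keep, drop = FALSE])
}
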