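#!/usr/bin/env Rscript
# Simulate the half-sib study panel and write it out as plain-text files
# (PLINK ped/map, pedigree and phenotype CSV, QTL truth TSV).

source(file.path("analysis", "00_config.R"))

sd <- study_data()
sim <- sd$sim
paths <- write_dataset(sim, file.path(RESULTS_DIR, "data"))

cat(sprintf("simulated %d individuals (%d founders), %d SNPs on %d chromosomes\n",
            nrow(sim$ped), sum(sim$ped$gen == 0),
            ncol(sim$geno$dosage), length(unique(sim$geno$map$chrom))))
cat(sprintf("phenotypic variance %.3f, binary prevalence %.3f\n",
            var(sim$phen$y_quant), mean(sim$phen$y_binary)))
cat("simulated QTL (variance fractions of the phenotypic variance):\n")
print(sim$truth)
cat("files:", paste(basename(paths), collapse = ", "), "\n")
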