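#!/usr/bin/env Rscript
# Pairwise Devlin-Risch LD statistics over the reduced top-SNP panel,
# Bayesian forest and greedy-search Bayesian network over the same SNPs
# (BDeu score, ess = 1), and the Pearson correlation matrix between the
# LD measures and the per-arc strengths.

source(file.path("analysis", "00_config.R"))

sd <- study_data()
g <- sd$qc$geno

snps <- readLines(file.path(RESULTS_DIR, "reduced_quant_snps.txt"))
if (length(snps) > 15) snps <- snps[1:15]
if (length(snps) < 4)
  snps <- readLines(file.path(RESULTS_DIR, "top_quant_snps.txt"))[1:10]
j <- match(snps, g$map$snp)
gb <- structure(list(dosage = g$dosage[, j, drop = FALSE],
                     map = g$map[j, , drop = FALSE], qtl = NULL),
                class = "geno_matrix")

ld <- ld_pairs(gb)
data.table::fwrite(ld, file.path(RESULTS_DIR, "ld_pairs.tsv"), sep = "\t")
cat(sprintf("LD over %d SNPs (%d pairs): |r| range %.2f-%.2f\n",
            length(snps), nrow(ld), min(abs(ld$CorrCoeff), na.rm = TRUE),
            max(abs(ld$CorrCoeff), na.rm = TRUE)))

dat <- gb$dosage + 1L
colnames(dat) <- gb$map$snp
forest <- learn_forest(dat, ess = 1)
dag <- greedy_dag_search(dat, ess = 1, restarts = 3, seed = 2012)
cat(sprintf("forest: %d arcs, score %.1f; greedy DAG: %d arcs, score %.1f\n",
            nrow(forest$arcs), forest$score, nrow(dag$arcs), dag$score))
data.table::fwrite(forest$arcs, file.path(RESULTS_DIR, "bn_forest.tsv"),
                   sep = "\t")
data.table::fwrite(dag$arcs, file.path(RESULTS_DIR, "bn_dag.tsv"),
                   sep = "\t")

if (nrow(forest$arcs) >= 3) {
  mc <- correlate_measures(ld, forest$arcs)
  cat(sprintf("forest arcs vs LD over %d common pairs:\n", mc$n_common))
  print(round(mc$cor, 3))
  data.table::fwrite(as.data.frame(mc$cor),
                     file.path(RESULTS_DIR, "measure_correlations.tsv"),
                     sep = "\t", row.names = TRUE)
}
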