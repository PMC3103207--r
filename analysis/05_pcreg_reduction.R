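#!/usr/bin/env Rscript
# PCReg: break the LD-induced collinearity among the top SNPs by
# regressing the trait on principal components of the top-SNP dosage
# submatrix (identity link for the quantitative list, logit for the
# binary list) and mapping significant components back to SNPs.

source(file.path("analysis", "00_config.R"))

sd <- study_data()
g <- sd$qc$geno
phen <- sd$qc$phen

subset_geno <- function(g, snps) {
  j <- match(snps, g$map$snp)
  structure(list(dosage = g$dosage[, j, drop = FALSE],
                 map = g$map[j, , drop = FALSE], qtl = NULL),
            class = "geno_matrix")
}

top_q <- readLines(file.path(RESULTS_DIR, "top_quant_snps.txt"))
top_b <- readLines(file.path(RESULTS_DIR, "top_binary_snps.txt"))

yq <- setNames(phen$y_quant, as.character(phen$id))
pr_q <- pcreg(yq, subset_geno(g, top_q), link = "identity",
              var_target = 0.8)
cat("quantitative list: "); print(pr_q)
data.table::fwrite(export_loading_plot_data(pr_q),
                   file.path(RESULTS_DIR, "loadings_quant.tsv"),
                   sep = "\t")
writeLines(pr_q$retained, file.path(RESULTS_DIR, "reduced_quant_snps.txt"))

ybin <- setNames(phen$y_binary, as.character(phen$id))
pr_b <- pcreg(ybin, subset_geno(g, top_b), link = "logit",
              var_target = 0.75)
cat("binary list: "); print(pr_b)
data.table::fwrite(export_loading_plot_data(pr_b),
                   file.path(RESULTS_DIR, "loadings_binary.tsv"),
                   sep = "\t")
writeLines(pr_b$retained, file.path(RESULTS_DIR, "reduced_binary_snps.txt"))
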