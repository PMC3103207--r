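#!/usr/bin/env Rscript
# Stage 2 association scans.
# Quantitative trait: single-SNP OLS on the GRAMMAR residuals with a
# 200-permutation genome-wide threshold at alpha = 0.05.
# Binary trait: logistic scan adjusted for 20 stratification PCs, with
# Grenander local-FDR selection.

source(file.path("analysis", "00_config.R"))

sd <- study_data()
g <- sd$qc$geno
phen <- sd$qc$phen
fit <- study_reml(sd)
resid <- grammar_residuals(fit)

scan_q <- snp_scan_linear(resid, g)
perm <- permutation_threshold(resid, g, n_perm = 200, alpha = 0.05,
                              seed = 2011)
cat(sprintf("quantitative scan: genome-wide p threshold %.2e, %d significant SNPs\n",
            perm$threshold, length(perm$significant)))
data.table::fwrite(scan_q, file.path(RESULTS_DIR, "scan_quant.tsv"),
                   sep = "\t")
writeLines(perm$significant, file.path(RESULTS_DIR, "top_quant_snps.txt"))

pcs <- stratification_pcs(g, K = 20)
cat(sprintf("20 stratification PCs explain %.1f%% of genotype variance\n",
            100 * sum(pcs$varexp[1:20])))
ybin <- setNames(phen$y_binary, as.character(phen$id))
scan_b <- snp_scan_logistic(ybin, g, pcs)
lam <- genomic_inflation(scan_b$p)
lf <- local_fdr(scan_b$p[!is.na(scan_b$p)], cutoff = 0.2)
sig_b <- scan_b$snp[!is.na(scan_b$p)][lf$significant]
cat(sprintf("binary scan: lambda_GC %.2f (PC adjustment does not remove half-sib\n", lam))
cat(sprintf("  family confounding), eta0 %.2f, %d SNPs at local fdr <= 0.2 (p <= %.2e)\n",
            lf$eta0, length(sig_b),
            ifelse(is.na(lf$p_cutoff), NA, lf$p_cutoff)))
data.table::fwrite(scan_b, file.path(RESULTS_DIR, "scan_binary.tsv"),
                   sep = "\t")
writeLines(sig_b, file.path(RESULTS_DIR, "top_binary_snps.txt"))
jsonlite::write_json(
  list(perm_threshold = perm$threshold,
       n_sig_quant = length(perm$significant),
       lambda_gc_binary = lam, eta0 = lf$eta0,
       n_sig_binary = length(sig_b)),
  file.path(RESULTS_DIR, "scan_summary.json"), auto_unbox = TRUE,
  digits = NA)
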