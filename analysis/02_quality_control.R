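#!/usr/bin/env Rscript
# Quality control: MAF < 1% SNP filter, IBS > 95% duplicate removal, and
# a Lilliefors normality check of the quantitative trait.

source(file.path("analysis", "00_config.R"))

sd <- study_data()
qc <- sd$qc
print(qc)
cat(sprintf("retained %d SNPs and %d individuals\n",
            ncol(qc$geno$dosage), nrow(qc$geno$dosage)))

data.table::fwrite(
  data.frame(item = c("snps_removed_maf", "individuals_removed_ibs",
                      "snps_retained", "individuals_retained"),
             n = c(qc$n_snps_removed_maf, qc$n_individuals_removed_ibs,
                   ncol(qc$geno$dosage), nrow(qc$geno$dosage))),
  file.path(RESULTS_DIR, "qc_summary.tsv"), sep = "\t")
jsonlite::write_json(list(ks_statistic = qc$ks_statistic, ks_p = qc$ks_p),
                     file.path(RESULTS_DIR, "ks_normality.json"),
                     auto_unbox = TRUE, digits = NA)
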