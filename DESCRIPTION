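Package: grammarbn
Title: Mixed-Model Association, Stratification PCA, Linkage Disequilibrium
    and Bayesian Networks for Half-Sib QTL Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Two-stage GRAMMAR genome-wide association for quantitative
    traits (animal-model REML residuals regressed on single SNPs with
    permutation-based genome-wide thresholds), principal-component
    stratification with local false discovery rate control for binary
    traits, principal-component regression to break linkage disequilibrium
    among top markers, Devlin-Risch pairwise LD statistics from
    EM-estimated haplotype frequencies, and Bayesian network / forest
    structure learning over SNP genotypes with BDeu scoring and per-arc
    strengths.  Includes a half-sib pedigree simulator (gene dropping with
    recombination, block LD, additive QTL, liability-threshold binary
    trait) that provides ground truth for evaluating the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    data.table,
    jsonlite,
    nortest
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
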