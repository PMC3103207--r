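---
title: "Mixed-model association, LD and Bayesian networks in half-sib populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mixed-model association, LD and Bayesian networks in half-sib populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(grammarbn)
```

This vignette is the package's account of its statistical machinery: the
models fitted, the estimators and their conventions, the design of the
synthetic-data generator, the numerical choices, and the limitations we
know about. Nothing here states an empirical result that the test suite
or the analysis scripts do not themselves compute.

## The problem

In pedigreed populations — the motivating case is a multi-generation
half-sib livestock design, where each sire is mated to many dams — trait
values and genotypes are both correlated within families. A naive
per-SNP regression then mistakes shared family background for marker
effects: its test statistics are inflated (genomic inflation
`lambda_GC > 1`) and top hits are enriched for false positives. The
package implements the two standard corrections (mixed-model residuals
for quantitative traits, principal-component adjustment for binary
traits), the multiplicity machinery around them (permutation thresholds,
local FDR), and a follow-up layer that characterises the LD among the
surviving markers by classical pairwise statistics and by Bayesian
network structure learning.

## Stage 1: the animal model

`reml_fit()` fits

$$y = Xb + Za + e, \qquad a \sim N(0, A\sigma^2_a), \qquad e \sim N(0, I\sigma^2_e)$$

with `X` an intercept plus sex, and `A` the pedigree numerator
relationship matrix from `additive_relationship()` (Henderson's tabular
recursion; founders unrelated and non-inbred). Restricted maximum
likelihood is computed after an eigendecomposition `A = U D U'`: rotating
`y` and `X` by `U'` diagonalises the covariance, so the profile REML
log-likelihood is a one-dimensional function of
`lambda = sigma2_a / sigma2_e`, maximised by Brent search on
`log(lambda)` over [-14, 14] with tolerance `1e-8`. `lambda` at either
search boundary is flagged (`boundary = TRUE`), which is the expected
outcome for a heritability of zero, not an error. Standard errors come
from the observed information in `(sigma2_a, sigma2_e)` by central
differences, with the heritability SE by the delta method. Individuals
with missing phenotype or sex are dropped and `A` is subset — the correct
marginal model for a multivariate normal. Repeated fits on the same
design can pass a precomputed `eigen_A`.

The binary trait is analysed on the observed 0/1 scale with the same
linear machinery; the resulting heritability is an observed-scale
quantity and no liability-scale conversion is attempted.

`grammar_residuals()` evaluates
`e_hat = sigma2_e V^{-1} (y - X b_hat)` in the eigenbasis, which equals
`y - X b_hat - Z a_hat` with `a_hat` the BLUP; the test suite checks this
identity against a dense mixed-model-equations solve.

## Stage 2: scans and multiplicity

`snp_scan_linear()` regresses the stage-1 residual on each SNP dosage
(0/1/2, additive coding, no dominance term) with per-SNP handling of
missing genotypes; `permutation_threshold()` permutes the residual
vector, rescans, and takes the empirical `alpha`-quantile of the
per-permutation minimum p-value as the genome-wide threshold. Permuting
the stage-2 response is justified by the approximate exchangeability of
residuals after polygenic correction; its consequences are discussed
under *Limitations*.

`stratification_pcs()` standardises each SNP by its allele frequency
(center `2p`, scale `sqrt(2p(1-p))`) and takes top left singular
vectors; the number of components can be fixed (the analysis scripts use
20) or chosen as the smallest K reaching a target cumulative variance
(default 75%). A fixed K is preferred in the drivers because on
simulated half-sib data the 75% rule selects ~60 diffuse family-driven
components, tripling the logistic scan cost without improving
calibration. `snp_scan_logistic()` then fits per-SNP logistic
regressions with the PC scores as covariates; separation and
non-convergence are flagged per SNP, never fatal.

`local_fdr()` estimates the p-value density by the Grenander estimator —
the slopes of the least concave majorant of the ECDF — and reports
`fdr(p) = min(1, eta0 / f(p))`. Two conventions matter. First, `eta0` is
the hull slope at the upper end of the *observed* p-values, floored at
`1/n`: the segment beyond the largest p-value has slope zero and would
otherwise make `eta0` degenerate exactly when the input is heavily
enriched. Second, the smallest order statistics give the first hull
segment a steep and noisy slope, so on a pure-null input a couple of the
smallest p-values can still be flagged; the tests bound this rather than
assuming an idealised empty set.

## PCReg

`pcreg()` computes principal components of the centered (not
frequency-scaled — the goal is collinearity removal, not stratification)
top-SNP dosage submatrix, regresses the trait on the top-K scores
(identity or logit link), and retains a SNP if it has absolute loading at
least `1/sqrt(m)` (an above-average contribution among m SNPs) on at
least one component significant at `pc_alpha = 0.05`. The published
analyses this mirrors do not state their reduction rule; ours is
explicit, configurable, and logged in the result object.

## LD statistics

`em_haplotypes()` estimates two-locus haplotype frequencies from
unphased dosages by EM over the double-heterozygote ambiguity (tolerance
`1e-10`, at most 1000 iterations; the likelihood trace is retained and
tested to be non-decreasing). `ld_measures()` then computes, on the
minor-allele orientation (signs are kept — negatively associated minor
alleles are informative):

* `D = pi11 - p q`, `D' = D / Dmax`,
* `r = D / sqrt(p(1-p)q(1-q))`,
* Yule's `Q = (pi11 pi22 - pi12 pi21) / (pi11 pi22 + pi12 pi21)`,
* proportional difference `d = pi11/q - pi12/(1-q)`,
* population attributable-risk form `delta = (pi11 pi22 - pi12 pi21) / (q pi22)`,
* `chisq = n r^2` with df = 1.

The chi-square uses `n` = number of individuals. That convention is
fixed by internal consistency of the published comparison tables: a row
reporting chi-square 692.12 alongside r = 0.55 implies
`n = 692.12 / 0.55^2 ~ 2289`, matching the individual count (2318, with
r rounded to two decimals) and not the gamete count.

## Bayesian networks

`bdeu_family_score()` implements the closed-form BDeu family score with
`alpha_jk = ess/(q r)`; the tests verify it against the prequential
product of predictive probabilities (which must be identical for every
row ordering) and verify likelihood equivalence numerically. The
"non-informative prior" is interpreted as BDeu with `ess = 1` and a
uniform structure prior; `ess` is configurable.

`learn_forest()` finds the exact maximum-score forest: edge gains
`w(i,j) = score(j|i) - score(j|empty)` are symmetric under likelihood
equivalence, so a maximum-weight spanning forest over the positive-gain
edges (Kruskal) is optimal; trees are rooted at their lowest-index
variable for deterministic orientation. `greedy_dag_search()` is
best-improvement hill climbing over add/delete/reverse moves with random
restarts and family-score caching. Arc strength is the local score drop
from deleting the arc, in natural-log units; `format_exp_arc()` converts
it to a Bayes factor `a x 10^b` by base-10 exponent decomposition
(`b = floor(ARC / ln 10)`), exact far beyond double-precision overflow.
SNPs enter the networks as 3-state categorical variables (genotype
coding), not binarised.

## The synthetic-data generator

`simulate_dataset()` emulates the structure the analyses assume, at desk
scale. Defaults (chosen once, as study conditions):

* **Design**: 20 sires x 10 dams x 10 offspring, one generation — 2220
  individuals; sexes alternate within litters.
* **Genome**: 5 chromosomes x 200 SNPs, 100 Mb each, 1-based positions.
* **Founder LD**: a first-order Markov allele-copying chain along each
  chromosome (copy probability `ld_decay_rho = 0.9`, otherwise a fresh
  draw at the locus frequency, frequencies uniform on [0.1, 0.9]) —
  adjacent-SNP founder r^2 ~ rho^2. The copying chain pulls realized
  frequencies toward a running average, so effects are always computed
  from realized, not nominal, frequencies.
* **Transmission**: gene dropping with Haldane recombination at
  1 cM/Mb; Mendelian consistency is tested exhaustively.
* **QTL**: hidden loci simulated inside the haplotype chain at their own
  map positions and removed from the panel (default), or attached to the
  nearest SNP (`qtl_mode = "at_snp"`). Effects are derived from target
  variance fractions as `a = sqrt(frac / (2p(1-p)))` on the unit
  phenotypic-variance scale; the default panel is five QTL at fractions
  4.49%, 3%, 2%, 1.5%, 1%.
* **Traits**: `y = sex effect (0.5) + QTL + polygenic + residual` with
  genetic/(genetic+residual) variance = `h2_quant = 0.58`; the binary
  trait thresholds an analogous latent liability (`h2 = 0.44`) at the
  empirical quantile of the configured prevalence (0.5). The 0.58/0.44
  targets are the heritabilities reported for the real workshop data,
  used here as simulation targets.

What the generator does **not** emulate: coalescent-accurate LD decay,
dominance and epistasis, X-linked inheritance, genotyping error and
missingness patterns of real arrays, and ascertainment of the binary
trait. Passing tests therefore show correctness of the estimators under
the stated generative model, not performance on any real dataset.

## Problem sizes used by the test suite

The suite exercises the full study design (2220 individuals, 1000 SNPs)
with 50 replicate phenotype draws for parameter recovery and 200 for
null calibration, reusing one eigendecomposition of `A` across
replicates; permutation thresholds use 200 permutations in place of the
1000 a full analysis would use. Oracle checks (gene-dropping IBD with
1e5 drops, exhaustive forest/DAG enumeration, 1000-case LD fuzzing,
prequential BDeu) run at small n.

## Known limitations

* **GRAMMAR deflation.** The BLUP removes a dosage-aligned fraction of
  any true SNP effect, so stage-2 statistics and effect estimates are
  deflated (on the default design the null residual scan has median
  `lambda_GC ~ 0.5`, and the variance explained by a planted
  4.49%-variance QTL measures ~1.7% on residuals vs ~4.6% on the
  sex-adjusted phenotype — the same direction as the published 2.9% vs
  7.7% contrast). Two consequences are deliberate, faithful behaviour
  rather than bugs: residual-based effect sizes under-estimate truth,
  and the residual-permutation genome-wide threshold is *conservative*
  (family-wise error well below nominal), because permutation destroys
  the family structure that deflates the observed statistics. Corrected
  variants (e.g. rescaling residuals by the deflation factor) exist in
  the literature but are outside this package's scope, which follows
  the uncorrected two-stage procedure.
* **PC adjustment does not fix family confounding.** On half-sib data
  the logistic PC scan remains inflated even with 20 PCs (the drivers
  print its `lambda_GC`); PCs correct discrete ancestral stratification,
  not dense kinship. This motivates stringent multiplicity control for
  binary traits in such designs.
* **Local FDR has bounded power by construction.** For a mixture of 95%
  uniform p-values and a 5% `Beta(0.1, 1)` spike, the Bayes-oracle local
  fdr at cutoff 0.2 recovers only ~48% of spike members; no correct
  estimator can do much better, and the Grenander estimator tracks that
  oracle. Local-fdr selections should be read as high-confidence sets,
  not high-recall sets.
* The greedy DAG search is a heuristic; exactness is only verified (and
  only claimed) against exhaustive enumeration at small variable counts.
* The EM haplotype estimator assumes Hardy-Weinberg within the sample;
  in a structured population its frequencies are population averages.
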