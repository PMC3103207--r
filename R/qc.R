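#' Minor-allele-frequency filter
#'
#' Removes SNPs whose minor allele frequency, computed from non-missing
#' dosages as `min(p, 1 - p)` with `p = mean(dosage) / 2`, falls below
#' `threshold`.
#'
#' @param g a `geno_matrix` (missing dosage coded -1).
#' @param threshold MAF threshold in \[0, 0.5\]; default 0.01.
#' @return list with `geno` (filtered `geno_matrix`), `removed`
#'   (character vector of removed SNP ids) and `maf` (per-input-SNP MAF).
#' @export
maf_filter <- function(g, threshold = 0.01) {
  stopifnot(inherits(g, "geno_matrix"))
  if (threshold < 0 || threshold > 0.5)
    stop("threshold must be in [0, 0.5]")
  D <- g$dosage
  D[D < 0] <- NA
  p <- colMeans(D, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  maf[is.na(maf)] <- 0       # all-missing SNP: treat as monomorphic
  drop <- maf < threshold
  if (all(drop)) stop("MAF filter removed every SNP")
  out <- g
  out$dosage <- g$dosage[, !drop, drop = FALSE]
  out$map <- g$map[!drop, , drop = FALSE]
  list(geno = out, removed = g$map$snp[drop],
       maf = setNames(maf, g$map$snp))
}

# pairwise IBS matrix: mean over non-missing SNPs of (2 - |d_i - d_j|)/2
ibs_matrix <- function(D) {
  n <- nrow(D)
  obs <- D >= 0
  G0 <- (D == 0) & obs; G1 <- (D == 1) & obs; G2 <- (D == 2) & obs
  storage.mode(G0) <- storage.mode(G1) <- storage.mode(G2) <- "double"
  n_obs <- tcrossprod(obs + 0)            # SNPs non-missing in both
  diff1 <- tcrossprod(G0, G1) + tcrossprod(G1, G0) +
    tcrossprod(G1, G2) + tcrossprod(G2, G1)
  diff2 <- tcrossprod(G0, G2) + tcrossprod(G2, G0)
  ibs <- 1 - (diff1 + 2 * diff2) / (2 * n_obs)
  ibs[n_obs == 0] <- NA
  dimnames(ibs) <- list(rownames(D), rownames(D))
  ibs
}

#' Remove near-duplicate individuals by identity-by-state
#'
#' Pairwise IBS is the mean over SNPs non-missing in both individuals of
#' `(2 - |d_i - d_j|) / 2`.  For each pair exceeding `threshold` the
#' later-listed individual is removed; removal is iterative, so an
#' individual already removed cannot trigger further removals.
#'
#' @param g a `geno_matrix`.
#' @param threshold IBS threshold in (0, 1\]; default 0.95.
#' @return list with `geno` (deduplicated), `removed` (ids in removal
#'   order) and `pairs` (data.frame of flagged pairs with their IBS).
#' @export
ibs_dedup <- function(g, threshold = 0.95) {
  stopifnot(inherits(g, "geno_matrix"))
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
  n <- nrow(g$dosage)
  if (n < 2) {
    warning("fewer than 2 individuals; nothing to deduplicate")
    return(list(geno = g, removed = character(),
                pairs = data.frame(i = character(), j = character(),
                                   ibs = numeric())))
  }
  ibs <- ibs_matrix(g$dosage)
  hits <- which(upper.tri(ibs) & !is.na(ibs) & ibs > threshold,
                arr.ind = TRUE)
  removed <- logical(n)
  kept_pairs <- list()
  if (nrow(hits)) {
    hits <- hits[order(hits[, 2], hits[, 1]), , drop = FALSE]
    for (r in seq_len(nrow(hits))) {
      i <- hits[r, 1]; j <- hits[r, 2]
      if (removed[i] || removed[j]) next
      removed[j] <- TRUE
      kept_pairs[[length(kept_pairs) + 1L]] <-
        data.frame(i = rownames(ibs)[i], j = rownames(ibs)[j],
                   ibs = ibs[i, j])
    }
  }
  out <- g
  out$dosage <- g$dosage[!removed, , drop = FALSE]
  list(geno = out, removed = rownames(g$dosage)[removed],
       pairs = if (length(kept_pairs)) do.call(rbind, kept_pairs)
               else data.frame(i = character(), j = character(),
                               ibs = numeric()))
}

#' Lilliefors-type normality check for a quantitative trait
#'
#' One-sample Kolmogorov-Smirnov test against a normal distribution with
#' mean and SD estimated from the sample, with the Lilliefors correction
#' for the estimated parameters.
#'
#' @param y numeric vector, n >= 8, non-constant.
#' @return list with `statistic` and `p`.
#' @export
ks_normality <- function(y) {
  y <- y[!is.na(y)]
  if (length(y) < 8) stop("need at least 8 observations")
  if (sd(y) == 0) stop("zero variance")
  res <- nortest::lillie.test(y)
  list(statistic = unname(res$statistic), p = unname(res$p.value))
}

#' Full genotype/trait quality-control pass
#'
#' Applies [maf_filter()] then [ibs_dedup()] and tests the quantitative
#' trait for normality with [ks_normality()].
#'
#' @param g a `geno_matrix`.
#' @param phen phenotype data.frame with `id` and `y_quant`.
#' @param maf_threshold,ibs_threshold filter settings.
#' @return list of class `qc_report`: filtered `geno`, aligned `phen`,
#'   and counts/ids of removed SNPs and individuals plus the KS result.
#' @export
qc_pipeline <- function(g, phen, maf_threshold = 0.01, ibs_threshold = 0.95) {
  mf <- maf_filter(g, maf_threshold)
  dd <- ibs_dedup(mf$geno, ibs_threshold)
  ks <- ks_normality(phen$y_quant)
  phen_kept <- phen[phen$id %in% as.numeric(rownames(dd$geno$dosage)) |
                    phen$id %in% rownames(dd$geno$dosage), , drop = FALSE]
  structure(list(
    geno = dd$geno, phen = phen_kept,
    n_snps_removed_maf = length(mf$removed),
    snps_removed = mf$removed,
    n_individuals_removed_ibs = length(dd$removed),
    individuals_removed = dd$removed,
    ks_statistic = ks$statistic, ks_p = ks$p
  ), class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf(
    "QC: removed %d SNP(s) by MAF, %d individual(s) by IBS; KS D = %.4f, p = %.3f\n",
    x$n_snps_removed_maf, x$n_individuals_removed_ibs,
    x$ks_statistic, x$ks_p))
  invisible(x)
}
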