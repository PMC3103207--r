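#' Pearson correlations between LD measures and arc strengths
#'
#' Matches LD results and Bayesian-network arcs on the unordered marker
#' pair and computes the Pearson correlation matrix among D, CorrCoeff,
#' Dprime, YulesQ and ARC over the common pairs.  Pairs present in only
#' one source are dropped (count reported); constant measures yield NA
#' with a flag.
#'
#' @param ld data.frame from [ld_pairs()] (Marker1, Marker2 + measures).
#' @param arcs data.frame with columns `parent`, `child`, `arc`.
#' @return list of class `measure_cor`: `cor` (5x5 matrix), `n_common`,
#'   `n_dropped`, `constant` (measures with zero variance).
#' @export
correlate_measures <- function(ld, arcs) {
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "|")
  ld_key <- key(ld$Marker1, ld$Marker2)
  arc_key <- key(arcs$parent, arcs$child)
  common <- intersect(ld_key, arc_key)
  if (length(common) < 3) stop("need at least 3 common marker pairs")
  li <- match(common, ld_key)
  ai <- match(common, arc_key)
  M <- cbind(D = ld$D[li], CorrCoeff = ld$CorrCoeff[li],
             Dprime = ld$Dprime[li], YulesQ = ld$YulesQ[li],
             ARC = arcs$arc[ai])
  sds <- apply(M, 2, sd, na.rm = TRUE)
  const <- colnames(M)[!is.na(sds) & sds == 0]
  cm <- suppressWarnings(cor(M, use = "pairwise.complete.obs"))
  structure(list(cor = cm, n_common = length(common),
                 n_dropped = length(ld_key) + length(arc_key) -
                   2 * length(common),
                 constant = const),
            class = "measure_cor")
}

#' Evaluate QTL mapping against simulated truth
#'
#' Assigns every significant SNP to the nearest true QTL on the same
#' chromosome.  A QTL counts as mapped if its nearest significant SNP
#' lies within `window_mb`; significant SNPs farther than `window_mb`
#' from every QTL (or on QTL-free chromosomes) count as false positives.
#' Distances are `|bp difference| / 1e6` megabases.
#'
#' @param sig data.frame of significant SNPs with `chrom` and `pos_bp`.
#' @param truth QTL truth data.frame with `chrom` and `pos_bp`.
#' @param window_mb mapping window in Mb (default 1).
#' @return list of class `mapping_report`: `qtl` (per-QTL nearest
#'   distance and mapped flag), `n_mapped`, `n_false_positive`,
#'   `mean_mapped_dist_mb`, `mean_fp_dist_mb`, `n_significant`.
#' @export
evaluate_mapping <- function(sig, truth, window_mb = 1) {
  nq <- nrow(truth)
  if (nrow(sig) == 0) {
    return(structure(list(
      qtl = data.frame(chrom = truth$chrom, pos_bp = truth$pos_bp,
                       nearest_dist_mb = NA_real_, mapped = FALSE),
      n_mapped = 0L, n_false_positive = 0L,
      mean_mapped_dist_mb = NA_real_, mean_fp_dist_mb = NA_real_,
      n_significant = 0L), class = "mapping_report"))
  }
  # distance from each significant SNP to each QTL (Inf across chromosomes)
  dist_mat <- outer(seq_len(nrow(sig)), seq_len(nq), function(i, j) {
    ifelse(sig$chrom[i] == truth$chrom[j],
           abs(sig$pos_bp[i] - truth$pos_bp[j]) / 1e6, Inf)
  })
  snp_nearest <- apply(dist_mat, 1, min)
  fp <- snp_nearest > window_mb
  qtl_nearest <- apply(dist_mat, 2, min)
  mapped <- is.finite(qtl_nearest) & qtl_nearest <= window_mb
  structure(list(
    qtl = data.frame(chrom = truth$chrom, pos_bp = truth$pos_bp,
                     nearest_dist_mb = ifelse(is.finite(qtl_nearest),
                                              qtl_nearest, NA_real_),
                     mapped = mapped),
    n_mapped = sum(mapped), n_false_positive = sum(fp),
    mean_mapped_dist_mb = if (any(mapped)) mean(qtl_nearest[mapped])
                          else NA_real_,
    mean_fp_dist_mb = if (any(fp))
      mean(snp_nearest[fp & is.finite(snp_nearest)]) else NA_real_,
    n_significant = nrow(sig)), class = "mapping_report")
}

#' @export
print.mapping_report <- function(x, ...) {
  cat(sprintf(
    "mapping: %d/%d QTL mapped (mean %.2f Mb), %d false positives (mean %s Mb)\n",
    x$n_mapped, nrow(x$qtl),
    ifelse(is.na(x$mean_mapped_dist_mb), NA, x$mean_mapped_dist_mb),
    x$n_false_positive,
    ifelse(is.na(x$mean_fp_dist_mb), "NA",
           sprintf("%.2f", x$mean_fp_dist_mb))))
  invisible(x)
}

#' Percentage of variance explained by a single SNP
#'
#' R-squared of the simple linear regression of the response on allele
#' dosage, times 100.
#'
#' @param response numeric vector (raw/adjusted phenotype or GRAMMAR
#'   residual).
#' @param dosage dosage vector aligned with `response` (missing -1/NA
#'   dropped).
#' @return percentage in \[0, 100\].
#' @export
snp_variance_explained <- function(response, dosage) {
  ok <- !is.na(response) & !is.na(dosage) & dosage >= 0
  y <- response[ok]; x <- dosage[ok]
  if (length(y) < 3) stop("too few complete observations")
  if (var(y) == 0 || var(x) == 0) stop("zero-variance input")
  unname(cor(y, x)^2 * 100)
}

#' QTL variance explained: phenotype-based vs residual-based
#'
#' Reports the single-SNP variance explained twice, the way the GRAMMAR
#' deflation is usually demonstrated: once with the sex-adjusted raw
#' phenotype as response and once with the animal-model residual.
#'
#' @param phen phenotype data.frame with `id`, `sex`, `y_quant`.
#' @param resid named GRAMMAR residual vector.
#' @param dosage named dosage vector.
#' @return list with `phenotype_pct` and `residual_pct`.
#' @export
variance_explained_both <- function(phen, resid, dosage) {
  adj <- residuals(lm(y_quant ~ factor(sex), data = phen))
  names(adj) <- as.character(phen$id)
  ids_p <- intersect(names(adj), names(dosage))
  ids_r <- intersect(names(resid), names(dosage))
  list(phenotype_pct = snp_variance_explained(adj[ids_p], dosage[ids_p]),
       residual_pct = snp_variance_explained(resid[ids_r], dosage[ids_r]))
}
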