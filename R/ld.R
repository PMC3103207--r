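#' EM haplotype-frequency estimation for two biallelic loci
#'
#' Estimates the 2x2 haplotype frequency table from unphased dosages.
#' Only the double heterozygote is phase-ambiguous; the EM algorithm
#' splits its count between the coupling (11/00) and repulsion (10/01)
#' phases in proportion to the current haplotype-frequency estimates,
#' converging to a stationary point of the two-locus multinomial
#' likelihood.
#'
#' Haplotype 1-alleles are the alleles counted by the dosages; `pi[1,1]`
#' is the frequency of the haplotype carrying allele 1 at both loci.
#'
#' @param g1,g2 dosage vectors in \{0,1,2\} (missing -1/NA dropped pairwise).
#' @param tol EM convergence tolerance on frequencies (default 1e-10).
#' @param max_iter maximum EM iterations (default 1000).
#' @return list of class `haplotype_table`: `pi` (2x2 matrix, rows =
#'   locus-1 allele 1/0, cols = locus-2 allele 1/0), `p` and `q`
#'   (marginal allele-1 frequencies), `n` (individuals), `iterations`,
#'   `monomorphic` flag, `loglik` trace.
#' @export
em_haplotypes <- function(g1, g2, tol = 1e-10, max_iter = 1000) {
  ok <- !is.na(g1) & !is.na(g2) & g1 >= 0 & g2 >= 0
  g1 <- g1[ok]; g2 <- g2[ok]
  n <- length(g1)
  if (n < 10) stop("need at least 10 complete genotype pairs")
  cnt <- matrix(0, 3, 3)
  for (i in 0:2) for (j in 0:2) cnt[i + 1, j + 1] <- sum(g1 == i & g2 == j)
  mono <- var(g1) == 0 || var(g2) == 0
  # unambiguous haplotype counts (h11, h10, h01, h00); double het ambiguous
  h <- c(
    h11 = 2 * cnt[3, 3] + cnt[3, 2] + cnt[2, 3],
    h10 = 2 * cnt[3, 1] + cnt[3, 2] + cnt[2, 1],
    h01 = 2 * cnt[1, 3] + cnt[1, 2] + cnt[2, 3],
    h00 = 2 * cnt[1, 1] + cnt[1, 2] + cnt[2, 1]
  )
  ndh <- cnt[2, 2]
  pi_v <- (h + ndh / 2) / (2 * n)
  ll <- numeric(0)
  it <- 0L
  if (ndh > 0 && !mono) {
    repeat {
      it <- it + 1L
      coup <- pi_v[1] * pi_v[4]
      rep_ <- pi_v[2] * pi_v[3]
      frac <- if (coup + rep_ > 0) coup / (coup + rep_) else 0.5
      newpi <- (h + ndh * c(frac, 1 - frac, 1 - frac, frac)) / (2 * n)
      ll <- c(ll, em_loglik(newpi, h, ndh))
      if (max(abs(newpi - pi_v)) < tol || it >= max_iter) { pi_v <- newpi; break }
      pi_v <- newpi
    }
  }
  pim <- matrix(unname(pi_v[c(1, 2, 3, 4)]), 2, 2, byrow = TRUE,
                dimnames = list(c("a1.1", "a1.0"), c("a2.1", "a2.0")))
  structure(list(pi = pim, p = unname(pi_v[1] + pi_v[2]),
                 q = unname(pi_v[1] + pi_v[3]),
                 n = n, iterations = it, monomorphic = mono, loglik = ll),
            class = "haplotype_table")
}

em_loglik <- function(pi_v, h, ndh) {
  lp <- ifelse(pi_v > 0, log(pi_v), 0)
  sum(h * lp) + ndh * log(max(2 * (pi_v[1] * pi_v[4] + pi_v[2] * pi_v[3]),
                              .Machine$double.xmin))
}

#' Devlin-Risch pairwise linkage-disequilibrium statistics
#'
#' From a 2x2 haplotype table computes the classical LD measures:
#' `D = pi11 - p q`; `D' = D / Dmax` with
#' `Dmax = min(p(1-q), (1-p)q)` for positive D and `min(pq, (1-p)(1-q))`
#' otherwise; the correlation `r = D / sqrt(p(1-p)q(1-q))`; Yule's
#' `Q = (pi11 pi22 - pi12 pi21) / (pi11 pi22 + pi12 pi21)`; the
#' proportional difference `d = pi11/q - pi12/(1-q)`; the population
#' attributable-risk form `delta = (pi11 pi22 - pi12 pi21) / (q pi22)`;
#' and `chisq = n r^2` (df = 1), with n the number of individuals.
#'
#' @param h a [em_haplotypes()] result.
#' @return one-row data.frame: ChiSq, P_Chi, D, CorrCoeff, Dprime,
#'   Delta, PropDiff, YulesQ, n, defined (FALSE when marginal
#'   frequencies make statistics undefined).
#' @export
ld_measures <- function(h) {
  stopifnot(inherits(h, "haplotype_table"))
  pi11 <- h$pi[1, 1]; pi12 <- h$pi[1, 2]
  pi21 <- h$pi[2, 1]; pi22 <- h$pi[2, 2]
  p <- h$p; q <- h$q
  defined <- p > 0 && p < 1 && q > 0 && q < 1
  if (!defined) {
    return(data.frame(ChiSq = NA_real_, P_Chi = NA_real_, D = NA_real_,
                      CorrCoeff = NA_real_, Dprime = NA_real_,
                      Delta = NA_real_, PropDiff = NA_real_,
                      YulesQ = NA_real_, n = h$n, defined = FALSE))
  }
  D <- pi11 - p * q
  Dmax <- if (D > 0) min(p * (1 - q), (1 - p) * q)
          else min(p * q, (1 - p) * (1 - q))
  Dprime <- if (Dmax > 0) D / Dmax else 0
  r <- D / sqrt(p * (1 - p) * q * (1 - q))
  cross <- pi11 * pi22 - pi12 * pi21
  denomQ <- pi11 * pi22 + pi12 * pi21
  Q <- if (denomQ > 0) cross / denomQ else NA_real_
  delta <- if (q * pi22 > 0) cross / (q * pi22) else NA_real_
  pd <- pi11 / q - pi12 / (1 - q)
  chi <- h$n * r^2
  data.frame(ChiSq = chi, P_Chi = pchisq(chi, 1, lower.tail = FALSE),
             D = D, CorrCoeff = r, Dprime = Dprime, Delta = delta,
             PropDiff = pd, YulesQ = Q, n = h$n, defined = TRUE)
}

#' LD statistics for a list of SNP pairs
#'
#' Convenience wrapper: for each requested marker pair, dosages are
#' oriented to count the minor allele at both loci (signed statistics are
#' kept), haplotype frequencies are estimated by EM, and the full
#' Devlin-Risch statistic set is reported.
#'
#' @param g a `geno_matrix`.
#' @param pairs two-column matrix or data.frame of SNP ids; if `NULL`,
#'   all pairs among the SNPs in `snps`.
#' @param snps optional SNP-id subset used when `pairs` is `NULL`.
#' @return data.frame with Marker1, Marker2 and the [ld_measures()]
#'   columns, one row per pair.
#' @export
ld_pairs <- function(g, pairs = NULL, snps = NULL) {
  stopifnot(inherits(g, "geno_matrix"))
  if (is.null(pairs)) {
    if (is.null(snps)) snps <- g$map$snp
    if (length(snps) < 2) stop("need at least 2 SNPs")
    pairs <- t(combn(snps, 2))
  }
  pairs <- as.matrix(pairs)
  out <- vector("list", nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    j1 <- match(pairs[k, 1], g$map$snp)
    j2 <- match(pairs[k, 2], g$map$snp)
    if (is.na(j1) || is.na(j2)) stop("unknown SNP id in pair ", k)
    d1 <- orient_minor(g$dosage[, j1])
    d2 <- orient_minor(g$dosage[, j2])
    res <- ld_measures(em_haplotypes(d1, d2))
    out[[k]] <- cbind(data.frame(Marker1 = pairs[k, 1],
                                 Marker2 = pairs[k, 2]), res)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# flip dosages so that allele 1 is the minor allele
orient_minor <- function(d) {
  dd <- d; dd[dd < 0] <- NA
  if (mean(dd, na.rm = TRUE) / 2 > 0.5) dd <- 2 - dd
  dd
}
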