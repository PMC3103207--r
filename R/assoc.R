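#' Single-SNP linear scan on GRAMMAR residuals
#'
#' Second stage of the GRAMMAR procedure: for each SNP an ordinary least
#' squares regression of the stage-1 animal-model residual on allele
#' dosage plus intercept, with a Wald t-test on the slope.  Missing
#' dosages (-1) are excluded per SNP; SNPs with zero dosage variance are
#' skipped with a flag.
#'
#' @param resid named residual vector from [grammar_residuals()] (or any
#'   named quantitative response).
#' @param g a `geno_matrix`; individuals matched to `resid` by name.
#' @return data.frame of class `assoc_result`: snp, chrom, pos_bp, n,
#'   beta, se, stat, p, skipped.
#' @export
snp_scan_linear <- function(resid, g) {
  stopifnot(inherits(g, "geno_matrix"))
  ids <- intersect(names(resid), rownames(g$dosage))
  if (!length(ids)) stop("no overlapping individuals between residuals and genotypes")
  y <- resid[ids]
  D <- g$dosage[ids, , drop = FALSE]
  obs <- D >= 0
  G <- D; G[!obs] <- 0
  storage.mode(G) <- "double"
  O <- obs + 0
  nk <- colSums(O)
  sy <- drop(crossprod(O, y))          # sum of y over non-missing
  syy <- drop(crossprod(O, y^2))
  sx <- colSums(G)
  sxx <- colSums(G^2)
  sxy <- drop(crossprod(G, y))
  Sxx <- sxx - sx^2 / nk
  Syy <- syy - sy^2 / nk
  Sxy <- sxy - sx * sy / nk
  skipped <- Sxx <= 1e-12 | nk < 3
  beta <- ifelse(skipped, NA_real_, Sxy / Sxx)
  rss <- pmax(Syy - beta^2 * Sxx, 0)
  s2 <- rss / (nk - 2)
  se <- sqrt(s2 / Sxx)
  tt <- beta / se
  p <- 2 * pt(abs(tt), df = nk - 2, lower.tail = FALSE)
  res <- data.frame(snp = g$map$snp, chrom = g$map$chrom,
                    pos_bp = g$map$pos_bp, n = nk,
                    beta = beta, se = se, stat = tt, p = p,
                    skipped = skipped)
  res$beta[skipped] <- res$se[skipped] <- res$stat[skipped] <-
    res$p[skipped] <- NA_real_
  class(res) <- c("assoc_result", "data.frame")
  res
}

#' Permutation-based genome-wide significance threshold
#'
#' Permutes the stage-2 response across individuals `n_perm` times,
#' re-runs the full single-SNP scan for each permutation, and returns the
#' empirical `alpha`-quantile of the per-permutation minimum p-value as
#' the genome-wide threshold.
#'
#' @param resid named residual vector.
#' @param g a `geno_matrix`.
#' @param n_perm number of permutations (>= 100 recommended; fewer
#'   triggers a warning about tail instability).
#' @param alpha genome-wide significance level.
#' @param seed optional RNG seed for the permutations.
#' @return list of class `perm_null`: `n_perm`, `alpha`, `min_p`
#'   (per-permutation minima), `threshold`, and `significant` (SNP ids
#'   from the observed scan with nominal p below the threshold).
#' @export
permutation_threshold <- function(resid, g, n_perm = 1000, alpha = 0.05,
                                  seed = NULL) {
  if (n_perm < 100) warning("n_perm < 100: threshold tail is unstable")
  if (!is.null(seed)) set.seed(seed)
  ids <- intersect(names(resid), rownames(g$dosage))
  y <- resid[ids]
  n <- length(y)
  D <- g$dosage[ids, , drop = FALSE]
  obs <- D >= 0
  G <- D; G[!obs] <- 0
  storage.mode(G) <- "double"
  O <- obs + 0
  nk <- colSums(O)
  sx <- colSums(G)
  sxx <- colSums(G^2)
  Sxx <- sxx - sx^2 / nk
  usable <- Sxx > 1e-12 & nk >= 3
  P <- vapply(seq_len(n_perm), function(i) y[sample.int(n)], numeric(n))
  sy <- crossprod(O, P)                # m x n_perm
  syy <- crossprod(O, P^2)
  sxy <- crossprod(G, P)
  Sxy <- sxy - sx * sy / nk            # recycles by column
  Syy <- syy - sy^2 / nk
  r2 <- (Sxy^2 / Sxx) / Syy
  r2 <- pmin(pmax(r2, 0), 1)
  tt2 <- r2 / (1 - r2) * (nk - 2)
  pmat <- 2 * pt(sqrt(tt2), df = nk - 2, lower.tail = FALSE)
  pmat[!usable, ] <- NA
  min_p <- apply(pmat, 2, min, na.rm = TRUE)
  threshold <- if (alpha >= 1) 1 else
    unname(quantile(min_p, probs = alpha, type = 1))
  scan <- snp_scan_linear(resid, g)
  sig <- scan$snp[!is.na(scan$p) & scan$p <= threshold]
  structure(list(n_perm = n_perm, alpha = alpha, min_p = min_p,
                 threshold = threshold, significant = sig),
            class = "perm_null")
}

#' Stratification principal components of a genotype matrix
#'
#' Price-style PCA: each SNP column is centered by `2p` and scaled by
#' `sqrt(2 p (1 - p))` (p = allele frequency from non-missing dosages;
#' missing values replaced by the column mean), monomorphic SNPs are
#' excluded, and the top-K left singular vectors provide per-individual
#' principal-component loadings for use as regression covariates.
#'
#' @param g a `geno_matrix`.
#' @param K number of components; if `NULL`, the smallest K whose
#'   cumulative variance explained reaches `var_target` is used.
#' @param var_target cumulative variance-explained target used when `K`
#'   is `NULL` (default 0.75).
#' @return list of class `strat_pcs`: `scores` (n x K), `varexp`
#'   (variance-explained proportions of all computed PCs), `K`,
#'   `excluded` (monomorphic SNP ids).
#' @export
stratification_pcs <- function(g, K = NULL, var_target = 0.75) {
  stopifnot(inherits(g, "geno_matrix"))
  D <- g$dosage
  D[D < 0] <- NA
  p <- colMeans(D, na.rm = TRUE) / 2
  mono <- is.na(p) | p <= 0 | p >= 1
  D <- D[, !mono, drop = FALSE]
  p <- p[!mono]
  Z <- sweep(D, 2, 2 * p, "-")
  Z <- sweep(Z, 2, sqrt(2 * p * (1 - p)), "/")
  Z[is.na(Z)] <- 0
  n <- nrow(Z); m <- ncol(Z)
  if (!is.null(K) && K >= min(n, m)) stop("K must be < min(n individuals, m SNPs)")
  sv <- svd(Z, nu = min(n, m), nv = 0)
  varexp <- sv$d^2 / sum(sv$d^2)
  if (is.null(K)) K <- which(cumsum(varexp) >= var_target)[1]
  scores <- sv$u[, seq_len(K), drop = FALSE] %*%
    diag(sv$d[seq_len(K)], K, K)
  rownames(scores) <- rownames(g$dosage)
  colnames(scores) <- paste0("PC", seq_len(K))
  structure(list(scores = scores, varexp = varexp, K = K,
                 excluded = g$map$snp[mono]),
            class = "strat_pcs")
}

# logistic regression via IRLS returning slope stats for column 2;
# returns c(beta, se, converged, separated)
logit_fit_snp <- function(Xmat, ybin, max_iter = 25, tol = 1e-8) {
  fit <- suppressWarnings(
    glm.fit(Xmat, ybin, family = binomial(),
            control = list(maxit = max_iter, epsilon = tol)))
  w <- fit$weights
  XtWX <- crossprod(Xmat * sqrt(w))
  cov2 <- tryCatch(chol2inv(chol(XtWX))[2, 2], error = function(e) NA_real_)
  beta <- fit$coefficients[2]
  se <- sqrt(cov2)
  separated <- !is.finite(se) || se > 50 || abs(beta) > 20
  c(beta = unname(beta), se = unname(se),
    converged = as.numeric(fit$converged), separated = as.numeric(separated))
}

#' PC-adjusted logistic single-SNP scan for a binary trait
#'
#' For each SNP, logistic regression of case status on dosage plus the
#' stratification principal components and an intercept, with a Wald
#' z-test on the dosage coefficient.  Zero-variance SNPs are skipped;
#' non-converged or separated fits are flagged, not fatal.
#'
#' @param y_binary 0/1 vector named by individual id.
#' @param g a `geno_matrix`.
#' @param pcs a [stratification_pcs()] result (or NULL for unadjusted).
#' @return `assoc_result` data.frame with columns snp, chrom, pos_bp, n,
#'   beta, se, stat, p, skipped, converged.
#' @export
snp_scan_logistic <- function(y_binary, g, pcs = NULL) {
  stopifnot(inherits(g, "geno_matrix"))
  ids <- intersect(names(y_binary), rownames(g$dosage))
  if (!length(ids)) stop("no overlapping individuals")
  y <- y_binary[ids]
  if (length(unique(y)) < 2) stop("both classes must be present")
  C <- if (is.null(pcs)) NULL else pcs$scores[ids, , drop = FALSE]
  D <- g$dosage[ids, , drop = FALSE]
  m <- ncol(D)
  out <- matrix(NA_real_, m, 4)
  skipped <- logical(m)
  for (k in seq_len(m)) {
    dk <- D[, k]
    ok <- dk >= 0
    if (var(dk[ok]) <= 1e-12 || sum(ok) < 10) { skipped[k] <- TRUE; next }
    X <- cbind(1, dk[ok], C[ok, , drop = FALSE])
    out[k, ] <- logit_fit_snp(X, y[ok])
  }
  z <- out[, 1] / out[, 2]
  res <- data.frame(snp = g$map$snp, chrom = g$map$chrom,
                    pos_bp = g$map$pos_bp, n = colSums(D >= 0),
                    beta = out[, 1], se = out[, 2], stat = z,
                    p = 2 * pnorm(abs(z), lower.tail = FALSE),
                    skipped = skipped,
                    converged = out[, 3] > 0 & out[, 4] == 0)
  res[skipped, c("beta", "se", "stat", "p")] <- NA_real_
  class(res) <- c("assoc_result", "data.frame")
  res
}

# Grenander decreasing-density estimate on [0,1]: slopes of the least
# concave majorant of the ECDF.  Returns a step function of p.
grenander_density <- function(p) {
  p <- pmax(p, 1e-15)           # an exact zero has no finite density
  x <- unique(c(0, sort(unique(p)), 1))
  Fx <- ecdf(p)(x)
  Fx[1] <- 0
  # least concave majorant via upper-hull scan: keep slopes decreasing
  hull <- 1L
  for (i in 2:length(x)) {
    while (length(hull) >= 2) {
      m <- length(hull)
      s1 <- (Fx[hull[m]] - Fx[hull[m - 1]]) / (x[hull[m]] - x[hull[m - 1]])
      s2 <- (Fx[i] - Fx[hull[m]]) / (x[i] - x[hull[m]])
      if (s2 > s1) hull <- hull[-m] else break
    }
    hull <- c(hull, i)
  }
  xs <- x[hull]
  slopes <- diff(Fx[hull]) / diff(xs)
  function(q) slopes[pmin(findInterval(q, xs, rightmost.closed = TRUE),
                          length(slopes))]
}

#' Local false discovery rate from a Grenander density estimate
#'
#' Fits a decreasing density f to the p-values (slopes of the least
#' concave majorant of their ECDF), estimates the null proportion
#' `eta0` as f near 1, and reports `fdr(p) = min(1, eta0 / f(p))` per
#' test.  Tests with `fdr <= cutoff` form the significant set; the
#' implied p-value cutoff (largest significant p) is also returned.
#'
#' @param p p-value vector in \[0,1\], length >= 100.
#' @param cutoff local-fdr significance cutoff (default 0.2).
#' @return list of class `local_fdr`: `eta0`, `fdr` (aligned with `p`),
#'   `significant` (logical), `p_cutoff`.
#' @export
local_fdr <- function(p, cutoff = 0.2) {
  p <- as.numeric(p)
  if (any(is.na(p) | p < 0 | p > 1)) stop("p-values must be in [0, 1]")
  if (length(p) < 100) stop("need at least 100 p-values")
  if (length(unique(p)) == 1) stop("degenerate p-value vector (all equal)")
  f <- grenander_density(p)
  # null proportion: density of the hull segment at the upper end of the
  # observed p-values, floored at the resolution 1/n (an empty tail
  # cannot witness eta0 = 0 exactly)
  eta0 <- min(max(f(min(max(p), 1 - 1e-9) - 1e-12), 1 / length(p)), 1)
  fdr <- pmin(1, eta0 / pmax(f(p), .Machine$double.eps))
  sig <- !is.na(fdr) & fdr <= cutoff
  structure(list(eta0 = eta0, fdr = fdr, significant = sig,
                 p_cutoff = if (any(sig)) max(p[sig]) else NA_real_),
            class = "local_fdr")
}

#' Genomic inflation factor
#'
#' Median observed chi-square statistic divided by the null median
#' (qchisq(0.5, 1) = 0.4549); values above 1 indicate residual
#' confounding or stratification.
#'
#' @param p nominal p-value vector (two-sided, df = 1 statistics).
#' @return lambda_GC.
#' @export
genomic_inflation <- function(p) {
  chi <- qchisq(p[!is.na(p)], df = 1, lower.tail = FALSE)
  median(chi) / qchisq(0.5, df = 1)
}
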