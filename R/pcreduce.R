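#' Principal-component regression over a top-SNP panel (PCReg)
#'
#' Breaks collinearity among significant SNPs: principal components are
#' computed from the centered dosage submatrix of the top SNPs, the trait
#' is regressed jointly (linear or logistic) on the top-K component
#' scores, and a SNP is retained if it loads at least
#' `loading_threshold` in absolute value on at least one component that
#' is significant at `pc_alpha`.
#'
#' @param trait numeric (identity link) or 0/1 (logit link) vector named
#'   by individual id.
#' @param g_top `geno_matrix` restricted to the top SNPs.
#' @param link `"identity"` or `"logit"`.
#' @param K number of components; if `NULL` chosen as the smallest K
#'   reaching `var_target` cumulative variance explained.
#' @param var_target cumulative variance target (default 0.8).
#' @param pc_alpha per-component significance level (default 0.05).
#' @param loading_threshold minimum |loading|; default `1 / sqrt(m)` (an
#'   above-average contribution among m SNPs).
#' @return list of class `pcreg_result`: `loadings` (SNPs x PCs),
#'   `varexp`, `K`, `coef` (per-PC estimate, se, stat, p, significant),
#'   `retained` (SNP ids), `map` (map rows of the top SNPs).
#' @export
pcreg <- function(trait, g_top, link = c("identity", "logit"), K = NULL,
                  var_target = 0.8, pc_alpha = 0.05,
                  loading_threshold = NULL) {
  link <- match.arg(link)
  stopifnot(inherits(g_top, "geno_matrix"))
  if (!ncol(g_top$dosage)) stop("empty top-SNP set")
  ids <- intersect(names(trait), rownames(g_top$dosage))
  y <- trait[ids]
  if (link == "logit" && !all(y %in% 0:1)) stop("logit link needs a 0/1 trait")
  D <- g_top$dosage[ids, , drop = FALSE]
  D[D < 0] <- NA
  cm <- colMeans(D, na.rm = TRUE)
  for (j in which(colSums(is.na(D)) > 0)) D[is.na(D[, j]), j] <- cm[j]
  m <- ncol(D)
  pr <- prcomp(D, center = TRUE, scale. = FALSE)
  varexp <- pr$sdev^2 / sum(pr$sdev^2)
  rank <- sum(pr$sdev > max(pr$sdev) * 1e-8)
  if (is.null(K)) K <- which(cumsum(varexp) >= var_target)[1]
  if (K > rank) {
    warning("K reduced to rank of the dosage submatrix (", rank, ")")
    K <- rank
  }
  scores <- pr$x[, seq_len(K), drop = FALSE]
  if (link == "identity") {
    fit <- lm(y ~ scores)
    ct <- summary(fit)$coefficients[-1, , drop = FALSE]
  } else {
    fit <- glm(y ~ scores, family = binomial())
    ct <- summary(fit)$coefficients[-1, , drop = FALSE]
  }
  coef_tab <- data.frame(pc = paste0("PC", seq_len(K)),
                         estimate = ct[, 1], se = ct[, 2],
                         stat = ct[, 3], p = ct[, 4])
  coef_tab$significant <- coef_tab$p <= pc_alpha
  if (is.null(loading_threshold)) loading_threshold <- 1 / sqrt(m)
  L <- pr$rotation[, seq_len(K), drop = FALSE]
  sig_pcs <- which(coef_tab$significant)
  keep <- if (length(sig_pcs))
    rowSums(abs(L[, sig_pcs, drop = FALSE]) >= loading_threshold) > 0
  else rep(FALSE, m)
  structure(list(loadings = pr$rotation, varexp = varexp, K = K,
                 coef = coef_tab, retained = g_top$map$snp[keep],
                 loading_threshold = loading_threshold,
                 map = g_top$map),
            class = "pcreg_result")
}

#' @export
print.pcreg_result <- function(x, ...) {
  cat(sprintf("PCReg: %d SNPs -> %d PCs (%d significant) -> %d retained SNPs\n",
              nrow(x$loadings), x$K, sum(x$coef$significant),
              length(x$retained)))
  invisible(x)
}

#' Export loading-plot coordinates for the top SNPs
#'
#' Tabular form of the first two principal-component loadings per SNP,
#' for plotting SNP clusters against chromosome and LD structure.
#'
#' @param res a [pcreg()] result with at least 2 components.
#' @return data.frame (snp, chrom, PC1, PC2), one row per top SNP.
#' @export
export_loading_plot_data <- function(res) {
  stopifnot(inherits(res, "pcreg_result"))
  if (ncol(res$loadings) < 2) stop("need at least 2 principal components")
  data.frame(snp = res$map$snp, chrom = res$map$chrom,
             PC1 = res$loadings[, 1], PC2 = res$loadings[, 2])
}
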