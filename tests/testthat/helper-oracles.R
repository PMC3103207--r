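# Independent oracle implementations used to cross-check the package.
# These deliberately re-derive each quantity from first principles and
# share no code with the implementation under test.

# --- gene-dropping IBD estimate of the additive relationship matrix ----
# Drop allele labels through the pedigree R times; the estimated
# relationship of i and j is half the expected number of IBD allele
# matches among the four cross-pairs.
gene_drop_relationship <- function(ped, pairs, R = 1e5) {
  n <- nrow(ped)
  si <- match(ped$sire, ped$id)
  di <- match(ped$dam, ped$id)
  a1 <- matrix(0L, n, R)
  a2 <- matrix(0L, n, R)
  nxt <- 1L
  for (i in seq_len(n)) {
    if (is.na(si[i]) || is.na(di[i])) {
      a1[i, ] <- nxt; a2[i, ] <- nxt + 1L; nxt <- nxt + 2L
    } else {
      pick <- runif(R) < 0.5
      a1[i, ] <- ifelse(pick, a1[si[i], ], a2[si[i], ])
      pick <- runif(R) < 0.5
      a2[i, ] <- ifelse(pick, a1[di[i], ], a2[di[i], ])
    }
  }
  vapply(seq_len(nrow(pairs)), function(r) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    if (i == j) 1 + mean(a1[i, ] == a2[i, ])
    else mean((a1[i, ] == a1[j, ]) + (a1[i, ] == a2[j, ]) +
              (a2[i, ] == a1[j, ]) + (a2[i, ] == a2[j, ])) / 2
  }, numeric(1))
}

# --- dense mixed-model-equations solver (Henderson) -------------------
# Returns fixed effects, BLUPs and residuals for y = Xb + a + e with
# var(a) = A s2a, var(e) = I s2e, all individuals phenotyped.
mme_solve <- function(y, X, A, s2a, s2e) {
  n <- length(y)
  alpha <- s2e / s2a
  Ainv <- solve(A)
  C <- rbind(cbind(crossprod(X), t(X)),
             cbind(X, diag(n) + Ainv * alpha))
  rhs <- c(crossprod(X, y), y)
  sol <- solve(C, rhs)
  b <- sol[seq_len(ncol(X))]
  a <- sol[-seq_len(ncol(X))]
  list(b = b, a = a, e = y - drop(X %*% b) - a)
}

# --- classical sire-model ANOVA heritability --------------------------
# Balanced paternal half-sib design: h2 = 4 * s2_sire / (s2_sire + s2_within).
anova_h2 <- function(y, sire) {
  k <- table(sire)
  stopifnot(length(unique(k)) == 1)
  k <- unname(k[1])
  fit <- aov(y ~ factor(sire))
  ms <- summary(fit)[[1]][["Mean Sq"]]
  s2s <- max((ms[1] - ms[2]) / k, 0)
  4 * s2s / (s2s + ms[2])
}

# --- LD statistics recomputed from the 2x2 haplotype table -------------
# Independent formula coding (different parameterisation: works from the
# four haplotype frequencies directly).
ld_oracle <- function(h11, h10, h01, h00, n) {
  pA <- h11 + h10
  pB <- h11 + h01
  D <- h11 * h00 - h10 * h01        # pi11 - pA pB, expanded form
  r <- D / sqrt(pA * (1 - pA) * pB * (1 - pB))
  Dmax <- if (D > 0) min(pA * (1 - pB), (1 - pA) * pB) else
    min(pA * pB, (1 - pA) * (1 - pB))
  list(
    D = D,
    Dprime = if (Dmax > 0) D / Dmax else 0,
    r = r,
    Q = (h11 * h00 - h10 * h01) / (h11 * h00 + h10 * h01),
    delta = (h11 * h00 - h10 * h01) / (pB * h00),
    propdiff = h11 / pB - h10 / (1 - pB),
    chisq = n * r^2
  )
}

# --- prequential BDeu oracle ------------------------------------------
# Product of sequential predictive probabilities under the Dirichlet
# prior; equals the closed-form marginal likelihood for every row order.
preq_score <- function(child, parents, data, arity, ess,
                       order = seq_len(nrow(data))) {
  q <- if (length(parents)) prod(arity[parents]) else 1
  r <- arity[child]
  a_jk <- ess / (q * r)
  a_j <- ess / q
  njk <- matrix(0, q, r)
  nj <- numeric(q)
  lp <- 0
  for (row in order) {
    j <- 1; mult <- 1
    for (pp in parents) {
      j <- j + (data[row, pp] - 1) * mult
      mult <- mult * arity[pp]
    }
    k <- data[row, child]
    lp <- lp + log((a_jk + njk[j, k]) / (a_j + nj[j]))
    njk[j, k] <- njk[j, k] + 1
    nj[j] <- nj[j] + 1
  }
  lp
}

# --- exhaustive forest / DAG enumeration -------------------------------
score_parent_list <- function(parents_list, data, arity, ess) {
  sum(vapply(seq_along(parents_list), function(j)
    grammarbn::bdeu_family_score(j, parents_list[[j]], data, arity, ess),
    numeric(1)))
}

# best score over all forests (each node has <= 1 parent, no cycles)
enumerate_best_forest <- function(data, arity, ess) {
  v <- ncol(data)
  grid <- expand.grid(lapply(seq_len(v), function(j)
    c(0L, setdiff(seq_len(v), j))))
  best <- -Inf
  for (rr in seq_len(nrow(grid))) {
    pa <- as.integer(grid[rr, ])
    ok <- TRUE
    for (s in seq_len(v)) {
      u <- s; steps <- 0L
      while (pa[u] != 0L) {
        u <- pa[u]; steps <- steps + 1L
        if (u == s || steps > v) { ok <- FALSE; break }
      }
      if (!ok) break
    }
    if (!ok) next
    pl <- lapply(pa, function(x) if (x == 0L) integer(0) else x)
    sc <- score_parent_list(pl, data, arity, ess)
    if (sc > best) best <- sc
  }
  best
}

# all DAGs on v nodes as parent-set lists (v = 3 gives the 25 DAGs)
enumerate_dags <- function(v) {
  subsets <- function(x) {
    out <- list(integer(0))
    for (e in x) out <- c(out, lapply(out, function(s) c(s, e)))
    out
  }
  per_node <- lapply(seq_len(v), function(j) subsets(setdiff(seq_len(v), j)))
  idx <- expand.grid(lapply(per_node, seq_along))
  dags <- list()
  for (rr in seq_len(nrow(idx))) {
    pl <- lapply(seq_len(v), function(j) per_node[[j]][[idx[rr, j]]])
    # topological-sort acyclicity check
    indeg <- lengths(pl)
    pl2 <- pl; removed <- logical(v); acyclic <- TRUE
    for (it in seq_len(v)) {
      free <- which(!removed & vapply(pl2, length, 1L) == 0L)
      if (!length(free)) { acyclic <- any(!removed) == FALSE; break }
      removed[free] <- TRUE
      pl2 <- lapply(pl2, function(s) setdiff(s, free))
    }
    if (all(removed)) dags[[length(dags) + 1L]] <- pl
  }
  dags
}

# --- misc helpers ------------------------------------------------------
# wrap a plain dosage matrix as the package's genotype container
make_geno <- function(dosage, chrom = NULL, pos_bp = NULL,
                      ids = NULL, snp = NULL) {
  n <- nrow(dosage); m <- ncol(dosage)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  rownames(dosage) <- ids
  map <- data.frame(
    snp = if (is.null(snp)) paste0("S", seq_len(m)) else snp,
    chrom = if (is.null(chrom)) rep(1L, m) else chrom,
    pos_bp = if (is.null(pos_bp)) seq_len(m) * 1e5 else pos_bp,
    allele1 = "A", allele2 = "B",
    freq_a1 = colMeans(pmax(dosage, 0)) / 2)
  structure(list(dosage = dosage, map = map, qtl = NULL),
            class = "geno_matrix")
}

# sample n unphased genotype pairs from a 2x2 haplotype distribution
sample_genotypes_from_haps <- function(n, h11, h10, h01, h00) {
  probs <- c(h11, h10, h01, h00)
  hap_alleles <- rbind(c(1, 1), c(1, 0), c(0, 1), c(0, 0))
  i1 <- sample.int(4, n, replace = TRUE, prob = probs)
  i2 <- sample.int(4, n, replace = TRUE, prob = probs)
  list(g1 = hap_alleles[i1, 1] + hap_alleles[i2, 1],
       g2 = hap_alleles[i1, 2] + hap_alleles[i2, 2],
       hap_counts = (tabulate(i1, 4) + tabulate(i2, 4)) / (2 * n))
}

# categorical chain sampler X1 -> X2 -> ... -> Xv, `stay` = copy prob
sample_chain <- function(n, v, states = 3, stay = 0.7) {
  X <- matrix(0L, n, v)
  X[, 1] <- sample.int(states, n, replace = TRUE)
  for (j in 2:v) {
    copy <- runif(n) < stay
    X[, j] <- ifelse(copy, X[, j - 1],
                     sample.int(states, n, replace = TRUE))
  }
  X
}
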