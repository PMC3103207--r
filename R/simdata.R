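#' Default additive QTL panel for the simulator
#'
#' Five QTL, one per chromosome, with variance fractions chosen as a
#' conventional decreasing series led by a 4.49\% locus.  Fractions are
#' proportions of the (unit) phenotypic variance of the quantitative trait.
#'
#' @return data.frame with columns `chrom`, `pos_bp`, `frac` (variance
#'   fraction of the phenotypic variance) and `freq` (founder allele
#'   frequency of the trait-increasing allele).
#' @export
default_qtl <- function() {
  data.frame(
    chrom  = 1:5,
    pos_bp = c(32750000L, 51250000L, 18750000L, 72250000L, 60750000L),
    frac   = c(0.0449, 0.030, 0.020, 0.015, 0.010),
    freq   = c(0.30, 0.35, 0.25, 0.40, 0.30)
  )
}

#' Simulation configuration for half-sib QTL data
#'
#' Bundles and validates every parameter of the generative model: a
#' multi-generation half-sib pedigree (each sire mated to several dams,
#' each dam with several offspring), linked biallelic SNPs with tunable
#' block LD, additive QTL acting on a quantitative trait, and a
#' liability-threshold binary trait, plus a fixed sex effect.
#'
#' Defaults emulate the structure of a half-sib workshop dataset at desk
#' scale: 5 chromosomes of 200 SNPs each, 20 sires x 10 dams x 10
#' offspring (2220 individuals), quantitative heritability 0.58 and
#' binary liability heritability 0.44.
#'
#' @param n_sires,n_dams_per_sire,n_offspring_per_dam,n_generations
#'   positive integer mating-design counts.
#' @param n_chromosomes,snps_per_chromosome positive integers.
#' @param chromosome_length_bp chromosome length in base pairs.
#' @param qtl data.frame with columns `chrom`, `pos_bp`, `freq` and either
#'   `frac` (variance fraction of phenotypic variance) or `effect`
#'   (additive allele-substitution effect in trait units).
#' @param qtl_mode `"hidden"` (default): QTL are unobserved loci placed at
#'   their own positions, in LD with flanking SNPs through the haplotype
#'   model; `"at_snp"`: each QTL is attached to the nearest simulated SNP.
#' @param h2_quant narrow-sense heritability of the quantitative trait in
#'   \[0,1\] (QTL + polygenic).
#' @param h2_binary heritability of the latent liability in \[0,1\].
#' @param prevalence binary-trait prevalence in (0,1).
#' @param sex_effect additive fixed effect of sex (added to females), trait
#'   units; applied to both the quantitative trait and the liability.
#' @param ld_decay_rho per-adjacent-locus haplotype copying probability in
#'   \[0,1\]; larger values give stronger block LD among founders.
#' @param cm_per_mb genetic map density (centimorgan per megabase) used by
#'   the Haldane recombination model during gene dropping.
#' @param freq_range range the founder allele frequencies of ordinary SNPs
#'   are drawn from.
#' @param seed integer seed; a fixed seed makes all three simulation stages
#'   bit-reproducible.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_sires = 20, n_dams_per_sire = 10,
                       n_offspring_per_dam = 10, n_generations = 1,
                       n_chromosomes = 5, snps_per_chromosome = 200,
                       chromosome_length_bp = 1e8,
                       qtl = default_qtl(), qtl_mode = c("hidden", "at_snp"),
                       h2_quant = 0.58, h2_binary = 0.44, prevalence = 0.5,
                       sex_effect = 0.5, ld_decay_rho = 0.9, cm_per_mb = 1,
                       freq_range = c(0.1, 0.9), seed = NULL) {
  qtl_mode <- match.arg(qtl_mode)
  counts <- c(n_sires = n_sires, n_dams_per_sire = n_dams_per_sire,
              n_offspring_per_dam = n_offspring_per_dam,
              n_generations = n_generations, n_chromosomes = n_chromosomes,
              snps_per_chromosome = snps_per_chromosome)
  if (any(counts < 1) || any(counts != round(counts)))
    stop("all design counts must be positive integers")
  for (p in c(h2_quant, h2_binary, ld_decay_rho))
    if (p < 0 || p > 1) stop("proportions must lie in [0, 1]")
  if (prevalence <= 0 || prevalence >= 1) stop("prevalence must be in (0, 1)")
  if (chromosome_length_bp < snps_per_chromosome)
    stop("chromosome too short for the requested SNP count")
  if (!is.null(qtl) && nrow(qtl)) {
    need <- c("chrom", "pos_bp", "freq")
    if (!all(need %in% names(qtl)) ||
        !any(c("frac", "effect") %in% names(qtl)))
      stop("qtl needs columns chrom, pos_bp, freq and frac or effect")
    if (any(qtl$chrom < 1 | qtl$chrom > n_chromosomes))
      stop("QTL chromosome outside the simulated genome")
    if (any(qtl$pos_bp < 1 | qtl$pos_bp > chromosome_length_bp))
      stop("QTL position outside chromosome length")
    if ("frac" %in% names(qtl) && sum(qtl$frac) > h2_quant)
      stop("QTL variance fractions exceed h2_quant")
  }
  structure(list(
    n_sires = as.integer(n_sires),
    n_dams_per_sire = as.integer(n_dams_per_sire),
    n_offspring_per_dam = as.integer(n_offspring_per_dam),
    n_generations = as.integer(n_generations),
    n_chromosomes = as.integer(n_chromosomes),
    snps_per_chromosome = as.integer(snps_per_chromosome),
    chromosome_length_bp = chromosome_length_bp,
    qtl = qtl, qtl_mode = qtl_mode,
    h2_quant = h2_quant, h2_binary = h2_binary, prevalence = prevalence,
    sex_effect = sex_effect, ld_decay_rho = ld_decay_rho,
    cm_per_mb = cm_per_mb, freq_range = freq_range,
    seed = if (is.null(seed)) NULL else as.integer(seed)
  ), class = "sim_config")
}

#' Simulate a multi-generation half-sib pedigree
#'
#' Founders are `n_sires` males and `n_sires * n_dams_per_sire` females.
#' In each generation every sire is mated to `n_dams_per_sire` dams and
#' every dam produces `n_offspring_per_dam` offspring whose sexes alternate
#' male/female.  For generations after the first, sires and dams are drawn
#' from the previous generation's offspring in record order.
#'
#' @param cfg a [sim_config()].
#' @return data.frame (id, sire, dam, sex, gen) with `sire`/`dam` 0 for
#'   founders and `sex` coded 1 = male, 2 = female; parents always precede
#'   their offspring.
#' @export
simulate_pedigree <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  S <- cfg$n_sires; Dp <- cfg$n_dams_per_sire; O <- cfg$n_offspring_per_dam
  nd <- S * Dp
  ped <- data.frame(id = seq_len(S + nd),
                    sire = 0L, dam = 0L,
                    sex = rep(c(1L, 2L), c(S, nd)),
                    gen = 0L)
  sires <- seq_len(S)
  dams <- S + seq_len(nd)
  next_id <- S + nd + 1L
  for (g in seq_len(cfg$n_generations)) {
    if (g > 1) {
      prev <- ped[ped$gen == g - 1L, ]
      males <- prev$id[prev$sex == 1L]
      females <- prev$id[prev$sex == 2L]
      if (length(males) < S || length(females) < nd)
        stop("not enough offspring of each sex to parent generation ", g)
      sires <- males[seq_len(S)]
      dams <- females[seq_len(nd)]
    }
    n_off <- nd * O
    off <- data.frame(
      id = seq.int(next_id, length.out = n_off),
      sire = rep(rep(sires, each = Dp * O)),
      dam = rep(dams, each = O),
      sex = rep_len(c(1L, 2L), n_off),
      gen = g
    )
    ped <- rbind(ped, off)
    next_id <- next_id + n_off
  }
  ped
}

# Haldane recombination fraction between loci d_bp apart
haldane_c <- function(d_bp, cm_per_mb) {
  morgans <- d_bp / 1e6 * cm_per_mb / 100
  0.5 * (1 - exp(-2 * morgans))
}

# cumulative sum mod 2 along rows; x is a 0/1 matrix
row_cumsum_mod2 <- function(x) {
  if (ncol(x) == 1L) return(x %% 2L)
  t(apply(x, 1L, cumsum)) %% 2L
}

#' Simulate linked genotypes by gene dropping through a pedigree
#'
#' Founder haplotypes follow a first-order Markov allele-copying chain
#' along each chromosome (with probability `ld_decay_rho` a locus copies
#' the allele at the previous locus, otherwise it draws a fresh allele at
#' its own frequency), which produces tunable block LD.  Offspring
#' gametes are generated by gene dropping with Haldane recombination at a
#' rate proportional to the base-pair distance between adjacent loci
#' (`cm_per_mb`).
#'
#' Hidden QTL (the default `qtl_mode`) are simulated as extra loci at
#' their own map positions inside the same haplotype chain and then
#' removed from the returned SNP panel, so they are in LD with their
#' flanking SNPs but unobserved; their dosages are kept for
#' [simulate_phenotypes()].
#'
#' @param cfg a [sim_config()].
#' @param ped pedigree from [simulate_pedigree()].
#' @return object of class `geno_matrix`: list with `dosage`
#'   (individuals x SNPs integer matrix of allele-1 counts, rownames =
#'   individual ids), `map` (snp, chrom, pos_bp, allele1, allele2,
#'   freq_a1), and `qtl` (list with `dosage` matrix and `info`
#'   data.frame for the simulated QTL).
#' @export
simulate_genotypes <- function(cfg, ped) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed + 1L)
  m <- cfg$snps_per_chromosome
  len <- cfg$chromosome_length_bp
  snp_pos <- round(seq_len(m) * len / (m + 1))
  loci <- data.frame(chrom = rep(seq_len(cfg$n_chromosomes), each = m),
                     pos_bp = rep(snp_pos, cfg$n_chromosomes),
                     is_qtl = FALSE, qtl_row = NA_integer_)
  qtl <- cfg$qtl
  has_qtl <- !is.null(qtl) && nrow(qtl) > 0
  if (has_qtl && cfg$qtl_mode == "hidden") {
    extra <- data.frame(chrom = qtl$chrom, pos_bp = qtl$pos_bp,
                        is_qtl = TRUE, qtl_row = seq_len(nrow(qtl)))
    loci <- rbind(loci, extra)
  }
  loci <- loci[order(loci$chrom, loci$pos_bp), ]
  if (anyDuplicated(loci[c("chrom", "pos_bp")]))
    stop("duplicate locus positions (QTL coincides with a SNP; use qtl_mode = 'at_snp')")
  L <- nrow(loci)
  freq <- runif(L, cfg$freq_range[1], cfg$freq_range[2])
  if (has_qtl) {
    if (cfg$qtl_mode == "hidden") {
      freq[loci$is_qtl] <- qtl$freq[loci$qtl_row[loci$is_qtl]]
    } else {
      # attach each QTL to the nearest SNP on its chromosome
      loci$qtl_row <- NA_integer_
      for (k in seq_len(nrow(qtl))) {
        on_chr <- which(loci$chrom == qtl$chrom[k])
        j <- on_chr[which.min(abs(loci$pos_bp[on_chr] - qtl$pos_bp[k]))]
        loci$is_qtl[j] <- TRUE
        loci$qtl_row[j] <- k
        freq[j] <- qtl$freq[k]
      }
    }
  }

  n <- nrow(ped)
  founder <- ped$sire == 0L & ped$dam == 0L
  pos_of <- match(ped$id, ped$id)  # identity, ids are row-ordered
  if (any(!founder & (match(ped$sire, ped$id) >= seq_len(n) |
                      match(ped$dam, ped$id) >= seq_len(n))))
    stop("pedigree not sorted parents-first")
  H <- matrix(0L, nrow = 2L * n, ncol = L)
  f_rows <- c(rbind(2L * which(founder) - 1L, 2L * which(founder)))
  gens <- sort(unique(ped$gen[!founder]))

  for (chr in seq_len(cfg$n_chromosomes)) {
    idx <- which(loci$chrom == chr)
    nf <- length(f_rows)
    # founder Markov copying chain
    H[f_rows, idx[1]] <- rbinom(nf, 1L, freq[idx[1]])
    for (j in seq_along(idx)[-1]) {
      copy <- runif(nf) < cfg$ld_decay_rho
      fresh <- rbinom(nf, 1L, freq[idx[j]])
      H[f_rows, idx[j]] <- ifelse(copy, H[f_rows, idx[j - 1L]], fresh)
    }
    cvec <- haldane_c(diff(loci$pos_bp[idx]), cfg$cm_per_mb)
    for (g in gens) {
      rows <- which(ped$gen == g & !founder)
      k <- length(rows)
      if (!k) next
      for (side in 1:2) {
        par_idx <- match(if (side == 1) ped$sire[rows] else ped$dam[rows],
                         ped$id)
        h1 <- H[2L * par_idx - 1L, idx, drop = FALSE]
        h2 <- H[2L * par_idx, idx, drop = FALSE]
        start <- rbinom(k, 1L, 0.5)
        if (length(idx) > 1L) {
          sw <- matrix(rbinom(k * length(cvec), 1L, rep(cvec, each = k)),
                       k, length(cvec))
          src <- row_cumsum_mod2(cbind(start, sw))
        } else src <- matrix(start, k, 1L)
        gam <- h1
        gam[src == 1L] <- h2[src == 1L]
        H[2L * rows - 2L + side, idx] <- gam
      }
    }
  }

  dosage_all <- H[seq(1L, 2L * n, by = 2L), , drop = FALSE] +
    H[seq(2L, 2L * n, by = 2L), , drop = FALSE]
  rownames(dosage_all) <- as.character(ped$id)

  qtl_cols <- which(loci$is_qtl)
  snp_cols <- if (cfg$qtl_mode == "hidden") setdiff(seq_len(L), qtl_cols)
              else seq_len(L)
  map <- data.frame(
    snp = sprintf("M%d", seq_along(snp_cols)),
    chrom = loci$chrom[snp_cols],
    pos_bp = loci$pos_bp[snp_cols],
    allele1 = "A", allele2 = "B",
    freq_a1 = colMeans(dosage_all[, snp_cols, drop = FALSE]) / 2
  )
  qtl_out <- NULL
  if (has_qtl) {
    qd <- dosage_all[, qtl_cols, drop = FALSE]
    ord <- order(loci$qtl_row[qtl_cols])
    qd <- qd[, ord, drop = FALSE]
    info <- qtl
    info$freq_realized <- colMeans(qd) / 2
    if (cfg$qtl_mode == "at_snp")
      info$snp <- map$snp[match(qtl_cols[ord], snp_cols)]
    qtl_out <- list(dosage = qd, info = info)
  }
  structure(list(dosage = dosage_all[, snp_cols, drop = FALSE],
                 map = map, qtl = qtl_out),
            class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("geno_matrix: %d individuals x %d SNPs on %d chromosome(s)\n",
              nrow(x$dosage), ncol(x$dosage), length(unique(x$map$chrom))))
  invisible(x)
}

#' Additive effect producing a target variance fraction
#'
#' Under Hardy-Weinberg a biallelic locus with allele frequency `p` and
#' allele-substitution effect `a` contributes `2 p (1 - p) a^2` to the
#' phenotypic variance; this inverts that relation.
#'
#' @param frac target fraction of the phenotypic variance.
#' @param p allele frequency.
#' @param var_p phenotypic variance (default 1, the simulator's target).
#' @return additive effect in trait units.
#' @export
qtl_effect_for_variance <- function(frac, p, var_p = 1) {
  sqrt(frac * var_p / (2 * p * (1 - p)))
}

# drop breeding values down a sorted pedigree: founder var s2, Mendelian
# sampling var s2/2 for non-founders (inbreeding ignored; founders unrelated)
drop_polygenic <- function(ped, s2) {
  n <- nrow(ped)
  a <- numeric(n)
  si <- match(ped$sire, ped$id)
  di <- match(ped$dam, ped$id)
  fo <- is.na(si) & is.na(di)
  a[fo] <- rnorm(sum(fo), 0, sqrt(s2))
  for (i in which(!fo))
    a[i] <- 0.5 * (a[si[i]] + a[di[i]]) + rnorm(1, 0, sqrt(s2 / 2))
  a
}

#' Simulate quantitative and binary phenotypes
#'
#' The quantitative trait is `y = sex effect + sum(QTL dosage * a) +
#' polygenic value + residual`, with the polygenic and residual variances
#' scaled so the total genetic variance over the phenotypic variance
#' equals `h2_quant` and the phenotypic variance is 1.  QTL effects are
#' derived from the configured variance fractions using realized founder
#' allele frequencies.  The binary trait is generated by thresholding an
#' analogous latent liability (heritability `h2_binary`, same QTL
#' variance fractions on the liability scale) at the empirical quantile
#' giving the configured prevalence.
#'
#' @param cfg a [sim_config()].
#' @param ped pedigree from [simulate_pedigree()].
#' @param g genotypes from [simulate_genotypes()].
#' @return list with `phen` (data.frame id, sex, y_quant, y_binary) and
#'   `truth` (data.frame chrom, pos_bp, effect, freq, var_frac), where
#'   `var_frac` is the simulated QTL variance fraction
#'   `2 p (1-p) a^2 / sigma2_P`.
#' @export
simulate_phenotypes <- function(cfg, ped, g) {
  stopifnot(inherits(cfg, "sim_config"), inherits(g, "geno_matrix"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed + 2L)
  n <- nrow(ped)
  qtl_part <- numeric(n)
  lia_qtl <- numeric(n)
  truth <- data.frame(chrom = integer(), pos_bp = numeric(),
                      effect = numeric(), freq = numeric(),
                      var_frac = numeric())
  frac_tot <- 0
  if (!is.null(g$qtl)) {
    info <- g$qtl$info
    qd <- g$qtl$dosage
    p <- info$freq_realized
    if ("frac" %in% names(info) && !all(is.na(info$frac))) {
      a <- qtl_effect_for_variance(info$frac, p)
    } else {
      a <- info$effect
    }
    var_frac <- 2 * p * (1 - p) * a^2
    frac_tot <- sum(var_frac)
    if (frac_tot > cfg$h2_quant)
      stop("realized QTL variance exceeds h2_quant")
    qtl_part <- drop(qd %*% a)
    # same variance fractions on the unit-variance liability scale
    if (frac_tot <= cfg$h2_binary)
      lia_qtl <- qtl_part
    truth <- data.frame(chrom = info$chrom, pos_bp = info$pos_bp,
                        effect = a, freq = p, var_frac = var_frac)
  }
  s2_poly <- cfg$h2_quant - frac_tot
  s2_e <- 1 - cfg$h2_quant
  if (s2_e <= 0 && cfg$h2_quant >= 1)
    stop("h2_quant = 1 leaves no residual variance")
  poly <- drop_polygenic(ped, s2_poly)
  e <- rnorm(n, 0, sqrt(s2_e))
  y <- cfg$sex_effect * (ped$sex == 2L) + qtl_part + poly + e

  lia_frac <- if (frac_tot <= cfg$h2_binary) frac_tot else 0
  lia_poly <- drop_polygenic(ped, cfg$h2_binary - lia_frac)
  lia <- cfg$sex_effect * (ped$sex == 2L) + lia_qtl + lia_poly +
    rnorm(n, 0, sqrt(1 - cfg$h2_binary))
  thr <- quantile(lia, 1 - cfg$prevalence, names = FALSE, type = 7)
  y_bin <- as.integer(lia > thr)

  list(phen = data.frame(id = ped$id, sex = ped$sex,
                         y_quant = y, y_binary = y_bin),
       truth = truth)
}

#' One-call simulation of a complete dataset
#'
#' Runs [simulate_pedigree()], [simulate_genotypes()] and
#' [simulate_phenotypes()] under one configuration.
#'
#' @param cfg a [sim_config()].
#' @return list with `ped`, `geno`, `phen`, `truth`.
#' @export
simulate_dataset <- function(cfg) {
  ped <- simulate_pedigree(cfg)
  g <- simulate_genotypes(cfg, ped)
  ph <- simulate_phenotypes(cfg, ped, g)
  list(ped = ped, geno = g, phen = ph$phen, truth = ph$truth)
}
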