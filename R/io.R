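#' Write genotypes as PLINK text .ped/.map
#'
#' One line per individual: FID IID PAT MAT SEX PHENO followed by two
#' allele columns per SNP; dosage 2 becomes `A A`, 1 `A B`, 0 `B B` and
#' missing (-1) `0 0` (allele letters from the map).  The .map file has
#' chromosome, SNP id, genetic position (cM, from `cm_per_mb = 1`) and
#' bp position.
#'
#' @param g a `geno_matrix`.
#' @param prefix output path prefix (writes `<prefix>.ped`, `<prefix>.map`).
#' @param ped optional pedigree data.frame (id, sire, dam, sex) for the
#'   family columns; defaults to unknown parents, sex 0.
#' @param phen optional phenotype data.frame (`id`, `y_quant`) for the
#'   phenotype column; defaults to -9.
#' @return invisibly, the two file paths.
#' @export
write_plink <- function(g, prefix, ped = NULL, phen = NULL) {
  stopifnot(inherits(g, "geno_matrix"))
  ids <- rownames(g$dosage)
  n <- length(ids); m <- ncol(g$dosage)
  pat <- mat <- rep("0", n); sex <- rep(0L, n); ph <- rep(-9, n)
  if (!is.null(ped)) {
    i <- match(ids, as.character(ped$id))
    pat <- ifelse(is.na(i), "0", as.character(ped$sire[i]))
    mat <- ifelse(is.na(i), "0", as.character(ped$dam[i]))
    sex <- ifelse(is.na(i), 0L, ped$sex[i])
  }
  if (!is.null(phen)) {
    i <- match(ids, as.character(phen$id))
    ph <- ifelse(is.na(i), -9, phen$y_quant[i])
  }
  a1 <- g$map$allele1; a2 <- g$map$allele2
  al <- matrix("0", n, 2 * m)
  D <- g$dosage
  for (j in seq_len(m)) {
    c1 <- ifelse(D[, j] < 0, "0", ifelse(D[, j] >= 1, a1[j], a2[j]))
    c2 <- ifelse(D[, j] < 0, "0", ifelse(D[, j] == 2, a1[j], a2[j]))
    al[, 2 * j - 1] <- c1
    al[, 2 * j] <- c2
  }
  ped_tab <- data.frame(FID = ids, IID = ids, PAT = pat, MAT = mat,
                        SEX = sex, PHENO = ph, al,
                        check.names = FALSE, stringsAsFactors = FALSE)
  ped_path <- paste0(prefix, ".ped")
  map_path <- paste0(prefix, ".map")
  data.table::fwrite(ped_tab, ped_path, sep = " ", col.names = FALSE)
  data.table::fwrite(data.frame(g$map$chrom, g$map$snp,
                                g$map$pos_bp / 1e6, g$map$pos_bp),
                     map_path, sep = "\t", col.names = FALSE)
  invisible(c(ped = ped_path, map = map_path))
}

#' Read PLINK text .ped/.map into a genotype matrix
#'
#' Dosages count the minor allele (determined from sample allele
#' frequencies; ties broken toward the alphabetically first allele);
#' missing genotypes (`0 0`) become -1.  Ragged rows, an odd allele
#' count and duplicate SNP ids are parse errors reported with line
#' numbers.
#'
#' @param ped_path,map_path file paths.
#' @return list with `geno` (a `geno_matrix`) and `fam` (data.frame FID,
#'   IID, PAT, MAT, SEX, PHENO).
#' @export
read_plink_pedmap <- function(ped_path, map_path) {
  if (!file.exists(ped_path)) stop("ped file not found: ", ped_path)
  if (!file.exists(map_path)) stop("map file not found: ", map_path)
  mp <- data.table::fread(map_path, header = FALSE,
                          colClasses = list(character = 1:2))
  if (ncol(mp) < 4) stop("map file needs 4 columns (chrom snp cM bp)")
  snp_ids <- mp[[2]]
  dup <- which(duplicated(snp_ids))
  if (length(dup)) stop("duplicate SNP id at map line ", dup[1])
  lines <- readLines(ped_path)
  lines <- lines[nzchar(trimws(lines))]
  toks <- strsplit(trimws(lines), "[ \t]+")
  lens <- lengths(toks)
  expected <- 6 + 2 * nrow(mp)
  if (any(lens != expected)) {
    bad <- which(lens != expected)[1]
    if (lens[bad] %% 2 == 1)
      stop("odd allele count at ped line ", bad)
    stop("ragged ped row at line ", bad, ": ", lens[bad],
         " fields, expected ", expected)
  }
  tm <- matrix(unlist(toks), nrow = length(toks), byrow = TRUE)
  fam <- data.frame(FID = tm[, 1], IID = tm[, 2], PAT = tm[, 3],
                    MAT = tm[, 4], SEX = as.integer(tm[, 5]),
                    PHENO = suppressWarnings(as.numeric(tm[, 6])))
  m <- nrow(mp)
  A1 <- tm[, 6 + 2 * seq_len(m) - 1, drop = FALSE]
  A2 <- tm[, 6 + 2 * seq_len(m), drop = FALSE]
  n <- nrow(tm)
  dosage <- matrix(-1L, n, m)
  minor <- major <- character(m)
  for (j in seq_len(m)) {
    als <- c(A1[, j], A2[, j])
    obs <- als != "0"
    tab <- sort(table(als[obs]))
    if (length(tab) == 0) { minor[j] <- major[j] <- "0"; next }
    if (length(tab) == 1) {
      major[j] <- names(tab)[1]
      minor[j] <- names(tab)[1]
    } else {
      if (length(tab) > 2) stop("more than 2 alleles for SNP ", snp_ids[j])
      # ties: table() sorts ties by allele name, so the first is kept
      minor[j] <- names(tab)[1]
      major[j] <- names(tab)[2]
    }
    miss <- A1[, j] == "0" | A2[, j] == "0"
    dosage[, j] <- (A1[, j] == minor[j]) + (A2[, j] == minor[j])
    dosage[miss, j] <- -1L
  }
  rownames(dosage) <- fam$IID
  map <- data.frame(snp = snp_ids, chrom = mp[[1]], pos_bp = as.numeric(mp[[4]]),
                    allele1 = minor, allele2 = major,
                    freq_a1 = {
                      dd <- dosage; dd[dd < 0] <- NA
                      colMeans(dd, na.rm = TRUE) / 2
                    })
  list(geno = structure(list(dosage = dosage, map = map, qtl = NULL),
                        class = "geno_matrix"),
       fam = fam)
}

#' Write the simulated dataset to plain-text files
#'
#' @param sim result of [simulate_dataset()].
#' @param dir output directory (created if needed).
#' @return invisibly, the written file paths.
#' @export
write_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    pedigree = file.path(dir, "pedigree.csv"),
    phenotypes = file.path(dir, "phenotypes.csv"),
    qtl_truth = file.path(dir, "qtl_truth.tsv")
  )
  data.table::fwrite(sim$ped[c("id", "sire", "dam", "sex")],
                     paths["pedigree"])
  data.table::fwrite(sim$phen, paths["phenotypes"])
  data.table::fwrite(sim$truth, paths["qtl_truth"], sep = "\t")
  plink <- write_plink(sim$geno, file.path(dir, "genotypes"),
                       ped = sim$ped, phen = sim$phen)
  invisible(c(paths, plink))
}

#' Read a pedigree CSV (id, sire, dam, sex)
#' @param path file path.
#' @return data.frame.
#' @export
read_pedigree_csv <- function(path) {
  as.data.frame(data.table::fread(path))
}

#' Read a phenotype CSV (id, sex, y_quant, y_binary)
#' @param path file path.
#' @return data.frame.
#' @export
read_phenotypes_csv <- function(path) {
  as.data.frame(data.table::fread(path))
}

#' Run the full association pipeline on a simulated dataset
#'
#' Orchestrates the analysis end to end on one simulated dataset:
#' quality control, animal-model REML and GRAMMAR residuals, the
#' permutation-thresholded quantitative scan, the PC-adjusted logistic
#' scan with local FDR, PCReg reduction of both top lists, pairwise LD
#' over the reduced quantitative top set, Bayesian forest and greedy DAG
#' learning over the same SNPs, the LD-vs-arc-strength correlation
#' matrix, and mapping evaluation against the simulated QTL truth.  All
#' artifacts are written to `out_dir` as TSV/CSV/JSON.
#'
#' @param cfg a [sim_config()]; its seed drives every stochastic stage.
#' @param out_dir output directory.
#' @param n_perm permutations for the genome-wide threshold.
#' @param alpha genome-wide significance level.
#' @param fdr_cutoff local-fdr cutoff for the binary scan.
#' @param K_binary stratification PCs for the logistic scan (default 20; NULL =
#'   75\% variance rule).
#' @param window_mb mapping window in Mb.
#' @param ess BDeu equivalent sample size.
#' @param max_bn_snps cap on the number of SNPs entering network
#'   learning and LD tabulation (top of the reduced list).
#' @return invisibly, a list with every stage result.
#' @export
run_pipeline <- function(cfg, out_dir, n_perm = 200, alpha = 0.05,
                         fdr_cutoff = 0.2, K_binary = 20, window_mb = 1,
                         ess = 1, max_bn_snps = 15) {
  stopifnot(inherits(cfg, "sim_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  sim <- stage("simulate", simulate_dataset(cfg))
  write_dataset(sim, file.path(out_dir, "data"))

  qc <- stage("qc", qc_pipeline(sim$geno, sim$phen))
  g <- qc$geno
  phen <- qc$phen
  data.table::fwrite(data.frame(item = c("snps_removed_maf",
                                         "individuals_removed_ibs"),
                                n = c(qc$n_snps_removed_maf,
                                      qc$n_individuals_removed_ibs)),
                     file.path(out_dir, "qc_report.tsv"), sep = "\t")

  ped_ids <- as.character(sim$ped$id)
  A <- stage("kinship", additive_relationship(sim$ped))
  keep <- match(as.character(phen$id), ped_ids)
  fit <- stage("reml", reml_fit(
    setNames(phen$y_quant, as.character(phen$id)),
    phen$sex, A[keep, keep, drop = FALSE]))
  resid <- stage("residuals", grammar_residuals(fit))
  jsonlite::write_json(
    list(sigma2_a = fit$sigma2_a, sigma2_e = fit$sigma2_e, h2 = fit$h2,
         se_h2 = fit$se_h2, loglik = fit$loglik, boundary = fit$boundary),
    file.path(out_dir, "variance_components.json"), auto_unbox = TRUE,
    digits = NA)
  data.table::fwrite(data.frame(id = names(resid), residual = resid),
                     file.path(out_dir, "grammar_residuals.csv"))

  scan_q <- stage("scan_quant", snp_scan_linear(resid, g))
  perm <- stage("permutation",
                permutation_threshold(resid, g, n_perm = n_perm,
                                      alpha = alpha,
                                      seed = if (is.null(cfg$seed)) NULL
                                             else cfg$seed + 10L))
  data.table::fwrite(scan_q, file.path(out_dir, "scan_quant.tsv"),
                     sep = "\t")
  jsonlite::write_json(list(n_perm = perm$n_perm, alpha = perm$alpha,
                            threshold = perm$threshold,
                            n_significant = length(perm$significant)),
                       file.path(out_dir, "permutation_null.json"),
                       auto_unbox = TRUE, digits = NA)

  pcs <- stage("strat_pcs", stratification_pcs(g, K = K_binary,
                                               var_target = 0.75))
  ybin <- setNames(phen$y_binary, as.character(phen$id))
  scan_b <- stage("scan_binary", snp_scan_logistic(ybin, g, pcs))
  lf <- stage("local_fdr",
              local_fdr(scan_b$p[!is.na(scan_b$p)], cutoff = fdr_cutoff))
  sig_b <- scan_b$snp[!is.na(scan_b$p)][lf$significant]
  data.table::fwrite(scan_b, file.path(out_dir, "scan_binary.tsv"),
                     sep = "\t")

  top_q <- perm$significant
  top_b <- sig_b
  results <- list(sim = sim, qc = qc, fit = fit, resid = resid,
                  scan_quant = scan_q, perm = perm, scan_binary = scan_b,
                  local_fdr = lf, top_quant = top_q, top_binary = top_b)

  subset_geno <- function(g, snps) {
    j <- match(snps, g$map$snp)
    structure(list(dosage = g$dosage[, j, drop = FALSE],
                   map = g$map[j, , drop = FALSE], qtl = NULL),
              class = "geno_matrix")
  }
  yq <- setNames(phen$y_quant, as.character(phen$id))
  if (length(top_q) >= 3) {
    pr_q <- stage("pcreg_quant",
                  pcreg(yq, subset_geno(g, top_q), link = "identity"))
    results$pcreg_quant <- pr_q
    data.table::fwrite(export_loading_plot_data(pr_q),
                       file.path(out_dir, "pcreg_quant_loadings.tsv"),
                       sep = "\t")
  }
  if (length(top_b) >= 3) {
    pr_b <- stage("pcreg_binary",
                  pcreg(ybin, subset_geno(g, top_b), link = "logit"))
    results$pcreg_binary <- pr_b
  }

  bn_snps <- head(if (!is.null(results$pcreg_quant) &&
                      length(results$pcreg_quant$retained) >= 3)
                    results$pcreg_quant$retained else top_q, max_bn_snps)
  if (length(bn_snps) >= 3) {
    gb <- subset_geno(g, bn_snps)
    dat <- gb$dosage + 1L
    colnames(dat) <- gb$map$snp
    ld <- stage("ld", ld_pairs(gb))
    forest <- stage("bn_forest", learn_forest(dat, ess = ess))
    dag <- stage("bn_dag",
                 greedy_dag_search(dat, ess = ess, restarts = 3,
                                   seed = if (is.null(cfg$seed)) NULL
                                          else cfg$seed + 11L))
    data.table::fwrite(ld, file.path(out_dir, "ld_pairs.tsv"), sep = "\t")
    data.table::fwrite(forest$arcs, file.path(out_dir, "bn_forest.tsv"),
                       sep = "\t")
    data.table::fwrite(dag$arcs, file.path(out_dir, "bn_dag.tsv"),
                       sep = "\t")
    results$ld <- ld; results$forest <- forest; results$dag <- dag
    if (nrow(forest$arcs) >= 3) {
      mc <- tryCatch(correlate_measures(ld, forest$arcs),
                     error = function(e) NULL)
      if (!is.null(mc)) {
        results$measure_cor <- mc
        data.table::fwrite(as.data.frame(mc$cor),
                           file.path(out_dir, "measure_correlations.tsv"),
                           sep = "\t", row.names = TRUE)
      }
    }
  }

  sig_pos <- scan_q[scan_q$snp %in% top_q, c("chrom", "pos_bp")]
  mapres <- stage("mapping",
                  evaluate_mapping(sig_pos, sim$truth, window_mb))
  results$mapping <- mapres
  jsonlite::write_json(list(n_mapped = mapres$n_mapped,
                            n_false_positive = mapres$n_false_positive,
                            mean_mapped_dist_mb = mapres$mean_mapped_dist_mb,
                            mean_fp_dist_mb = mapres$mean_fp_dist_mb),
                       file.path(out_dir, "mapping_report.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    list(seed = cfg$seed, n_perm = n_perm, alpha = alpha,
         fdr_cutoff = fdr_cutoff, window_mb = window_mb, ess = ess,
         package_version = as.character(utils::packageVersion("grammarbn"))),
    file.path(out_dir, "run_log.json"), auto_unbox = TRUE)
  invisible(results)
}
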