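#' SNP dosage container
#'
#' Holds an N x M additive dosage matrix (0/1/2 copies of the minor
#' allele, `NA` allowed) together with individual ids and a SNP map.
#'
#' @param dosage integer/numeric matrix, individuals in rows.
#' @param ids individual ids.
#' @param snps data.frame with columns `id`, `chr`, `pos` (and optionally
#'   `freq`); generated if missing.
#' @return object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosage, ids = rownames(dosage), snps = NULL) {
  dosage <- as.matrix(dosage)
  if (is.null(ids)) ids <- sprintf("ID%05d", seq_len(nrow(dosage)))
  if (is.null(snps))
    snps <- data.frame(id = colnames(dosage) %||%
                         sprintf("snp%06d", seq_len(ncol(dosage))),
                       chr = 1L, pos = seq_len(ncol(dosage)),
                       stringsAsFactors = FALSE)
  bad <- !(dosage %in% c(0, 1, 2) | is.na(dosage))
  if (any(bad)) stopf("dosages must be 0/1/2 or missing")
  dimnames(dosage) <- list(ids, snps$id)
  structure(list(dosage = dosage, ids = as.character(ids), snps = snps),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d individuals x %d SNPs, %.2f%% missing\n",
              nrow(x$dosage), ncol(x$dosage),
              100 * mean(is.na(x$dosage))))
  invisible(x)
}

#' Gene-drop SNP genotypes down a pedigree
#'
#' Founders receive two haplotypes drawn under Hardy-Weinberg equilibrium;
#' minor-allele frequencies are drawn uniformly on `config$maf_range`, one
#' frequency per LD block so that blockwise allele copying (adjacent
#' alleles within a block are copied from their neighbour with probability
#' `config$ld_corr`, otherwise drawn fresh) leaves the marginal frequency
#' intact.  Each non-founder inherits, independently per SNP, one randomly
#' segregated allele from each parent, so realized relatedness varies
#' around its pedigree expectation exactly as in a real cohort.
#'
#' @param ped pedigree from [sim_pedigrees()].
#' @param config a [sim_config()]; uses `n_snps`, `maf_range`,
#'   `ld_block_size`, `ld_corr` and `seed`.
#' @return a [genotype_matrix] with the realized per-SNP allele frequency
#'   in `snps$freq`.
#' @export
sim_genotypes <- function(ped, config) {
  validate_pedigree(ped)
  m <- config$n_snps
  if (m < 1) stopf("n_snps must be positive")
  bs <- max(1L, as.integer(config$ld_block_size))
  rho <- config$ld_corr
  if (rho < 0 || rho >= 1) stopf("ld_corr must be in [0, 1)")
  with_seed(sub_seed(config$seed, 2L), {
    block <- rep(seq_len(ceiling(m / bs)), each = bs)[seq_len(m)]
    p_block <- stats::runif(max(block), config$maf_range[1], config$maf_range[2])
    p <- p_block[block]
    ord <- order(pedigree_depth(ped))
    n <- nrow(ped)
    fa <- match(ped$father, ped$id)
    mo <- match(ped$mother, ped$id)
    H1 <- matrix(0L, n, m)
    H2 <- matrix(0L, n, m)
    new_block <- c(TRUE, diff(block) != 0)
    for (i in ord) {
      if (is.na(fa[i])) {
        h1 <- stats::rbinom(m, 1L, p)
        h2 <- stats::rbinom(m, 1L, p)
        if (rho > 0) {
          copy1 <- stats::runif(m) < rho & !new_block
          copy2 <- stats::runif(m) < rho & !new_block
          h1 <- copy_runs(h1, copy1)
          h2 <- copy_runs(h2, copy2)
        }
        H1[i, ] <- h1; H2[i, ] <- h2
      } else {
        pick <- stats::runif(m) < 0.5
        H1[i, ] <- ifelse(pick, H1[fa[i], ], H2[fa[i], ])
        pick <- stats::runif(m) < 0.5
        H2[i, ] <- ifelse(pick, H1[mo[i], ], H2[mo[i], ])
      }
    }
    dosage <- H1 + H2
    snps <- data.frame(id = sprintf("snp%06d", seq_len(m)),
                       chr = 1L, pos = seq_len(m) * 1000L,
                       freq = colMeans(dosage) / 2,
                       stringsAsFactors = FALSE)
    genotype_matrix(dosage, ids = ped$id, snps = snps)
  })
}

# Propagate alleles along copy runs: where copy[j] is TRUE the allele at
# j is replaced by the (possibly already copied) allele at j - 1.
copy_runs <- function(h, copy) {
  for (j in which(copy)) h[j] <- h[j - 1L]
  h
}

#' Greedy LD pruning of a dosage matrix
#'
#' Scans SNPs left to right with a sliding window and drops the
#' later-positioned SNP of any pair whose squared dosage correlation
#' exceeds the threshold, leaving a panel in approximate linkage
#' equilibrium (all surviving within-window pairs have r-squared at or
#' below the threshold).
#'
#' @param G a [genotype_matrix].
#' @param r2_threshold squared-correlation threshold in (0, 1]; pairs
#'   strictly above it are pruned.
#' @param window_snps window width in SNPs.
#' @return a [genotype_matrix] restricted to the retained SNPs, with the
#'   kept-column indices in `attr(, "kept")`.
#' @export
ld_prune <- function(G, r2_threshold = 0.1, window_snps = 50L) {
  if (r2_threshold <= 0 || r2_threshold > 1)
    stopf("r2_threshold must be in (0, 1]")
  X <- G$dosage
  m <- ncol(X)
  if (m < 2) stopf("need at least two SNPs to prune")
  all_missing <- colSums(!is.na(X)) == 0
  if (any(all_missing))
    warning(sprintf("%d all-missing SNP column(s) excluded", sum(all_missing)),
            call. = FALSE)
  keep <- logical(m)
  active <- integer(0)  # retained SNPs still inside the window
  for (j in seq_len(m)) {
    if (all_missing[j]) next
    active <- active[active > j - window_snps]
    drop_j <- FALSE
    for (i in active) {
      r <- suppressWarnings(stats::cor(X[, i], X[, j],
                                       use = "pairwise.complete.obs"))
      if (!is.na(r) && r * r > r2_threshold) { drop_j <- TRUE; break }
    }
    if (!drop_j) { keep[j] <- TRUE; active <- c(active, j) }
  }
  out <- genotype_matrix(G$dosage[, keep, drop = FALSE], ids = G$ids,
                         snps = G$snps[keep, , drop = FALSE])
  attr(out, "kept") <- which(keep)
  out
}

#' Empirical genetic relatedness from standardized dosages
#'
#' Estimates realized relatedness for every pair of individuals as the
#' average over SNPs of the product of centred, standardized dosages:
#' `K_ij = mean_m (x_im - 2 p_m) (x_jm - 2 p_m) / (2 p_m (1 - p_m))`.
#' Allele frequencies are taken from the sample itself.  Missing dosages
#' are handled by pairwise-complete averaging (each pair is averaged over
#' the SNPs observed in both individuals), which keeps the estimator
#' unbiased under data missing completely at random.  Monomorphic SNPs
#' carry no information and are skipped.
#'
#' @param G a [genotype_matrix] (ideally LD-pruned; at least 100 SNPs
#'   recommended for a usable matrix).
#' @return a [relmat] with `provenance = "empirical"`.
#' @export
empirical_grm <- function(G) {
  X <- G$dosage
  p <- colMeans(X, na.rm = TRUE) / 2
  poly <- !is.na(p) & p > 0 & p < 1
  X <- X[, poly, drop = FALSE]
  p <- p[poly]
  if (ncol(X) < 2) stopf("fewer than 2 usable (polymorphic) SNPs")
  Z <- sweep(X, 2, 2 * p, `-`)
  Z <- sweep(Z, 2, sqrt(2 * p * (1 - p)), `/`)
  obs <- !is.na(Z)
  Zc <- Z; Zc[!obs] <- 0
  num <- tcrossprod(Zc)
  den <- tcrossprod(obs * 1)          # per-pair count of jointly observed SNPs
  if (any(den < 2)) stopf("some pairs share fewer than 2 observed SNPs")
  relmat(num / den, ids = G$ids, provenance = "empirical",
         n_snps = ncol(X))
}

#' Write / read dosages as PLINK .raw-style additive-coding text
#'
#' Header `FID IID PAT MAT SEX PHENOTYPE <snp ids>`; one space-separated
#' row per individual, dosages 0/1/2 with `NA` for missing.
#'
#' @param G a [genotype_matrix].
#' @param path output file.
#' @param ped optional pedigree supplying family/parent/sex columns.
#' @return `write_raw` returns `path` invisibly; `read_raw` a
#'   [genotype_matrix].
#' @export
write_raw <- function(G, path, ped = NULL) {
  n <- length(G$ids)
  meta <- data.frame(FID = G$ids, IID = G$ids, PAT = "0", MAT = "0",
                     SEX = 0L, PHENOTYPE = -9, stringsAsFactors = FALSE)
  if (!is.null(ped)) {
    i <- match(G$ids, ped$id)
    meta$FID <- ped$fam[i]
    meta$PAT <- ifelse(is.na(ped$father[i]), "0", ped$father[i])
    meta$MAT <- ifelse(is.na(ped$mother[i]), "0", ped$mother[i])
    meta$SEX <- ped$sex[i]
  }
  tab <- cbind(meta, as.data.frame(G$dosage, check.names = FALSE))
  utils::write.table(tab, path, quote = FALSE, row.names = FALSE, sep = " ")
  invisible(path)
}

#' @rdname write_raw
#' @export
read_raw <- function(path) {
  tab <- utils::read.table(path, header = TRUE, check.names = FALSE,
                           stringsAsFactors = FALSE)
  meta_cols <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
  if (!all(meta_cols %in% names(tab)[1:6]))
    stopf("not a .raw dosage table: missing meta columns")
  dos <- as.matrix(tab[, -(1:6), drop = FALSE])
  storage.mode(dos) <- "double"
  genotype_matrix(dos, ids = as.character(tab$IID))
}
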