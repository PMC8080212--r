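#' Genetic relatedness matrix container
#'
#' A light S3 wrapper pairing an N x N symmetric relatedness matrix with
#' individual ids and a provenance tag.  Empirical matrices come from
#' standardized SNP dosages ([empirical_grm()]); expected matrices come
#' from pedigree kinship ([kinship_from_pedigree()]).
#'
#' @param K numeric symmetric matrix.
#' @param ids character vector of individual ids, one per row of `K`.
#' @param provenance `"pedigree"` or `"empirical"`.
#' @param n_snps optional SNP count behind an empirical estimate.
#' @return an object of class `relmat` with elements `K`, `ids`,
#'   `provenance`, `n_snps`.
#' @export
relmat <- function(K, ids = rownames(K), provenance = c("empirical", "pedigree"),
                   n_snps = NA_integer_) {
  provenance <- match.arg(provenance)
  K <- as.matrix(K)
  if (is.null(ids)) ids <- sprintf("ID%05d", seq_len(nrow(K)))
  if (length(ids) != nrow(K) || nrow(K) != ncol(K))
    stopf("relatedness matrix must be square with one id per row")
  dimnames(K) <- list(ids, ids)
  structure(list(K = K, ids = as.character(ids), provenance = provenance,
                 n_snps = n_snps),
            class = "relmat")
}

as_relmat <- function(x, provenance = "empirical") {
  if (inherits(x, "relmat")) x else relmat(x, provenance = provenance)
}

#' @export
print.relmat <- function(x, ...) {
  cat(sprintf("<relmat> %d individuals, provenance: %s%s\n",
              length(x$ids), x$provenance,
              if (!is.na(x$n_snps)) sprintf(" (%d SNPs)", x$n_snps) else ""))
  off <- x$K[upper.tri(x$K)]
  cat(sprintf("  diag: [%.3f, %.3f]  off-diag: [%.3f, %.3f]  trace/N: %.3f\n",
              min(diag(x$K)), max(diag(x$K)),
              if (length(off)) min(off) else NA, if (length(off)) max(off) else NA,
              mean(diag(x$K))))
  invisible(x)
}

#' Validate the structural properties of a relatedness matrix
#'
#' Reports the checks a relatedness matrix must pass before entering a
#' variance-component model: symmetry, positive semi-definiteness, trace
#' close to N (empirical matrices), and plausible diagonal / off-diagonal
#' ranges.  It always returns a report rather than erroring, so callers
#' can decide what is fatal.
#'
#' @param K a [relmat] or plain square matrix.
#' @param psd_tol eigenvalue tolerance below which the matrix is declared
#'   non-PSD.
#' @param trace_tol relative tolerance for trace/N around 1 (applied to
#'   empirical matrices only).
#' @param offdiag_range plausible off-diagonal interval; values outside
#'   flag the check.  The bounds are conventions, not estimator theory,
#'   and are configurable.
#' @param diag_range plausible diagonal interval.
#' @return a list of class `grm_validation`: per-property observed values,
#'   per-property pass flags, and an overall `ok`.
#' @export
validate_grm <- function(K, psd_tol = 1e-8, trace_tol = 0.1,
                         offdiag_range = c(-0.2, 1.2),
                         diag_range = c(0.7, 1.6)) {
  R <- as_relmat(K)
  M <- R$K
  n <- nrow(M)
  sym_err <- max(abs(M - t(M)))
  Ms <- (M + t(M)) / 2
  min_eig <- min(eigen(Ms, symmetric = TRUE, only.values = TRUE)$values)
  off <- Ms[upper.tri(Ms)]
  res <- list(
    n = n,
    symmetry_error = sym_err,
    min_eigenvalue = min_eig,
    trace_over_n = mean(diag(Ms)),
    diag_range = range(diag(Ms)),
    offdiag_range = if (length(off)) range(off) else c(NA_real_, NA_real_),
    provenance = R$provenance)
  res$pass <- c(
    symmetry = sym_err < 1e-8,
    psd = min_eig > -psd_tol,
    trace = if (R$provenance == "empirical")
      abs(res$trace_over_n - 1) < trace_tol else TRUE,
    diag = res$diag_range[1] >= diag_range[1] &&
      res$diag_range[2] <= diag_range[2],
    offdiag = !length(off) || (res$offdiag_range[1] >= offdiag_range[1] &&
      res$offdiag_range[2] <= offdiag_range[2]))
  res$ok <- all(res$pass)
  class(res) <- "grm_validation"
  res
}

#' @export
print.grm_validation <- function(x, ...) {
  cat(sprintf("GRM validation (N = %d, %s)\n", x$n, x$provenance))
  cat(sprintf("  symmetry error : %.3g  [%s]\n", x$symmetry_error,
              ifelse(x$pass["symmetry"], "pass", "FAIL")))
  cat(sprintf("  min eigenvalue : %.3g  [%s]\n", x$min_eigenvalue,
              ifelse(x$pass["psd"], "pass", "FAIL")))
  cat(sprintf("  trace / N      : %.4f  [%s]\n", x$trace_over_n,
              ifelse(x$pass["trace"], "pass", "FAIL")))
  cat(sprintf("  diagonal range : [%.3f, %.3f]  [%s]\n", x$diag_range[1],
              x$diag_range[2], ifelse(x$pass["diag"], "pass", "FAIL")))
  cat(sprintf("  off-diag range : [%.3f, %.3f]  [%s]\n", x$offdiag_range[1],
              x$offdiag_range[2], ifelse(x$pass["offdiag"], "pass", "FAIL")))
  cat(sprintf("  overall        : %s\n", ifelse(x$ok, "pass", "FAIL")))
  invisible(x)
}

#' Write / read genetic relatedness matrices
#'
#' Two text dialects are supported.  `format = "gcta"` writes the
#' GCTA-style pair: `<path>.grm` with one row per lower-triangle element
#' (columns: row index i, column index j, SNP count, relatedness) plus a
#' companion `<path>.grm.id` id file (family id, individual id).
#' `format = "tsv"` writes a square tab-separated matrix with header ids.
#' Values are printed with 17 significant digits so a round trip is exact
#' to double precision.
#'
#' @param K a [relmat] (or square matrix).
#' @param path base path (`gcta`) or file path (`tsv`).
#' @param format `"gcta"` or `"tsv"`.
#' @return `write_grm` returns the path(s) invisibly; `read_grm` returns a
#'   [relmat].
#' @export
write_grm <- function(K, path, format = c("gcta", "tsv")) {
  format <- match.arg(format)
  R <- as_relmat(K)
  M <- R$K
  n <- nrow(M)
  if (format == "tsv") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste(c("id", R$ids), collapse = "\t"), con)
    for (i in seq_len(n))
      writeLines(paste(c(R$ids[i], sprintf("%.17g", M[i, ])), collapse = "\t"),
                 con)
    return(invisible(path))
  }
  ii <- rep(seq_len(n), seq_len(n))
  jj <- sequence(seq_len(n))
  vals <- M[cbind(ii, jj)]
  m <- if (is.na(R$n_snps)) 0L else R$n_snps
  utils::write.table(
    data.frame(i = ii, j = jj, m = m, v = sprintf("%.17g", vals)),
    paste0(path, ".grm"), quote = FALSE, row.names = FALSE,
    col.names = FALSE, sep = "\t")
  utils::write.table(data.frame(fam = R$ids, id = R$ids),
                     paste0(path, ".grm.id"), quote = FALSE,
                     row.names = FALSE, col.names = FALSE, sep = "\t")
  invisible(c(paste0(path, ".grm"), paste0(path, ".grm.id")))
}

#' @rdname write_grm
#' @export
read_grm <- function(path, format = c("gcta", "tsv")) {
  format <- match.arg(format)
  if (format == "tsv") {
    tab <- utils::read.table(path, header = TRUE, sep = "\t",
                             check.names = FALSE, stringsAsFactors = FALSE)
    ids <- as.character(tab[[1]])
    M <- as.matrix(tab[, -1, drop = FALSE])
    if (!identical(colnames(M), ids))
      stopf("GRM header ids do not match row ids")
    storage.mode(M) <- "double"
    return(relmat(M, ids = ids))
  }
  tri <- utils::read.table(paste0(path, ".grm"), header = FALSE,
                           col.names = c("i", "j", "m", "v"))
  ids <- utils::read.table(paste0(path, ".grm.id"), header = FALSE,
                           stringsAsFactors = FALSE)[[2]]
  n <- max(tri$i)
  if (length(ids) != n)
    stopf("GRM id file has %d ids but matrix dimension is %d", length(ids), n)
  if (nrow(tri) != n * (n + 1) / 2)
    stopf("GRM lower triangle is incomplete")
  M <- matrix(0, n, n)
  M[cbind(tri$i, tri$j)] <- tri$v
  M[cbind(tri$j, tri$i)] <- tri$v
  relmat(M, ids = as.character(ids),
         n_snps = if (all(tri$m > 0)) as.integer(tri$m[1]) else NA_integer_)
}

#' Zero out near-zero relatedness entries
#'
#' Empirical relatedness between truly unrelated pairs is sampling noise
#' of order `1/sqrt(M)`.  Setting off-diagonal entries below a cutoff to
#' zero restores the block structure of the cohort (families plus
#' singletons), over which the variance-component likelihood factorizes.
#'
#' @param K a [relmat] or square matrix.
#' @param cutoff absolute value below which off-diagonal entries are set
#'   to 0.
#' @return a [relmat] with the same diagonal.
#' @export
threshold_grm <- function(K, cutoff = 0.05) {
  R <- as_relmat(K)
  M <- R$K
  M[abs(M) < cutoff & row(M) != col(M)] <- 0
  relmat(M, ids = R$ids, provenance = R$provenance, n_snps = R$n_snps)
}
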