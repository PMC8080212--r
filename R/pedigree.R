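#' Simulate a cross-sectional cohort pedigree
#'
#' Generates a cohort of nuclear families (two unrelated founder parents
#' plus their children) and unrelated singletons, the family structure a
#' developmental cohort of related and unrelated individuals assumes.
#' Every individual receives one cross-sectional age drawn uniformly on the
#' configured range and a sex; fathers are coded male (1) and mothers
#' female (2), other sexes are Bernoulli(0.5).
#'
#' @param config a [sim_config()] list; the fields used are `n_families`,
#'   `children_per_family`, `n_singletons`, `age_range` and `seed`.
#' @return a `data.frame` of class `pedigree` with columns `id`, `father`,
#'   `mother` (`NA` for founders), `sex` (1 = male, 2 = female), `age`
#'   (years) and `fam`.
#' @examples
#' ped <- sim_pedigrees(sim_config(n_families = 2, n_singletons = 3,
#'                                 seed = 1))
#' table(is.na(ped$father))
#' @export
sim_pedigrees <- function(config) {
  nf <- config$n_families
  ns <- config$n_singletons
  cpf <- config$children_per_family
  rng <- config$age_range
  if (nf < 0 || ns < 0 || nf + ns == 0) stopf("cohort counts must be positive")
  with_seed(sub_seed(config$seed, 1L), {
    nkids <- draw_children(nf, cpf)
    rows <- vector("list", nf + 1L)
    for (f in seq_len(nf)) {
      fid <- sprintf("F%04d", f)
      pa <- paste0(fid, "_P1"); ma <- paste0(fid, "_P2")
      kid_ids <- if (nkids[f] > 0)
        sprintf("%s_C%d", fid, seq_len(nkids[f])) else character(0)
      rows[[f]] <- data.frame(
        id = c(pa, ma, kid_ids),
        father = c(NA, NA, rep(pa, nkids[f])),
        mother = c(NA, NA, rep(ma, nkids[f])),
        sex = c(1L, 2L, sample(1:2, nkids[f], replace = TRUE)),
        fam = fid,
        stringsAsFactors = FALSE)
    }
    if (ns > 0) {
      sid <- sprintf("S%04d", seq_len(ns))
      rows[[nf + 1L]] <- data.frame(
        id = sid, father = NA_character_, mother = NA_character_,
        sex = sample(1:2, ns, replace = TRUE),
        fam = paste0("U", sid), stringsAsFactors = FALSE)
    }
    ped <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
    ped$age <- stats::runif(nrow(ped), rng[1], rng[2])
    ped <- ped[, c("id", "father", "mother", "sex", "age", "fam")]
    rownames(ped) <- NULL
    class(ped) <- c("pedigree", "data.frame")
    validate_pedigree(ped)
    ped
  })
}

draw_children <- function(nf, cpf) {
  if (nf == 0L) return(integer(0))
  if (is.numeric(cpf)) return(rep(as.integer(cpf), nf))
  if (!is.list(cpf) || is.null(cpf$dist))
    stopf("invalid children-per-family distribution spec")
  switch(cpf$dist,
    fixed = rep(as.integer(cpf$n %||% 2L), nf),
    # zero-truncated-ish: at least one child so every family is informative
    poisson = pmax(1L, stats::rpois(nf, cpf$mean %||% 2)),
    stopf("unknown children-per-family distribution '%s'", cpf$dist))
}

#' Validate pedigree structure
#'
#' Checks the structural invariants every downstream consumer relies on:
#' unique ids, parent links that resolve, founders with both parents
#' absent, no individual its own ancestor, ages inside the stated range.
#'
#' @param ped a pedigree `data.frame` (columns `id`, `father`, `mother`,
#'   `sex`, `age`, `fam`).
#' @param age_range permitted age interval; `NULL` skips the age check.
#' @return `ped`, invisibly; errors describe the first violation found.
#' @export
validate_pedigree <- function(ped, age_range = NULL) {
  if (anyDuplicated(ped$id)) stopf("duplicated individual ids in pedigree")
  both <- is.na(ped$father) == is.na(ped$mother)
  if (!all(both)) stopf("individuals must have both parents present or both absent")
  for (col in c("father", "mother")) {
    ref <- ped[[col]][!is.na(ped[[col]])]
    if (!all(ref %in% ped$id)) stopf("pedigree references unknown %s id", col)
  }
  pedigree_depth(ped)  # errors on cycles
  if (!all(ped$sex %in% c(1L, 2L))) stopf("sex must be coded 1/2")
  if (!is.null(age_range) &&
      (any(ped$age < age_range[1]) || any(ped$age > age_range[2])))
    stopf("ages outside configured range")
  invisible(ped)
}

# Generation number per individual (founders 0); errors on cyclic links.
pedigree_depth <- function(ped) {
  n <- nrow(ped)
  fa <- match(ped$father, ped$id)
  mo <- match(ped$mother, ped$id)
  depth <- ifelse(is.na(fa), 0L, NA_integer_)
  for (pass in seq_len(n + 1L)) {
    todo <- which(is.na(depth))
    if (!length(todo)) return(depth)
    ready <- todo[!is.na(depth[fa[todo]]) & !is.na(depth[mo[todo]])]
    if (!length(ready)) stopf("pedigree contains a cycle or unresolved parent")
    depth[ready] <- pmax(depth[fa[ready]], depth[mo[ready]]) + 1L
  }
  stopf("pedigree contains a cycle")
}

#' Expected relatedness (numerator relationship matrix) from a pedigree
#'
#' Computes twice the kinship coefficient, the expected proportion of
#' alleles shared identical by descent, for every pair via the standard
#' recursive (tabular) algorithm.  Diagonal entries are 1 plus the
#' inbreeding coefficient.
#'
#' @param ped a validated pedigree.
#' @return a [relmat] with `provenance = "pedigree"`.
#' @examples
#' ped <- sim_pedigrees(sim_config(n_families = 1, n_singletons = 0, seed = 1))
#' kinship_from_pedigree(ped)$K
#' @export
kinship_from_pedigree <- function(ped) {
  validate_pedigree(ped)
  ord <- order(pedigree_depth(ped))
  ped <- ped[ord, ]
  n <- nrow(ped)
  fa <- match(ped$father, ped$id)
  mo <- match(ped$mother, ped$id)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    f <- fa[i]; m <- mo[i]
    A[i, i] <- 1 + if (!is.na(f)) 0.5 * A[f, m] else 0
    j <- seq_len(i - 1L)
    if (length(j)) {
      aij <- if (!is.na(f)) 0.5 * (A[j, f] + A[j, m]) else rep(0, length(j))
      A[i, j] <- A[j, i] <- aij
    }
  }
  back <- order(ord)
  relmat(A[back, back], ids = ped$id[back], provenance = "pedigree")
}

#' Write / read a pedigree as six-column PLINK-style .fam text
#'
#' Columns: family id, individual id, father id, mother id, sex,
#' phenotype (age is stored in the phenotype slot so the cohort's
#' cross-sectional design survives the round trip).
#'
#' @param ped a pedigree `data.frame`.
#' @param path output file.
#' @return `write_fam` returns `path` invisibly; `read_fam` returns a
#'   `pedigree` `data.frame`.
#' @export
write_fam <- function(ped, path) {
  out <- data.frame(fam = ped$fam, id = ped$id,
                    father = ifelse(is.na(ped$father), "0", ped$father),
                    mother = ifelse(is.na(ped$mother), "0", ped$mother),
                    sex = ped$sex, age = sprintf("%.10g", ped$age))
  utils::write.table(out, path, quote = FALSE, row.names = FALSE,
                     col.names = FALSE, sep = " ")
  invisible(path)
}

#' @rdname write_fam
#' @export
read_fam <- function(path) {
  raw <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("fam", "id", "father", "mother",
                                         "sex", "age"))
  ped <- data.frame(id = as.character(raw$id),
                    father = ifelse(raw$father == "0", NA_character_,
                                    as.character(raw$father)),
                    mother = ifelse(raw$mother == "0", NA_character_,
                                    as.character(raw$mother)),
                    sex = as.integer(raw$sex), age = as.numeric(raw$age),
                    fam = as.character(raw$fam), stringsAsFactors = FALSE)
  class(ped) <- c("pedigree", "data.frame")
  ped
}
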