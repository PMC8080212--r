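#' Drop subjects missing too much cognitive data
#'
#' Keeps subjects missing strictly less than `max_missing_fraction` of the
#' named trait columns (the conventional "less than 50% missing"
#' eligibility rule).  The exclusion count and ids are attached as the
#' `"filter_log"` attribute.
#'
#' @param table trait data.frame (one row per subject).
#' @param trait_cols character vector of cognitive columns; defaults to
#'   all numeric columns except `id`, `age`, `sex`.
#' @param max_missing_fraction exclusion threshold; a subject with
#'   missing fraction `>=` this value is removed.
#' @return the filtered table.
#' @export
eligibility_filter <- function(table, trait_cols = NULL,
                               max_missing_fraction = 0.5) {
  trait_cols <- trait_cols %||% default_trait_cols(table)
  frac <- rowMeans(is.na(table[, trait_cols, drop = FALSE]))
  keep <- frac < max_missing_fraction
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "filter_log") <- list(n_removed = sum(!keep),
                                  removed_ids = table$id[!keep],
                                  threshold = max_missing_fraction)
  out
}

default_trait_cols <- function(table)
  setdiff(names(table)[vapply(table, is.numeric, logical(1))],
          c("id", "age", "sex"))

#' Chained-equation imputation with predictive mean matching
#'
#' Fills missing cognitive entries by iterated per-column linear
#' regressions on age, sex, and all other cognitive columns.  Each
#' missing cell is imputed by predictive mean matching: the fitted value
#' is compared with the fitted values of the observed cases and the
#' imputed value is drawn from the `k` nearest observed donors, so every
#' imputed value is an actually observed value of that column.  A single
#' completed table is returned (no pooling over multiple imputations) and
#' observed entries are never altered.
#'
#' @param table trait data.frame with `age` and `sex` columns.
#' @param trait_cols columns to impute; defaults as in
#'   [eligibility_filter()].
#' @param n_iterations number of passes over the columns.
#' @param k donor-pool size for predictive mean matching.
#' @param seed integer seed (donor draws are random).
#' @return the completed table; the imputed cell positions are attached
#'   as the `"imputation_log"` attribute (data.frame of row, column).
#' @export
chained_impute <- function(table, trait_cols = NULL, n_iterations = 10L,
                           k = 5L, seed = 1L) {
  trait_cols <- trait_cols %||% default_trait_cols(table)
  miss <- lapply(trait_cols, function(cl) which(is.na(table[[cl]])))
  names(miss) <- trait_cols
  if (!any(lengths(miss) > 0)) return(table)
  for (cl in trait_cols)
    if (all(is.na(table[[cl]]))) stopf("column '%s' has no observed values", cl)
  work <- table
  # initialize with column means
  for (cl in trait_cols)
    work[[cl]][miss[[cl]]] <- mean(table[[cl]], na.rm = TRUE)
  covs <- cbind(age = table$age, sex = as.numeric(table$sex))
  with_seed(sub_seed(seed, 8L), {
    for (it in seq_len(n_iterations)) {
      for (cl in trait_cols) {
        mi <- miss[[cl]]
        if (!length(mi)) next
        X <- cbind(1, covs, as.matrix(work[, setdiff(trait_cols, cl),
                                           drop = FALSE]))
        obs <- setdiff(seq_len(nrow(work)), mi)
        fit <- stats::lm.fit(X[obs, , drop = FALSE], table[[cl]][obs])
        beta <- ifelse(is.na(fit$coefficients), 0, fit$coefficients)
        pred <- drop(X %*% beta)
        donors <- table[[cl]][obs]
        pred_obs <- pred[obs]
        for (r in mi) {
          d <- abs(pred_obs - pred[r])
          pool <- order(d)[seq_len(min(k, length(d)))]
          work[[cl]][r] <- donors[sample(pool, 1L)]
        }
      }
    }
  })
  attr(work, "imputation_log") <-
    do.call(rbind, lapply(trait_cols, function(cl)
      if (length(miss[[cl]]))
        data.frame(row = miss[[cl]], column = cl, stringsAsFactors = FALSE)))
  work
}

#' First-principal-component composite score
#'
#' Standardizes the named columns, extracts the first principal
#' component, rescales the score to unit variance, and orients the sign
#' so the anchor column's loading is positive (by convention the
#' composite then increases with the anchor: accuracy composites increase
#' with ability, speed composites with slowness when anchored on a raw
#' reaction time).
#'
#' @param table completed trait data.frame.
#' @param columns character vector of >= 2 complete numeric columns.
#' @param orientation_anchor column whose loading fixes the sign;
#'   defaults to the first of `columns`.
#' @return numeric score vector with attributes `loadings` and
#'   `var_explained`.
#' @export
pca_composite <- function(table, columns, orientation_anchor = columns[1]) {
  if (length(columns) < 2) stopf("need at least 2 columns for a composite")
  X <- as.matrix(table[, columns, drop = FALSE])
  if (anyNA(X)) stopf("composite columns must be complete (impute first)")
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) stopf("zero-variance column: %s",
                           paste(columns[sds == 0], collapse = ", "))
  Z <- scale(X)
  pc <- stats::prcomp(Z, center = FALSE, scale. = FALSE)
  score <- pc$x[, 1]
  load1 <- pc$rotation[, 1]
  if (load1[orientation_anchor] < 0) { score <- -score; load1 <- -load1 }
  score <- score / stats::sd(score)
  attr(score, "loadings") <- load1
  attr(score, "var_explained") <- pc$sdev[1]^2 / sum(pc$sdev^2)
  score
}

#' Covariate design for age, age squared, sex and their interactions
#'
#' Ages are centred at the sample mean so the intercept refers to the
#' average age.  Columns: intercept, age_c, age_c^2, sex (0 = male,
#' 1 = female), age_c x sex, age_c^2 x sex.
#'
#' @param ages numeric ages in years.
#' @param sexes sex codes (1 = male, 2 = female).
#' @return numeric design matrix with 6 named columns.
#' @export
build_covariates <- function(ages, sexes) {
  ac <- ages - mean(ages)
  sx <- as.numeric(sexes) - 1
  X <- cbind(intercept = 1, age_c = ac, age_c2 = ac^2, sex = sx,
             age_sex = ac * sx, age2_sex = ac^2 * sx)
  X
}
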