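# Phenotype generators: every drawn trait follows the exact covariance
# model the fitting functions assume, so parameter-recovery tests are
# meaningful end to end.

# Gene x Age covariance for one set of individuals:
#   Omega_ij = K_ij sg(a_i) sg(a_j) exp(-lambda |a_i - a_j|) + [i==j] se2(a_i)
# with sg2(a) = sg2_0 exp(gamma_g (a - abar)), se2(a) = se2_0 exp(gamma_e (a - abar)).
# The age kernel exp(-lambda |da|) is a valid correlation matrix and the
# Schur product of PSD matrices is PSD, so Omega is PSD by construction.
gxage_cov <- function(K, ages, sg2_0, se2_0, gamma_g, gamma_e, lambda,
                      ref_age) {
  ac <- ages - ref_age
  sg <- sqrt(sg2_0 * exp(gamma_g * ac))
  se2 <- se2_0 * exp(gamma_e * ac)
  Omega <- K * tcrossprod(sg) * exp(-lambda * abs(outer(ac, ac, `-`)))
  diag(Omega) <- diag(Omega) + se2
  Omega
}

# Draw one MVN(0, Omega) vector exploiting the block structure of K.
rmvn_blocked <- function(K, cov_fun) {
  comps <- matrix_components(K)
  y <- numeric(nrow(K))
  for (idx in comps) {
    Om <- cov_fun(idx)
    L <- tryCatch(chol(Om), error = function(e) NULL)
    if (is.null(L)) {
      Om <- Om + diag(1e-10 * mean(diag(Om)), length(idx))
      L <- chol(Om)
    }
    y[idx] <- drop(crossprod(L, stats::rnorm(length(idx))))
  }
  y
}

#' Simulate a phenotype with age-varying genetic architecture
#'
#' Draws `y ~ MVN(0, Omega)` where the genetic covariance between
#' individuals i and j is `K_ij * sigma_g(a_i) * sigma_g(a_j) *
#' exp(-lambda |a_i - a_j|)` and the environmental variance is diagonal,
#' with `sigma_g^2(a) = sg2_0 exp(gamma_g (a - abar))` and
#' `sigma_e^2(a) = se2_0 exp(gamma_e (a - abar))`.  This is exactly the
#' model [fit_gxage()] estimates: `gamma_g`/`gamma_e` are per-year
#' log-linear trends in variance, `lambda >= 0` is the per-year decay rate
#' of the cross-age genetic correlation (imperfect pleiotropy across
#' ages).
#'
#' @param K a [relmat] or square relatedness matrix.
#' @param ages numeric vector of ages (years), aligned with `K`.
#' @param config a [sim_config()]; the `trait` block supplies `sg2_0`,
#'   `se2_0`, `gamma_g`, `gamma_e`, `lambda` and `ref_age` (`NULL` means
#'   the sample mean age).
#' @param seed optional override of `config$seed`.
#' @return numeric trait vector, one entry per individual.
#' @export
sim_phenotype_gxage <- function(K, ages, config, seed = NULL) {
  R <- as_relmat(K)
  if (length(ages) != nrow(R$K)) stopf("ages not aligned with K")
  tr <- config$trait
  if (tr$sg2_0 < 0 || tr$se2_0 < 0 || tr$lambda < 0)
    stopf("variances and lambda must be non-negative")
  abar <- tr$ref_age %||% mean(ages)
  with_seed(sub_seed(seed %||% config$seed, 3L), {
    rmvn_blocked(R$K, function(idx)
      gxage_cov(R$K[idx, idx, drop = FALSE], ages[idx], tr$sg2_0, tr$se2_0,
                tr$gamma_g, tr$gamma_e, tr$lambda, abar))
  })
}

#' Simulate a pair of traits with a given genetic correlation
#'
#' Draws two unit-variance traits whose genetic covariance is
#' `rho_g * sqrt(h2_1 h2_2) * K` and whose environmental covariance is
#' `rho_e * sqrt((1 - h2_1)(1 - h2_2))` per individual, so the implied
#' phenotypic correlation is `rho_g sqrt(h2_1 h2_2) + rho_e
#' sqrt((1 - h2_1)(1 - h2_2))`.
#'
#' @param K a [relmat] or square relatedness matrix.
#' @param params list with `h2_1`, `h2_2` in `[0, 1]` and `rho_g`,
#'   `rho_e` in `[-1, 1]`.
#' @param seed integer seed.
#' @return a two-column matrix `cbind(y1, y2)`.
#' @export
sim_bivariate <- function(K, params, seed) {
  R <- as_relmat(K)
  h1 <- params$h2_1; h2 <- params$h2_2
  rg <- params$rho_g; re <- params$rho_e
  if (any(c(h1, h2) < 0 | c(h1, h2) > 1)) stopf("h2 must be in [0, 1]")
  if (abs(rg) > 1 || abs(re) > 1) stopf("correlations must be in [-1, 1]")
  n <- nrow(R$K)
  with_seed(sub_seed(seed, 4L), {
    comps <- matrix_components(R$K)
    y <- matrix(0, n, 2)
    for (idx in comps) {
      m <- length(idx)
      Kb <- R$K[idx, idx, drop = FALSE]
      G <- rbind(cbind(h1 * Kb, rg * sqrt(h1 * h2) * Kb),
                 cbind(rg * sqrt(h1 * h2) * Kb, h2 * Kb))
      E <- diag(c(rep(1 - h1, m), rep(1 - h2, m)))
      if (m > 0 && (1 - h1) * (1 - h2) > 0) {
        E[cbind(seq_len(m), m + seq_len(m))] <- re * sqrt((1 - h1) * (1 - h2))
        E[cbind(m + seq_len(m), seq_len(m))] <- re * sqrt((1 - h1) * (1 - h2))
      }
      Om <- G + E
      ee <- eigen(Om, symmetric = TRUE)
      if (min(ee$values) < -1e-8 * max(abs(ee$values)))
        stopf("parameter combination yields a non-PSD covariance")
      rt <- ee$vectors %*% (sqrt(pmax(ee$values, 0)) * t(ee$vectors))
      z <- drop(rt %*% stats::rnorm(2 * m))
      y[idx, 1] <- z[seq_len(m)]
      y[idx, 2] <- z[m + seq_len(m)]
    }
    colnames(y) <- c("y1", "y2")
    y
  })
}

#' Simulate binary item responses from factor scores
#'
#' Item j of subject i is Bernoulli with success probability
#' `pnorm(sum_f L[j, f] * eta[i, f] - tau[j])`: a probit item-response
#' model under the factor structure in `model`.
#'
#' @param scores matrix of latent factor scores (subjects x factors) or a
#'   `factor_scores` object.
#' @param model a [bifactor_model] (its `L` and `tau` are used).
#' @param seed integer seed.
#' @return an [item_matrix] of 0/1 responses.
#' @export
sim_items <- function(scores, model, seed) {
  eta <- if (inherits(scores, "factor_scores")) as.matrix(scores$scores)
         else as.matrix(scores)
  L <- model$L
  if (ncol(eta) != ncol(L))
    stopf("scores have %d factors but model expects %d", ncol(eta), ncol(L))
  with_seed(sub_seed(seed, 5L), {
    pr <- stats::pnorm(tcrossprod(eta, L) - matrix(model$tau, nrow(eta),
                                                   nrow(L), byrow = TRUE))
    resp <- matrix(stats::rbinom(length(pr), 1L, pr), nrow(pr),
                   dimnames = list(rownames(eta), rownames(L)))
    item_matrix(resp)
  })
}

#' Set trait-table entries missing completely at random
#'
#' @param table data.frame with an id column and numeric trait columns.
#' @param rate missingness probability in `[0, 1)`.
#' @param seed integer seed.
#' @param columns which columns to perforate; defaults to all numeric
#'   columns except `id`, `age`, `sex`.
#' @return the table with entries set to `NA`.
#' @export
inject_missingness <- function(table, rate, seed,
                               columns = setdiff(names(table)[vapply(table,
                                 is.numeric, logical(1))],
                                 c("id", "age", "sex"))) {
  if (rate < 0 || rate >= 1) stopf("rate must be in [0, 1)")
  if (rate == 0) return(table)
  with_seed(sub_seed(seed, 6L), {
    for (cl in columns) {
      hit <- stats::runif(nrow(table)) < rate
      table[[cl]][hit] <- NA
    }
    table
  })
}
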