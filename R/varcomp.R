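# Maximum-likelihood variance-component inference.  The univariate model
# uses a per-component eigendecomposition of the relatedness matrix (the
# likelihood is then diagonal in the rotated basis and heritability can
# be profiled in one dimension); the bivariate and Gene x Age models use
# the blocked Cholesky kernels in src/.

#' Rank-based inverse normal transform
#'
#' Maps values through Blom-offset rank quantiles,
#' `qnorm((rank - 3/8) / (n + 1/4))`, with average ranks for ties and
#' missing values preserved.  Applied to traits before variance-component
#' modelling to ensure normality.
#'
#' @param values numeric vector (>= 3 non-missing values).
#' @return transformed vector of the same length.
#' @examples
#' inverse_normal(c(3, 1, 2))  # middle value maps to 0
#' @export
inverse_normal <- function(values) {
  obs <- !is.na(values)
  x <- values[obs]
  if (length(x) < 3) stopf("need at least 3 non-missing values")
  if (length(unique(x)) == 1) stopf("all values identical; no ordering")
  r <- rank(x, ties.method = "average")
  out <- values
  out[obs] <- stats::qnorm((r - 3 / 8) / (length(x) + 1 / 4))
  out
}

#' Benjamini-Hochberg false discovery rate control
#'
#' Step-up procedure at level `q`: p-values are adjusted with
#' [stats::p.adjust()] (method `"BH"`) and tests with adjusted p at or
#' below `q` are rejected.
#'
#' @param p numeric p-values in `[0, 1]`.
#' @param q FDR level.
#' @return data.frame with columns `p`, `p_adjusted`, `reject`.
#' @export
bh_fdr <- function(p, q = 0.05) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stopf("p-values must be in [0, 1]")
  adj <- stats::p.adjust(p, method = "BH")
  data.frame(p = p, p_adjusted = adj, reject = !is.na(adj) & adj <= q)
}

# ---- univariate polygenic model ------------------------------------------

# Rotate (y, X) into the eigenbasis of K, component by component.
rotate_by_components <- function(y, K, X) {
  comps <- matrix_components(K)
  n <- length(y)
  d <- numeric(n); yt <- numeric(n); Xt <- matrix(0, n, ncol(X))
  pos <- 1L
  for (idx in comps) {
    m <- length(idx)
    if (m == 1L) {
      d[pos] <- K[idx, idx]
      yt[pos] <- y[idx]
      Xt[pos, ] <- X[idx, ]
    } else {
      ee <- eigen(K[idx, idx, drop = FALSE], symmetric = TRUE)
      d[pos:(pos + m - 1L)] <- ee$values
      yt[pos:(pos + m - 1L)] <- crossprod(ee$vectors, y[idx])
      Xt[pos:(pos + m - 1L), ] <- crossprod(ee$vectors, X[idx, , drop = FALSE])
    }
    pos <- pos + m
  }
  list(d = d, y = yt, X = Xt, n = n)
}

# Profile log-likelihood of h2 with sigma2_p and beta maximized out.
profile_h2_loglik <- function(h2, rot) {
  w <- h2 * rot$d + (1 - h2)
  if (any(w <= 0)) return(-Inf)
  sw <- 1 / w
  XtW <- rot$X * sw
  A <- crossprod(rot$X, XtW)
  b <- crossprod(XtW, rot$y)
  beta <- tryCatch(solve(A, b), error = function(e) NULL)
  if (is.null(beta)) return(-Inf)
  r <- rot$y - drop(rot$X %*% beta)
  rss <- sum(r^2 * sw)
  n <- rot$n
  sp2 <- rss / n
  ll <- -0.5 * (n * log(2 * pi) + n * log(sp2) + sum(log(w)) + n)
  attr(ll, "beta") <- drop(beta)
  attr(ll, "sp2") <- sp2
  attr(ll, "A") <- A
  ll
}

#' Fit the univariate polygenic model
#'
#' Maximizes the Gaussian likelihood of `y ~ N(X beta, sg2 * K + se2 * I)`
#' over fixed effects and variance components.  Heritability
#' `h2 = sg2 / (sg2 + se2)` is profiled in one dimension (total variance
#' and fixed effects have closed-form maximizers given `h2`), which makes
#' the boundary `h2 = 0` exactly attainable.  Rows with missing phenotype
#' are dropped, with `K` and `X` subset accordingly.
#'
#' @param y numeric trait vector (`NA` allowed).
#' @param K a [relmat] or square relatedness matrix.
#' @param X covariate design matrix including an intercept; defaults to an
#'   intercept-only design.  See [build_covariates()].
#' @param h2_fixed optionally pin heritability (e.g. `0` for the null
#'   model of the heritability likelihood-ratio test).
#' @param se compute observed-information standard errors.
#' @return an object of class `polygenic_fit`: variance components `sg2`,
#'   `se2`, `sp2`, `h2`, fixed effects `beta` with `beta_se`, standard
#'   errors `se` for `(sg2, se2, h2)`, the maximized `loglik`, and the
#'   heritability LRT (`lrt`, boundary mixture null) unless `h2_fixed`
#'   was given.
#' @export
fit_polygenic <- function(y, K, X = NULL, h2_fixed = NULL, se = TRUE) {
  R <- as_relmat(K)
  n_all <- length(y)
  if (nrow(R$K) != n_all) stopf("y and K are not aligned")
  if (is.null(X)) X <- matrix(1, n_all, 1, dimnames = list(NULL, "intercept"))
  keep <- which(!is.na(y))
  if (length(keep) < ncol(X) + 2) stopf("too few observations for the design")
  yk <- y[keep]
  Xk <- X[keep, , drop = FALSE]
  Kk <- R$K[keep, keep, drop = FALSE]
  rot <- rotate_by_components(yk, Kk, Xk)

  fit_at <- function(h2) profile_h2_loglik(h2, rot)
  if (is.null(h2_fixed)) {
    opt <- stats::optimize(function(h) as.numeric(fit_at(h)),
                           interval = c(0, 1 - 1e-9), maximum = TRUE,
                           tol = 1e-9)
    cand <- c(opt$maximum, 0, 1 - 1e-9)
    lls <- vapply(cand, function(h) as.numeric(fit_at(h)), numeric(1))
    h2 <- cand[which.max(lls)]
  } else {
    if (h2_fixed < 0 || h2_fixed >= 1) stopf("h2_fixed must be in [0, 1)")
    h2 <- h2_fixed
  }
  ll <- fit_at(h2)
  sp2 <- attr(ll, "sp2")
  beta <- attr(ll, "beta")
  A <- attr(ll, "A")
  sg2 <- h2 * sp2
  se2 <- (1 - h2) * sp2

  ses <- c(sg2 = NA_real_, se2 = NA_real_, h2 = NA_real_)
  vc_cov <- NULL
  if (se && is.null(h2_fixed)) {
    nll_vc <- function(p) {
      s_g <- p[1]; s_e <- p[2]
      if (s_e <= 0 || s_g < 0) return(1e10)
      -as.numeric(loglik_given_vc(s_g, s_e, rot))
    }
    H <- fd_hessian(nll_vc, c(sg2, se2))
    if (h2 > 1e-8) {
      vc_cov <- tryCatch(solve(H), error = function(e) NULL)
      if (!is.null(vc_cov) && all(diag(vc_cov) > 0)) {
        ses["sg2"] <- sqrt(vc_cov[1, 1])
        ses["se2"] <- sqrt(vc_cov[2, 2])
        gr <- c(se2, -sg2) / sp2^2
        v <- drop(t(gr) %*% vc_cov %*% gr)
        if (v > 0) ses["h2"] <- sqrt(v)
      }
    }
  }
  beta_se <- sqrt(pmax(diag(solve(A)) * sp2, 0))

  fit <- structure(list(
    sg2 = sg2, se2 = se2, sp2 = sp2, h2 = h2,
    beta = stats::setNames(beta, colnames(X)),
    beta_se = stats::setNames(beta_se, colnames(X)),
    se = ses, vc_cov = vc_cov,
    loglik = as.numeric(ll), n = rot$n, df = ncol(X) + 2,
    h2_fixed = h2_fixed, converged = TRUE,
    call = match.call()), class = "polygenic_fit")
  if (is.null(h2_fixed)) {
    null_ll <- as.numeric(fit_at(0))
    fit$lrt <- lrt_nested(fit$loglik, null_ll, boundary = TRUE)
  }
  fit
}

# log-likelihood at given (sg2, se2) with beta profiled, rotated basis
loglik_given_vc <- function(sg2, se2, rot) {
  w <- sg2 * rot$d + se2
  if (any(w <= 0)) return(-Inf)
  sw <- 1 / w
  XtW <- rot$X * sw
  A <- crossprod(rot$X, XtW)
  beta <- solve(A, crossprod(XtW, rot$y))
  r <- rot$y - drop(rot$X %*% beta)
  -0.5 * (rot$n * log(2 * pi) + sum(log(w)) + sum(r^2 * sw))
}

#' Evaluate the univariate polygenic log-likelihood at given parameters
#'
#' Exposes the model's likelihood computation (per-component
#' eigendecomposition) at user-supplied variance components, for checking
#' against direct dense-matrix evaluation.
#'
#' @inheritParams fit_polygenic
#' @param sg2,se2 genetic and environmental variances.
#' @param beta fixed effects; `NULL` profiles them by GLS.
#' @return log-likelihood value.
#' @export
polygenic_loglik <- function(y, K, X = NULL, sg2, se2, beta = NULL) {
  R <- as_relmat(K)
  if (is.null(X)) X <- matrix(1, length(y), 1)
  keep <- which(!is.na(y))
  rot <- rotate_by_components(y[keep], R$K[keep, keep, drop = FALSE],
                              X[keep, , drop = FALSE])
  if (is.null(beta)) return(as.numeric(loglik_given_vc(sg2, se2, rot)))
  w <- sg2 * rot$d + se2
  r <- rot$y - drop(rot$X %*% beta)
  -0.5 * (rot$n * log(2 * pi) + sum(log(w)) + sum(r^2 / w))
}

# ---- likelihood-ratio tests ----------------------------------------------

#' Likelihood-ratio test for nested variance-component models
#'
#' Computes `2 * (logLik_full - logLik_null)`.  For interior parameters
#' (`gamma_g`, `gamma_e`, `rho_g`, `rho_e`) the null distribution is
#' chi-squared with `df` degrees of freedom; for a parameter tested on
#' the boundary of its space (a variance component at 0, or the decay
#' rate `lambda = 0`) it is the `1/2 chi2_0 + 1/2 chi2_1` mixture.
#'
#' @param full,null fitted model objects (anything with a `loglik`
#'   element or a [logLik()] method) or bare log-likelihood values.
#' @param boundary is the constrained parameter on its boundary?
#' @param df degrees of freedom for the interior case.
#' @return object of class `lrt_result` with `statistic`, `df`,
#'   `boundary` and `p`.
#' @examples
#' lrt_nested(-99.5, -100.853, boundary = TRUE)   # statistic 2.706, p = 0.05
#' @export
lrt_nested <- function(full, null, boundary = FALSE, df = 1L) {
  ll_full <- extract_ll(full)
  ll_null <- extract_ll(null)
  stat <- 2 * (ll_full - ll_null)
  if (stat < -1e-6)
    stopf("full model log-likelihood below the null's (%.3g); refit needed", stat)
  stat <- max(stat, 0)
  p <- if (boundary) 0.5 * stats::pchisq(stat, df = 1, lower.tail = FALSE)
       else stats::pchisq(stat, df = df, lower.tail = FALSE)
  structure(list(statistic = stat, df = if (boundary) NA_integer_ else df,
                 boundary = boundary, p = p),
            class = "lrt_result")
}

extract_ll <- function(x) {
  if (is.numeric(x) && length(x) == 1L) return(as.numeric(x))
  if (!is.null(x$loglik)) return(x$loglik)
  as.numeric(stats::logLik(x))
}

#' @export
print.lrt_result <- function(x, ...) {
  cat(sprintf("LRT: statistic = %.4f, null = %s, p = %.4g\n", x$statistic,
              if (x$boundary) "0.5*chi2_0 + 0.5*chi2_1"
              else sprintf("chi2_%d", x$df), x$p))
  invisible(x)
}

# ---- bivariate polygenic model -------------------------------------------

prep_blocks <- function(K, X, extra = list()) {
  comps <- matrix_components(K)
  list(comps = comps,
       Kb = lapply(comps, function(i) K[i, i, drop = FALSE]),
       Xb = lapply(comps, function(i) X[i, , drop = FALSE]))
}

#' Fit the bivariate polygenic model
#'
#' Decomposes the phenotypic covariance of two traits into genetic and
#' environmental parts: the stacked covariance has genetic blocks
#' `sg2_1 K`, `sg2_2 K` and cross-block `rho_g sqrt(sg2_1 sg2_2) K`, and
#' environmental blocks diagonal per individual with within-person
#' cross-trait covariance `rho_e sqrt(se2_1 se2_2)`.  Subjects missing
#' one trait contribute through the observed entries only (row deletion
#' per trait).  Variances are optimized on the log scale and
#' correlations through the Fisher z transform, with quasi-Newton
#' multi-starts.
#'
#' @param y1,y2 trait vectors (`NA` allowed).
#' @param K a [relmat] or square relatedness matrix.
#' @param X covariate design (shared by both traits); intercept-only if
#'   `NULL`.
#' @param fixed named list pinning parameters, e.g. `list(rho_g = 0)`.
#' @param tests compute likelihood-ratio tests for `rho_g = 0` and
#'   `rho_e = 0` (interior chi-squared, 1 df).
#' @param n_starts,seed multi-start control.
#' @return an object of class `bivariate_fit`: per-trait `(sg2, se2, h2)`,
#'   `rho_g`, `rho_e`, the implied phenotypic correlation `rho_p`,
#'   standard errors, `loglik`, and `lrt_rho_g` / `lrt_rho_e`.
#' @export
fit_bivariate <- function(y1, y2, K, X = NULL, fixed = list(), tests = TRUE,
                          n_starts = 3L, seed = 1L) {
  R <- as_relmat(K)
  n <- nrow(R$K)
  if (length(y1) != n || length(y2) != n) stopf("traits not aligned with K")
  if (is.null(X)) X <- matrix(1, n, 1, dimnames = list(NULL, "intercept"))
  if (sum(!is.na(y1)) < ncol(X) + 2 || sum(!is.na(y2)) < ncol(X) + 2)
    stopf("too few observations for the design")
  pb <- prep_blocks(R$K, X)
  y1b <- lapply(pb$comps, function(i) y1[i])
  y2b <- lapply(pb$comps, function(i) y2[i])

  # starts from the univariate fits
  f1 <- fit_polygenic(y1, R, X, se = FALSE)
  f2 <- fit_polygenic(y2, R, X, se = FALSE)
  base <- c(log(max(f1$sg2, 0.02 * f1$sp2)), log(max(f1$se2, 0.02 * f1$sp2)),
            log(max(f2$sg2, 0.02 * f2$sp2)), log(max(f2$se2, 0.02 * f2$sp2)),
            0, 0)
  par_names <- c("lsg1", "lse1", "lsg2", "lse2", "zg", "ze")
  fix_map <- c(rho_g = 5L, rho_e = 6L)
  fixed_idx <- integer(0); fixed_val <- numeric(0)
  for (nm in names(fixed)) {
    if (!nm %in% names(fix_map)) stopf("cannot fix parameter '%s'", nm)
    fixed_idx <- c(fixed_idx, fix_map[[nm]])
    fixed_val <- c(fixed_val, atanh(fixed[[nm]]))
  }
  free <- setdiff(seq_along(base), fixed_idx)

  nll_free <- function(pf) {
    par <- base
    par[free] <- pf
    par[fixed_idx] <- fixed_val
    cpp_bivar_nll(par, pb$Kb, pb$Xb, y1b, y2b)
  }
  starts <- with_seed(sub_seed(seed, 9L), {
    lapply(seq_len(n_starts), function(k) {
      st <- base[free]
      if (k > 1) st <- st + stats::rnorm(length(free), 0, 0.3)
      st
    })
  })
  fits <- lapply(starts, function(st)
    stats::optim(st, nll_free, method = "L-BFGS-B",
                 lower = ifelse(free >= 5, -6, -20),
                 upper = ifelse(free >= 5, 6, 20),
                 control = list(maxit = 500)))
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]
  par <- base; par[free] <- best$par; par[fixed_idx] <- fixed_val
  det <- cpp_bivar_details(par, pb$Kb, pb$Xb, y1b, y2b)

  sg2_1 <- exp(par[1]); se2_1 <- exp(par[2])
  sg2_2 <- exp(par[3]); se2_2 <- exp(par[4])
  rho_g <- tanh(par[5]); rho_e <- tanh(par[6])
  h2_1 <- sg2_1 / (sg2_1 + se2_1); h2_2 <- sg2_2 / (sg2_2 + se2_2)
  rho_p <- rho_g * sqrt(h2_1 * h2_2) + rho_e * sqrt((1 - h2_1) * (1 - h2_2))

  # delta-method SEs from the observed information on the free scale
  ses <- rep(NA_real_, 6)
  H <- fd_hessian(nll_free, best$par)
  Vf <- tryCatch(solve(H), error = function(e) NULL)
  if (!is.null(Vf) && all(diag(Vf) > 0)) {
    V <- matrix(0, 6, 6); V[free, free] <- Vf
    jac <- c(sg2_1, se2_1, sg2_2, se2_2, 1 - rho_g^2, 1 - rho_e^2)
    ses <- sqrt(pmax(diag(V) * jac^2, 0))
    ses[fixed_idx] <- NA_real_
  }
  names(ses) <- c("sg2_1", "se2_1", "sg2_2", "se2_2", "rho_g", "rho_e")

  fit <- structure(list(
    traits = data.frame(trait = c("y1", "y2"), sg2 = c(sg2_1, sg2_2),
                        se2 = c(se2_1, se2_2), h2 = c(h2_1, h2_2)),
    rho_g = rho_g, rho_e = rho_e, rho_p = rho_p,
    beta = det$beta, se = ses, loglik = det$loglik,
    n = c(n1 = sum(!is.na(y1)), n2 = sum(!is.na(y2))),
    fixed = fixed, convergence = best$convergence,
    call = match.call()), class = "bivariate_fit")
  if (tests && !"rho_g" %in% names(fixed))
    fit$lrt_rho_g <- lrt_nested(fit$loglik,
      fit_bivariate(y1, y2, R, X, fixed = c(fixed, list(rho_g = 0)),
                    tests = FALSE, n_starts = n_starts, seed = seed)$loglik,
      boundary = FALSE)
  if (tests && !"rho_e" %in% names(fixed))
    fit$lrt_rho_e <- lrt_nested(fit$loglik,
      fit_bivariate(y1, y2, R, X, fixed = c(fixed, list(rho_e = 0)),
                    tests = FALSE, n_starts = n_starts, seed = seed)$loglik,
      boundary = FALSE)
  fit
}

#' Evaluate the bivariate log-likelihood at given parameters
#'
#' @inheritParams fit_bivariate
#' @param pars named list: `sg2_1`, `se2_1`, `sg2_2`, `se2_2`, `rho_g`,
#'   `rho_e`.
#' @param beta stacked fixed effects `(beta_1, beta_2)`; `NULL` profiles
#'   them.
#' @return log-likelihood value.
#' @export
bivariate_loglik <- function(y1, y2, K, X = NULL, pars, beta = NULL) {
  R <- as_relmat(K)
  n <- nrow(R$K)
  if (is.null(X)) X <- matrix(1, n, 1)
  pb <- prep_blocks(R$K, X)
  y1b <- lapply(pb$comps, function(i) y1[i])
  y2b <- lapply(pb$comps, function(i) y2[i])
  par <- c(log(pars$sg2_1), log(pars$se2_1), log(pars$sg2_2), log(pars$se2_2),
           atanh(pars$rho_g), atanh(pars$rho_e))
  -cpp_bivar_nll(par, pb$Kb, pb$Xb, y1b, y2b,
                 if (is.null(beta)) NULL else as.numeric(beta))
}

# ---- Gene x Age model ----------------------------------------------------

#' Fit the Gene x Age variance-component interaction model
#'
#' Extends the polygenic model with age-dependent variance components:
#' `log sigma_g^2(a) = alpha_g + gamma_g (a - abar)` and
#' `log sigma_e^2(a) = alpha_e + gamma_e (a - abar)`, and with an
#' exponential decay of the cross-age genetic correlation,
#' `exp(-lambda |a_i - a_j|)` with `lambda >= 0`.  A nonzero `gamma_g`
#' means the magnitude of genetic effects changes with age; a nonzero
#' `lambda` means imperfect pleiotropy across ages (the genetic factors
#' themselves change).  The covariance between individuals i and j is
#' `K_ij sigma_g(a_i) sigma_g(a_j) exp(-lambda |a_i - a_j|)` plus
#' diagonal `sigma_e^2(a_i)`.
#'
#' @param y trait vector (`NA` allowed).
#' @param K a [relmat] or square relatedness matrix.
#' @param ages numeric ages in years, aligned with `y`.
#' @param X covariate design; intercept-only if `NULL`.
#' @param fixed named list pinning any of `gamma_g`, `gamma_e`, `lambda`
#'   (e.g. `list(gamma_g = 0, gamma_e = 0, lambda = 0)` reduces the model
#'   to [fit_polygenic()]).
#' @param ref_age centring age `abar`; defaults to the sample mean, so
#'   `exp(alpha_g)` is the genetic variance at the average age.
#' @param tests likelihood-ratio tests for `gamma_g = 0`, `gamma_e = 0`
#'   (interior) and `lambda = 0` (boundary mixture).
#' @param n_starts,seed multi-start control.
#' @return an object of class `gxage_fit` with elements `par`
#'   (`alpha_g`, `gamma_g`, `alpha_e`, `gamma_e`, `lambda`), `se`,
#'   `ref_age`, `beta`, `loglik`, and the requested `lrt_*` entries.
#' @export
fit_gxage <- function(y, K, ages, X = NULL, fixed = list(), ref_age = NULL,
                      tests = TRUE, n_starts = 3L, seed = 1L) {
  R <- as_relmat(K)
  n <- nrow(R$K)
  if (length(y) != n || length(ages) != n) stopf("y/ages not aligned with K")
  if (is.null(X)) X <- matrix(1, n, 1, dimnames = list(NULL, "intercept"))
  keep <- which(!is.na(y))
  if (length(keep) < ncol(X) + 2) stopf("too few observations for the design")
  yk <- y[keep]; Xk <- X[keep, , drop = FALSE]; agek <- ages[keep]
  Kk <- R$K[keep, keep, drop = FALSE]
  abar <- ref_age %||% mean(agek)
  ac <- agek - abar
  pb <- prep_blocks(Kk, Xk)
  ab <- lapply(pb$comps, function(i) ac[i])
  yb <- lapply(pb$comps, function(i) yk[i])

  par_names <- c("alpha_g", "gamma_g", "alpha_e", "gamma_e", "lambda")
  base <- {
    f0 <- fit_polygenic(yk, Kk, Xk, se = FALSE)
    c(log(max(f0$sg2, 0.02 * f0$sp2)), 0,
      log(max(f0$se2, 0.02 * f0$sp2)), 0, 0.01)
  }
  fixed_idx <- match(names(fixed), par_names)
  if (anyNA(fixed_idx)) stopf("cannot fix parameter '%s'",
                              names(fixed)[is.na(fixed_idx)][1])
  fixed_val <- as.numeric(unlist(fixed))
  if (any(par_names[fixed_idx] == "lambda" & fixed_val < 0))
    stopf("lambda must be >= 0")
  free <- setdiff(seq_along(base), fixed_idx)
  base[fixed_idx] <- fixed_val
  lower <- c(-20, -2, -20, -2, 0)
  upper <- c(20, 2, 20, 2, 5)

  nll_free <- function(pf) {
    par <- base; par[free] <- pf
    cpp_gxage_nll(par, pb$Kb, ab, pb$Xb, yb)
  }
  starts <- with_seed(sub_seed(seed, 10L), {
    lapply(seq_len(n_starts), function(k) {
      st <- base[free]
      if (k > 1) st <- st + stats::rnorm(length(free), 0, 0.2)
      pmin(pmax(st, lower[free] + 1e-6), upper[free] - 1e-6)
    })
  })
  fits <- lapply(starts, function(st)
    stats::optim(st, nll_free, method = "L-BFGS-B", lower = lower[free],
                 upper = upper[free], control = list(maxit = 500)))
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]
  par <- base; par[free] <- best$par
  names(par) <- par_names
  det <- cpp_gxage_details(par, pb$Kb, ab, pb$Xb, yb)
  if (par["lambda"] >= upper[5] - 1e-6)
    warning("lambda pinned at its upper bound", call. = FALSE)

  ses <- stats::setNames(rep(NA_real_, 5), par_names)
  at_bound <- par[free] <= lower[free] + 1e-8 | par[free] >= upper[free] - 1e-8
  if (length(free)) {
    H <- fd_hessian(nll_free, best$par)
    Vf <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(Vf)) {
      dv <- diag(Vf)
      ok <- dv > 0 & !at_bound
      ses[par_names[free][ok]] <- sqrt(dv[ok])
    }
  }

  fit <- structure(list(
    par = par, se = ses, ref_age = abar,
    sg2_ref = exp(par[["alpha_g"]]), se2_ref = exp(par[["alpha_e"]]),
    beta = det$beta, loglik = det$loglik, n = length(keep),
    fixed = fixed, convergence = best$convergence,
    call = match.call()), class = "gxage_fit")

  if (tests) {
    refit_null <- function(extra)
      fit_gxage(y, R, ages, X, fixed = utils::modifyList(fixed, extra),
                ref_age = abar, tests = FALSE, n_starts = n_starts,
                seed = seed)$loglik
    if (!"gamma_g" %in% names(fixed))
      fit$lrt_gamma_g <- lrt_nested(fit$loglik, refit_null(list(gamma_g = 0)),
                                    boundary = FALSE)
    if (!"gamma_e" %in% names(fixed))
      fit$lrt_gamma_e <- lrt_nested(fit$loglik, refit_null(list(gamma_e = 0)),
                                    boundary = FALSE)
    if (!"lambda" %in% names(fixed))
      fit$lrt_lambda <- lrt_nested(fit$loglik, refit_null(list(lambda = 0)),
                                   boundary = TRUE)
  }
  fit
}

#' Evaluate the Gene x Age log-likelihood at given parameters
#'
#' @inheritParams fit_gxage
#' @param pars named list/vector: `alpha_g`, `gamma_g`, `alpha_e`,
#'   `gamma_e`, `lambda`.
#' @param beta fixed effects; `NULL` profiles them.
#' @return log-likelihood value.
#' @export
gxage_loglik <- function(y, K, ages, X = NULL, pars, ref_age = NULL,
                         beta = NULL) {
  R <- as_relmat(K)
  n <- nrow(R$K)
  if (is.null(X)) X <- matrix(1, n, 1)
  abar <- ref_age %||% mean(ages)
  pb <- prep_blocks(R$K, X)
  ab <- lapply(pb$comps, function(i) ages[i] - abar)
  yb <- lapply(pb$comps, function(i) y[i])
  p <- unlist(pars)[c("alpha_g", "gamma_g", "alpha_e", "gamma_e", "lambda")]
  -cpp_gxage_nll(as.numeric(p), pb$Kb, ab, pb$Xb, yb,
                 if (is.null(beta)) NULL else as.numeric(beta))
}

#' Variance and heritability curves over age
#'
#' Evaluates the fitted age-varying components on a grid:
#' `sg2(a) = exp(alpha_g + gamma_g (a - abar))`,
#' `se2(a) = exp(alpha_e + gamma_e (a - abar))`, and
#' `h2(a) = sg2(a) / (sg2(a) + se2(a))`.
#'
#' @param fit a [fit_gxage()] result.
#' @param ages age grid in years.
#' @return data.frame with columns `age`, `sg2`, `se2`, `h2`.
#' @export
variance_by_age <- function(fit, ages = seq(8, 21, by = 0.5)) {
  p <- fit$par
  sg2 <- exp(p[["alpha_g"]] + p[["gamma_g"]] * (ages - fit$ref_age))
  se2 <- exp(p[["alpha_e"]] + p[["gamma_e"]] * (ages - fit$ref_age))
  data.frame(age = ages, sg2 = sg2, se2 = se2, h2 = sg2 / (sg2 + se2))
}
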