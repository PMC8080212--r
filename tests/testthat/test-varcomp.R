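test_that("the rank-based inverse normal transform matches its quantiles", {
  v <- inverse_normal(c(3, 1, 2))
  expect_equal(v[2], qnorm((1 - 3 / 8) / 3.25))
  expect_equal(v[3], 0)
  expect_equal(v[1], qnorm((3 - 3 / 8) / 3.25))
  expect_equal(abs(v[1]), 0.870, tolerance = 1e-3)

  set.seed(41)
  y <- inverse_normal(rexp(1000))
  expect_lt(abs(mean(y)), 0.01)
  expect_lt(abs(sd(y) - 1), 0.01)

  # ties get average ranks; missing preserved
  vt <- inverse_normal(c(1, 2, 2, 5, NA))
  expect_equal(vt[2], vt[3])
  expect_true(is.na(vt[5]))
  expect_error(inverse_normal(c(1, 1, 1)), "identical")
  expect_error(inverse_normal(c(1, 2)), "3 non-missing")
})

test_that("likelihood evaluations match the dense MVN oracle", {
  set.seed(42)
  K <- toy_K6()
  X <- cbind(1, rnorm(6))
  y <- rnorm(6)
  beta <- c(0.3, -0.2)

  sg2 <- 0.7; se2 <- 0.4
  Om <- sg2 * K + se2 * diag(6)
  expect_lt(abs(polygenic_loglik(y, K, X, sg2, se2, beta = beta) -
                  dmvn_oracle(y, drop(X %*% beta), Om)), 1e-8)

  ages <- c(9, 12, 15, 10, 18, 20)
  pars <- list(alpha_g = -0.4, gamma_g = -0.12, alpha_e = -0.8,
               gamma_e = 0.05, lambda = 0.15)
  ac <- ages - mean(ages)
  sg <- sqrt(exp(pars$alpha_g + pars$gamma_g * ac))
  Om2 <- K * outer(sg, sg) * exp(-pars$lambda * abs(outer(ages, ages, "-")))
  diag(Om2) <- diag(Om2) + exp(pars$alpha_e + pars$gamma_e * ac)
  expect_lt(abs(gxage_loglik(y, K, ages, X, pars, beta = beta) -
                  dmvn_oracle(y, drop(X %*% beta), Om2)), 1e-8)

  y2 <- rnorm(6)
  bp <- list(sg2_1 = 0.6, se2_1 = 0.4, sg2_2 = 0.5, se2_2 = 0.6,
             rho_g = -0.4, rho_e = 0.2)
  G <- rbind(cbind(bp$sg2_1 * K, bp$rho_g * sqrt(bp$sg2_1 * bp$sg2_2) * K),
             cbind(bp$rho_g * sqrt(bp$sg2_1 * bp$sg2_2) * K, bp$sg2_2 * K))
  E <- diag(c(rep(bp$se2_1, 6), rep(bp$se2_2, 6)))
  E[cbind(1:6, 7:12)] <- E[cbind(7:12, 1:6)] <-
    bp$rho_e * sqrt(bp$se2_1 * bp$se2_2)
  bb <- c(beta, 0.1, 0.4)
  Xs <- rbind(cbind(X, 0 * X), cbind(0 * X, X))
  expect_lt(abs(bivariate_loglik(y, y2, K, X, bp, beta = bb) -
                  dmvn_oracle(c(y, y2), drop(Xs %*% bb), G + E)), 1e-8)
})

test_that("boundary and interior likelihood-ratio tests use the stated nulls", {
  same <- lrt_nested(-100, -100, boundary = TRUE)
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 0.5)
  expect_equal(lrt_nested(-100, -100, boundary = FALSE)$p, 1)

  expect_equal(lrt_nested(-99, -99 - 2.706 / 2, boundary = TRUE)$p, 0.05,
               tolerance = 1e-3)
  expect_equal(lrt_nested(-99, -99 - 3.841 / 2, boundary = FALSE)$p, 0.05,
               tolerance = 1e-3)
  expect_error(lrt_nested(-101, -100), "refit")
})

test_that("heritability estimates are invariant to scaling and permutation", {
  ped <- quad_cohort(40, 40, seed = 43)
  K <- kinship_from_pedigree(ped)
  X <- build_covariates(ped$age, ped$sex)
  y <- draw_polygenic_trait(K$K, 0.5, 0.5, seed = 44) + X[, "age_c"] * 0.1
  f1 <- fit_polygenic(y, K, X, se = FALSE)
  f2 <- fit_polygenic(3 + 2.5 * y, K, X, se = FALSE)
  expect_lt(abs(f1$h2 - f2$h2), 1e-6)

  set.seed(45); perm <- sample(nrow(ped))
  f3 <- fit_polygenic(y[perm], relmat(K$K[perm, perm]), X[perm, , drop = FALSE],
                      se = FALSE)
  expect_lt(abs(f1$h2 - f3$h2), 1e-6)
  expect_lt(abs(f1$loglik - f3$loglik), 1e-6)

  # internal consistency of the decomposition
  expect_lt(abs(f1$h2 * f1$sp2 - f1$sg2), 1e-10)
})

test_that("polygenic recovery and estimator consistency across cohort sizes", {
  h2hat <- function(n_fam, n_sing, reps, seed0) {
    ped <- quad_cohort(n_fam, n_sing, seed = 46)
    K <- kinship_from_pedigree(ped)
    sapply(seq_len(reps), function(r) {
      y <- draw_polygenic_trait(K$K, 0.5, 0.5, seed = seed0 + r)
      fit_polygenic(y, K, se = FALSE)$h2
    })
  }
  est <- h2hat(200, 200, reps = 8, seed0 = 100)
  expect_lt(abs(mean(est) - 0.5), 0.07)

  # bias shrinks with N on a small grid
  bias <- sapply(c(50, 120, 250), function(nf)
    abs(mean(h2hat(nf, nf, reps = 6, seed0 = 300 + nf)) - 0.5))
  expect_lt(bias[3], bias[1] + 0.05)
})

test_that("null traits give calibrated heritability estimates", {
  ped <- quad_cohort(60, 60, seed = 47)
  K <- kinship_from_pedigree(ped)
  set.seed(48)
  est <- replicate(60, fit_polygenic(rnorm(nrow(ped)), K, se = FALSE)$h2)
  expect_lt(mean(est), 0.08)
  expect_gt(mean(est == 0), 0.3)   # boundary attained exactly
})

test_that("bivariate fits satisfy the phenotypic-correlation identity", {
  ped <- quad_cohort(150, 100, seed = 49)
  K <- kinship_from_pedigree(ped)
  yy <- sim_bivariate(K, list(h2_1 = .5, h2_2 = .5, rho_g = -.4, rho_e = 0),
                      seed = 50)
  fit <- fit_bivariate(yy[, 1], yy[, 2], K, tests = FALSE, n_starts = 1)
  with(fit, {
    h <- traits$h2
    expect_lt(abs(rho_p - (rho_g * sqrt(h[1] * h[2]) +
                             rho_e * sqrt((1 - h[1]) * (1 - h[2])))), 1e-8)
  })
  expect_lt(abs(fit$rho_g + 0.4), 0.25)   # single replicate, loose bound

  # null recovery
  yy0 <- sim_bivariate(K, list(h2_1 = .5, h2_2 = .5, rho_g = 0, rho_e = 0),
                       seed = 51)
  fit0 <- fit_bivariate(yy0[, 1], yy0[, 2], K, tests = FALSE, n_starts = 1)
  expect_lt(abs(fit0$rho_g), 0.25)

  # missing rows are tolerated (row deletion per trait)
  y1m <- yy[, 1]; y1m[1:30] <- NA
  y2m <- yy[, 2]; y2m[20:50] <- NA
  fitm <- fit_bivariate(y1m, y2m, K, tests = FALSE, n_starts = 1)
  expect_true(is.finite(fitm$loglik))
})

test_that("the Gene x Age model nests the polygenic model", {
  ped <- quad_cohort(50, 50, seed = 52)
  K <- kinship_from_pedigree(ped)
  X <- build_covariates(ped$age, ped$sex)
  y <- draw_polygenic_trait(K$K, 0.5, 0.5, seed = 53)
  f0 <- fit_polygenic(y, K, X)
  fr <- fit_gxage(y, K, ped$age, X,
                  fixed = list(gamma_g = 0, gamma_e = 0, lambda = 0),
                  tests = FALSE)
  expect_lt(abs(f0$loglik - fr$loglik), 1e-6)
  expect_lt(abs(exp(fr$par[["alpha_g"]]) - f0$sg2), 0.02)

  # full model log-likelihood always at least the nested one's
  ff <- fit_gxage(y, K, ped$age, X, tests = TRUE)
  expect_gte(ff$loglik, fr$loglik - 1e-8)
  expect_true(all(c(ff$lrt_gamma_g$p, ff$lrt_gamma_e$p, ff$lrt_lambda$p) >= 0))
  expect_true(all(c(ff$lrt_gamma_g$p, ff$lrt_gamma_e$p, ff$lrt_lambda$p) <= 1))
})

test_that("variance-by-age curves follow the closed form", {
  fit <- structure(list(par = c(alpha_g = log(0.46), gamma_g = -0.146,
                                alpha_e = log(0.54), gamma_e = 0),
                        ref_age = 14.5), class = "gxage_fit")
  fit$par <- c(fit$par, lambda = 0)
  cv <- variance_by_age(fit, ages = c(8, 14.5, 21))
  expect_equal(cv$sg2[3] / cv$sg2[1], exp(-0.146 * 13), tolerance = 1e-12)
  expect_equal(cv$sg2[2], 0.46, tolerance = 1e-12)
  expect_equal(cv$se2, rep(0.54, 3), tolerance = 1e-12)
  expect_equal(cv$h2, cv$sg2 / (cv$sg2 + cv$se2), tolerance = 1e-12)

  flat <- structure(list(par = c(alpha_g = 0, gamma_g = 0, alpha_e = 0,
                                 gamma_e = 0, lambda = 0), ref_age = 12),
                    class = "gxage_fit")
  cvf <- variance_by_age(flat)
  expect_true(all(cvf$sg2 == 1) && all(cvf$h2 == 0.5))
})

test_that("Benjamini-Hochberg control matches hand enumeration", {
  p <- c(0.001, 0.01, 0.02, 0.04, 0.5)
  out <- bh_fdr(p, q = 0.05)
  expect_equal(out$reject, c(TRUE, TRUE, TRUE, TRUE, FALSE))
  expect_equal(out$p_adjusted, c(0.005, 0.025, 1 / 30, 0.05, 0.5),
               tolerance = 1e-12)
  expect_false(any(bh_fdr(rep(1, 6))$reject))
  expect_true(bh_fdr(0.04, 0.05)$reject)
})

test_that("missing phenotypes are dropped consistently with K and X", {
  ped <- quad_cohort(30, 30, seed = 54)
  K <- kinship_from_pedigree(ped)
  y <- draw_polygenic_trait(K$K, 0.5, 0.5, seed = 55)
  ym <- y; ym[c(3, 17, 40)] <- NA
  keep <- !is.na(ym)
  f_full <- fit_polygenic(ym, K, se = FALSE)
  f_sub <- fit_polygenic(y[keep], relmat(K$K[keep, keep]), se = FALSE)
  expect_equal(f_full$loglik, f_sub$loglik, tolerance = 1e-10)
  expect_equal(f_full$n, sum(keep))
  expect_error(fit_polygenic(rep(NA_real_, nrow(ped)), K), "few observations")
})
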