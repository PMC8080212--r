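test_that("pedigree generator produces the requested family structure", {
  cfg <- sim_config(n_families = 0L, n_singletons = 10L, n_snps = 10L, seed = 1)
  ped <- sim_pedigrees(cfg)
  expect_equal(nrow(ped), 10L)
  expect_true(all(is.na(ped$father)) && all(is.na(ped$mother)))
  expect_equal(anyDuplicated(ped$fam), 0L)

  cfg <- sim_config(n_families = 1L, children_per_family = 2L,
                    n_singletons = 0L, n_snps = 10L, seed = 1)
  ped <- sim_pedigrees(cfg)
  expect_equal(nrow(ped), 4L)
  founders <- ped$id[is.na(ped$father)]
  expect_length(founders, 2L)
  kids <- ped[!is.na(ped$father), ]
  expect_true(all(kids$father == founders[1]) || all(kids$father == founders[2]))
  expect_setequal(unique(c(kids$father, kids$mother)), founders)

  expect_error(sim_pedigrees(sim_config(n_families = 2L,
                                        children_per_family = list(dist = "zeta"),
                                        n_snps = 10L)),
               "distribution")
})

test_that("cohort size and age distribution match the configuration", {
  sizes <- ages <- numeric(10)
  for (s in 1:10) {
    ped <- sim_pedigrees(sim_config(n_families = 250L,
                                    children_per_family = list(dist = "poisson",
                                                               mean = 2),
                                    n_singletons = 500L, n_snps = 10L,
                                    seed = s))
    sizes[s] <- nrow(ped)
    ages[s] <- mean(ped$age)
  }
  expect_gt(mean(sizes), 1300)   # 250 * (2 parents + ~2 kids) + 500
  expect_lt(mean(sizes), 1700)
  expect_lt(abs(mean(ages) - 14.5), 0.3)
  expect_true(all(ages >= 8 & ages <= 21))
})

test_that("generators are bit-reproducible for a fixed seed", {
  cfg <- sim_config(n_families = 20L, n_singletons = 30L, n_snps = 200L,
                    seed = 42)
  expect_identical(sim_pedigrees(cfg), sim_pedigrees(cfg))
  ped <- sim_pedigrees(cfg)
  expect_identical(sim_genotypes(ped, cfg)$dosage, sim_genotypes(ped, cfg)$dosage)
  K <- kinship_from_pedigree(ped)
  expect_identical(sim_phenotype_gxage(K, ped$age, cfg),
                   sim_phenotype_gxage(K, ped$age, cfg))
})

test_that("gene-dropped genotypes are Mendelian-consistent and match the MAF", {
  cfg <- sim_config(n_families = 40L, n_singletons = 20L, n_snps = 600L,
                    maf_range = c(0.3, 0.3), ld_block_size = 5L,
                    ld_corr = 0.5, seed = 5)
  ped <- sim_pedigrees(cfg)
  G <- sim_genotypes(ped, cfg)
  # every trio: child dosage achievable from parents (a parent with dosage
  # 0 cannot transmit the alternate allele, etc.)
  fa <- match(ped$father, ped$id)
  mo <- match(ped$mother, ped$id)
  for (i in which(!is.na(fa))) {
    lo <- (G$dosage[fa[i], ] == 2) + (G$dosage[mo[i], ] == 2)
    hi <- 2 - ((G$dosage[fa[i], ] == 0) + (G$dosage[mo[i], ] == 0))
    expect_true(all(G$dosage[i, ] >= lo & G$dosage[i, ] <= hi))
  }
  # founders-only allele frequency near the configured MAF
  founders <- is.na(ped$father)
  expect_lt(abs(mean(G$dosage[founders, ]) / 2 - 0.3), 0.02)
})

test_that("full sibs realize relatedness near 0.5 under gene dropping", {
  cfg <- sim_config(n_families = 100L, children_per_family = 2L,
                    n_singletons = 0L, n_snps = 3000L, ld_corr = 0,
                    maf_range = c(0.1, 0.5), seed = 8)
  ped <- sim_pedigrees(cfg)
  G <- sim_genotypes(ped, cfg)
  K <- empirical_grm(G)
  kid_rows <- which(!is.na(ped$father))
  sib_idx <- cbind(kid_rows[seq(1, length(kid_rows), 2)],
                   kid_rows[seq(2, length(kid_rows), 2)])
  expect_lt(abs(mean(K$K[sib_idx]) - 0.5), 0.05)
})

test_that("age-structured phenotype draws follow the generating covariance", {
  # gamma = lambda = 0, K = I reduces to i.i.d. draws
  cfg <- sim_config(n_snps = 10L, seed = 2,
                    trait = list(sg2_0 = 0.5, se2_0 = 0.5, gamma_g = 0,
                                 gamma_e = 0, lambda = 0))
  n <- 4000
  y <- sim_phenotype_gxage(diag(n), runif(n, 8, 21), cfg)
  expect_lt(abs(var(y) - 1), 0.08)

  # sib pairs: phenotypic correlation = 0.5 * h2 = 0.25
  nf <- 2000
  K <- kronecker(diag(nf), matrix(c(1, .5, .5, 1), 2))
  y <- sim_phenotype_gxage(K, rep(12, 2 * nf), cfg)
  r <- cor(y[seq(1, 2 * nf, 2)], y[seq(2, 2 * nf, 2)])
  expect_lt(abs(r - 0.25), 0.05)
})

test_that("the cross-age genetic correlation decays at the configured rate", {
  # sib pairs with age gap 5 vs gap 0; gamma = 0 so variances are flat and
  # the sib covariance ratio is exp(-lambda * 5)
  lam <- 0.2
  cfg <- sim_config(n_snps = 10L, seed = 6,
                    trait = list(sg2_0 = 1, se2_0 = 0.25, gamma_g = 0,
                                 gamma_e = 0, lambda = lam, ref_age = 14))
  nf <- 5000
  K <- kronecker(diag(nf), matrix(c(1, .5, .5, 1), 2))
  ages_gap0 <- rep(c(12, 12), nf)
  ages_gap5 <- rep(c(10, 15), nf)
  y0 <- sim_phenotype_gxage(K, ages_gap0, cfg)
  y5 <- sim_phenotype_gxage(K, ages_gap5, cfg, seed = 7)
  odd <- seq(1, 2 * nf, 2); even <- odd + 1
  ratio <- cov(y5[odd], y5[even]) / cov(y0[odd], y0[even])
  expect_lt(abs(ratio - exp(-lam * 5)), 0.08)
})

test_that("the age-structured covariance is PSD across random configurations", {
  set.seed(30)
  for (rep in 1:5) {
    ped <- quad_cohort(8, 4, seed = rep)
    K <- kinship_from_pedigree(ped)
    Om <- devgen:::gxage_cov(K$K, ped$age, sg2_0 = runif(1, .1, 1),
                             se2_0 = runif(1, .1, 1),
                             gamma_g = runif(1, -.3, .3),
                             gamma_e = runif(1, -.3, .3),
                             lambda = runif(1, 0, .5), ref_age = 14)
    expect_gt(min(eigen(Om, symmetric = TRUE, only.values = TRUE)$values),
              -1e-8)
  }
})

test_that("bivariate trait draws realize the implied correlations", {
  n <- 2000
  yy <- sim_bivariate(diag(n), list(h2_1 = .5, h2_2 = .5, rho_g = 0,
                                    rho_e = 0), seed = 3)
  expect_lt(abs(cor(yy[, 1], yy[, 2])), 0.05)

  yy <- sim_bivariate(diag(n), list(h2_1 = 1, h2_2 = 1, rho_g = 1,
                                    rho_e = 0), seed = 3)
  expect_gt(cor(yy[, 1], yy[, 2]), 0.999)

  yy <- sim_bivariate(diag(n), list(h2_1 = .5, h2_2 = .5, rho_g = -0.4,
                                    rho_e = 0), seed = 4)
  expect_lt(abs(cor(yy[, 1], yy[, 2]) - (-0.2)), 0.05)

  expect_error(sim_bivariate(diag(4), list(h2_1 = .5, h2_2 = .5,
                                           rho_g = 1.2, rho_e = 0), seed = 1),
               "correlations")
})

test_that("item generation hits the calibrated endorsement targets", {
  dom <- rep(1:4, each = 6)
  # all loadings zero: threshold alone sets the rate
  L0 <- matrix(0, 24, 5)
  m0 <- bifactor_model(L0, tau = rep(qnorm(0.79), 24), pattern = dom,
                       converged = TRUE)
  eta <- matrix(rnorm(10000 * 5), ncol = 5)
  it <- sim_items(eta, m0, seed = 2)
  expect_lt(abs(mean(it$responses) - 0.21), 0.01)

  # eta = 0 and tau = 0: endorsement probability exactly one half
  mz <- bifactor_model(matrix(0.5, 4, 2), tau = rep(0, 4), pattern = rep(1, 4),
                       converged = TRUE)
  it <- sim_items(matrix(0, 20000, 2), mz, seed = 3)
  expect_lt(abs(mean(it$responses) - 0.5), 0.01)

  # higher general score raises every item's endorsement
  truth <- default_bifactor_truth(sim_config(n_snps = 10L)$items)
  hi <- matrix(0, 5000, 5); hi[, 5] <- 1.5
  lo <- matrix(0, 5000, 5); lo[, 5] <- -1.5
  it_hi <- sim_items(hi, truth, seed = 4)
  it_lo <- sim_items(lo, truth, seed = 4)
  expect_true(all(colMeans(it_hi$responses) > colMeans(it_lo$responses)))

  expect_error(sim_items(matrix(0, 5, 3), truth, seed = 1), "factors")
})

test_that("calibrated thresholds reproduce the per-domain endorsement rates", {
  cfg <- sim_config(n_snps = 10L)
  truth <- default_bifactor_truth(cfg$items)
  eta <- matrix(rnorm(20000 * 5), ncol = 5)
  it <- sim_items(eta, truth, seed = 5)
  rates <- tapply(colMeans(it$responses), truth$pattern, mean)
  targets <- cfg$items$endorsement
  expect_true(all(abs(rates - targets) < 0.01))
})

test_that("missingness injection is MCAR at the configured rate", {
  tab <- data.frame(id = sprintf("S%d", 1:1000), age = runif(1000, 8, 21),
                    sex = rep(1:2, 500))
  for (k in 1:15) tab[[paste0("t", k)]] <- rnorm(1000)
  expect_identical(inject_missingness(tab, 0, seed = 1), tab)

  out <- inject_missingness(tab, 0.1, seed = 1)
  expect_lt(abs(mean(is.na(out[, -(1:3)])) - 0.1), 0.01)

  # observed-mean preservation across seeds (value-independence)
  devs <- sapply(1:10, function(s) {
    o <- inject_missingness(tab, 0.2, seed = s)
    mean(o$t1, na.rm = TRUE) - mean(tab$t1)
  })
  expect_lt(max(abs(devs)), 3 * sd(tab$t1) / sqrt(800))
  expect_error(inject_missingness(tab, 1, seed = 1), "rate")
})
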