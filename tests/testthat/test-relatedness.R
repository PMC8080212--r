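test_that("pedigree kinship reproduces the textbook coefficients", {
  ped <- toy_pedigree_3gen()
  A <- kinship_from_pedigree(ped)$K
  expect_equal(unname(A["gf", "f1"]), 0.5)        # parent-offspring
  expect_equal(unname(A["c1", "c2"]), 0.5)        # full sibs
  expect_equal(unname(A["c1", "c3"]), 0.25)       # half sibs (shared mother)
  expect_equal(unname(A["gf", "gm"]), 0)          # unrelated founders
  expect_equal(unname(A["u1", "c1"]), 0)
  expect_equal(unname(A["gf", "c1"]), 0.25)       # grandparent
  expect_equal(unname(diag(A)), rep(1, 9))        # no inbreeding here

  bad <- ped; bad$father[1] <- "c1"; bad$mother[1] <- "m1"
  expect_error(kinship_from_pedigree(bad), "cycle")
})

test_that("pedigree kinship matches gene-drop realized relatedness", {
  ped <- toy_pedigree_3gen()
  A <- kinship_from_pedigree(ped)$K
  Kdrop <- gene_drop_relatedness(ped, n_loci = 10000, seed = 2)
  expect_lt(max(abs(A - Kdrop)), 0.05)
})

test_that("LD pruning drops duplicated and correlated SNPs", {
  set.seed(4)
  x <- rbinom(200, 2, 0.4)
  X <- cbind(s1 = x, s2 = x, s3 = rbinom(200, 2, 0.4))
  G <- genotype_matrix(X)
  out <- ld_prune(G, 0.1)
  expect_equal(attr(out, "kept"), c(1L, 3L))
})

test_that("pruning at threshold 0.1 retains independent SNPs", {
  set.seed(5)
  X <- matrix(rbinom(5000 * 60, 2, 0.3), 5000, 60)
  G <- genotype_matrix(X)
  out <- ld_prune(G, 0.1)
  expect_gte(ncol(out$dosage), 0.99 * 60)
})

test_that("greedy pruning matches the exhaustive pairwise-r2 oracle", {
  # deterministic 5-SNP toy: r2(1,2) ~ 0.5, r2(1,3) small
  set.seed(11)
  n <- 400
  z <- rbinom(n, 2, 0.5)
  toy <- cbind(a = z,
               b = ifelse(runif(n) < 0.7, z, rbinom(n, 2, 0.5)),
               c = rbinom(n, 2, 0.5),
               d = rbinom(n, 2, 0.4),
               e = rbinom(n, 2, 0.3))
  r2_ab <- cor(toy[, "a"], toy[, "b"])^2
  r2_ac <- cor(toy[, "a"], toy[, "c"])^2
  expect_gt(r2_ab, 0.3)
  expect_lt(r2_ac, 0.1)
  kept <- attr(ld_prune(genotype_matrix(toy), 0.1), "kept")
  expect_equal(kept, prune_oracle(toy, 0.1))
  expect_equal(kept, c(1L, 3L, 4L, 5L))

  # randomized instances with blocky LD, window covering everything
  for (s in 1:8) {
    cfg <- sim_config(n_families = 0L, n_singletons = 150L, n_snps = 40L,
                      ld_block_size = 8L, ld_corr = 0.6, seed = s)
    ped <- sim_pedigrees(cfg)
    G <- sim_genotypes(ped, cfg)
    expect_equal(attr(ld_prune(G, 0.1, window_snps = 50L), "kept"),
                 prune_oracle(G$dosage, 0.1))
  }
})

test_that("the standardized-dosage GRM matches hand evaluation", {
  # identical dosage rows give K_ij = K_ii
  X <- rbind(c(0, 1, 2, 1, 0, 2), c(0, 1, 2, 1, 0, 2), c(2, 1, 0, 1, 2, 0),
             c(1, 1, 1, 0, 2, 1))
  K <- empirical_grm(genotype_matrix(X))
  expect_equal(K$K[1, 2], K$K[1, 1], tolerance = 1e-12)

  # hand evaluation of the formula at p = 0.5: (2 - 1)(2 - 1)/0.5 = 2
  X2 <- cbind(s1 = c(2, 2, 0, 0), s2 = c(2, 2, 0, 0))
  K2 <- empirical_grm(genotype_matrix(X2))
  expect_equal(K2$K[1, 2], 2, tolerance = 1e-12)

  expect_error(empirical_grm(genotype_matrix(cbind(c(1, 1, 1), c(0, 0, 0)))),
               "usable")
})

test_that("GRM sampling noise for unrelated pairs scales as 1/sqrt(M)", {
  cfg <- sim_config(n_families = 0L, n_singletons = 120L, n_snps = 1500L,
                    ld_corr = 0, maf_range = c(0.1, 0.5), seed = 13)
  ped <- sim_pedigrees(cfg)
  K <- empirical_grm(sim_genotypes(ped, cfg))
  off <- K$K[upper.tri(K$K)]
  expect_lt(abs(mean(off)), 0.01)
  expect_lt(mean(abs(off)), 1.5 * 3 / sqrt(K$n_snps))
})

test_that("GRM validation flags the right properties", {
  ok <- validate_grm(relmat(diag(10)))
  expect_true(ok$ok)
  expect_equal(ok$trace_over_n, 1)

  M <- diag(10); M[1, 2] <- 0.01   # asymmetric
  bad <- validate_grm(relmat(M))
  expect_false(bad$pass[["symmetry"]])

  ped <- quad_cohort(1, 0, seed = 1)
  fam <- kinship_from_pedigree(ped)
  v <- validate_grm(fam)
  expect_gt(v$min_eigenvalue, 0)
  expect_true(v$ok)
})

test_that("GRM files round-trip losslessly in both dialects", {
  set.seed(9)
  B <- matrix(rnorm(25), 5)
  K <- relmat(crossprod(B) / 5 + diag(5) * 0.5,
              ids = sprintf("ind%02d", 1:5), n_snps = 100L)
  d <- withr::local_tempdir()

  write_grm(K, file.path(d, "k"), format = "gcta")
  K2 <- read_grm(file.path(d, "k"), format = "gcta")
  expect_lt(max(abs(K$K - K2$K)), 1e-12)
  expect_identical(K2$ids, K$ids)
  expect_equal(K2$n_snps, 100L)

  write_grm(K, file.path(d, "k.tsv"), format = "tsv")
  K3 <- read_grm(file.path(d, "k.tsv"), format = "tsv")
  expect_lt(max(abs(K$K - K3$K)), 1e-12)

  # 3x3 lower triangle reconstructs the full symmetric matrix
  writeLines(c("1\t1\t0\t1", "2\t1\t0\t0.3", "2\t2\t0\t1",
               "3\t1\t0\t0.1", "3\t2\t0\t0.2", "3\t3\t0\t1"),
             file.path(d, "t.grm"))
  writeLines(c("a\ta", "b\tb", "c\tc"), file.path(d, "t.grm.id"))
  Kt <- read_grm(file.path(d, "t"), format = "gcta")
  expect_equal(unname(Kt$K),
               matrix(c(1, .3, .1, .3, 1, .2, .1, .2, 1), 3), tolerance = 0)

  # id file shorter than the matrix dimension errors
  writeLines(c("a\ta", "b\tb"), file.path(d, "t.grm.id"))
  expect_error(read_grm(file.path(d, "t"), format = "gcta"), "id file")
})

test_that("dosage .raw files and .fam pedigrees round-trip", {
  cfg <- sim_config(n_families = 5L, n_singletons = 3L, n_snps = 30L, seed = 3)
  ped <- sim_pedigrees(cfg)
  G <- sim_genotypes(ped, cfg)
  d <- withr::local_tempdir()
  write_raw(G, file.path(d, "g.raw"), ped = ped)
  G2 <- read_raw(file.path(d, "g.raw"))
  expect_equal(unname(G2$dosage), unname(G$dosage))
  expect_identical(G2$ids, G$ids)

  write_fam(ped, file.path(d, "p.fam"))
  ped2 <- read_fam(file.path(d, "p.fam"))
  expect_equal(ped2$id, ped$id)
  expect_equal(ped2$father, ped$father)
  expect_equal(ped2$age, ped$age, tolerance = 1e-9)
})

test_that("thresholding a GRM restores family block structure", {
  ped <- quad_cohort(10, 20, seed = 2)
  K <- kinship_from_pedigree(ped)
  n <- nrow(ped)
  set.seed(3)
  noisy <- K$K + matrix(runif(n^2, -0.02, 0.02), n)
  noisy <- (noisy + t(noisy)) / 2; diag(noisy) <- 1
  Kt <- threshold_grm(relmat(noisy), 0.05)
  comps <- devgen:::matrix_components(Kt$K)
  expect_equal(max(lengths(comps)), 4L)
  expect_equal(diag(Kt$K), diag(noisy))
})
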