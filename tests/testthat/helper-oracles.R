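# Independent oracles used by the tests; none of them share code with the
# package's computational paths.

# Dense multivariate-normal log-density via solve(), no eigen/Cholesky
# factorization shared with the package internals.
dmvn_oracle <- function(y, mu, Omega) {
  r <- y - mu
  n <- length(y)
  ld <- as.numeric(determinant(Omega, logarithm = TRUE)$modulus)
  -0.5 * (n * log(2 * pi) + ld + drop(crossprod(r, solve(Omega, r))))
}

# Upper-orthant probability P(Z1 > h, Z2 > k; rho) by fixed-grid Simpson
# integration (the package uses adaptive quadrature via integrate()).
orthant_simpson <- function(h, k, rho, n = 4001, upper = 9) {
  s <- sqrt(1 - rho^2)
  x <- seq(h, upper, length.out = n)
  f <- dnorm(x) * pnorm((rho * x - k) / s)
  w <- c(1, rep(c(4, 2), length.out = n - 2), 1)
  sum(w * f) * (x[2] - x[1]) / 3
}

# Tetrachoric correlation by inverting the Simpson orthant oracle on a
# rho grid + uniroot, fully independent of the package's estimator.
tetrachoric_oracle <- function(n11, n10, n01, n00) {
  n <- n11 + n10 + n01 + n00
  h <- qnorm(1 - (n11 + n10) / n)
  k <- qnorm(1 - (n11 + n01) / n)
  uniroot(function(r) orthant_simpson(h, k, r) - n11 / n,
          c(-0.999, 0.999), tol = 1e-9)$root
}

# Exhaustive greedy LD pruning from the full pairwise r^2 matrix
# (quadratic algorithm; valid for small instances where the window spans
# everything).
prune_oracle <- function(X, r2_threshold) {
  R2 <- suppressWarnings(cor(X, use = "pairwise.complete.obs"))^2
  keep <- integer(0)
  for (j in seq_len(ncol(X))) {
    if (all(is.na(X[, j]))) next
    if (!length(keep) || all(R2[keep, j] <= r2_threshold, na.rm = TRUE))
      keep <- c(keep, j)
  }
  keep
}

# Gene-dropping oracle for realized relatedness: drops founder-allele
# labels down the pedigree at `n_loci` unlinked loci and counts
# identity-by-descent directly.
gene_drop_relatedness <- function(ped, n_loci, seed = 1) {
  set.seed(seed)
  n <- nrow(ped)
  fa <- match(ped$father, ped$id)
  mo <- match(ped$mother, ped$id)
  depth <- integer(n)
  repeat {
    new <- ifelse(is.na(fa), 0L, pmax(depth[fa], depth[mo]) + 1L)
    if (identical(new, depth)) break
    depth <- new
  }
  A1 <- matrix(0L, n, n_loci)
  A2 <- matrix(0L, n, n_loci)
  lab <- 0L
  for (i in order(depth)) {
    if (is.na(fa[i])) {
      A1[i, ] <- lab + seq_len(n_loci)
      A2[i, ] <- lab + n_loci + seq_len(n_loci)
      lab <- lab + 2L * n_loci
    } else {
      pick <- runif(n_loci) < 0.5
      A1[i, ] <- ifelse(pick, A1[fa[i], ], A2[fa[i], ])
      pick <- runif(n_loci) < 0.5
      A2[i, ] <- ifelse(pick, A1[mo[i], ], A2[mo[i], ])
    }
  }
  K <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) {
    for (j in i:n) {
      ibd <- (A1[i, ] == A1[j, ]) + (A1[i, ] == A2[j, ]) +
        (A2[i, ] == A1[j, ]) + (A2[i, ] == A2[j, ])
      K[i, j] <- K[j, i] <- mean(ibd) / 2
    }
  }
  K
}

# A printed three-generation pedigree used by several relatedness tests.
toy_pedigree_3gen <- function() {
  ped <- data.frame(
    id     = c("gf", "gm", "f1", "f2", "m1", "c1", "c2", "c3", "u1"),
    father = c(NA, NA, "gf", NA, NA, "f1", "f1", "f2", NA),
    mother = c(NA, NA, "gm", NA, NA, "m1", "m1", "m1", NA),
    sex    = c(1L, 2L, 1L, 1L, 2L, 1L, 2L, 1L, 1L),
    age    = c(20, 20, 15, 14, 16, 9, 10, 11, 12),
    fam    = "T1", stringsAsFactors = FALSE)
  class(ped) <- c("pedigree", "data.frame")
  ped
}

# Six-individual relatedness toy (one trio-ish family, one sib pair, one
# singleton) with hand-checkable block structure.
toy_K6 <- function() {
  K <- diag(6)
  K[1, 3] <- K[3, 1] <- 0.5; K[2, 3] <- K[3, 2] <- 0.5
  K[1, 2] <- K[2, 1] <- 0
  K[4, 5] <- K[5, 4] <- 0.5
  K
}

# Family cohort builders used by the recovery tests.
quad_cohort <- function(n_fam, n_sing, seed = 1) {
  sim_pedigrees(sim_config(n_families = n_fam, children_per_family = 2L,
                           n_singletons = n_sing, n_snps = 10L, seed = seed))
}

# Trait draw y = sqrt(sg2) * g + sqrt(se2) * e with g ~ N(0, K), blockwise.
draw_polygenic_trait <- function(K, sg2, se2, seed) {
  set.seed(seed)
  n <- nrow(K)
  comps <- devgen:::matrix_components(K)
  g <- numeric(n)
  for (idx in comps) {
    ee <- eigen(K[idx, idx, drop = FALSE], symmetric = TRUE)
    g[idx] <- ee$vectors %*% (sqrt(pmax(ee$values, 0)) * rnorm(length(idx)))
  }
  sqrt(sg2) * g + sqrt(se2) * rnorm(n)
}
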