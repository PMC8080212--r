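test_that("tetrachoric estimates match the latent bivariate-normal model", {
  set.seed(21)
  n <- 10000
  # latent rho = 0.5, both thresholds 0
  z1 <- rnorm(n); z2 <- 0.5 * z1 + sqrt(1 - 0.25) * rnorm(n)
  X <- cbind(a = as.integer(z1 > 0), b = as.integer(z2 > 0),
             c = as.integer(rnorm(n) > 0.8))
  R <- tetrachoric_matrix(item_matrix(X))
  expect_lt(abs(R["a", "b"] - 0.5), 0.03)
  expect_lt(abs(R["a", "c"]), 0.05)   # independent latents

  # an exact copy gives correlation one
  X2 <- cbind(X, d = X[, "a"])
  R2 <- tetrachoric_matrix(item_matrix(X2))
  expect_equal(R2["a", "d"], 1)
})

test_that("tetrachoric agrees with the Simpson orthant-probability oracle", {
  tables <- list(c(300, 200, 150, 350), c(50, 100, 80, 770),
                 c(120, 30, 40, 810), c(400, 100, 100, 400))
  for (tb in tables) {
    est <- devgen:::tetrachoric_from_table(tb[1], tb[2], tb[3], tb[4])
    orc <- tetrachoric_oracle(tb[1], tb[2], tb[3], tb[4])
    expect_lt(abs(est - orc), 1e-3)
  }
})

test_that("items with empty margins are flagged and excluded", {
  X <- cbind(a = c(1, 0, 1, 0, 1), b = rep(1, 5), c = c(0, 0, 1, 1, 0))
  it <- item_matrix(X)
  expect_false(it$usable[["b"]])
  expect_warning(R <- tetrachoric_matrix(it), "excluded")
  expect_equal(colnames(R), c("a", "c"))
})

test_that("bifactor fit reduces to a single factor when specifics are absent", {
  dom <- rep(1:4, each = 6)
  L <- matrix(0, 24, 5); L[, 5] <- 0.6
  tau <- -qnorm(0.2) * sqrt(1 + rowSums(L^2))
  truth <- bifactor_model(L, tau, dom, converged = TRUE)
  eta <- matrix(rnorm(4000 * 5), ncol = 5)
  it <- sim_items(eta, truth, seed = 31)
  fit <- fit_bifactor(tetrachoric_matrix(it), dom, it$endorsement, seed = 1)
  spec <- fit$L[cbind(1:24, dom)]
  expect_lt(max(abs(spec)), 0.08)
  expect_gt(min(fit$L[, 5]), 0.4)
})

test_that("bifactor recovery: loadings, implied matrix, and residuals", {
  cfg_items <- list(n_items = 24L,
                    domains = c(am = 6L, ext = 6L, fear = 6L, psy = 6L),
                    endorsement = c(am = .15, ext = .21, fear = .16, psy = .11),
                    general_loading = 0.6, specific_loading = 0.4)
  truth <- default_bifactor_truth(cfg_items)
  eta <- matrix(rnorm(4000 * 5), ncol = 5)
  it <- sim_items(eta, truth, seed = 32)
  R <- tetrachoric_matrix(it)
  fit <- fit_bifactor(R, truth$pattern, it$endorsement, seed = 2)
  expect_true(fit$converged)
  expect_lt(sqrt(mean((fit$L - truth$L)^2)), 0.08)

  # model-implied correlations reproduce the tetrachoric matrix
  imp <- tcrossprod(fit$L_std)
  diag(imp) <- 1
  resid <- (R - imp)[upper.tri(R)]
  expect_lt(sqrt(mean(resid^2)), 0.05)

  # the optimum is at least as good as the generating loadings
  Ls_truth <- truth$L / sqrt(1 + rowSums(truth$L^2))
  disc_truth <- sum(((R - tcrossprod(Ls_truth)) *
                       (1 - diag(24)))^2)
  expect_lte(fit$discrepancy, disc_truth + 1e-8)
})

test_that("hierarchical fit recovers second-order structure", {
  dom <- rep(1:4, each = 8)
  b_true <- c(0.7, 0.6, 0.5, 0.4)
  f_true <- rep(0.7, 32)
  Psi <- tcrossprod(b_true) + diag(1 - b_true^2)
  R_true <- tcrossprod(f_true) * Psi[dom, dom]
  diag(R_true) <- 1
  # implied inter-factor correlation is the outer product of second-order
  # loadings: domains 1,2 give 0.42
  expect_equal(Psi[1, 2], 0.42)

  # fit directly to the population matrix plus the sampling noise of
  # n = 4000 tetrachorics
  set.seed(33)
  ch <- chol(R_true)
  Z <- matrix(rnorm(4000 * 32), ncol = 32) %*% ch
  X <- (Z > qnorm(0.8)) * 1L
  it <- item_matrix(X)
  fit <- fit_hierarchical(tetrachoric_matrix(it), dom, it$endorsement,
                          seed = 3)
  expect_lt(max(abs(fit$second_order - b_true)), 0.1)
  expect_lt(max(abs(fit$L_std[cbind(1:32, dom)] - f_true)), 0.1)
})

test_that("degenerate hierarchical truth collapses to one factor", {
  b <- c(1, 1, 1, 1) - 1e-9
  Psi <- tcrossprod(b) + diag(1 - b^2)
  f <- rep(0.6, 12)
  dom <- rep(1:4, each = 3)
  R <- tcrossprod(f) * Psi[dom, dom]
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  expect_lt(ev[2] / ev[1], 1e-6)   # rank one off-structure
})

test_that("factor scores behave at the symmetric and extreme patterns", {
  dom <- rep(1, 8)
  L <- matrix(0.5, 8, 2)
  m <- bifactor_model(L, tau = rep(0, 8), pattern = dom, converged = TRUE)
  # endorse exactly half of equally loaded items at tau = 0
  X <- matrix(c(1, 1, 1, 1, 0, 0, 0, 0), 1)
  sc <- score_map(item_matrix(X), m)
  expect_lt(abs(sc$scores[1, "general"]), 0.05)

  # endorsing nothing pushes the general score strictly negative
  X0 <- matrix(0, 1, 8)
  sc0 <- score_map(item_matrix(X0), m)
  expect_lt(sc0$scores[1, "general"], -0.2)
  sc0m <- score_map(item_matrix(X0), m, method = "map")
  expect_lt(sc0m$scores[1, "general"], -0.2)

  # all-missing subject gets NA scores
  Xna <- matrix(NA_real_, 1, 8)
  scna <- score_map(item_matrix(rbind(X, Xna)), m)
  expect_true(all(is.na(scna$scores[2, ])))

  expect_error(score_map(item_matrix(matrix(0, 2, 5)), m), "match")
})

test_that("EAP and MAP agree with each other on well-identified subjects", {
  cfg_items <- list(n_items = 40L,
                    domains = c(a = 10L, b = 10L, c = 10L, d = 10L),
                    endorsement = c(a = .4, b = .4, c = .4, d = .4),
                    general_loading = 0.6, specific_loading = 0.7)
  truth <- default_bifactor_truth(cfg_items)
  eta <- matrix(rnorm(300 * 5), ncol = 5)
  it <- sim_items(eta, truth, seed = 35)
  eap <- score_map(it, truth, method = "eap")
  map <- score_map(it, truth, method = "map")
  expect_gt(cor(eap$scores[, 5], map$scores[, 5]), 0.98)
})

test_that("score columns are near-orthogonal when factor coupling is weak", {
  # Posterior scores decorrelate when the general-specific information
  # coupling is weak; here half of each domain's items mark the general
  # factor alone, the realistic pattern for a broad symptom bank.
  dom <- rep(1:4, each = 12)
  J <- 48
  L <- matrix(0, J, 5)
  L[, 5] <- 0.6
  spec_items <- as.vector(sapply(0:3, function(d) d * 12 + 1:6))
  L[cbind(spec_items, dom[spec_items])] <- 0.8
  tau <- -qnorm(0.35) * sqrt(1 + rowSums(L^2))
  truth <- bifactor_model(L, tau, dom, converged = TRUE)
  set.seed(36)
  eta <- matrix(rnorm(2000 * 5), ncol = 5)
  it <- sim_items(eta, truth, seed = 36)
  sc <- score_map(it, truth)
  cm <- cor(sc$scores)
  expect_lt(max(abs(cm[upper.tri(cm)])), 0.2)
  expect_gt(min(diag(cor(sc$scores, eta))), 0.6)
})
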