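# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's stream afterwards.  All generators and seeded
# fits funnel through this so a fixed (seed, config) pair is
# bit-reproducible regardless of surrounding RNG use.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single integer", call. = FALSE)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

# Derive a sub-seed for stage `k` of a seeded procedure; keeps every
# stream below 2^31 and distinct across stages.
sub_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + 7907 * k) %% 2147483629)
}

# Connected components of the off-diagonal nonzero pattern of a symmetric
# matrix (union-find).  Variance-component likelihoods factorize over these
# blocks, which keeps family cohorts cheap; a dense empirical GRM simply
# yields a single component.
matrix_components <- function(K, tol = 0) {
  n <- nrow(K)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  idx <- which(abs(K) > tol & row(K) < col(K), arr.ind = TRUE)
  if (nrow(idx)) {
    for (r in seq_len(nrow(idx))) {
      a <- find(idx[r, 1L]); b <- find(idx[r, 2L])
      if (a != b) parent[b] <- a
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  unname(split(seq_len(n), match(roots, unique(roots))))
}

# Central finite-difference Hessian of a scalar function; used for
# observed-information standard errors on the optimizer's transformed scale.
fd_hessian <- function(fn, par, eps = 1e-4) {
  p <- length(par)
  H <- matrix(NA_real_, p, p)
  h <- pmax(abs(par), 1) * eps
  f0 <- fn(par)
  for (i in seq_len(p)) {
    for (j in i:p) {
      if (i == j) {
        pp <- par; pp[i] <- par[i] + h[i]; fp <- fn(pp)
        pm <- par; pm[i] <- par[i] - h[i]; fm <- fn(pm)
        H[i, i] <- (fp - 2 * f0 + fm) / h[i]^2
      } else {
        ppp <- par; ppp[c(i, j)] <- par[c(i, j)] + h[c(i, j)]
        ppm <- par; ppm[i] <- par[i] + h[i]; ppm[j] <- par[j] - h[j]
        pmp <- par; pmp[i] <- par[i] - h[i]; pmp[j] <- par[j] + h[j]
        pmm <- par; pmm[c(i, j)] <- par[c(i, j)] - h[c(i, j)]
        H[i, j] <- H[j, i] <-
          (fn(ppp) - fn(ppm) - fn(pmp) + fn(pmm)) / (4 * h[i] * h[j])
      }
    }
  }
  H
}

# Standard errors from a (negative log-likelihood) Hessian; returns NA for
# directions where the information matrix is not positive definite.
se_from_hessian <- function(H) {
  se <- rep(NA_real_, nrow(H))
  ok <- tryCatch({
    V <- solve(H)
    d <- diag(V)
    se[d > 0] <- sqrt(d[d > 0])
    TRUE
  }, error = function(e) FALSE)
  if (!ok) warning("information matrix is singular; standard errors set to NA",
                   call. = FALSE)
  se
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
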