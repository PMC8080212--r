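#' Binary item-response container
#'
#' @param responses 0/1 matrix (subjects x items), `NA` allowed.
#' @param ids subject ids.
#' @return object of class `item_matrix` with per-item endorsement rates
#'   and a `usable` flag (items endorsed by nobody or everybody carry no
#'   pairwise information and are flagged).
#' @export
item_matrix <- function(responses, ids = rownames(responses)) {
  X <- as.matrix(responses)
  if (!all(X %in% c(0, 1) | is.na(X))) stopf("responses must be 0/1 or missing")
  if (is.null(ids)) ids <- sprintf("S%05d", seq_len(nrow(X)))
  if (is.null(colnames(X))) colnames(X) <- sprintf("item%03d", seq_len(ncol(X)))
  rownames(X) <- ids
  endorse <- colMeans(X, na.rm = TRUE)
  structure(list(responses = X, ids = as.character(ids),
                 endorsement = endorse,
                 usable = endorse > 0 & endorse < 1 & !is.na(endorse)),
            class = "item_matrix")
}

#' @export
print.item_matrix <- function(x, ...) {
  cat(sprintf("<item_matrix> %d subjects x %d items (%d usable), endorsement %.1f%%-%.1f%%\n",
              nrow(x$responses), ncol(x$responses), sum(x$usable),
              100 * min(x$endorsement), 100 * max(x$endorsement)))
  invisible(x)
}

# Upper-orthant probability P(Z1 > h, Z2 > k) for standard bivariate
# normals with correlation rho, by one-dimensional quadrature of
# phi(x) * Phi((rho x - k) / sqrt(1 - rho^2)) over x > h.
binorm_upper <- function(h, k, rho) {
  if (abs(rho) >= 1) {
    # degenerate: Z2 = sign(rho) Z1
    return(if (rho > 0) stats::pnorm(max(h, k), lower.tail = FALSE)
           else max(0, stats::pnorm(h, lower.tail = FALSE) -
                      stats::pnorm(-k)))
  }
  s <- sqrt(1 - rho^2)
  f <- function(x) stats::dnorm(x) * stats::pnorm((rho * x - k) / s)
  stats::integrate(f, h, Inf, rel.tol = 1e-10, abs.tol = 1e-12)$value
}

# ML tetrachoric correlation from a 2x2 table (n11, n10, n01, n00) with
# thresholds fixed at the margins; reduces to a monotone root-find of the
# implied cell probability.
tetrachoric_from_table <- function(n11, n10, n01, n00) {
  n <- n11 + n10 + n01 + n00
  cells <- c(n11, n10, n01, n00)
  if (n == 0 || sum(cells > 0) < 3) {
    if (n10 == 0 && n01 == 0 && n11 > 0 && n00 > 0) return(1)
    if (n11 == 0 && n00 == 0 && n10 > 0 && n01 > 0) return(-1)
    return(NA_real_)
  }
  p1 <- (n11 + n10) / n
  p2 <- (n11 + n01) / n
  if (p1 %in% c(0, 1) || p2 %in% c(0, 1)) return(NA_real_)
  h <- stats::qnorm(1 - p1)
  k <- stats::qnorm(1 - p2)
  target <- n11 / n
  f <- function(r) binorm_upper(h, k, r) - target
  lo <- -0.9999; hi <- 0.9999
  flo <- f(lo); fhi <- f(hi)
  if (flo >= 0) return(-1)
  if (fhi <= 0) return(1)
  stats::uniroot(f, c(lo, hi), f.lower = flo, f.upper = fhi,
                 tol = 1e-8)$root
}

#' Pairwise tetrachoric correlation matrix
#'
#' Estimates, for every pair of binary items, the correlation of the
#' latent bivariate-normal variables assumed to underlie them, with
#' probit thresholds fixed at the pairwise-complete margins.  Pairs whose
#' 2x2 table has fewer than three occupied cells get `NA` (except the
#' degenerate all-agree / all-disagree tables, which are +/-1); items
#' endorsed by nobody or everybody are excluded.
#'
#' @param items an [item_matrix] (or 0/1 matrix).
#' @return correlation matrix over usable items, unit diagonal, with the
#'   excluded item names in `attr(, "excluded")`.
#' @export
tetrachoric_matrix <- function(items) {
  if (!inherits(items, "item_matrix")) items <- item_matrix(items)
  X <- items$responses[, items$usable, drop = FALSE]
  excluded <- colnames(items$responses)[!items$usable]
  if (length(excluded))
    warning(sprintf("%d item(s) with empty margins excluded", length(excluded)),
            call. = FALSE)
  J <- ncol(X)
  O <- (!is.na(X)) * 1
  X0 <- X; X0[is.na(X0)] <- 0
  N11 <- crossprod(X0)
  N1o <- crossprod(X0, O)   # item i = 1, item j observed
  No1 <- crossprod(O, X0)
  Noo <- crossprod(O)
  R <- diag(1, J)
  dimnames(R) <- list(colnames(X), colnames(X))
  for (i in seq_len(J - 1L)) {
    for (j in (i + 1L):J) {
      n11 <- N11[i, j]
      n10 <- N1o[i, j] - n11
      n01 <- No1[i, j] - n11
      n00 <- Noo[i, j] - n11 - n10 - n01
      R[i, j] <- R[j, i] <- tetrachoric_from_table(n11, n10, n01, n00)
    }
  }
  attr(R, "excluded") <- excluded
  R
}

#' Bifactor / hierarchical factor model object
#'
#' @param L loading matrix, items x (specific factors + general), on the
#'   probit-regression metric (unit residual variance), the scale the
#'   item likelihood `Phi(L eta - tau)` uses; in the bifactor variant
#'   each item has its general loading and one specific loading; in the
#'   hierarchical variant the general column is zero and `second_order`
#'   holds the loadings of the specific factors on the second-order
#'   general factor.
#' @param tau per-item probit thresholds (same metric as `L`).
#' @param L_std loadings on the standardized latent scale (unit
#'   propensity variance), as estimated from the tetrachoric matrix.
#' @param pattern integer domain index per item.
#' @param variant `"bifactor"` or `"hierarchical"`.
#' @param second_order numeric vector (hierarchical only).
#' @param discrepancy achieved least-squares discrepancy.
#' @param converged logical.
#' @return object of class `bifactor_model`.
#' @export
bifactor_model <- function(L, tau, pattern, variant = c("bifactor", "hierarchical"),
                           second_order = NULL, discrepancy = NA_real_,
                           converged = NA, L_std = NULL) {
  variant <- match.arg(variant)
  if (is.null(colnames(L)))
    colnames(L) <- c(sprintf("specific%d", seq_len(ncol(L) - 1L)), "general")
  if (is.null(rownames(L)))
    rownames(L) <- sprintf("item%03d", seq_len(nrow(L)))
  if (is.null(L_std)) {
    h2 <- rowSums(L^2)
    L_std <- L / sqrt(1 + h2)
  }
  structure(list(L = L, tau = tau, pattern = pattern, variant = variant,
                 second_order = second_order, discrepancy = discrepancy,
                 converged = converged, L_std = L_std),
            class = "bifactor_model")
}

#' @export
print.bifactor_model <- function(x, ...) {
  S <- ncol(x$L) - 1L
  cat(sprintf("<bifactor_model> variant: %s, %d items, %d specific factors\n",
              x$variant, nrow(x$L), S))
  cat(sprintf("  discrepancy: %.5g, converged: %s\n", x$discrepancy,
              x$converged))
  if (!is.null(x$second_order))
    cat("  second-order loadings:",
        paste(sprintf("%.3f", x$second_order), collapse = ", "), "\n")
  invisible(x)
}

# Model-implied correlation matrix (off-diagonal part is what ULS fits).
implied_corr <- function(g, s, dom, b = NULL) {
  if (is.null(b)) {
    R <- tcrossprod(g) + tcrossprod(s) * outer(dom, dom, `==`)
  } else {
    Psi <- tcrossprod(b) + diag(1 - b^2)
    R <- tcrossprod(s) * Psi[dom, dom]
    R <- R + 0 * tcrossprod(g)
  }
  diag(R) <- 1
  R
}

uls_discrepancy <- function(R, Rimp, W) sum(W * (R - Rimp)^2)

#' Fit a confirmatory bifactor model to a tetrachoric matrix
#'
#' Free loadings (one general loading per item plus one loading on the
#' item's own specific factor, all factors orthogonal) minimize the
#' unweighted least-squares discrepancy between the observed and
#' model-implied correlation matrices; `NA` correlations get zero weight.
#' Thresholds are set from the endorsement rates,
#' `tau_j = qnorm(1 - endorsement_j)`.  Five seeded random starts guard
#' against local minima; factor signs are fixed by making each factor's
#' largest-magnitude loading positive.
#'
#' @param R tetrachoric (or other) correlation matrix, unit diagonal.
#' @param pattern integer/character domain assignment per item (>= 3
#'   items per specific factor required).
#' @param endorsement per-item endorsement rates in (0, 1).
#' @param n_starts number of random starts.
#' @param seed seed for the starts.
#' @return a [bifactor_model] with `variant = "bifactor"`.
#' @export
fit_bifactor <- function(R, pattern, endorsement, n_starts = 5L, seed = 1L) {
  prep <- check_fa_inputs(R, pattern)
  dom <- prep$dom; J <- prep$J; W <- prep$W; R0 <- prep$R0
  D <- outer(dom, dom, `==`)
  make_obj <- function(ridge, s_free) {
    list(
      obj = function(par) {
        g <- par[1:J]; s <- par[J + 1:J] * s_free
        E <- R0 - tcrossprod(g) - tcrossprod(s) * D
        sum(W * E^2) + commun_penalty(g, s) + ridge * sum(s^2)
      },
      grad = function(par) {
        g <- par[1:J]; s <- par[J + 1:J] * s_free
        E <- (R0 - tcrossprod(g) - tcrossprod(s) * D) * W
        cp <- commun_penalty_grad(g, s)
        c(-4 * E %*% g + cp$g,
          (-4 * (E * D) %*% s + cp$s + 2 * ridge * s) * s_free)
      })
  }
  # Stage 1: a ridge on the specific loadings resolves the flat direction
  # left by a lone within-domain specific (its pairwise products vanish
  # when the other specifics are near 0, so the off-diagonal objective
  # alone cannot pin it, and it otherwise soaks up sampling noise).
  st1 <- make_obj(ridge = 0.25, s_free = rep(1, J))
  best <- multistart_fa(st1$obj, st1$grad, 2L * J, n_starts, seed,
                        init = function(k)
                          c(stats::runif(J, 0.3, 0.6), stats::runif(J, 0.15, 0.4)))
  # Stage 2: refit without the ridge, pinning at zero the specifics the
  # shrinkage stage collapsed, so surviving loadings are unbiased.
  s_free <- as.numeric(abs(best$par[J + 1:J]) > 0.05)
  st2 <- make_obj(ridge = 0, s_free = s_free)
  ref <- stats::optim(best$par, st2$obj, gr = st2$grad, method = "BFGS",
                      control = list(maxit = 1000, reltol = 1e-12))
  ref$converged <- best$converged && ref$convergence == 0
  best <- ref
  g <- best$par[1:J]; s <- best$par[J + 1:J] * s_free
  # sign convention: dominant loading of each factor positive
  if (g[which.max(abs(g))] < 0) g <- -g
  for (d in unique(dom)) {
    sd_ <- s[dom == d]
    if (sd_[which.max(abs(sd_))] < 0) s[dom == d] <- -s[dom == d]
  }
  S <- max(dom)
  nm <- list(rownames(R0) %||% sprintf("item%03d", 1:J),
             c(prep$dom_names, "general"))
  Ls <- matrix(0, J, S + 1L, dimnames = nm)
  Ls[cbind(1:J, dom)] <- s
  Ls[, S + 1L] <- g
  # The tetrachoric/ULS solution lives on the standardized latent scale
  # (unit propensity variance).  Rescale to the probit-regression metric
  # (unit residual variance) used by the item likelihood, so loadings,
  # thresholds, and factor scores share one parameterization.
  h2s <- pmin(rowSums(Ls^2), 0.99)
  scl <- 1 / sqrt(1 - h2s)
  bifactor_model(L = Ls * scl, tau = stats::qnorm(1 - endorsement) * scl,
                 pattern = dom, variant = "bifactor",
                 discrepancy = best$value, converged = best$converged,
                 L_std = Ls)
}

#' Fit a hierarchical (second-order) factor model
#'
#' Each item loads only on its own specific factor; the specific factors
#' load on a single second-order general factor, so the implied
#' inter-factor correlation matrix is the outer product of the
#' second-order loadings (off the diagonal).  Estimation is unweighted
#' least squares on the tetrachoric matrix, as in [fit_bifactor()].
#'
#' @inheritParams fit_bifactor
#' @return a [bifactor_model] with `variant = "hierarchical"`; item
#'   loadings sit in the specific columns of `L` and `second_order` holds
#'   the factor-on-general loadings.
#' @export
fit_hierarchical <- function(R, pattern, endorsement, n_starts = 5L, seed = 1L) {
  prep <- check_fa_inputs(R, pattern)
  dom <- prep$dom; J <- prep$J; W <- prep$W; R0 <- prep$R0
  S <- max(dom)
  obj <- function(par) {
    f <- par[1:J]; b <- tanh(par[J + 1:S])
    Psi <- tcrossprod(b) + diag(1 - b^2)
    E <- R0 - tcrossprod(f) * Psi[dom, dom]
    sum(W * E^2) + commun_penalty(f, 0 * f)
  }
  best <- multistart_fa(obj, NULL, J + S, n_starts, seed,
                        init = function(k)
                          c(stats::runif(J, 0.5, 0.8), atanh(stats::runif(S, 0.3, 0.7))))
  f <- best$par[1:J]; b <- tanh(best$par[J + 1:S])
  # flipping a domain's loadings must flip its second-order loading too,
  # so the implied cross-domain correlations are unchanged
  for (d in unique(dom)) {
    fd <- f[dom == d]
    if (fd[which.max(abs(fd))] < 0) { f[dom == d] <- -fd; b[d] <- -b[d] }
  }
  if (b[which.max(abs(b))] < 0) b <- -b
  Ls <- matrix(0, J, S + 1L,
               dimnames = list(rownames(R0) %||% sprintf("item%03d", 1:J),
                               c(prep$dom_names, "general")))
  Ls[cbind(1:J, dom)] <- f
  h2s <- pmin(rowSums(Ls^2), 0.99)
  scl <- 1 / sqrt(1 - h2s)
  bifactor_model(L = Ls * scl, tau = stats::qnorm(1 - endorsement) * scl,
                 pattern = dom, variant = "hierarchical", second_order = b,
                 discrepancy = best$value, converged = best$converged,
                 L_std = Ls)
}

check_fa_inputs <- function(R, pattern) {
  R <- as.matrix(R)
  J <- nrow(R)
  if (J != ncol(R) || any(abs(diag(R) - 1) > 1e-8))
    stopf("R must be square with unit diagonal")
  if (max(abs(R - t(R)), na.rm = TRUE) > 1e-8) stopf("R must be symmetric")
  dom_f <- factor(pattern)
  if (length(dom_f) != J) stopf("pattern length must match R dimension")
  if (any(table(dom_f) < 3))
    stopf("each specific factor needs at least 3 items")
  W <- 1 - diag(1, J)
  W[is.na(R)] <- 0
  R0 <- R; R0[is.na(R0)] <- 0
  list(dom = as.integer(dom_f), dom_names = levels(dom_f), J = J, W = W,
       R0 = R0)
}

# soft barrier keeping per-item communality below 1
commun_penalty <- function(g, s) {
  h2 <- g^2 + s^2
  sum(pmax(h2 - 0.98, 0)^2) * 100
}
commun_penalty_grad <- function(g, s) {
  h2 <- g^2 + s^2
  w <- 400 * pmax(h2 - 0.98, 0)
  list(g = w * g, s = w * s)
}

multistart_fa <- function(obj, grad, npar, n_starts, seed, init) {
  fits <- with_seed(sub_seed(seed, 7L), {
    lapply(seq_len(n_starts), function(k) {
      st <- init(k)
      stats::optim(st, obj, gr = grad, method = "BFGS",
                   control = list(maxit = 1000, reltol = 1e-12))
    })
  })
  vals <- vapply(fits, `[[`, numeric(1), "value")
  best <- fits[[which.min(vals)]]
  best$converged <- best$convergence == 0
  if (!any(vapply(fits, function(f) f$convergence == 0, logical(1)))) {
    cond <- structure(class = c("fa_nonconvergence", "error", "condition"),
                      list(message = "factor model failed to converge; best incumbent attached",
                           call = NULL, incumbent = best))
    stop(cond)
  }
  best
}

#' Factor scores container
#'
#' @param scores numeric matrix, subjects x factors.
#' @param ids subject ids.
#' @return object of class `factor_scores` (also `data.frame`-coercible
#'   via `as.data.frame`).
#' @export
factor_scores <- function(scores, ids = rownames(scores)) {
  structure(list(scores = scores, ids = as.character(ids)),
            class = "factor_scores")
}

#' @export
print.factor_scores <- function(x, ...) {
  cat(sprintf("<factor_scores> %d subjects x %d factors\n", nrow(x$scores),
              ncol(x$scores)))
  print(utils::head(round(x$scores, 3)))
  invisible(x)
}

#' @export
as.data.frame.factor_scores <- function(x, ...) {
  data.frame(id = x$ids, x$scores, stringsAsFactors = FALSE,
             check.names = FALSE)
}

#' Factor scores for binary items
#'
#' Scores each subject under the probit item likelihood
#' `prod_j Phi(L_j eta - tau_j)^y (1 - Phi)^(1-y)` and the model's latent
#' prior: independent standard normals for the bifactor variant, the
#' implied correlated prior (`bb' + diag(1 - b^2)`) for the hierarchical
#' variant.  Two estimators are available.  `"eap"` (the default)
#' returns posterior means, computed exactly (to quadrature accuracy)
#' with the bifactor dimension-reduction identity -- conditional on the
#' general factor the specific factors are independent, so the
#' five-dimensional integral collapses into nested one-dimensional
#' quadratures.  Posterior means are the orthogonality-preserving
#' choice: over the population their covariance is the prior covariance
#' minus the mean posterior covariance, so scores on model-generated
#' data are close to uncorrelated, which is the point of the bifactor
#' decomposition.  `"map"` returns posterior modes via damped Newton to
#' gradient norm below 1e-6 (the log posterior is concave); modes are
#' pulled jointly negative for the many low-symptom subjects, which
#' induces spurious positive correlations between the general and
#' specific score columns.  Missing responses drop out of the
#' likelihood; a subject with no observed items gets `NA` scores.
#'
#' @param items an [item_matrix] (or 0/1 matrix).
#' @param model a converged [bifactor_model].
#' @param method `"eap"` (posterior mean) or `"map"` (posterior mode).
#' @param n_quad quadrature points per dimension for `"eap"`.
#' @return a [factor_scores] with one column per specific factor plus
#'   `general`.
#' @export
score_map <- function(items, model, method = c("eap", "map"), n_quad = 41L) {
  method <- match.arg(method)
  if (!inherits(items, "item_matrix")) items <- item_matrix(items)
  X <- items$responses
  if (ncol(X) != nrow(model$L))
    stopf("items and model dimensions do not match")
  if (method == "eap") return(eap_scores(items, model, n_quad))
  hier <- model$variant == "hierarchical"
  if (hier) {
    S <- ncol(model$L) - 1L
    Lw <- model$L[, seq_len(S), drop = FALSE]
    b <- model$second_order
    Psi <- tcrossprod(b) + diag(1 - b^2)
    Prec <- solve(Psi)
  } else {
    Lw <- model$L
    Prec <- diag(ncol(Lw))
  }
  out <- matrix(NA_real_, nrow(X), ncol(model$L),
                dimnames = list(rownames(X), colnames(model$L)))
  for (i in seq_len(nrow(X))) {
    obs <- which(!is.na(X[i, ]))
    if (!length(obs)) next
    eta <- map_newton(X[i, obs], Lw[obs, , drop = FALSE], model$tau[obs], Prec)
    if (hier) {
      gsc <- drop(crossprod(b, Prec %*% eta))
      out[i, ] <- c(eta, gsc)
    } else out[i, ] <- eta
  }
  factor_scores(out, ids = items$ids)
}

# Posterior-mean scores by nested one-dimensional quadrature.
# Conditional on the general factor g, the domains are independent:
# bifactor:      item j in domain s has propensity a_g g + a_s f - tau,
#                f ~ N(0, 1);
# hierarchical:  F_s = b_s g + sqrt(1 - b_s^2) u, u ~ N(0, 1), items load
#                only on F_s.
eap_scores <- function(items, model, n_quad = 41L) {
  X <- items$responses
  n <- nrow(X); J <- ncol(X)
  S <- ncol(model$L) - 1L
  hier <- model$variant == "hierarchical"
  grid <- seq(-6, 6, length.out = n_quad)
  lw <- stats::dnorm(grid, log = TRUE)
  Y0 <- X; Y0[is.na(Y0)] <- 0
  Obs <- (!is.na(X)) * 1

  # one domain at a time: build the n x (Q*Q) conditional log-likelihood
  # over (g, f/u) node pairs, then collapse over the domain node to get
  # the per-g marginal and the conditional posterior mean of the domain
  # latent given g
  gg <- rep(grid, times = n_quad)    # general node, varies fastest
  uu <- rep(grid, each = n_quad)     # domain-specific node
  margin_g <- matrix(0, n, n_quad)      # sum_s log p(y_s | g)
  cond_mean <- vector("list", S)        # E[latent_s | g, y], n x Q
  for (s in seq_len(S)) {
    js <- which(model$pattern == s)
    latent <- if (hier) {
      b <- model$second_order[s]
      b * gg + sqrt(1 - b^2) * uu
    } else uu
    z <- if (hier) outer(model$L[js, s], latent) - model$tau[js]
         else outer(model$L[js, S + 1L], gg) + outer(model$L[js, s], uu) -
           model$tau[js]
    lp1 <- stats::pnorm(z, log.p = TRUE)
    lp0 <- stats::pnorm(-z, log.p = TRUE)
    A <- Y0[, js, drop = FALSE] %*% lp1 +
      (Obs[, js, drop = FALSE] - Y0[, js, drop = FALSE]) %*% lp0
    num <- matrix(0, n, n_quad)
    den <- matrix(0, n, n_quad)
    Mx <- matrix(0, n, n_quad)
    for (q in seq_len(n_quad)) {
      cols <- (seq_len(n_quad) - 1L) * n_quad + q   # fixed g-node q
      Aq <- sweep(A[, cols, drop = FALSE], 2, lw, `+`)
      mx <- apply(Aq, 1, max)
      E <- exp(Aq - mx)
      den[, q] <- rowSums(E)
      num[, q] <- E %*% latent[cols]
      Mx[, q] <- mx
    }
    margin_g <- margin_g + Mx + log(den)
    cond_mean[[s]] <- num / den
  }

  post_g <- margin_g + matrix(lw, n, n_quad, byrow = TRUE)
  mg <- apply(post_g, 1, max)
  W <- exp(post_g - mg)
  W <- W / rowSums(W)
  scores <- matrix(NA_real_, n, S + 1L,
                   dimnames = list(rownames(X), colnames(model$L)))
  scores[, S + 1L] <- drop(W %*% grid)
  for (s in seq_len(S)) scores[, s] <- rowSums(W * cond_mean[[s]])
  none <- rowSums(Obs) == 0
  scores[none, ] <- NA_real_
  factor_scores(scores, ids = items$ids)
}

# Damped Newton ascent of the per-subject log posterior.
map_newton <- function(y, L, tau, Prec, tol = 1e-6, maxit = 100L) {
  p <- ncol(L)
  eta <- numeric(p)
  logpost <- function(eta) {
    z <- drop(L %*% eta) - tau
    sum(ifelse(y == 1, stats::pnorm(z, log.p = TRUE),
               stats::pnorm(-z, log.p = TRUE))) -
      0.5 * drop(crossprod(eta, Prec %*% eta))
  }
  lp <- logpost(eta)
  for (it in seq_len(maxit)) {
    z <- drop(L %*% eta) - tau
    # inverse Mills ratios, computed on the log scale for stability
    m1 <- exp(stats::dnorm(z, log = TRUE) - stats::pnorm(z, log.p = TRUE))
    m0 <- exp(stats::dnorm(z, log = TRUE) - stats::pnorm(-z, log.p = TRUE))
    w <- ifelse(y == 1, m1, -m0)
    curv <- ifelse(y == 1, m1 * (z + m1), m0 * (m0 - z))  # -d2/dz2, > 0
    gr <- drop(crossprod(L, w)) - drop(Prec %*% eta)
    if (max(abs(gr)) < tol) break
    H <- crossprod(L * sqrt(curv)) + Prec
    step <- solve(H, gr)
    alpha <- 1
    repeat {
      cand <- eta + alpha * step
      lpc <- logpost(cand)
      if (lpc >= lp - 1e-12 || alpha < 1e-4) break
      alpha <- alpha / 2
    }
    eta <- eta + alpha * step
    lp <- logpost(eta)
  }
  eta
}
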