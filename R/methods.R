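# print / summary / coef / logLik / plot methods for the fitted models.

#' @export
print.polygenic_fit <- function(x, ...) {
  cat("Univariate polygenic model (ML)\n")
  cat(sprintf("  N = %d, logLik = %.3f\n", x$n, x$loglik))
  cat(sprintf("  h2   = %.3f%s\n", x$h2,
              if (!is.na(x$se["h2"])) sprintf(" (SE %.3f)", x$se["h2"]) else ""))
  cat(sprintf("  sg2  = %.4f, se2 = %.4f, sp2 = %.4f\n", x$sg2, x$se2, x$sp2))
  if (!is.null(x$lrt))
    cat(sprintf("  h2 > 0 LRT: statistic %.3f, p = %.4g (boundary mixture)\n",
                x$lrt$statistic, x$lrt$p))
  invisible(x)
}

#' @export
summary.polygenic_fit <- function(object, ...) {
  out <- list(fit = object,
              coef_table = data.frame(
                estimate = c(object$sg2, object$se2, object$h2),
                se = unname(object$se),
                row.names = c("sg2", "se2", "h2")),
              beta_table = data.frame(estimate = object$beta,
                                      se = object$beta_se))
  class(out) <- "summary.polygenic_fit"
  out
}

#' @export
print.summary.polygenic_fit <- function(x, ...) {
  print(x$fit)
  cat("\nVariance components:\n")
  print(round(x$coef_table, 4))
  cat("\nFixed effects:\n")
  print(round(x$beta_table, 4))
  invisible(x)
}

#' @export
coef.polygenic_fit <- function(object, ...)
  c(sg2 = object$sg2, se2 = object$se2, h2 = object$h2, object$beta)

#' @export
logLik.polygenic_fit <- function(object, ...)
  structure(object$loglik, df = object$df, nobs = object$n, class = "logLik")

#' Draw new phenotypes from a fitted polygenic model
#'
#' @param object a `polygenic_fit`.
#' @param nsim number of replicate vectors.
#' @param seed integer seed.
#' @param K,X the relatedness matrix and design to simulate under (the
#'   fit does not retain them).
#' @param ... unused.
#' @return matrix with `nsim` columns.
#' @export
simulate.polygenic_fit <- function(object, nsim = 1, seed = 1L, K, X = NULL,
                                   ...) {
  R <- as_relmat(K)
  n <- nrow(R$K)
  if (is.null(X)) X <- matrix(1, n, 1)
  mu <- drop(X %*% object$beta)
  with_seed(sub_seed(seed, 11L), {
    out <- replicate(nsim, mu + rmvn_blocked(R$K, function(idx) {
      Om <- object$sg2 * R$K[idx, idx, drop = FALSE]
      diag(Om) <- diag(Om) + object$se2
      Om
    }))
    matrix(out, ncol = nsim)
  })
}

#' @export
print.bivariate_fit <- function(x, ...) {
  cat("Bivariate polygenic model (ML)\n")
  cat(sprintf("  logLik = %.3f\n", x$loglik))
  print(transform(x$traits, sg2 = round(sg2, 4), se2 = round(se2, 4),
                  h2 = round(h2, 3)))
  cat(sprintf("  rho_g = %.3f%s, rho_e = %.3f%s, rho_p = %.3f\n",
              x$rho_g,
              if (!is.na(x$se["rho_g"])) sprintf(" (SE %.3f)", x$se["rho_g"]) else "",
              x$rho_e,
              if (!is.na(x$se["rho_e"])) sprintf(" (SE %.3f)", x$se["rho_e"]) else "",
              x$rho_p))
  if (!is.null(x$lrt_rho_g))
    cat(sprintf("  rho_g = 0 LRT: %.3f, p = %.4g\n", x$lrt_rho_g$statistic,
                x$lrt_rho_g$p))
  if (!is.null(x$lrt_rho_e))
    cat(sprintf("  rho_e = 0 LRT: %.3f, p = %.4g\n", x$lrt_rho_e$statistic,
                x$lrt_rho_e$p))
  invisible(x)
}

#' @export
coef.bivariate_fit <- function(object, ...)
  c(sg2_1 = object$traits$sg2[1], se2_1 = object$traits$se2[1],
    sg2_2 = object$traits$sg2[2], se2_2 = object$traits$se2[2],
    h2_1 = object$traits$h2[1], h2_2 = object$traits$h2[2],
    rho_g = object$rho_g, rho_e = object$rho_e, rho_p = object$rho_p)

#' @export
logLik.bivariate_fit <- function(object, ...)
  structure(object$loglik, class = "logLik")

#' @export
print.gxage_fit <- function(x, ...) {
  cat("Gene x Age variance-component model (ML)\n")
  cat(sprintf("  N = %d, logLik = %.3f, reference age = %.2f\n", x$n,
              x$loglik, x$ref_age))
  tab <- data.frame(estimate = x$par, se = x$se)
  print(round(tab, 4))
  if (!is.null(x$lrt_gamma_g))
    cat(sprintf("  gamma_g = 0 LRT: %.3f, p = %.4g\n",
                x$lrt_gamma_g$statistic, x$lrt_gamma_g$p))
  if (!is.null(x$lrt_gamma_e))
    cat(sprintf("  gamma_e = 0 LRT: %.3f, p = %.4g\n",
                x$lrt_gamma_e$statistic, x$lrt_gamma_e$p))
  if (!is.null(x$lrt_lambda))
    cat(sprintf("  lambda = 0 LRT: %.3f, p = %.4g (boundary mixture)\n",
                x$lrt_lambda$statistic, x$lrt_lambda$p))
  invisible(x)
}

#' @export
coef.gxage_fit <- function(object, ...) object$par

#' @export
logLik.gxage_fit <- function(object, ...)
  structure(object$loglik, class = "logLik")

#' Plot age-varying variance components
#'
#' Draws the fitted genetic variance, environmental variance, and
#' heritability curves over the age range.
#'
#' @param x a `gxage_fit`.
#' @param ages age grid.
#' @param ... passed to [graphics::matplot()].
#' @return the curve table, invisibly.
#' @export
plot.gxage_fit <- function(x, ages = seq(8, 21, by = 0.25), ...) {
  cv <- variance_by_age(x, ages)
  graphics::matplot(cv$age, cbind(cv$sg2, cv$se2, cv$h2), type = "l",
                    lty = 1, lwd = 2, col = c("#1b9e77", "#d95f02", "#7570b3"),
                    xlab = "Age (years)", ylab = "Variance / proportion", ...)
  graphics::legend("topright",
                   legend = c("genetic variance", "environmental variance",
                              "heritability"),
                   col = c("#1b9e77", "#d95f02", "#7570b3"), lty = 1, lwd = 2,
                   bty = "n")
  invisible(cv)
}
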