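#' Synthetic-cohort configuration
#'
#' Bundles every knob of the generators with defaults chosen to emulate a
#' developmental cohort aged 8-21: nuclear families plus unrelated
#' singletons, a common-SNP panel with blockwise LD, a psychopathology
#' item bank with four symptom domains whose endorsement rates match the
#' reported domain averages (externalizing 21%, anxious-misery 15%, fear
#' 16%, psychosis-spectrum 11%), and a trait whose genetic variance
#' declines log-linearly with age (`gamma_g = -0.146` per year) while
#' environmental variance grows (`gamma_e = 0.059`), with a small
#' cross-age genetic-correlation decay (`lambda = 0.027`).
#'
#' @param n_families number of nuclear families.
#' @param children_per_family either an integer (fixed family size) or a
#'   list such as `list(dist = "poisson", mean = 2)` (truncated so every
#'   family has at least one child).
#' @param n_singletons number of unrelated individuals.
#' @param age_range cross-sectional age interval in years.
#' @param n_snps number of SNPs to gene-drop.
#' @param maf_range interval in (0, 0.5] for block minor-allele
#'   frequencies.
#' @param ld_block_size SNPs per LD block.
#' @param ld_corr within-block allele-copying probability in [0, 1);
#'   adjacent-SNP dosage correlation equals this value.
#' @param trait list: `sg2_0`, `se2_0` (variances at the reference age),
#'   `gamma_g`, `gamma_e` (per-year log-linear variance trends), `lambda`
#'   (per-year genetic-correlation decay, >= 0), `ref_age` (`NULL` =
#'   sample mean age).
#' @param items list: `n_items`, `domains` (named item counts),
#'   `endorsement` (named target rates in (0,1)), `general_loading`,
#'   `specific_loading`.
#' @param missing_rate MCAR rate for cognitive entries in [0, 1).
#' @param seed integer master seed; every generator derives its own
#'   sub-stream from it.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_families = 300L,
                       children_per_family = 2L,
                       n_singletons = 800L,
                       age_range = c(8, 21),
                       n_snps = 50000L,
                       maf_range = c(0.05, 0.5),
                       ld_block_size = 10L,
                       ld_corr = 0.7,
                       trait = list(),
                       items = list(),
                       missing_rate = 0.1,
                       seed = 1L) {
  trait_def <- list(sg2_0 = 0.46, se2_0 = 0.54, gamma_g = -0.146,
                    gamma_e = 0.059, lambda = 0.027, ref_age = NULL)
  trait <- utils::modifyList(trait_def, trait, keep.null = TRUE)
  items_def <- list(
    n_items = 112L,
    domains = c(anxious_misery = 34L, externalizing = 30L, fear = 26L,
                psychosis = 22L),
    endorsement = c(anxious_misery = 0.15, externalizing = 0.21,
                    fear = 0.16, psychosis = 0.11),
    general_loading = 0.6, specific_loading = 0.4)
  items <- utils::modifyList(items_def, items)
  cfg <- list(n_families = as.integer(n_families),
              children_per_family = children_per_family,
              n_singletons = as.integer(n_singletons),
              age_range = as.numeric(age_range),
              n_snps = as.integer(n_snps),
              maf_range = as.numeric(maf_range),
              ld_block_size = as.integer(ld_block_size),
              ld_corr = ld_corr,
              trait = trait, items = items,
              missing_rate = missing_rate,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (maf_range[1] <= 0 || maf_range[2] > 0.5 || maf_range[1] > maf_range[2])
      stopf("maf_range must lie in (0, 0.5]")
    if (trait$sg2_0 < 0 || trait$se2_0 < 0) stopf("variances must be >= 0")
    if (trait$lambda < 0) stopf("lambda must be >= 0")
    if (missing_rate < 0 || missing_rate >= 1)
      stopf("missing_rate must be in [0, 1)")
    if (any(items$endorsement <= 0) || any(items$endorsement >= 1))
      stopf("endorsement targets must be in (0, 1)")
    if (sum(items$domains) != items$n_items)
      stopf("domain item counts must sum to n_items")
  })
  invisible(cfg)
}

#' Write / read a generator configuration as YAML
#'
#' @param config a [sim_config()].
#' @param path file path.
#' @return `write_sim_config` returns `path` invisibly; `read_sim_config`
#'   a `sim_config`.
#' @export
write_sim_config <- function(config, path) {
  raw <- unclass(config)
  # named atomic vectors must become YAML maps, not bare sequences
  raw$items$domains <- as.list(raw$items$domains)
  raw$items$endorsement <- as.list(raw$items$endorsement)
  yaml::write_yaml(raw, path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$items$domains <- unlist(raw$items$domains)
  raw$items$endorsement <- unlist(raw$items$endorsement)
  do.call(sim_config, raw[setdiff(names(raw), character(0))])
}

#' Default bifactor truth implied by an item configuration
#'
#' Builds the generating loading matrix (one general factor plus one
#' specific factor per domain), the domain pattern, and probit thresholds
#' calibrated so each item's *marginal* endorsement probability hits its
#' domain target: with standard-normal orthogonal factors the latent item
#' propensity has variance `1 + ||L_j||^2`, so
#' `tau_j = -qnorm(target) * sqrt(1 + ||L_j||^2)`.
#'
#' @param items the `items` block of a [sim_config()].
#' @return a [bifactor_model] usable as simulation truth.
#' @export
default_bifactor_truth <- function(items) {
  domains <- items$domains
  dom_id <- rep(seq_along(domains), domains)
  J <- length(dom_id)
  S <- length(domains)
  L <- matrix(0, J, S + 1L,
              dimnames = list(sprintf("item%03d", seq_len(J)),
                              c(names(domains), "general")))
  L[, S + 1L] <- items$general_loading
  L[cbind(seq_len(J), dom_id)] <- items$specific_loading
  target <- items$endorsement[dom_id]
  tau <- -stats::qnorm(target) * sqrt(1 + rowSums(L^2))
  bifactor_model(L = L, tau = tau, pattern = dom_id, variant = "bifactor",
                 converged = TRUE, discrepancy = 0)
}
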