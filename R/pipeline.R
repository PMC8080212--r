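#' End-to-end pipeline configuration
#'
#' @param sim a [sim_config()]; the default is a desk-scale cohort (150
#'   two-child families plus 300 singletons, 4,000 SNPs) so a full run
#'   completes in minutes on one CPU.
#' @param cognitive list describing the synthetic cognitive battery:
#'   `n_accuracy` / `n_speed` test counts, `loading` of each test on its
#'   latent composite, `h2_ability` / `h2_speed` latent heritabilities,
#'   and `rho_g`, the genetic correlation between the externalizing
#'   factor and latent cognitive ability.
#' @param factor_h2 named heritabilities for the non-externalizing
#'   psychopathology factors (externalizing follows `sim$trait`).
#' @param q FDR level for the heritability screen and downstream
#'   families.
#' @param grm_cutoff off-diagonal threshold applied to the empirical GRM
#'   before model fitting (see [threshold_grm()]).
#' @param out_dir output directory for stage artifacts.
#' @param seed master seed.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(n_families = 150L,
                                             n_singletons = 300L,
                                             n_snps = 4000L),
                            cognitive = list(),
                            factor_h2 = c(anxious_misery = 0.09, fear = 0.04,
                                          psychosis = 0.0, general = 0.21),
                            q = 0.05,
                            grm_cutoff = 0.125,
                            out_dir = tempfile("devgen_run_"),
                            seed = 7L) {
  cog_def <- list(n_accuracy = 8L, n_speed = 4L, loading = 0.6,
                  h2_ability = 0.5, h2_speed = 0.3, rho_g = -0.4)
  cognitive <- utils::modifyList(cog_def, cognitive)
  if (q <= 0 || q >= 1) stopf("q must be in (0, 1)")
  structure(list(sim = sim, cognitive = cognitive, factor_h2 = factor_h2,
                 q = q, grm_cutoff = grm_cutoff, out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

# Correlated latent draws for the pipeline cohort.  The externalizing
# factor carries the full age trend in genetic variance; latent cognitive
# ability shares a fraction rho_g of its genetic factor with
# externalizing, so the generating genetic correlation is exact.
draw_cohort_latents <- function(Kped, ages, cfg) {
  tr <- cfg$sim$trait
  cg <- cfg$cognitive
  abar <- tr$ref_age %||% mean(ages)
  n <- length(ages)
  with_seed(sub_seed(cfg$seed, 20L), {
    K <- Kped$K
    u_ext <- rmvn_blocked(K, function(i) K[i, i, drop = FALSE])
    u_ind <- rmvn_blocked(K, function(i) K[i, i, drop = FALSE])
    sg <- sqrt(tr$sg2_0 * exp(tr$gamma_g * (ages - abar)))
    se <- sqrt(tr$se2_0 * exp(tr$gamma_e * (ages - abar)))
    ext <- sg * u_ext + se * stats::rnorm(n)
    g_cog <- cg$rho_g * u_ext + sqrt(1 - cg$rho_g^2) * u_ind
    ability <- sqrt(cg$h2_ability) * g_cog +
      sqrt(1 - cg$h2_ability) * stats::rnorm(n)
    u_spd <- rmvn_blocked(K, function(i) K[i, i, drop = FALSE])
    speed <- sqrt(cg$h2_speed) * u_spd + sqrt(1 - cg$h2_speed) * stats::rnorm(n)
    others <- vapply(names(cfg$factor_h2), function(f) {
      h2 <- cfg$factor_h2[[f]]
      uf <- rmvn_blocked(K, function(i) K[i, i, drop = FALSE])
      sqrt(h2) * uf + sqrt(1 - h2) * stats::rnorm(n)
    }, numeric(n))
    eta <- cbind(anxious_misery = others[, "anxious_misery"],
                 externalizing = scale(ext)[, 1],
                 fear = others[, "fear"],
                 psychosis = others[, "psychosis"],
                 general = others[, "general"])
    rownames(eta) <- Kped$ids
    list(eta = eta, ability = ability, speed = speed)
  })
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Executes, in order: cohort simulation (pedigree, gene-dropped
#' genotypes, latent factors, items, cognitive battery), psychometrics
#' (tetrachoric matrix, bifactor fit, MAP factor scores), phenotype prep
#' (eligibility filter, chained imputation, PCA composites g and gs,
#' inverse-normal transforms, covariates), relatedness (LD pruning,
#' empirical GRM, validation, thresholding), the FDR-screened
#' heritability stage, bivariate genetic correlations between screened
#' psychopathology factors and screened cognitive composites, Gene x Age
#' fits for screened psychopathology factors, and report tables.  All
#' artifacts are written under `config$out_dir` together with a manifest
#' of content hashes; a rerun with the same config is byte-identical.
#'
#' @param config a [pipeline_config()].
#' @return a `run_report`: stage counts, the fitted tables
#'   (`h2_table`, `rhog_table`, `gxage_table`, `curve_table`), the GRM
#'   validation report, and the manifest.
#' @export
run_pipeline <- function(config) {
  cfg <- config
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_msg <- function(...) message(sprintf(...))
  counts <- list()

  # --- simulate ----------------------------------------------------------
  ped <- sim_pedigrees(cfg$sim)
  counts$cohort <- nrow(ped)
  G <- sim_genotypes(ped, cfg$sim)
  Kped <- kinship_from_pedigree(ped)
  lat <- draw_cohort_latents(Kped, ped$age, cfg)
  truth <- default_bifactor_truth(cfg$sim$items)
  items <- sim_items(lat$eta, truth, seed = sub_seed(cfg$seed, 21L))
  cg <- cfg$cognitive
  battery <- with_seed(sub_seed(cfg$seed, 22L), {
    acc <- sapply(seq_len(cg$n_accuracy), function(t)
      cg$loading * lat$ability +
        sqrt(1 - cg$loading^2) * stats::rnorm(counts$cohort))
    spd <- sapply(seq_len(cg$n_speed), function(t)
      cg$loading * lat$speed +
        sqrt(1 - cg$loading^2) * stats::rnorm(counts$cohort))
    colnames(acc) <- sprintf("acc_%02d", seq_len(cg$n_accuracy))
    colnames(spd) <- sprintf("rt_%02d", seq_len(cg$n_speed))
    cbind(acc, spd)
  })
  traits <- data.frame(id = ped$id, age = ped$age, sex = ped$sex, battery,
                       stringsAsFactors = FALSE)
  traits <- inject_missingness(traits, cfg$sim$missing_rate,
                               seed = sub_seed(cfg$seed, 23L))
  write_fam(ped, file.path(cfg$out_dir, "cohort.fam"))
  write_raw(G, file.path(cfg$out_dir, "genotypes.raw"), ped = ped)
  write_tsv(as.data.frame(items$responses, check.names = FALSE) |>
              (\(d) cbind(id = ped$id, d))(),
            file.path(cfg$out_dir, "items.tsv"))
  write_tsv(traits, file.path(cfg$out_dir, "traits_raw.tsv"))
  log_msg("simulate: %d individuals, %d SNPs, %d items", counts$cohort,
          cfg$sim$n_snps, ncol(items$responses))

  # --- psychometrics -----------------------------------------------------
  R <- tetrachoric_matrix(items)
  pattern <- names(cfg$sim$items$domains)[
    truth$pattern[match(rownames(R), rownames(truth$L))]]
  endorse <- items$endorsement[items$usable]
  model <- fit_bifactor(R, pattern, endorse, seed = sub_seed(cfg$seed, 24L))
  scr <- score_map(item_matrix(items$responses[, items$usable, drop = FALSE]),
                   model)
  counts$items_usable <- sum(items$usable)
  write_tsv(as.data.frame(scr), file.path(cfg$out_dir, "factor_scores.tsv"))

  # --- phenotype prep ----------------------------------------------------
  elig <- eligibility_filter(traits)
  counts$prep_removed <- attr(elig, "filter_log")$n_removed
  imp <- chained_impute(elig, seed = sub_seed(cfg$seed, 25L))
  acc_cols <- grep("^acc_", names(imp), value = TRUE)
  rt_cols <- grep("^rt_", names(imp), value = TRUE)
  gcomp <- pca_composite(imp, acc_cols)
  gscomp <- pca_composite(imp, rt_cols)
  analysis <- data.frame(id = imp$id, age = imp$age, sex = imp$sex,
                         g = as.numeric(gcomp), gs = as.numeric(gscomp),
                         stringsAsFactors = FALSE)
  sidx <- match(analysis$id, scr$ids)
  analysis <- cbind(analysis,
                    as.data.frame(scr$scores[sidx, , drop = FALSE]))
  counts$analysis_n <- nrow(analysis)
  write_tsv(analysis, file.path(cfg$out_dir, "traits_prepared.tsv"))

  # --- relatedness -------------------------------------------------------
  Gp <- ld_prune(G, r2_threshold = 0.1)
  counts$snps_pruned <- ncol(Gp$dosage)
  Kemp <- empirical_grm(Gp)
  grm_report <- validate_grm(Kemp)
  Kfit <- threshold_grm(Kemp, cfg$grm_cutoff)
  write_grm(Kemp, file.path(cfg$out_dir, "cohort"), format = "gcta")
  log_msg("grm: %d SNPs retained, validation %s", counts$snps_pruned,
          ifelse(grm_report$ok, "pass", "FAIL"))

  # --- variance components -----------------------------------------------
  ids <- analysis$id
  ki <- match(ids, Kfit$ids)
  Ka <- relmat(Kfit$K[ki, ki], ids = ids, provenance = "empirical",
               n_snps = Kfit$n_snps)
  X <- build_covariates(analysis$age, analysis$sex)
  trait_names <- c("anxious_misery", "externalizing", "fear", "psychosis",
                   "general", "g", "gs")
  ytab <- lapply(trait_names, function(tn) inverse_normal(analysis[[tn]]))
  names(ytab) <- trait_names

  h2_fits <- lapply(ytab, function(yy) fit_polygenic(yy, Ka, X))
  h2_table <- data.frame(
    trait = trait_names,
    h2 = vapply(h2_fits, `[[`, numeric(1), "h2"),
    se = vapply(h2_fits, function(f) unname(f$se["h2"]), numeric(1)),
    p = vapply(h2_fits, function(f) f$lrt$p, numeric(1)),
    row.names = NULL)
  fdr <- bh_fdr(h2_table$p, cfg$q)
  h2_table$p_adjusted <- fdr$p_adjusted
  h2_table$fdr_pass <- fdr$reject
  passing <- h2_table$trait[h2_table$fdr_pass]
  log_msg("h2 screen: %d/%d traits pass FDR at q = %.2f", length(passing),
          length(trait_names), cfg$q)

  psych_pass <- intersect(c("anxious_misery", "externalizing", "fear",
                            "psychosis", "general"), passing)
  cog_pass <- intersect(c("g", "gs"), passing)
  pairs <- expand.grid(factor = psych_pass, cognitive = cog_pass,
                       stringsAsFactors = FALSE)
  rhog_rows <- lapply(seq_len(nrow(pairs)), function(r) {
    bf <- fit_bivariate(ytab[[pairs$factor[r]]], ytab[[pairs$cognitive[r]]],
                        Ka, X, seed = sub_seed(cfg$seed, 26L + r))
    data.frame(trait1 = pairs$factor[r], trait2 = pairs$cognitive[r],
               rho_g = bf$rho_g, rho_e = bf$rho_e, rho_p = bf$rho_p,
               p_rho_g = bf$lrt_rho_g$p, p_rho_e = bf$lrt_rho_e$p)
  })
  gxage_rows <- lapply(psych_pass, function(tn) {
    gf <- fit_gxage(ytab[[tn]], Ka, analysis$age, X,
                    seed = sub_seed(cfg$seed, 40L))
    list(row = data.frame(trait = tn,
                          gamma_g = gf$par[["gamma_g"]],
                          gamma_e = gf$par[["gamma_e"]],
                          lambda = gf$par[["lambda"]],
                          p_gamma_g = gf$lrt_gamma_g$p,
                          p_gamma_e = gf$lrt_gamma_e$p,
                          p_lambda = gf$lrt_lambda$p),
         curves = cbind(trait = tn,
                        variance_by_age(gf, seq(cfg$sim$age_range[1],
                                                cfg$sim$age_range[2], by = 0.5))))
  })

  report <- make_report_tables(h2_table, rhog_rows, gxage_rows, q = cfg$q)
  report$counts <- counts
  report$grm_validation <- grm_report
  report$config <- cfg

  write_tsv(report$h2_table, file.path(cfg$out_dir, "table_h2.tsv"))
  write_tsv(report$rhog_table, file.path(cfg$out_dir, "table_rhog.tsv"))
  write_tsv(report$gxage_table, file.path(cfg$out_dir, "table_gxage.tsv"))
  write_tsv(report$curve_table, file.path(cfg$out_dir, "table_curves.tsv"))

  files <- sort(setdiff(list.files(cfg$out_dir), "manifest.json"))
  manifest <- list(seed = cfg$seed,
                   package_version = as.character(utils::packageVersion("devgen")),
                   files = lapply(files, function(f)
                     list(name = f, md5 = unname(tools::md5sum(
                       file.path(cfg$out_dir, f))))))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  report$manifest <- manifest
  class(report) <- "run_report"
  report
}

#' Assemble report tables from fitted results
#'
#' Formats the heritability screen, genetic-correlation, and Gene x Age
#' results as the flat tables a cohort report prints, with
#' FDR flags computed per family via [bh_fdr()].  Empty stages yield
#' empty but well-formed tables.
#'
#' @param h2_table data.frame from the heritability screen (columns
#'   `trait`, `h2`, `se`, `p`, and optionally precomputed FDR columns).
#' @param rhog_rows list of per-pair data.frames (`trait1`, `trait2`,
#'   `rho_g`, `rho_e`, `rho_p`, `p_rho_g`, `p_rho_e`).
#' @param gxage_rows list of per-trait lists with elements `row` and
#'   `curves` (as built by [run_pipeline()]).
#' @param q FDR level.
#' @return list with `h2_table`, `rhog_table`, `gxage_table`,
#'   `curve_table`.
#' @export
make_report_tables <- function(h2_table, rhog_rows = list(),
                               gxage_rows = list(), q = 0.05) {
  if (is.null(h2_table$fdr_pass)) {
    fdr <- bh_fdr(h2_table$p, q)
    h2_table$p_adjusted <- fdr$p_adjusted
    h2_table$fdr_pass <- fdr$reject
  }
  rhog_table <- if (length(rhog_rows)) {
    tab <- do.call(rbind, rhog_rows)
    fg <- bh_fdr(tab$p_rho_g, q)
    tab$p_rho_g_adjusted <- fg$p_adjusted
    tab$rho_g_fdr_pass <- fg$reject
    tab
  } else data.frame(trait1 = character(0), trait2 = character(0),
                    rho_g = numeric(0), rho_e = numeric(0),
                    rho_p = numeric(0), p_rho_g = numeric(0),
                    p_rho_e = numeric(0), p_rho_g_adjusted = numeric(0),
                    rho_g_fdr_pass = logical(0))
  gxage_table <- if (length(gxage_rows)) {
    tab <- do.call(rbind, lapply(gxage_rows, `[[`, "row"))
    fg <- bh_fdr(tab$p_gamma_g, q)
    tab$p_gamma_g_adjusted <- fg$p_adjusted
    tab$gamma_g_fdr_pass <- fg$reject
    tab
  } else data.frame(trait = character(0), gamma_g = numeric(0),
                    gamma_e = numeric(0), lambda = numeric(0),
                    p_gamma_g = numeric(0), p_gamma_e = numeric(0),
                    p_lambda = numeric(0), p_gamma_g_adjusted = numeric(0),
                    gamma_g_fdr_pass = logical(0))
  curve_table <- if (length(gxage_rows))
    do.call(rbind, lapply(gxage_rows, `[[`, "curves"))
  else data.frame(trait = character(0), age = numeric(0), sg2 = numeric(0),
                  se2 = numeric(0), h2 = numeric(0))
  rownames(rhog_table) <- rownames(gxage_table) <- rownames(curve_table) <- NULL
  list(h2_table = h2_table, rhog_table = rhog_table,
       gxage_table = gxage_table, curve_table = curve_table)
}

#' @export
print.run_report <- function(x, ...) {
  cat("devgen pipeline report\n")
  cat(sprintf("  cohort: %d individuals (%d analyzed), %d SNPs after pruning\n",
              x$counts$cohort, x$counts$analysis_n, x$counts$snps_pruned))
  cat(sprintf("  GRM validation: %s\n",
              ifelse(x$grm_validation$ok, "pass", "FAIL")))
  cat("\nHeritability screen:\n")
  print(transform(x$h2_table, h2 = round(h2, 3), se = round(se, 3),
                  p = signif(p, 3), p_adjusted = signif(p_adjusted, 3)))
  if (nrow(x$rhog_table)) {
    cat("\nGenetic correlations (screened pairs):\n")
    print(transform(x$rhog_table, rho_g = round(rho_g, 3),
                    rho_e = round(rho_e, 3), rho_p = round(rho_p, 3),
                    p_rho_g = signif(p_rho_g, 3), p_rho_e = signif(p_rho_e, 3)))
  }
  if (nrow(x$gxage_table)) {
    cat("\nGene x Age fits (screened psychopathology factors):\n")
    print(transform(x$gxage_table, gamma_g = round(gamma_g, 3),
                    gamma_e = round(gamma_e, 3), lambda = round(lambda, 3),
                    p_gamma_g = signif(p_gamma_g, 3),
                    p_gamma_e = signif(p_gamma_e, 3),
                    p_lambda = signif(p_lambda, 3)))
  }
  invisible(x)
}

write_tsv <- function(tab, path) {
  utils::write.table(tab, path, quote = FALSE, sep = "\t", row.names = FALSE)
  invisible(path)
}
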