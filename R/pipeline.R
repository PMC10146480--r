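#' Configuration for a full heritability experiment
#'
#' Describes one run of the factorial analysis: SNP sets (all SNPs, APOE
#' region excluded, APOE plus GWAS-hit windows excluded, gene-set only)
#' crossed with liability prevalences and covariate models. Input is either
#' a simulated cohort ([simulate_cohort()] output) or PLINK-format files of
#' the same shape; exactly one of the two must be given.
#'
#' @param sim A `"cohort_sim"`, or a named list of arguments for
#'   [simulate_cohort()] (simulated on demand using `seed`).
#' @param bed_prefix Path prefix of a PLINK `.bed/.bim/.fam` triple.
#' @param pheno,covar Paths of phenotype (`FID IID status`) and covariate
#'   (`FID IID sex age`) files; required with `bed_prefix`.
#' @param apoe_bed,gwas_bed,geneset_bed Optional BED interval files for the
#'   exclusion region, GWAS-hit positions and the gene-set; defaults for
#'   simulated input come from the simulation itself.
#' @param prevalences Population prevalences for the liability rescaling
#'   (default 0.02, 0.05, 0.15).
#' @param covariate_models Subset of `"pcs_sex"` and `"pcs_sex_age"`.
#' @param n_pcs Number of ancestry principal components (default 5).
#' @param snp_sets Subset of `"all"`, `"no_apoe"`, `"no_apoe_gwas"`,
#'   `"geneset"`.
#' @param ldms Fit one GRM per LD/MAF stratum (GREML-LDMS, default `TRUE`)
#'   or a single all-SNP GRM per set.
#' @param maf_split,n_ld_bins,segment_bp LDMS binning parameters (MAF split
#'   0.05, LD-score quartiles, 200 kb segments).
#' @param gwas_flank Flank around GWAS hits in bp (default 5e5).
#' @param geneset_exclude_apoe Drop gene-set SNPs inside the APOE region
#'   (default `FALSE`).
#' @param seed Seed for on-demand simulation.
#' @param out_dir Optional directory; when set, `run_experiment` writes
#'   `results.csv` there.
#' @return An object of class `"experiment_config"`.
#' @export
experiment_config <- function(sim = NULL, bed_prefix = NULL, pheno = NULL,
                              covar = NULL, apoe_bed = NULL, gwas_bed = NULL,
                              geneset_bed = NULL,
                              prevalences = c(0.02, 0.05, 0.15),
                              covariate_models = c("pcs_sex", "pcs_sex_age"),
                              n_pcs = 5,
                              snp_sets = c("all", "no_apoe", "no_apoe_gwas",
                                           "geneset"),
                              ldms = TRUE, maf_split = 0.05, n_ld_bins = 4,
                              segment_bp = 200000, gwas_flank = 5e5,
                              geneset_exclude_apoe = FALSE, seed = NULL,
                              out_dir = NULL) {
  .assert(xor(is.null(sim), is.null(bed_prefix)),
          "exactly one of 'sim' and 'bed_prefix' must be given")
  .assert(all(prevalences > 0 & prevalences < 1),
          "'prevalences' must lie in (0, 1)")
  covariate_models <- match.arg(covariate_models,
                                c("pcs_sex", "pcs_sex_age"), several.ok = TRUE)
  snp_sets <- match.arg(snp_sets,
                        c("all", "no_apoe", "no_apoe_gwas", "geneset"),
                        several.ok = TRUE)
  if (!is.null(bed_prefix))
    .assert(!is.null(pheno), "'pheno' is required with 'bed_prefix'")
  structure(list(sim = sim, bed_prefix = bed_prefix, pheno = pheno,
                 covar = covar, apoe_bed = apoe_bed, gwas_bed = gwas_bed,
                 geneset_bed = geneset_bed, prevalences = prevalences,
                 covariate_models = covariate_models, n_pcs = n_pcs,
                 snp_sets = snp_sets, ldms = ldms, maf_split = maf_split,
                 n_ld_bins = n_ld_bins, segment_bp = segment_bp,
                 gwas_flank = gwas_flank,
                 geneset_exclude_apoe = geneset_exclude_apoe,
                 seed = seed, out_dir = out_dir),
            class = "experiment_config")
}

## resolve config inputs into geno / phenotype / covariates / regions
.load_experiment_inputs <- function(config) {
  if (!is.null(config$sim)) {
    sim <- config$sim
    if (!inherits(sim, "cohort_sim"))
      sim <- do.call(simulate_cohort, c(sim, list(seed = config$seed)))
    geno <- sim$geno
    i <- match(geno$sample_ids, sim$cohort$sample_id)
    list(geno = geno,
         status = sim$cohort$status[i],
         sex = sim$cohort$sex[i],
         age = sim$cohort$age_years[i],
         apoe = sim$apoe_region, gwas = sim$gwas_hits,
         geneset_ids = sim$geneset_ids)
  } else {
    pl <- read_plink(config$bed_prefix)
    ph <- read_phenotype(config$pheno)
    i <- match(pl$geno$sample_ids, ph$sample_id)
    .assert(!anyNA(i), "phenotype file does not cover all genotyped samples")
    sex <- age <- rep(NA_real_, length(i))
    if (!is.null(config$covar)) {
      cv <- read_covariates(config$covar)
      j <- match(pl$geno$sample_ids, cv$sample_id)
      sex <- cv$sex[j]; age <- cv$age_years[j]
    }
    apoe <- if (!is.null(config$apoe_bed)) read_bed_regions(config$apoe_bed)
    else apoe_region()
    gwas <- if (!is.null(config$gwas_bed)) read_bed_regions(config$gwas_bed)
    geneset_ids <- if (!is.null(config$geneset_bed)) {
      gs <- read_bed_regions(config$geneset_bed)
      setdiff(pl$geno$snp_meta$snp_id, exclude_regions(pl$geno$snp_meta, gs))
    }
    list(geno = pl$geno, status = ph$status[i], sex = sex, age = age,
         apoe = apoe, gwas = gwas, geneset_ids = geneset_ids)
  }
}

#' Run the factorial heritability analysis
#'
#' For every requested SNP set the pipeline re-derives the analysis panel
#' (region exclusion with 1-based inclusive boundaries; LDMS strata are
#' recomputed within each SNP subset, since LD-score quartiles are defined
#' on the SNPs being analyzed), builds one GRM per stratum (or a single
#' GRM), fits GREML under each covariate model, and rescales the
#' observed-scale estimate to the liability scale at each prevalence.
#' Non-converged cells are flagged in the table and the run continues.
#'
#' @param config An [experiment_config()].
#' @return A `"herit_results"` data frame with one row per
#'   (snp_set, covariate_model, prevalence) cell: `h2_obs`, `se_obs`,
#'   `h2_liab`, `se_liab`, `p_lrt`, `n_snps`, `n_cases`, `n_controls`,
#'   `converged`. The underlying `"greml"` fits are attached as attribute
#'   `"fits"` (named `snp_set.covariate_model`).
#' @examples
#' sim <- simulate_cohort(n_cases = 80, n_controls = 80, n_snps = 300, seed = 7)
#' cfg <- experiment_config(sim = sim, snp_sets = c("all", "no_apoe"),
#'                          covariate_models = "pcs_sex", n_pcs = 2,
#'                          ldms = FALSE)
#' res <- run_experiment(cfg)
#' @export
run_experiment <- function(config) {
  .assert(inherits(config, "experiment_config"),
          "'config' must be an experiment_config")
  inp <- .load_experiment_inputs(config)
  geno <- inp$geno
  y <- inp$status
  P <- mean(y)
  n_cases <- sum(y == 1); n_controls <- sum(y == 0)

  ## ancestry PCs from the all-SNP GRM, shared across cells
  grm_all <- compute_grm(geno)
  pcs <- pcs_from_grm(grm_all, config$n_pcs)

  snp_ids_for_set <- function(set) {
    switch(set,
      all = geno$snp_meta$snp_id,
      no_apoe = exclude_regions(geno$snp_meta, inp$apoe),
      no_apoe_gwas = {
        keep <- exclude_regions(geno$snp_meta, inp$apoe)
        drop_gwas <- if (!is.null(inp$gwas) && nrow(inp$gwas) > 0)
          exclude_regions(geno$snp_meta, inp$gwas, flank_bp = config$gwas_flank)
        else geno$snp_meta$snp_id
        intersect(keep, drop_gwas)
      },
      geneset = {
        ids <- inp$geneset_ids
        if (is.null(ids)) character(0)
        else if (config$geneset_exclude_apoe)
          intersect(ids, exclude_regions(geno$snp_meta, inp$apoe))
        else ids
      })
  }

  design_for_model <- function(model) {
    X <- cbind(`(Intercept)` = 1, pcs, sex = inp$sex)
    if (model == "pcs_sex_age") X <- cbind(X, age = inp$age)
    keep <- stats::complete.cases(X)
    .assert(all(keep), "missing covariate values; drop those individuals first")
    X
  }

  rows <- list(); fits <- list()
  for (set in config$snp_sets) {
    ids <- snp_ids_for_set(set)
    if (length(ids) == 0L) {
      message("SNP set '", set, "' is empty; skipped")
      next
    }
    sub <- subset_genotypes(geno, snp_ids = ids)
    grms <- if (config$ldms && ncol(sub$dosages) >= 2L) {
      ld <- segment_ld_scores(sub, segment_bp = config$segment_bp)
      strata <- make_ldms_strata(ld, sub$snp_meta$freq,
                                 maf_split = config$maf_split,
                                 n_ld_bins = config$n_ld_bins,
                                 snp_ids = sub$snp_meta$snp_id)
      lapply(split(strata$snp_id, strata$stratum),
             function(s) compute_grm(sub, snp_subset = s))
    } else list(compute_grm(sub))
    for (model in config$covariate_models) {
      X <- design_for_model(model)
      fit <- withCallingHandlers(
        reml_fit(y, X, grms),
        warning = function(w) invokeRestart("muffleWarning"))
      fits[[paste(set, model, sep = ".")]] <- fit
      for (K in config$prevalences) {
        fac <- observed_to_liability(1, K, P)
        rows[[length(rows) + 1L]] <- data.frame(
          snp_set = set, covariate_model = model, prevalence = K,
          h2_obs = fit$h2_obs, se_obs = fit$se_h2,
          h2_liab = fit$h2_obs * fac, se_liab = fit$se_h2 * fac,
          p_lrt = fit$p_lrt, n_snps = sum(vapply(grms, `[[`, 0, "n_snps")),
          n_cases = n_cases, n_controls = n_controls,
          converged = fit$converged, stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  class(res) <- c("herit_results", "data.frame")
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(as.data.frame(res),
                     file.path(config$out_dir, "results.csv"),
                     row.names = FALSE)
  }
  attr(res, "fits") <- fits
  attr(res, "case_proportion") <- P
  res
}

#' Proportion of heritability captured by the gene-set
#'
#' Compares the gene-set-only fit with the all-SNP fit per prevalence and
#' covariate model: `proportion_h2 = h2(gene-set) / h2(all)` on the
#' liability scale, together with the proportion of SNPs in the set.
#' Because numerator and denominator share the same prevalence and case
#' proportion, the liability factor cancels and the proportion is identical
#' across prevalences.
#'
#' @param results A `"herit_results"` table containing both `"geneset"` and
#'   `"all"` rows.
#' @return Data frame with columns `prevalence`, `covariate_model`,
#'   `proportion_h2`, `proportion_snps`. `proportion_h2` is `NA` when the
#'   all-SNP heritability is zero.
#' @export
geneset_proportion <- function(results) {
  .assert(inherits(results, "data.frame"), "'results' must be a results table")
  .assert(all(c("geneset", "all") %in% results$snp_set),
          "results must contain both 'geneset' and 'all' rows")
  a <- results[results$snp_set == "all", ]
  g <- results[results$snp_set == "geneset", ]
  key <- c("prevalence", "covariate_model")
  mg <- merge(a, g, by = key, suffixes = c("_all", "_gs"))
  out <- data.frame(prevalence = mg$prevalence,
                    covariate_model = mg$covariate_model,
                    proportion_h2 = ifelse(mg$h2_liab_all > 0,
                                           mg$h2_liab_gs / mg$h2_liab_all,
                                           NA_real_),
                    proportion_snps = mg$n_snps_gs / mg$n_snps_all,
                    stringsAsFactors = FALSE)
  out[order(out$covariate_model, out$prevalence), , drop = FALSE]
}

#' Summarize heritability changes under region exclusion across replicates
#'
#' Computes, per prevalence and covariate model, the paired mean and SD of
#' the liability-scale heritability drop when the APOE region is excluded
#' (`all` minus `no_apoe`) and when GWAS-hit windows are additionally
#' excluded (`no_apoe` minus `no_apoe_gwas`).
#'
#' @param results_list List of `"herit_results"` tables, one per replicate
#'   (at least 2).
#' @return Data frame with columns `comparison`, `prevalence`,
#'   `covariate_model`, `mean_delta`, `sd_delta`, `n_reps`.
#' @export
summarize_deltas <- function(results_list) {
  .assert(is.list(results_list) && length(results_list) >= 2L,
          "need at least 2 replicates")
  one <- function(res, from, to) {
    f <- res[res$snp_set == from, ]
    t <- res[res$snp_set == to, ]
    mg <- merge(f, t, by = c("prevalence", "covariate_model"),
                suffixes = c("_from", "_to"))
    data.frame(prevalence = mg$prevalence,
               covariate_model = mg$covariate_model,
               delta = mg$h2_liab_from - mg$h2_liab_to,
               stringsAsFactors = FALSE)
  }
  agg <- function(from, to, label) {
    d <- do.call(rbind, lapply(results_list, one, from = from, to = to))
    if (is.null(d) || nrow(d) == 0L) return(NULL)
    s <- stats::aggregate(delta ~ prevalence + covariate_model, data = d,
                          FUN = function(v) c(mean(v), stats::sd(v), length(v)))
    data.frame(comparison = label, prevalence = s$prevalence,
               covariate_model = s$covariate_model,
               mean_delta = s$delta[, 1L], sd_delta = s$delta[, 2L],
               n_reps = s$delta[, 3L], stringsAsFactors = FALSE)
  }
  out <- rbind(agg("all", "no_apoe", "apoe_exclusion"),
               agg("no_apoe", "no_apoe_gwas", "gwas_exclusion"))
  .assert(!is.null(out), "results lack the SNP sets needed for deltas")
  out
}

#' Write a markdown report of a results table
#'
#' Emits the grouped values behind a prevalence-by-SNP-set bar chart (one
#' section per covariate model, one row per SNP set and prevalence) plus the
#' gene-set proportions when both gene-set and all-SNP rows are present.
#'
#' @param results A `"herit_results"` table from [run_experiment()].
#' @param path Output markdown file.
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path) {
  .assert(inherits(results, "herit_results"), "'results' must be a herit_results")
  lines <- c("# SNP-based heritability report", "")
  for (model in unique(results$covariate_model)) {
    lines <- c(lines, sprintf("## Covariate model: %s", model), "",
               "| SNP set | prevalence | h2 (observed) | SE | h2 (liability) | SE | LRT p | SNPs |",
               "|---|---|---|---|---|---|---|---|")
    r <- results[results$covariate_model == model, ]
    for (i in seq_len(nrow(r))) {
      lines <- c(lines, sprintf(
        "| %s | %.2f | %.4f | %.4f | %.4f | %.4f | %.3g | %d |%s",
        r$snp_set[i], r$prevalence[i], r$h2_obs[i], r$se_obs[i],
        r$h2_liab[i], r$se_liab[i], r$p_lrt[i], r$n_snps[i],
        if (!r$converged[i]) " (not converged)" else ""))
    }
    lines <- c(lines, "")
  }
  if (all(c("geneset", "all") %in% results$snp_set)) {
    gp <- geneset_proportion(results)
    lines <- c(lines, "## Gene-set proportion of heritability", "",
               "| covariate model | prevalence | proportion of h2 | proportion of SNPs |",
               "|---|---|---|---|",
               sprintf("| %s | %.2f | %.3f | %.3f |", gp$covariate_model,
                       gp$prevalence, gp$proportion_h2, gp$proportion_snps),
               "")
  }
  lines <- c(lines, sprintf("Sample: %d cases / %d controls.",
                            results$n_cases[1], results$n_controls[1]))
  writeLines(lines, path)
  invisible(path)
}
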