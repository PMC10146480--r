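#' Simulate a complete case-control cohort under the age-structured
#' liability-threshold model
#'
#' End-to-end generator emulating the study designs of late-onset disease
#' cohorts: LD-blocked genotypes on a main chromosome plus a chromosome-19
#' analog carrying a designated 2.1 Mb major-locus region
#' (chr19:44.4-46.5 Mb), a concentrated gene-set occupying a few percent of
#' SNPs, liabilities and onset ages from an [age_onset_model()], and
#' case-control ascertainment with optional unscreened (age-mismatched)
#' controls and clinical misdiagnosis.
#'
#' Two design presets are provided. `"age_matched"` emulates pathologically
#' confirmed series: case and control ages drawn from the same distribution
#' (normal, mean 80, sd 5) and controls screened to be disease-free.
#' `"age_mismatched"` emulates clinical case/population control series:
#' old cases (mean 80) against young unscreened controls (uniform 50-62),
#' a fraction of whom are latent cases.
#'
#' @param n_cases,n_controls Sample sizes after ascertainment.
#' @param arch An [architecture()].
#' @param n_snps Total number of SNPs (default 2000).
#' @param ld_block_size,ld_rho LD structure passed to
#'   [simulate_genotypes()] (defaults: blocks of 20 SNPs, latent correlation
#'   0.7).
#' @param spacing_bp Inter-SNP spacing on the main chromosome (default
#'   5000 bp).
#' @param onset_model An [age_onset_model()].
#' @param design `"age_matched"` or `"age_mismatched"` preset.
#' @param case_age_dist,control_age_dist,screened Optional overrides of the
#'   preset ascertainment.
#' @param misdiagnosis_rate Fraction of case labels given to unaffected
#'   individuals (default 0).
#' @param n_gwas_hits Number of GWAS-hit analogs: the largest per-SNP
#'   variance contributors outside the major-locus region (default 5).
#' @param n_pop Population size to simulate before ascertainment; sized
#'   automatically from the onset model and requested strata when `NULL`.
#' @param seed Integer seed; the whole cohort is reproducible from it.
#' @return An object of class `"cohort_sim"`: list with `geno` (sampled
#'   individuals only), `cohort` (the ascertained `cohort_table`),
#'   `effects`, `apoe_region`, `gwas_hits` (both [region_set()]s),
#'   `geneset_ids`, `geneset_regions`, and `truth` (true architecture
#'   values, the latent-case fraction and sizing, for validation).
#' @examples
#' sim <- simulate_cohort(n_cases = 50, n_controls = 50, n_snps = 200, seed = 1)
#' table(sim$cohort$status)
#' @export
simulate_cohort <- function(n_cases, n_controls, arch = architecture(),
                            n_snps = 2000, ld_block_size = 20, ld_rho = 0.7,
                            spacing_bp = 5000,
                            onset_model = age_onset_model(),
                            design = c("age_matched", "age_mismatched"),
                            case_age_dist = NULL, control_age_dist = NULL,
                            screened = NULL, misdiagnosis_rate = 0,
                            n_gwas_hits = 5, n_pop = NULL, seed = NULL) {
  design <- match.arg(design)
  if (design == "age_matched") {
    case_age_dist <- case_age_dist %||%
      function(n) pmin(pmax(stats::rnorm(n, 80, 5), 66), 95)
    control_age_dist <- control_age_dist %||% case_age_dist
    screened <- screened %||% TRUE
  } else {
    case_age_dist <- case_age_dist %||%
      function(n) pmin(pmax(stats::rnorm(n, 80, 5), 66), 95)
    control_age_dist <- control_age_dist %||%
      function(n) stats::runif(n, 50, 62)
    screened <- screened %||% FALSE
  }

  .with_seed(seed, {
    ## --- population sizing: enough affected individuals at every drawn age
    if (is.null(n_pop)) {
      probe <- sort(case_age_dist(2000L))
      Kp <- onset_model$K(probe)
      quota <- (seq_along(probe) / 2000) * n_cases
      ## binomial safety margin so every cumulative age quota is coverable
      need_cases <- max((quota + 4 * sqrt(quota) + 10) / Kp)
      amax <- max(onset_model$anchors[, "age"])
      frac_never <- 1 - onset_model$K(amax)
      nc <- n_controls * (1 + misdiagnosis_rate)
      need_ctls <- (nc + 4 * sqrt(nc) + 10) /
        (if (screened) frac_never else 0.8)
      n_pop <- ceiling(max(need_cases, need_ctls,
                           (n_cases + n_controls) * 1.5))
    }

    ## --- SNP layout: main chromosome plus a chr19 analog around the
    ##     major-locus region
    m19 <- max(ld_block_size, round(0.15 * n_snps))
    m19 <- min(m19, n_snps)
    m1 <- n_snps - m19
    chrom <- rep(c(1L, 19L), c(m1, m19))
    pos <- c(spacing_bp * seq_len(m1),
             44.4e6 + 10000 * (seq_len(m19) - 1L))
    geno_pop <- simulate_genotypes(n_pop, n_snps, maf_range = arch$maf_range,
                                   ld_block_size = ld_block_size,
                                   ld_rho = ld_rho, chrom = chrom,
                                   pos_bp = pos)
    meta <- geno_pop$snp_meta
    apoe <- apoe_region()

    ## --- gene-set: contiguous runs of ~10 SNPs on the main chromosome
    n_gs <- round(arch$geneset_snp_fraction * n_snps)
    geneset_ids <- character(0)
    if (n_gs > 0) {
      run <- min(10L, n_gs)
      n_runs <- ceiling(n_gs / run)
      starts <- sort(sample(seq_len(max(1L, m1 - run)), n_runs))
      idx <- unique(unlist(lapply(starts, function(s) s:(s + run - 1L))))
      idx <- idx[idx <= m1][seq_len(min(n_gs, sum(idx <= m1)))]
      geneset_ids <- meta$snp_id[idx]
    }

    ## --- major locus: a common SNP near the centre of the region
    in_apoe <- meta$chrom == 19L & meta$pos_bp >= apoe$start_bp &
      meta$pos_bp <= apoe$end_bp
    major_id <- NULL
    if (arch$major_locus_share > 0) {
      .assert(any(in_apoe), "no SNPs inside the major-locus region")
      cand <- which(in_apoe & meta$freq >= 0.15 & meta$freq <= 0.45)
      if (length(cand) == 0L) cand <- which(in_apoe)
      centre <- (apoe$start_bp + apoe$end_bp) / 2
      major_id <- meta$snp_id[cand[which.min(abs(meta$pos_bp[cand] - centre))]]
    }

    effects <- draw_effects(meta, arch, geneset_ids = geneset_ids,
                            major_snp_id = major_id)
    population <- simulate_liability_onset(geno_pop, effects, onset_model)
    cohort <- ascertain(population, n_cases, n_controls,
                        case_age_dist = case_age_dist,
                        control_age_dist = control_age_dist,
                        screened = screened,
                        misdiagnosis_rate = misdiagnosis_rate)

    ## --- GWAS-hit analogs: largest per-SNP variance outside the region
    hit_pool <- which(!in_apoe & effects$beta_std != 0)
    hit_pool <- setdiff(hit_pool, which(meta$snp_id %in% major_id))
    ord <- hit_pool[order(effects$beta_std[hit_pool]^2, decreasing = TRUE)]
    hits <- utils::head(ord, n_gwas_hits)
    gwas_hits <- if (length(hits))
      region_set(meta$chrom[hits], meta$pos_bp[hits], meta$pos_bp[hits],
                 label = "GWAS hits")
    else region_set(integer(0), numeric(0), numeric(0), label = "GWAS hits")

    ## --- gene-set intervals (consecutive SNP runs become BED intervals)
    geneset_regions <- NULL
    if (length(geneset_ids)) {
      gi <- sort(match(geneset_ids, meta$snp_id))
      brk <- c(0L, which(diff(gi) > 1L), length(gi))
      iv <- do.call(rbind, lapply(seq_len(length(brk) - 1L), function(j) {
        run <- gi[(brk[j] + 1L):brk[j + 1L]]
        c(meta$chrom[run[1L]], meta$pos_bp[run[1L]], meta$pos_bp[run[length(run)]])
      }))
      geneset_regions <- region_set(iv[, 1L], iv[, 2L], iv[, 3L],
                                    label = "gene-set")
    }

    geno <- subset_genotypes(geno_pop, samples = cohort$sample_id)
    truth <- list(h2_liability = arch$h2_liability,
                  major_locus_share = arch$major_locus_share,
                  geneset_h2_share = arch$geneset_h2_share,
                  geneset_snp_fraction = length(geneset_ids) / n_snps,
                  major_snp_id = major_id,
                  latent_case_fraction = attr(cohort, "latent_case_fraction"),
                  n_pop = n_pop, design = design, screened = screened,
                  misdiagnosis_rate = misdiagnosis_rate)
    structure(list(geno = geno, cohort = cohort, effects = effects,
                   apoe_region = apoe, gwas_hits = gwas_hits,
                   geneset_ids = geneset_ids,
                   geneset_regions = geneset_regions, truth = truth),
              class = "cohort_sim")
  })
}

#' @export
print.cohort_sim <- function(x, ...) {
  cat(sprintf("cohort_sim (%s%s): %d cases / %d controls, %d SNPs\n",
              x$truth$design, if (x$truth$screened) ", screened" else ", unscreened",
              sum(x$cohort$status == 1), sum(x$cohort$status == 0),
              ncol(x$geno$dosages)))
  cat(sprintf("  true liability h2 = %.2f (major locus %.2f, gene-set %.2f on %.1f%% of SNPs)\n",
              x$truth$h2_liability, x$truth$major_locus_share,
              x$truth$geneset_h2_share, 100 * x$truth$geneset_snp_fraction))
  if (!is.null(x$truth$latent_case_fraction) &&
      !is.nan(x$truth$latent_case_fraction))
    cat(sprintf("  latent-case fraction among controls: %.3f\n",
                x$truth$latent_case_fraction))
  invisible(x)
}

#' Write a simulated cohort to disk in PLINK/BED text formats
#'
#' Writes the PLINK 1 binary genotype triple, phenotype and covariate files,
#' BED interval files for the major-locus region, the GWAS-hit windows and
#' the gene-set, and a `truth.json` sidecar with the simulation truth (for
#' validation only; estimation never reads it).
#'
#' @param sim A `"cohort_sim"`.
#' @param dir Output directory (created if needed).
#' @param basename File name stem (default `"cohort"`).
#' @return The directory path, invisibly.
#' @export
write_cohort <- function(sim, dir, basename = "cohort") {
  .assert(inherits(sim, "cohort_sim"), "'sim' must be a cohort_sim")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  prefix <- file.path(dir, basename)
  write_plink(sim$geno, prefix, cohort = sim$cohort)
  write_phenotype(sim$cohort, paste0(prefix, ".pheno"))
  write_covariates(sim$cohort, paste0(prefix, ".covar"))
  write_bed_regions(sim$apoe_region, file.path(dir, "apoe_region.bed"))
  if (nrow(sim$gwas_hits) > 0)
    write_bed_regions(sim$gwas_hits, file.path(dir, "gwas_hits.bed"))
  if (!is.null(sim$geneset_regions))
    write_bed_regions(sim$geneset_regions, file.path(dir, "geneset.bed"))
  jsonlite::write_json(sim$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
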