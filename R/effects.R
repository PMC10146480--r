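#' Draw per-SNP effect sizes matching an architecture exactly
#'
#' Samples standardized-scale effects for a causal subset of SNPs and then
#' rescales each component (major locus, gene-set, polygenic background) so
#' that its sum of squared standardized effects equals the requested share of
#' `h2_liability` exactly. On the per-allele scale this is the identity
#' `sum(beta^2 * 2 p (1-p)) = h2`.
#'
#' @param snp_meta SNP metadata (`snp_id`, `freq`) as in a
#'   [genotype_matrix()].
#' @param arch An [architecture()].
#' @param geneset_ids Character vector of gene-set SNP ids; if `NULL`, a
#'   random set of `round(geneset_snp_fraction * m)` SNPs is designated.
#' @param major_snp_id Id of the major-locus SNP; if `NULL` and the major
#'   share is positive, one SNP outside the gene-set is picked at random.
#' @param seed Optional integer seed.
#' @return Data frame aligned with `snp_meta` rows, columns `snp_id`,
#'   `beta_std` (effect on the standardized genotype) and `beta_allele`
#'   (per-allele effect), with attributes `h2`, `major_snp_id`,
#'   `geneset_ids`.
#' @export
draw_effects <- function(snp_meta, arch, geneset_ids = NULL,
                         major_snp_id = NULL, seed = NULL) {
  .assert(inherits(arch, "architecture"), "'arch' must be an architecture")
  m <- nrow(snp_meta)
  ids <- snp_meta$snp_id
  .with_seed(seed, {
    if (is.null(geneset_ids)) {
      n_gs <- round(arch$geneset_snp_fraction * m)
      geneset_ids <- if (n_gs > 0) sample(ids, n_gs) else character(0)
    }
    .assert(length(geneset_ids) <= m, "gene-set larger than the SNP panel")
    .assert(all(geneset_ids %in% ids), "gene-set ids not present in snp_meta")
    if (is.null(major_snp_id) && arch$major_locus_share > 0)
      major_snp_id <- sample(setdiff(ids, geneset_ids), 1L)
    n_causal <- arch$n_causal %||% max(50L, round(0.1 * m))
    n_causal <- min(n_causal, m)
    .assert(m >= n_causal, "more causal SNPs requested than available")

    is_gs <- ids %in% geneset_ids
    is_major <- !is.null(major_snp_id) & ids %in% major_snp_id
    ## causal set: the major locus, all gene-set SNPs, and random background
    n_bg <- max(0L, n_causal - sum(is_gs) - sum(is_major))
    bg_pool <- which(!is_gs & !is_major)
    .assert(arch$background_share <= 0 || n_bg > 0 || length(bg_pool) == 0,
            "background share is positive but no background causal SNPs remain")
    bg_idx <- if (n_bg > 0) sample(bg_pool, min(n_bg, length(bg_pool))) else integer(0)

    beta <- numeric(m)
    scale_group <- function(idx, target_var) {
      if (length(idx) == 0 || target_var <= 0) return()
      b <- stats::rnorm(length(idx))
      beta[idx] <<- b * sqrt(target_var / sum(b^2))
    }
    h2 <- arch$h2_liability
    if (any(is_major))
      beta[which(is_major)[1L]] <- sample(c(-1, 1), 1L) *
        sqrt(arch$major_locus_share * h2)
    scale_group(which(is_gs), arch$geneset_h2_share * h2)
    scale_group(bg_idx, arch$background_share * h2)

    p <- snp_meta$freq
    het <- 2 * p * (1 - p)
    beta_allele <- ifelse(het > 0, beta / sqrt(het), 0)
    structure(data.frame(snp_id = ids, beta_std = beta,
                         beta_allele = beta_allele,
                         stringsAsFactors = FALSE),
              h2 = h2, major_snp_id = major_snp_id,
              geneset_ids = geneset_ids)
  })
}
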