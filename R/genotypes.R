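#' Construct a genotype matrix object
#'
#' Bundles an N x M additive dosage matrix (0/1/2 counts of the A1 allele)
#' with per-SNP metadata. Positions must be strictly increasing within each
#' chromosome; the stored allele frequency is the realized A1 frequency of
#' the sample.
#'
#' @param dosages Integer matrix, individuals in rows, SNPs in columns,
#'   entries in \{0, 1, 2\} (missing values allowed only for real data read
#'   from disk).
#' @param snp_meta Data frame with columns `chrom`, `snp_id`, `pos_bp`,
#'   `a1`, `a2`; a `freq` column is recomputed from `dosages`.
#' @param sample_ids Character vector of individual identifiers.
#' @return An object of class `"genotype_matrix"`.
#' @export
genotype_matrix <- function(dosages, snp_meta, sample_ids = NULL) {
  dosages <- as.matrix(dosages)
  .assert(ncol(dosages) == nrow(snp_meta),
          "ncol(dosages) must match nrow(snp_meta)")
  need <- c("chrom", "snp_id", "pos_bp", "a1", "a2")
  .assert(all(need %in% names(snp_meta)),
          paste("snp_meta must have columns:", paste(need, collapse = ", ")))
  ok_rng <- all(dosages %in% c(0L, 1L, 2L) | is.na(dosages))
  .assert(ok_rng, "dosages must be 0, 1, 2 or NA")
  for (ch in unique(snp_meta$chrom)) {
    p <- snp_meta$pos_bp[snp_meta$chrom == ch]
    .assert(all(diff(p) > 0),
            sprintf("positions must be strictly increasing on chromosome %s", ch))
  }
  if (is.null(sample_ids)) sample_ids <- sprintf("id%05d", seq_len(nrow(dosages)))
  snp_meta$freq <- colMeans(dosages, na.rm = TRUE) / 2
  dimnames(dosages) <- list(sample_ids, snp_meta$snp_id)
  structure(list(dosages = dosages,
                 snp_meta = as.data.frame(snp_meta, stringsAsFactors = FALSE),
                 sample_ids = sample_ids),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d individuals x %d SNPs on %d chromosome(s)\n",
              nrow(x$dosages), ncol(x$dosages), length(unique(x$snp_meta$chrom))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

#' Subset a genotype matrix by SNP id or by individual
#'
#' @param geno A [genotype_matrix()].
#' @param snp_ids Character vector of SNP ids to keep (order preserved as in
#'   the object), or `NULL` to keep all.
#' @param samples Indices or identifiers of individuals to keep, or `NULL`.
#' @return A `genotype_matrix` with frequencies recomputed on the subset.
#' @export
subset_genotypes <- function(geno, snp_ids = NULL, samples = NULL) {
  .assert(inherits(geno, "genotype_matrix"), "'geno' must be a genotype_matrix")
  keep_snp <- if (is.null(snp_ids)) seq_len(ncol(geno$dosages)) else {
    .assert(all(snp_ids %in% geno$snp_meta$snp_id), "unknown SNP id in subset")
    which(geno$snp_meta$snp_id %in% snp_ids)
  }
  keep_ind <- if (is.null(samples)) seq_along(geno$sample_ids) else {
    if (is.character(samples)) match(samples, geno$sample_ids) else samples
  }
  .assert(!anyNA(keep_ind), "unknown sample in subset")
  genotype_matrix(geno$dosages[keep_ind, keep_snp, drop = FALSE],
                  geno$snp_meta[keep_snp, , drop = FALSE],
                  geno$sample_ids[keep_ind])
}

#' Simulate genotypes with block-wise linkage disequilibrium
#'
#' Generates biallelic dosages by sampling two haplotypes per individual from
#' a latent Gaussian first-order autoregressive process: within blocks of
#' `ld_block_size` consecutive SNPs, latent variables have correlation
#' `ld_rho` between neighbours (decaying geometrically with distance) and
#' blocks are mutually independent. Thresholding the latent variable at the
#' allele-frequency quantile yields haplotype alleles with the drawn marginal
#' frequency and positive LD inside blocks, producing a non-degenerate
#' segment LD-score distribution for LD-stratified analyses.
#'
#' @param n Number of individuals.
#' @param m Number of SNPs.
#' @param maf_range Range for the uniform draw of allele frequencies; must
#'   lie in `(0, 0.5]`.
#' @param ld_block_size Number of consecutive SNPs per LD block.
#' @param ld_rho Latent adjacent-SNP correlation in `[0, 1)`; 0 gives
#'   independent SNPs.
#' @param chrom Chromosome code per SNP (scalar or length-`m`), default 1.
#' @param pos_bp Optional base-pair positions (strictly increasing within
#'   chromosome); default places SNPs every `spacing_bp` bp.
#' @param spacing_bp Default inter-SNP spacing in bp (default 5000, so a
#'   200 kb LD-score window spans about 40 SNPs).
#' @param seed Optional integer seed; the same seed reproduces the matrix
#'   exactly.
#' @return A [genotype_matrix()].
#' @examples
#' g <- simulate_genotypes(50, 100, ld_rho = 0.7, seed = 1)
#' range(g$dosages)
#' @export
simulate_genotypes <- function(n, m, maf_range = c(0.01, 0.5),
                               ld_block_size = 20, ld_rho = 0,
                               chrom = 1L, pos_bp = NULL, spacing_bp = 5000,
                               seed = NULL) {
  .assert(n >= 1 && m >= 1, "'n' and 'm' must be at least 1")
  .assert(is.numeric(maf_range) && length(maf_range) == 2L &&
            maf_range[1] > 0 && maf_range[2] <= 0.5 &&
            maf_range[1] <= maf_range[2],
          "'maf_range' must lie in (0, 0.5]")
  .assert(ld_rho >= 0 && ld_rho < 1, "'ld_rho' must be in [0, 1)")
  if (length(chrom) == 1L) chrom <- rep(as.integer(chrom), m)
  .assert(length(chrom) == m, "'chrom' must be scalar or length m")
  if (is.null(pos_bp)) {
    pos_bp <- integer(m)
    for (ch in unique(chrom)) {
      idx <- which(chrom == ch)
      pos_bp[idx] <- spacing_bp * seq_along(idx)
    }
  }
  .with_seed(seed, {
    p <- stats::runif(m, maf_range[1], maf_range[2])
    if (ld_rho == 0) {
      dos <- matrix(stats::rbinom(n * m, 2L, rep(p, each = n)), nrow = n)
    } else {
      dos <- matrix(0L, n, m)
      thr <- stats::qnorm(p)
      starts <- seq(1L, m, by = ld_block_size)
      for (hap in 1:2) {
        for (s in starts) {
          e <- min(s + ld_block_size - 1L, m)
          u <- matrix(0, n, e - s + 1L)
          u[, 1L] <- stats::rnorm(n)
          if (e > s) {
            sc <- sqrt(1 - ld_rho^2)
            for (j in 2:(e - s + 1L))
              u[, j] <- ld_rho * u[, j - 1L] + sc * stats::rnorm(n)
          }
          dos[, s:e] <- dos[, s:e] + (u < rep(thr[s:e], each = n))
        }
      }
    }
    storage.mode(dos) <- "integer"
    meta <- data.frame(chrom = chrom,
                       snp_id = sprintf("snp%06d", seq_len(m)),
                       pos_bp = as.integer(pos_bp),
                       a1 = "A", a2 = "C",
                       stringsAsFactors = FALSE)
    genotype_matrix(dos, meta)
  })
}
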