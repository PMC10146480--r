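#' Segment-based LD scores
#'
#' For each SNP, the LD score is the sum of squared Pearson correlations
#' (r-squared) between its dosages and those of every SNP on the same
#' chromosome whose position lies within half the segment width on either
#' side (a sliding window of total width `segment_bp`, default 200 kb). The
#' self term is included, so scores are at least 1 for polymorphic SNPs.
#' Missing dosages are mean-imputed before correlation.
#'
#' @param geno A [genotype_matrix()] with positions sorted within
#'   chromosome.
#' @param segment_bp Window width in base pairs (default 200 000, i.e.
#'   plus/minus 100 kb around the focal SNP).
#' @return Numeric vector of LD scores, one per SNP, named by SNP id.
#' @export
segment_ld_scores <- function(geno, segment_bp = 200000) {
  .assert(inherits(geno, "genotype_matrix"), "'geno' must be a genotype_matrix")
  w <- segment_bp / 2
  meta <- geno$snp_meta
  out <- numeric(nrow(meta))
  n <- nrow(geno$dosages)
  for (ch in unique(meta$chrom)) {
    idx <- which(meta$chrom == ch)
    pos <- meta$pos_bp[idx]
    x <- geno$dosages[, idx, drop = FALSE]
    storage.mode(x) <- "double"
    if (anyNA(x)) {
      mu <- colMeans(x, na.rm = TRUE)
      na <- which(is.na(x), arr.ind = TRUE)
      x[na] <- mu[na[, 2L]]
    }
    sds <- apply(x, 2L, stats::sd)
    z <- sweep(x, 2L, colMeans(x), "-")
    ok <- sds > 0
    z[, ok] <- sweep(z[, ok, drop = FALSE], 2L, sds[ok], "/")
    z[, !ok] <- 0
    lo <- findInterval(pos - w - 0.5, pos) + 1L
    hi <- findInterval(pos + w + 0.5, pos)
    sc <- numeric(length(idx))
    chunk <- 256L
    for (a in seq(1L, length(idx), by = chunk)) {
      b <- min(a + chunk - 1L, length(idx))
      span <- lo[a]:hi[b]
      r <- crossprod(z[, span, drop = FALSE], z[, a:b, drop = FALSE]) / (n - 1)
      r2 <- r * r
      for (i in a:b) {
        rows <- (lo[i] - span[1L] + 1L):(hi[i] - span[1L] + 1L)
        sc[i] <- sum(r2[rows, i - a + 1L])
      }
    }
    sc[!ok] <- 1   # monomorphic: self term only, by convention
    ## guard against tiny negative drift and enforce the self term
    sc <- pmax(sc, 1)
    out[idx] <- sc
  }
  names(out) <- meta$snp_id
  out
}

#' Stratify SNPs by LD score within MAF groups (LDMS binning)
#'
#' Splits SNPs at a minor-allele-frequency threshold (default 0.05), then
#' splits each MAF group at its own LD-score quantiles into `n_ld_bins`
#' right-closed bins (quantile type 7). A SNP whose LD score equals a bin
#' boundary falls in the lower bin. Groups with fewer SNPs than bins, or
#' with tied quantile boundaries, collapse to fewer bins with a warning;
#' empty strata are dropped.
#'
#' @param ld_scores Numeric vector of per-SNP LD scores.
#' @param mafs Numeric vector of minor allele frequencies, aligned with
#'   `ld_scores`.
#' @param maf_split MAF threshold separating the low-MAF group
#'   (`maf < maf_split`) from the rest.
#' @param n_ld_bins Number of LD-score bins per MAF group (default 4,
#'   quartiles).
#' @param snp_ids Optional SNP ids for the output.
#' @return An object of class `"snp_strata"`: data frame with columns
#'   `snp_id`, `maf`, `ld_score`, `stratum` (integer, 1-based, consecutive
#'   over non-empty strata), with attribute `boundaries`.
#' @export
make_ldms_strata <- function(ld_scores, mafs, maf_split = 0.05, n_ld_bins = 4,
                             snp_ids = NULL) {
  .assert(length(ld_scores) == length(mafs),
          "'ld_scores' and 'mafs' must be aligned")
  m <- length(ld_scores)
  if (is.null(snp_ids)) snp_ids <- names(ld_scores) %||% sprintf("snp%06d", seq_len(m))
  maf <- pmin(mafs, 1 - mafs)
  group <- ifelse(maf < maf_split, "lowMAF", "highMAF")
  stratum <- integer(m)
  boundaries <- list()
  nxt <- 0L
  for (gname in c("lowMAF", "highMAF")) {
    gi <- which(group == gname)
    if (length(gi) == 0L) next
    bins <- n_ld_bins
    if (length(gi) < bins) {
      bins <- max(1L, length(gi))
      warning(sprintf("%s: fewer SNPs (%d) than LD bins; using %d bin(s)",
                      gname, length(gi), bins))
    }
    br <- unique(stats::quantile(ld_scores[gi], probs = seq(0, 1, length.out = bins + 1),
                                 type = 7, names = FALSE))
    if (length(br) < 2L) {
      ## all LD scores tied: single stratum
      if (bins > 1L)
        warning(sprintf("%s: tied LD-score quantiles; strata collapsed to 1", gname))
      stratum[gi] <- nxt + 1L
      nxt <- nxt + 1L
      boundaries[[gname]] <- br
      next
    }
    if (length(br) < bins + 1L && bins > 1L)
      warning(sprintf("%s: tied LD-score quantiles; strata collapsed from %d to %d",
                      gname, bins, length(br) - 1L))
    cutv <- cut(ld_scores[gi], breaks = br, include.lowest = TRUE, right = TRUE,
                labels = FALSE)
    ## renumber only non-empty bins
    lev <- sort(unique(cutv))
    stratum[gi] <- nxt + match(cutv, lev)
    nxt <- nxt + length(lev)
    boundaries[[gname]] <- br
  }
  structure(data.frame(snp_id = snp_ids, maf = maf, ld_score = ld_scores,
                       stratum = stratum, stringsAsFactors = FALSE,
                       row.names = NULL),
            boundaries = boundaries, maf_split = maf_split,
            class = c("snp_strata", "data.frame"))
}

#' Export SNP stratum assignments as TSV
#'
#' @param strata A `"snp_strata"` object from [make_ldms_strata()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_snp_strata <- function(strata, path) {
  utils::write.table(as.data.frame(strata)[, c("snp_id", "maf", "ld_score", "stratum")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
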