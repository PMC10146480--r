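#' Compute a genetic relatedness matrix (GRM)
#'
#' Implements the standard GCTA estimator
#' \deqn{A_{jk} = \frac{1}{M} \sum_i \frac{(x_{ij} - 2p_i)(x_{ik} - 2p_i)}
#' {2 p_i (1 - p_i)},}
#' with allele frequencies \eqn{p_i} computed from the analyzed sample
#' (cases and controls jointly). Monomorphic SNPs are excluded from the sum
#' and from the SNP count. Missing dosages (possible in real data) are
#' mean-imputed before standardization.
#'
#' @param geno A [genotype_matrix()].
#' @param snp_subset Character vector of SNP ids to use, or `NULL` for all.
#' @return An object of class `"grm"`: list with `values` (symmetric N x N
#'   matrix), `n_snps` (SNPs actually used), `sample_ids`.
#' @examples
#' g <- simulate_genotypes(100, 200, seed = 1)
#' A <- compute_grm(g)
#' mean(diag(A$values))
#' @export
compute_grm <- function(geno, snp_subset = NULL) {
  .assert(inherits(geno, "genotype_matrix"), "'geno' must be a genotype_matrix")
  x <- geno$dosages
  if (!is.null(snp_subset)) {
    .assert(all(snp_subset %in% colnames(x)), "unknown SNP id in 'snp_subset'")
    x <- x[, colnames(x) %in% snp_subset, drop = FALSE]
  }
  storage.mode(x) <- "double"
  if (anyNA(x)) {
    mu <- colMeans(x, na.rm = TRUE)
    na <- which(is.na(x), arr.ind = TRUE)
    x[na] <- mu[na[, 2L]]
  }
  p <- colMeans(x) / 2
  poly <- p > 0 & p < 1
  .assert(any(poly), "no polymorphic SNPs left after filtering")
  x <- x[, poly, drop = FALSE]
  p <- p[poly]
  z <- sweep(x, 2L, 2 * p, "-")
  z <- sweep(z, 2L, sqrt(2 * p * (1 - p)), "/")
  m <- ncol(z)
  A <- tcrossprod(z) / m
  A <- (A + t(A)) / 2
  structure(list(values = A, n_snps = m, sample_ids = geno$sample_ids),
            class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  cat(sprintf("grm: %d individuals, built from %d SNPs (mean diagonal %.4f)\n",
              nrow(x$values), x$n_snps, mean(diag(x$values))))
  invisible(x)
}

#' Read and write GRMs in the GCTA binary triple format
#'
#' The format comprises `<prefix>.grm.bin` (lower-triangle values including
#' the diagonal, row by row, little-endian float32), `<prefix>.grm.N.bin`
#' (the per-pair SNP count, float32) and `<prefix>.grm.id` (tab-separated
#' FID/IID text). Values are stored in single precision, so a written matrix
#' re-reads bit-identically but equals the in-memory double-precision matrix
#' only to float32 resolution.
#'
#' @param grm A `"grm"` object.
#' @param prefix Path prefix for the three files.
#' @return `write_gcta_grm` returns `prefix` invisibly; `read_gcta_grm`
#'   returns a `"grm"` object.
#' @export
write_gcta_grm <- function(grm, prefix) {
  .assert(inherits(grm, "grm"), "'grm' must be a grm object")
  n <- nrow(grm$values)
  lt <- grm$values[upper.tri(grm$values, diag = TRUE)]
  ## upper triangle by column == lower triangle by row
  con <- file(paste0(prefix, ".grm.bin"), "wb")
  writeBin(as.numeric(lt), con, size = 4L, endian = "little")
  close(con)
  con <- file(paste0(prefix, ".grm.N.bin"), "wb")
  writeBin(rep(as.numeric(grm$n_snps), length(lt)), con, size = 4L,
           endian = "little")
  close(con)
  utils::write.table(data.frame(grm$sample_ids, grm$sample_ids),
                     paste0(prefix, ".grm.id"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' @rdname write_gcta_grm
#' @export
read_gcta_grm <- function(prefix) {
  ids <- utils::read.table(paste0(prefix, ".grm.id"), header = FALSE,
                           stringsAsFactors = FALSE)
  n <- nrow(ids)
  npair <- n * (n + 1) / 2
  con <- file(paste0(prefix, ".grm.bin"), "rb")
  lt <- readBin(con, "numeric", n = npair, size = 4L, endian = "little")
  close(con)
  .assert(length(lt) == npair, "truncated .grm.bin file")
  con <- file(paste0(prefix, ".grm.N.bin"), "rb")
  nsnp <- readBin(con, "numeric", n = npair, size = 4L, endian = "little")
  close(con)
  A <- matrix(0, n, n)
  A[upper.tri(A, diag = TRUE)] <- lt
  A <- A + t(A) - diag(diag(A))
  dimnames(A) <- list(ids[[2L]], ids[[2L]])
  structure(list(values = A, n_snps = round(nsnp[1L]),
                 sample_ids = as.character(ids[[2L]])),
            class = "grm")
}
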