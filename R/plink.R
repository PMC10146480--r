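#' Write genotypes in PLINK 1 binary format
#'
#' Writes the SNP-major `.bed` (magic bytes `6c 1b 01`; per SNP, individuals
#' packed four to a byte, first individual in the lowest-order bits; code
#' `00` = homozygous A1, `10` = heterozygous, `11` = homozygous A2, `01` =
#' missing), the `.bim` (chrom, id, 0 cM, bp, A1, A2) and the `.fam`
#' (FID IID 0 0 sex pheno) files. Dosages count the A1 allele.
#'
#' @param geno A [genotype_matrix()].
#' @param prefix Output path prefix.
#' @param cohort Optional `cohort_table` supplying sex (written as 1 =
#'   male, 2 = female from the 0/1 code) and disease status (written as
#'   1 = control, 2 = case); otherwise both are written as missing.
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(geno, prefix, cohort = NULL) {
  .assert(inherits(geno, "genotype_matrix"), "'geno' must be a genotype_matrix")
  n <- nrow(geno$dosages); m <- ncol(geno$dosages)
  ## dosage (A1 count) -> 2-bit code
  codes <- matrix(3L, n, m)                       # 0 copies of A1
  codes[geno$dosages == 1L] <- 2L                 # het
  codes[geno$dosages == 2L] <- 0L                 # 2 copies of A1
  codes[is.na(geno$dosages)] <- 1L                # missing
  pad <- (4L - n %% 4L) %% 4L
  if (pad > 0) codes <- rbind(codes, matrix(0L, pad, m))
  dim(codes) <- c(4L, (n + pad) / 4L, m)
  bytes <- codes[1L, , ] + 4L * codes[2L, , ] + 16L * codes[3L, , ] +
    64L * codes[4L, , ]
  con <- file(paste0(prefix, ".bed"), "wb")
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(as.raw(bytes), con)
  close(con)

  bim <- data.frame(geno$snp_meta$chrom, geno$snp_meta$snp_id, 0L,
                    geno$snp_meta$pos_bp, geno$snp_meta$a1, geno$snp_meta$a2)
  utils::write.table(bim, paste0(prefix, ".bim"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)

  sex <- rep(0L, n); pheno <- rep(-9L, n)
  if (!is.null(cohort)) {
    i <- match(geno$sample_ids, cohort$sample_id)
    sex <- ifelse(is.na(i), 0L, cohort$sex[i] + 1L)
    pheno <- ifelse(is.na(i), -9L, cohort$status[i] + 1L)
  }
  fam <- data.frame(geno$sample_ids, geno$sample_ids, 0L, 0L, sex, pheno)
  utils::write.table(fam, paste0(prefix, ".fam"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' Read PLINK 1 binary genotypes
#'
#' @param prefix Path prefix of the `.bed`/`.bim`/`.fam` triple.
#' @return A list with `geno` (a [genotype_matrix()], dosages counting the
#'   A1 allele) and `fam` (the six-column .fam table with columns `fid`,
#'   `iid`, `pat`, `mat`, `sex`, `pheno`).
#' @export
read_plink <- function(prefix) {
  bim <- utils::read.table(paste0(prefix, ".bim"), header = FALSE,
                           stringsAsFactors = FALSE,
                           col.names = c("chrom", "snp_id", "cm", "pos_bp",
                                         "a1", "a2"))
  fam <- utils::read.table(paste0(prefix, ".fam"), header = FALSE,
                           stringsAsFactors = FALSE,
                           col.names = c("fid", "iid", "pat", "mat", "sex",
                                         "pheno"))
  n <- nrow(fam); m <- nrow(bim)
  bpr <- ceiling(n / 4)
  con <- file(paste0(prefix, ".bed"), "rb")
  magic <- readBin(con, "raw", 3L)
  .assert(identical(as.integer(magic), c(108L, 27L, 1L)),
          "not a SNP-major PLINK 1 .bed file")
  raw <- readBin(con, "raw", bpr * m)
  close(con)
  .assert(length(raw) == bpr * m, "truncated .bed file")
  b <- as.integer(raw)
  ## unpack 4 individuals per byte, low bits first
  codes <- rbind(b %% 4L, (b %/% 4L) %% 4L, (b %/% 16L) %% 4L, b %/% 64L)
  dim(codes) <- c(4L * bpr, m)
  codes <- codes[seq_len(n), , drop = FALSE]
  dos <- matrix(NA_integer_, n, m)
  dos[codes == 0L] <- 2L
  dos[codes == 2L] <- 1L
  dos[codes == 3L] <- 0L
  meta <- bim[, c("chrom", "snp_id", "pos_bp", "a1", "a2")]
  list(geno = genotype_matrix(dos, meta, sample_ids = as.character(fam$iid)),
       fam = fam)
}

#' Read and write PLINK-style phenotype and covariate files
#'
#' The phenotype file is `FID IID status` (0 = control, 1 = case) and the
#' covariate file is `FID IID sex age`, both tab-separated without headers.
#'
#' @param cohort A `cohort_table`.
#' @param path Output file.
#' @return Writers return `path` invisibly; readers return a data frame.
#' @export
write_phenotype <- function(cohort, path) {
  utils::write.table(data.frame(cohort$sample_id, cohort$sample_id,
                                cohort$status),
                     path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_phenotype
#' @export
write_covariates <- function(cohort, path) {
  utils::write.table(data.frame(cohort$sample_id, cohort$sample_id,
                                cohort$sex, cohort$age_years),
                     path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_phenotype
#' @export
read_phenotype <- function(path) {
  utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                    col.names = c("fid", "sample_id", "status"))
}

#' @rdname write_phenotype
#' @export
read_covariates <- function(path) {
  utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                    col.names = c("fid", "sample_id", "sex", "age_years"))
}
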