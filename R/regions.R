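#' Genomic region sets for SNP filtering
#'
#' A region set is a list of `(chromosome, start_bp, end_bp)` intervals,
#' 1-based and inclusive at both ends, with union semantics (intervals may
#' overlap). The APOE exclusion region chr19:44,400,000-46,500,000 used for
#' late-onset Alzheimer's analyses is available as [apoe_region()].
#'
#' @param chrom Integer or character chromosome codes.
#' @param start_bp,end_bp 1-based inclusive interval bounds, `start_bp <=
#'   end_bp`.
#' @param label Optional label for the set.
#' @return An object of class `"region_set"` (a data frame).
#' @export
region_set <- function(chrom, start_bp, end_bp, label = "regions") {
  .assert(length(chrom) == length(start_bp) && length(chrom) == length(end_bp),
          "chrom, start_bp, end_bp must have the same length")
  .assert(all(start_bp <= end_bp), "start_bp must be <= end_bp")
  structure(data.frame(chrom = chrom, start_bp = as.numeric(start_bp),
                       end_bp = as.numeric(end_bp), stringsAsFactors = FALSE),
            label = label, class = c("region_set", "data.frame"))
}

#' @rdname region_set
#' @export
apoe_region <- function() {
  region_set(19L, 44.4e6, 46.5e6, label = "APOE")
}

#' Read and write region sets as BED files
#'
#' BED intervals are 0-based, half-open; they are converted to the package's
#' 1-based inclusive convention on read (`start + 1`, `end`) and back on
#' write. Only the first three columns are used.
#'
#' @param path File path.
#' @param label Label for the resulting set.
#' @return `read_bed_regions` returns a [region_set()]; `write_bed_regions`
#'   returns `path` invisibly.
#' @export
read_bed_regions <- function(path, label = basename(path)) {
  bed <- utils::read.table(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE)
  .assert(ncol(bed) >= 3L, "BED file needs at least 3 columns")
  chrom <- sub("^chr", "", as.character(bed[[1L]]))
  suppressWarnings(chrom_i <- as.integer(chrom))
  if (!anyNA(chrom_i)) chrom <- chrom_i
  region_set(chrom, as.numeric(bed[[2L]]) + 1, as.numeric(bed[[3L]]),
             label = label)
}

#' @rdname read_bed_regions
#' @param regions A [region_set()].
#' @export
write_bed_regions <- function(regions, path) {
  .assert(inherits(regions, "region_set"), "'regions' must be a region_set")
  df <- data.frame(chrom = regions$chrom,
                   start = format(regions$start_bp - 1, scientific = FALSE, trim = TRUE),
                   end = format(regions$end_bp, scientific = FALSE, trim = TRUE))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Exclude SNPs falling inside genomic regions
#'
#' Returns the ids of SNPs whose position lies outside every interval of the
#' region set after expanding each interval by `flank_bp` on both sides.
#' Containment is 1-based inclusive: a SNP exactly at an (expanded) boundary
#' is excluded.
#'
#' @param snp_meta SNP metadata with columns `chrom`, `pos_bp`, `snp_id`.
#' @param regions A [region_set()] (possibly empty or `NULL`, which keeps
#'   all SNPs).
#' @param flank_bp Flank added to each side of every interval (e.g. 5e5 for
#'   the 0.5 Mb windows around GWAS hits).
#' @return Character vector of retained SNP ids, in input order.
#' @export
exclude_regions <- function(snp_meta, regions, flank_bp = 0) {
  if (is.null(regions) || nrow(regions) == 0L) return(snp_meta$snp_id)
  .assert(inherits(regions, "region_set"), "'regions' must be a region_set")
  drop <- rep(FALSE, nrow(snp_meta))
  for (i in seq_len(nrow(regions))) {
    drop <- drop | (snp_meta$chrom == regions$chrom[i] &
                      snp_meta$pos_bp >= regions$start_bp[i] - flank_bp &
                      snp_meta$pos_bp <= regions$end_bp[i] + flank_bp)
  }
  snp_meta$snp_id[!drop]
}
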