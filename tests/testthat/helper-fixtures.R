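# small in-code fixture builders shared across test files

# genotype_matrix from a literal dosage matrix
make_geno <- function(dosages, chrom = 1L, pos_bp = NULL) {
  dosages <- as.matrix(dosages)
  m <- ncol(dosages)
  if (is.null(pos_bp)) pos_bp <- 1000L * seq_len(m)
  meta <- data.frame(chrom = if (length(chrom) == 1L) rep(chrom, m) else chrom,
                     snp_id = sprintf("s%03d", seq_len(m)),
                     pos_bp = pos_bp, a1 = "A", a2 = "C",
                     stringsAsFactors = FALSE)
  genotype_matrix(dosages, meta)
}

# naive O(N^2 M) GRM: the independent oracle for compute_grm
grm_naive <- function(dosages) {
  x <- as.matrix(dosages)
  p <- colMeans(x) / 2
  keep <- p > 0 & p < 1
  x <- x[, keep, drop = FALSE]; p <- p[keep]
  n <- nrow(x); m <- ncol(x)
  A <- matrix(0, n, n)
  for (j in seq_len(n)) for (k in seq_len(n)) {
    s <- 0
    for (i in seq_len(m))
      s <- s + (x[j, i] - 2 * p[i]) * (x[k, i] - 2 * p[i]) / (2 * p[i] * (1 - p[i]))
    A[j, k] <- s / m
  }
  A
}

# direct dense evaluation of the restricted log-likelihood (same
# dropped-constant convention as the fitting engine), used as grid oracle
reml_loglik_direct <- function(sg, se, y, X, A) {
  n <- length(y)
  V <- sg * A + se * diag(n)
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  b <- solve(XtViX, t(X) %*% Vi %*% y)
  Py <- Vi %*% y - Vi %*% X %*% b
  as.numeric(-0.5 * (determinant(V)$modulus + determinant(XtViX)$modulus +
                       t(y) %*% Py))
}

# a small polygenic case-control cohort for REML tests
make_signal_cohort <- function(n = 300, m = 400, h2 = 0.5, seed = 1) {
  g <- simulate_genotypes(n, m, maf_range = c(0.05, 0.5), ld_rho = 0,
                          seed = seed)
  arch <- architecture(h2_liability = h2, major_locus_share = 0,
                       geneset_h2_share = 0, geneset_snp_fraction = 0,
                       n_causal = m)
  eff <- draw_effects(g$snp_meta, arch, seed = seed + 1)
  pop <- simulate_liability_onset(g, eff, seed = seed + 2)
  list(geno = g, pop = pop, effects = eff)
}
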