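#' Genetic architecture specification for simulated cohorts
#'
#' Describes how liability-scale genetic variance is distributed across a
#' major-effect locus (an APOE-like region), a concentrated gene-set (a
#' microglia-like set occupying a few percent of SNPs), and a polygenic
#' background. Variance shares are fractions of the total genetic variance
#' and must not exceed 1 jointly; the background receives the remainder.
#'
#' @param h2_liability Total narrow-sense heritability of liability, in
#'   `[0, 1]`. Liability is normalized to unit total variance, so the
#'   environmental standard deviation is derived as `sqrt(1 - h2_liability)`.
#' @param major_locus_share Fraction of genetic variance carried by the single
#'   major locus. The default 0.24 puts 12 percentage points of a 0.5
#'   liability heritability on the locus, matching the average drop seen when
#'   the dominant late-onset Alzheimer's locus region is excluded.
#' @param geneset_snp_fraction Fraction of SNPs belonging to the gene-set
#'   (default 0.03, i.e. about 3% of SNPs).
#' @param geneset_h2_share Fraction of genetic variance carried jointly by
#'   gene-set SNPs (default 0.60).
#' @param n_causal Number of causal SNPs, or `NULL` to use 10% of SNPs
#'   (at least 50) at draw time.
#' @param maf_range Length-2 numeric, lower and upper bound for simulated
#'   minor allele frequencies; must lie in `(0, 0.5]`.
#' @return An object of class `"architecture"`.
#' @seealso [draw_effects()], [simulate_cohort()]
#' @export
architecture <- function(h2_liability = 0.5,
                         major_locus_share = 0.24,
                         geneset_snp_fraction = 0.03,
                         geneset_h2_share = 0.60,
                         n_causal = NULL,
                         maf_range = c(0.01, 0.5)) {
  .assert(is.numeric(h2_liability) && h2_liability >= 0 && h2_liability <= 1,
          "'h2_liability' must be in [0, 1]")
  shares <- c(major_locus_share, geneset_h2_share, geneset_snp_fraction)
  .assert(all(is.numeric(shares)) && all(shares >= 0) && all(shares <= 1),
          "variance shares and SNP fractions must be in [0, 1]")
  .assert(major_locus_share + geneset_h2_share <= 1 + 1e-12,
          "major_locus_share + geneset_h2_share must not exceed 1")
  .assert(length(maf_range) == 2L && maf_range[1] > 0 && maf_range[2] <= 0.5 &&
            maf_range[1] <= maf_range[2],
          "'maf_range' must lie in (0, 0.5]")
  structure(list(
    h2_liability = h2_liability,
    major_locus_share = major_locus_share,
    geneset_snp_fraction = geneset_snp_fraction,
    geneset_h2_share = geneset_h2_share,
    background_share = 1 - major_locus_share - geneset_h2_share,
    n_causal = n_causal,
    maf_range = maf_range
  ), class = "architecture")
}

#' @export
print.architecture <- function(x, ...) {
  cat("Simulated genetic architecture\n")
  cat(sprintf("  liability h2      : %.3f\n", x$h2_liability))
  cat(sprintf("  major locus share : %.3f\n", x$major_locus_share))
  cat(sprintf("  gene-set share    : %.3f (on %.1f%% of SNPs)\n",
              x$geneset_h2_share, 100 * x$geneset_snp_fraction))
  cat(sprintf("  background share  : %.3f\n", x$background_share))
  invisible(x)
}

#' Age-dependent onset model for a late-onset disease
#'
#' A liability-threshold model in which the threshold decreases with age,
#' equivalently the cumulative prevalence K(a) increases with age. K is
#' interpolated log-linearly between anchor (age, prevalence) pairs. The
#' default anchors place 2% prevalence at age 65, 5% at 75 and 15% at 85,
#' the three prevalences commonly used when rescaling late-onset Alzheimer's
#' heritability to the liability scale.
#'
#' The model is a stand-in for an unknown true liability-to-onset process:
#' it is exact at the anchors and log-linear in between, and it is the single
#' place where age enters the simulations.
#'
#' @param anchors Two-column matrix or data frame of (age, prevalence) pairs;
#'   prevalences must be strictly increasing with age and lie in (0, 1).
#' @return An object of class `"age_onset_model"` with elements `anchors`,
#'   and functions `K(age)` (cumulative prevalence), `threshold(age)`
#'   (liability threshold `qnorm(1 - K)`), and `onset_age(liability)`.
#' @seealso [prevalence_for_age()], [simulate_liability_onset()]
#' @export
age_onset_model <- function(anchors = cbind(age = c(65, 75, 85),
                                            prevalence = c(0.02, 0.05, 0.15))) {
  anchors <- as.matrix(anchors)
  .assert(ncol(anchors) == 2L && nrow(anchors) >= 2L,
          "'anchors' needs at least two (age, prevalence) rows")
  o <- order(anchors[, 1L])
  age <- anchors[o, 1L]
  K <- anchors[o, 2L]
  .assert(all(K > 0 & K < 1), "anchor prevalences must lie in (0, 1)")
  .assert(all(diff(age) > 0), "anchor ages must be distinct")
  .assert(all(diff(K) > 0), "prevalence must increase with age")
  logK <- log(K)
  Kfun <- function(a) {
    exp(stats::approx(age, logK, xout = pmin(pmax(a, age[1L]), age[length(age)]),
                      method = "linear", rule = 2)$y)
  }
  tfun <- function(a) stats::qnorm(1 - Kfun(a))
  onset <- function(liability) {
    ## smallest age at which threshold(age) <= liability; K is increasing so
    ## this is the age where K(a) first reaches 1 - pnorm(liability)
    q <- stats::pnorm(liability, lower.tail = FALSE)
    out <- stats::approx(logK, age, xout = log(q), method = "linear",
                         rule = 2, ties = "ordered")$y
    out[q > K[length(K)]] <- NA_real_   # threshold never reached in range
    out[q <= K[1L]] <- age[1L]          # already above threshold at youngest anchor
    out
  }
  structure(list(anchors = cbind(age = age, prevalence = K),
                 K = Kfun, threshold = tfun, onset_age = onset),
            class = "age_onset_model")
}

#' @export
print.age_onset_model <- function(x, ...) {
  cat("Age-dependent liability-threshold onset model\n")
  a <- x$anchors
  for (i in seq_len(nrow(a)))
    cat(sprintf("  age %3g : K = %.3f (threshold %.3f)\n",
                a[i, 1], a[i, 2], stats::qnorm(1 - a[i, 2])))
  invisible(x)
}

#' Cumulative disease prevalence at a given age
#'
#' Evaluates the age-specific cumulative prevalence K(age) of an onset model,
#' used to choose the population prevalence matching the mean age of cases
#' when converting heritability to the liability scale.
#'
#' @param onset_model An [age_onset_model()].
#' @param age Numeric vector of ages. Ages outside the anchor range are
#'   clamped to the nearest anchor with a warning.
#' @return Numeric vector of prevalences.
#' @export
prevalence_for_age <- function(onset_model, age) {
  .assert(inherits(onset_model, "age_onset_model"),
          "'onset_model' must be an age_onset_model")
  rng <- range(onset_model$anchors[, "age"])
  if (any(age < rng[1] | age > rng[2]))
    warning("age outside anchor range [", rng[1], ", ", rng[2],
            "]; prevalence clamped to the nearest anchor")
  onset_model$K(age)
}
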