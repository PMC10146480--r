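#' Simulate liabilities, onset ages and current ages for a population
#'
#' Builds each individual's liability as the standardized-genotype score plus
#' independent Gaussian noise, assigns the onset age as the youngest age at
#' which liability exceeds the age-varying threshold of the onset model, and
#' draws a current (assessment) age from `age_dist`. Disease status is 1 when
#' onset has already occurred by the current age.
#'
#' Liability is normalized to unit total variance: the environmental standard
#' deviation defaults to `sqrt(1 - h2)` with `h2 = sum(beta_std^2)`, and by
#' default the realized genetic score is rescaled to variance exactly `h2`
#' so that the realized variance decomposition matches the architecture.
#' Because higher-liability individuals cross the threshold younger, risk
#' allele frequency among still-unaffected individuals declines with age.
#'
#' @param geno A [genotype_matrix()].
#' @param effects Output of [draw_effects()], aligned to `geno`'s SNPs.
#' @param onset_model An [age_onset_model()].
#' @param age_dist Function `n -> ages` for current ages; default uniform on
#'   60 to 90 years.
#' @param env_sd Environmental standard deviation; derived from the effects
#'   when `NULL`.
#' @param exact_scale Rescale the genetic score to its target variance
#'   (default `TRUE`).
#' @param seed Optional integer seed.
#' @return A `cohort_table` data frame with columns `sample_id`, `status`,
#'   `sex`, `age_years`, `liability_true`, `onset_age_years`,
#'   `genetic_score`. Sex is a balanced 0/1 covariate with no effect on
#'   liability.
#' @export
simulate_liability_onset <- function(geno, effects, onset_model = age_onset_model(),
                                     age_dist = function(n) stats::runif(n, 60, 90),
                                     env_sd = NULL, exact_scale = TRUE,
                                     seed = NULL) {
  .assert(inherits(geno, "genotype_matrix"), "'geno' must be a genotype_matrix")
  .assert(nrow(effects) == ncol(geno$dosages),
          "'effects' must align with the SNPs of 'geno'")
  .assert(all(effects$snp_id == geno$snp_meta$snp_id),
          "'effects' rows must match geno$snp_meta SNP order")
  beta <- effects$beta_std
  h2 <- sum(beta^2)
  .assert(h2 <= 1 + 1e-8, "total genetic variance exceeds 1")
  .with_seed(seed, {
    n <- nrow(geno$dosages)
    ## standardized-genotype score without materializing the scaled matrix
    p <- colMeans(geno$dosages) / 2
    sds <- sqrt(2 * p * (1 - p))
    w <- ifelse(sds > 0, beta / sds, 0)
    g <- as.numeric(geno$dosages %*% w) - sum(2 * p * w)
    if (exact_scale && h2 > 0 && stats::sd(g) > 0) {
      g <- (g - mean(g)) * sqrt(h2) / stats::sd(g)
    }
    if (is.null(env_sd)) env_sd <- sqrt(max(0, 1 - h2))
    liab <- g + stats::rnorm(n, 0, env_sd)
    onset <- onset_model$onset_age(liab)
    age <- age_dist(n)
    status <- as.integer(!is.na(onset) & onset <= age)
    out <- data.frame(sample_id = geno$sample_ids,
                      status = status,
                      sex = stats::rbinom(n, 1L, 0.5),
                      age_years = age,
                      liability_true = liab,
                      onset_age_years = onset,
                      genetic_score = g,
                      stringsAsFactors = FALSE)
    structure(out, class = c("cohort_table", "data.frame"),
              h2_true = h2, env_sd = env_sd)
  })
}
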