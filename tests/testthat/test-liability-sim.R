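test_that("population case rate at age a matches K(a)", {
  om <- age_onset_model()
  sc <- make_signal_cohort(n = 5000, m = 300, h2 = 0.5, seed = 20)
  for (a in c(70, 80)) {
    pop <- simulate_liability_onset(sc$geno, sc$effects, onset_model = om,
                                    age_dist = function(n) rep(a, n),
                                    seed = 21)
    K <- om$K(a)
    tol <- 4 * sqrt(K * (1 - K) / 5000)
    expect_lt(abs(mean(pop$status) - K), tol)
  }
})

test_that("liability variance decomposition matches the architecture", {
  sc <- make_signal_cohort(n = 5000, m = 400, h2 = 0.5, seed = 22)
  pop <- simulate_liability_onset(sc$geno, sc$effects, seed = 23)
  ratio <- var(pop$genetic_score) / var(pop$liability_true)
  expect_lt(abs(ratio - 0.5), 0.02)
})

test_that("with zero genetic variance onset is independent of genotype", {
  g <- simulate_genotypes(3000, 100, seed = 24)
  arch <- architecture(h2_liability = 0, major_locus_share = 0,
                       geneset_h2_share = 0, geneset_snp_fraction = 0)
  eff <- draw_effects(g$snp_meta, arch, seed = 25)
  pop <- simulate_liability_onset(g, eff, seed = 26)
  expect_true(all(pop$genetic_score == 0))
  # onset age unrelated to an overall genotype burden score
  burden <- rowMeans(scale(g$dosages))
  has_onset <- !is.na(pop$onset_age_years)
  fit <- lm(pop$onset_age_years[has_onset] ~ burden[has_onset])
  expect_gt(summary(fit)$coefficients[2, 4], 0.001)  # slope not significant
})

test_that("risk-allele frequency declines with age among the unaffected", {
  sc <- make_signal_cohort(n = 8000, m = 300, h2 = 0.5, seed = 27)
  pop <- simulate_liability_onset(sc$geno, sc$effects, seed = 28)
  beta <- sc$effects$beta_std
  causal <- which(beta != 0)
  raf <- function(rows) {
    f <- colMeans(sc$geno$dosages[rows, causal, drop = FALSE]) / 2
    mean(ifelse(beta[causal] > 0, f, 1 - f))
  }
  unaff_young <- which(pop$status == 0 & pop$age_years < 70)
  unaff_old <- which(pop$status == 0 & pop$age_years > 82)
  expect_gt(raf(unaff_young), raf(unaff_old))
})

test_that("onset model interpolation honours its anchors and monotonicity", {
  om <- age_onset_model()
  expect_equal(om$K(65), 0.02)
  expect_equal(om$K(75), 0.05)
  expect_equal(om$K(85), 0.15)
  ages <- seq(65, 85, by = 0.5)
  expect_true(all(diff(om$K(ages)) > 0))
  expect_true(all(diff(om$threshold(ages)) < 0))
  # onset age inverts the threshold: liability exactly at threshold(a) onsets at a
  for (a in c(68, 75, 81)) {
    expect_equal(om$onset_age(om$threshold(a)), a, tolerance = 1e-8)
  }
  # extreme liabilities: clamped to youngest anchor or never onsetting
  expect_equal(om$onset_age(10), 65)
  expect_true(is.na(om$onset_age(-10)))
})
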