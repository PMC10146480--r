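# deterministic toy population with known onsets
toy_population <- function() {
  structure(data.frame(
    sample_id = sprintf("p%02d", 1:10),
    status = 0L, sex = rep(0:1, 5),
    age_years = rep(75, 10),
    liability_true = 0,
    onset_age_years = c(66, 70, 74, 78, 82, NA, NA, NA, NA, NA),
    genetic_score = 0, stringsAsFactors = FALSE),
    class = c("cohort_table", "data.frame"))
}

test_that("screened, age-matched ascertainment labels match truth exactly", {
  pop <- toy_population()
  coh <- ascertain(pop, n_cases = 3, n_controls = 3,
                   case_age_dist = function(n) rep(85, n),
                   control_age_dist = function(n) rep(85, n),
                   screened = TRUE, seed = 1)
  cases <- coh[coh$status == 1, ]
  ctls <- coh[coh$status == 0, ]
  expect_true(all(cases$onset_age_years <= cases$age_years))
  expect_true(all(is.na(ctls$onset_age_years)))
  expect_equal(attr(coh, "latent_case_fraction"), 0)
})

test_that("unscreened young controls include latent cases and report the fraction", {
  sc <- make_signal_cohort(n = 4000, m = 100, h2 = 0.5, seed = 30)
  pop <- simulate_liability_onset(sc$geno, sc$effects, seed = 31)
  coh <- ascertain(pop, n_cases = 300, n_controls = 300,
                   case_age_dist = function(n) rep(85, n),
                   control_age_dist = function(n) runif(n, 50, 60),
                   screened = FALSE, seed = 32)
  ctls <- coh[coh$status == 0, ]
  frac <- mean(!is.na(ctls$onset_age_years))
  expect_gt(frac, 0)
  expect_equal(attr(coh, "latent_case_fraction"), frac)
  # every control is symptom-free at its assessment age
  lat <- ctls[!is.na(ctls$onset_age_years), ]
  expect_true(all(lat$onset_age_years > lat$age_years))
})

test_that("misdiagnosis relabels the requested fraction of cases", {
  sc <- make_signal_cohort(n = 4000, m = 100, h2 = 0.5, seed = 33)
  pop <- simulate_liability_onset(sc$geno, sc$effects, seed = 34)
  coh <- ascertain(pop, n_cases = 200, n_controls = 200,
                   case_age_dist = function(n) rep(85, n),
                   control_age_dist = function(n) rep(85, n),
                   screened = TRUE, misdiagnosis_rate = 0.3, seed = 35)
  cases <- coh[coh$status == 1, ]
  not_onset <- is.na(cases$onset_age_years) |
    cases$onset_age_years > cases$age_years
  expect_equal(sum(not_onset), round(0.3 * 200))
  expect_equal(length(attr(coh, "misdiagnosed_ids")), 60)
})

test_that("infeasible requests fail with the offending stratum named", {
  pop <- toy_population()
  expect_error(ascertain(pop, n_cases = 8, n_controls = 1,
                         case_age_dist = function(n) rep(85, n),
                         seed = 2),
               "stratum: cases")
  expect_error(ascertain(pop, n_cases = 1, n_controls = 8,
                         case_age_dist = function(n) rep(85, n),
                         control_age_dist = function(n) rep(85, n),
                         screened = TRUE, seed = 3),
               "stratum: controls")
})
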