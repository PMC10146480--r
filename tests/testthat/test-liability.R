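test_that("the GR@ACE worked example reproduces", {
  P_actual <- uplift_case_proportion(0.56, 0.15)
  expect_equal(P_actual, 0.626)
  # agrees with the reported two-decimal value 0.62 at printed precision
  expect_lt(abs(P_actual - 0.62), 0.01)
  expect_equal(round(observed_to_liability(0.30, K = 0.15, P = P_actual), 2),
               0.38)
})

test_that("uplift arithmetic and edge cases", {
  expect_equal(uplift_case_proportion(0.5, 0.5), 0.75)
  expect_equal(uplift_case_proportion(0.4, 0), 0.4)
  expect_error(uplift_case_proportion(0, 0.1), "P")
  expect_error(uplift_case_proportion(0.5, 1), "f")
})

test_that("P = K reduces to the classic unascertained transform", {
  for (K in c(0.02, 0.05, 0.15, 0.3)) {
    t <- qnorm(1 - K); z <- dnorm(t)
    classic <- 0.4 * K * (1 - K) / z^2     # independent computation
    expect_equal(observed_to_liability(0.4, K, K), classic, tolerance = 1e-12)
  }
})

test_that("transform round-trips through its algebraic inverse", {
  grid <- expand.grid(h2 = c(0.05, 0.3, 0.8), K = c(0.02, 0.05, 0.15),
                      P = c(0.3, 0.5, 0.626))
  for (i in seq_len(nrow(grid))) {
    h2l <- observed_to_liability(grid$h2[i], grid$K[i], grid$P[i])
    back <- liability_to_observed(h2l, grid$K[i], grid$P[i])
    expect_equal(back, grid$h2[i], tolerance = 1e-12)
  }
})

test_that("transform is monotone in its arguments", {
  # increasing in h2_obs
  h <- observed_to_liability(seq(0.1, 0.6, by = 0.1), 0.05, 0.5)
  expect_true(all(diff(h) > 0))
  # increasing in K on (0, 0.5) for fixed h2, P
  Ks <- seq(0.01, 0.45, by = 0.02)
  hk <- observed_to_liability(0.3, Ks, 0.5)
  expect_true(all(diff(hk) > 0))
  # maximal where P(1-P) is smallest: moving P away from 0.5 increases h2_l
  hp <- observed_to_liability(0.3, 0.05, c(0.5, 0.6, 0.7, 0.8))
  expect_true(all(diff(hp) > 0))
  expect_equal(observed_to_liability(0, 0.1, 0.4), 0)
})

test_that("domain errors are raised at the boundaries", {
  expect_error(observed_to_liability(0.3, 0, 0.5), "K")
  expect_error(observed_to_liability(0.3, 1, 0.5), "K")
  expect_error(observed_to_liability(0.3, 0.1, 0), "P")
  expect_error(observed_to_liability(-0.1, 0.1, 0.5), "h2_obs")
})

test_that("liability_spec is internally consistent", {
  sp <- liability_spec(K = 0.15, P = 0.56, control_conversion = 0.15)
  expect_equal(pnorm(sp$t, lower.tail = FALSE), sp$K, tolerance = 1e-12)
  expect_equal(dnorm(sp$t), sp$z, tolerance = 1e-12)
  expect_equal(sp$P_actual, 0.626)
  expect_gt(sp$P_actual, 0); expect_lt(sp$P_actual, 1)
})

test_that("prevalence_for_age reproduces anchors and clamps outside range", {
  om <- age_onset_model()
  expect_equal(prevalence_for_age(om, 75), 0.05)
  expect_equal(prevalence_for_age(om, 85), 0.15)
  expect_true(prevalence_for_age(om, 70) <= prevalence_for_age(om, 80))
  expect_warning(res <- prevalence_for_age(om, 50), "clamped")
  expect_equal(res, 0.02)
})
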