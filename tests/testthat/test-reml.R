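test_that("AI-REML matches a dense grid search of the restricted likelihood", {
  set.seed(80)
  g <- simulate_genotypes(12, 40, maf_range = c(0.1, 0.5), seed = 80)
  A <- compute_grm(g)
  y <- as.numeric(scale(A$values %*% rnorm(12) + rnorm(12)))
  X <- matrix(1, 12, 1)
  fit <- reml_fit(y, X, A, method = "dense", tol = 1e-10)
  # independent oracle: direct evaluation over a parameter grid
  sg <- seq(0.01, 1.5, length.out = 60)
  se <- seq(0.01, 1.5, length.out = 60)
  ll <- outer(sg, se, Vectorize(function(a, b)
    reml_loglik_direct(a, b, y, X, A$values)))
  best <- which(ll == max(ll), arr.ind = TRUE)[1, ]
  step <- sg[2] - sg[1]
  expect_lt(abs(fit$sigma2[1] - sg[best[1]]), 1.5 * step)
  expect_lt(abs(fit$sigma2[2] - se[best[2]]), 1.5 * step)
  expect_gte(fit$loglik, max(ll) - 1e-6)
  # and the engine's likelihood agrees with the direct formula at the optimum
  expect_equal(fit$loglik,
               reml_loglik_direct(fit$sigma2[1], fit$sigma2[2], y, X,
                                  A$values),
               tolerance = 1e-8)
})

test_that("spectral and dense paths agree on the same problem", {
  set.seed(81)
  g <- simulate_genotypes(120, 150, ld_rho = 0.5, seed = 81)
  A <- compute_grm(g)
  y <- as.numeric(A$values %*% rnorm(120) * 0.2 + rnorm(120))
  X <- cbind(1, rnorm(120))
  f1 <- reml_fit(y, X, A, method = "spectral", tol = 1e-9)
  f2 <- reml_fit(y, X, A, method = "dense", tol = 1e-9)
  expect_equal(f1$sigma2, f2$sigma2, tolerance = 1e-4)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-6)
  expect_equal(f1$fixef, f2$fixef, tolerance = 1e-5)
  expect_equal(f1$h2_obs, f2$h2_obs, tolerance = 1e-4)
})

test_that("a null phenotype yields a near-zero estimate and sane LRT", {
  set.seed(82)
  g <- simulate_genotypes(500, 300, ld_rho = 0, seed = 82)
  A <- compute_grm(g)
  y <- rbinom(500, 1, 0.5)
  fit <- reml_fit(y, matrix(1, 500, 1), A)
  expect_lt(fit$h2_obs, 0.25)
  expect_gte(fit$loglik, fit$loglik_null - 1e-6)
  expect_gte(fit$p_lrt, 0)
  expect_lte(fit$p_lrt, 1)
  expect_true(all(fit$sigma2 >= 0))
})

test_that("an identity GRM is flagged as non-identifiable", {
  set.seed(83)
  y <- rnorm(60)
  I_grm <- structure(list(values = diag(60), n_snps = 100L,
                          sample_ids = sprintf("i%02d", 1:60)),
                     class = "grm")
  expect_warning(fit <- reml_fit(y, matrix(1, 60, 1), I_grm),
                 "near-singular")
  expect_true(fit$singular_ai)
})

test_that("non-convergence is flagged, not thrown", {
  set.seed(84)
  g <- simulate_genotypes(80, 100, seed = 84)
  A <- compute_grm(g)
  y <- rnorm(80)
  expect_warning(fit <- reml_fit(y, matrix(1, 80, 1), A, max_iter = 2),
                 "did not converge")
  expect_false(fit$converged)
  expect_s3_class(fit, "greml")
})

test_that("a singular design matrix errors explicitly", {
  g <- simulate_genotypes(50, 60, seed = 85)
  A <- compute_grm(g)
  X <- cbind(rep(1, 50), rep(1, 50))  # collinear
  expect_error(reml_fit(rnorm(50), X, A), "singular")
})

test_that("parameter recovery on the observed scale is unbiased with honest SEs", {
  # scaled-down recovery study: continuous trait with known h2_obs;
  # unconstrained fits, since only those are mean-unbiased at h2 = 0
  reps <- 30
  for (h2 in c(0, 0.4)) {
    est <- se <- numeric(reps)
    for (r in seq_len(reps)) {
      g <- simulate_genotypes(800, 600, maf_range = c(0.05, 0.5), ld_rho = 0,
                              seed = 8600 + 50 * h2 + r)
      A <- compute_grm(g)
      set.seed(8700 + 50 * h2 + r)
      gscore <- if (h2 > 0) {
        z <- scale(g$dosages) %*% rnorm(600)
        sqrt(h2) * as.numeric(scale(z))
      } else numeric(800)
      y <- gscore + rnorm(800, 0, sqrt(1 - h2))
      fit <- reml_fit(y, matrix(1, 800, 1), A, constrain = FALSE)
      est[r] <- fit$h2_obs; se[r] <- fit$se_h2
    }
    mc_se <- sd(est) / sqrt(reps)
    expect_lt(abs(mean(est) - h2), max(2 * mc_se, 0.02))
    if (h2 > 0) {
      # reported SE within a factor band of the empirical SD (20 replicates)
      expect_gt(mean(se) / sd(est), 0.6)
      expect_lt(mean(se) / sd(est), 1.6)
    }
  }
})

test_that("an irrelevant covariate barely moves the estimate", {
  sc <- make_signal_cohort(n = 500, m = 400, h2 = 0.5, seed = 87)
  pop <- simulate_liability_onset(sc$geno, sc$effects, seed = 88)
  A <- compute_grm(sc$geno)
  y <- pop$liability_true
  set.seed(89)
  junk <- rnorm(500)
  f0 <- reml_fit(y, matrix(1, 500, 1), A)
  f1 <- reml_fit(y, cbind(1, junk), A)
  expect_lt(abs(f0$h2_obs - f1$h2_obs), f0$se_h2)
})

test_that("GRM principal components behave as population-structure covariates", {
  g <- simulate_genotypes(80, 150, seed = 90)
  A <- compute_grm(g)
  expect_equal(ncol(pcs_from_grm(A, 0)), 0L)
  V <- pcs_from_grm(A, 4)
  expect_equal(unname(crossprod(V)), diag(4), tolerance = 1e-8)
  # sign convention: the largest-magnitude loading is positive
  for (j in 1:4) expect_gt(V[which.max(abs(V[, j])), j], 0)
  # two allele-frequency-divergent subpopulations separate on PC1
  set.seed(91)
  m <- 200
  p1 <- runif(m, 0.05, 0.25); p2 <- runif(m, 0.3, 0.5)
  d <- rbind(matrix(rbinom(60 * m, 2, rep(p1, each = 60)), 60, m),
             matrix(rbinom(60 * m, 2, rep(p2, each = 60)), 60, m))
  Ad <- compute_grm(make_geno(d))
  pc1 <- pcs_from_grm(Ad, 1)[, 1]
  expect_gt(abs(mean(pc1[1:60]) - mean(pc1[61:120])),
            3 * (sd(pc1[1:60]) + sd(pc1[61:120])) / 2)
})

test_that("h2_partition reports shares that sum to one", {
  set.seed(92)
  g <- simulate_genotypes(150, 200, seed = 92)
  A <- compute_grm(g)
  y <- as.numeric(A$values %*% rnorm(150) * 0.3 + rnorm(150))
  f1 <- reml_fit(y, matrix(1, 150, 1), A)
  p1 <- h2_partition(f1)
  expect_equal(p1$share_h2, 1)
  f2 <- suppressWarnings(reml_fit(y, matrix(1, 150, 1), list(A, A)))
  p2 <- h2_partition(f2)
  expect_equal(sum(p2$share_h2), 1)
  expect_equal(p2$share_h2, c(0.5, 0.5), tolerance = 0.05)
})

test_that("formula interface and methods are coherent", {
  sim <- simulate_cohort(n_cases = 60, n_controls = 60, n_snps = 150,
                         seed = 93)
  A <- compute_grm(sim$geno)
  fit <- greml(status ~ sex + age_years, data = sim$cohort, grms = A)
  expect_s3_class(fit, "greml")
  expect_named(coef(fit), c("(Intercept)", "sex", "age_years"))
  expect_equal(dim(vcov(fit)), c(3L, 3L))
  expect_equal(as.numeric(logLik(fit)), fit$loglik)
  expect_equal(fitted(fit) + residuals(fit), fit$y, tolerance = 1e-10)
  s <- summary(fit)
  expect_s3_class(s, "summary.greml")
  expect_output(print(s), "V\\(G\\)/Vp")
  expect_output(print(fit), "h2 \\(observed scale\\)")
})
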