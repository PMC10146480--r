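test_that("PLINK bed/bim/fam round-trips byte-identically", {
  sim <- simulate_cohort(n_cases = 30, n_controls = 31, n_snps = 90,
                         seed = 100)  # n = 61, not a multiple of 4
  dir <- withr::local_tempdir()
  p1 <- file.path(dir, "a")
  write_plink(sim$geno, p1, cohort = sim$cohort)
  back <- read_plink(p1)
  expect_equal(back$geno$dosages, sim$geno$dosages)
  expect_equal(back$geno$snp_meta$pos_bp, sim$geno$snp_meta$pos_bp)
  expect_equal(back$geno$snp_meta$chrom, sim$geno$snp_meta$chrom)
  expect_equal(back$fam$iid, sim$geno$sample_ids)
  # status 0/1 encoded as 1/2
  i <- match(back$fam$iid, sim$cohort$sample_id)
  expect_equal(back$fam$pheno, sim$cohort$status[i] + 1L)
  # second write of the re-read genotypes is byte-identical
  p2 <- file.path(dir, "b")
  write_plink(back$geno, p2, cohort = sim$cohort)
  for (ext in c(".bed", ".bim")) {
    expect_identical(readBin(paste0(p1, ext), "raw", 1e6),
                     readBin(paste0(p2, ext), "raw", 1e6))
  }
})

test_that("missing genotypes survive the PLINK codec", {
  d <- matrix(c(0L, 1L, 2L, NA, 2L, 0L), 3, 2)
  g <- make_geno(d)
  dir <- withr::local_tempdir()
  write_plink(g, file.path(dir, "m"))
  back <- read_plink(file.path(dir, "m"))
  expect_equal(back$geno$dosages, g$dosages)
})

test_that("GCTA binary GRM triple round-trips bit-identically", {
  g <- simulate_genotypes(25, 60, seed = 101)
  A <- compute_grm(g)
  dir <- withr::local_tempdir()
  write_gcta_grm(A, file.path(dir, "g1"))
  back <- read_gcta_grm(file.path(dir, "g1"))
  # float32 storage: re-read equals original to single precision
  expect_equal(back$values, A$values, tolerance = 1e-6)
  expect_equal(back$n_snps, A$n_snps)
  expect_equal(back$sample_ids, A$sample_ids)
  # write -> read -> write is byte-identical
  write_gcta_grm(back, file.path(dir, "g2"))
  for (ext in c(".grm.bin", ".grm.N.bin", ".grm.id")) {
    expect_identical(readBin(file.path(dir, paste0("g1", ext)), "raw", 1e6),
                     readBin(file.path(dir, paste0("g2", ext)), "raw", 1e6))
  }
})

test_that("phenotype and covariate files round-trip", {
  sim <- simulate_cohort(n_cases = 20, n_controls = 20, n_snps = 60,
                         seed = 102)
  dir <- withr::local_tempdir()
  write_phenotype(sim$cohort, file.path(dir, "p.txt"))
  write_covariates(sim$cohort, file.path(dir, "c.txt"))
  ph <- read_phenotype(file.path(dir, "p.txt"))
  cv <- read_covariates(file.path(dir, "c.txt"))
  expect_equal(ph$status, sim$cohort$status)
  expect_equal(cv$sex, sim$cohort$sex)
  expect_equal(cv$age_years, sim$cohort$age_years, tolerance = 1e-6)
})

test_that("write_cohort emits the full file bundle with a truth sidecar", {
  sim <- simulate_cohort(n_cases = 20, n_controls = 20, n_snps = 100,
                         seed = 103)
  dir <- withr::local_tempdir()
  write_cohort(sim, dir)
  expect_true(all(file.exists(file.path(dir, c(
    "cohort.bed", "cohort.bim", "cohort.fam", "cohort.pheno", "cohort.covar",
    "apoe_region.bed", "gwas_hits.bed", "geneset.bed", "truth.json")))))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_equal(truth$h2_liability, sim$truth$h2_liability)
  expect_equal(truth$major_locus_share, 0.24)
})

test_that("the .hsq report contains the fitted quantities", {
  set.seed(104)
  g <- simulate_genotypes(80, 100, seed = 104)
  A <- compute_grm(g)
  fit <- reml_fit(rnorm(80), matrix(1, 80, 1), A)
  path <- withr::local_tempfile(fileext = ".hsq")
  write_hsq(fit, path)
  lines <- readLines(path)
  expect_equal(lines[1], "Source\tVariance\tSE")
  vg <- as.numeric(strsplit(lines[2], "\t")[[1]][2])
  expect_equal(vg, unname(fit$sigma2[1]), tolerance = 1e-6)
  expect_true(any(grepl("^Pval\t", lines)))
  expect_true(any(grepl(sprintf("^n\t%d$", fit$n), lines)))
})

test_that("reml_fit accepts a GCTA GRM path prefix", {
  set.seed(105)
  g <- simulate_genotypes(60, 80, seed = 105)
  A <- compute_grm(g)
  y <- rnorm(60)
  dir <- withr::local_tempdir()
  write_gcta_grm(A, file.path(dir, "k"))
  f_mem <- reml_fit(y, matrix(1, 60, 1), A)
  f_path <- reml_fit(y, matrix(1, 60, 1), file.path(dir, "k"))
  expect_equal(f_path$h2_obs, f_mem$h2_obs, tolerance = 1e-4)
})
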