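test_that("simulated dosages are valid 0/1/2 with consistent metadata", {
  g <- simulate_genotypes(4, 10, ld_rho = 0, seed = 1)
  expect_equal(dim(g$dosages), c(4L, 10L))
  expect_true(all(g$dosages %in% 0:2))
  expect_false(anyNA(g$dosages))
  # stored frequency is the realized sample frequency
  expect_equal(g$snp_meta$freq, unname(colMeans(g$dosages) / 2))
  # positions strictly increasing within chromosome
  expect_true(all(diff(g$snp_meta$pos_bp) > 0))
})

test_that("invalid parameters are rejected", {
  expect_error(simulate_genotypes(10, 10, maf_range = c(0, 0.5)), "maf_range")
  expect_error(simulate_genotypes(10, 10, maf_range = c(0.1, 0.6)), "maf_range")
  expect_error(simulate_genotypes(10, 10, ld_rho = 1), "ld_rho")
  bad_meta <- data.frame(chrom = 1L, snp_id = c("a", "b"),
                         pos_bp = c(10L, 10L), a1 = "A", a2 = "C")
  expect_error(genotype_matrix(matrix(0L, 2, 2), bad_meta), "increasing")
})

test_that("generation is byte-identical under a fixed seed", {
  g1 <- simulate_genotypes(50, 80, ld_rho = 0.7, seed = 42)
  g2 <- simulate_genotypes(50, 80, ld_rho = 0.7, seed = 42)
  expect_identical(g1, g2)
})

test_that("ld_rho = 0 yields uncorrelated SNPs", {
  g <- simulate_genotypes(1000, 60, ld_rho = 0, seed = 3)
  r <- cor(g$dosages)
  off <- abs(r[upper.tri(r)])
  expect_lt(mean(off), 0.05)  # ~1/sqrt(n) Monte-Carlo scale
})

test_that("block LD exceeds cross-block LD and matches direct correlation", {
  g <- simulate_genotypes(2000, 200, ld_rho = 0.8, ld_block_size = 20,
                          seed = 4)
  r2 <- cor(g$dosages)^2
  block <- (seq_len(200) - 1L) %/% 20L
  adj <- vapply(seq_len(199), function(i) {
    if (block[i] == block[i + 1]) r2[i, i + 1] else NA_real_
  }, 0)
  cross <- r2[block == 0, block == 5]
  expect_gt(mean(adj, na.rm = TRUE), mean(cross) + 0.1)
})

test_that("genotype subsetting preserves metadata and recomputes frequency", {
  g <- simulate_genotypes(30, 20, seed = 5)
  ids <- g$snp_meta$snp_id[c(3, 7, 11)]
  sub <- subset_genotypes(g, snp_ids = ids, samples = 1:10)
  expect_equal(sub$snp_meta$snp_id, ids)
  expect_equal(sub$snp_meta$freq, unname(colMeans(sub$dosages) / 2))
  expect_error(subset_genotypes(g, snp_ids = "nope"), "unknown")
})
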