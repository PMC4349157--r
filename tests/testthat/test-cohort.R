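test_that("spec validation rejects malformed inputs", {
  expect_error(cohort_spec(n_subpopulations = 0), "n_subpopulations")
  expect_error(cohort_spec(mixing_proportions = c(0.5, 0.2)), "simplex")
  expect_error(planted_interaction(1, 1, 0.2), "differ")
  expect_error(planted_interaction(1, 2, 1.0), "target_variance_fraction")
  expect_error(
    generate_cohort(cohort_spec(
      n_snps = 6, fraction_monomorphic = 0,
      planted_interactions = list(planted_interaction(1, 2, 0.6),
                                  planted_interaction(3, 4, 0.5)))),
    "must be < 1")
})

test_that("zero noise and no planted effects give a trait constant within class", {
  spec <- cohort_spec(n_subjects = 200, n_snps = 4, n_subpopulations = 3,
                      noise_sd = c(0, 0), fraction_monomorphic = 0,
                      missing_rate = 0, seed = 3)
  co <- generate_cohort(spec)
  by_class <- split(co$phenotypes$diastolic_bp, co$assignments$class_label)
  for (v in by_class) expect_lt(diff(range(v)), 1e-12)
})

test_that("planted interaction realizes its target variance fraction (ANOVA oracle)", {
  spec <- cohort_spec(n_subjects = 5000, n_snps = 6, n_subpopulations = 1,
                      maf_bounds = c(0.3, 0.3), fraction_monomorphic = 0,
                      planted_interactions = list(planted_interaction(1, 2, 0.20)),
                      noise_sd = c(8, 12), missing_rate = 0, seed = 11)
  co <- generate_cohort(spec)
  y <- co$phenotypes$diastolic_bp
  cell <- interaction(co$genotypes$snp_001, co$genotypes$snp_002)
  cell_means <- ave(y, cell)
  realized <- mean((cell_means - mean(y))^2) / mean((y - mean(y))^2)
  expect_lt(abs(realized - 0.20), 0.02)
})

test_that("generation is deterministic and default dimensions mirror the study design", {
  spec <- cohort_spec(seed = 5)
  expect_equal(spec$n_subjects, 2556L)
  expect_equal(spec$n_snps, 353L)
  expect_equal(spec$n_subpopulations, 14L)
  expect_equal(spec$fraction_monomorphic, 0.55)
  # ~160 of 353 SNPs stay polymorphic under the default monomorphic fraction
  expect_equal(353L - round(0.55 * 353), 159L)

  small <- cohort_spec(n_subjects = 60, n_snps = 5, n_subpopulations = 2,
                       seed = 99)
  c1 <- generate_cohort(small)
  c2 <- generate_cohort(small)
  expect_identical(c1$genotypes, c2$genotypes)
  expect_identical(c1$phenotypes, c2$phenotypes)
  expect_identical(c1$assignments, c2$assignments)
})

test_that("class genotype frequencies follow HWE at the sampled MAF", {
  spec <- cohort_spec(n_subjects = 6000, n_snps = 4, n_subpopulations = 2,
                      maf_bounds = c(0.2, 0.4), fraction_monomorphic = 0,
                      missing_rate = 0, seed = 21)
  co <- generate_cohort(spec)
  cls <- co$assignments$class_label
  for (k in 1:2) {
    g <- co$genotypes$snp_002[cls == k]
    q <- mean(g) / 2
    expected <- c((1 - q)^2, 2 * q * (1 - q), q^2)
    observed <- tabulate(g + 1L, 3L) / length(g)
    expect_lt(max(abs(observed - expected)), 0.03)
  }
})

test_that("fully monomorphic panel leaves no valid SNPs downstream", {
  spec <- cohort_spec(n_subjects = 100, n_snps = 6, n_subpopulations = 1,
                      fraction_monomorphic = 1, missing_rate = 0, seed = 2)
  co <- generate_cohort(spec)
  expect_length(filter_snps(co$genotypes), 0L)
})

test_that("class-specific monomorphism empties the SNP only in that class", {
  spec <- cohort_spec(n_subjects = 400, n_snps = 4, n_subpopulations = 2,
                      maf_bounds = c(0.3, 0.4), fraction_monomorphic = 0,
                      class_monomorphic = list("1" = 2L),
                      missing_rate = 0, seed = 8)
  co <- generate_cohort(spec)
  cls <- co$assignments$class_label
  expect_true(all(co$genotypes$snp_002[cls == 1] == 0))
  expect_gt(sum(co$genotypes$snp_002[cls == 2]), 0)
})

test_that("allocation probabilities are graded, peaked on the true class", {
  spec <- cohort_spec(n_subjects = 800, n_snps = 4, n_subpopulations = 14,
                      seed = 13)
  co <- generate_cohort(spec)
  p <- co$assignments$allocation_probability
  expect_true(all(p > 1 / 14 & p <= 1))
  expect_gt(mean(p >= 0.9), 0.25) # most subjects confidently allocated
  expect_gt(mean(p < 0.9), 0.05)  # but reliability is graded, not uniform
})

test_that("fixture is hard-pinned, deterministic and physiologically plausible", {
  fx <- make_fixture()
  expect_equal(unname(table(fx$genotypes$snp_001)), c(15L, 10L, 5L),
               ignore_attr = TRUE)
  expect_equal(compute_maf(fx$genotypes$snp_001), 1 / 3)
  fx2 <- make_fixture()
  expect_identical(fx, fx2)
  bp <- c(fx$phenotypes$diastolic_bp, fx$phenotypes$systolic_bp)
  expect_true(all(is.finite(bp)))
  expect_true(all(bp > 40 & bp < 260))
})
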