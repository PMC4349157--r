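test_that("hypertension classification is boundary-inclusive at 90/140 mmHg", {
  ph <- tibble::tibble(subject_id = c("a", "b", "c", "d"),
                       diastolic_bp = c(89, 90, 91, NA),
                       systolic_bp = c(139, 140, 141, 150))
  cl <- classify_hypertension(ph)
  expect_equal(cl$affected_dia, c(FALSE, TRUE, TRUE, NA))
  expect_equal(cl$affected_sys, c(FALSE, TRUE, TRUE, TRUE))
  # all-normotensive cohort: nobody affected
  ph0 <- tibble::tibble(subject_id = "x", diastolic_bp = 75, systolic_bp = 115)
  expect_false(classify_hypertension(ph0)$affected_dia)
})

test_that("Fisher p equals hypergeometric enumeration and flags direction", {
  g <- tibble::tibble(subject_id = sprintf("S%04d", 1:1020),
                      s1 = c(rep(0L, 20), rep(1L, 1000)),
                      s2 = c(rep(0L, 20), rep(1L, 1000)))
  affected <- c(rep(TRUE, 10), rep(FALSE, 10), rep(TRUE, 100), rep(FALSE, 900))
  r <- genotype_prevalence_test(g, affected, "s1", 0L, "s2", 0L)
  expect_equal(r$n_carriers, 20L)
  expect_equal(r$affected_fraction_carriers, 50)
  expect_equal(r$p_value, fisher_oracle(10, 10, 100, 900), tolerance = 1e-10)
  expect_equal(r$direction, "above")
  expect_equal(r$genotype_frequency_population, 100 * 20 / 1020)

  # prevalence equal to the population: p = 1, no direction
  g2 <- tibble::tibble(subject_id = sprintf("S%03d", 1:100),
                       s1 = rep(c(0L, 1L), c(10, 90)),
                       s2 = rep(c(0L, 1L), c(10, 90)))
  aff2 <- rep(c(TRUE, FALSE, TRUE, FALSE), c(2, 8, 18, 72))
  r2 <- genotype_prevalence_test(g2, aff2, "s1", 0L, "s2", 0L)
  expect_equal(r2$p_value, 1)
  expect_equal(r2$direction, "none")

  # no carriers: suppressed with a warning
  expect_warning(out <- genotype_prevalence_test(g2, aff2, "s1", 2L, "s2", 2L),
                 "suppressed")
  expect_null(out)
})

test_that("Fisher wrapper matches enumeration across random sparse tables", {
  set.seed(91)
  for (i in 1:50) {
    a <- sample(0:8, 1); b <- sample(0:12, 1)
    c <- sample(0:60, 1); d <- sample(0:120, 1)
    if ((a + b) == 0 || (c + d) == 0 || (a + c) == 0 || (b + d) == 0) next
    p_pkg <- stats::fisher.test(matrix(c(a, b, c, d), 2, 2, byrow = TRUE))$p.value
    expect_equal(p_pkg, fisher_oracle(a, b, c, d), tolerance = 1e-9,
                 info = sprintf("table (%d,%d,%d,%d)", a, b, c, d))
  }
})

test_that("case-control scan corrects over all tested genotype cells", {
  spec <- cohort_spec(n_subjects = 400, n_snps = 4, n_subpopulations = 1,
                      maf_bounds = c(0.3, 0.4), fraction_monomorphic = 0,
                      missing_rate = 0, seed = 92)
  co <- generate_cohort(spec)
  ph <- classify_hypertension(co$phenotypes)
  pairs <- tibble::tibble(snp_a = "snp_001", snp_b = "snp_002")
  cc <- case_control_scan(co$genotypes, ph, pairs, trait = "diastolic")
  expect_true(all(cc$affected_fraction_carriers >= 0 &
                    cc$affected_fraction_carriers <= 100))
  # carrier counts and percentages are mutually consistent
  expect_equal(cc$n_affected_carriers,
               round(cc$n_carriers * cc$affected_fraction_carriers / 100))
  expect_true(all(!cc$significant_bonferroni | cc$p_value <= 0.05))
})

test_that("genotype distributions: identical scopes give p 1; a planted shift is found", {
  g <- tibble::tibble(subject_id = sprintf("S%03d", 1:120),
                      s1 = rep(c(0L, 1L, 2L), 40),
                      s2 = rep(c(0L, 1L), 60))
  a_same <- tibble::tibble(subject_id = g$subject_id,
                           class_label = rep(1:2, each = 60),
                           allocation_probability = 1)
  # classes built to have identical genotype composition
  g_same <- g
  g_same$s1 <- rep(rep(c(0L, 1L, 2L), each = 20), 2)
  g_same$s2 <- rep(rep(c(0L, 1L), each = 30), 2)
  r <- compare_genotype_distributions(g_same, a_same, include_rest = FALSE)
  expect_true(all(r$p_value > 0.999))

  spec <- cohort_spec(n_subjects = 500, n_snps = 5, n_subpopulations = 2,
                      maf_bounds = c(0.3, 0.4), fraction_monomorphic = 0,
                      class_monomorphic = list("1" = 3L),
                      allocation_concentration = 1e5,
                      missing_rate = 0, seed = 93)
  co <- generate_cohort(spec)
  rc <- compare_genotype_distributions(co$genotypes, co$assignments,
                                       include_rest = FALSE)
  best <- rc$snp_id[which.min(rc$p_value)]
  expect_equal(best, "snp_003")

  # null cohort: nothing survives correction
  spec0 <- cohort_spec(n_subjects = 400, n_snps = 8, n_subpopulations = 3,
                       maf_bounds = c(0.2, 0.4), fraction_monomorphic = 0,
                       missing_rate = 0, seed = 94)
  co0 <- generate_cohort(spec0)
  r0 <- compare_genotype_distributions(co0$genotypes, co0$assignments)
  expect_false(any(r0$significant_bonferroni))
})

test_that("trait mean comparisons detect a planted +15 mmHg cell after correction", {
  set.seed(95)
  n <- 2000
  g <- tibble::tibble(subject_id = sprintf("S%05d", 1:n),
                      s1 = rbinom(n, 2, 0.4), s2 = rbinom(n, 2, 0.4))
  y <- rnorm(n, 85, 8) + 15 * (g$s1 == 0 & g$s2 == 0)
  ph <- tibble::tibble(subject_id = g$subject_id, diastolic_bp = y,
                       systolic_bp = y + 40)
  pairs <- tibble::tibble(snp_a = "s1", snp_b = "s2")
  r <- trait_mean_comparison(g, ph, pairs, trait = "diastolic_bp")
  hit <- r[r$genotype_a == 0 & r$genotype_b == 0, ]
  expect_true(hit$significant_bonferroni)
  expect_equal(hit$mean_difference, 15, tolerance = 2)

  # identical groups: no signal
  y0 <- rep(c(80, 90), n / 2)
  ph0 <- tibble::tibble(subject_id = g$subject_id, diastolic_bp = y0,
                        systolic_bp = y0)
  r0 <- trait_mean_comparison(g, ph0, pairs, trait = "diastolic_bp")
  expect_false(any(r0$significant_bonferroni))
})
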