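boltz <- function(x, A1, A2, x0, dx) A2 + (A1 - A2) / (1 + exp((x - x0) / dx))

test_that("curve assembly refuses sparse inputs and sorts by WMI", {
  res <- tibble::tibble(
    snp_a = c("a", "b", "c"), snp_b = c("b", "c", "d"),
    scope = "1", trait = "diastolic_bp",
    wmi_abs = c(3, 1, 2), relative_genetic_variance = c(0.5, 0.1, 0.3),
    n_cells = 9L, n = 500L,
    significant_bonferroni = TRUE, significant_nominal = TRUE,
    epistasis_bonferroni = TRUE, epistasis_nominal = TRUE)
  expect_error(assemble_curve(res), "fit refused")
  res5 <- dplyr::bind_rows(res, res |> dplyr::mutate(snp_a = c("e", "f", "g")))
  pts <- assemble_curve(res5, min_points = 5)
  expect_false(is.unsorted(pts$x))
  expect_equal(nrow(pts), 6L)
  cum <- assemble_curve(res5, mode = "cumulative", min_points = 5)
  expect_false(is.unsorted(cum$y))
  expect_lte(max(cum$y), 1)
})

test_that("noise-free Boltzmann points recover the plateau to 1e-6", {
  x <- seq(0, 10, length.out = 40)
  pts <- tibble::tibble(x = x, y = boltz(x, 0.05, 0.6, 4, 1.2))
  fit <- fit_saturating(pts, "boltzmann")
  expect_true(fit$converged)
  expect_equal(fit$h2, 0.6, tolerance = 1e-6)
  expect_equal(unname(fit$parameters["x0"]), 4, tolerance = 1e-4)
})

test_that("noisy sigmoid points recover the plateau within 0.05 for all models", {
  set.seed(81)
  x <- sort(runif(60, 0, 10))
  y <- boltz(x, 0.05, 0.6, 4, 1.2) + rnorm(60, 0, 0.03)
  pts <- tibble::tibble(x = x, y = y)
  h2s <- vapply(c("polynomial", "boltzmann", "gaussian"), function(m) {
    f <- fit_saturating(pts, m)
    expect_true(f$converged)
    f$h2
  }, 0)
  expect_true(all(abs(h2s - 0.6) < 0.05))
  # the three families agree with each other on a well-behaved cloud
  expect_lt(max(h2s) - min(h2s), 0.05)
})

test_that("plateau estimates are invariant to rescaling the trait units", {
  co <- generate_cohort(recovery_spec(82))
  ph2 <- co$phenotypes
  ph2$diastolic_bp <- ph2$diastolic_bp / stats::sd(ph2$diastolic_bp)
  r1 <- scan_pairs(co$genotypes, co$phenotypes, snp_info = co$snp_info,
                   hwe_alpha = 1e-4, geff_mode = "interaction_only")
  r2 <- scan_pairs(co$genotypes, ph2, snp_info = co$snp_info,
                   hwe_alpha = 1e-4, geff_mode = "interaction_only")
  expect_equal(r1$relative_genetic_variance, r2$relative_genetic_variance,
               tolerance = 1e-9)
  p1 <- assemble_curve(r1, gate = "epistasis_bonferroni", mode = "cumulative")
  p2 <- assemble_curve(r2, gate = "epistasis_bonferroni", mode = "cumulative")
  f1 <- fit_saturating(p1, "boltzmann")
  f2 <- fit_saturating(p2, "boltzmann")
  expect_equal(f1$h2, f2$h2, tolerance = 0.02)
})

test_that("a cohort without planted effects yields near-zero heritability", {
  spec <- cohort_spec(n_subjects = 800, n_snps = 20, n_subpopulations = 1,
                      maf_bounds = c(0.25, 0.45), fraction_monomorphic = 0,
                      missing_rate = 0, seed = 83)
  co <- generate_cohort(spec)
  r <- scan_pairs(co$genotypes, co$phenotypes, snp_info = co$snp_info,
                  hwe_alpha = 1e-4, scope = "1")
  h <- estimate_heritability(r, gate = "epistasis_nominal", B = 30, seed = 1)
  cons <- h$h2[h$model == "consensus"]
  expect_false(is.na(cons)) # nominal false positives populate the curve
  expect_lte(cons, 0.1)
})

test_that("estimate_heritability reports all models plus a consensus with CI", {
  co <- generate_cohort(recovery_spec(84))
  r <- scan_pairs(co$genotypes, co$phenotypes, snp_info = co$snp_info,
                  hwe_alpha = 1e-4, scope = "1",
                  geff_mode = "interaction_only")
  h <- estimate_heritability(r, gate = "epistasis_bonferroni",
                             mode = "cumulative", B = 60, seed = 1)
  expect_setequal(h$model, c("polynomial", "boltzmann", "gaussian",
                             "consensus"))
  cons <- h[h$model == "consensus", ]
  expect_true(cons$converged)
  expect_true(cons$ci_lo <= cons$h2 && cons$h2 <= cons$ci_hi)
  # deterministic given the seed
  h2 <- estimate_heritability(r, gate = "epistasis_bonferroni",
                              mode = "cumulative", B = 60, seed = 1)
  expect_identical(h$h2, h2$h2)
  expect_identical(h$ci_lo, h2$ci_lo)

  fits <- attr(h, "fits")[[1]]
  expect_named(fits, c("polynomial", "boltzmann", "gaussian"))
  g <- glance(fits$boltzmann)
  expect_equal(g$model, "boltzmann")
  td <- tidy(fits$boltzmann)
  expect_setequal(td$term, c("A1", "A2", "x0", "dx"))
})

test_that("clamping is flagged when a plateau leaves [0, 1]", {
  x <- seq(1, 10, length.out = 12)
  pts <- tibble::tibble(x = x, y = 0.2 * x) # keeps rising: poly exceeds 1
  f <- fit_saturating(pts, "polynomial")
  expect_true(f$h2_clamped)
  expect_equal(f$h2, 1)
})
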