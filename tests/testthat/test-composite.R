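test_that("composite table matches a hand tally and always has 9 cells", {
  g_a <- c(0L, 0L, 1L, 1L, 2L, 2L)
  g_b <- c(0L, 1L, 1L, 1L, 0L, 2L)
  y <- c(80, 82, 90, 92, 85, 100)
  tab <- composite_table(g_a, g_b, y)
  expect_equal(dim(tab$n_ij), c(3L, 3L))
  expect_equal(length(tab$n_ij), 9L)
  expect_equal(tab$n_ij["0", "0"], 1L)
  expect_equal(tab$n_ij["0", "1"], 1L)
  expect_equal(tab$n_ij["1", "1"], 2L)
  expect_equal(tab$n_ij["2", "0"], 1L)
  expect_equal(tab$n_ij["2", "2"], 1L)
  expect_equal(sum(tab$n_ij), 6L)
  expect_equal(tab$m_ij["1", "1"], 91)
  expect_true(is.na(tab$m_ij["0", "2"]))
  expect_equal(sum(tab$p_ij), 1)
  expect_equal(rowSums(tab$p_ij), tab$p_i)
  expect_equal(colSums(tab$p_ij), tab$p_j)
})

test_that("pairwise deletion drops subjects missing either dosage", {
  tab <- composite_table(c(0L, NA, 1L, 2L), c(0L, 1L, NA, 2L), c(1, 2, 3, 4))
  expect_equal(tab$n_total, 2L)
})

test_that("independent uniform SNPs give p_ij ~ p_i p_j", {
  set.seed(51)
  g_a <- sample(0:2, 20000, replace = TRUE)
  g_b <- sample(0:2, 20000, replace = TRUE)
  tab <- composite_table(g_a, g_b, rnorm(20000))
  expect_lt(max(abs(tab$p_ij - outer(tab$p_i, tab$p_j))), 0.01)
})

test_that("degenerate traits are rejected with informative errors", {
  g <- rep(0:2, each = 10)
  tab <- composite_table(g, rev(g), rep(100, 30))
  expect_error(decompose_variance(tab), "variance is zero")
  tab1 <- composite_table(rep(0L, 20), rep(0L, 20), rnorm(20))
  expect_error(decompose_variance(tab1), "nonempty cells")
})

test_that("a purely additive trait has zero interaction variance", {
  set.seed(52)
  g_a <- rbinom(4000, 2, 0.4); g_b <- rbinom(4000, 2, 0.3)
  y <- 80 + 5 * g_a # depends on SNP a only
  d <- decompose_variance(composite_table(g_a, g_b, y))
  expect_lt(d$var_interaction, 1e-18)
  expect_lt(max(abs(d$d_ij), na.rm = TRUE), 1e-9)
  expect_equal(d$var_genotypic, d$var_marginal, tolerance = 1e-12)
  # additive marginal effects are recovered
  expect_equal(unname(diff(d$marginal_effects_a)), c(5, 5), tolerance = 1e-9)
})

test_that("planted double-centred pattern under equal cell frequencies matches the direct sum", {
  # equal frequency cells: each of the 9 combinations 4 times
  g_a <- rep(rep(0:2, each = 3), 4)
  g_b <- rep(rep(0:2, times = 3), 4)
  E <- outer(c(-1, 0, 1), c(1, 0, -1)) # double-centred under uniform margins
  y <- 90 + 3 * E[cbind(g_a + 1, g_b + 1)]
  tab <- composite_table(g_a, g_b, y)
  d <- decompose_variance(tab)
  hand <- sum(tab$p_ij * (3 * E)^2)
  expect_equal(d$var_interaction, hand, tolerance = 1e-12)
  expect_equal(d$var_marginal, 0, tolerance = 1e-12)
})

test_that("variance conservation holds to 1e-9 on random full tables", {
  set.seed(53)
  for (i in 1:40) {
    d <- decompose_variance(random_full_table())
    expect_lt(abs(d$var_marginal + d$var_interaction - d$var_genotypic),
              1e-9 * max(1, d$var_genotypic))
    expect_gte(d$relative_genetic_variance, 0)
    expect_lte(d$relative_genetic_variance, 1)
  }
})

test_that("noise-free genetic traits have relative genetic variance 1", {
  set.seed(54)
  g_a <- rbinom(500, 2, 0.4); g_b <- rbinom(500, 2, 0.3)
  y <- 85 + 2 * g_a + 3 * g_b + 4 * (g_a == 1) * (g_b == 1)
  d <- decompose_variance(composite_table(g_a, g_b, y))
  expect_equal(d$relative_genetic_variance, 1, tolerance = 1e-9)
})

test_that("decomposition is invariant to subject order and SNP swap", {
  set.seed(55)
  g_a <- rbinom(300, 2, 0.35); g_b <- rbinom(300, 2, 0.25)
  y <- rnorm(300, 90, 8) + g_a * g_b
  d <- decompose_variance(composite_table(g_a, g_b, y))
  perm <- sample(300)
  d_perm <- decompose_variance(composite_table(g_a[perm], g_b[perm], y[perm]))
  expect_equal(d$var_interaction, d_perm$var_interaction, tolerance = 1e-12)
  expect_equal(d$geff_ij, d_perm$geff_ij, tolerance = 1e-12)
  d_swap <- decompose_variance(composite_table(g_b, g_a, y))
  expect_equal(d_swap$var_interaction, d$var_interaction, tolerance = 1e-12)
  expect_equal(d_swap$geff_ij, t(d$geff_ij), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(d_swap$marginal_effects_a, d$marginal_effects_b,
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("interaction F-test is calibrated under the additive null and powered under epistasis", {
  set.seed(56)
  p_null <- replicate(200, {
    g_a <- rbinom(300, 2, 0.4); g_b <- rbinom(300, 2, 0.3)
    y <- 85 + 2 * g_a - 1.5 * g_b + rnorm(300, 0, 8)
    decompose_variance(composite_table(g_a, g_b, y))$interaction_p
  })
  expect_gt(mean(p_null < 0.05), 0.01)
  expect_lt(mean(p_null < 0.05), 0.11)
  g_a <- rbinom(800, 2, 0.4); g_b <- rbinom(800, 2, 0.3)
  y <- 85 + 8 * (g_a == 2) * (g_b == 0) + rnorm(800, 0, 8)
  expect_lt(decompose_variance(composite_table(g_a, g_b, y))$interaction_p,
            1e-3)
})

test_that("geff modes give total vs interaction-only cell effects", {
  set.seed(57)
  tab <- random_full_table()
  d_tot <- decompose_variance(tab, geff_mode = "total")
  d_int <- decompose_variance(tab, geff_mode = "interaction_only")
  expect_equal(d_tot$geff_ij, tab$m_ij - d_tot$grand_mean, tolerance = 1e-12)
  expect_equal(d_int$geff_ij, d_int$d_ij, tolerance = 1e-12)
})
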