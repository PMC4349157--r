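mk_result <- function(sa, sb, ga, gb, wmi_abs, sig = TRUE) tibble::tibble(
  snp_a = sa, snp_b = sb, gene_a = ga, gene_b = gb,
  scope = "1", trait = "diastolic_bp", wmi = wmi_abs, wmi_abs = wmi_abs,
  significant_bonferroni = sig, significant_nominal = sig)

test_that("three pairs sharing one SNP form a star with degrees 3,1,1,1", {
  res <- dplyr::bind_rows(
    mk_result("hub", "x1", "GH", "G1", 3),
    mk_result("hub", "x2", "GH", "G2", 2),
    mk_result("hub", "x3", "GH", "G3", 1))
  nw <- build_network(res, level = "snp")
  expect_equal(sort(nw$nodes$degree, decreasing = TRUE), c(3L, 1L, 1L, 1L))
  hubs <- identify_hubs(nw, 1)
  expect_equal(hubs$node, "hub")
  expect_equal(sum(nw$nodes$degree), 2L * nrow(nw$edges))
})

test_that("intragenic pairs collapse to flagged gene self-loops with degree 2", {
  res <- dplyr::bind_rows(
    mk_result("s1", "s2", "SPHK1", "SPHK1", 5),
    mk_result("s3", "s4", "ASAH1", "GALC", 2))
  nw <- build_network(res, level = "gene")
  loop <- nw$edges[nw$edges$self_loop, ]
  expect_equal(nrow(loop), 1L)
  expect_equal(loop$from, "SPHK1")
  expect_equal(nw$nodes$degree[nw$nodes$node == "SPHK1"], 2L)
  expect_equal(sum(nw$nodes$degree), 2L * nrow(nw$edges))
})

test_that("edge weights take the maximum |WMI| across scopes and dedupe pairs", {
  res <- dplyr::bind_rows(
    mk_result("a", "b", "GA", "GB", 1.5),
    mk_result("a", "b", "GA", "GB", 2.5), # same pair, another scope
    mk_result("b", "a", "GB", "GA", 0.5)) # swapped order
  nw <- build_network(res, level = "snp")
  expect_equal(nrow(nw$edges), 1L)
  expect_equal(nw$edges$weight, 2.5)
  expect_equal(nw$edges$n_occurrences, 3L)
  # row order must not matter
  nw2 <- build_network(res[c(3, 1, 2), ], level = "snp")
  expect_identical(nw$edges, nw2$edges)
})

test_that("hub ranking has a deterministic tie-break", {
  res <- dplyr::bind_rows(
    mk_result("b", "c", "G1", "G2", 5),
    mk_result("a", "c", "G3", "G2", 1))
  nw <- build_network(res, level = "snp")
  h <- identify_hubs(nw, 3)
  expect_equal(h$node[1], "c")           # degree 2
  expect_equal(h$node[2], "b")           # degree 1, heavier edge
  expect_equal(h$node[3], "a")
})

test_that("empty gates give empty networks, not errors", {
  res <- mk_result("a", "b", "GA", "GB", 1, sig = FALSE)
  nw <- build_network(res, level = "snp", gate = "bonferroni")
  expect_equal(nrow(nw$edges), 0L)
  expect_equal(nrow(nw$nodes), 0L)
})

test_that("continuous power-law MLE recovers alpha across seeds", {
  ok <- 0
  for (s in 1:20) {
    set.seed(600 + s)
    x <- rpowerlaw(1000, 2.5, 1)
    f <- fit_power_law(x, discrete = FALSE)
    if (abs(f$alpha - 2.5) <= 0.2) ok <- ok + 1
  }
  expect_gte(ok, 18) # >= 90% of seeds
})

test_that("discrete fit agrees with the independent plfit implementation", {
  set.seed(601)
  x <- rpowerlaw(800, 2.3, 1, discrete = TRUE)
  f <- fit_power_law(x, discrete = TRUE)
  ig <- igraph::fit_power_law(x, implementation = "plfit")
  expect_equal(f$alpha, ig$alpha, tolerance = 0.02)
  expect_equal(f$xmin, ig$xmin, tolerance = 1e-9)
})

test_that("likelihood ratios discriminate exponential from power-law tails", {
  set.seed(602)
  xe <- 1 + stats::rexp(1000, 0.5)
  fe <- fit_power_law(xe, discrete = FALSE)
  lr_exp <- fe$comparisons[fe$comparisons$alternative == "exponential", ]
  # no significant support for a power law on exponential data
  expect_false(lr_exp$loglik_ratio > 0 && lr_exp$p_value < 0.05)
  xp <- rpowerlaw(1000, 2.5, 1)
  fp <- fit_power_law(xp, discrete = FALSE)
  lr2 <- fp$comparisons[fp$comparisons$alternative == "exponential", ]
  expect_gt(lr2$loglik_ratio, 0)    # power law preferred on its own data
  expect_lt(lr2$p_value, 0.05)
})

test_that("degenerate inputs are rejected", {
  expect_error(fit_power_law(rep(2, 50)), "all values equal")
  expect_error(fit_power_law(1:10), "at least 20")
  set.seed(603)
  x <- rpowerlaw(100, 2.5, 5)
  expect_error(fit_poisson_residual(x, list(xmin = min(x))), "refused")
})

test_that("Poisson residual fit recovers lambda and rejects a constant bulk", {
  set.seed(604)
  lam <- fit_poisson_residual(c(rpois(500, 3), rep(50, 30)),
                              list(xmin = 40))
  expect_lt(abs(lam$lambda - 3), 0.2)
  expect_gt(lam$gof_p, 0.001)
  const <- fit_poisson_residual(c(rep(4, 400), rep(50, 30)), list(xmin = 40))
  expect_lt(const$gof_p, 1e-6) # constants are not Poisson
})

test_that("mixture of Poisson bulk and power-law tail splits into both parts", {
  set.seed(605)
  mix <- c(rpois(600, 3), rpowerlaw(500, 2.5, 12, discrete = TRUE))
  f <- fit_power_law(mix, discrete = TRUE, xmin = 12) # generative split
  expect_lt(abs(f$alpha - 2.5), 0.2)
  pr <- fit_poisson_residual(mix, f)
  expect_lt(abs(pr$lambda - 3), 0.2)
  # the KS-selected cutoff lands near the generative boundary
  f_auto <- fit_power_law(mix, discrete = TRUE)
  expect_gte(f_auto$xmin, 8)
  expect_lte(f_auto$xmin, 25)
  expect_gt(f$fraction_captured, 0.2)
  expect_lt(f$fraction_captured, 0.8)
})

test_that("hurwitz zeta matches direct summation and the Basel closed form", {
  # s = 4: the truncation tail of the direct sum is ~1e-16, negligible
  direct <- sum((5:200000)^(-4))
  expect_equal(wmiscan:::hurwitz_zeta(4, 5), direct, tolerance = 1e-12)
  expect_equal(wmiscan:::hurwitz_zeta(2, 1), pi^2 / 6, tolerance = 1e-10)
})
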