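# Shared scenario builders for the test suite. All randomness is seeded by
# the caller.

# single-class panel with one planted pure interaction, used for ranking and
# calibration experiments
ranking_spec <- function(seed, n_subjects = 1000, n_snps = 6,
                         fraction = 0.20) {
  cohort_spec(
    n_subjects = n_subjects, n_snps = n_snps, n_subpopulations = 1,
    maf_bounds = c(0.2, 0.5), fraction_monomorphic = 0,
    planted_interactions = list(planted_interaction(1, 2, fraction)),
    noise_sd = c(8, 12), missing_rate = 0.005, seed = seed
  )
}

# polygenic architecture: ten disjoint pure interactions with geometrically
# decaying variance fractions summing to ~0.6 of the phenotypic variance
recovery_spec <- function(seed, n_subjects = 2000) {
  fr <- 0.159 * 0.75^(0:9) # sums to 0.600
  cohort_spec(
    n_subjects = n_subjects, n_snps = 20, n_subpopulations = 1,
    maf_bounds = c(0.3, 0.3), fraction_monomorphic = 0,
    planted_interactions = lapply(1:10, function(k)
      planted_interaction(2 * k - 1, 2 * k, fr[k])),
    noise_sd = c(8, 12), missing_rate = 0, seed = seed
  )
}

# random full 3x3 composite tables (all cells populated) for oracle and
# conservation checks
random_full_table <- function(n = 180) {
  repeat {
    g_a <- sample(0:2, n, replace = TRUE, prob = runif(3, 0.2, 1))
    g_b <- sample(0:2, n, replace = TRUE, prob = runif(3, 0.2, 1))
    trait <- rnorm(n, 90, 10) + runif(1, -3, 3) * g_a * g_b
    tab <- composite_table(g_a, g_b, trait)
    if (all(tab$n_ij > 0)) return(tab)
  }
}

# random joint probability matrix (strictly positive cells)
random_joint <- function() {
  p <- matrix(runif(9, 0.05, 1), 3, 3)
  p / sum(p)
}

# independent SNP pair under HWE, returns the 3x3 count matrix
sim_independent_pair <- function(n = 500, maf = 0.3) {
  ga <- rbinom(n, 2, maf)
  gb <- rbinom(n, 2, maf)
  matrix(table(factor(ga, 0:2), factor(gb, 0:2)), 3, 3)
}

# brute-force 9-term mutual information (triple-purpose oracle)
mi_oracle <- function(p_ij) {
  ri <- rowSums(p_ij); cj <- colSums(p_ij)
  s <- 0
  for (i in 1:3) for (j in 1:3) {
    if (p_ij[i, j] > 0) s <- s + p_ij[i, j] * log(p_ij[i, j] / (ri[i] * cj[j]))
  }
  s
}

wmi_oracle <- function(geff, p_ij) {
  ri <- rowSums(p_ij); cj <- colSums(p_ij)
  s <- 0; sa <- 0
  for (i in 1:3) for (j in 1:3) {
    if (p_ij[i, j] > 0) {
      pmi <- log(p_ij[i, j] / (ri[i] * cj[j]))
      s <- s - geff[i, j] * p_ij[i, j] * pmi
      sa <- sa + abs(geff[i, j]) * p_ij[i, j] * abs(pmi)
    }
  }
  c(wmi = s, wmi_abs = sa)
}

# two-sided Fisher p by direct hypergeometric tail enumeration
fisher_oracle <- function(a, b, c, d) {
  m <- a + b; n_ <- c + d; k <- a + c
  lo <- max(0, k - n_); hi <- min(k, m)
  probs <- dhyper(lo:hi, m, n_, k)
  p_obs <- dhyper(a, m, n_, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# exact HWE p-value oracle: conditional distribution derived from the
# multinomial likelihood (independent code path from the implementation)
hwe_oracle <- function(n0, n1, n2) {
  n <- n0 + n1 + n2
  n_minor <- n1 + 2 * n2
  hets <- seq(n_minor %% 2, min(n_minor, 2 * n - n_minor), by = 2)
  q <- n_minor / (2 * n) # any q in (0,1) gives the same conditional law
  if (q == 0 || q == 1) return(NA_real_)
  probs <- vapply(hets, function(h) {
    hom2 <- (n_minor - h) / 2
    hom0 <- n - h - hom2
    stats::dmultinom(c(hom0, h, hom2),
                     prob = c((1 - q)^2, 2 * q * (1 - q), q^2))
  }, 0)
  probs <- probs / sum(probs)
  p_obs <- probs[match(n1, hets)]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-10)]))
}
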