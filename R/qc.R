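#' Minor allele frequency of one SNP
#'
#' `maf = min(q, 1 - q)` with `q = (n1 + 2 n2) / (2 n_nonmissing)`; missing
#' dosages are excluded from the denominator.
#'
#' @param dosages integer vector of minor-allele counts (0/1/2, NA missing).
#' @return frequency in `[0, 0.5]`; `NA` when every dosage is missing.
#' @export
compute_maf <- function(dosages) {
  check_dosages(dosages)
  d <- dosages[!is.na(dosages)]
  if (length(d) == 0L) return(NA_real_)
  q <- sum(d) / (2 * length(d))
  min(q, 1 - q)
}

#' Hardy-Weinberg equilibrium test
#'
#' Default is the 1-df chi-square goodness-of-fit of the observed genotype
#' counts against the HWE proportions implied by the estimated allele
#' frequency. `method = "exact"` instead computes the exact conditional test:
#' given the observed minor-allele count, the probability of every possible
#' heterozygote count is evaluated and the two-sided p-value sums all
#' configurations no more probable than the observed one. The exact test is
#' the right choice for the very small subpopulations that stratified designs
#' produce (classes of ~12 subjects occur).
#'
#' @param n0,n1,n2 genotype counts (major homozygote, heterozygote, minor
#'   homozygote).
#' @param method `"chisq"` or `"exact"`.
#' @return tibble with columns `statistic` (NA for exact), `p_value`, `method`.
#' @examples
#' hwe_test(36, 48, 16)   # exactly HWE: statistic 0, p = 1
#' hwe_test(50, 0, 50)    # maximal disequilibrium
#' @export
hwe_test <- function(n0, n1, n2, method = c("chisq", "exact")) {
  method <- match.arg(method)
  n <- n0 + n1 + n2
  assert_that(n >= 1, "need at least one genotyped subject")
  q <- (n1 + 2 * n2) / (2 * n)
  if (q == 0 || q == 1) {
    abort("HWE test undefined for a monomorphic SNP; exclude it as monomorphic instead")
  }
  if (method == "chisq") {
    p <- 1 - q
    expected <- n * c(p^2, 2 * p * q, q^2)
    stat <- sum((c(n0, n1, n2) - expected)^2 / expected)
    tibble(statistic = stat,
           p_value = pchisq(stat, df = 1, lower.tail = FALSE),
           method = "chisq")
  } else {
    tibble(statistic = NA_real_, p_value = hwe_exact_p(n0, n1, n2),
           method = "exact")
  }
}

# exact HWE p-value: conditional distribution of the heterozygote count given
# n and the minor-allele count, P(n_het) = n! nA! nB! 2^het /
# ((2n)! n_AA! het! n_BB!), evaluated in log space over the whole support
hwe_exact_p <- function(n0, n1, n2) {
  n <- n0 + n1 + n2
  n_minor <- n1 + 2 * n2
  if (n_minor > n) { # work with the rarer allele
    n_minor <- 2 * n - n_minor
    tmp <- n0; n0 <- n2; n2 <- tmp
  }
  hets <- seq(n_minor %% 2, n_minor, by = 2)
  hom_minor <- (n_minor - hets) / 2
  hom_major <- n - hets - hom_minor
  logp <- lfactorial(n) - lfactorial(hom_major) - lfactorial(hets) -
    lfactorial(hom_minor) + hets * log(2) +
    lfactorial(n_minor) + lfactorial(2 * n - n_minor) - lfactorial(2 * n)
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  p_obs <- p[match(n1, hets)]
  min(1, sum(p[p <= p_obs * (1 + 1e-10)]))
}

#' Per-scope SNP quality control
#'
#' Evaluates every SNP within one scope (the whole population or one class):
#' call rate, MAF, monomorphism and HWE. A SNP is `valid` when it is
#' polymorphic in scope, its MAF exceeds `maf_min` and its HWE p-value is at
#' least `hwe_alpha`. Validity is a per-scope notion -- a SNP monomorphic or
#' out of HWE in one class may be perfectly usable in another, and the bulk of
#' exclusions in small classes come from SNPs that turn monomorphic there.
#'
#' @param genotypes genotype tibble (`subject_id` + dosage columns).
#' @param subjects optional character vector restricting to a scope; `NULL`
#'   uses everyone.
#' @param scope label recorded in the output (e.g. `"population"` or a class).
#' @param maf_min minimum MAF, exclusive (default 0.01).
#' @param hwe_alpha SNPs with HWE p below this are excluded (default 0.05,
#'   unadjusted, per scope).
#' @param hwe_method passed to [hwe_test()].
#' @return tibble with one row per SNP: `snp_id`, `scope`, `n_called`,
#'   `call_rate`, `maf`, `hwe_p`, `monomorphic`, `valid`.
#' @export
snp_qc <- function(genotypes, subjects = NULL, scope = "population",
                   maf_min = 0.01, hwe_alpha = 0.05,
                   hwe_method = c("chisq", "exact")) {
  hwe_method <- match.arg(hwe_method)
  if (!is.null(subjects)) {
    genotypes <- genotypes[genotypes$subject_id %in% subjects, , drop = FALSE]
  }
  snps <- snp_cols(genotypes)
  if (nrow(genotypes) == 0L) {
    warn(sprintf("scope '%s' contains no subjects; no SNP is valid there", scope))
  }
  template <- tibble(snp_id = character(), scope = character(),
                     n_called = integer(), call_rate = double(),
                     maf = double(), hwe_p = double(),
                     monomorphic = logical(), valid = logical())
  rows <- lapply(snps, function(s) {
    d <- genotypes[[s]]
    check_dosages(d, s)
    called <- sum(!is.na(d))
    maf <- if (called > 0) compute_maf(d) else NA_real_
    mono <- is.na(maf) || maf == 0
    hwe_p <- NA_real_
    if (!mono) {
      counts <- tabulate(d[!is.na(d)] + 1L, nbins = 3L)
      hwe_p <- hwe_test(counts[1], counts[2], counts[3], method = hwe_method)$p_value
    }
    tibble(snp_id = s, scope = as.character(scope),
           n_called = called,
           call_rate = if (length(d)) called / length(d) else NA_real_,
           maf = maf, hwe_p = hwe_p, monomorphic = mono,
           valid = !mono && !is.na(maf) && maf > maf_min &&
             !is.na(hwe_p) && hwe_p >= hwe_alpha)
  })
  bind_rows(c(list(template), rows))
}

#' Valid SNPs in a scope
#'
#' Convenience wrapper around [snp_qc()] returning just the identifiers of
#' SNPs passing all filters.
#'
#' @inheritParams snp_qc
#' @return character vector of valid SNP ids (possibly empty).
#' @export
filter_snps <- function(genotypes, subjects = NULL, scope = "population",
                        maf_min = 0.01, hwe_alpha = 0.05,
                        hwe_method = c("chisq", "exact")) {
  qc <- snp_qc(genotypes, subjects, scope, maf_min, hwe_alpha, hwe_method)
  qc$snp_id[qc$valid]
}

#' Filter subjects by class-allocation reliability
#'
#' Retains subjects whose allocation probability is at least `threshold`
#' (so a threshold of 0.9 keeps probability exactly 0.9). Mixture-model class
#' assignments come with a posterior probability; dropping unreliably
#' allocated subjects trades sample size for class purity, and the valid
#' subject count per class shrinks monotonically as the threshold rises.
#'
#' @param assignments tibble with `subject_id`, `class_label`,
#'   `allocation_probability`.
#' @param threshold minimum allocation probability in `[0, 1]` (default 0.9;
#'   0.7 is a common sensitivity setting for small classes).
#' @return the retained rows of `assignments`, grouped order by class then id.
#' @export
filter_subjects_by_allocation <- function(assignments, threshold = 0.9) {
  assert_that(is.numeric(threshold) && threshold >= 0 && threshold <= 1,
              "threshold must lie in [0, 1]")
  assert_that(is_probability(assignments$allocation_probability),
              "allocation_probability must lie in [0, 1]")
  assignments |>
    filter(.data$allocation_probability >= threshold) |>
    arrange(.data$class_label, .data$subject_id)
}
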