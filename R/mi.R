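#' Mutual information of a joint genotype distribution
#'
#' `MI = sum_ij p_ij * ln(p_ij / (p_i p_j))` in nats, with `0 * ln(0) := 0`.
#' Natural logarithms are used throughout so that the scaled statistic
#' `2 N MI` has the chi-square calibration (it is the G statistic of
#' independence).
#'
#' @param p_ij 3x3 (or r x c) joint probability matrix.
#' @param p_i,p_j marginals; computed from `p_ij` when omitted. When supplied
#'   they must agree with the joint's row/column sums to `1e-9`.
#' @return mutual information in nats (non-negative up to rounding).
#' @examples
#' p <- outer(c(.25, .5, .25), c(.49, .42, .09))
#' mutual_information(p) # independent: 0
#' @export
mutual_information <- function(p_ij, p_i = NULL, p_j = NULL) {
  assert_that(is.matrix(p_ij) && all(p_ij >= 0) &&
                abs(sum(p_ij) - 1) < 1e-6,
              "p_ij must be a non-negative matrix summing to 1")
  ri <- rowSums(p_ij); cj <- colSums(p_ij)
  if (!is.null(p_i) && max(abs(p_i - ri)) > 1e-9)
    abort("supplied p_i inconsistent with rowSums(p_ij)")
  if (!is.null(p_j) && max(abs(p_j - cj)) > 1e-9)
    abort("supplied p_j inconsistent with colSums(p_ij)")
  pos <- p_ij > 0
  sum(p_ij[pos] * log(p_ij[pos] / (outer(ri, cj)[pos])))
}

#' Chi-square test of two-SNP mutual information
#'
#' The statistic is `2 N MI` computed on the empirical joint genotype
#' frequencies; under independence it is asymptotically chi-square with
#' `(r - 1)(c - 1)` degrees of freedom -- 4 for a full 3x3 composite-genotype
#' table. When a marginal genotype class is absent the support collapses and
#' the degrees of freedom are reduced accordingly (`df_reduced` flags this).
#'
#' @param n_ij matrix of genotype counts (typically 3x3).
#' @return tibble with `mi` (nats), `statistic`, `df`, `p_value`,
#'   `df_reduced`.
#' @export
mi_test <- function(n_ij) {
  assert_that(is.matrix(n_ij) && all(n_ij >= 0), "n_ij must be a count matrix")
  n <- sum(n_ij)
  assert_that(n >= 1, "need at least one subject")
  keep_r <- rowSums(n_ij) > 0
  keep_c <- colSums(n_ij) > 0
  sub <- n_ij[keep_r, keep_c, drop = FALSE]
  df <- (nrow(sub) - 1L) * (ncol(sub) - 1L)
  mi <- mutual_information(sub / n)
  stat <- 2 * n * mi
  tibble(mi = mi, statistic = stat, df = df,
         p_value = if (df >= 1) pchisq(stat, df, lower.tail = FALSE) else NA_real_,
         df_reduced = df < (nrow(n_ij) - 1L) * (ncol(n_ij) - 1L))
}

#' Weighted mutual information (WMI) of a SNP pair
#'
#' The interaction score weighting each composite genotype's pointwise
#' mutual-information term by its effect size:
#' `WMI = -sum_ij geff_ij * p_ij * ln(p_ij / (p_i p_j))` (the literal
#' definition, in mmHg x nats), together with an absolute-value variant
#' `sum_ij |geff_ij| * p_ij * |ln(p_ij / (p_i p_j))|` that is sign-proof and
#' is the default quantity for ranking interactions. Empty cells contribute
#' zero; `geff` entries on empty cells may be `NA`.
#'
#' @param geff_ij matrix of per-cell effect sizes (mmHg).
#' @param p_ij joint genotype frequency matrix.
#' @param p_i,p_j optional marginals, validated as in
#'   [mutual_information()].
#' @return tibble with `wmi` (literal signed score) and `wmi_abs`.
#' @export
weighted_mutual_information <- function(geff_ij, p_ij, p_i = NULL, p_j = NULL) {
  assert_that(is.matrix(geff_ij) && all(dim(geff_ij) == dim(p_ij)),
              "geff_ij and p_ij must be matrices of the same shape")
  ri <- rowSums(p_ij); cj <- colSums(p_ij)
  if (!is.null(p_i) && max(abs(p_i - ri)) > 1e-9)
    abort("supplied p_i inconsistent with rowSums(p_ij)")
  if (!is.null(p_j) && max(abs(p_j - cj)) > 1e-9)
    abort("supplied p_j inconsistent with colSums(p_ij)")
  pos <- which(p_ij > 0)
  if (any(!is.finite(geff_ij[pos]))) {
    abort("geff_ij must be finite on all nonempty cells")
  }
  pmi <- log(p_ij[pos] / outer(ri, cj)[pos])
  tibble(
    wmi = -sum(geff_ij[pos] * p_ij[pos] * pmi),
    wmi_abs = sum(abs(geff_ij[pos]) * p_ij[pos] * abs(pmi))
  )
}

#' Bonferroni significance flags
#'
#' @param p_values numeric vector.
#' @param family_size number of tests in the family (defaults to
#'   `length(p_values)`); must be at least that length.
#' @param alpha nominal family-wise level (default 0.05).
#' @return logical vector: `p <= alpha / family_size`.
#' @export
bonferroni_adjust <- function(p_values, family_size = length(p_values),
                              alpha = 0.05) {
  assert_that(family_size >= length(p_values),
              "family_size must be at least the number of tests")
  if (family_size == 0L) return(logical(0))
  !is.na(p_values) & p_values <= alpha / family_size
}
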