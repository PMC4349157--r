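#' Composite 3x3 genotype table for a SNP pair
#'
#' Cross-tabulates the dosages of two biallelic SNPs -- nine composite
#' genotypes -- after pairwise deletion of subjects missing either dosage,
#' and attaches cell counts, joint and marginal genotype frequencies, and
#' per-cell trait means and variances.
#'
#' @param g_a,g_b integer dosage vectors (0/1/2, NA missing), same length.
#' @param trait numeric trait vector (mmHg), same length.
#' @return an object of class `composite_table`: list with `n_ij` (3x3
#'   counts), `p_ij`, `p_i`, `p_j`, `m_ij` (cell means, NA where empty),
#'   `v_ij` (population within-cell variances), `n_total`, and the retained
#'   subject-level vectors `g_a`, `g_b`, `trait`.
#' @examples
#' tab <- composite_table(c(0, 1, 2, 0, 1), c(1, 1, 0, 2, 0),
#'                        c(80, 85, 90, 78, 88))
#' tab$n_ij
#' @export
composite_table <- function(g_a, g_b, trait) {
  assert_that(length(g_a) == length(g_b) && length(g_a) == length(trait),
              "g_a, g_b and trait must have the same length")
  check_dosages(g_a, "g_a"); check_dosages(g_b, "g_b")
  keep <- !is.na(g_a) & !is.na(g_b) & !is.na(trait)
  g_a <- as.integer(g_a[keep]); g_b <- as.integer(g_b[keep])
  trait <- as.numeric(trait[keep])
  n <- length(trait)

  cell <- 3L * g_a + g_b + 1L # 1..9, row-major by g_a
  n_vec <- tabulate(cell, nbins = 9L)
  sum_vec <- vapply(1:9, function(k) sum(trait[cell == k]), 0)
  m_vec <- ifelse(n_vec > 0, sum_vec / pmax(n_vec, 1L), NA_real_)
  v_vec <- vapply(1:9, function(k) {
    if (n_vec[k] == 0L) return(NA_real_)
    x <- trait[cell == k]
    mean((x - mean(x))^2)
  }, 0)

  dn <- list(g_a = as.character(0:2), g_b = as.character(0:2))
  n_ij <- matrix(n_vec, 3, 3, byrow = TRUE, dimnames = dn)
  p_ij <- if (n > 0) n_ij / n else n_ij * NA_real_
  structure(list(
    n_ij = n_ij, p_ij = p_ij,
    p_i = rowSums(p_ij), p_j = colSums(p_ij),
    m_ij = matrix(m_vec, 3, 3, byrow = TRUE, dimnames = dn),
    v_ij = matrix(v_vec, 3, 3, byrow = TRUE, dimnames = dn),
    n_total = n, g_a = g_a, g_b = g_b, trait = trait
  ), class = "composite_table")
}

#' @export
print.composite_table <- function(x, ...) {
  cat(sprintf("<composite_table> n = %d\ncounts:\n", x$n_total))
  print(x$n_ij)
  invisible(x)
}

#' Stepwise variance decomposition of a composite genotype table
#'
#' Decomposes the trait variance attributable to a SNP pair into marginal
#' (additive, single-SNP) and interaction components.
#'
#' Step 1 takes the grand mean `mu = sum(p_ij * m_ij)`. Step 2 removes
#' frequency-weighted marginal genotype effects; step 3 leaves interaction
#' deviations `d_ij` on the nonempty cells. Marginal effects and the variance
#' split come from the weighted least-squares projection of the cell means
#' onto the additive (row + column) model with weights `p_ij` and weighted
#' sum-to-zero constraints, for which
#' `var_marginal + var_interaction = var_genotypic` holds exactly for any
#' table (weighted-projection orthogonality) and `d_ij` vanishes identically
#' for purely additive traits. These effects equal the classical row-mean
#' deviations `a_i = sum_j(p_ij m_ij)/p_i - mu` whenever the joint genotype
#' frequencies factorize. All variances use the population (divide-by-n)
#' convention, so `var_genotypic <= var_phenotypic` and the relative genetic
#' variance lies in `[0, 1]` by construction.
#'
#' Significance of the interaction is the F-test of the full cell-means model
#' against the additive model (4 df for full 3x3 support, reduced for
#' degenerate tables).
#'
#' @param tab a [composite_table()].
#' @param geff_mode `"total"` (default): per-cell effect size
#'   `geff_ij = m_ij - mu`, the whole genotypic signal of the cell;
#'   `"interaction_only"`: the stepwise deviation `d_ij` after removing
#'   marginal effects.
#' @param min_cells minimum number of nonempty cells (default 2).
#' @return an object of class `variance_decomposition`: list with
#'   `grand_mean`, `marginal_effects_a`, `marginal_effects_b`, `d_ij`,
#'   `geff_ij`, `var_marginal`, `var_interaction`, `var_genotypic`,
#'   `var_phenotypic`, `relative_genetic_variance`, `interaction_p`,
#'   `interaction_df`, `n_total`.
#' @export
decompose_variance <- function(tab, geff_mode = c("total", "interaction_only"),
                               min_cells = 2L) {
  geff_mode <- match.arg(geff_mode)
  assert_that(inherits(tab, "composite_table"), "tab must be a composite_table")
  nonempty <- which(tab$n_ij > 0)
  if (length(nonempty) < min_cells) {
    abort(sprintf("only %d nonempty cells (need >= %d)", length(nonempty), min_cells))
  }
  var_phenotypic <- pop_var(tab$trait)
  if (is.na(var_phenotypic) || var_phenotypic == 0) {
    abort("trait variance is zero in scope; decomposition undefined")
  }

  p <- tab$p_ij; m <- tab$m_ij
  mu <- sum(p[nonempty] * m[nonempty])

  # weighted LS projection of cell means onto the additive model; exact
  # orthogonal split of the genotypic variance for arbitrary tables
  mvec <- m[nonempty]                               # column-major cell means
  ra <- droplevels(factor((nonempty - 1L) %% 3L, levels = 0:2))  # snp_a dosage
  ca <- droplevels(factor((nonempty - 1L) %/% 3L, levels = 0:2)) # snp_b dosage
  w <- p[nonempty]
  fit <- if (nlevels(ra) > 1 && nlevels(ca) > 1) {
    lm(mvec ~ ra + ca, weights = w)
  } else if (nlevels(ra) > 1) {
    lm(mvec ~ ra, weights = w)
  } else if (nlevels(ca) > 1) {
    lm(mvec ~ ca, weights = w)
  } else {
    lm(mvec ~ 1, weights = w)
  }
  fitted_add <- stats::fitted(fit)

  # marginal genotype effects in the weighted sum-to-zero parameterization
  # (sum_i p_i a_i = 0, sum_j p_j b_j = 0); these equal the classical
  # frequency-weighted row-mean deviations whenever the joint genotype
  # frequencies factorize
  cf <- coef(fit)
  pick <- function(lv, prefix) {
    out <- setNames(rep(NA_real_, 3), as.character(0:2))
    out[lv] <- c(0, cf[paste0(prefix, lv[-1])])[seq_along(lv)]
    out
  }
  alpha <- pick(levels(ra), "ra")
  beta <- pick(levels(ca), "ca")
  if (nlevels(ra) <= 1) alpha[levels(ra)] <- 0
  if (nlevels(ca) <= 1) beta[levels(ca)] <- 0
  a <- alpha - sum(tab$p_i * alpha, na.rm = TRUE)
  b <- beta - sum(tab$p_j * beta, na.rm = TRUE)

  # interaction deviations: the residual of the additive projection
  d_ij <- m
  d_ij[] <- NA_real_
  d_ij[nonempty] <- mvec - fitted_add

  var_genotypic <- sum(w * (mvec - mu)^2)
  var_marginal <- sum(w * (fitted_add - mu)^2)
  var_interaction <- sum(w * (mvec - fitted_add)^2)

  # F-test: cell-means vs additive model on subject-level sums of squares
  n <- tab$n_total
  sse_full <- sum(tab$n_ij[nonempty] * tab$v_ij[nonempty])
  ss_int <- n * var_interaction
  df_int <- length(nonempty) - fit$rank
  df_resid <- n - length(nonempty)
  interaction_p <- if (df_int <= 0) {
    NA_real_
  } else if (df_resid <= 0 || sse_full <= 1e-12 * var_phenotypic * n) {
    if (ss_int > 1e-12 * var_phenotypic * n) 0 else 1
  } else {
    fstat <- (ss_int / df_int) / (sse_full / df_resid)
    pf(fstat, df_int, df_resid, lower.tail = FALSE)
  }

  geff <- if (geff_mode == "total") m - mu else d_ij
  geff[tab$n_ij == 0] <- NA_real_

  structure(list(
    grand_mean = mu,
    marginal_effects_a = a, marginal_effects_b = b,
    d_ij = d_ij, geff_ij = geff, geff_mode = geff_mode,
    var_marginal = var_marginal, var_interaction = var_interaction,
    var_genotypic = var_genotypic, var_phenotypic = var_phenotypic,
    relative_genetic_variance = var_genotypic / var_phenotypic,
    interaction_p = interaction_p, interaction_df = max(df_int, 0L),
    n_cells = length(nonempty), n_total = n
  ), class = "variance_decomposition")
}

#' @export
print.variance_decomposition <- function(x, ...) {
  cat(sprintf(
    "<variance_decomposition> n = %d\n  var: marginal %.4g + interaction %.4g = genotypic %.4g (phenotypic %.4g)\n  relative genetic variance %.4f, interaction p %.3g (%d df)\n",
    x$n_total, x$var_marginal, x$var_interaction, x$var_genotypic,
    x$var_phenotypic, x$relative_genetic_variance, x$interaction_p,
    x$interaction_df))
  invisible(x)
}
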