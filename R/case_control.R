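#' Classify hypertension from blood-pressure cutoffs
#'
#' Adds affected flags using the conventional clinical cutoffs, boundary
#' inclusive: diastolic >= 90 mmHg, systolic >= 140 mmHg by default. Subjects
#' with a missing pressure get `NA` and drop out of prevalence denominators.
#'
#' @param phenotypes tibble with `diastolic_bp` and `systolic_bp` (mmHg).
#' @param dia_cut,sys_cut cutoffs in mmHg.
#' @return `phenotypes` with logical columns `affected_dia`, `affected_sys`.
#' @export
classify_hypertension <- function(phenotypes, dia_cut = 90, sys_cut = 140) {
  mutate(phenotypes,
         affected_dia = .data$diastolic_bp >= dia_cut,
         affected_sys = .data$systolic_bp >= sys_cut)
}

#' Prevalence of hypertension for one composite two-SNP genotype
#'
#' Carriers of the composite genotype (`snp_a == genotype_a` and
#' `snp_b == genotype_b`) are compared with all other subjects in a 2x2
#' carrier x affected table tested with the two-sided Fisher exact test
#' (composite-genotype cells are typically sparse). Reported fractions are
#' percents: prevalence of affected among carriers, and the genotype's
#' frequency in the population. `direction` is `"above"`/`"below"` depending
#' on how the carrier prevalence compares with the population prevalence.
#'
#' @param genotypes genotype tibble for the analysis population.
#' @param affected named logical vector (or tibble column) of affected flags
#'   aligned with `genotypes$subject_id`.
#' @param snp_a,snp_b SNP column names.
#' @param genotype_a,genotype_b dosages in 0/1/2 defining the cell.
#' @param method `"fisher"` (default) or `"chisq"`.
#' @return one-row tibble (`NULL` invisibly if there are no carriers):
#'   columns `snp_a`, `genotype_a`, `snp_b`, `genotype_b`, `n_carriers`,
#'   `n_affected_carriers`, `affected_fraction_carriers`,
#'   `genotype_frequency_population`, `population_prevalence`, `p_value`,
#'   `direction`.
#' @export
genotype_prevalence_test <- function(genotypes, affected, snp_a, genotype_a,
                                     snp_b, genotype_b,
                                     method = c("fisher", "chisq")) {
  method <- match.arg(method)
  ga <- genotypes[[snp_a]]; gb <- genotypes[[snp_b]]
  ok <- !is.na(ga) & !is.na(gb) & !is.na(affected)
  carrier <- ok & ga == genotype_a & gb == genotype_b
  n_car <- sum(carrier)
  if (n_car == 0L) {
    warn(sprintf("no carriers of %s=%d / %s=%d; result suppressed",
                 snp_a, genotype_a, snp_b, genotype_b))
    return(invisible(NULL))
  }
  aff <- affected[ok]; car <- carrier[ok]
  tab <- matrix(c(sum(car & aff), sum(car & !aff),
                  sum(!car & aff), sum(!car & !aff)), 2, 2)
  p <- if (method == "fisher") fisher.test(tab)$p.value
       else suppressWarnings(chisq.test(tab, correct = FALSE)$p.value)
  prev_car <- 100 * sum(car & aff) / sum(car)
  prev_pop <- 100 * mean(aff)
  tibble(snp_a = snp_a, genotype_a = as.integer(genotype_a),
         snp_b = snp_b, genotype_b = as.integer(genotype_b),
         n_carriers = sum(car), n_affected_carriers = sum(car & aff),
         affected_fraction_carriers = prev_car,
         genotype_frequency_population = 100 * sum(car) / length(car),
         population_prevalence = prev_pop,
         p_value = p,
         direction = if (prev_car > prev_pop) "above"
                     else if (prev_car < prev_pop) "below" else "none")
}

#' Case-control analysis of significant two-SNP genotypes
#'
#' Runs [genotype_prevalence_test()] over every observed composite genotype
#' of the supplied SNP pairs (typically the WMI-significant pairs of a scan)
#' in the entire population, for one trait's affected flag, with Bonferroni
#' correction over all tested cells.
#'
#' @param genotypes genotype tibble (whole population).
#' @param phenotypes output of [classify_hypertension()].
#' @param pairs tibble with `snp_a`, `snp_b` columns (de-duplicated).
#' @param trait `"diastolic"` or `"systolic"`; selects the affected flag.
#' @param alpha nominal level.
#' @param method `"fisher"` or `"chisq"`.
#' @return tibble of per-cell results with `significant_bonferroni`.
#' @export
case_control_scan <- function(genotypes, phenotypes, pairs,
                              trait = c("diastolic", "systolic"),
                              alpha = 0.05, method = c("fisher", "chisq")) {
  trait <- match.arg(trait)
  method <- match.arg(method)
  flag_col <- if (trait == "diastolic") "affected_dia" else "affected_sys"
  assert_that(flag_col %in% names(phenotypes),
              "phenotypes must come from classify_hypertension()")
  affected <- phenotypes[[flag_col]][match(genotypes$subject_id,
                                           phenotypes$subject_id)]
  pairs <- distinct(pairs[c("snp_a", "snp_b")])
  rows <- list()
  for (i in seq_len(nrow(pairs))) {
    sa <- pairs$snp_a[i]; sb <- pairs$snp_b[i]
    ga <- genotypes[[sa]]; gb <- genotypes[[sb]]
    seen <- unique(stats::na.omit(data.frame(a = ga, b = gb)))
    for (j in seq_len(nrow(seen))) {
      r <- suppressWarnings(
        genotype_prevalence_test(genotypes, affected, sa, seen$a[j],
                                 sb, seen$b[j], method = method))
      if (!is.null(r)) rows[[length(rows) + 1L]] <- r
    }
  }
  out <- bind_rows(rows)
  if (nrow(out) > 0L) {
    out$trait <- trait
    out$significant_bonferroni <- bonferroni_adjust(out$p_value, nrow(out), alpha)
  }
  out
}

#' Compare genotype distributions between scopes
#'
#' Classical case-control comparison of per-SNP genotype distributions: each
#' class against each other class, and each class against all remaining
#' subjects. Tests are 3-level genotype chi-square tests, switching to the
#' Fisher exact test when any expected count is small (< 5). SNPs
#' monomorphic in both scopes are skipped. Bonferroni correction is applied
#' over all SNP x scope-pair tests.
#'
#' @param genotypes genotype tibble.
#' @param assignments assignment tibble (`subject_id`, `class_label`).
#' @param include_rest also compare each class to the rest of the population.
#' @param alpha nominal level.
#' @return tibble with `snp_id`, `scope_a`, `scope_b`, `test`, `p_value`,
#'   `significant_bonferroni`.
#' @export
compare_genotype_distributions <- function(genotypes, assignments,
                                           include_rest = TRUE, alpha = 0.05) {
  classes <- sort(unique(assignments$class_label))
  snps <- snp_cols(genotypes)
  class_of <- assignments$class_label[match(genotypes$subject_id,
                                            assignments$subject_id)]
  pairs <- list()
  if (length(classes) > 1) {
    cmb <- utils::combn(classes, 2)
    for (k in seq_len(ncol(cmb))) {
      pairs[[length(pairs) + 1L]] <- list(a = cmb[1, k], b = cmb[2, k], rest = FALSE)
    }
  }
  if (include_rest && length(classes) > 1) {
    for (cl in classes) {
      pairs[[length(pairs) + 1L]] <- list(a = cl, b = NA, rest = TRUE)
    }
  }
  rows <- list()
  for (pp in pairs) {
    in_a <- class_of == pp$a
    in_b <- if (pp$rest) !in_a else class_of == pp$b
    if (!any(in_a, na.rm = TRUE) || !any(in_b, na.rm = TRUE)) next
    for (s in snps) {
      g <- genotypes[[s]]
      ca <- tabulate(g[which(in_a)] + 1L, nbins = 3L)
      cb <- tabulate(g[which(in_b)] + 1L, nbins = 3L)
      keep <- (ca + cb) > 0
      if (sum(keep) < 2L) next # monomorphic in both scopes
      tab <- rbind(ca[keep], cb[keep])
      expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
      if (any(expected < 5)) {
        p <- fisher.test(tab)$p.value
        test <- "fisher"
      } else {
        p <- suppressWarnings(chisq.test(tab, correct = FALSE)$p.value)
        test <- "chisq"
      }
      rows[[length(rows) + 1L]] <- tibble(
        snp_id = s, scope_a = as.character(pp$a),
        scope_b = if (pp$rest) "rest" else as.character(pp$b),
        test = test, p_value = p)
    }
  }
  out <- bind_rows(rows)
  if (nrow(out) > 0L) {
    out$significant_bonferroni <- bonferroni_adjust(out$p_value, nrow(out), alpha)
  }
  out
}

#' Trait means conditional on a composite two-SNP genotype
#'
#' Welch two-sample comparison of the trait between carriers of each
#' composite genotype and all other subjects, Bonferroni-corrected over all
#' tested cells. Cells with fewer than 2 carriers or 2 non-carriers are
#' suppressed.
#'
#' @param genotypes genotype tibble.
#' @param phenotypes tibble with the trait column.
#' @param pairs tibble with `snp_a`, `snp_b`.
#' @param trait trait column name.
#' @param alpha nominal level.
#' @return tibble with per-cell mean difference (carriers minus others),
#'   p-value and `significant_bonferroni`.
#' @export
trait_mean_comparison <- function(genotypes, phenotypes, pairs,
                                  trait = "diastolic_bp", alpha = 0.05) {
  y <- phenotypes[[trait]][match(genotypes$subject_id, phenotypes$subject_id)]
  pairs <- distinct(pairs[c("snp_a", "snp_b")])
  rows <- list()
  for (i in seq_len(nrow(pairs))) {
    sa <- pairs$snp_a[i]; sb <- pairs$snp_b[i]
    ga <- genotypes[[sa]]; gb <- genotypes[[sb]]
    seen <- unique(stats::na.omit(data.frame(a = ga, b = gb)))
    for (j in seq_len(nrow(seen))) {
      carrier <- !is.na(ga) & !is.na(gb) & ga == seen$a[j] & gb == seen$b[j]
      yc <- y[carrier & !is.na(y)]; yo <- y[!carrier & !is.na(y)]
      if (length(yc) < 2L || length(yo) < 2L) next
      if (sd(yc) == 0 && sd(yo) == 0) next # degenerate, Welch undefined
      tt <- t.test(yc, yo)
      rows[[length(rows) + 1L]] <- tibble(
        snp_a = sa, genotype_a = as.integer(seen$a[j]),
        snp_b = sb, genotype_b = as.integer(seen$b[j]),
        trait = trait, n_carriers = length(yc),
        mean_carriers = mean(yc), mean_others = mean(yo),
        mean_difference = mean(yc) - mean(yo),
        p_value = tt$p.value)
    }
  }
  out <- bind_rows(rows)
  if (nrow(out) > 0L) {
    out$significant_bonferroni <- bonferroni_adjust(out$p_value, nrow(out), alpha)
  }
  out
}
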