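#' Exhaustive two-SNP epistasis scan within one scope
#'
#' For every unordered pair of QC-valid SNPs, builds the composite 3x3
#' genotype table (pairwise deletion of missing dosages), decomposes the
#' trait variance into marginal and interaction components, tests the
#' interaction (F-test of cell means vs additive model), computes mutual
#' information with its chi-square(4 df) test, and the weighted
#' mutual-information score. Pairs are enumerated in lexicographic SNP-id
#' order, so results are invariant to subject ordering and column order.
#'
#' @param genotypes genotype tibble (`subject_id` + dosage columns).
#' @param phenotypes tibble with `subject_id` and the trait column.
#' @param trait name of the trait column (e.g. `"diastolic_bp"`).
#' @param subjects optional subject-id vector defining the scope.
#' @param scope label recorded on every row.
#' @param snp_info optional tibble `snp_id`, `gene` for gene annotation.
#' @param maf_min,hwe_alpha,hwe_method SNP QC settings, see [snp_qc()].
#' @param min_cell_subjects minimum subjects per pair after pairwise deletion
#'   (default 10); smaller pairs are skipped and logged.
#' @param nominal_alpha nominal significance level (default 0.05).
#' @param family_size Bonferroni family for the MI test; defaults to the
#'   number of tested pairs in this scope x trait.
#' @param geff_mode passed to [decompose_variance()].
#' @return tibble, one row per tested pair, with decomposition, MI/WMI and
#'   significance columns. Attributes: `skipped` (tibble of skipped pairs
#'   with reasons), `n_subjects`, `n_valid_snps`.
#' @export
scan_pairs <- function(genotypes, phenotypes, trait = "diastolic_bp",
                       subjects = NULL, scope = "population",
                       snp_info = NULL,
                       maf_min = 0.01, hwe_alpha = 0.05,
                       hwe_method = c("chisq", "exact"),
                       min_cell_subjects = 10L,
                       nominal_alpha = 0.05,
                       family_size = NULL,
                       geff_mode = c("total", "interaction_only")) {
  hwe_method <- match.arg(hwe_method)
  geff_mode <- match.arg(geff_mode)
  assert_that(trait %in% names(phenotypes),
              sprintf("phenotypes has no column '%s'", trait))
  if (!is.null(subjects)) {
    genotypes <- genotypes[genotypes$subject_id %in% subjects, , drop = FALSE]
  }
  genotypes <- genotypes[order(genotypes$subject_id), , drop = FALSE]
  y <- phenotypes[[trait]][match(genotypes$subject_id, phenotypes$subject_id)]
  valid <- sort(filter_snps(genotypes, scope = scope, maf_min = maf_min,
                            hwe_alpha = hwe_alpha, hwe_method = hwe_method))

  empty <- tibble(snp_a = character(), snp_b = character(),
                  gene_a = character(), gene_b = character(),
                  scope = character(), trait = character(), n = integer(),
                  grand_mean = double(), var_marginal = double(),
                  var_interaction = double(), var_genotypic = double(),
                  var_phenotypic = double(),
                  relative_genetic_variance = double(), n_cells = integer(),
                  interaction_p = double(), epistasis_nominal = logical(),
                  epistasis_bonferroni = logical(), mi = double(),
                  mi_statistic = double(), mi_df = integer(),
                  mi_p = double(), mi_df_reduced = logical(),
                  wmi = double(), wmi_abs = double(),
                  significant_nominal = logical(),
                  significant_bonferroni = logical())
  skipped <- tibble(snp_a = character(), snp_b = character(), reason = character())
  if (length(valid) < 2L) {
    out <- empty
    attr(out, "skipped") <- skipped
    attr(out, "n_subjects") <- nrow(genotypes)
    attr(out, "n_valid_snps") <- length(valid)
    return(out)
  }

  gmat <- as.matrix(genotypes[valid])
  pairs <- utils::combn(valid, 2L)
  rows <- vector("list", ncol(pairs))
  skip_rows <- list()
  for (k in seq_len(ncol(pairs))) {
    sa <- pairs[1, k]; sb <- pairs[2, k]
    tab <- composite_table(gmat[, sa], gmat[, sb], y)
    if (tab$n_total < min_cell_subjects) {
      skip_rows[[length(skip_rows) + 1L]] <-
        tibble(snp_a = sa, snp_b = sb,
               reason = sprintf("only %d subjects after pairwise deletion", tab$n_total))
      next
    }
    dec <- tryCatch(decompose_variance(tab, geff_mode = geff_mode),
                    error = function(e) conditionMessage(e))
    if (is.character(dec)) {
      skip_rows[[length(skip_rows) + 1L]] <- tibble(snp_a = sa, snp_b = sb, reason = dec)
      next
    }
    mt <- mi_test(tab$n_ij)
    wm <- weighted_mutual_information(dec$geff_ij, tab$p_ij)
    rows[[k]] <- tibble(
      snp_a = sa, snp_b = sb, gene_a = NA_character_, gene_b = NA_character_,
      scope = as.character(scope), trait = trait, n = tab$n_total,
      grand_mean = dec$grand_mean, var_marginal = dec$var_marginal,
      var_interaction = dec$var_interaction,
      var_genotypic = dec$var_genotypic,
      var_phenotypic = dec$var_phenotypic,
      relative_genetic_variance = dec$relative_genetic_variance,
      n_cells = dec$n_cells,
      interaction_p = dec$interaction_p,
      epistasis_nominal = NA, epistasis_bonferroni = NA,
      mi = mt$mi, mi_statistic = mt$statistic, mi_df = as.integer(mt$df),
      mi_p = mt$p_value, mi_df_reduced = mt$df_reduced,
      wmi = wm$wmi, wmi_abs = wm$wmi_abs,
      significant_nominal = NA, significant_bonferroni = NA
    )
  }
  out <- bind_rows(rows)
  if (nrow(out) == 0L) out <- empty
  if (length(skip_rows)) skipped <- bind_rows(skipped, bind_rows(skip_rows))

  if (nrow(out) > 0L) {
    fam <- family_size %||% nrow(out)
    out$epistasis_nominal <- !is.na(out$interaction_p) &
      out$interaction_p < nominal_alpha
    out$epistasis_bonferroni <- bonferroni_adjust(out$interaction_p, fam,
                                                  nominal_alpha)
    out$significant_nominal <- !is.na(out$mi_p) & out$mi_p <= nominal_alpha
    out$significant_bonferroni <- bonferroni_adjust(out$mi_p, fam, nominal_alpha)
    if (!is.null(snp_info)) {
      gmap <- setNames(snp_info$gene, snp_info$snp_id)
      out$gene_a <- unname(gmap[out$snp_a])
      out$gene_b <- unname(gmap[out$snp_b])
    }
  }
  attr(out, "skipped") <- skipped
  attr(out, "n_subjects") <- nrow(genotypes)
  attr(out, "n_valid_snps") <- length(valid)
  out
}

#' Scan every subpopulation and trait of a cohort
#'
#' Applies the allocation-probability filter, then runs [scan_pairs()] in
#' each class for each requested trait. Any partition can be supplied as the
#' assignment table -- mixture-model classes with posterior probabilities, or
#' a hard labelling such as sex with probability 1.
#'
#' @param cohort a `wmi_cohort`, or a list with `genotypes`, `phenotypes`,
#'   `assignments` (and optionally `snp_info`) tibbles.
#' @param traits trait columns to scan.
#' @param allocation_threshold minimum allocation probability (default 0.9).
#' @param min_class_size classes with fewer retained subjects are skipped.
#' @param ... passed to [scan_pairs()].
#' @return tibble of all per-pair results; attribute `scope_info` holds one
#'   row per scope x trait with subject and valid-SNP counts.
#' @export
scan_cohort <- function(cohort, traits = c("diastolic_bp", "systolic_bp"),
                        allocation_threshold = 0.9, min_class_size = 10L,
                        ...) {
  kept <- filter_subjects_by_allocation(cohort$assignments, allocation_threshold)
  classes <- sort(unique(kept$class_label))
  res <- list(); info <- list()
  for (cl in classes) {
    ids <- kept$subject_id[kept$class_label == cl]
    if (length(ids) < min_class_size) next
    for (tr in traits) {
      r <- scan_pairs(cohort$genotypes, cohort$phenotypes, trait = tr,
                      subjects = ids, scope = as.character(cl),
                      snp_info = cohort$snp_info, ...)
      info[[length(info) + 1L]] <- tibble(
        scope = as.character(cl), trait = tr,
        n_subjects = attr(r, "n_subjects"),
        n_valid_snps = attr(r, "n_valid_snps"))
      res[[length(res) + 1L]] <- r
    }
  }
  out <- bind_rows(res)
  attr(out, "scope_info") <- bind_rows(info)
  out
}

#' Per-scope summary of an epistasis scan
#'
#' Reproduces the usual summary-table structure: subjects, valid SNPs,
#' epistasis count (nominally significant interaction F-tests), total WMI,
#' Bonferroni-significant WMI count, and the WMI/epistasis ratio. Both the
#' total over all epistatic pairs and over Bonferroni-passed pairs are
#' reported, since either reading of "total" is defensible.
#'
#' @param results output of [scan_pairs()] or [scan_cohort()].
#' @param scope_info optional tibble (`scope`, `trait`, `n_subjects`,
#'   `n_valid_snps`); taken from the results attribute when present.
#' @return tibble, one row per scope x trait.
#' @export
summarize_scan <- function(results, scope_info = attr(results, "scope_info")) {
  if (nrow(results) == 0L) {
    return(tibble(scope = character(), trait = character(),
                  n_subjects = integer(), n_valid_snps = integer(),
                  n_pairs = integer(), epistasis_n = integer(),
                  total_wmi = double(), total_wmi_bonferroni = double(),
                  wmi_significant_n = integer(), wmi_epistasis_ratio = double()))
  }
  out <- results |>
    group_by(.data$scope, .data$trait) |>
    summarise(
      n_pairs = dplyr::n(),
      epistasis_n = sum(.data$epistasis_nominal, na.rm = TRUE),
      total_wmi = sum(.data$wmi_abs[.data$epistasis_nominal], na.rm = TRUE),
      total_wmi_bonferroni = sum(.data$wmi_abs[.data$significant_bonferroni],
                                 na.rm = TRUE),
      wmi_significant_n = sum(.data$significant_bonferroni, na.rm = TRUE),
      .groups = "drop") |>
    mutate(wmi_epistasis_ratio = ifelse(.data$epistasis_n > 0,
                                        .data$wmi_significant_n / .data$epistasis_n,
                                        NA_real_))
  if (!is.null(scope_info)) {
    out <- left_join(scope_info, out, by = c("scope", "trait"))
  }
  out
}

#' Unique significant pairs across scopes
#'
#' De-duplicates Bonferroni-significant WMI interactions across
#' subpopulations, per trait: the same SNP pair recovered in several classes
#' counts once.
#'
#' @param results output of [scan_cohort()].
#' @return tibble with `trait`, `n_occurrences` (significant scope-level
#'   hits) and `n_unique` (distinct pairs).
#' @export
unique_significant_pairs <- function(results) {
  sig <- filter(results, .data$significant_bonferroni)
  sig |>
    group_by(.data$trait) |>
    summarise(n_occurrences = dplyr::n(),
              n_unique = dplyr::n_distinct(paste(.data$snp_a, .data$snp_b)),
              .groups = "drop")
}
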