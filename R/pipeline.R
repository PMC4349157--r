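#' Pipeline configuration
#'
#' All analysis thresholds in one serializable object. Defaults follow the
#' conventions of stratified blood-pressure epistasis analysis: MAF cutoff
#' 0.01, per-scope HWE exclusion at 0.05, allocation-probability threshold
#' 0.9 (with 0.7 the usual sensitivity setting for small classes), nominal
#' alpha 0.05 with Bonferroni correction per scope x trait, hypertension
#' cutoffs 90/140 mmHg.
#'
#' @param maf_min minimum minor allele frequency (exclusive).
#' @param hwe_alpha per-scope HWE exclusion level.
#' @param hwe_method `"chisq"` or `"exact"`.
#' @param allocation_threshold minimum allocation probability.
#' @param nominal_alpha nominal significance level.
#' @param min_cell_subjects minimum subjects per SNP pair.
#' @param min_class_size minimum retained subjects per class.
#' @param dia_cut,sys_cut hypertension cutoffs in mmHg.
#' @param wmi_ranking `"absolute"` (rank by |WMI|) or `"literal"`.
#' @param geff_mode `"total"` or `"interaction_only"` effect sizes.
#' @param curve_gate,curve_mode heritability-curve settings, see
#'   [assemble_curve()].
#' @param bootstrap_B bootstrap replicates for heritability CIs.
#' @param network_gate `"bonferroni"` or `"nominal"`.
#' @param seed master seed; all pipeline randomness flows from it.
#' @return object of class `pipeline_config` (named list).
#' @export
pipeline_config <- function(maf_min = 0.01, hwe_alpha = 0.05,
                            hwe_method = "chisq",
                            allocation_threshold = 0.9,
                            nominal_alpha = 0.05,
                            min_cell_subjects = 10L, min_class_size = 10L,
                            dia_cut = 90, sys_cut = 140,
                            wmi_ranking = "absolute", geff_mode = "total",
                            curve_gate = "wmi_bonferroni",
                            curve_mode = "per_pair",
                            bootstrap_B = 500L,
                            network_gate = "bonferroni", seed = 1L) {
  cfg <- list(maf_min = maf_min, hwe_alpha = hwe_alpha,
              hwe_method = hwe_method,
              allocation_threshold = allocation_threshold,
              nominal_alpha = nominal_alpha,
              min_cell_subjects = as.integer(min_cell_subjects),
              min_class_size = as.integer(min_class_size),
              dia_cut = dia_cut, sys_cut = sys_cut,
              wmi_ranking = wmi_ranking, geff_mode = geff_mode,
              curve_gate = curve_gate, curve_mode = curve_mode,
              bootstrap_B = as.integer(bootstrap_B),
              network_gate = network_gate, seed = as.integer(seed))
  assert_that(is_probability(c(cfg$maf_min, cfg$hwe_alpha,
                               cfg$allocation_threshold, cfg$nominal_alpha)),
              "probabilities/thresholds must lie in [0, 1]")
  assert_that(cfg$maf_min <= 0.5, "maf_min cannot exceed 0.5")
  assert_that(cfg$dia_cut > 0 && cfg$sys_cut > 0, "cutoffs must be positive mmHg")
  assert_that(cfg$wmi_ranking %in% c("absolute", "literal"),
              "wmi_ranking must be 'absolute' or 'literal'")
  assert_that(cfg$geff_mode %in% c("total", "interaction_only"),
              "geff_mode must be 'total' or 'interaction_only'")
  assert_that(cfg$hwe_method %in% c("chisq", "exact"),
              "hwe_method must be 'chisq' or 'exact'")
  assert_that(cfg$network_gate %in% c("bonferroni", "nominal"),
              "network_gate must be 'bonferroni' or 'nominal'")
  structure(cfg, class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  for (nm in names(x)) cat(sprintf("  %s: %s\n", nm, x[[nm]]))
  invisible(x)
}

#' Serialize / restore a pipeline configuration
#'
#' YAML round trips are lossless: `read_config(write_config(cfg, f))` equals
#' `cfg`.
#'
#' @param config a [pipeline_config()].
#' @param path YAML file path.
#' @return `write_config` the path invisibly; `read_config` the config.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' Hash of a configuration
#'
#' Stamped into every pipeline output file so downstream consumers can refuse
#' tables produced under a different configuration.
#'
#' @param config a [pipeline_config()].
#' @return 8-hex-digit string.
#' @export
config_hash <- function(config) {
  fnv1a_hash(paste(names(config), vapply(config, format, ""),
                   sep = "=", collapse = ";"))
}

write_stamped_tsv <- function(df, path, hash) {
  header <- c("# wmiscan schema_version: 1",
              sprintf("# config_hash: %s", hash))
  body <- readr::format_tsv(df)
  writeLines(c(header, sub("\n$", "", body)), path, sep = "\n")
  invisible(path)
}

#' Read a pipeline output table, checking its configuration stamp
#'
#' @param path TSV written by [run_pipeline()].
#' @param config the configuration the caller is operating under; a mismatch
#'   between its hash and the file's stamp is an error.
#' @return tibble.
#' @export
read_pipeline_table <- function(path, config = NULL) {
  hdr <- readr::read_lines(path, n_max = 2)
  stamp <- sub("^# config_hash: ", "", hdr[2])
  if (!is.null(config) && stamp != config_hash(config)) {
    abort(sprintf("config hash mismatch: file %s was written under %s, current config is %s",
                  basename(path), stamp, config_hash(config)))
  }
  readr::read_tsv(path, comment = "#", show_col_types = FALSE, progress = FALSE)
}

validate_cohort_inputs <- function(cohort) {
  problems <- character(0)
  g_ids <- cohort$genotypes$subject_id
  p_ids <- cohort$phenotypes$subject_id
  a_ids <- cohort$assignments$subject_id
  miss_g <- setdiff(p_ids, g_ids)
  miss_a <- setdiff(p_ids, a_ids)
  if (length(miss_g)) {
    problems <- c(problems, sprintf(
      "%d phenotype subject(s) missing from genotypes (e.g. %s)",
      length(miss_g), paste(head(miss_g, 3), collapse = ", ")))
  }
  if (length(miss_a)) {
    problems <- c(problems, sprintf(
      "%d phenotype subject(s) missing from assignments (e.g. %s)",
      length(miss_a), paste(head(miss_a, 3), collapse = ", ")))
  }
  if (length(problems)) {
    abort(paste(c("input cross-reference failures:", problems), collapse = "\n  "))
  }
  invisible(TRUE)
}

#' Run the full epistasis analysis pipeline
#'
#' Stages, in order: input cross-referencing, per-scope SNP QC, the
#' exhaustive pair scan in every class for both traits, scope summaries,
#' heritability estimation, hypertension case-control analysis of the
#' significant pairs, genotype-distribution comparisons between classes,
#' trait-mean comparisons, and network construction with heavy-tail fits.
#' Every output table is stamped with a schema version and the configuration
#' hash; given the same inputs, configuration and seed, two runs produce
#' byte-identical files.
#'
#' @param cohort a `wmi_cohort` (or equivalent list of tibbles).
#' @param config a [pipeline_config()].
#' @param out_dir output directory; `NULL` skips file output.
#' @return (invisibly) a list with every intermediate result: `qc`, `scan`,
#'   `summary`, `unique_pairs`, `heritability`, `case_control`,
#'   `genotype_distributions`, `trait_comparisons`, `networks`, `hubs`,
#'   `heavy_tail`, `files`.
#' @export
run_pipeline <- function(cohort, config = pipeline_config(), out_dir = NULL) {
  validate_cohort_inputs(cohort)
  set.seed(config$seed)
  traits <- c("diastolic_bp", "systolic_bp")

  kept <- filter_subjects_by_allocation(cohort$assignments,
                                        config$allocation_threshold)
  qc_pop <- snp_qc(cohort$genotypes, scope = "population",
                   maf_min = config$maf_min, hwe_alpha = config$hwe_alpha,
                   hwe_method = config$hwe_method)
  qc_cls <- lapply(sort(unique(kept$class_label)), function(cl) {
    snp_qc(cohort$genotypes,
           subjects = kept$subject_id[kept$class_label == cl],
           scope = as.character(cl), maf_min = config$maf_min,
           hwe_alpha = config$hwe_alpha, hwe_method = config$hwe_method)
  })
  qc <- bind_rows(c(list(qc_pop), qc_cls))

  scan <- scan_cohort(cohort, traits = traits,
                      allocation_threshold = config$allocation_threshold,
                      min_class_size = config$min_class_size,
                      maf_min = config$maf_min, hwe_alpha = config$hwe_alpha,
                      hwe_method = config$hwe_method,
                      min_cell_subjects = config$min_cell_subjects,
                      nominal_alpha = config$nominal_alpha,
                      geff_mode = config$geff_mode)
  summary_tbl <- summarize_scan(scan)
  uniq <- unique_significant_pairs(scan)

  herit <- estimate_heritability(scan, gate = config$curve_gate,
                                 mode = config$curve_mode,
                                 B = config$bootstrap_B, seed = config$seed)

  phen <- classify_hypertension(cohort$phenotypes, config$dia_cut,
                                config$sys_cut)
  sig_pairs <- distinct(scan[which(scan$significant_bonferroni),
                             c("snp_a", "snp_b")])
  cc <- bind_rows(lapply(c("diastolic", "systolic"), function(tr) {
    if (nrow(sig_pairs) == 0L) return(tibble())
    case_control_scan(cohort$genotypes, phen, sig_pairs, trait = tr,
                      alpha = config$nominal_alpha)
  }))
  gdist <- compare_genotype_distributions(cohort$genotypes,
                                          cohort$assignments,
                                          alpha = config$nominal_alpha)
  tmc <- bind_rows(lapply(traits, function(tr) {
    if (nrow(sig_pairs) == 0L) return(tibble())
    trait_mean_comparison(cohort$genotypes, phen, sig_pairs, trait = tr,
                          alpha = config$nominal_alpha)
  }))

  networks <- list(
    snp = build_network(scan, level = "snp", gate = config$network_gate),
    gene = build_network(scan, level = "gene", gate = config$network_gate)
  )
  hubs <- lapply(networks, function(nw) {
    if (nrow(nw$nodes) == 0L) tibble() else identify_hubs(nw, k = 10L)
  })
  heavy_tail <- list()
  wvals <- networks$snp$edges$weight
  if (length(wvals) >= 20 && length(unique(wvals)) > 1) {
    ht <- fit_power_law(wvals, discrete = FALSE)
    heavy_tail$wmi <- ht
  }
  dvals <- networks$snp$nodes$degree
  if (length(dvals) >= 20 && length(unique(dvals)) > 1) {
    heavy_tail$degree <- fit_power_law(dvals, discrete = TRUE)
  }

  files <- character(0)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    hash <- config_hash(config)
    tabs <- list(qc = qc, scan = scan, summary = summary_tbl,
                 unique_pairs = uniq,
                 heritability = herit, case_control = cc,
                 genotype_distributions = gdist, trait_comparisons = tmc,
                 network_edges_snp = networks$snp$edges,
                 network_edges_gene = networks$gene$edges,
                 hubs_snp = hubs$snp, hubs_gene = hubs$gene)
    for (nm in names(tabs)) {
      f <- file.path(out_dir, paste0(nm, ".tsv"))
      write_stamped_tsv(tabs[[nm]], f, hash)
      files[nm] <- f
    }
    write_config(config, file.path(out_dir, "config.yaml"))
    files["config"] <- file.path(out_dir, "config.yaml")
    if (nrow(networks$gene$nodes) > 0) {
      f <- file.path(out_dir, "network_gene.graphml")
      write_network(networks$gene, graphml_path = f)
      files["graphml"] <- f
    }
  }

  invisible(list(qc = qc, scan = scan, summary = summary_tbl,
                 unique_pairs = uniq, heritability = herit,
                 case_control = cc, genotype_distributions = gdist,
                 trait_comparisons = tmc, networks = networks, hubs = hubs,
                 heavy_tail = heavy_tail, config = config, files = files))
}
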