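# Readers and writers for the pipeline's three standard inputs:
# genotypes (TSV or PLINK-style ped/map), phenotypes (TSV), assignments (TSV).

#' Read a genotype table
#'
#' TSV dialect: a `subject_id` column plus one integer dosage column per SNP
#' (0/1/2, `NA` missing). ped/map dialect: PLINK-style text pedigree file
#' (`FID IID PAT MAT SEX PHENO` then two allele characters per SNP, `0 0`
#' missing) with the companion `.map` file supplying SNP ids; dosages are
#' counts of the minor allele (ties broken towards the lexicographically
#' later allele).
#'
#' Strict validation: dosages outside {0,1,2,NA} and duplicated subject ids
#' are rejected with row locations.
#'
#' @param path genotype file (`.tsv` or `.ped`).
#' @param dialect `"tsv"` or `"pedmap"`.
#' @param map_path `.map` file path (pedmap dialect; default replaces the
#'   extension).
#' @param missing missing-value token for the TSV dialect.
#' @return genotype tibble.
#' @export
read_genotypes <- function(path, dialect = c("tsv", "pedmap"),
                           map_path = NULL, missing = "NA") {
  dialect <- match.arg(dialect)
  if (dialect == "tsv") {
    g <- readr::read_tsv(path, na = missing, show_col_types = FALSE,
                         progress = FALSE)
    assert_that("subject_id" %in% names(g),
                "genotype TSV must have a subject_id column")
    g$subject_id <- as.character(g$subject_id)
    for (s in snp_cols(g)) {
      bad <- which(!(g[[s]] %in% DOSAGE_LEVELS) & !is.na(g[[s]]))
      if (length(bad)) {
        abort(sprintf("invalid dosage in column '%s', data row(s) %s",
                      s, paste(head(bad, 5), collapse = ", ")))
      }
      g[[s]] <- as.integer(g[[s]])
    }
  } else {
    map_path <- map_path %||% sub("\\.ped$", ".map", path)
    map <- readr::read_tsv(map_path,
                           col_names = c("chrom", "snp_id", "cm", "bp"),
                           show_col_types = FALSE, progress = FALSE)
    lines <- readr::read_lines(path)
    toks <- strsplit(trimws(lines), "[ \t]+")
    n_expect <- 6L + 2L * nrow(map)
    bad <- which(lengths(toks) != n_expect)
    if (length(bad)) {
      abort(sprintf("malformed .ped line(s) %s: expected %d fields",
                    paste(head(bad, 5), collapse = ", "), n_expect))
    }
    ids <- vapply(toks, `[[`, "", 2L)
    g <- tibble(subject_id = as.character(ids))
    for (j in seq_len(nrow(map))) {
      a1 <- vapply(toks, `[[`, "", 6L + 2L * j - 1L)
      a2 <- vapply(toks, `[[`, "", 6L + 2L * j)
      miss <- a1 == "0" | a2 == "0"
      alleles <- sort(unique(c(a1[!miss], a2[!miss])))
      if (length(alleles) > 2L) {
        abort(sprintf("SNP %s has >2 alleles in %s", map$snp_id[j], path))
      }
      if (length(alleles) == 0L) {
        g[[map$snp_id[j]]] <- NA_integer_
        next
      }
      counts <- vapply(alleles, function(al) sum(a1 == al) + sum(a2 == al), 0)
      # minor allele = rarer; ties go to the later-sorting allele
      minor <- if (length(alleles) == 1L) NA_character_
               else alleles[order(counts, -seq_along(alleles))][1L]
      dos <- if (is.na(minor)) rep(0L, length(a1))
             else (a1 == minor) + (a2 == minor)
      dos[miss] <- NA_integer_
      g[[map$snp_id[j]]] <- as.integer(dos)
    }
  }
  dup <- which(duplicated(g$subject_id))
  if (length(dup)) {
    abort(sprintf("duplicated subject id(s) at data row(s) %s",
                  paste(head(dup, 5), collapse = ", ")))
  }
  g
}

#' Read a phenotype table
#'
#' @param path TSV with `subject_id`, `diastolic_bp`, `systolic_bp` (mmHg)
#'   and optionally `sex`.
#' @return phenotype tibble; negative or zero pressures are rejected with
#'   row locations, missing values allowed.
#' @export
read_phenotypes <- function(path) {
  ph <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("subject_id", "diastolic_bp", "systolic_bp")
  assert_that(all(need %in% names(ph)),
              paste("phenotype TSV must have columns:", paste(need, collapse = ", ")))
  ph$subject_id <- as.character(ph$subject_id)
  for (col in c("diastolic_bp", "systolic_bp")) {
    bad <- which(!is.na(ph[[col]]) & ph[[col]] <= 0)
    if (length(bad)) {
      abort(sprintf("non-positive %s at data row(s) %s", col,
                    paste(head(bad, 5), collapse = ", ")))
    }
  }
  dup <- which(duplicated(ph$subject_id))
  if (length(dup)) {
    abort(sprintf("duplicated subject id(s) at data row(s) %s",
                  paste(head(dup, 5), collapse = ", ")))
  }
  ph
}

#' Read a subpopulation-assignment table
#'
#' @param path TSV with `subject_id`, `class_label`,
#'   `allocation_probability`. A hard partition (e.g. sex) is expressed with
#'   probability 1.
#' @return assignment tibble; probabilities outside `[0, 1]` are rejected
#'   with row locations.
#' @export
read_assignments <- function(path) {
  a <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("subject_id", "class_label", "allocation_probability")
  assert_that(all(need %in% names(a)),
              paste("assignment TSV must have columns:", paste(need, collapse = ", ")))
  a$subject_id <- as.character(a$subject_id)
  bad <- which(is.na(a$allocation_probability) |
                 a$allocation_probability < 0 | a$allocation_probability > 1)
  if (length(bad)) {
    abort(sprintf("allocation_probability outside [0, 1] at data row(s) %s",
                  paste(head(bad, 5), collapse = ", ")))
  }
  dup <- which(duplicated(a$subject_id))
  if (length(dup)) {
    abort(sprintf("duplicated subject id(s) at data row(s) %s",
                  paste(head(dup, 5), collapse = ", ")))
  }
  a
}

#' Write a cohort to the pipeline's standard input files
#'
#' @param cohort a `wmi_cohort`.
#' @param dir output directory (created if needed).
#' @param dialect `"tsv"` writes `genotypes.tsv`; `"pedmap"` writes
#'   `cohort.ped`/`cohort.map` (alleles A = reference, B = minor).
#'   Phenotypes, assignments and the SNP-gene map are always TSV.
#' @return named character vector of the files written, invisibly.
#' @export
write_cohort <- function(cohort, dir, dialect = c("tsv", "pedmap")) {
  dialect <- match.arg(dialect)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- c(phenotypes = file.path(dir, "phenotypes.tsv"),
             assignments = file.path(dir, "assignments.tsv"),
             snp_info = file.path(dir, "snp_info.tsv"))
  readr::write_tsv(cohort$phenotypes, files["phenotypes"])
  readr::write_tsv(cohort$assignments, files["assignments"])
  readr::write_tsv(cohort$snp_info, files["snp_info"])
  if (dialect == "tsv") {
    files["genotypes"] <- file.path(dir, "genotypes.tsv")
    readr::write_tsv(cohort$genotypes, files["genotypes"])
  } else {
    files["genotypes"] <- file.path(dir, "cohort.ped")
    files["map"] <- file.path(dir, "cohort.map")
    snps <- snp_cols(cohort$genotypes)
    sex_code <- if ("sex" %in% names(cohort$phenotypes)) {
      ifelse(cohort$phenotypes$sex[match(cohort$genotypes$subject_id,
                                         cohort$phenotypes$subject_id)] == "M",
             1L, 2L)
    } else rep(0L, nrow(cohort$genotypes))
    allele_str <- vapply(snps, function(s) {
      d <- cohort$genotypes[[s]]
      out <- c("A A", "A B", "B B")[d + 1L]
      out[is.na(d)] <- "0 0"
      out
    }, character(nrow(cohort$genotypes)))
    ped <- paste(cohort$genotypes$subject_id, cohort$genotypes$subject_id,
                 0L, 0L, sex_code, -9L,
                 apply(allele_str, 1, paste, collapse = "\t"), sep = "\t")
    readr::write_lines(ped, files["genotypes"])
    map <- tibble(chrom = 1L, snp_id = snps, cm = 0, bp = seq_along(snps))
    readr::write_tsv(map, files["map"], col_names = FALSE)
  }
  invisible(files)
}
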