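#' @importFrom rlang abort warn .data :=
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter select arrange group_by ungroup summarise
#'   bind_rows left_join distinct n across rename row_number pull
#' @importFrom stats pchisq pf var sd rnorm rbinom runif setNames coef lm
#'   predict quantile median fisher.test chisq.test t.test optimize dpois
#'   ppois complete.cases
#' @importFrom utils head
NULL

# dosage domain used throughout: minor-allele counts 0/1/2, NA = missing
DOSAGE_LEVELS <- 0:2

`%||%` <- function(x, y) if (is.null(x)) y else x

assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) abort(msg)
  invisible(TRUE)
}

is_probability <- function(x) is.numeric(x) && all(x >= 0 & x <= 1, na.rm = TRUE)

#' FNV-1a hash of a character string
#'
#' Small stable 32-bit hash used to stamp pipeline outputs with the
#' configuration they were produced under, so mismatched intermediate files
#' are detectable. Not cryptographic.
#'
#' @param x a character scalar
#' @return an 8-character lowercase hex string
#' @keywords internal
fnv1a_hash <- function(x) {
  bytes <- as.integer(charToRaw(paste(x, collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    # xor on 16-bit halves (bitwXor is limited to signed 32-bit inputs)
    lo <- bitwXor(h %% 65536, b)
    h <- (h %/% 65536) * 65536 + lo
    # 32-bit modular multiply by the FNV prime 16777619, done in doubles:
    # split h to keep every intermediate product below 2^53
    h <- ((h %% 65536) * 16777619 + ((h %/% 65536) * 16777619 %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

# population (divide-by-n) variance; guarantees the law-of-total-variance
# identity used to keep relative genetic variance inside [0, 1]
pop_var <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(NA_real_)
  mean((x - mean(x))^2)
}

check_dosages <- function(d, what = "dosages") {
  bad <- !(d %in% DOSAGE_LEVELS) & !is.na(d)
  if (any(bad)) {
    abort(sprintf("%s must be 0, 1, 2 or NA; found %s",
                  what, paste(unique(d[bad])[1:min(3, sum(bad))], collapse = ", ")))
  }
  invisible(TRUE)
}

# columns of a genotype tibble that hold SNP dosages (all but subject_id)
snp_cols <- function(genotypes) setdiff(names(genotypes), "subject_id")

# genotype tibble -> plain integer matrix (subjects x SNPs)
dosage_matrix <- function(genotypes) {
  snps <- snp_cols(genotypes)
  m <- as.matrix(genotypes[snps])
  storage.mode(m) <- "integer"
  rownames(m) <- genotypes$subject_id
  m
}
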