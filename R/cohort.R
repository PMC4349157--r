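#' Specify a synthetic stratified cohort
#'
#' Describes a population with the structure the epistasis pipeline assumes:
#' subjects partitioned into physiologically defined subpopulations (classes),
#' biallelic SNPs drawn under Hardy-Weinberg equilibrium at per-SNP minor
#' allele frequencies, two correlated blood-pressure traits built from class
#' baselines plus planted genetic effects plus Gaussian noise, and per-subject
#' class-allocation probabilities with graded reliability.
#'
#' The defaults mirror a mid-1990s Danish population survey design:
#' 2556 subjects, 353 assayed SNPs of which roughly 45% are polymorphic
#' (`fraction_monomorphic = 0.55` leaves ~160 informative SNPs), 14
#' subpopulations, and within-class residual standard deviations of 8 mmHg
#' (diastolic) and 12 mmHg (systolic).
#'
#' @param n_subjects number of subjects.
#' @param n_snps number of assayed SNPs.
#' @param maf_bounds length-2 numeric; per-SNP minor allele frequencies are
#'   drawn uniformly between these bounds.
#' @param fraction_monomorphic proportion of SNPs forced monomorphic in the
#'   whole population (emulating assay panels where many annotated SNPs carry
#'   no variation in the sampled population).
#' @param n_subpopulations number of classes (>= 1).
#' @param mixing_proportions class weights on the simplex; default uniform.
#' @param subpop_trait_baselines numeric matrix `n_subpopulations` x 2
#'   (columns diastolic, systolic) of class baseline pressures in mmHg;
#'   default an evenly spaced gradient 70-105 / 110-165 mmHg.
#' @param planted_interactions list of [planted_interaction()] objects.
#' @param planted_main_effects list of [planted_main_effect()] objects.
#' @param noise_sd length-2 numeric (diastolic, systolic) residual SD in mmHg,
#'   or an `n_subpopulations` x 2 matrix for class-specific noise.
#' @param trait_correlation correlation of the diastolic and systolic noise
#'   components (the planted genetic terms are shared between traits, so total
#'   trait correlation is at least this).
#' @param allocation_concentration Dirichlet concentration placed on the true
#'   class (off-classes get 0.5); larger values concentrate allocation
#'   probabilities near 1 and so control how many subjects survive a
#'   reliability threshold such as 0.9.
#' @param class_monomorphic optional named list, class label -> integer SNP
#'   indices forced monomorphic (all-reference) inside that class only,
#'   emulating SNPs that "turn" monomorphic in a subpopulation.
#' @param missing_rate per-genotype missingness probability.
#' @param snps_per_gene SNPs are annotated to synthetic gene symbols in runs
#'   of this length, so intragenic pairs exist at the gene level.
#' @param seed integer RNG seed; fixed seed gives bit-identical cohorts.
#' @return an object of class `cohort_spec` (a named list).
#' @seealso [generate_cohort()], [planted_interaction()]
#' @export
cohort_spec <- function(n_subjects = 2556L,
                        n_snps = 353L,
                        maf_bounds = c(0.05, 0.5),
                        fraction_monomorphic = 0.55,
                        n_subpopulations = 14L,
                        mixing_proportions = NULL,
                        subpop_trait_baselines = NULL,
                        planted_interactions = list(),
                        planted_main_effects = list(),
                        noise_sd = c(8, 12),
                        trait_correlation = 0.6,
                        allocation_concentration = 60,
                        class_monomorphic = list(),
                        missing_rate = 0.005,
                        snps_per_gene = 3L,
                        seed = 1L) {
  n_subpopulations <- as.integer(n_subpopulations)
  assert_that(n_subpopulations >= 1L, "n_subpopulations must be >= 1")
  assert_that(n_subjects >= 1 && n_snps >= 2, "need >= 1 subject and >= 2 SNPs")
  assert_that(length(maf_bounds) == 2 && all(maf_bounds >= 0 & maf_bounds <= 0.5),
              "maf_bounds must be two values in [0, 0.5]")
  assert_that(is_probability(fraction_monomorphic) && is_probability(missing_rate),
              "fraction_monomorphic and missing_rate must lie in [0, 1]")
  if (is.null(mixing_proportions)) {
    mixing_proportions <- rep(1 / n_subpopulations, n_subpopulations)
  }
  assert_that(length(mixing_proportions) == n_subpopulations &&
                abs(sum(mixing_proportions) - 1) < 1e-8 &&
                all(mixing_proportions >= 0),
              "mixing_proportions must be a simplex weight vector over the classes")
  if (is.null(subpop_trait_baselines)) {
    subpop_trait_baselines <- cbind(
      diastolic = seq(70, 105, length.out = n_subpopulations),
      systolic  = seq(110, 165, length.out = n_subpopulations)
    )
  }
  subpop_trait_baselines <- matrix(as.numeric(subpop_trait_baselines),
                                   nrow = n_subpopulations, ncol = 2)
  if (is.null(dim(noise_sd)) || length(noise_sd) == 2) {
    noise_sd <- matrix(rep(as.numeric(noise_sd), each = n_subpopulations),
                       nrow = n_subpopulations, ncol = 2)
  }
  assert_that(all(noise_sd >= 0), "noise_sd must be non-negative")
  for (pi in planted_interactions) {
    assert_that(inherits(pi, "planted_interaction"),
                "planted_interactions must be built with planted_interaction()")
    assert_that(pi$snp_a <= n_snps && pi$snp_b <= n_snps,
                "planted interaction SNP index out of range")
  }
  structure(
    list(n_subjects = as.integer(n_subjects), n_snps = as.integer(n_snps),
         maf_bounds = maf_bounds, fraction_monomorphic = fraction_monomorphic,
         n_subpopulations = n_subpopulations,
         mixing_proportions = mixing_proportions,
         subpop_trait_baselines = subpop_trait_baselines,
         planted_interactions = planted_interactions,
         planted_main_effects = planted_main_effects,
         noise_sd = noise_sd, trait_correlation = trait_correlation,
         allocation_concentration = allocation_concentration,
         class_monomorphic = class_monomorphic,
         missing_rate = missing_rate,
         snps_per_gene = as.integer(snps_per_gene),
         seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

#' Plant a two-SNP epistatic effect
#'
#' The effect matrix gives the trait shift (mmHg) of each of the nine
#' composite genotypes. By default it is an additive-by-additive pattern
#' built from allele-frequency-centred dosages, which has (asymptotically)
#' zero marginal single-SNP effects -- a pure interaction, matching
#' populations where epistasis is present but main effects are not.
#' The matrix is rescaled at generation time so the realized fraction of
#' phenotypic variance explained by the pair approaches
#' `target_variance_fraction`.
#'
#' @param snp_a,snp_b distinct SNP column indices.
#' @param target_variance_fraction fraction of total phenotypic variance in
#'   `[0, 1)` this interaction should explain.
#' @param effect_matrix optional 3x3 numeric matrix (rows: dosage of `snp_a`
#'   0/1/2; columns: dosage of `snp_b`); `NULL` for the centred
#'   additive-by-additive default.
#' @param traits which traits receive the effect.
#' @param subpop_scope `"all"` or an integer vector of class labels in which
#'   the effect is active.
#' @return an object of class `planted_interaction`.
#' @export
planted_interaction <- function(snp_a, snp_b, target_variance_fraction,
                                effect_matrix = NULL,
                                traits = c("diastolic_bp", "systolic_bp"),
                                subpop_scope = "all") {
  assert_that(snp_a != snp_b, "snp_a and snp_b must differ")
  assert_that(is.numeric(target_variance_fraction) &&
                target_variance_fraction >= 0 && target_variance_fraction < 1,
              "target_variance_fraction must lie in [0, 1)")
  if (!is.null(effect_matrix)) {
    effect_matrix <- matrix(as.numeric(effect_matrix), 3, 3)
  }
  structure(list(snp_a = as.integer(snp_a), snp_b = as.integer(snp_b),
                 target_variance_fraction = target_variance_fraction,
                 effect_matrix = effect_matrix, traits = traits,
                 subpop_scope = subpop_scope),
            class = "planted_interaction")
}

#' Plant a single-SNP main effect
#'
#' @param snp SNP column index.
#' @param shifts length-3 numeric: trait shift in mmHg for dosages 0, 1, 2.
#' @param traits which traits receive the effect.
#' @return an object of class `planted_main_effect`.
#' @export
planted_main_effect <- function(snp, shifts,
                                traits = c("diastolic_bp", "systolic_bp")) {
  assert_that(length(shifts) == 3, "shifts must have length 3 (dosages 0/1/2)")
  structure(list(snp = as.integer(snp), shifts = as.numeric(shifts),
                 traits = traits),
            class = "planted_main_effect")
}

# default pure-interaction pattern: outer product of dosages centred at their
# HWE means, so marginal genotype-class means are zero in expectation
axa_effect_matrix <- function(maf_a, maf_b) {
  ua <- (0:2) - 2 * maf_a
  ub <- (0:2) - 2 * maf_b
  outer(ua, ub)
}

#' Generate a synthetic cohort
#'
#' Draws class labels, genotypes (HWE within class at the sampled MAFs),
#' correlated diastolic/systolic traits with the planted genetic effects, and
#' Dirichlet allocation probabilities peaked on the true class. Interaction
#' effect matrices are rescaled so each pair's realized share of phenotypic
#' variance approaches its `target_variance_fraction`; the rescaling solves
#' `V_p = V_nongenetic / (1 - sum(fractions))`, so a total planted fraction
#' `>= 1` is rejected as impossible.
#'
#' @param spec a [cohort_spec()].
#' @return a list of class `wmi_cohort` with tibbles `genotypes` (subject_id +
#'   one integer dosage column per SNP), `snp_info` (snp_id, gene),
#'   `phenotypes` (subject_id, diastolic_bp, systolic_bp, sex) and
#'   `assignments` (subject_id, class_label, allocation_probability).
#' @examples
#' co <- generate_cohort(cohort_spec(n_subjects = 100, n_snps = 10,
#'                                   n_subpopulations = 2, seed = 7))
#' dim(co$genotypes)
#' @export
generate_cohort <- function(spec) {
  assert_that(inherits(spec, "cohort_spec"), "spec must be a cohort_spec")
  set.seed(spec$seed)
  n <- spec$n_subjects
  m <- spec$n_snps
  K <- spec$n_subpopulations
  traits <- c("diastolic_bp", "systolic_bp")

  total_fraction <- sum(vapply(spec$planted_interactions,
                               function(p) p$target_variance_fraction, 0))
  if (total_fraction >= 1) {
    abort(sprintf(
      "planted interaction variance fractions sum to %.3f; must be < 1 given nonzero noise",
      total_fraction))
  }

  class_label <- sample.int(K, n, replace = TRUE, prob = spec$mixing_proportions)

  # SNP panel: sampled MAFs, with a fixed fraction forced monomorphic
  maf <- runif(m, spec$maf_bounds[1], spec$maf_bounds[2])
  planted_snps <- unique(c(
    unlist(lapply(spec$planted_interactions, function(p) c(p$snp_a, p$snp_b))),
    unlist(lapply(spec$planted_main_effects, function(p) p$snp))
  ))
  n_mono <- round(spec$fraction_monomorphic * m)
  mono_pool <- setdiff(seq_len(m), planted_snps)
  mono <- if (n_mono > 0) sort(sample(mono_pool, min(n_mono, length(mono_pool)))) else integer(0)
  maf[mono] <- 0

  dosages <- matrix(0L, n, m)
  for (k in seq_len(K)) {
    idx <- which(class_label == k)
    if (length(idx) == 0L) next
    maf_k <- maf
    mono_k <- spec$class_monomorphic[[as.character(k)]]
    if (!is.null(mono_k)) maf_k[mono_k] <- 0
    dosages[idx, ] <- vapply(maf_k, function(q) rbinom(length(idx), 2L, q),
                             integer(length(idx)))
  }

  # non-genetic trait components: class baseline + correlated Gaussian noise
  rho <- spec$trait_correlation
  e1 <- rnorm(n); e2 <- rnorm(n)
  sd_d <- spec$noise_sd[class_label, 1]
  sd_s <- spec$noise_sd[class_label, 2]
  nongenetic <- cbind(
    diastolic_bp = spec$subpop_trait_baselines[class_label, 1] + sd_d * e1,
    systolic_bp  = spec$subpop_trait_baselines[class_label, 2] +
      sd_s * (rho * e1 + sqrt(1 - rho^2) * e2)
  )

  # main effects in stated mmHg, added as-is
  main_term <- matrix(0, n, 2, dimnames = list(NULL, traits))
  for (pm in spec$planted_main_effects) {
    shift <- pm$shifts[dosages[, pm$snp] + 1L]
    for (tr in pm$traits) main_term[, tr] <- main_term[, tr] + shift
  }

  # interactions rescaled to hit their target phenotypic-variance fractions:
  # V_p = V_rest / (1 - F) where F is the total planted interaction fraction
  int_term <- matrix(0, n, 2, dimnames = list(NULL, traits))
  raw_terms <- lapply(spec$planted_interactions, function(p) {
    E <- p$effect_matrix %||% axa_effect_matrix(maf[p$snp_a], maf[p$snp_b])
    e <- E[cbind(dosages[, p$snp_a] + 1L, dosages[, p$snp_b] + 1L)]
    if (!identical(p$subpop_scope, "all")) {
      e[!(class_label %in% p$subpop_scope)] <- 0
    }
    e
  })
  for (tr in traits) {
    rest <- nongenetic[, tr] + main_term[, tr]
    active <- vapply(spec$planted_interactions,
                     function(p) tr %in% p$traits, TRUE)
    f_tot <- sum(vapply(spec$planted_interactions[active],
                        function(p) p$target_variance_fraction, 0))
    v_target <- pop_var(rest) / (1 - f_tot)
    for (i in which(active)) {
      p <- spec$planted_interactions[[i]]
      v_raw <- pop_var(raw_terms[[i]])
      if (v_raw <= 0) {
        if (p$target_variance_fraction > 0)
          abort(sprintf("planted interaction %d has zero raw variance (monomorphic SNPs?)", i))
        next
      }
      scl <- sqrt(p$target_variance_fraction * v_target / v_raw)
      int_term[, tr] <- int_term[, tr] + scl * (raw_terms[[i]] - mean(raw_terms[[i]]))
    }
  }

  trait_values <- nongenetic + main_term + int_term

  # allocation probabilities: Dirichlet peaked on the true class; the true
  # class is guaranteed the argmax by swapping in the rare other case
  if (K == 1L) {
    alloc <- rep(1, n)
  } else {
    alpha_off <- 0.5
    g_true <- stats::rgamma(n, shape = spec$allocation_concentration)
    g_rest <- matrix(stats::rgamma(n * (K - 1), shape = alpha_off), n, K - 1)
    tot <- g_true + rowSums(g_rest)
    p_true <- g_true / tot
    p_maxrest <- apply(g_rest, 1, max) / tot
    swap <- p_maxrest > p_true
    alloc <- ifelse(swap, p_maxrest, p_true)
  }

  # missingness
  if (spec$missing_rate > 0) {
    miss <- matrix(runif(n * m) < spec$missing_rate, n, m)
    dosages[miss] <- NA_integer_
  }

  subject_id <- sprintf("S%04d", seq_len(n))
  snp_id <- sprintf("snp_%03d", seq_len(m))
  gene <- sprintf("GENE%03d", (seq_len(m) - 1L) %/% spec$snps_per_gene + 1L)

  genotypes <- as_tibble(as.data.frame(dosages))
  names(genotypes) <- snp_id
  genotypes <- dplyr::bind_cols(tibble(subject_id = subject_id), genotypes)

  phenotypes <- tibble(
    subject_id = subject_id,
    diastolic_bp = as.numeric(trait_values[, 1]),
    systolic_bp = as.numeric(trait_values[, 2]),
    sex = sample(c("F", "M"), n, replace = TRUE)
  )

  assignments <- tibble(subject_id = subject_id,
                        class_label = as.integer(class_label),
                        allocation_probability = as.numeric(alloc))

  structure(list(genotypes = genotypes,
                 snp_info = tibble(snp_id = snp_id, gene = gene),
                 phenotypes = phenotypes,
                 assignments = assignments,
                 spec = spec),
            class = "wmi_cohort")
}

#' @export
print.wmi_cohort <- function(x, ...) {
  cat(sprintf("<wmi_cohort> %d subjects, %d SNPs, %d subpopulation(s)\n",
              nrow(x$genotypes), length(snp_cols(x$genotypes)),
              x$spec$n_subpopulations))
  invisible(x)
}

#' Tiny deterministic cohort for exact regression tests
#'
#' 30 subjects, 6 SNPs, 2 classes, one planted interaction, no missing data.
#' The first SNP is pinned to dosage counts {0: 15, 1: 10, 2: 5}, i.e.
#' MAF = (10 + 2*5) / 60 = 1/3. Regenerating the fixture always yields
#' byte-identical tables.
#'
#' @return a `wmi_cohort`.
#' @export
make_fixture <- function() {
  spec <- cohort_spec(
    n_subjects = 30L, n_snps = 6L, n_subpopulations = 2L,
    maf_bounds = c(0.2, 0.4), fraction_monomorphic = 0,
    planted_interactions = list(planted_interaction(3L, 5L, 0.25)),
    noise_sd = c(6, 9), missing_rate = 0, snps_per_gene = 2L,
    allocation_concentration = 40, seed = 1907L
  )
  co <- generate_cohort(spec)
  co$genotypes$snp_001 <- rep(0:2, times = c(15L, 10L, 5L))
  co
}
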