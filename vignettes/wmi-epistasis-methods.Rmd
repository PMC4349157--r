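---
title: "Methods: weighted mutual-information epistasis scanning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: weighted mutual-information epistasis scanning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wmiscan)
```

## The analysis in one paragraph

Blood pressure is polygenic, and most of its genetic signal is carried by
interactions between variants rather than by single-SNP main effects. The
approach implemented here therefore evaluates every *pair* of biallelic SNPs
inside physiologically homogeneous subpopulations (classes produced by a
prior mixture model, supplied as an input table together with per-subject
allocation probabilities). For a pair, the nine composite genotypes form a
3×3 table; the trait variance attributable to the pair is decomposed into
marginal and interaction parts, the dependence between the two genotype
distributions is measured by mutual information (MI) and tested against a
χ² reference with 4 degrees of freedom, and the two are combined into the
weighted mutual-information score

$$\mathrm{WMI} \;=\; -\sum_{ij} \mathrm{Geff}_{ij}\; p_{ij}\,
  \log\!\frac{p_{ij}}{p_i\,p_j},$$

where $\mathrm{Geff}_{ij}$ is the effect size (mmHg) of composite genotype
$(i,j)$, $p_{ij}$ its frequency, and $p_i, p_j$ the single-SNP genotype
frequencies. Downstream, the plateau of relative genetic variance as a
function of WMI is read as a broad-sense heritability; significant pairs are
carried into a hypertension case-control analysis (cutoffs 90/140 mmHg);
and the interaction network built from significant WMIs is characterized by
power-law and Poisson fits of its weight and degree distributions.

## Variance decomposition

For a pair the decomposition is stepwise: grand mean
$\mu = \sum_{ij} p_{ij} m_{ij}$ over the cell means $m_{ij}$; marginal
(additive) genotype effects; then interaction deviations $d_{ij}$ on the
nonempty cells. On real tables the joint genotype frequencies never
factorize exactly, and the textbook row-mean effects
$a_i = \sum_j p_{ij} m_{ij} / p_i - \mu$ leave a decomposition that does not
conserve variance. We therefore compute the marginal effects as the weighted
least-squares projection of the cell means onto the additive (row + column)
model with weights $p_{ij}$ and weighted sum-to-zero constraints
($\sum_i p_i a_i = 0$). Orthogonality of a weighted projection then makes

$$\sigma^2_{\text{marginal}} + \sigma^2_{\text{interaction}}
  = \sigma^2_{\text{genotypic}}$$

an exact identity for *any* table (the suite asserts it to $10^{-9}$ on
random tables), and $d_{ij}$ vanishes identically for purely additive
traits. When the frequencies do factorize, the projection coincides with the
row-mean formula. All variance components use the population
(divide-by-$n$) convention, so the law of total variance guarantees
$\sigma^2_{\text{genotypic}} \le \sigma^2_{\text{phenotypic}}$ and the
relative genetic variance lies in $[0,1]$ without clamping.

Interaction significance is the F-test of the full cell-means model against
the additive model (4 df on full 3×3 support; reduced and flagged on
degenerate support). Empty cells carry $p_{ij}=0$ and annihilate their
terms; their means are undefined but never dereferenced.

### The effect size $\mathrm{Geff}_{ij}$

Two readings are implemented and switchable (`geff_mode`):

* `"total"` (default): $\mathrm{Geff}_{ij} = m_{ij} - \mu$, the whole
  genotypic signal of the cell. This makes WMI reflect the total network
  information a pair carries, which matches the interpretation of "total
  WMI" in per-class summary tables.
* `"interaction_only"`: the additive-adjusted deviation $d_{ij}$. This is
  the better-powered weight when the question is specifically *epistasis*:
  in a pure-interaction experiment the marginal part of a null pair's cell
  means is noise, and removing it measurably improves the probability that
  a planted interacting pair attains the top |WMI| rank. The synthetic
  recovery experiments in the test suite use this mode for that reason.

## Mutual information and its test

MI is computed in nats ($0\log 0 := 0$). The natural log is forced by the
χ² calibration: $2N\cdot\mathrm{MI}$ is the G statistic of independence,
asymptotically χ² with $(r-1)(c-1) = 4$ df on full support. The test
statistic is $2N\cdot\mathrm{MI}$ (not $N\cdot\mathrm{MI}$, which has no
such calibration). At $n = 500$ and MAF 0.3 the empirical null mean of the
statistic is ≈ 4.1 — the small positive finite-sample bias typical of the G
statistic with an expected corner-cell count of about 4 — and the type-I
error at 0.05 is within Monte-Carlo error of 0.05.

A note on signs: written with a leading minus, the MI sum is negative for
the standard orientation of its terms; we implement MI in its usual
non-negative form, keep the WMI formula literal (so its sign depends on the
alignment of effect sizes with pointwise MI terms), and rank interactions by
an absolute-value variant
$\sum_{ij} |\mathrm{Geff}_{ij}|\, p_{ij}\, |\log(p_{ij}/p_i p_j)|$
(`wmi_abs`), which is invariant under allele relabeling and sign
conventions. Both are reported.

Multiple testing is Bonferroni at nominal 0.05, with the family defaulting
to all tested pairs within one scope × trait (a `family_size` argument
allows a global family). Per-scope summaries count epistasis at the nominal
level and WMI significance after correction; both "total WMI" readings
(over all epistatic pairs, and over corrected-significant pairs only) are
emitted because the choice is genuinely ambiguous.

## Quality control

* **MAF**: $\min(q, 1-q)$ with missing dosages excluded; default cutoff
  0.01 (exclusive), chosen to suppress sporadic interactions from
  near-monomorphic SNPs.
* **HWE**: per-scope exclusion at unadjusted α = 0.05. The default test is
  the 1-df χ² goodness of fit; an exact conditional test (two-sided,
  summing configurations no more probable than the observed heterozygote
  count) is available and is the right choice for classes as small as a
  dozen subjects. The exact test is verified against an independent
  multinomial-conditioning oracle for every configuration with n ≤ 50.
* **Validity is a per-scope notion**: a SNP may be valid in the population
  and monomorphic (or out of HWE) inside a class; most exclusions in small
  classes come from SNPs turning monomorphic there. Both population-level
  and per-class QC are computed; the scan consumes the per-scope result.
* **Missingness**: pairwise deletion — a subject missing either SNP of a
  pair drops out of that pair only. No imputation, no LD pruning
  (intragenic pairs are kept deliberately; they are among the strongest
  expected signals).
* **Allocation filter**: subjects with allocation probability ≥ 0.9 are
  kept by default (boundary inclusive), 0.7 being the standard sensitivity
  setting for small classes where 0.9 starves the scan.

## Heritability from the WMI curve

Relative genetic variance is plotted against |WMI| for the significant
interactions of one scope × trait, and the plateau of a saturating fit is
read as the broad-sense heritability $h^2$. Three families are fitted, with
multi-start Levenberg–Marquardt least squares and a consensus (median of
converged plateaus) plus a percentile bootstrap CI over curve points
(default B = 500):

* Boltzmann sigmoid $y = A_2 + (A_1 - A_2)/(1 + e^{(x - x_0)/dx})$,
  $dx > 0$: $h^2 = A_2$, the large-$x$ plateau.
* Gaussian $y = y_0 + A e^{-(x - x_c)^2/2w^2}$: a Gaussian has no
  asymptote, so $h^2$ is taken as the fitted maximum over the observed
  x-range — an explicit heuristic.
* Polynomial (degree 3): $h^2$ is the fitted value at the maximum observed
  x.

Plateaus are clamped to $[0,1]$ with a flag. Two curve modes exist. The
default `per_pair` mode plots each pair's own variance share — appropriate
when top pairs individually approach the heritability (as strong within-gene
haplotype pairs do in real data). The `cumulative` mode accumulates variance
fractions over pairs in ascending-WMI order, treating disjoint significant
pairs as independent contributions; it is the natural estimator of the
*total* planted fraction in simulated architectures built from many disjoint
interactions. Because the per-pair variance ratio (an $\eta^2$) is biased
upward by roughly $(k-1)/n$ per pair ($k$ = occupied cells) and a sum over
tens of pairs accumulates that bias, the cumulative mode applies the
standard $\epsilon^2$ correction
$y - \frac{k-1}{n-k}(1-y)$ before summation.

The curve gate is configurable. The default admits Bonferroni-corrected
MI-significant pairs, mirroring the analysis on real stratified cohorts
where phenotype-derived classes and within-gene linkage make genotype
dependence informative. On simulated panels of *unlinked* SNPs, genotype
pairs are independent by construction and the MI gate has (correctly) no
power beyond its type-I rate, so the interaction-F-test gates
(`epistasis_nominal` / `epistasis_bonferroni`) are the meaningful choice
there; the parameter-recovery experiments use them.

## Case-control analysis

Hypertension is classified boundary-inclusively at ≥ 90 mmHg diastolic and
≥ 140 mmHg systolic. For each composite genotype of the significant pairs,
carriers vs all others are cross-tabulated against affected status and
tested with the two-sided Fisher exact test (composite-genotype cells are
sparse; a χ² option exists), reporting carrier prevalence and population
genotype frequency in percent and the direction relative to population
prevalence. Genotype distributions are compared between every pair of
classes and each class vs the rest (3-level χ², Fisher when any expected
count is below 5), and trait means conditional on composite genotypes use
Welch's test. Each battery is Bonferroni-corrected over its own tests.
Medication status is not modeled.

## Network topology

Significant pairs define a weighted network at SNP or gene level; the edge
weight is the maximum |WMI| across the scopes and traits that recovered the
pair. Intragenic pairs collapse to gene-level self-loops, which are kept,
flagged, and counted with degree contribution 2 — removing them would erase
precisely the strongest expected signals. Hubs are ranked by degree with a
deterministic tie-break (total weight, then id).

Weight and degree distributions are fitted as $p(x) \sim x^{-\alpha}$ by
maximum likelihood with the lower cutoff $x_{\min}$ selected by KS-distance
minimization (closed-form MLE for continuous values; a Hurwitz-zeta
likelihood, evaluated by Euler–Maclaurin summation, for discrete degrees —
the discrete fit agrees with the independent `plfit` implementation in
igraph, which the test suite uses as a cross-check). The fraction of values
at or above $x_{\min}$ is reported, since a power law typically captures
only part of such distributions; the remainder below the cutoff is fitted as
Poisson (MLE $\hat\lambda$ = mean, χ² goodness of fit with pooled bins).
Vuong-style likelihood-ratio comparisons against truncated lognormal and
exponential alternatives accompany every fit; on genuinely exponential data
the power law receives no significant support, which is the property the
tests assert (a lognormal can mimic a power law closely enough that the sign
of that particular ratio is not a reliable test).

## The synthetic cohort generator

`generate_cohort()` emulates the structure the analysis assumes, so every
stage is testable without any external data:

* ~2556 subjects, 353 assayed SNPs of which ~45% polymorphic
  (`fraction_monomorphic = 0.55` leaves ≈ 160 informative SNPs), 14
  classes — the default dimensions of a mid-1990s population survey with a
  candidate-pathway SNP panel.
* Genotypes are drawn under HWE within class at per-SNP MAFs sampled from
  `maf_bounds`; a configurable subset of SNPs can be forced monomorphic
  within single classes, emulating SNPs that "turn" monomorphic in a
  subpopulation.
* Traits are class baseline + planted main effects + planted interactions +
  Gaussian noise. Within-class noise defaults to 8 mmHg (diastolic) and
  12 mmHg (systolic) — conventional within-stratum residual spreads, since
  no published value exists for them — and the two traits share their
  genetic terms and have correlated noise (default 0.6), which is the
  simplest mechanism producing the observed situation of two traits with
  largely shared interactions.
* Planted interactions default to an additive×additive, frequency-centred
  3×3 pattern with (asymptotically) zero marginal effects — epistasis
  without main effects, the regime of interest. Each matrix is rescaled so
  the pair's realized share of phenotypic variance approaches its
  `target_variance_fraction`; the solver uses
  $V_p = V_{\text{rest}}/(1 - \sum_k f_k)$, so a total planted fraction
  ≥ 1 is rejected as impossible. Realized fractions verify within ±0.02 of
  target at n = 5000 against a direct ANOVA oracle.
* Allocation probabilities are Dirichlet draws with concentration boosted
  on the true class (off-class concentration 0.5, default boost 60), which
  produces the graded reliability that a posterior-probability filter needs:
  most subjects above 0.9, a tail between 0.7 and 0.9, and the per-class
  count shrinking monotonically as the threshold rises.

What the generator does **not** emulate: linkage disequilibrium between
SNPs, phenotype-conditioned class assignment (classes are drawn first, so
genotypes are independent of class except through planted class-specific
MAFs), genotyping error, and medication effects. The practical consequence
is stated above: on generated panels the MI test is null for all pairs, so
passing recovery tests demonstrates the decomposition, scoring, fitting and
plumbing — not that the MI gate would fire on real, linked,
phenotype-stratified data. Interaction terms sharing a SNP also acquire
finite-sample correlations that leak variance between planted pairs, which
is why the recovery architectures below use disjoint pairs.

## Experiment sizes used by the test suite

Chosen as realistic desk-scale designs for the properties being
demonstrated:

* MI null calibration: 2000 independent pairs, n = 500, MAF 0.3.
* Ranking: one planted pair at variance fraction 0.20, n = 1000, a 6-SNP
  panel (MAF 0.2–0.5), 100 seeds; the planted pair must top |WMI| in ≥ 95.
* Heritability recovery: ten disjoint planted interactions with
  geometrically decaying fractions summing to 0.60, n = 2000, 20 SNPs at
  MAF 0.3; cumulative curve, epistasis-Bonferroni gate; consensus within
  ±0.07 of 0.6.
* Topology: discrete power-law samples (α = 2.5, n = 1000) and a
  Poisson(3) + power-law(α = 2.5, x ≥ 12) mixture split at the generative
  boundary.

## Numerical choices and edge cases

* Pairs with fewer than `min_cell_subjects` (default 10) subjects after
  pairwise deletion are skipped and logged, as are zero-variance traits.
* Degenerate MI tables reduce their df to the observed support and are
  flagged.
* Noise-free decompositions report interaction p = 0 (signal without
  residual) or 1 (no signal), avoiding 0/0.
* Curve fits refuse fewer than 5 points; non-convergence of one family is
  reported per model and excluded from the consensus median.
* Bootstrap refits start from the full-data parameters (single start) to
  keep B = 500 affordable; the full-data fits use the deterministic
  multi-start grid.
* All pipeline randomness flows from one seed; outputs are stamped with a
  schema version and an FNV-1a hash of the configuration, and
  `read_pipeline_table()` refuses tables whose stamp mismatches the current
  configuration. Two runs with identical inputs, configuration and seed
  produce byte-identical files.

## Known limitations

* Only two-SNP interactions; no higher orders.
* The Gaussian "plateau" is a bounded heuristic, not an asymptote.
* The discrete lognormal/exponential alternatives in the likelihood-ratio
  comparisons are normalized over the observed support, a pragmatic
  truncation.
* Case-control analysis is unadjusted contingency analysis; no covariates.
* The parallelism of a production scan is treated as an implementation
  detail: the contract here is single-process determinism.
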