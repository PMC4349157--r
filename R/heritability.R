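#' Assemble the relative-genetic-variance vs WMI curve
#'
#' Broad-sense heritability is read off as the plateau of the relative
#' genetic variance (genotypic / phenotypic) as a function of the weighted
#' mutual information: pairs carrying more information approach the maximal
#' genetic share of the trait. Points are the significant interactions of one
#' scope x trait, sorted by ascending |WMI|.
#'
#' @param results rows of a scan for a single scope and trait.
#' @param gate which significance flag admits a pair into the curve:
#'   `"wmi_bonferroni"` (default, the multiple-testing-corrected MI test),
#'   `"wmi_nominal"`, `"epistasis_bonferroni"` or `"epistasis_nominal"` (the
#'   interaction F-test; appropriate when SNP pairs are unlinked so the MI
#'   gate has no power by design, as in simulated panels without LD).
#' @param mode `"per_pair"` (default): y is each pair's own relative genetic
#'   variance; `"cumulative"`: y accumulates variance fractions over pairs in
#'   ascending-WMI order (treats pairs as independent contributions). In
#'   cumulative mode each pair's fraction is first given the epsilon-squared
#'   small-sample correction
#'   `y - (k - 1)/(n - k) * (1 - y)` (k = nonempty cells), since the plain
#'   ratio is biased upward by about `(k - 1)/n` per pair and summation would
#'   accumulate that bias.
#' @param min_points fits are refused below this (default 5).
#' @return tibble with `x` (|WMI|), `y`, `snp_a`, `snp_b`, sorted by `x`.
#' @export
assemble_curve <- function(results,
                           gate = c("wmi_bonferroni", "wmi_nominal",
                                    "epistasis_bonferroni", "epistasis_nominal"),
                           mode = c("per_pair", "cumulative"),
                           min_points = 5L) {
  gate <- match.arg(gate)
  mode <- match.arg(mode)
  assert_that(length(unique(results$scope)) <= 1 &&
                length(unique(results$trait)) <= 1,
              "assemble_curve expects results from a single scope and trait")
  flag <- switch(gate,
                 wmi_bonferroni = results$significant_bonferroni,
                 wmi_nominal = results$significant_nominal,
                 epistasis_bonferroni = results$epistasis_bonferroni,
                 epistasis_nominal = results$epistasis_nominal)
  pts <- results[which(flag), c("snp_a", "snp_b", "wmi_abs",
                                "relative_genetic_variance", "n_cells", "n")]
  if (nrow(pts) < min_points) {
    abort(sprintf("only %d %s-significant interactions (need >= %d) -- fit refused",
                  nrow(pts), gate, min_points))
  }
  pts <- arrange(pts, .data$wmi_abs, .data$snp_a, .data$snp_b)
  y <- pts$relative_genetic_variance
  if (mode == "cumulative") {
    eps2 <- y - (pts$n_cells - 1) / pmax(pts$n - pts$n_cells, 1) * (1 - y)
    y <- pmin(cumsum(pmax(eps2, 0)), 1)
  }
  tibble(x = pts$wmi_abs, y = y, snp_a = pts$snp_a, snp_b = pts$snp_b)
}

#' Fit a saturating curve and read off its plateau
#'
#' Three curve families estimate the plateau of the relative-genetic-variance
#' vs WMI relationship, i.e. the broad-sense heritability:
#'
#' * `"boltzmann"` (sigmoid): `y = A2 + (A1 - A2) / (1 + exp((x - x0)/dx))`
#'   with `dx > 0`, so `A1` is the initial level and `A2` the final (large-x)
#'   plateau -- the heritability. Fitted by Levenberg-Marquardt nonlinear
#'   least squares with a deterministic grid of starting values.
#' * `"gaussian"`: `y = y0 + A exp(-(x - xc)^2 / (2 w^2))`; a Gaussian has no
#'   asymptote, so the heritability is taken as the fitted maximum over the
#'   observed x-range (a heuristic, flagged as such).
#' * `"polynomial"` (default degree 3, ordinary least squares): heritability
#'   is the fitted value at the maximum observed x.
#'
#' The plateau is clamped to `[0, 1]` with `h2_clamped` set when clamping
#' occurred.
#'
#' @param points tibble from [assemble_curve()] (columns `x`, `y`).
#' @param model one of `"boltzmann"`, `"gaussian"`, `"polynomial"`.
#' @param degree polynomial degree.
#' @param init optional named parameter vector used as the single starting
#'   point instead of the grid (used internally to keep bootstrap refits
#'   cheap).
#' @return object of class `heritability_fit`: list with `model`,
#'   `parameters`, `h2`, `h2_clamped`, `r_squared`, `n_points`, `converged`,
#'   `iterations`, `predict_fn` and the `points` used.
#' @export
fit_saturating <- function(points, model = c("boltzmann", "gaussian",
                                             "polynomial"),
                           degree = 3L, init = NULL) {
  model <- match.arg(model)
  x <- points$x; y <- points$y
  assert_that(length(x) >= 5, "need at least 5 points")
  out <- switch(model,
                polynomial = fit_poly(x, y, degree),
                boltzmann = fit_boltzmann(x, y, init),
                gaussian = fit_gaussian(x, y, init))
  out$n_points <- length(x)
  out$points <- tibble(x = x, y = y)
  out$h2_clamped <- !is.na(out$h2) && (out$h2 < 0 || out$h2 > 1)
  if (out$h2_clamped) out$h2 <- min(max(out$h2, 0), 1)
  class(out) <- "heritability_fit"
  out
}

fit_poly <- function(x, y, degree) {
  degree <- min(degree, length(unique(x)) - 1L)
  fit <- lm(y ~ poly(x, degree, raw = TRUE))
  cf <- coef(fit)
  pred <- function(xx) as.numeric(cbind(1, outer(xx, seq_len(degree), `^`)) %*% cf)
  list(model = "polynomial",
       parameters = setNames(cf, c("c0", paste0("c", seq_len(degree)))),
       h2 = pred(max(x)), r_squared = r_sq(y, stats::fitted(fit)),
       converged = TRUE, iterations = 1L, predict_fn = pred)
}

fit_boltzmann <- function(x, y, init = NULL) {
  xs <- sort(x)
  near_top <- if (length(xs) >= 2) mean(xs[length(xs) - 1:0]) else max(x)
  starts <- expand.grid(
    x0 = c(quantile(x, c(0.25, 0.5, 0.75, 0.9), names = FALSE), near_top),
    dx = diff(range(x)) * c(0.01, 0.05, 0.2, 0.5)
  )
  start_list <- if (is.null(init)) {
    lapply(seq_len(nrow(starts)), function(i)
      list(A1 = min(y), A2 = max(y), x0 = starts$x0[i], dx = starts$dx[i]))
  } else {
    list(as.list(init))
  }
  best <- NULL
  for (st in start_list) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ A2 + (A1 - A2) / (1 + exp((x - x0) / dx)),
        start = st,
        lower = c(A1 = -Inf, A2 = -Inf, x0 = -Inf, dx = 1e-12),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(stats::resid(fit)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) {
    return(list(model = "boltzmann", parameters = c(A1 = NA, A2 = NA, x0 = NA, dx = NA),
                h2 = NA_real_, r_squared = NA_real_, converged = FALSE,
                iterations = NA_integer_, predict_fn = function(xx) rep(NA_real_, length(xx))))
  }
  cf <- coef(best$fit)
  pred <- function(xx) cf["A2"] + (cf["A1"] - cf["A2"]) /
    (1 + exp((xx - cf["x0"]) / cf["dx"]))
  list(model = "boltzmann", parameters = cf,
       h2 = unname(cf["A2"]),
       r_squared = r_sq(y, stats::fitted(best$fit)),
       converged = TRUE,
       iterations = best$fit$convInfo$finIter %||% NA_integer_,
       predict_fn = pred)
}

fit_gaussian <- function(x, y, init = NULL) {
  rng <- diff(range(x))
  starts <- expand.grid(xc = c(max(x), quantile(x, 0.75, names = FALSE)),
                        w = rng * c(0.25, 0.75, 2))
  start_list <- if (is.null(init)) {
    lapply(seq_len(nrow(starts)), function(i)
      list(y0 = min(y), A = diff(range(y)),
           xc = starts$xc[i], w = starts$w[i]))
  } else {
    list(as.list(init))
  }
  best <- NULL
  for (st in start_list) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ y0 + A * exp(-(x - xc)^2 / (2 * w^2)),
        start = st,
        lower = c(y0 = -Inf, A = -Inf, xc = -Inf, w = 1e-12),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(stats::resid(fit)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) {
    return(list(model = "gaussian", parameters = c(y0 = NA, A = NA, xc = NA, w = NA),
                h2 = NA_real_, r_squared = NA_real_, converged = FALSE,
                iterations = NA_integer_, predict_fn = function(xx) rep(NA_real_, length(xx))))
  }
  cf <- coef(best$fit)
  pred <- function(xx) cf["y0"] + cf["A"] * exp(-(xx - cf["xc"])^2 / (2 * cf["w"]^2))
  grid <- seq(min(x), max(x), length.out = 512)
  list(model = "gaussian", parameters = cf,
       h2 = max(pred(grid)),
       r_squared = r_sq(y, stats::fitted(best$fit)),
       converged = TRUE,
       iterations = best$fit$convInfo$finIter %||% NA_integer_,
       predict_fn = pred)
}

r_sq <- function(y, yhat) {
  ss <- sum((y - mean(y))^2)
  if (ss == 0) return(NA_real_)
  1 - sum((y - yhat)^2) / ss
}

#' @export
print.heritability_fit <- function(x, ...) {
  cat(sprintf("<heritability_fit> %s: h2 = %.4f%s (R2 = %.3f, %d points)\n",
              x$model, x$h2, if (x$h2_clamped) " [clamped]" else "",
              x$r_squared, x$n_points))
  invisible(x)
}

#' Estimate broad-sense heritability per scope and trait
#'
#' For every scope x trait present in the scan results, assembles the
#' relative-genetic-variance vs WMI curve, fits all three saturating models
#' ([fit_saturating()]), takes the consensus (median of converged plateau
#' estimates), and attaches a bootstrap confidence interval obtained by
#' resampling curve points with replacement.
#'
#' @param results output of [scan_cohort()] (or [scan_pairs()]).
#' @inheritParams assemble_curve
#' @param B bootstrap replicates (default 500).
#' @param conf confidence level of the percentile interval.
#' @param seed RNG seed for the bootstrap.
#' @return tibble with one row per scope x trait x model (the three families
#'   plus `"consensus"`): `h2`, `r_squared`, `ci_lo`, `ci_hi`, `converged`,
#'   `n_points`. Scope x trait combinations with too few significant
#'   interactions are reported with `converged = FALSE` and a `note`.
#'   Attribute `fits` keeps the fitted objects for plotting.
#' @export
estimate_heritability <- function(results,
                                  gate = c("wmi_bonferroni", "wmi_nominal",
                                           "epistasis_bonferroni",
                                           "epistasis_nominal"),
                                  mode = c("per_pair", "cumulative"),
                                  min_points = 5L, B = 500L, conf = 0.95,
                                  seed = 1L) {
  gate <- match.arg(gate); mode <- match.arg(mode)
  combos <- distinct(results[c("scope", "trait")])
  rows <- list(); fits <- list()
  set.seed(seed)
  for (i in seq_len(nrow(combos))) {
    sc <- combos$scope[i]; tr <- combos$trait[i]
    sub <- filter(results, .data$scope == sc, .data$trait == tr)
    pts <- tryCatch(assemble_curve(sub, gate = gate, mode = mode,
                                   min_points = min_points),
                    error = function(e) conditionMessage(e))
    if (is.character(pts)) {
      rows[[length(rows) + 1L]] <- tibble(
        scope = sc, trait = tr, model = "consensus", h2 = NA_real_,
        r_squared = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
        converged = FALSE, n_points = 0L, note = pts)
      next
    }
    mods <- c("polynomial", "boltzmann", "gaussian")
    fit3 <- lapply(mods, function(mo) fit_saturating(pts, mo))
    names(fit3) <- mods
    fits[[paste(sc, tr, sep = "/")]] <- fit3
    h2s <- vapply(fit3, function(f) if (f$converged) f$h2 else NA_real_, 0)
    consensus <- median(h2s, na.rm = TRUE)

    boot <- replicate(B, {
      idx <- sample.int(nrow(pts), replace = TRUE)
      bp <- pts[idx, ]
      bh <- vapply(mods, function(mo) {
        ini <- if (mo != "polynomial" && fit3[[mo]]$converged)
          fit3[[mo]]$parameters else NULL
        f <- tryCatch(fit_saturating(bp, mo, init = ini),
                      error = function(e) NULL)
        if (is.null(f) || !f$converged) NA_real_ else f$h2
      }, 0)
      median(bh, na.rm = TRUE)
    })
    qs <- quantile(boot, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                   na.rm = TRUE, names = FALSE)
    for (mo in mods) {
      f <- fit3[[mo]]
      rows[[length(rows) + 1L]] <- tibble(
        scope = sc, trait = tr, model = mo, h2 = f$h2,
        r_squared = f$r_squared, ci_lo = NA_real_, ci_hi = NA_real_,
        converged = f$converged, n_points = f$n_points, note = NA_character_)
    }
    rows[[length(rows) + 1L]] <- tibble(
      scope = sc, trait = tr, model = "consensus", h2 = consensus,
      r_squared = NA_real_, ci_lo = qs[1], ci_hi = qs[2],
      converged = !is.na(consensus), n_points = nrow(pts),
      note = NA_character_)
  }
  out <- bind_rows(rows)
  attr(out, "fits") <- fits
  out
}
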