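#' @importFrom generics tidy glance
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a saturating-curve heritability fit
#'
#' @param x a `heritability_fit`.
#' @param ... unused.
#' @return tibble with one row per fitted parameter (`term`, `estimate`).
#' @export
tidy.heritability_fit <- function(x, ...) {
  tibble(term = names(x$parameters),
         estimate = as.numeric(x$parameters))
}

#' One-row summary of a heritability fit
#'
#' @param x a `heritability_fit`.
#' @param ... unused.
#' @return tibble with `model`, `h2`, `h2_clamped`, `r_squared`, `n_points`,
#'   `converged`, `iterations`.
#' @export
glance.heritability_fit <- function(x, ...) {
  tibble(model = x$model, h2 = x$h2, h2_clamped = x$h2_clamped,
         r_squared = x$r_squared, n_points = x$n_points,
         converged = x$converged, iterations = x$iterations)
}

#' Tidy a heavy-tail fit
#'
#' @param x a `heavy_tail_fit`.
#' @param ... unused.
#' @return the model-comparison tibble, one row per alternative.
#' @export
tidy.heavy_tail_fit <- function(x, ...) x$comparisons

#' One-row summary of a heavy-tail fit
#'
#' @param x a `heavy_tail_fit`.
#' @param ... unused.
#' @return tibble with `alpha`, `xmin`, `n`, `n_tail`, `fraction_captured`,
#'   `ks_distance`, `discrete`.
#' @export
glance.heavy_tail_fit <- function(x, ...) {
  tibble(alpha = x$alpha, xmin = x$xmin, n = x$n, n_tail = x$n_tail,
         fraction_captured = x$fraction_captured,
         ks_distance = x$ks_distance, discrete = x$discrete)
}
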