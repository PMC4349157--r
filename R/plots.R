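#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_line geom_col labs
#'   theme_minimal
NULL

#' @export
ggplot2::autoplot

#' Plot a heritability fit: points and the fitted curve
#'
#' Relative genetic variance against |WMI| with the fitted saturating curve
#' overlaid, the usual way a heritability plateau is displayed.
#'
#' @param object a `heritability_fit`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.heritability_fit <- function(object, ...) {
  pts <- object$points
  grid <- tibble(x = seq(min(pts$x), max(pts$x), length.out = 256))
  grid$y <- object$predict_fn(grid$x)
  ggplot(pts, aes(x = .data$x, y = .data$y)) +
    geom_point(alpha = 0.7) +
    geom_line(data = grid, colour = "firebrick") +
    labs(x = "|WMI| (mmHg · nats)", y = "relative genetic variance",
         title = sprintf("%s fit: h² = %.3f", object$model, object$h2)) +
    theme_minimal()
}

#' Plot the three saturating fits of one scope together
#'
#' @param fits a named list of `heritability_fit` objects sharing the same
#'   points (one entry of the `fits` attribute of
#'   [estimate_heritability()]).
#' @return a ggplot.
#' @export
plot_heritability_fits <- function(fits) {
  pts <- fits[[1]]$points
  grid_x <- seq(min(pts$x), max(pts$x), length.out = 256)
  curves <- bind_rows(lapply(fits, function(f) {
    tibble(x = grid_x, y = f$predict_fn(grid_x), model = f$model)
  }))
  ggplot(pts, aes(x = .data$x, y = .data$y)) +
    geom_point(alpha = 0.7) +
    geom_line(data = curves, aes(colour = .data$model)) +
    labs(x = "|WMI| (mmHg · nats)", y = "relative genetic variance",
         colour = "model") +
    theme_minimal()
}

#' Degree histogram of an interaction network
#'
#' @param object an `interaction_network`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.interaction_network <- function(object, ...) {
  dd <- object$nodes |>
    dplyr::count(.data$degree, name = "n_nodes")
  ggplot(dd, aes(x = .data$degree, y = .data$n_nodes)) +
    geom_col() +
    labs(x = "node degree", y = "nodes",
         title = sprintf("%s-level network (%s gate)", object$level, object$gate)) +
    theme_minimal()
}

#' Tail plot of a heavy-tail fit
#'
#' Empirical complementary CDF on log-log axes with the fitted power-law
#' tail.
#'
#' @param object a `heavy_tail_fit`.
#' @param values the data the fit was computed from.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.heavy_tail_fit <- function(object, values, ...) {
  x <- sort(values[!is.na(values) & values > 0])
  ccdf <- tibble(x = x, p = 1 - (seq_along(x) - 1) / length(x))
  tail_frac <- object$fraction_captured
  grid <- tibble(x = exp(seq(log(object$xmin), log(max(x)), length.out = 128)))
  grid$p <- tail_frac * (grid$x / object$xmin)^(1 - object$alpha)
  ggplot(ccdf, aes(x = .data$x, y = .data$p)) +
    geom_point(size = 0.8, alpha = 0.6) +
    geom_line(data = grid, colour = "firebrick") +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    labs(x = "value", y = "P(X ≥ x)",
         title = sprintf("power-law tail: alpha = %.2f, xmin = %.3g",
                         object$alpha, object$xmin)) +
    theme_minimal()
}
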