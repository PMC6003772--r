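#' Plot a collated positional error profile
#'
#' Heatmap of incorporated-base rates per (position, encoded base); the
#' diagonal cells are the per-base fidelities.
#'
#' @param object A `positional_profile` (see [collate_positional()]).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.positional_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = .data$incorporated_base, y = .data$encoded_base, fill = .data$rate)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.3f", .data$rate)),
                       size = 2.6) +
    ggplot2::facet_wrap(~ position,
                        labeller = ggplot2::labeller(
                          position = function(p) paste("position", p))) +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick",
                                 trans = "sqrt") +
    ggplot2::labs(x = "incorporated base", y = "encoded product base",
                  fill = "rate")
}

#' Plot per-position fidelities of a fidelity result
#'
#' @param object A `fidelity_result` (see [positional_fidelity()]).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fidelity_result <- function(object, ...) {
  ggplot2::ggplot(object$per_base, ggplot2::aes(
    x = .data$base, y = .data$fidelity_pct)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = object$overall_pct, linetype = 2) +
    ggplot2::facet_wrap(~ position,
                        labeller = ggplot2::labeller(
                          position = function(p) paste("position", p))) +
    ggplot2::coord_cartesian(
      ylim = c(max(0, min(object$per_base$fidelity_pct) - 2), 100)) +
    ggplot2::labs(x = "encoded base", y = "fidelity (%)",
                  subtitle = sprintf("overall %.2f%% (dashed)",
                                     object$overall_pct))
}

#' Plot a Hill fit
#'
#' @param object A `hill_fit` (see [hill_fit()]).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.hill_fit <- function(object, ...) {
  pos <- object$fitted$conc[object$fitted$conc > 0]
  grid <- tibble(conc = exp(seq(log(min(pos) / 2), log(max(pos) * 2),
                                length.out = 200)))
  grid$fitted <- hill_curve(grid$conc, object$fmax, object$K, object$n)
  ggplot2::ggplot(object$fitted, ggplot2::aes(.data$conc, .data$response)) +
    ggplot2::geom_line(data = grid, ggplot2::aes(y = .data$fitted),
                       colour = "firebrick") +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "substrate concentration",
                  y = "fraction extended",
                  subtitle = sprintf("fmax = %.3g, K = %.3g, n = %.2f",
                                     object$fmax, object$K, object$n))
}

#' Plot free fractions of a dimerizing pool by GC content
#'
#' @param object A `pool_free` table (see [pool_free_concentrations()]).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pool_free <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = factor(.data$gc_count), y = .data$free_fraction)) +
    ggplot2::geom_jitter(width = 0.12, height = 0, alpha = 0.6) +
    ggplot2::labs(x = "G/C base pairs in triplet duplex",
                  y = "free fraction of total")
}

#' Plot an extension-product ladder
#'
#' @param object A `ladder` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ladder <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object), ggplot2::aes(
    x = .data$n_added, y = .data$intensity)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::labs(x = "substrates added", y = "band intensity")
}
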