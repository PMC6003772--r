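#' Tidy and glance methods
#'
#' broom-style accessors for the package's fitted/summary objects:
#' `tidy()` returns the per-component table, `glance()` a one-row summary.
#'
#' @param x A `fidelity_result`, `segment_fidelity` or `hill_fit`.
#' @param ... Unused.
#' @return A tibble.
#' @name tripletr-tidiers
NULL

#' @rdname tripletr-tidiers
#' @export
tidy.fidelity_result <- function(x, ...) {
  x$per_base
}

#' @rdname tripletr-tidiers
#' @export
glance.fidelity_result <- function(x, ...) {
  wide <- setNames(x$positional$fidelity_pct,
                   paste0("position", x$positional$position, "_pct"))
  dplyr::bind_cols(tibble(overall_pct = x$overall_pct),
                   as_tibble(as.list(wide)),
                   tibble(floor = x$floor))
}

#' @rdname tripletr-tidiers
#' @export
tidy.segment_fidelity <- function(x, ...) {
  x$per_position
}

#' @rdname tripletr-tidiers
#' @export
glance.segment_fidelity <- function(x, ...) {
  tibble(
    internal_average_pct = x$internal_average_pct,
    excluded_fraction = x$excluded_fraction,
    n_kept = x$n_kept,
    n_length_mismatch = x$n_length_mismatch,
    max_mutations = x$max_mutations
  )
}

#' @rdname tripletr-tidiers
#' @export
tidy.hill_fit <- function(x, ...) {
  tibble(term = c("fmax", "K", "n"), estimate = c(x$fmax, x$K, x$n))
}

#' @rdname tripletr-tidiers
#' @export
glance.hill_fit <- function(x, ...) {
  tibble(rss = x$rss, n_obs = x$n_obs,
         n_starts = nrow(x$starts), n_converged = sum(x$starts$converged))
}
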