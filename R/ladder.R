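#' Per-junction ligation extents from an intensity ladder
#'
#' A ladder records one band intensity per number of triplets (or
#' oligonucleotides) added, from 0 up to full length N. The extent of
#' ligation at junction `j` is the fraction of molecules that reached
#' junction `j` and were ligated through it:
#'
#'   `extent_j = sum(I_k, k >= j) / sum(I_k, k >= j - 1)`
#'
#' This survival-ratio definition makes the per-junction extents and the
#' full-length yield mutually consistent: their product telescopes exactly to
#' [full_length_yield()]. Junctions that no molecule reached (zero
#' denominator) are returned as `NA` and flagged with a warning.
#'
#' @param ladder A `ladder` tibble (`n_added`, `intensity`) as produced by
#'   [gen_ladder()] or [read_ladder()], or a bare intensity vector indexed
#'   0..N.
#' @return Tibble with columns `junction` (1..N) and `extent`.
#' @examples
#' junction_extents(c(1, 1, 1, 1)) # extents 0.75, 0.667, 0.5
#' @export
junction_extents <- function(ladder) {
  intensity <- ladder_intensity(ladder)
  N <- length(intensity) - 1L
  if (N < 1L) abort("a ladder needs at least one junction.")
  # tail[k+1] = sum of intensities at >= k additions
  tails <- rev(cumsum(rev(intensity)))
  extent <- tails[-1L] / tails[-length(tails)]
  if (anyNA(extent) || any(is.nan(extent))) {
    warn("junction(s) with zero reach: extent undefined (NA).")
    extent[is.nan(extent)] <- NA_real_
  }
  tibble(junction = seq_len(N), extent = extent)
}

#' Average extent of ligation
#'
#' Summarises per-junction extents by their geometric (default) or arithmetic
#' mean — the per-lane "average extent of ligation" statistic.
#'
#' @param extents Numeric vector of extents, or the tibble returned by
#'   [junction_extents()].
#' @param method `"geometric"` or `"arithmetic"`.
#' @return A single rate. With the geometric method, any zero extent gives 0
#'   with a warning.
#' @export
mean_extent <- function(extents, method = c("geometric", "arithmetic")) {
  method <- match.arg(method)
  if (is.data.frame(extents)) extents <- extents$extent
  if (anyNA(extents)) abort("all extents must be defined.")
  if (method == "arithmetic") return(mean(extents))
  if (any(extents == 0)) {
    warn("zero extent present: geometric mean is 0.")
    return(0)
  }
  geometric_mean(extents)
}

#' Full-length yield of a ladder
#'
#' Fraction of total intensity in the full-length band, `I_N / sum(I)`. By
#' the telescoping identity this equals the product of all junction extents.
#'
#' @inheritParams junction_extents
#' @return A single rate.
#' @export
full_length_yield <- function(ladder) {
  intensity <- ladder_intensity(ladder)
  intensity[length(intensity)] / sum(intensity)
}

ladder_intensity <- function(ladder) {
  intensity <- if (is.data.frame(ladder)) {
    ladder$intensity[order(ladder$n_added)]
  } else {
    as.numeric(ladder)
  }
  if (any(intensity < 0)) abort("intensities must be non-negative.")
  if (all(intensity == 0)) abort("all-zero ladder.")
  intensity
}
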