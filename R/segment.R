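#' Filter segment reads by mutation count
#'
#' Keeps full-length reads whose Hamming distance to the expected product
#' sequence is at most `max_mutations` (default 9, the filter used to exclude
#' unrelated amplified products such as off-target priming artefacts; 6 is
#' the conventional robustness threshold). Reads whose length differs from
#' the reference are excluded and tallied separately, not aligned.
#'
#' @param reads Tibble with a `seq` column or a character vector.
#' @param reference Expected product sequence (5'->3', RNA).
#' @param max_mutations Maximum tolerated substitutions (inclusive).
#' @return Tibble of kept reads with attributes `excluded_fraction` (fraction
#'   of length-matched reads above the threshold; `NA` for empty input),
#'   `n_excluded`, `n_length_mismatch`, `n_input`.
#' @export
filter_segment_reads <- function(reads, reference, max_mutations = 9L) {
  seqs <- if (is.data.frame(reads)) reads$seq else reads
  reference <- toupper(reference)
  n_input <- length(seqs)
  if (n_input == 0L) {
    out <- tibble(id = character(), seq = character())
    attr(out, "excluded_fraction") <- NA_real_
    warn("empty read set: excluded fraction undefined.")
    attr(out, "n_excluded") <- 0L
    attr(out, "n_length_mismatch") <- 0L
    attr(out, "n_input") <- 0L
    return(out)
  }
  full <- nchar(seqs) == nchar(reference)
  mm <- rep(NA_integer_, n_input)
  mm[full] <- hamming(seqs[full], reference)
  keep <- full & mm <= max_mutations
  out <- if (is.data.frame(reads)) reads[keep, ] else tibble(seq = seqs[keep])
  attr(out, "excluded_fraction") <- sum(full & !keep) / sum(full)
  attr(out, "n_excluded") <- sum(full & !keep)
  attr(out, "n_length_mismatch") <- sum(!full)
  attr(out, "n_input") <- n_input
  out
}

#' Per-position base fidelity of a read set
#'
#' Fidelity at position `p` is the percentage of kept reads whose base at `p`
#' equals the reference base.
#'
#' @param reads Kept reads (tibble with `seq`, or character vector), all the
#'   same length as `reference`.
#' @param reference Expected product sequence.
#' @return Tibble with columns `position`, `ref_base`, `fidelity_pct`.
#' @export
per_position_fidelity <- function(reads, reference) {
  seqs <- if (is.data.frame(reads)) reads$seq else reads
  reference <- toupper(reference)
  if (length(seqs) == 0L) abort("at least one kept read is required.")
  if (!all(nchar(seqs) == nchar(reference)))
    abort("all reads must match the reference length.")
  ref <- strsplit(reference, "", fixed = TRUE)[[1]]
  m <- seq_matrix(seqs)
  match_frac <- colMeans(m == matrix(ref, nrow = nrow(m), ncol = length(ref),
                                     byrow = TRUE))
  tibble(position = seq_along(ref), ref_base = ref,
         fidelity_pct = 100 * match_frac)
}

#' Internal-triplet geometric average fidelity
#'
#' The overall fidelity of a synthesised segment is gauged as the geometric
#' mean of per-position fidelities over the internal triplet positions: all
#' synthesised (non-primer) positions except the final triplet's three, which
#' form a known error hot-spot (the fidelity domain cannot operate without a
#' downstream triplet).
#'
#' @param fidelity_pct Numeric vector of per-position fidelities in percent,
#'   or the tibble returned by [per_position_fidelity()].
#' @param primer_length Leading positions contributed by the primer, dropped
#'   before averaging (0 when the vector already covers only synthesised
#'   positions).
#' @param final_triplet Trailing positions to drop (default 3).
#' @param floor Zero floor for the geometric mean (percent scale).
#' @return The geometric average, in percent.
#' @examples
#' internal_triplet_average(rep(90, 18)) # 90
#' @export
internal_triplet_average <- function(fidelity_pct, primer_length = 0L,
                                     final_triplet = 3L, floor = 0) {
  if (is.data.frame(fidelity_pct)) fidelity_pct <- fidelity_pct$fidelity_pct
  x <- fidelity_pct
  if (primer_length > 0L) {
    if (primer_length >= length(x)) abort("primer spans the whole vector.")
    x <- x[-seq_len(primer_length)]
  }
  if (length(x) %% 3L != 0L)
    abort("synthesised span must be a whole number of triplets.")
  if (length(x) - final_triplet < 3L)
    abort("fewer than one internal triplet after excluding the final one.")
  internal <- x[seq_len(length(x) - final_triplet)]
  geometric_mean(internal, floor = floor)
}

#' Segment fidelity analysis
#'
#' Convenience wrapper chaining [filter_segment_reads()],
#' [per_position_fidelity()] and [internal_triplet_average()] for a set of
#' full-length segment reads against the expected product sequence.
#'
#' @inheritParams filter_segment_reads
#' @param primer_length Leading positions contributed by the primer.
#' @return Object of class `segment_fidelity`: list with `per_position`
#'   (tibble), `internal_average_pct`, `excluded_fraction`,
#'   `n_length_mismatch`, `n_kept`, `max_mutations`, `primer_length`.
#' @export
segment_fidelity <- function(reads, reference, primer_length,
                             max_mutations = 9L) {
  reference <- toupper(reference)
  if ((nchar(reference) - primer_length) %% 3L != 0L)
    abort("reference length minus primer length must be a multiple of 3.")
  kept <- filter_segment_reads(reads, reference, max_mutations)
  per_pos <- per_position_fidelity(kept, reference)
  structure(
    list(
      per_position = per_pos,
      internal_average_pct = internal_triplet_average(
        per_pos$fidelity_pct, primer_length = primer_length),
      excluded_fraction = attr(kept, "excluded_fraction"),
      n_length_mismatch = attr(kept, "n_length_mismatch"),
      n_kept = nrow(kept),
      max_mutations = max_mutations,
      primer_length = primer_length
    ),
    class = "segment_fidelity"
  )
}

#' @export
print.segment_fidelity <- function(x, ...) {
  cat(sprintf(
    "Segment fidelity: internal-triplet average %.2f%% (%d reads kept, %.2f%% excluded)\n",
    x$internal_average_pct, x$n_kept, 100 * x$excluded_fraction))
  invisible(x)
}
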