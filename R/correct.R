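#' Background-correct an experimental count table
#'
#' Removes the background of apparent misincorporations (sequencing,
#' amplification, recombination) measured in a positive-control sample from
#' the experimental counts, template by template. With `C_x`/`C_p` the
#' experimental/control cognate counts and `E_x`/`E_p` the experimental/
#' control counts of an error triplet, the ribozyme-mediated error count is
#'
#'   `E_r = E_x - E_p * (C_x / C_p)`
#'
#' not reduced below 0, and every subtracted count is reallocated to the
#' corrected cognate count `C_r`, so the per-template total is conserved
#' exactly. Triplets in the control substrate set (the cognate, `CCC`, and
#' `UCC` on the `ACC`-cognate template) are never corrected: their raw
#' experimental counts are kept.
#'
#' @param exp_counts Experimental `triplet_counts` (from [count_triplets()]).
#' @param ctrl_counts Control `triplet_counts` over the same templates.
#' @param design The [assay_design()].
#' @return A `triplet_counts` table with `sample_kind = "corrected"`; counts
#'   may be fractional.
#' @examples
#' # worked example: E_x = 10, E_p = 2, C_x = 1000, C_p = 500
#' # E_r = 10 - 2 * (1000/500) = 6, and 4 counts move to the cognate
#' @export
background_correct <- function(exp_counts, ctrl_counts, design) {
  validate_assay_design(design)
  ids <- design$template_id
  if (!setequal(unique(exp_counts$template_id), ids) ||
      !setequal(unique(ctrl_counts$template_id), ids))
    abort("experimental/control tables must cover exactly the design's templates.")

  csets <- control_sets(design)
  ex <- count_matrix(exp_counts, ids)
  cp <- count_matrix(ctrl_counts, ids)
  corrected <- ex

  for (i in seq_along(ids)) {
    id <- ids[i]
    cognate <- design$cognate[i]
    C_x <- ex[id, cognate]
    C_p <- cp[id, cognate]
    if (C_p <= 0)
      abort(sprintf("control cognate count is zero for template %s.", id))
    err <- setdiff(colnames(ex), csets[[id]])
    s <- pmin(ex[id, err], cp[id, err] * (C_x / C_p))
    corrected[id, err] <- ex[id, err] - s
    corrected[id, cognate] <- C_x + sum(s)
  }

  out <- tidyr::pivot_longer(
    as_tibble(corrected, rownames = "template_id"),
    -"template_id", names_to = "triplet", values_to = "count"
  )
  out$sample_kind <- "corrected"
  out <- dplyr::arrange(out, .data$template_id, .data$triplet)
  new_triplet_counts(out, sample_kind = "corrected",
                     n_reads = attr(exp_counts, "n_reads"),
                     discards = discard_tallies(exp_counts))
}

# templates x 64 matrix of counts, zero-filled.
count_matrix <- function(counts, ids) {
  trips <- all_triplets()
  m <- matrix(0, nrow = length(ids), ncol = length(trips),
              dimnames = list(ids, trips))
  keep <- counts$triplet %in% trips
  m[cbind(match(counts$template_id[keep], ids),
          match(counts$triplet[keep], trips))] <- counts$count[keep]
  m
}
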