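#' Collate positional error profiles across templates
#'
#' For each template and product position (1 = 5' base of the incorporated
#' triplet), the marginal incorporated-base frequencies are computed from the
#' (corrected) counts; the collated profile entry for a (position, encoded
#' product base) cell is then the unweighted arithmetic mean over the three
#' templates whose cognate base at that position is that base. Counts of the
#' control-set triplets (`CCC`, `UCC`) remain in the tally — they are never
#' background-corrected, but still contribute to marginal frequencies.
#'
#' @param counts A `triplet_counts` table (typically corrected, see
#'   [background_correct()]) covering all 12 templates.
#' @param design The [assay_design()].
#' @return Tibble of class `positional_profile`: columns `position` (1-3),
#'   `encoded_base`, `incorporated_base`, `rate`; for each
#'   (position, encoded_base) the rates sum to 1. Attribute `total_count`
#'   carries the summed counts (used for the default zero floor of
#'   [positional_fidelity()]).
#' @export
collate_positional <- function(counts, design) {
  validate_assay_design(design)
  ids <- design$template_id
  if (!setequal(unique(counts$template_id), ids))
    abort("count table must cover all templates of the design.")
  m <- count_matrix(counts, ids)
  totals <- rowSums(m)
  if (any(totals <= 0))
    abort(sprintf("no counts for template %s.",
                  paste(ids[totals <= 0], collapse = ", ")))
  trips <- colnames(m)
  marg <- tidyr::expand_grid(template_id = ids, position = 1:3,
                             incorporated_base = rna_bases())
  marg$rate <- purrr::pmap_dbl(marg, function(template_id, position,
                                              incorporated_base) {
    sel <- substr(trips, position, position) == incorporated_base
    sum(m[template_id, sel]) / totals[template_id]
  })
  out <- collate_marginals(marg, design)
  attr(out, "total_count") <- sum(totals)
  out
}

# Average per-template marginal rates over the three templates encoding each
# base at each position. marg: tibble(template_id, position,
# incorporated_base, rate).
collate_marginals <- function(marg, design) {
  enc <- tidyr::expand_grid(template_id = design$template_id, position = 1:3)
  enc$encoded_base <- substr(
    design$cognate[match(enc$template_id, design$template_id)],
    enc$position, enc$position
  )
  grid <- tidyr::expand_grid(position = 1:3, encoded_base = rna_bases(),
                             incorporated_base = rna_bases())
  grid$rate <- purrr::pmap_dbl(grid, function(position, encoded_base,
                                              incorporated_base) {
    tpls <- enc$template_id[enc$position == position &
                              enc$encoded_base == encoded_base]
    if (length(tpls) == 0L)
      abort(sprintf(
        "no template encodes %s at position %d: design not balanced.",
        encoded_base, position))
    mean(marg$rate[marg$template_id %in% tpls &
                     marg$position == position &
                     marg$incorporated_base == incorporated_base])
  })
  structure(grid, class = c("positional_profile", class(tibble())))
}

#' Geometric-mean fidelity summaries of a positional profile
#'
#' Per-base fidelity at a position is the diagonal rate of the collated
#' profile (the fraction of incorporations matching the encoded base); the
#' positional fidelity is the geometric mean of the four per-base fidelities,
#' and the overall fidelity the geometric mean of the three positional
#' fidelities. All reported as percentages. Zero diagonal entries are
#' replaced by `floor` before taking logs.
#'
#' @param profile A `positional_profile` (see [collate_positional()]).
#' @param floor Replacement for zero diagonal rates; defaults to
#'   `1 / (total count + 1)` when the profile carries its total count, else
#'   `1e-12`.
#' @return Object of class `fidelity_result`: list with `per_base` (tibble:
#'   `position`, `base`, `fidelity_pct`), `positional` (tibble: `position`,
#'   `fidelity_pct`), `overall_pct`, and `floor`.
#' @examples
#' d <- design_balanced_templates(seed = 0)
#' m <- incorporation_model(d)
#' positional_fidelity(expected_profile(m, d))
#' @export
positional_fidelity <- function(profile, floor = NULL) {
  stopifnot(inherits(profile, "positional_profile"))
  if (is.null(floor)) {
    total <- attr(profile, "total_count")
    floor <- if (!is.null(total)) 1 / (total + 1) else 1e-12
  }
  diag <- profile |>
    dplyr::filter(.data$encoded_base == .data$incorporated_base) |>
    dplyr::transmute(position = .data$position, base = .data$encoded_base,
                     fidelity = .data$rate)
  positional <- diag |>
    dplyr::group_by(.data$position) |>
    dplyr::summarise(fidelity = geometric_mean(.data$fidelity, floor = floor),
                     .groups = "drop")
  overall <- geometric_mean(positional$fidelity, floor = floor)
  structure(
    list(
      per_base = dplyr::mutate(diag, fidelity_pct = 100 * .data$fidelity)[
        c("position", "base", "fidelity_pct")],
      positional = dplyr::mutate(positional,
                                 fidelity_pct = 100 * .data$fidelity)[
        c("position", "fidelity_pct")],
      overall_pct = 100 * overall,
      floor = floor
    ),
    class = "fidelity_result"
  )
}

#' @export
print.fidelity_result <- function(x, ...) {
  cat("Triplet polymerase fidelity (geometric means)\n")
  cat(sprintf("  overall: %.2f%%\n", x$overall_pct))
  for (i in seq_len(nrow(x$positional)))
    cat(sprintf("  position %d: %.2f%%\n",
                x$positional$position[i], x$positional$fidelity_pct[i]))
  invisible(x)
}

#' Mispair contest ratio and its reduction between conditions
#'
#' `contest_ratio()` returns the mispair incorporation fraction
#' `mispair / (mispair + cognate)` for one template of a count table —
#' the readout of a direct pair-vs-mispair triplet contest.
#' `contest_reduction()` compares two conditions (e.g. without and with
#' complementary anti-triplets added) and returns the proportional reduction
#' `1 - ratio2 / ratio1`.
#'
#' @param counts,counts1,counts2 `triplet_counts` tables.
#' @param template_id Template to read the contest from.
#' @param cognate,mispair The two competing triplets.
#' @return A single rate; `NA` with a warning when the denominator is zero.
#' @export
contest_ratio <- function(counts, template_id, cognate, mispair) {
  sub <- counts[counts$template_id == template_id, ]
  if (!all(c(cognate, mispair) %in% sub$triplet))
    abort("both triplets must be present in the table's key space.")
  c_n <- sum(sub$count[sub$triplet == cognate])
  m_n <- sum(sub$count[sub$triplet == mispair])
  if (c_n + m_n <= 0) {
    warn("zero cognate + mispair counts: contest ratio undefined.")
    return(NA_real_)
  }
  m_n / (m_n + c_n)
}

#' @rdname contest_ratio
#' @export
contest_reduction <- function(counts1, counts2, template_id, cognate, mispair) {
  r1 <- contest_ratio(counts1, template_id, cognate, mispair)
  r2 <- contest_ratio(counts2, template_id, cognate, mispair)
  if (is.na(r1) || is.na(r2) || r1 == 0) {
    warn("contest reduction undefined (zero or missing baseline ratio).")
    return(NA_real_)
  }
  1 - r2 / r1
}
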