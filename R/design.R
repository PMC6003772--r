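#' Construct an assay design
#'
#' An assay design describes the set of primer/template pairs used to profile
#' triplet incorporation. Each template presents the product context
#' `CCC-XXX-CCC`: extension starts with a fixed `CCC` triplet, the cognate
#' triplet `XXX` (the reverse complement of the template trinucleotide) is the
#' queried incorporation, and a downstream context triplet follows (`CCC`,
#' except `UCC` on the template whose cognate is `ACC`, which avoids a
#' terminal run of Gs on the template strand). A distinct primer-variant tag
#' at the 5' end of each primer identifies the template a sequenced product
#' came from.
#'
#' @param templates Tibble with columns `template_id`, `template` (template
#'   trinucleotide, 5'->3'), and `primer_variant` (distinct tag prepended to
#'   the shared primer core).
#' @param primer_core Shared primer sequence following the variant tag.
#' @param adaptor 3' adaptor sequence ligated to extension products.
#' @return A tibble of class `assay_design` with columns `template_id`,
#'   `template`, `cognate`, `upstream`, `downstream`, `primer_variant`, and
#'   attributes `primer_core` and `adaptor`.
#' @seealso [design_balanced_templates()] for the default balanced design.
#' @export
assay_design <- function(templates, primer_core, adaptor) {
  stopifnot(is.data.frame(templates),
            all(c("template_id", "template", "primer_variant") %in% names(templates)))
  out <- tibble(
    template_id    = as.character(templates$template_id),
    template       = toupper(templates$template),
    cognate        = rna_revcomp(toupper(templates$template)),
    upstream       = "CCC",
    downstream     = NA_character_,
    primer_variant = toupper(templates$primer_variant)
  )
  out$downstream <- ifelse(out$cognate == "ACC", "UCC", "CCC")
  attr(out, "primer_core") <- toupper(primer_core)
  attr(out, "adaptor") <- toupper(adaptor)
  class(out) <- c("assay_design", class(tibble()))
  validate_assay_design(out)
  out
}

#' Validate an assay design
#'
#' Checks the structural invariants of an [assay_design()]: cognates are
#' reverse complements of templates, downstream context is `CCC` except `UCC`
#' for the `ACC` cognate, primer variants are pairwise distinct and of one
#' length, and — for 12-template designs — each base occurs exactly three
#' times at each template position.
#'
#' @param design An `assay_design`.
#' @return The design, invisibly; errors if an invariant is violated.
#' @export
validate_assay_design <- function(design) {
  stopifnot(inherits(design, "assay_design"))
  if (anyDuplicated(design$template_id))
    abort("template ids must be distinct.")
  if (!all(design$cognate == rna_revcomp(design$template)))
    abort("cognate triplets must be reverse complements of the templates.")
  bad_down <- ifelse(design$cognate == "ACC", "UCC", "CCC") != design$downstream
  if (any(bad_down))
    abort("downstream context must be CCC (UCC for the ACC cognate).")
  if (anyDuplicated(design$primer_variant))
    abort("primer-variant tags must be pairwise distinct.")
  if (length(unique(nchar(design$primer_variant))) != 1L)
    abort("primer-variant tags must share one length.")
  if (nrow(design) == 12L) {
    for (p in 1:3) {
      tab <- table(factor(substr(design$cognate, p, p), levels = rna_bases()))
      if (!all(tab == 3L))
        abort(sprintf("base composition unbalanced at cognate position %d.", p))
    }
  }
  invisible(design)
}

#' Generate a compositionally balanced 12-template design
#'
#' Draws 12 distinct cognate product triplets such that each of A, C, G and U
#' occurs exactly three times at each of the three triplet positions, so that
#' positional error collation averages every (position, base) cell over
#' exactly three templates. The `ACC` cognate is always included so that the
#' `UCC` downstream-context special case is represented. Primer-variant tags
#' are distinct 4-nt sequences at pairwise Hamming distance >= 2.
#'
#' The true template set used in the original assay is not public; this
#' generator produces a synthetic stand-in satisfying the same printed
#' balance constraint, and any design can be supplied instead via
#' [assay_design()] or [read_assay_design()].
#'
#' @param seed Integer seed; the design is deterministic given the seed.
#' @param primer_core Shared primer core sequence.
#' @param adaptor 3' adaptor sequence.
#' @param include_acc Force inclusion of the `ACC` cognate (default `TRUE`).
#' @return An [assay_design()] with 12 templates.
#' @examples
#' d <- design_balanced_templates(seed = 0)
#' table(substr(d$cognate, 1, 1)) # each base three times
#' @export
design_balanced_templates <- function(seed = 0L,
                                      primer_core = "GACUCGAUCGUA",
                                      adaptor = "UGGAAUUCUCGG",
                                      include_acc = TRUE) {
  b <- rna_bases()
  withr::with_seed(seed, {
    repeat {
      cognates <- paste0(sample(rep(b, 3L)), sample(rep(b, 3L)), sample(rep(b, 3L)))
      if (anyDuplicated(cognates)) next
      if (include_acc && !("ACC" %in% cognates)) next
      break
    }
    variants <- pick_variant_tags(12L, width = 4L, min_dist = 2L)
  })
  assay_design(
    tibble(
      template_id    = sprintf("T%02d", seq_len(12L)),
      template       = rna_revcomp(cognates),
      primer_variant = variants
    ),
    primer_core = primer_core, adaptor = adaptor
  )
}

# Greedy selection of n tags of the given width with pairwise Hamming
# distance >= min_dist, from a shuffled enumeration of all tags.
pick_variant_tags <- function(n, width = 4L, min_dist = 2L) {
  b <- rna_bases()
  pool <- apply(as.matrix(expand.grid(rep(list(b), width),
                                      stringsAsFactors = FALSE)),
                1L, paste, collapse = "")
  pool <- sample(pool)
  chosen <- character(0)
  for (tag in pool) {
    if (length(chosen) == 0L || all(hamming(chosen, tag) >= min_dist))
      chosen <- c(chosen, tag)
    if (length(chosen) == n) break
  }
  if (length(chosen) < n) abort("could not assemble enough distinct tags.")
  chosen
}

#' Control substrate sets of a design
#'
#' In the positive-control reaction each template is extended with only its
#' cognate triplet plus the context substrate `CCC` (and `UCC` for the
#' `ACC`-cognate template). Counts of these triplets are never
#' background-corrected; everything outside the set is treated as an error
#' count.
#'
#' @param design An [assay_design()].
#' @return Named list (by `template_id`) of character vectors of triplets.
#' @export
control_sets <- function(design) {
  stopifnot(inherits(design, "assay_design"))
  setNames(
    lapply(seq_len(nrow(design)), function(i) {
      unique(c(design$cognate[i], "CCC", design$downstream[i]))
    }),
    design$template_id
  )
}

#' Full primer sequences of a design
#'
#' @param design An [assay_design()].
#' @return Named character vector: primer-variant tag + shared primer core,
#'   one per template.
#' @export
design_primers <- function(design) {
  setNames(paste0(design$primer_variant, attr(design, "primer_core")),
           design$template_id)
}
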