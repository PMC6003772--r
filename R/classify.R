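#' Classify reads by primer variant and extract incorporated triplets
#'
#' Demultiplexes each read by matching the primer (variant tag + shared core)
#' at the read start within `max_mismatch` substitutions, requires the
#' extension to begin with the fixed `CCC` triplet, trims at the first exact
#' adaptor occurrence, and splits the remaining insert into 3-nt frames
#' (trailing partial frames are dropped). Reads with 0 or more than 3
#' complete post-`CCC` triplets are unassigned ("gating"), mirroring the gel
#' excision window of 1-3 triplet additions used in the assay.
#'
#' Unassignment reasons: `n_base` (ambiguous base), `too_short`,
#' `primer_unmatched`, `primer_ambiguous` (two variants within
#' `max_mismatch`), `no_ccc_start`, `gating`.
#'
#' @param reads Character vector of read sequences, or a tibble with a `seq`
#'   column (as returned by [read_fastq()]).
#' @param design An [assay_design()].
#' @param max_mismatch Substitutions tolerated across the primer region when
#'   matching (default 0 = exact).
#' @return Tibble with one row per read: `template_id`, `triplets` (list
#'   column of complete incorporated triplets), `first_triplet`, `n_triplets`,
#'   `reason` (`NA` for assigned reads).
#' @examples
#' d <- design_balanced_templates(seed = 0)
#' read <- paste0(design_primers(d)[3], "CCCGAU", attr(d, "adaptor"))
#' classify_read(read, d)
#' @export
classify_read <- function(reads, design, max_mismatch = 0L) {
  core <- classify_core(reads, design, max_mismatch)
  core$triplets <- lapply(seq_len(nrow(core)), function(i) {
    if (is.na(core$template_id[i]) || core$n_triplets[i] == 0L) character(0)
    else substring(core$insert[i],
                   seq(1L, by = 3L, length.out = core$n_triplets[i]),
                   seq(3L, by = 3L, length.out = core$n_triplets[i]))
  })
  core[c("template_id", "triplets", "first_triplet", "n_triplets", "reason")]
}

# Vectorised classification engine shared by classify_read()/count_triplets().
# Returns tibble(template_id, insert, first_triplet, n_triplets, reason).
classify_core <- function(reads, design, max_mismatch = 0L) {
  if (is.data.frame(reads)) reads <- reads$seq
  validate_assay_design(design)
  primers <- unname(design_primers(design))
  plen <- nchar(primers[1L])
  adaptor <- attr(design, "adaptor")

  n <- length(reads)
  template_id <- rep(NA_character_, n)
  reason <- rep(NA_character_, n)
  insert <- rep(NA_character_, n)

  ok <- !grepl("[^ACGU]", reads)
  reason[!ok] <- "n_base"

  long_enough <- nchar(reads) >= plen + 3L
  reason[ok & !long_enough] <- "too_short"
  ok <- ok & long_enough

  prefix <- substr(reads, 1L, plen)
  if (max_mismatch == 0L) {
    m <- match(prefix, primers)
  } else {
    m <- rep(NA_integer_, n)
    idx <- which(ok)
    if (length(idx)) {
      mm <- vapply(primers, function(p) hamming(prefix[idx], p),
                   integer(length(idx)))
      mm <- matrix(mm, nrow = length(idx))
      hits <- rowSums(mm <= max_mismatch)
      best <- apply(mm, 1L, which.min)
      m[idx][hits == 1L] <- best[hits == 1L]
      amb <- idx[hits >= 2L]
      reason[amb] <- "primer_ambiguous"
      ok[amb] <- FALSE
    }
  }
  unmatched <- ok & is.na(m) & is.na(reason)
  reason[unmatched] <- "primer_unmatched"
  ok <- ok & !is.na(m) & is.na(reason)

  has_ccc <- substr(reads, plen + 1L, plen + 3L) == "CCC"
  reason[ok & !has_ccc] <- "no_ccc_start"
  ok <- ok & has_ccc

  rest <- substr(reads, plen + 4L, nchar(reads))
  apos <- regexpr(adaptor, rest, fixed = TRUE)
  ins <- ifelse(apos > 0L, substr(rest, 1L, apos - 1L), rest)
  n_trip <- nchar(ins) %/% 3L       # trailing partial frames dropped
  gated <- ok & (n_trip < 1L | n_trip > 3L)
  reason[gated] <- "gating"
  ok <- ok & !gated

  template_id[ok] <- design$template_id[m[ok]]
  insert[ok] <- substr(ins[ok], 1L, 3L * n_trip[ok])
  tibble(
    template_id = template_id,
    insert = insert,
    first_triplet = ifelse(ok, substr(ins, 1L, 3L), NA_character_),
    n_triplets = ifelse(ok, n_trip, 0L),
    reason = reason
  )
}

#' Count incorporated triplets per template
#'
#' Classifies every read (see [classify_read()]) and tallies the FIRST
#' post-`CCC` triplet of each assigned read, producing the raw count table a
#' fidelity analysis starts from. Assigned counts plus discard tallies equal
#' the input read count.
#'
#' @inheritParams classify_read
#' @param sample_kind One of `"experimental"`, `"control"`; recorded on the
#'   table.
#' @return Tibble of class `triplet_counts` with one row per
#'   (template, triplet) over the full 64-triplet grid: columns
#'   `template_id`, `triplet`, `count`, `sample_kind`. Attributes: `discards`
#'   (tibble of reason/n), `n_reads`, `sample_kind`.
#' @export
count_triplets <- function(reads, design, max_mismatch = 0L,
                           sample_kind = c("experimental", "control")) {
  sample_kind <- match.arg(sample_kind)
  if (is.data.frame(reads)) reads <- reads$seq
  cls <- classify_core(reads, design, max_mismatch)
  assigned <- cls[!is.na(cls$template_id), ]
  tab <- table(factor(assigned$template_id, levels = design$template_id),
               factor(assigned$first_triplet, levels = all_triplets()))
  counts <- as_tibble(tab, .name_repair = ~ c("template_id", "triplet", "count"))
  counts$count <- as.numeric(counts$count)
  counts$sample_kind <- sample_kind
  counts <- dplyr::arrange(counts, .data$template_id, .data$triplet)
  discards <- cls |>
    dplyr::filter(!is.na(.data$reason)) |>
    dplyr::count(.data$reason, name = "n")
  new_triplet_counts(counts, sample_kind = sample_kind,
                     n_reads = length(reads), discards = discards)
}

#' Construct a triplet count table
#'
#' Builds a `triplet_counts` table from a data frame of per-(template,
#' triplet) counts, completing the 64-triplet grid with zeros — useful for
#' entering externally tabulated counts or worked examples.
#'
#' @param tbl Data frame with columns `template_id`, `triplet`, `count`.
#' @param sample_kind One of `"experimental"`, `"control"`, `"corrected"`.
#' @param template_ids Templates the table covers (default: those present).
#' @return A `triplet_counts` tibble (see [count_triplets()]).
#' @export
triplet_counts <- function(tbl, sample_kind = "experimental",
                           template_ids = unique(tbl$template_id)) {
  stopifnot(all(c("template_id", "triplet", "count") %in% names(tbl)),
            all(tbl$count >= 0), all(tbl$triplet %in% all_triplets()))
  agg <- tbl |>
    dplyr::group_by(.data$template_id, .data$triplet) |>
    dplyr::summarise(count = sum(.data$count), .groups = "drop")
  out <- tidyr::expand_grid(template_id = template_ids,
                            triplet = all_triplets()) |>
    dplyr::left_join(agg, by = c("template_id", "triplet")) |>
    dplyr::mutate(count = dplyr::coalesce(.data$count, 0),
                  sample_kind = sample_kind)
  new_triplet_counts(out, sample_kind = sample_kind,
                     n_reads = sum(out$count))
}

new_triplet_counts <- function(tbl, sample_kind, n_reads = NA_integer_,
                               discards = tibble(reason = character(),
                                                 n = integer())) {
  structure(
    as_tibble(tbl),
    sample_kind = sample_kind,
    n_reads = n_reads,
    discards = discards,
    class = c("triplet_counts", class(tibble()))
  )
}

#' Discard tallies of a count table
#'
#' @param counts A `triplet_counts` table.
#' @return Tibble with columns `reason`, `n`.
#' @export
discard_tallies <- function(counts) {
  attr(counts, "discards") %||% tibble(reason = character(), n = integer())
}
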