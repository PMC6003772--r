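# Independent oracles used to cross-check the package implementations.
# These deliberately share no code with the functions they verify.

# Plain-loop FASTQ tally: demultiplex by exact primer prefix, require CCC,
# strip the adaptor with a regex, and count the first complete triplet.
brute_tally <- function(seqs, design) {
  primers <- paste0(design$primer_variant, attr(design, "primer_core"))
  adaptor <- attr(design, "adaptor")
  counts <- list()
  n_discard <- 0L
  for (s in seqs) {
    hit <- NA_integer_
    for (i in seq_along(primers)) {
      p <- primers[i]
      if (nchar(s) >= nchar(p) && substring(s, 1, nchar(p)) == p) {
        hit <- i
        break
      }
    }
    if (is.na(hit) || grepl("[^ACGU]", s)) { n_discard <- n_discard + 1L; next }
    body <- substring(s, nchar(primers[hit]) + 1L)
    if (substring(body, 1, 3) != "CCC") { n_discard <- n_discard + 1L; next }
    ins <- sub(paste0(gsub("([^ACGU])", "\\\\\\1", adaptor), ".*$"), "",
               substring(body, 4))
    nt <- floor(nchar(ins) / 3)
    if (nt < 1 || nt > 3) { n_discard <- n_discard + 1L; next }
    key <- paste(design$template_id[hit], substring(ins, 1, 3), sep = "|")
    counts[[key]] <- (counts[[key]] %||% 0) + 1
  }
  list(counts = counts, n_discard = n_discard)
}

# Direct evaluation of the background-correction formula for one error
# triplet: subtract the depth-scaled control error count, clamp at zero,
# return both the corrected count and the amount reallocated to the cognate.
brute_correct_one <- function(e_x, e_p, c_x, c_p) {
  e_r <- e_x - e_p * (c_x / c_p)
  if (e_r < 0) e_r <- 0
  list(e_r = e_r, realloc = e_x - e_r)
}

# 1-D bisection for the dimer concentration of a complementary pair:
# solves (A - D)(B - D) = Kd * D on [0, min(A, B)].
bisect_pair <- function(total_a, total_b, kd, tol = 1e-13) {
  f <- function(d) (total_a - d) * (total_b - d) - kd * d
  lo <- 0
  hi <- min(total_a, total_b)
  if (hi == 0) return(0)
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
    if (hi - lo < tol * max(1, hi)) break
  }
  (lo + hi) / 2
}

# Naive product-form geometric mean.
naive_gm <- function(x) prod(x)^(1 / length(x))

`%||%` <- function(a, b) if (is.null(a)) b else a

# Small shared fixtures.
test_design <- function() design_balanced_templates(seed = 0)

# A count table in which every template incorporated only its cognate.
cognate_only_counts <- function(design, n = 1000, sample_kind = "experimental") {
  triplet_counts(
    tibble::tibble(template_id = design$template_id,
                   triplet = design$cognate, count = n),
    sample_kind = sample_kind, template_ids = design$template_id
  )
}
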