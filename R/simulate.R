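#' Simulate fidelity-assay reads
#'
#' Generates sequencing reads of primer-extension products for a whole assay:
#' each read is primer-variant tag + primer core + `CCC` + the first
#' incorporated triplet (drawn from the template's 64-way distribution) +
#' further downstream-context triplets (for 2 or 3 additions) + adaptor, with
#' i.i.d. per-base substitution noise at the model's `seq_error`. Templates
#' are assigned to reads at random (uniformly unless `template_weights` is
#' given), so reads arrive shuffled across templates. Output is
#' bit-reproducible given the seed.
#'
#' @param design An [assay_design()].
#' @param model An [incorporation_model()] built for `design`.
#' @param n_reads Number of reads (> 0).
#' @param seed Integer seed.
#' @param template_weights Optional per-template sampling weights.
#' @return Tibble with columns `id`, `seq`, `qual`, carrying a `truth`
#'   attribute (tibble: `id`, `template_id`, `k`, `first_triplet`) for
#'   recovery experiments.
#' @export
gen_fidelity_reads <- function(design, model, n_reads, seed,
                               template_weights = NULL) {
  check_model_design(model, design)
  stopifnot(n_reads > 0)
  trips <- colnames(model$prob)
  withr::with_seed(seed, {
    tpl <- sample.int(nrow(design), n_reads, replace = TRUE,
                      prob = template_weights)
    k <- sample.int(3L, n_reads, replace = TRUE, prob = model$k_probs)
    first <- character(n_reads)
    for (i in seq_len(nrow(design))) {
      idx <- which(tpl == i)
      if (length(idx))
        first[idx] <- sample(trips, length(idx), replace = TRUE,
                             prob = model$prob[i, ])
    }
    seqs <- assemble_reads(design, tpl, k, first)
    seqs <- apply_read_noise(seqs, model$seq_error)
  })
  reads <- tibble(
    id = sprintf("read%07d", seq_len(n_reads)),
    seq = seqs,
    qual = strrep("I", nchar(seqs))
  )
  attr(reads, "truth") <- tibble(
    id = reads$id, template_id = design$template_id[tpl],
    k = k, first_triplet = first
  )
  reads
}

#' Simulate positive-control reads
#'
#' The positive-control reaction extends each primer/template with only its
#' control substrate set (cognate triplet plus `CCC`, and `UCC` on the
#' `ACC`-cognate template): the first incorporated triplet is the cognate and
#' subsequent additions are the downstream context. Substitution noise at
#' `control_error` then produces the background of apparent misincorporations
#' (from amplification and sequencing) that [background_correct()] removes.
#'
#' @inheritParams gen_fidelity_reads
#' @param control_error Per-base substitution rate in `[0, 0.5)`.
#' @param k_probs Distribution of 1-3 triplet additions.
#' @return Tibble of reads as in [gen_fidelity_reads()].
#' @export
gen_control_reads <- function(design, n_reads, control_error = 0, seed = 0L,
                              k_probs = c(0.5, 0.3, 0.2),
                              template_weights = NULL) {
  stopifnot(inherits(design, "assay_design"), n_reads > 0,
            control_error >= 0, control_error < 0.5)
  withr::with_seed(seed, {
    tpl <- sample.int(nrow(design), n_reads, replace = TRUE,
                      prob = template_weights)
    k <- sample.int(3L, n_reads, replace = TRUE, prob = k_probs)
    first <- design$cognate[tpl]
    seqs <- assemble_reads(design, tpl, k, first)
    seqs <- apply_read_noise(seqs, control_error)
  })
  reads <- tibble(
    id = sprintf("ctrl%07d", seq_len(n_reads)),
    seq = seqs,
    qual = strrep("I", nchar(seqs))
  )
  attr(reads, "truth") <- tibble(
    id = reads$id, template_id = design$template_id[tpl],
    k = k, first_triplet = first
  )
  reads
}

# primer + CCC + first + (k-1) downstream-context triplets + adaptor
assemble_reads <- function(design, tpl, k, first) {
  primers <- unname(design_primers(design))
  down <- design$downstream[tpl]
  paste0(primers[tpl], "CCC", first,
         ifelse(k >= 2L, down, ""), ifelse(k >= 3L, down, ""),
         attr(design, "adaptor"))
}

# i.i.d. per-base substitution noise; groups reads by length so each group is
# a rectangular character matrix. RNG already seeded by caller.
apply_read_noise <- function(seqs, rate) {
  if (rate == 0) return(seqs)
  out <- seqs
  for (len in sort(unique(nchar(seqs)))) {
    idx <- which(nchar(seqs) == len)
    m <- seq_matrix(seqs[idx])
    hit <- matrix(stats::runif(length(m)) < rate, nrow = nrow(m))
    m[] <- substitute_bases(as.vector(m), as.vector(hit))
    out[idx] <- apply(m, 1L, paste, collapse = "")
  }
  out
}

#' Simulate full-length segment reads
#'
#' Reads are full-length copies of `reference` with independent per-position
#' substitutions at the given rates (uniform over the three alternative
#' bases), emulating sequencing of a long ribozyme-synthesised segment.
#'
#' @param reference Reference product sequence (5'->3', RNA).
#' @param per_position_error Vector of substitution rates, one per reference
#'   position, each in `[0, 1)`.
#' @param n_reads Number of reads (> 0).
#' @param seed Integer seed.
#' @return Tibble with columns `id`, `seq`, `qual`.
#' @export
gen_segment_reads <- function(reference, per_position_error, n_reads, seed) {
  reference <- toupper(reference)
  L <- nchar(reference)
  if (length(per_position_error) != L)
    abort("per_position_error must have one rate per reference position.")
  if (any(per_position_error < 0) || any(per_position_error >= 1))
    abort("per-position error rates must lie in [0, 1).")
  stopifnot(n_reads > 0)
  ref <- strsplit(reference, "", fixed = TRUE)[[1]]
  withr::with_seed(seed, {
    m <- matrix(rep(ref, each = n_reads), nrow = n_reads)
    hit <- matrix(stats::runif(n_reads * L), nrow = n_reads) <
      matrix(rep(per_position_error, each = n_reads), nrow = n_reads)
    m[] <- substitute_bases(as.vector(m), as.vector(hit))
    seqs <- apply(m, 1L, paste, collapse = "")
  })
  tibble(
    id = sprintf("seg%07d", seq_len(n_reads)),
    seq = seqs,
    qual = strrep("I", L)
  )
}

#' Simulate an extension-product intensity ladder
#'
#' Produces the band-intensity vector a gel lane would show for a ligation
#' reaction with the given per-junction extents: the expected intensity at
#' `k` additions is proportional to the probability of ligating through
#' junctions 1..k and stopping at junction k+1 (survival product), with
#' optional multiplicative log-normal noise.
#'
#' @param junction_extents Vector of per-junction ligation extents in `[0, 1]`
#'   (junction `j` = fraction of molecules reaching junction `j` that ligate
#'   through it).
#' @param n_molecules Total intensity scale.
#' @param noise Standard deviation of multiplicative log-normal noise
#'   (0 = exact expectations).
#' @param seed Integer seed (required when `noise > 0`).
#' @return Tibble of class `ladder` with columns `n_added` (0..N) and
#'   `intensity`.
#' @examples
#' gen_ladder(rep(1, 3)) # all intensity at full length
#' @export
gen_ladder <- function(junction_extents, n_molecules = 1e6, noise = 0,
                       seed = NULL) {
  e <- junction_extents
  if (any(e < 0) || any(e > 1)) abort("extents must lie in [0, 1].")
  N <- length(e)
  surv <- cumprod(e)                      # P(reach beyond junction k)
  p <- c(1 - e[1], surv[-N] * (1 - e[-1]), surv[N])
  intensity <- n_molecules * p
  if (noise > 0) {
    if (is.null(seed)) abort("a seed is required when noise > 0.")
    withr::with_seed(seed, {
      intensity <- intensity * exp(stats::rnorm(N + 1L, 0, noise))
    })
  }
  structure(tibble(n_added = 0:N, intensity = intensity),
            class = c("ladder", class(tibble())))
}

#' Simulate a dose-response table
#'
#' Cooperative (Hill) extension response to substrate concentration:
#' `y = fmax * c^n / (K^n + c^n)` plus Gaussian noise, truncated to `[0, 1]`.
#' This is the sigmoidal concentration dependence produced by cooperative
#' triplet invasion of structured templates.
#'
#' @param fmax Saturating extension fraction.
#' @param K Half-saturation concentration (same units as `concentrations`).
#' @param n Hill coefficient (> 0).
#' @param concentrations Vector of substrate concentrations (>= 0).
#' @param noise_sd Gaussian noise standard deviation.
#' @param seed Integer seed (required when `noise_sd > 0`).
#' @return Tibble with columns `conc` and `response`.
#' @export
gen_dose_response <- function(fmax, K, n, concentrations, noise_sd = 0,
                              seed = NULL) {
  stopifnot(K > 0, n > 0, all(concentrations >= 0))
  y <- hill_curve(concentrations, fmax, K, n)
  if (noise_sd > 0) {
    if (is.null(seed)) abort("a seed is required when noise_sd > 0.")
    withr::with_seed(seed, {
      y <- y + stats::rnorm(length(y), 0, noise_sd)
    })
  }
  tibble(conc = concentrations, response = pmin(pmax(y, 0), 1))
}

check_model_design <- function(model, design) {
  stopifnot(inherits(model, "incorporation_model"),
            inherits(design, "assay_design"))
  if (!identical(rownames(model$prob), design$template_id))
    abort("model template ids do not match the design.")
  invisible(TRUE)
}
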