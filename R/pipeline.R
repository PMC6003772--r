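#' Run the full fidelity pipeline on simulated reads
#'
#' Convenience wrapper for recovery experiments: simulates experimental and
#' positive-control reads for a design/model, counts first incorporated
#' triplets, background-corrects, collates the positional error profile and
#' summarises geometric-mean fidelities.
#'
#' @param design An [assay_design()].
#' @param model An [incorporation_model()].
#' @param n_reads Experimental reads to simulate.
#' @param seed Integer seed (control reads use `seed + 1`).
#' @param n_control_reads Control reads to simulate (default `n_reads`).
#' @param control_error Per-base noise rate of the control sample; defaults
#'   to the model's `seq_error` (matched background).
#' @param correct Apply background correction (`TRUE`) or summarise raw
#'   experimental counts (`FALSE`).
#' @return List with elements `counts` (experimental), `control_counts`,
#'   `corrected` (or the raw counts when `correct = FALSE`), `profile`,
#'   `fidelity`, `discards`.
#' @export
run_fidelity_pipeline <- function(design, model, n_reads, seed,
                                  n_control_reads = n_reads,
                                  control_error = model$seq_error,
                                  correct = TRUE) {
  reads <- gen_fidelity_reads(design, model, n_reads, seed = seed)
  counts <- count_triplets(reads, design, sample_kind = "experimental")
  ctrl_reads <- gen_control_reads(design, n_control_reads,
                                  control_error = control_error,
                                  seed = seed + 1L, k_probs = model$k_probs)
  ctrl_counts <- count_triplets(ctrl_reads, design, sample_kind = "control")
  table_for_profile <- if (correct) {
    background_correct(counts, ctrl_counts, design)
  } else {
    counts
  }
  profile <- collate_positional(table_for_profile, design)
  list(
    counts = counts,
    control_counts = ctrl_counts,
    corrected = table_for_profile,
    profile = profile,
    fidelity = positional_fidelity(profile),
    discards = discard_tallies(counts)
  )
}
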