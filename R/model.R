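#' Specify a triplet incorporation model
#'
#' The incorporation model is the ground truth behind the read simulators:
#' for each template, a probability distribution over the 64 incorporable
#' triplets; a distribution over the number of triplet additions (1-3) beyond
#' the leading `CCC`; and an i.i.d. per-base sequencing/amplification error
#' rate applied to finished reads.
#'
#' By default the 64-way distribution is assembled from independent
#' per-position base errors: at product position `i` the encoded (cognate)
#' base is incorporated with probability `1 - positional_error[i]`, and the
#' error mass is split among the other three bases, with `wobble_weight`
#' going to the G:U wobble partner where one exists (template G accepts U,
#' template U accepts G) and the remainder split evenly. Position 1 is the 5'
#' base of the incorporated product triplet. A full 12 x 64 probability
#' matrix may be supplied instead via `prob`.
#'
#' @param design An [assay_design()].
#' @param positional_error Length-3 vector of per-position error rates.
#'   Defaults emulate an accurate triplet polymerase with a mild 5'->3'
#'   accuracy gradient (overall fidelity around 97.5%).
#' @param wobble_weight Fraction of the error mass given to the wobble
#'   partner where one exists.
#' @param k_probs Probabilities of 1, 2 or 3 triplet additions beyond `CCC`.
#' @param seq_error Per-base substitution error rate in `[0, 0.5)`.
#' @param prob Optional 12 x 64 matrix (rows = template ids, columns =
#'   [all_triplets()]) overriding the positional construction.
#' @return An object of class `incorporation_model`: list with elements
#'   `prob`, `k_probs`, `seq_error`, `control_sets`.
#' @examples
#' d <- design_balanced_templates(seed = 0)
#' m <- incorporation_model(d)
#' rowSums(m$prob) # each template distribution sums to 1
#' @export
incorporation_model <- function(design,
                                positional_error = c(0.035, 0.020, 0.012),
                                wobble_weight = 0.6,
                                k_probs = c(0.5, 0.3, 0.2),
                                seq_error = 0,
                                prob = NULL) {
  stopifnot(inherits(design, "assay_design"))
  trips <- all_triplets()
  if (is.null(prob)) {
    stopifnot(length(positional_error) == 3L,
              all(positional_error >= 0), all(positional_error < 1),
              wobble_weight >= 0, wobble_weight <= 1)
    prob <- t(vapply(seq_len(nrow(design)), function(i) {
      per_pos <- lapply(1:3, function(p) {
        base_error_dist(substr(design$cognate[i], p, p),
                        positional_error[p], wobble_weight)
      })
      p1 <- per_pos[[1]][substr(trips, 1, 1)]
      p2 <- per_pos[[2]][substr(trips, 2, 2)]
      p3 <- per_pos[[3]][substr(trips, 3, 3)]
      unname(p1 * p2 * p3)
    }, numeric(64L)))
    dimnames(prob) <- list(design$template_id, trips)
  } else {
    prob <- as.matrix(prob)
    if (is.null(rownames(prob))) rownames(prob) <- design$template_id
    prob <- prob[design$template_id, trips, drop = FALSE]
  }
  if (any(prob < 0)) abort("incorporation probabilities must be >= 0.")
  if (any(abs(rowSums(prob) - 1) > 1e-12))
    abort("each per-template distribution must sum to 1 (within 1e-12).")
  stopifnot(length(k_probs) == 3L, all(k_probs >= 0),
            abs(sum(k_probs) - 1) < 1e-12)
  if (seq_error < 0 || seq_error >= 0.5)
    abort("seq_error must lie in [0, 0.5).")
  structure(
    list(prob = prob, k_probs = k_probs, seq_error = seq_error,
         control_sets = control_sets(design)),
    class = "incorporation_model"
  )
}

# Distribution over incorporated bases at one position given the encoded
# (cognate product) base. The wobble partner is the base read through a G:U
# pair with the template base (= complement of the encoded base).
base_error_dist <- function(encoded, error, wobble_weight) {
  b <- rna_bases()
  out <- setNames(rep(0, 4L), b)
  out[encoded] <- 1 - error
  others <- setdiff(b, encoded)
  template_base <- chartr("ACGU", "UGCA", encoded)
  wobble <- switch(template_base, G = "U", U = "G", NA_character_)
  if (!is.na(wobble)) {
    out[wobble] <- error * wobble_weight
    rest <- setdiff(others, wobble)
    out[rest] <- error * (1 - wobble_weight) / 2
  } else {
    out[others] <- error / 3
  }
  out
}

#' Expected positional error profile of a model
#'
#' The exact collated profile the pipeline should recover from infinitely
#' many noise-free reads: per-template first-triplet marginal base
#' frequencies derived from the model's 64-way distributions, averaged
#' (unweighted) over the three templates encoding each base at each position.
#' Used as ground truth in recovery experiments.
#'
#' @param model An [incorporation_model()].
#' @param design The matching [assay_design()].
#' @return A `positional_profile` tibble (see [collate_positional()]).
#' @export
expected_profile <- function(model, design) {
  stopifnot(inherits(model, "incorporation_model"))
  trips <- colnames(model$prob)
  marg <- tidyr::expand_grid(
    template_id = design$template_id,
    position = 1:3,
    incorporated_base = rna_bases()
  )
  marg$rate <- purrr::pmap_dbl(marg, function(template_id, position, incorporated_base) {
    sum(model$prob[template_id, substr(trips, position, position) == incorporated_base])
  })
  collate_marginals(marg, design)
}

#' Expected fidelity summary of a model
#'
#' @inheritParams expected_profile
#' @param floor Zero-diagonal floor passed to [positional_fidelity()].
#' @return A `fidelity_result` (see [positional_fidelity()]).
#' @export
expected_fidelity <- function(model, design, floor = 1e-12) {
  positional_fidelity(expected_profile(model, design), floor = floor)
}
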