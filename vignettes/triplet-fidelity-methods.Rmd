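---
title: "Models and methods for triplet-based RNA synthesis analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for triplet-based RNA synthesis analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tripletr)
```

## The problem

Triplet polymerase ribozymes copy RNA templates three bases at a time from
pools of trinucleotide triphosphates. Two questions dominate their
characterisation. First, *fidelity*: at each step the ribozyme must select
one cognate substrate out of 64, and misincorporation rates must be measured
per position and per base from deep sequencing of extension products —
against a background of errors introduced by reverse transcription,
amplification and sequencing itself. Second, *substrate behaviour*: triplet
substrates act collectively, cooperatively invading structured templates and
forming triplet:anti-triplet dimers that buffer the free concentrations of
strongly pairing species. This package implements the statistical pipeline
for both question families, together with seeded simulators that provide
known ground truth for every stage.

## The fidelity assay and its pipeline

The assay uses 12 primer/template pairs. Each template encodes the product
context `CCC-XXX-CCC`: extension starts with a fixed `CCC`, the cognate
triplet `XXX` (reverse complement of the template trinucleotide) is the
queried incorporation, and a downstream `CCC` context follows (`UCC` for the
template whose cognate is `ACC`, avoiding a terminal run of Gs). Across the
12 cognates each base occurs exactly three times at each triplet position, so
every (position, base) cell of the collated profile averages exactly three
templates. The true template set of the original assay is not public;
`design_balanced_templates()` generates a synthetic stand-in satisfying the
same balance constraint (and always containing `ACC`, so the `UCC`
special case is exercised), overridable via `assay_design()` or YAML.

Primer-variant tags identify the template of each read. We use 4-nt tags at
pairwise Hamming distance ≥ 2 prepended to a shared primer core; the original
assay states only that upstream primer variations identify templates, so the
tag scheme is a design choice of this package. Primer matching is exact by
default (`max_mismatch = 0`); no tolerance is claimed by the assay
description, and distance-2 tags make single-mismatch matching safe if
enabled.

Classification (`classify_read()`) requires the extension to begin with
`CCC`, trims at the first exact adaptor occurrence, splits the insert into
3-nt frames (dropping a trailing partial frame rather than rounding it), and
*gates* reads to 1–3 complete post-`CCC` triplets — the sequence-level
consequence of excising the +4 to +14 nt gel window. Only the **first**
post-`CCC` triplet is counted (`count_triplets()`); every unassigned read is
tallied by reason, and counts plus discards always equal the input read
count. Reads containing ambiguous bases are discarded and tallied, never
fatal.

### Background correction

The positive-control sample extends each template with only its control
substrate set (cognate + `CCC`, plus `UCC` for the `ACC` template), so any
other triplet observed there is background. With experimental/control
cognate counts `C_x`/`C_p` and error-triplet counts `E_x`/`E_p`,

```
E_r = E_x − E_p · (C_x / C_p)
```

clamped at zero, with all subtracted mass reallocated to the corrected
cognate `C_r` — correction conserves per-template totals exactly, which is
enforced by tests to 1e-12. Control-set triplets are never corrected: their
raw counts are kept, and they remain in the downstream error tally (their
treatment is otherwise unspecified in the assay description; keeping them is
this package's explicit choice, visible in the profile). Corrected counts
are real-valued and never re-rounded. A zero control cognate count is a hard
error naming the template.

### Collation and geometric-mean fidelities

Per template and product position (position 1 = 5' base of the incorporated
triplet, pairing with the 3' base of the template trinucleotide), marginal
incorporated-base frequencies are computed from the corrected counts; the
collated rate for a (position, encoded base) cell is the **unweighted**
arithmetic mean over its three templates. Whether the original analysis
weighted templates by read depth is unstated; unweighted means are used so a
deep template cannot dominate a cell.

Fidelity summaries are geometric means of *fidelities* (1 − error): per-base
fidelity is the profile diagonal, positional fidelity the geometric mean of
the four per-base fidelities, overall fidelity the geometric mean of the
three positional ones. (Some descriptions of this statistic say "geometric
mean of positional errors"; means of fidelities at both levels is the reading
consistent with the printed values, and is what is implemented.) Geometric
means are computed in log space; a zero diagonal entry would be
log-divergent, so zeros are floored at `1 / (total count + 1)` by default
(configurable) — real data never encounters this, but simulated extremes can.

### Segment fidelity

For long synthesised segments sequenced against a known reference,
`filter_segment_reads()` keeps reads with Hamming distance ≤ 9 (the
conventional filter for unrelated amplified products; 6 as robustness check
via the same argument). Length-mismatched reads are excluded as a separate
tally, not gap-aligned — the products are fixed-length and the filter is a
mutation count. `internal_triplet_average()` takes the geometric mean of
per-position fidelities over synthesised positions excluding the final
triplet, which is an error hot-spot (the fidelity-enhancing domain requires a
downstream triplet and cannot act on the last incorporation). The bundled
worked example (`segment_fidelity_example()`) reproduces the published
internal averages for defined, random and low-G substrate pools:

```{r}
ex <- segment_fidelity_example()
sapply(split(ex$fidelity_pct, ex$pool), internal_triplet_average)
```

Excluding only the final triplet (not also the primer-adjacent first one) is
the rule consistent with those printed averages, verified numerically.

## Ligation extents from ladders

A gel lane of an iterative ligation reaction gives one intensity per number
of substrates added, 0..N. The extent of ligation at junction *j* is defined
as the survival ratio `Σ_{k≥j} I_k / Σ_{k≥j−1} I_k` — the fraction of
molecules that reached junction *j* and were ligated through it. No formula
is given in the original description of the "average extent of ligation";
this definition is chosen because it makes the per-junction extents and the
full-length yield mutually consistent: the product of all extents telescopes
*exactly* to `I_N / ΣI`, a property-tested identity. Whether the lane
average is arithmetic or geometric is unstated for some figures, so
`mean_extent()` reports either (geometric by default, matching the
70-junction self-synthesis summary). Junctions that no molecule reached are
flagged `NA` rather than invented.

## Cooperative invasion (Hill fits)

Extension on structured templates switches on steeply with triplet
concentration; the package fits the phenomenological Hill form
`y = fmax·c^n/(K^n + c^n)`. A mechanistic all-or-none m-triplet invasion
model is mathematically the `n = m` Hill case, so it is not implemented
separately. The functional form behind the original sigmoid curve was not
stated; Hill is this package's choice. Fitting is deterministic multi-start
Levenberg–Marquardt (`minpack.lm`): `n` starts at {0.5, 1, 2, 4, 8}, `K` at
the quartiles of the positive concentrations, `fmax` at the maximum response,
bounded to (0, 1.2] to absorb normalisation slack; the best converged start
wins, and the result never exceeds any start's initial residual. At least 4
points spanning a ≥ 4-fold concentration range are required.

## Pool dimerization equilibria

The proposed systems-level fidelity mechanism — dimer formation selectively
buffering free concentrations of strongly pairing, GC-rich triplets — is
described verbally in the literature without equations. The model here is
deliberately minimal:

- only perfect reverse-complement pairs form dimers (no near-cognate
  network). Each triplet has exactly one such partner and none is its own
  (impossible at odd length), so the 64 triplets split into 32 independent
  pairs, each solved in closed form by the mass-action quadratic
  (`pair_free_concentration()`, cross-checked against a bisection oracle to
  1e-9);
- duplex stability is composition-based:
  `ΔG = g_init + n_GC·g_GC + n_AU·g_AU`, `Kd = exp(ΔG/RT)`. Defaults
  `g_GC = −2.0`, `g_AU = −0.5`, `g_init = +3.5` kcal/mol at `T = 266 K`
  (the −7 °C eutectic phase) are illustrative composition parameters,
  not fitted thermodynamics, and are all overridable;
- error modulation assumes misincorporation odds proportional to the ratio of
  free mispair to free cognate concentration
  (`predicted_error_modulation()`).

These choices support *direction-level* predictions only: free fractions are
non-increasing in GC content, adding complementary triplets is predicted to
reduce a GC-rich mispair's contest ratio, and raising equimolar pool
concentrations is predicted to reduce GC-rich error ratios. The published
magnitudes of such reductions (and the published overall fidelities and
ligation-extent averages) are measurements on real sequencing and gel data
and are validated here in direction only. Eutectic-phase solute
concentration (~4–5 fold) is not modelled; all concentrations are
operational.

## The simulators and what they do (not) emulate

Every pipeline input has a seeded, bit-reproducible generator:
`gen_fidelity_reads()` / `gen_control_reads()` (assay reads with a known
64-way misincorporation model, 1–3 triplet additions, i.i.d. per-base
substitution noise, constant `I` qualities), `gen_segment_reads()`
(per-position substitution rates), `gen_ladder()` (survival-product band
intensities with multiplicative noise) and `gen_dose_response()`. Reads are
generated in product-strand sense 5'→3'. The default incorporation model
assembles each template's 64-way distribution from independent per-position
base errors (defaults 3.5/2.0/1.2% at positions 1–3, i.e. a mild 5'→3'
accuracy gradient and ~97.8% overall fidelity, in the range reported for
accurate triplet polymerases), with 60% of each position's error mass on the
G:U wobble partner where one exists — wobble pairing being the dominant
misincorporation mode. One global RNG stream is seeded per call
(`withr::with_seed`), so generators never perturb the session RNG.

Deliberately not modelled: indels, PCR amplification bias, quality-score
structure, paired-end reads, primer-template assortment, and the off-target
priming contaminants seen in real segment libraries. Passing recovery tests
therefore demonstrates correctness of the counting, correction and collation
arithmetic under substitution-type noise — not robustness to every artefact
of real libraries.

## Numerical and design choices

- Geometric means in log space; configurable zero floors as above.
- Correction clamps at zero per error triplet; reallocation preserves totals
  to machine precision.
- Gating drops a dangling single base rather than rounding it to a triplet.
- The equilibrium quadratic is evaluated in its cancellation-free form
  (`2ab / (s + sqrt(s² − 4ab))`), exact in the `Kd → ∞` and absent-partner
  limits.
- Problem sizes used by the test-suite recovery experiments: 1.2 × 10⁶ reads
  for the headline recovery (positional fidelities recovered well within 0.3
  percentage points), 20 replicates of 6 × 10⁴ reads for the
  corrected-vs-raw comparison under 0.5% control noise, 100 seeds for Hill
  recovery, 1000 random ladders/pairs for the exact identities.

## Limitations

The collation assumes the balanced 12-template design; unbalanced designs
are a hard error rather than a reweighted estimate. Background correction
assumes control and experimental samples share the same per-read error
process and sufficient control depth (`C_p > 0` enforced). The dimerization
model ignores near-cognate (mismatched) dimers and sequence-dependent
nearest-neighbour stacking, so its quantitative outputs should be read as
qualitative structure, not binding predictions.
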