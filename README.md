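# tripletr

Fidelity and substrate-pool analysis for RNA-catalysed RNA synthesis from
trinucleotide triphosphate ("triplet") substrates.

Triplet polymerase ribozymes extend a primer on an RNA template three bases at
a time, selecting one of 64 possible triplets at each step. `tripletr` is a
toolkit for the quantitative questions that arise when characterising such a
ribozyme from deep sequencing and gel data:

- **Fidelity profiling.** Reads of primer-extension products carried out on a
  panel of 12 templates (product context `CCC-XXX-CCC`, each base encoded
  three times at each triplet position) are demultiplexed by primer-variant
  tags, and the first triplet incorporated after the leading `CCC` is counted
  per template. A positive-control sample — each template extended with only
  its cognate triplet and the `CCC` context substrate — measures the
  background of apparent errors from amplification and sequencing, which is
  subtracted with the depth-scaled correction

  `E_r = E_x − E_p · (C_x / C_p)`

  (clamped at zero, all subtracted counts reallocated to the corrected
  cognate count `C_r`, so per-template totals are conserved exactly).
  Corrected counts are collated into a position × encoded-base × incorporated
  base error profile (unweighted means over the three templates per base),
  and summarised as geometric-mean fidelities: per-base → positional →
  overall.

- **Segment fidelity.** For long synthesised segments sequenced against a
  known reference: a Hamming mutation filter (default: exclude reads with >9
  mutations), per-position base fidelities, and the geometric average over
  internal triplet positions (excluding the primer and the error-hot-spot
  final triplet).

- **Ligation extents.** Band-intensity ladders of extension products are
  converted to per-junction ligation extents via survival ratios
  `extent_j = Σ_{k≥j} I_k / Σ_{k≥j−1} I_k`, whose product telescopes exactly
  to the full-length yield `I_N / ΣI`; geometric or arithmetic lane averages.

- **Cooperative invasion.** Hill fits
  `y = fmax · c^n / (K^n + c^n)` to extension dose-response data, capturing
  the steep sigmoidal concentration dependence of triplet-mediated unfolding
  of structured templates (deterministic multi-start Levenberg–Marquardt).

- **Pool dimerization equilibria.** A mass-action model of
  triplet:anti-triplet dimer formation in substrate pools: the 64 triplets
  form 32 independent perfect-complement pairs, each solved in closed form
  with a composition-based duplex Kd (`ΔG = g_init + n_GC·g_GC + n_AU·g_AU`,
  `Kd = exp(ΔG/RT)`). GC-rich triplets are buffered to lower free
  concentrations, predicting the direction of the observed mispair-error
  reductions when complementary triplets are present.

Every input has a seeded simulator with known ground truth (reads,
positive controls, segment reads, ladders, dose-response tables), so the full
pipeline is testable without any external data.

## Worked example

```r
library(tripletr)

design <- design_balanced_templates(seed = 0)
model  <- incorporation_model(design)   # ground-truth misincorporation model

res <- run_fidelity_pipeline(design, model, n_reads = 12e5, seed = 2024)
res$fidelity
#> Triplet polymerase fidelity (geometric means)
#>   overall: 97.77%
#>   position 1: 96.52%
#>   position 2: 98.00%
#>   position 3: 98.80%
```

The overall fidelity is the geometric mean of the three positional
fidelities, each of which is the geometric mean of that position's four
per-base fidelities (the diagonal of the collated error profile). Here the
pipeline recovers the generator's true fidelities (96.50 / 98.00 / 98.80%,
overall 97.76%) to within ~0.02 percentage points from 1.2 million reads.

Published per-position fidelities of a ribozyme-synthesised segment are
bundled as a worked example:

```r
ex <- segment_fidelity_example()
sapply(split(ex$fidelity_pct, ex$pool), internal_triplet_average)
#>  defined    low_g   random
#> 98.78035 98.56283 96.65761
```

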