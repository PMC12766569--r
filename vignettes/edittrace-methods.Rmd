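---
title: "Models and methods behind edittrace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind edittrace}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(edittrace)
```

This vignette documents the models implemented in edittrace, the
parameters that matter, the numerical conventions adopted where a design
choice was genuinely open, and what the synthetic generators do and do not
emulate. Nothing here states an empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The recording model

A lineage-tracing cassette carries an integration barcode (intBC) and a
small number of edit sites. Each site starts **unedited** and, while
editing is active, irreversibly acquires one of `S` lineage marks (LMs),
drawn from an installation distribution. Site states are inherited by
both daughters at division. The observable is a cells × sites character
matrix over {unedited, LM 1..S, missing}; missingness is a readout
artifact (a cassette not captured or an amplicon not decoded), never a
biological state.

Two laws govern the design calculators:

* **Saturation.** A site editing independently with per-day probability
  `R` is still unedited after `T` days with probability `(1-R)^T`, so the
  population edit fraction is `F = 1-(1-R)^T`.
  `edit_rate_for_target_fraction()` inverts this exactly.
* **Division marking.** Under the simplified design framework (one
  division per day, no death, site depletion), the number of unedited
  sites entering division `t` is Binomial(`M`, `(1-R)^(t-1)`), so the
  probability that division `t` is marked by at least one new edit is
  `1 - (1 - (1-R)^(t-1) R)^M` (`expected_marked_fraction()`). The marked
  fraction is maximized at an intermediate rate: editing too fast
  exhausts sites before late divisions, too slow misses early ones.

`min_edit_sites_for_marked_fraction()` runs the literal stochastic scan
(100 modeled lineages, rate grid 0–0.3 by 0.001, 10 repetitions, best
rate per site count) and uses the closed form only to prune site counts
and rates that sit more than `prune_margin = 0.01` — several Monte-Carlo
standard errors — below the target; pruned cells cannot alter the
reported minimum.

## Birth-death simulation

`simulate_birth_death()` grows a single founder: division waiting times
are log-normal and a competing exponential death clock at
`death_rate = 0.25`/day kills a cell whose death draw precedes its
division draw. Two statements in the model description required a
convention:

* *"log-normal (mean = 1, sigma = 0.5)"* — we read `sigma = 0.5` as the
  log-scale shape parameter and set the log-scale mean to `-sigma²/2` so
  the natural-scale mean lifetime is exactly 1 day. The alternative
  (log-scale mean 1) would give a mean lifetime of e^1.125 ≈ 3 days,
  inconsistent with "one division per day".
* *"death rate 0.25"* — implemented as a rate per lineage per day in a
  competing-risk race, the simplest reading consistent with a
  birth-death process (not a per-division death probability).

The process stops when the number of living lineages reaches `N`; the
population is observed *just before its next event*, so extant cells have
strictly positive ages and all tips are contemporaneous. Extinct subtrees
are pruned and pass-through nodes suppressed. Extinction is surfaced as a
condition rather than silently retried; `max_retries` re-runs with seeds
derived deterministically from the caller's seed, keeping composite
pipelines bit-reproducible (`derive_seed()` gives every component its own
stream).

Mark overlay uses the continuous form: an unedited site edits along a
branch of duration `t` with probability `1-(1-R)^t`, including the
founder's own lifetime (`root.edge`) — recording is active from
induction, so marks installed before the first division are shared by
every cell. Detection dropout replaces each matrix entry independently
with missing at probability `1-D`, which leaves conditional mark
frequencies among detected entries unbiased.

Mark-installation skew is parameterized by normalized entropy: mark `i`
has probability proportional to `exp(-λ i)`, and
`lm_distribution_for_entropy()` finds λ by bisection (entropy is strictly
decreasing in λ) to a 1e-3 entropy tolerance; a target of 1 returns the
exact uniform.

## Distances and tree reconstruction

The weighted Hamming distance compares two cells site by site: cost 0 on
a match or when either state is missing, 1 when exactly one cell is
unedited, 2 when both carry different marks, summed and divided by the
number `L` of co-detected sites. The 1/2 asymmetry is the established
convention for irreversible recorders: two different installed marks
witness two independent editing events, while unedited-vs-mark may
reflect a single event. Optional per-site weights multiply the cost and
contribute their weight to `L`. Pairs with `L = 0` cannot be compared;
rather than abort a 200-cell reconstruction for one pathological pair,
they receive the maximum finite distance plus one and are reported in an
attribute.

Neighbor joining (via ape) runs on the matrix augmented with a synthetic
all-unedited cell; the tree is rooted on that outgroup — the experiment
demonstrably started from an unedited founder — and the outgroup removed.
Negative NJ edge lengths are clipped at zero; topology, not edge length,
is the deliverable here (durations come from `estimate_branch_lengths()`).
UPGMA is average-linkage `hclust`. The greedy splitter recursively picks
a (site, mark) pair, splits on mark presence, sends missing cells with
the larger side, and emits a multifurcation when no informative mark
remains. The default picks the *most* frequent informative mark; a flag
inverts to least-frequent. With only ~8 marks per site the greedy
approach suffers badly from homoplasy (independent installations of the
same mark), and the test suite reproduces this directionally against NJ.

## Evaluation metrics

*Normalized RF* counts nontrivial bipartitions unique to either tree
(compared as unrooted) over the total number of nontrivial bipartitions
in both — the maximum attainable symmetric difference — so multifurcating
trees normalize sensibly and the value sits in [0, 1].

*Depth-normalized triplets correct* samples leaf triplets evenly across
the occupied depths of their truth-tree LCA (plain uniform sampling is
dominated by near-root triplets, which are easy). Per stratum it samples
without replacement when possible, with replacement otherwise; per-depth
quotas differ by at most one. A triplet is correct when the out-taxon
agrees; under multifurcations, "both unresolved" counts correct and
"resolved in exactly one tree" incorrect (strict agreement). Exhaustive
enumeration replaces sampling for small trees.

*FMI* between a barcode group and a clade is `√(precision · recall)` on
the overlap; `best_lca_clade()` scans every internal node and breaks
ties toward the deepest node, then the smallest clade (determinism; note
a two-cell group in a balanced tree ties the root with small cherries at
the same FMI, and the deep tie-break picks the cherry).

## Ancestral inference and timing

`sankoff_ancestral_states()` minimizes total transition cost per site by
dynamic programming over {unedited, LM 1..S} with the asymmetric cost
table: identity 0, installation (unedited→LM) 0.6, anything else 1.
Installation must be cheaper than reversal — editing is irreversible, so
apparent reversals are readout noise — but expensive enough that a
spurious shared mark does not get hoisted to the root. The root is
constrained to all-unedited (the day-0 state), missing leaves cost zero
in every state, and backtrace ties resolve toward unedited then the
lowest mark index. An exhaustive-enumeration oracle verifies the DP on
all small instances in the test suite.

Edges whose endpoints share identical state vectors carry no recorded
information; `collapse_unsupported_branches()` removes them
(deepest-first, children reattached to the grandparent), yielding
multifurcations exactly where divisions went unmarked. Leaves are never
collapsed.

Branch durations then follow from constant-rate editing: an edge whose
parent has `u` unedited sites of which `k` edit along the edge has
maximum-likelihood duration `-log(1 - k/u)/R`, guarded by
`ε = 1/(2u)` at full saturation; `k = 0` edges get duration 0 (no
evidence of elapsed time) and zero-exposure edges the minimum positive
duration. The tree is rescaled so the **mean** root-to-leaf path equals
the known tracing duration — the mean is robust to a single noisy deep
lineage, where the maximum is not. `lca_timing()` reads the inferred age
of a barcode group's best clade off this tree; `extant_counts()` cuts the
tree at a time `t` and counts branches spanning it (before the first
division the count is defined as 1, the founding lineage).

## Sequencing QC and clone calling

Count thresholds adapt per dataset: `gmm_threshold()` fits a
two-component Gaussian mixture to log counts (counts are heavy-tailed;
the scale was an open choice) and removes the lower-mean component. A
forced two-component fit of *unimodal* data happily splits it in half, so
the degeneracy guard is a bimodality criterion — Ashman's
`D = |μ₁-μ₂| / √((σ₁²+σ₂²)/2) ≥ 2` — rather than mere mean inequality;
unimodal fits land near 1.3, genuinely bimodal count data far above 2.
When the unequal-variance model collapses on a point mass of tied low
counts, a pooled-variance fit takes over. Filtering runs on reads per
record capture-wide (PCR/sequencing errors), then on UMIs per record
within each intBC (ambient RNA, whose support scales with expression).

Allele conflicts within (cell, intBC) resolve by edit state: when exactly
two alleles differ at a single site with one unedited there, the edited
allele wins if it holds >20% of UMIs (RNA turnover delays newly installed
marks); otherwise the max-UMI allele (ties lexicographic). Duplicate
integrations (same intBC twice in one clone) are detected **before**
conflict resolution — resolution collapses the very conflicts that reveal
them — and dropped clone-wide when >25% of UMIs sit in multi-allele
cells. Cells whose conflicted-intBC UMI fraction exceeds 25% (sequencing)
or 50% (imaging) are doublets. All thresholds are strict, matching their
definitions.

`call_clones()` factorizes the cell × intBC UMI matrix by NMF
(Frobenius objective, multiplicative updates, NNDSVD initialization —
deterministic, so clone calls are invariant to row order and count
scaling) or by spectral clustering of binarized detections (for imaging
data, where doublets are rare). Clone intBC sets are the intBCs detected
in >50% of a clone's cells; cells are re-assigned by Jaccard similarity
against every single clone and every pairwise union — union winners are
doublets, best similarity <0.5 unassigned. The number of clones is a
required analyst-supplied parameter. The greedy static-barcode grouping
iterates seed (most-detected barcode among unassigned cells, ties
lexicographic), cluster (co-detected in >80% of seed cells), assign
(cluster holds >80% of a cell's barcode UMIs), validate (≥5 cells),
and terminates after at most one iteration per distinct barcode.

## Kinetics

`fit_saturating_exponential()` fits `f(t) = s(1 - e^{-rt})` by bounded
nonlinear least squares (`minpack.lm`), `s ∈ [0.8, 1]`, `r ∈ [1e-4, 0.6]`,
with three starts across the rate range (the objective is nearly flat in
the small-`r` corner) and timepoints under 20 cells dropped. A day-0
anchor `f(0) = 0` is added when absent — editing starts at induction.
Fits are unweighted by default; a flag weights residuals by cell count
(the source analysis does not state a weighting).

## Imaging decoding

intBC codebooks are constant-weight binary codes (21 bits, weight 6,
minimum pairwise Hamming distance 4, so single-bit errors are
correctable). `build_codebook()` constructs one greedily over the
lexicographic candidate list — a deterministic construction with the same
validated contract as design-theoretic constructions; externally supplied
codebooks load through `read_codebook()` and are checked by
`validate_codebook()`, which reports every violation.

`em_decode_intbc()` alternates normalization and nearest-codeword
assignment: color balancing once before the loop (per-channel mean
equalization given a bit→channel map, else per-bit), correction
`X / (s ⊗ b)` with the spot intensity `s` initialized at the 95th row
percentile and bit intensity `b` at the 95th column percentile, the
per-bit noise-floor adjustment `(X - 1/snr)/(1 - 1/snr)` clipped to
[0, 1], Euclidean nearest-codeword assignment, masking at distance ≥1.7
(≥2 with an intBC whitelist), and M-step updates of `s` from all spots
but `b` and the SNR only from unmasked ("confidently assigned") spots.
SNR estimates are floored at 1.05 to keep the correction finite. Ten
iterations; the mean assigned distance is monitored and, while the
update is heuristic rather than provably monotone, the suite asserts the
final value never exceeds the initial one. Decoding is invariant to
global intensity rescaling.

Lineage marks read out over `S+1` bits per site; rows are normalized to
sum to one and either argmax-decoded or classified by per-site
multinomial logistic regression (`nnet`, weight decay 1.0) trained on
spots with known truth; calls with probability <0.7 are flagged
low-confidence. Imaging QC applies five rules in order: mean assignment
probability ≥0.7 across sites; brightest spot per identical
(intBC, mark-set) duplicate detection; duplicate-integration removal at
>40% conflicted cells per clone; >50%-conflict segmentation-doublet
removal; and conflict resolution preferring in-mask, then brightest.

## Spatial-lineage statistics

Neighbor graphs are binary and symmetric: phylogenetic neighbors share an
LCA within the last 10 days (both cells), spatial neighbors sit within
100 μm in x-y on the same section. Moran's I on z-scored values follows
`I = N/Σw · Σ w_ij x_i x_j / Σ x_i²`; significance comes from value
permutations (one-sided, `(1 + #{I* ≥ I}) / (1 + n_perm)` so p is never
zero) with Benjamini-Hochberg adjustment across the submitted feature
batch. Local LM diversity is the mean pairwise weighted-Hamming distance
within a 100 μm neighborhood (focal cell included — the definition does
not say, so it is a documented, parameterized choice). The
tree-independent fitness proxy is the mean distance to a cell's 20
nearest neighbors *in mark space* (fitter cells expanded recently and
had less time to diverge); ties at the k-th rank break by cell id.
Pairwise distance tables sample up to 20,000 same-section pairs without
replacement and emit phylogenetic (path length through the LCA, days),
mark, spatial, and shuffled-position control distances. Analyses are
2-D per section throughout.

## Synthetic generators, and what passing tests show

Every input class has a seeded generator: `synth_umi_table()` (clones
with disjoint intBC sets, Poisson UMI depths, low-count PCR-error
alleles, 1-UMI ambient records, merged doublet profiles, optional
duplicate integrations, two-round static barcodes) and
`synth_spot_intensities()` (log-normal spot brightness × uniform per-bit
efficiency on "1" bits, background at the configured SNR on "0" bits,
additive noise, optional cross-hybridization bleed). The generators
implement the same structural assumptions the corresponding estimators
make. Passing tests therefore demonstrate *correctness of the
implementations under their stated models* and calibrated behavior on
data resembling published summaries — not performance on real captures,
which add batch structure, expression-correlated dropout, chimeric PCR
artifacts, and optical crowding that these generators deliberately omit.

## Problem sizes and determinism

The test suite runs simulations at 20–200 cells with 10–20 seeds per
stochastic property, 2,000–5,000 spots for decoding, and 480-cell UMI
fixtures — sizes chosen so the full suite documents every contract in a
few minutes while leaving Monte-Carlo margins of several standard errors
on each asserted bound. All randomness flows from explicit integer
seeds through `derive_seed()`, so every table, tree, and matrix in the
package — and the acceptance script's outputs — are bit-reproducible.

## Known limitations

* Branch-length estimation assumes a single constant edit rate shared by
  all sites; per-site kinetic variation biases durations on edges where
  fast sites dominate the unedited pool.
* The greedy reconstruction is provided for comparison; with few marks
  per site it is not competitive and is not used downstream.
* Clone-count selection is manual by design; no automatic model-order
  criterion is shipped.
* The EM decoder's M-step is heuristic (monitored, not guaranteed
  monotone), matching its published usage.
* Spatial statistics ignore z; sections are treated as independent
  planes.
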