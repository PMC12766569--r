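# edittrace

Tools for evolving lineage tracing with irreversible edit marks: simulate
recording experiments on birth-death phylogenies, reconstruct and evaluate
single-cell trees from categorical character matrices, infer ancestral
states and branch lengths, quality-control sequencing readouts and call
clones, decode imaging-based barcode intensities, and compute joint
spatial-lineage statistics.

## The problem

Evolving lineage recorders write cell ancestry into the genome: an
expressed cassette carries an integration barcode (intBC) identifying the
insertion plus a handful of edit sites, each of which starts *unedited*
and stochastically, irreversibly acquires one of `S` predefined lineage
marks (LMs). Reading the cassettes out — by scRNA-seq or by multiplexed
FISH imaging — yields a cells × edit-sites **character matrix** over the
alphabet {unedited, LM 1..S, missing}, from which a phylogeny of the
sampled cells can be reconstructed. The package covers the full
computational stack around such recorders:

| stage | functions |
|---|---|
| simulation | `simulate_birth_death`, `overlay_lineage_marks`, `apply_detection_dropout`, `plant_barcode_groups` |
| recorder design | `edit_rate_for_target_fraction`, `saturation_rate_table`, `min_edit_sites_for_marked_fraction`, `lm_distribution_for_entropy` |
| reconstruction | `weighted_hamming_matrix`, `reconstruct_nj`, `reconstruct_upgma`, `reconstruct_greedy` |
| evaluation | `normalized_rf`, `depth_normalized_triplets_correct`, `fmi`, `best_lca_clade`, `downsampling_sweep` |
| ancestral inference | `sankoff_ancestral_states`, `collapse_unsupported_branches`, `estimate_branch_lengths`, `lca_timing`, `extant_counts` |
| sequencing QC / clones | `gmm_threshold`, `resolve_conflicting_alleles`, `filter_duplicate_intbcs`, `filter_conflict_doublets`, `call_clones`, `call_barcode_groups` |
| kinetics | `per_cell_edit_fraction`, `fit_saturating_exponential` |
| imaging decoding | `build_codebook`, `em_decode_intbc`, `decode_lm`, `imaging_lm_qc` |
| spatial statistics | `build_neighbor_graph`, `morans_i`, `local_lm_diversity`, `mean_neighbor_lm_distance`, `pairwise_distance_table` |

Key quantities, in the field's notation: cells are compared with a
weighted Hamming distance `d(i,j) = Σ_m δ(C_im, C_jm) / L` (δ = 0 on a
match or missing entry, 1 when exactly one state is unedited, 2 when two
different marks disagree; `L` = co-detected sites). Editing follows the
saturation law `F = 1 − (1 − R)^T` for per-day rate `R` over `T` days.
Mark balance is summarized by the normalized entropy
`H_norm = −Σ p_i log p_i / log S`. Clade–barcode agreement uses the
Fowlkes–Mallows index `FMI = √(TP/(TP+FP) · TP/(TP+FN))`, and heritability
and spatial coherence use Moran's
`I = N/Σw · Σ w_ij x_i x_j / Σ x_i²` on a recent-ancestor or spatial
radius graph.

## Worked example

Simulate a 50-cell recording experiment (8 uniform marks, 40 edit sites,
70% target saturation, 80% detection), reconstruct the tree, and score it:

```r
library(edittrace)

tree  <- simulate_birth_death(50, seed = 3, max_retries = 10)
probs <- lm_distribution_for_entropy(8, target_hnorm = 1)
ov    <- overlay_lineage_marks(tree, n_sites = 40, lm_probs = probs,
                               target_fraction = 0.7, seed = 2)
cm    <- apply_detection_dropout(ov$cm, detection = 0.8, seed = 5)

recon <- reconstruct_nj(cm)
normalized_rf(tree, recon)
#> [1] 0.2978723
depth_normalized_triplets_correct(tree, recon, seed = 1)
#> [1] 0.886
```

A normalized Robinson–Foulds distance of 0.30 means 70% of the
nontrivial bipartitions were recovered exactly despite 20% dropout, and
89% of depth-stratified leaf triplets keep their true orientation (RF
penalizes every slight clade rearrangement, so it reads much more
pessimistically than triplet accuracy). Barcode groups planted halfway
through the experiment are recovered perfectly as clades:

```r
groups <- plant_barcode_groups(tree, at_time = 0.5 * max(ape::node.depth.edgelength(tree)))
mean(sapply(groups, function(g) best_lca_clade(recon, g)$fmi))
#> [1] 1
```

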