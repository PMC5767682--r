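# condock

Consensus small-molecule docking analysis for pentameric ligand-gated ion
channels — and for any docking campaign where two engines, several scoring
functions, and a chemical series have to be reconciled into one answer
about where a ligand binds.

`condock` is aimed at structural bioinformaticians studying allosteric
modulators (e.g. type II positive allosteric modulators of the α7
nicotinic acetylcholine receptor) in transmembrane cavities. Docking
engines are run elsewhere; this package does everything around them:

* **Symmetry-corrected pose RMSD.** The element-constrained
  Hungarian-assignment RMSD, computed in the fixed receptor frame with no
  superposition:
  `RMSD(A,B) = min over element-respecting permutations π of
  sqrt(mean_i ||a_i − b_π(i)||²)`.
  A flipped aromatic ring relabels equivalent atoms but occupies the same
  space; the optimal assignment sees through the relabelling while an
  index-paired RMSD does not.
* **Two-engine agreement filtering** at a 2.0 Å threshold, refined
  search-region derivation (sphere and box dialects), and prioritized
  flexible side-chain selection (mutated → polar → even spatial spread).
* **Borda rank aggregation** of heterogeneous scoring metrics
  (points = Σ over metrics of the number of items ranked below).
* **Hierarchical RMSD clustering** of top-ranked poses across a chemical
  series; the most populated clusters are the consensus binding modes.
* **Interaction reports**: minimal ligand–residue distances, geometric
  hydrogen bonds, pocket residue lists with (+)/(−) interface sides.
* **Model-assessment scores** for density-fitted models: simulated maps,
  segment-based cross-correlation, segment-based Manders' overlap, loop
  ranking, register-shift alignment correction, and region-restricted
  percent identity. Includes a minimal MRC2014 map reader/writer.
* **A deterministic fixture generator** (two-engine ensembles with
  planted binding modes, planted score tables, toy receptors, planted
  density) so the whole pipeline is testable end to end with no
  downloads.

## Worked example

A synthetic two-engine campaign with two planted binding modes, 50 + 20
poses, 0.3 Å coordinate noise and 30 % decoys:

```r
library(condock)

lig <- make_symmetric_ligand(6, 1.4, marker = TRUE)
ens <- make_pose_ensemble(lig, n_modes = 2, poses_per_engine = c(50, 20),
                          noise_sd = 0.3, decoy_fraction = 0.3, seed = 7)

pairs <- match_poses(ens$set_a, ens$set_b, threshold = 2.0)
nrow(pairs)
#> [1] 245
head(pairs[c("ligand_id", "idx_a", "idx_b", "rmsd")], 3)
#> # A tibble: 3 × 4
#>   ligand_id idx_a idx_b  rmsd
#>   <chr>     <int> <int> <dbl>
#> 1 LIG1         34     6 0.483
#> 2 LIG1         17     3 0.508
#> 3 LIG1         12    10 0.522
```

245 of the 1000 cross-engine pairs agree within 2 Å — exactly the
intra-mode pairs (the noise puts them near 0.3·√6 ≈ 0.73 Å), while every
decoy pose fails the filter. Borda-rank the agreements over the three
scoring metrics, remove redundant pairs, and cluster:

```r
scores <- make_score_table(ens, seed = 7)
ranked <- borda_rank(attach_pair_scores(pairs, scores, "engine_A",
                                        "engine_B", metric_specs()))
dedup  <- deduplicate_pairs(ranked,
                            order = order(ranked$final_rank, na.last = NA))
cl <- cluster_poses(dplyr::tibble(ligand_id = dedup$ligand_id,
                                  engine = "engine_A",
                                  pose_index = dedup$idx_a,
                                  atoms = dedup$atoms_a,
                                  final_rank = dedup$final_rank))
cl
#> <pose clusters> 2 poses in 2 cluster(s); populations: 1, 1
```

Redundancy removal at the protocol's 2 Å radius collapses each planted
mode to its single best-ranked representative, and clustering finds
exactly the two planted modes with zero decoy members. (Across a
multi-compound series the same call yields multi-member clusters whose
populations rank the candidate binding sites — see `run_pipeline()`.)

The refined second-stage search region grown from the consensus subset:

```r
derive_region(pairs, pad = 2)
#> <search region> center (1.70, -7.08, -1.99) A; sphere r = 27.18 A; box 45.68 x 14.23 x 35.74 A
```

And the symmetry correction itself, on a hexagonal ring rotated by its
own symmetry angle:

```r
hex <- make_symmetric_ligand(6, 1.4)
naive_rmsd(hex, rot60(hex))      # index-paired: the 60° chord, r = 1.4
#> [1] 1.4
hungarian_rmsd(hex, rot60(hex))  # assignment-corrected
#> [1] 0
```

(`rot60` above is any 60° rotation about the ring axis, e.g. via
`dplyr::mutate` on the coordinate columns.)

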