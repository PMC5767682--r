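---
title: "Consensus docking analysis: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus docking analysis: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(condock)
```

# The problem

Allosteric modulators of pentameric ligand-gated ion channels — the
nicotinic acetylcholine receptor family in particular — are thought to bind
in cavities between and within the transmembrane helix bundles, far from
the orthosteric agonist site. Docking a single compound with a single
engine into a comparative model of such a receptor produces many plausible
poses and little basis to choose among them. `condock` implements a
*consensus* protocol that filters poses by cross-engine agreement, narrows
the search volume, aggregates heterogeneous scoring functions, and reads
binding modes off clusters that recur across a chemically related series
of compounds. It also provides the model-assessment side of such a study:
segment-based density-fit scores for cryo-EM-refined models, and the
register-shift alignment correction needed when a template structure has a
mis-traced helix turn.

# The pose-agreement metric

Everything in the protocol runs on one distance: the **element-constrained
Hungarian-assignment RMSD** between two poses, computed in the fixed
receptor frame with *no superposition*. For poses $A$ and $B$ with heavy
atoms $a_i$, $b_j$,

$$\mathrm{RMSD}(A,B) \;=\; \min_{\pi}
\sqrt{\tfrac{1}{N}\sum_{i=1}^{N} \lVert a_i - b_{\pi(i)}\rVert^2},$$

where $\pi$ ranges over permutations mapping each atom to one of the same
chemical element. The assignment corrects for topological symmetry — a
flipped phenyl ring relabels equivalent carbons but occupies the same
space — which an index-paired ("naive") RMSD misreads as a large
displacement. The minimization is solved exactly by a shortest
augmenting path assignment solver, applied independently within each
element class (block-diagonal solving is exactly equivalent to a full
matrix with infinite cross-element costs, and much cheaper).

Choices worth stating:

* **No superposition.** The question the 2 Å filter answers is "did both
  engines put the ligand in the same place in the receptor", not "are the
  conformers similar". Superposing first would erase exactly the
  information being tested, and the search-region derivation (which takes
  the positions of all consensus atoms) only makes sense in the shared
  frame.
* **Heavy atoms only, by default.** Engines differ in whether and where
  they write hydrogens; heavy-atom positions carry the placement signal.
* **Relaxed (cross-ligand) mode.** Clustering runs across a chemical
  series, so molecules differ in size. The relaxed mode matches every
  heavy atom of the smaller molecule to a distinct atom of the larger,
  ignoring element, and normalizes by the matched-atom count. This is a
  pragmatic definition — the protocol needs "do these two compounds sit in
  the same place", not a chemically exact correspondence.
* **Ties.** Equal-cost assignments can differ as permutations, but the
  minimized RMSD value is unique, which is all the pipeline consumes.

# The consensus protocol

For each compound, two engines dock into a generous first-stage region:
a *sphere of 18 Å radius* and a *cube of 32 Å edge*, both centered on the
γ-carbon of the anchor threonine at the top of the pore-facing helix
(`seed_region()`). The first engine keeps 50 diverse solutions, the
second 20 — these are the defaults the fixture generator reproduces.

1. **Match** (`match_poses()`): every cross-engine pair of poses at
   Hungarian RMSD ≤ 2.0 Å is an agreement. Pairs are sorted by RMSD.
2. **Rank** (`borda_rank()`): matched pairs are ranked by the Borda count
   over three metrics — the second engine's energy-like score (lower
   better) and the first engine's two fitness scores (higher better),
   each metric read from its native engine's pose of the pair. An item's
   Borda points are $\sum_m (n - r_m)$, the number of items it beats,
   summed over metrics; only the relative order matters downstream, so
   the point convention is immaterial as long as it is fixed. Ties
   within a metric take fractional (mean) ranks, which keeps the result
   independent of input order; final ties break by the first metric's
   value and then input order.
3. **Deduplicate** (`deduplicate_pairs()`): walking pairs from best to
   worst Borda rank, a pair is kept only if its engine-A pose is more
   than 2.0 Å from every already-kept engine-A pose, stopping at 20
   pairs. The redundancy criterion is not fully specified in the source
   protocol; greedy best-rank-first at the same 2.0 Å radius as matching
   was chosen so the whole pipeline works on a single distance scale.
4. **Carry forward** (`top_k()`): the top 5 per compound.
5. **Cluster** (`cluster_poses()`, `consensus_modes()`): engine-A members
   of the carried-forward pairs of all compounds in a chemical class are
   clustered agglomeratively on the pairwise RMSD matrix (complete
   linkage, cut at 2.0 Å — the linkage and cutoff are this package's
   choices, exposed as parameters, since the source protocol states
   neither). Clusters with population ≥ 2 are consensus binding modes,
   ordered by population then mean Borda rank; the most populated one is
   read as the most probable binding site. Cluster representatives are
   the best-Borda-ranked member, ties going to the member with the
   lowest mean RMSD to its cluster.

The refined second-stage search region (`derive_region()`) is grown from
the centroid of all heavy atoms of all matched poses: sphere radius = the
maximum atom distance from the centroid, box edges = twice the per-axis
maximum deviation, plus optional padding. Zero extents (a single
consensus atom) are floored at 1 Å per dimension with a warning because
docking engines reject zero volumes.

**Flexible side chains** (`select_flexible_residues()`): ten residues
whose side chains reach into the region, picked in priority tiers —
(1) residues mutated in the accompanying mutagenesis work, (2) polar
residues, (3) the rest. Within tiers 2–3 residues are chosen by greedy
farthest-point sampling on side-chain centroids, a deterministic
operationalization of "spread flexibility evenly over the pocket";
ties break by `(chain, resno)`. The polar set
(S, T, Y, C, N, Q, H, K, R, D, E) is configurable.

# Interaction reports

`min_distance()` reports the minimum heavy-atom distance between a ligand
selection and a residue side chain — published "~X Å from residue"
figures rarely state their convention, so a centroid–centroid mode is
also provided and `contact_report()` prints both. Hydrogen bonds use the
standard geometric criteria (donor–acceptor N/O distance ≤ 3.5 Å; when
explicit hydrogens exist, D–H···A angle ≥ 120°); heavy-atom-only inputs
degrade to distance-only detection and the report says so. Pocket
residues are those with any side-chain heavy atom within 4.5 Å of the
ligand; the chain burying the larger contact share is labelled the
principal (+) interface side.

# Density-fit assessment

`simulate_map()` renders a model as a sum of spherical Gaussians,
amplitude proportional to atomic number. The width convention matters:
by default σ = resolution / (2√(2 ln 2)) (resolution read as the FWHM of
the point-spread function), with the historical resolution/π convention
selectable — published segment scores depend on which convention the
original fitting tool used, so reproducing a printed value to the last
digit may require matching it. The segment-based cross-correlation
(`segment_ccc()`) is the Pearson correlation between experimental and
simulated map over voxels within 3 Å of the segment's atoms; the
segment-based Manders' overlap (`manders_overlap()`) is the normalized
inner product of nonnegative densities over the same kind of mask.
Congruence between grids is enforced, with an explicit trilinear
`regrid()` helper rather than implicit resampling, so scores are
bit-stable. A minimal MRC2014 (mode 2) reader/writer is included.

`apply_register_shift()` implements the alignment correction for a
mis-assigned helix register: a run of gap columns (default four — one
helix turn) inserted in the structure-bearing sequence immediately after
a named residue, with downstream columns and region annotations shifted
and the partner sequence padded. `percent_identity()` counts identical
over aligned columns within a named region; columns where exactly one
sequence has a gap count in the denominator, double-gap columns are
excluded (the source reports no denominator convention, so this one is
stated here and tested).

# The synthetic campaign generator

All end-to-end tests run on `make_pose_ensemble()`, which emulates the
*statistical shape* of a two-engine campaign under the study's stated
conditions: 50 + 20 poses, a small number of true binding modes sampled
by both engines with i.i.d. Gaussian coordinate noise (0.3 Å per
coordinate by default, giving intra-mode cross-engine RMSDs around
0.3·√6 ≈ 0.73 Å, comfortably inside the 2 Å filter), within-element atom
permutation (so only an assignment-corrected metric can see through the
relabelling), and a 30 % fraction of decoys. Decoys are placed by
rejection sampling at least 8 Å from every mode center and 6 Å from
every other decoy — the clearances make threshold tests unambiguous by
construction: no decoy can agree with any other pose at 2 Å. Mode
centers are likewise kept ≥ 8 Å apart. Score tables are rank-structured
synthetics whose noiseless Borda aggregate reproduces a planted order;
they do not mimic real docking energetics. The toy receptor is a
golden-spiral shell of residues with one inward side-chain atom each and
an anchor threonine whose γ-carbon sits exactly at the pocket center.

What passing these tests shows: the pipeline's logic — matching,
deduplication, aggregation, clustering, mode calling — recovers planted
ground truth exactly under realistic noise. What it does not show:
anything about real docking accuracy, receptor model quality, scoring
function reliability, or conformational sampling, none of which the
generator models.

# Problem sizes and numerics

The test suite and the acceptance script use deliberately small problem
sizes chosen to exercise every code path with exact oracles: exhaustive
permutation oracles up to 7 heavy atoms (5040 permutations), 200 random
pose pairs for the assignment-solver check, 100 random 6×3 tables for
the Borda check, 20-residue toy receptors on ~30³ voxel grids at 6.2 Å
resolution / 1.5 Å voxels. Coordinates compare at 1e-8–1e-12 tolerances;
PDB round trips are exact at the format's 3-decimal precision; MRC round
trips at 32-bit float precision. Degenerate inputs are handled
explicitly: empty pose sets error, sub-threshold candidate pools return
all with a warning, zero-extent regions floor at 1 Å, zero-variance
grids refuse to correlate.

# Known limitations

* The relaxed cross-ligand RMSD is geometric, not chemical: it has no
  notion of substructure correspondence (no maximum-common-substructure
  or pharmacophore matching).
* Hydrogen-bond detection is purely geometric; no energetics,
  π-stacking or halogen bonds.
* The simulated-map model (isotropic Gaussians, amplitude ∝ Z) is the
  standard low-resolution approximation; reproducing segment scores
  printed by other tools may require their exact width convention and
  mask definition.
* Docking engines themselves are out of scope: the package consumes
  their pose files and score tables and emits search-region parameters,
  but never runs them.
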