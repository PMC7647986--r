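---
title: "Gyral 3-hinges as connectome hubs: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gyral 3-hinges as connectome hubs: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hingenet)
```

## The scientific question

The cerebral cortex folds into outward ridges (gyri) and inward valleys
(sulci). Along a gyral ridge, the crest line occasionally meets two other
crest lines in a three-way junction — a *3-hinge*. The hypothesis this
package operationalises is that 3-hinge patches are network *hubs* of the
cortico-cortical structural connectome: compared with ordinary gyral
segments (2-hinges), they should show higher degree, strength and
betweenness, higher participation coefficients (connector-hub character),
and they should dominate the high-level cores of the network.

hingenet implements the full analysis chain on triangulated surfaces and
streamline sets, plus seeded synthetic generators that plant the relevant
ground truth, so every stage can be validated quantitatively without any
imaging data.

## Hinge identification

Four stages, each exported separately and composed by `detect_hinges()`:

1. **Gyral altitude** (`compute_gyral_altitude()`). The mid-surface is the
   mesh after heavy Laplacian smoothing; a vertex's altitude is the
   projection of its displacement from the mid-surface onto the outward
   normal (mm, positive on gyri). We smooth with *implicit*
   (backward-Euler) diffusion steps, `(I + step * L)^-1` with the graph
   Laplacian `L`: explicit averaging needs thousands of iterations to
   flatten fold-scale detail and degrades the sheet, whereas ~200 implicit
   steps at `step = 10` (one sparse Cholesky factorisation, reused) remove
   millimetre-scale folds while preserving the global sheet. On synthetic
   folded sheets the recovered altitude sign agrees with the generating
   field on more than 99% of vertices; a flat sheet maps to zero altitude
   and face-orientation flips negate the field exactly.

2. **Watershed crest segmentation** (`watershed_segment()`). Vertices
   below the altitude `level` (default 0 mm, the mid-surface) are flooded
   in ascending altitude order: a vertex joins its neighbours' basin,
   founds a new basin at a fresh local minimum, or marks a collision
   ridge where two basins meet. Vertices at or above the level plus the
   collision ridges form the gyral crest mask. Two numerical choices
   matter. Plateaus are resolved by the deterministic
   (altitude, vertex index) order. And basins shallower than
   `min_basin_depth` (default 0.5 mm) at their first collision are merged
   into the deeper neighbour: almost-flat sulcal floors carry many
   spurious pocket minima whose watershed lines would otherwise thread
   false crest lines (and false hinges) through the basins. Real sulcal
   basins are an order of magnitude deeper than this threshold, so only
   numerical pockets are suppressed.

3. **Distance transform and tree marching**
   (`distance_transform_crest()`, `build_crest_trees()`). Each crest
   vertex gets its shortest-path distance (Dijkstra on the mesh edge
   graph, Euclidean edge lengths) to the crest border, with border
   vertices — crest vertices adjacent to a basin — at 0. Exact polyhedral
   geodesics are unnecessary at this precision. Per connected crest
   component a spanning tree grows from the maximum-distance vertex
   (the crest centre), always attaching the highest-distance frontier
   vertex to its highest-distance in-tree neighbour, i.e. following the
   descending distance gradient to the borders. Ties break on the lowest
   vertex index, making the whole pipeline deterministic.

4. **Pruning and hinge extraction** (`prune_and_extract()`). Leaf-to-
   nearest-bifurcation paths shorter than the pruning threshold are
   removed, iterated to a fixpoint — pruning one twig can expose another
   short leaf path, so a single pass is not stable. The threshold
   defaults to six median edge lengths (6 mm on a 1 mm mesh), long enough
   to remove the centre-to-border twigs (at most the crest half-width,
   2–4 mm) and short enough to keep genuine arms. Surviving trunks are
   the gyral crest lines; vertices of degree >= 3 are gyral hinges with
   `arm_count` equal to their degree. We report all hinges but analyse
   3-hinges (exactly three arms); junctions with four or more arms are
   rare and appear in the census only. (The degree >= 3 convention treats
   the source description's "degrees more than 3" as a slip: a three-arm
   junction has graph degree exactly 3.)

## Synthetic surfaces with planted junctions

`gen_folded_surface()` builds a rectangular triangulated sheet whose
altitude is a sum of Gaussian ridge bumps (amplitude 4 mm, half-width
sigma 1.5 mm) along a planted skeleton of Y-junctions (three 10 mm arms,
120 degrees apart, random orientation) and standalone ridges, recentred
to zero mean so ridges are positive and basins negative. Features sit in
separate layout cells, so junctions cannot collide; infeasible requests
(resolution coarser than the ridge width, arms shorter than the junction
core) error out rather than overlapping silently. The ground truth
records junction centres, skeleton polylines and basin count.

What the sheet does *not* emulate: closed cortical topology, curvature
of the embedding, spatially varying fold wavelength, and scanner-like
noise. Passing recovery tests therefore demonstrates the correctness of
the crest-line machinery on well-posed folds, not performance on real
MRI surfaces. At the default parameters, recovery over 20 seeded
surfaces with five junctions each runs at sensitivity ~0.9 with no
spurious detections beyond 5 mm of any planted junction.

## Parcellation and patch labelling

`equal_area_parcellate()` seeds `n_patches` locations by farthest-point
sampling on the mesh graph and grows patches by *balanced region
growing*: the patch with the smallest accumulated area claims the
unassigned frontier vertex nearest its seed. Two deterministic repair
passes then tighten the areas — local area diffusion between adjacent
patches, and chain moves that shift one vertex of area along a
patch-graph path from a rich patch to the poorest one (every move
checked to keep the donor connected). Lloyd-style centroidal iterations
were rejected: they equalise patch *shapes*, not areas, and could not
guarantee the 1.5 max/min area ratio this package promises. The default
resolution elsewhere in the pipeline is 1000 patches.

`label_patches()` applies the two labelling rules in order: a patch is
SULCAL when more than half of its *area* (not vertex count — area is the
unit used for fiber densities) lies in sulcal basins; a remaining gyral
patch is H3 when a hinge vertex lies inside it ("touched"), else H2.
Sulcal-majority wins over hinge touch, so a sulcal patch grazed by a
hinge stays SULCAL.

## Connectome construction

Connectivity between two patches is the number of streamlines with one
endpoint in each (`assign_endpoints()` + `build_connectivity()`).
Endpoints snap to the patch of the nearest mesh vertex within
`snap_mm = 2` mm; farther endpoints are non-cortical. "Passing through
both patches" is operationalised as endpoint membership — termination,
matching the fiber termination density map (`termination_density()`,
endpoints per mm^2) — rather than interior intersection. Within-patch
fibers and fibers with a non-cortical endpoint are excluded from the
weight matrix but kept in the exclusion counts, so cortical + excluded
always equals the fiber total; with a fixed per-subject total
(4 x 10^4 in the reference setting) no cross-subject normalisation is
needed. `class_connection_counts()` reports fibers joining the H3/H2/NON
classes divided by the summed area (cm^2) of the classes involved; NON
defaults to non-cortical terminations plus sulcal patches, with a
non-cortical-only mode available since the convention is not fixed by
the source description.

`gen_streamlines()` inverts the counting rule — it realises a requested
symmetric count matrix exactly, which gives the round-trip identity used
in the tests: build_connectivity(gen_streamlines(M)) == M, exactly.

## Nodal graph metrics

For a weighted network W (symmetric, nonnegative, zero diagonal) with
adjacency `a_ij = [w_ij > 0]`:

* degree `d_i = sum_j a_ij`; strength `s_i = sum_j w_ij`;
* betweenness `b_i = sum_{s<t} sigma_st(i) / sigma_st`, unnormalised,
  with shortest paths on edge lengths `1 / w_ij` — the standard
  connectomics weight-to-length map; the source prints the formula
  without a normalisation and only z-scores enter downstream, so none is
  applied. A binarised mode (unit lengths) is available since the choice
  is not stated there;
* local efficiency
  `e_i = sum_{j != h in N_i} (w_ij w_ih / p_jh(N_i))^{1/3} / (d_i (d_i - 1))`,
  where `p_jh(N_i)` is the shortest path between neighbours j and h
  within the subgraph induced by N_i (original weights, i removed);
  unreachable pairs contribute 0;
* Onnela clustering
  `c_i = 2 / (d_i (d_i - 1)) * sum_{j<k} (w~_ij w~_jk w~_ki)^{1/3}`
  with weights scaled by the network maximum;
* participation `p_i = 1 - sum_m (d_i(m) / d_i)^2` over a Louvain
  modularity partition at resolution gamma = 1 (module count chosen by
  the optimisation, seeded and deterministic).

Degenerate conventions: `c_i = e_i = 0` for degree < 2, `p_i = 0` for
isolated nodes. Every metric is checked against an independent
brute-force oracle (Floyd–Warshall with explicit path counting,
exhaustive triangle and neighbourhood enumeration) to 1e-9 on random
weighted graphs.

## Core decompositions and ratio curves

The **s-core** (`s_core()`) iteratively removes nodes whose residual
strength falls below s until a fixpoint, the weighted analogue of the
k-core — and exactly the k-core on unit weights, which the tests verify
against an independent coreness computation. An `edge_prune` variant
(drop edges lighter than s each round) exists for comparison, but it is
not the default: with unit weights it empties the graph at s = 2 and so
cannot reduce to the k-core. The **nodal strength decomposition**
(`strength_decompose()`) is the single-pass variant: drop nodes whose
full-network strength is below s, no iteration.

`ratio_curves()` reports, per level, the fraction of surviving nodes in
each convolution class; at level 0 these equal the intact class
fractions. The default grid is 50 linear levels from 0 to the maximum
nodal strength. The hub hypothesis predicts the H3 curve rising with s
and crossing the falling H2 curve at high levels.

**Crossing permutation test.** Node labels are shuffled (class sizes
preserved) and the crossing event — some level with strictly more H3
than H2 survivors — recorded over `n_perm = 1000` shuffles; survivor
sets are label-free and computed once. When the observed curves cross,
`p = (1 + #events) / (1 + n_perm)`; when they do not, p = 1 and the raw
null crossing rate is still reported. `cohort_crossing_test()` evaluates
the event on the cross-subject *mean* curves — the form in which cohort
curves are reported — and only at levels where every subject still
preserves at least one node: beyond that point the "group mean" is a
single subject's 1-node ratio, and the any-level event would reject a
quarter of null shuffles on tail noise alone. Even so, a residual null
crossing rate of a few percent can remain for the single-pass strength
method when the last complete levels hold very few nodes per subject.

## Statistics

Metrics are z-scored within subject over *all* patches
(`zscore_within_subject()`), sulcal included — the reference class means
for both gyral classes are positive, which is only consistent if sulcal
patches enter the normalisation. Group contrasts use Welch two-sample
t-tests (`ttest_two_sample()`; the pooled-variance test sits behind
`var_equal = TRUE` since the source says only "two-sample t-test") and a
label permutation test (`label_permutation_test()`): statistic
|mean_H3 - mean_H2| for the observed and every shuffled labelling,
shuffles within subject with the statistic pooled across subjects,
`p = (1 + #{null >= observed}) / (1 + n_perm)` with 1000 shuffles by
default. The absolute-difference statistic makes the test two-sided and
calibrated; a literal post-hoc-direction one-tail would double the
type-I error, and the source's prose description of which tail to count
is self-contradictory (large effects would get large p), so it is noted
but not followed. No multiple-testing correction is applied, matching
the uncorrected alpha = 0.05 convention. Type-I error is verified to sit
in [0.03, 0.07] at alpha = 0.05 over hundreds of null cohorts.

`cross_species_compare()` adds the second normalisation round — z-scores
across subjects within species — then runs pairwise species t-tests per
metric and class.

## Planted-hub network cohorts

`gen_network_cohort()` draws stochastic block models with `n_modules`
planted modules (within/cross-module edge probabilities 0.35 / 0.05,
baseline weights 8 / 4, lognormal weight noise sd 0.3). H3 nodes are
boosted *per endpoint*: an edge's probability and weight are multiplied
by `(1 + hub_degree_boost)` once per H3 endpoint, and H3 cross-module
pairs use `hub_crossmodule_prob = 0.25`. The squared hub–hub boost
creates a rich club whose internal weights survive core decomposition on
their own — without it, H3 nodes lose their strength exactly when their
H2 neighbours are pruned and no curve crossing can occur, which would
contradict the hub phenotype the cohort is meant to embody. Defaults
(10 subjects, 150 patches, 25 H3 / 75 H2 / 50 sulcal,
`hub_degree_boost = 2`) give a clear but not degenerate contrast: the
class sizes scale down the reference analysis (roughly 1000 patches with
a few hundred 3-hinges) to desk size. With `hub_degree_boost = 0` and
`hub_crossmodule_prob` equal to the background, H3 and H2 are
exchangeable — the null cohorts used for calibration. Per-subject
randomness uses counter-derived seeds (`derive_seed()`), so cohorts are
order-independent.

## Functional involvement via dictionary learning

`learn_dictionary()` factorises a signal matrix X (time points x
signals) as D alpha with sparse alpha, by online mini-batch alternation:
coordinate-descent lasso coding (soft-thresholding steps, so converged
coefficients carry exact zeros), accumulation of the sufficient
statistics, and block-coordinate dictionary updates with unit-ball
projection. Columns are centred and variance-normalised first (the
source does not state its normalisation; unit-variance columns make a
single lambda meaningful), lambda defaults to 0.1, batch size 256.
Initial atoms are chosen by a greedy max-incoherence scan of the data
columns — random column draws duplicate atoms and leave others
uncovered, inflating the recovered supports — and atoms unused in an
epoch are re-seeded from the worst-reconstructed column, a standard
online-learning repair. `involvement_counts()` counts per-column
coefficients above `zero_tol = 1e-8` (guarding accumulated rounding, not
thresholding real values): the number of functional networks each vertex
participates in. The reference component count is k = 400;
`gen_signal_matrix()` plants known sparse supports on lightly smoothed
white-noise atoms — smooth enough to resemble slow haemodynamics,
incoherent enough that supports are identifiable, which is the standard
premise of sparse recovery. On noiseless 1-sparse signals the model
reaches relative reconstruction error ~0.013 with median involvement 1.

## The pipeline and problem sizes

`run_pipeline()` chains surface generation, hinge detection,
parcellation, labelling, streamline synthesis (fiber counts drawn from a
multinomial whose pair intensities favour H3 patches and nearby
patches), connectome construction, metrics, decompositions and the
pooled statistics, writing CSVs and a manifest (config, per-subject
seeds, md5 checksums) that is byte-identical across re-runs of the same
configuration. All randomness descends from the single master seed via
`derive_seed()`.

The test-suite problem sizes are chosen for thorough-but-fast
verification: 20 surfaces of ~8.6k vertices for recovery, oracle checks
on graphs of up to 25 nodes, cohorts of 10 x 150-node networks, 500-
replicate calibrations at 200 permutations, and a 2-subject / 60-patch
pipeline determinism check. These are scaled-down study conditions, not
estimates of real-data effect sizes.

## Known limitations

* The synthetic sheets are flat rectangles; no test exercises closed
  surfaces, poles, or strongly anisotropic meshes.
* Tractography biases (gyral bias, crossing fibers) are deliberately out
  of scope: streamlines are synthesised from endpoint counts.
* The Louvain partition is seeded and deterministic but still a local
  optimiser; participation coefficients inherit its variability across
  seeds.
* Dictionary learning is a shallow linear model; involvement counts
  depend on lambda, and only the noiseless recovery regime is verified
  quantitatively.
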