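# hingenet

Cortical gyri occasionally meet in three-way crest-line junctions —
**3-hinges** — and a growing body of morphometry suggests these junctions
are not ordinary gyral tissue: they carry denser long-range connections
and sit at the crossroads of cortical communities. `hingenet` implements
the full analysis that turns this idea into numbers:

1. **Hinge identification** on a triangulated cortical surface: gyral
   altitude (signed distance to a heavily smoothed mid-surface), watershed
   segmentation of gyral crests from sulcal basins, a distance-transform
   tree marching over the crest, and branch pruning. Crest-line vertices
   of degree ≥ 3 are gyral hinges; three-arm junctions are 3-hinges.
2. **Equal-area parcellation** of the surface into patches (default 1000),
   labelled `H3` (touched by a 3-hinge), `H2` (other gyral patches) or
   `SULCAL` (majority of area in sulcal basins).
3. **Structural connectome** construction: patch-pair weights `w_ij` count
   the streamlines terminating in both patches; fiber termination density
   per mm²; area-corrected class-connection tables.
4. **Nodal graph metrics**: degree `d_i = Σ_j a_ij`, strength
   `s_i = Σ_j w_ij`, betweenness `b_i = Σ_{s≠i≠t} σ_st(i)/σ_st` (shortest
   paths on lengths `1/w`), weighted local efficiency, Onnela clustering
   `c_i = 2/(d_i(d_i−1)) Σ (w̃_ij w̃_jk w̃_ki)^{1/3}`, and participation
   `p_i = 1 − Σ_m (d_i(m)/d_i)²` over a Louvain partition (γ = 1).
5. **Core decompositions**: the weighted s-core (iterative removal of
   nodes with residual strength < s) and the single-pass nodal-strength
   decomposition, with H3/H2 ratio curves and label-shuffling
   curve-crossing permutation tests (per subject and cohort-level).
6. **Statistics**: within-subject z-scoring, Welch t-tests,
   size-preserving label permutation tests (default 1000 shuffles),
   cross-species comparison tables.
7. **Functional involvement**: online dictionary learning (mini-batch
   sparse coding `X ≈ Dα`, k = 400 by default) and per-vertex counts of
   nonzero coefficients `‖α_i‖₀` — how many functional networks a vertex
   participates in — compared between H3 and H2.

Because real diffusion/functional MRI inputs are large and proprietary,
the package ships first-class **synthetic generators** with full seed
control: folded sheets with planted Y-junction skeletons
(`gen_folded_surface`), modular network cohorts with planted hub classes
(`gen_network_cohort`), streamline sets realising exact endpoint count
matrices (`gen_streamlines`), and sparse-coded signal matrices
(`gen_signal_matrix`). Every pipeline stage is validated against this
planted ground truth or an independent brute-force oracle.

## Worked example

Detect planted hinges on a synthetic folded sheet, then contrast planted
hub patches in a 10-subject synthetic cohort:

```r
library(hingenet)

surf <- gen_folded_surface(n_junctions = 5, n_ridges = 1, seed = 1)
cg <- detect_hinges(surf$mesh)
glance(cg)
#> # A tibble: 1 × 5
#>   n_crest_vertices n_edges n_hinges n_3hinges length_threshold
#>              <int>   <int>    <int>     <int>            <dbl>
#> 1              202     196        4         4             6.00
```

Four of the five planted Y-junctions are recovered on this seed (the
aggregate sensitivity over 20 seeds is ~0.94, with no spurious hinges).

```r
coh <- gen_network_cohort(cohort_spec(seed = 1))   # 10 subjects, 150 patches
metrics <- dplyr::bind_rows(lapply(seq_along(coh), function(s)
  compute_all_metrics(coh[[s]]$network, seed = s, subject_id = s)))
compare_metrics(metrics, n_perm = 1000, seed = 1)
#>          metric mean_h3 mean_h2   p_ttest p_permutation direction
#> 1        degree    2.21  -0.440  0.00e+00      0.000999     h3>h2
#> 2      strength    2.22  -0.446  0.00e+00      0.000999     h3>h2
#> 3   betweenness    1.95  -0.390  1.67e-88      0.000999     h3>h2
#> 4    efficiency    1.54  -0.353  0.00e+00      0.000999     h3>h2
#> 5    clustering   -1.53   0.261 2.94e-319      0.000999     h2>h3
#> 6 participation    1.38  -0.225  3.98e-255     0.000999     h3>h2
```

The columns are within-subject z-scored class means: planted hub (H3)
patches exceed ordinary gyral (H2) patches in degree, strength,
betweenness and participation, and every contrast survives the 1000-fold
label permutation test (`p = 1/1001`, the smallest attainable value).
The cohort-level ratio-curve crossing — the H3 fraction of the surviving
core overtaking the H2 fraction at high core levels — is likewise not a
labelling artefact:

```r
tidy(cohort_crossing_test(lapply(coh, `[[`, "network"),
                          method = "s_core", n_perm = 1000, seed = 1))
#> # A tibble: 1 × 5
#>    p_value n_perm observed direction method
#>      <dbl>  <dbl>    <dbl> <chr>     <chr>
#> 1 0.000999   1000        1 <NA>      s_core
```

`run_pipeline(pipeline_config(...))` chains all stages per subject and
writes CSV tables plus a seed/checksum manifest; re-runs with the same
configuration are byte-identical.

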