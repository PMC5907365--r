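# regmaxs

Spatial co-registration of neuron morphologies by maximizing the overlap
of the volumes they occupy.

Stereotypic neurons — common in invertebrates — conserve their gross
spatial layout across specimens while varying considerably in their fine
branches. Comparing reconstructions of such neurons, or averaging them
into dendritic density profiles, requires registering them into a common
frame, and often no standard brain atlas or fiduciary landmarks are
available. Point-matching methods (ICP variants, RANSAC-based affine
alignment) then struggle, because there simply is no point-to-point
correspondence between fine branches of different specimens.

`regmaxs` implements registration by volume overlap instead. A morphology
(SWC format, coordinates in µm) is represented at a spatial scale *v* by
the set of cubic voxels of edge *v* (one voxel centered at the origin)
containing at least one point of its cable. For two voxel sets the
spatial dissimilarity is the Jaccard complement

    D(A, B) = 1 − n(A ∩ B) / n(A ∪ B),

and for a group of N morphologies it is the Earth-Mover-Distance between
the group's normalized voxel-occupancy histogram and the ideal histogram
of perfect overlap (all mass at occupancy N), Σₖ pₖ·(N − k).

Two algorithms minimize these measures over affine transforms:

* **Reg-MaxS** (`reg_maxs()`) registers a pair: after centroid alignment
  it alternates translation and rotation estimation, interleaved with
  scale estimation (centric measure), each estimated by exhaustive search
  refined across a descending schedule of voxel sizes (default 160, 80,
  40, 20, 10 µm). The solution is the visited state with the lowest
  finest-scale dissimilarity. Reflections are not handled.
* **Reg-MaxS-N** (`reg_maxs_n()`) co-registers a group by iterative
  averaging: every member is registered to the union volume of the
  previous iteration's members, gated by a coarse-first acceptance rule,
  with cumulative per-member scaling restricted to [0.5, 2]; the
  iteration minimizing the occupancy-based group dissimilarity wins, and
  results are normalized back into the initial reference's frame.

Supporting modules provide SWC I/O and resampling (`read_swc()`,
`write_swc()`, `resample_morphology()`), affine-transform utilities
including the measure of anisotropic scaling (`mas()`), a synthetic
morphology generator and randomized test-suite builder (`generate_tree()`,
`make_suite()`), registration performance statistics (exact sign test,
`sign_test()`, `performance_summary()`), a PCA baseline registration
(`pca_register()`), and dendritic density profiles with maximal
projections (`density_profile()`, `max_projection()`).

## Worked example

Generate a synthetic dendritic tree, disturb it with a random affine
transform plus positional noise, and register the transformed copy back
onto the original:

```r
library(regmaxs)

base <- generate_tree(tree_gen_params(n_nodes = 300, seed = 3))
case <- make_suite(base, n_transforms = 1, noise_stds = 5, seed = 21)[[1]]
round(case$true_transform$scales, 2)
#> [1] 1.19 1.40 1.47
round(case$mas, 2)
#> [1] 0.13

res <- reg_maxs(case$transformed, base)
res
#> reg_maxs_result
#>   steps recorded : 10
#>   solution index : 9
#>   voxel sizes    : 160, 80, 40, 20, 10 um
#>   dissimilarity  : 0.2000, 0.0588, 0.1923, 0.3371, 0.6034

d <- correspondences(case$noisy, res$registered, "known")$distance
round(median(d), 1)
#> [1] 4
sign_test(d, threshold = 10)
#> $p_value
#> [1] 7.107852e-73
#> $significant
#> [1] TRUE
#> $k
#> [1] 290
#> $n
#> [1] 300
```

The residual dissimilarity of 0.60 at the 10 µm working scale reflects
the injected 5 µm noise, which no affine transform can remove — voxel
overlap at the finest scale is bounded by the noise, not by the
registration. What matters is the point-level error: the median
corresponding-point distance is 4 µm, well below the 10 µm working voxel
size, and the exact sign test confirms that 290 of the 300 points landed
closer than that, i.e. the registration recovered the planted transform
at the finest scale it optimizes.

A group of jittered copies can be co-registered and averaged into a
density profile:

```r
group <- lapply(1:5, function(i) {
  noisy <- add_noise(base, 2, seed = i)
  apply_transform(noisy, random_transform(center = centroid(noisy)))
})
gres <- reg_maxs_n(group, initial_ref_index = 1)
gres$solution_iteration
gres$group_dissimilarity
prof <- density_profile(gres$final_morphologies, voxel_size = 2,
                        resample_spacing = 1, kernel_std = 2)
image(max_projection(prof, 3))
```

## Command line

A thin CLI over the same functions lives in `inst/cli/regmaxs`:

```sh
regmaxs simulate --seed 1 --n-nodes 300 --n-transforms 20 --noise-stds 0,5 --out-dir suite/
regmaxs register-pair --test suite/case001_transformed.swc --ref suite/base.swc \
        --voxel-sizes 160,80,40,20,10 --out registered.swc --transform-out t.json
regmaxs register-group --swc-dir registered/ --ref-index 1 --out-dir group/ --report report.json
regmaxs evaluate --ref suite/base.swc --test-dir group/ --mode nn --threshold 10 --out metrics.csv
regmaxs density --swc-dir group/ --voxel-size 0.25 --resample 0.1 --kernel-std 1.25 --out density.nrrd
```

## Vignette

`vignettes/volume-overlap-registration.Rmd` describes the measures, the
search strategy, the acceptance and restriction rules, the synthetic data
generator and its limitations, and all numerical choices.
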