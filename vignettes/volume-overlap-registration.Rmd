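---
title: "Registering neuron morphologies by maximizing volume overlap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Registering neuron morphologies by maximizing volume overlap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(regmaxs)
```

## The problem

Invertebrate neurons of a given type are often structurally stereotypic:
their gross spatial layout is highly conserved across specimens while their
fine branches vary considerably. Comparing such reconstructions — or
computing a dendritic density profile for the type — requires bringing the
morphologies into a common spatial frame. When no standard brain atlas (or
too few fiduciary landmarks) is available, the registration has to work
from the morphologies alone.

Point-matching approaches (ICP variants, RANSAC-based affine alignment)
seek point-to-point correspondence, which the biology does not guarantee:
two specimens place their fine dendrites differently even when the arbor
occupies the same region. The approach implemented here instead maximizes
the overlap of the *volumes* occupied by the morphologies across a range
of spatial scales, which is exactly the notion of similarity that
stereotypy supports.

## Volume representation and dissimilarity measures

A morphology (an SWC tree: nodes with xyz coordinates, radius and parent
links, coordinates in micrometres) is discretized into the set of cubic
voxels of edge length $v$ that contain at least one point of it, with one
voxel centered at the coordinate origin. Two choices deserve mention:

* **Edge sampling.** Voxels are "occupied" by cable, not only by SWC
  nodes: before indexing, every edge is sampled so consecutive points are
  at most $v/2$ apart. Without this, a long straight neurite would occupy
  only the voxels of its endpoints.
* **Centerline model.** Radii are ignored. At the registration scales of
  interest (voxels of 10 µm and above) dendrite thickness is negligible;
  registration quality is unaffected and the representation stays simple.
  Radii are carried through transforms (scaled by the geometric mean of
  the axis scale factors) purely so that written SWC output remains
  sensible.

Indexing uses round-half-up, so voxel $i$ covers the half-open interval
$[iv - v/2,\; iv + v/2)$ and boundary points are assigned unambiguously.

For two voxel sets $A$ and $B$ the spatial dissimilarity is the Jaccard
complement
$$D(A, B) \;=\; 1 - \frac{n(A \cap B)}{n(A \cup B)},$$
which is 0 for identical and 1 for disjoint sets. The *non-centric*
measure applies $D$ as given and is used when estimating translations and
rotations. The *centric* measure first translates the test morphology so
that the centroid of its occupied voxel centers coincides with that of
the reference set, and is used when estimating scale differences — a pure
size difference should not be penalized for the translation offset it
induces. The centroid translation is applied in continuous space before
re-voxelization, not snapped to the grid, and uses voxel-center centroids
so that both operands live in the same discretized space (the reference
in group registration is a voxel set without nodes).

For a *group* of morphologies, the occupancy of a voxel is the number of
members occupying it. From the histogram of occupancy values over all
occupied voxels, a weighted histogram (counts times occupancy) is
normalized to unit sum; a perfectly co-registered group has all mass at
occupancy $N$. Group dissimilarity is the Earth-Mover-Distance between
the normalized histogram and that ideal, with ground distance $|i - j|$
in raw occupancy units; in 1-D this reduces to the closed form
$\sum_k p_k (N - k)$. `group_dissimilarity(h, normalized = TRUE)` divides
by $N - 1$ so that fully disjoint groups score 1 regardless of group
size, which is convenient when comparing groups of different sizes; raw
units are the default.

```{r}
a <- voxelize(generate_tree(tree_gen_params(n_nodes = 60, seed = 1)), 10)
h <- occupancy_histogram(list(a, a))
group_dissimilarity(h)   # identical members overlap perfectly
```

## Estimating transform differences

Dissimilarity as a function of transform parameters has many local minima
at small voxel sizes, so gradient methods are unsuitable; parameters are
estimated by exhaustive search over finite grids instead. To keep that
affordable and accurate, estimation is multi-scale, over a descending
schedule of voxel sizes (default 160, 80, 40, 20, 10 µm; geometric
halving down to the 10 µm working scale, with coarse levels larger than
half the test's bounding-box diagonal dropped as uninformative).

At the coarsest level the full plausible region is searched: rotation
±30° per axis in 10° steps, translation ±2v per axis in steps of v/2,
scale log-spaced over the allowed bounds with 7 samples per axis. Each
finer level then searches the *region of uncertainty* of the previous
estimate: the span of all candidates whose dissimilarity tied with the
optimum (ties are exact, on voxel counts), widened by one grid step. An
informative level thus shrinks the window for refinement, while a level
too coarse to discriminate — at 160 µm a small morphology occupies a
handful of voxels and most candidates tie — leaves the window wide so
that finer, informative levels can still reach the true optimum. The
identity and the previous level's estimate are inserted into every
level's grid, so neither can be lost when an asymmetric window is
resampled. Tied optima are resolved deterministically: smallest
parameter norm first (log-scale norm for scales), then candidate order,
so the identity is preferred when the data cannot distinguish.

One sampling subtlety matters for correctness: rigid candidates
(translations, rotations) preserve edge lengths, so the edge-resampled
point cloud can be computed once per level and transformed per
candidate. Scale candidates change edge lengths, so each candidate
scales the node geometry first and resamples edges afterwards at v/2 —
evaluating them on a denser pre-resampled cloud would occupy extra
boundary voxels and visibly bias the scale estimate.

## Pairwise registration

`reg_maxs()` registers a test morphology to a reference by repeatedly
estimating and removing differences:

1. centroid alignment (node centroid onto reference centroid);
2. an inner loop alternating translation and rotation estimation —
   rotation and translation do not bias each other's estimation, so their
   order is fixed (translation first) purely for determinism;
3. one scale estimation (centric measure, about the current centroid,
   within the scale bounds), applied together with the voxel-centroid
   alignment shift that the centric objective assumed;
4. repeat 2–3 until a full pass makes no progress, or `max_outer = 30`
   passes.

Whether an estimated step is *applied* depends on its kind. Translation
and rotation steps are applied iff they do not worsen the finest-level
dissimilarity; ties are allowed, so plateaus can be traversed, but the
coarse levels — which hold only a handful of voxels and fluctuate by
single counts — are never allowed to override the fine alignment. A
scale step is applied iff it improves the per-level dissimilarity vector
lexicographically from the coarsest level down: escaping a large scale
difference legitimately repairs the large-scale picture at a transient
fine-scale price, and the coarse-first comparison is exactly the logic
the group-level acceptance rule uses. All comparisons are exact on voxel
counts — dissimilarity changes in discrete rational steps, so no
floating tolerance is involved. Loop progress is measured against the
best state seen so far; when a full outer pass neither improves the best
fine-level value nor applies a scale step, the iteration stops.

The returned solution is the recorded state with minimal finest-level
dissimilarity, earliest on ties — so exploratory steps that did not pay
off are discarded, and the result is never worse than the initial
centroid alignment. The entire search is deterministic. Reflections are
out of scope and must be removed beforehand; shear is not searched
explicitly (combinations of rotation and anisotropic scaling compensate
it only approximately). Scaling differences that are strongly anisotropic
*and* rotated relative to the world axes are the known hard case: the
per-axis scale model cannot represent them exactly, and success rates
drop as the measure of anisotropic scaling (MAS) grows:

```{r}
mas(c(1, 1, 1))          # isotropic
mas(c(1.12, 0.61, 1.27)) # the kind of case where registration struggles
```

## Group registration

`reg_maxs_n()` co-registers a group by iterative averaging. Iteration 0
aligns all centroids to the chosen initial reference. Each iteration
registers every member to the current reference volume — the initial
reference itself in iteration 1, afterwards the *union* of the members'
voxel sets. The union is deliberately conservative: a majority vote would
delete parts that have not yet overlapped and they could never attract
registration again, whereas the union keeps every member fully
represented. Because members are registered to an average that is not a
real morphology, each pairwise result is accepted only if its per-level
dissimilarity vector improves lexicographically from the *coarsest* level
down (`accept_registration()`); sacrificing coarse structure for fine
overlap against an average would be over-fitting. Rejected members are
carried unchanged (within `reg_maxs()` itself, iterations 1 and later do
not redo the centroid alignment — the group-level alignment of iteration
0 is the only initial registration).

Unbounded repetition of scale estimation would let members grow without
limit toward the union volume, so the cumulative per-axis scaling of each
member is tracked and the per-step scale search interval is shrunk to
keep it inside global bounds (default [0.5, 2]; `restrict_scaling()`).

Iterations stop when every registration in an iteration is rejected (or
at `max_iters = 20`, a safety cap). The solution is the recorded
iteration — iteration 0 competes, so the algorithm is never worse than
doing nothing — with minimal occupancy-based group dissimilarity at the
smallest voxel size, the scale at which registration is finalized
(per-size values are recorded for diagnosis). Finally all members are
mapped by the inverse of the initial reference's accumulated transform
(including its iteration-0 centroid alignment, which is the identity),
so results are directly comparable with the original reference; the
reference itself returns to its input coordinates.

## Synthetic test data

`generate_tree()` grows a connected tree by a seeded stochastic branching
walk: direction-persistent steps of roughly 10 µm, occasional branch
points (probability 0.12 per grown node), reflected at the faces of a
bounding box of half-widths (150, 150, 50) µm, a moderately flattened
arbor. Flatness is a genuine design dimension here: for a *perfectly*
planar arbor the scale normal to the plane is nearly inert (which is how
densely planar morphologies tolerate strongly anisotropic test
transforms), yet in a voxel representation a very thin slab also loses
overlap catastrophically when tilted, so extreme planarity makes the
search landscape worse rather than better. The moderate default reflects
that trade-off. Beyond extent, the generator emulates only what matters
for volume-overlap registration — a coherent arbor of bounded extent
with a few hundred sample points — and nothing more: no biophysical
branching statistics, no realistic taper, no somatic
or axonal specialization. Passing tests on these trees therefore
demonstrates recovery of affine differences under positional noise, not
performance on any particular real neuron class; real reconstructions
additionally contain non-affine inter-specimen differences that no affine
method can remove.

`make_suite()` reproduces the randomized test protocol: noise of a given
standard deviation is added independently to every coordinate (the noisy
morphology `N(M)`), then a random affine transform — translation
U[−20, 20] µm, rotation U[−30, 30]° and scale U[0.5, 2] per axis, all
uniform in linear scale — is applied about the noisy morphology's
centroid to give the test `TN(M)`. The registered result `RTN(M)` is
compared against `N(M)`, the best achievable answer. Node ids are shared
across the triple, so true point correspondence is known. Where the full
protocol used 1000 noiseless plus 100 transforms per noise level, the
desk-scale default is 20 transforms and noise levels {0, 5} µm on a
300-node tree, which keeps a full suite in minutes; suites can be
stratified by MAS (`max_mas`) to study the anisotropy effect. The center
of the random transforms (unspecified in the original protocol) is the
noisy morphology's centroid, which keeps test cases inside the search
ranges.

## Performance statistics

`correspondences()` pairs reference and test nodes by id (synthetic
cases) or by nearest neighbor (real data). `sign_test()` is the exact
one-sided binomial sign test on the number of distances below a threshold
— typically the smallest voxel size, the finest scale at which the
algorithm aligns anything — with ties at the threshold counted as
failures (conservative), significance at 1%. A Wilcoxon signed-rank
variant is available behind a flag for sensitivity analysis, since the
two are easily conflated and the exact binomial test is the intended
default. `performance_summary()` regroups a suite's distance table both
per test across points and per point across tests and reports the two
percentages of significant cases.

`pca_register()` provides the classical baseline: centroid alignment,
rotation mapping principal axes onto principal axes (axis signs chosen
for a proper rotation of maximal trace, consistent with the assumption
that the inputs are similarly oriented), scales from the ratios of
standard deviations along corresponding axes. When two principal
variances are within 1% the axis correspondence is ambiguous; the
function warns and leaves the rotation at identity rather than guessing.

## Density profiles

`density_profile()` computes the voxel-wise fraction of co-registered
morphologies occupying each 0.25 µm voxel (edges resampled at 0.1 µm),
optionally smoothed per morphology by a unity-sum 3-D Gaussian kernel.
The kernel σ is a required per-group choice (structure scale differs
between neuron classes); it is truncated at 3σ and renormalized to sum
exactly 1, and the grid is padded by 3σ so interior mass is conserved.
With σ → 0 the profile is exactly the binary occupancy fraction.
`max_projection()` yields the 2-D maximal projections used for
visualization.

## Numerical choices, sizes and limitations

* All dissimilarity comparisons inside the registration loops are exact
  (integer voxel counts compared by cross-multiplication); tolerances
  appear only where floating point genuinely enters (transform
  round-trips at 1e−9 µm, SWC I/O at 1e−6 µm).
* Voxel indices are encoded as single doubles (exact below 2^53) for fast
  set operations; indices beyond ±32768 voxels are rejected, far beyond
  any morphology at the supported scales.
* The test and acceptance suites run on 80–300 node trees with schedules
  ending at 10 µm; these sizes were chosen so a full suite completes in
  minutes while the 300-node tree still spans several hundred µm of
  cable, i.e. several voxels at every level of the default schedule.
* Runtime is dominated by candidate evaluation at the finest level and is
  inherently variable: the voxel set changes with every rotation and
  scale, and the number of passes depends on how the landscape unfolds.
* Known limitations: no reflections, no explicit shear, degraded
  performance under strongly anisotropic rotated scaling (high MAS), and
  dependence on similarly situated centroids — partial reconstructions
  violate that assumption and need caution.
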