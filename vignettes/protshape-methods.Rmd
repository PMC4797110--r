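---
title: "Salient shape-index similarity for protein surface meshes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Salient shape-index similarity: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protshape)
```

# Overview

`protshape` scores the similarity of three-dimensional protein surface
models. A model is a triangle mesh; the pipeline is

1. discrete curvature per vertex (Gaussian `kG`, mean `kM`, principal
   `k1 >= k2`),
2. two derived per-vertex fields — the shape index (SI) and the salient
   geometric feature (SGF),
3. condensation of each field by one-dimensional K-means into a sorted
   K-vector of cluster means (`T` for SI, `P` for SGF),
4. the K x K feature-matrix descriptor `M = T T' + P P'`,
5. pairwise similarity by a matrix-extended grey relation degree
   `eta` in (0, 1].

This vignette explains each stage's model and assumptions, the
parameters that matter, the numerical choices, what the synthetic
generators do and do not emulate, and known limitations. Nothing here
states an empirical result that the test suite does not itself compute.

# Mesh handling

Meshes are read from OFF, PLY (ASCII or binary little-endian) or OBJ;
polygons are fan-triangulated. `clean_mesh()` merges duplicate vertices
(tolerance `1e-8` times the bounding-box diagonal, i.e. scale-free),
drops zero-area and duplicate faces and unreferenced vertices.
`orient_outward()` makes windings consistent by breadth-first
propagation over face adjacency and flips each closed component so its
signed volume is positive. Orientation matters because the sign of the
mean curvature — and therefore the sign of SI — is only defined
relative to an outward normal. Open meshes (e.g. surfaces with small
holes) are accepted: their windings are made consistent, outwardness is
reported as undefined, and boundary vertices are flagged and excluded
from descriptors by default, because curvature estimates at a boundary
use incomplete neighborhoods and are biased.

# Discrete curvature

Gaussian curvature is the classical angle deficit
`kG(i) = (2*pi - sum of incident-triangle angles at i) / A(i)`
(`pi - sum` at boundary vertices), and mean curvature accumulates
edge-length-weighted signed dihedral angles,
`kM(i) = -(1/(4 A(i))) * sum over incident edges of len(e) * beta(e)`,
with `beta(e)` positive at locally convex edges.

Two calibration choices deserve attention:

* **Vertex area `A(i)`.** We use the mixed Voronoi area (the cotangent
  Voronoi cell, clipped for obtuse triangles), which partitions the
  total surface area exactly. The simpler barycentric third-of-face
  area was measured on icospheres and leaves a persistent ~15% error
  at the twelve valence-5 vertices that does not shrink with
  refinement, which would corrupt the discriminant `kM^2 - kG` and with
  it the principal curvatures; the mixed area brings every vertex of an
  icosphere with 2562 vertices within 0.2% of the analytic values, with
  errors decreasing monotonically under refinement (asserted in the
  test suite). The barycentric area is still used — appropriately — as
  the partition-of-unity weight `Area(i)` inside SGF, where only
  relative weights within a cluster matter.
* **Sign of `kM` (convex-negative).** The leading minus sign makes an
  outward-oriented unit sphere come out at `kM = -1`. Under the SI
  formula below this is exactly the convention that sends convex caps
  to +1 and concave cups to -1; the unit-sphere test pins it down.

Principal curvatures follow as `k1,2 = kM +/- sqrt(d)` with
`d = max(kM^2 - kG, 0)`. A negative discriminant is a numerically
inconsistent pair of estimates; it is clamped to an umbilic (`k1 = k2 =
kM`) and counted, the count serving as a mesh-quality signal. On smooth
synthetic meshes the clamped fraction is below 1%.

# Shape index

`SI = -(2/pi) * arctan((k1 + k2) / (k1 - k2))` is scale-free (it
depends only on the ratio of the principal curvatures) and classifies
the local surface type: +1 convex cap, 0 symmetric saddle, -1 concave
cup. At umbilics (`k1 = k2`) the quotient is singular while the limit
value is well defined (+1 or -1 with the sign of `-kM`), and near
umbilics the discretization noise in `k1 - k2` makes the formula
wild. Vertices with `|k1 - k2| <= umbilic_tol * max(|k1|, |k2|, 1)`
therefore receive the limit value directly.

`umbilic_tol` defaults to 0.25, chosen from the measured geometric
separation on the synthetic oracles: discretized spheres (subdivision
2-5) show `|k1 - k2| / max(|k1|, |k2|, 1)` at most ~0.16 (pure
discretization noise around a true umbilic), while genuinely
anisotropic surfaces sit far above it (at least ~0.8 on a torus with
tube ratio 4, at least ~1 on the saddle patch, where `k1 = -k2` makes
the ratio 2 at the center). Any value in roughly [0.2, 0.5] separates
the two regimes; 0.25 leaves margin on both sides. The absolute floor
of 1 in the guard protects flat regions (`k1, k2 -> 0`), at a price
recorded under Limitations.

# Salient geometric feature

For each vertex `i`, `F(i)` is its topological 2-ring (all vertices
within `ring_depth = 2` edge hops — mesh-resolution-adaptive, cheap and
deterministic), and

`SGF(i) = w1 * sum_{j in F} AreaFrac(j) * SI(j)^3 + w2 * N * Var`,

with `w1 = w2 = 0.5`. `AreaFrac` normalizes the barycentric vertex
areas within the cluster (so the first term is a bounded, area-weighted
average of cubed SI — cubing preserves sign while emphasizing strong
convexity/concavity); `N` counts cluster members whose SI is a local
extremum over their own 1-ring; `Var` is the population variance of SI
over the cluster. The `N * Var` term is added once per cluster, not
once per member — otherwise SGF would scale with cluster size even on
constant fields, contradicting its role as a weighted combination. A
constant field `SI = c` therefore gives `SGF = w1 * c^3` everywhere
(the unit sphere gives exactly 0.5), and population variance makes the
degenerate single-member cluster well defined.

Local extrema are strict, with a 1e-9 margin: a vertex counts only if
its SI clears every 1-ring neighbor by more than 1e-9. Strictness keeps
plateaus (constant fields) at `N = 0`; the margin makes the integer
count stable under rounding-level jitter, which matters on meshes with
exact symmetries where equal SI values would otherwise flip in and out
of the count nondeterministically.

# The descriptor

Vertex counts differ across models, so the per-vertex fields are
condensed to a common length K by one-dimensional K-means over the
field values (each channel independently). `K = 48` by default —
enough resolution for the SI/SGF distributions while keeping the K x K
comparison cheap.

`kmeans_1d()` initializes with K data values sampled without
replacement under an explicit seed and iterates Lloyd assignment/update
steps (ties to the lower cluster; empty clusters re-seeded with the
farthest point). Because single-run Lloyd with random initialization
stalls in poor local optima for 1-D quantization once K grows — cluster
boundaries cannot migrate across occupied territory — the converged
solution is then polished deterministically, exploiting the fact that
optimal 1-D clusters of sorted data are contiguous intervals: every
boundary is relocated exactly given its neighbors, and a split-merge
step moves a center from the least useful cluster to the optimal binary
split of the costliest cluster while that strictly lowers the
within-cluster sum of squares. A few seeded restarts plus one
deterministic quantile-spaced start are polished this way and the best
kept. The test suite holds the result to within 5% of the exact
dynamic-programming optimum across mixture, uniform, Gaussian and
skewed instances up to K = 48. Everything is deterministic given the
seed, and the values are sorted internally so the outcome depends only
on the multiset of field values, never on vertex order.

The two channel vectors are sorted ascending (cluster labels carry no
meaning, so sorting makes the descriptor canonical and
permutation-invariant; comparisons between unsorted vectors would be
ill-defined) and combined as `M = T T' + P P'` — a symmetric, positive
semi-definite matrix of rank at most 2 whose entries mix the two
channels. The SGF channel is not normalized before combination; a
min-max switch exists for sensitivity studies but the default mirrors
the method's design of avoiding normalization artifacts.

In batch operations every model's K-means seed is the global seed
offset by a small hash of the model name, so descriptors are
reproducible and adding a model to a library never changes the other
models' descriptors.

# Grey relation similarity

Given two equal-shaped matrices, each row is reduced to its zero-start
image (subtract the first entry), rows are summed to `s(k)` and `t(k)`,
and `eps(k) = (1 + |s| + |t|) / (1 + |s| + |t| + |s - t|)`; likewise
down columns; `eta` is the average of the two directional means. The
implementation follows the formulas literally — in particular the sums
run over all columns with no endpoint half-weighting — and is checked
against an independent double-loop transcription to 1e-12 on random
matrices. Exact identities (eta = 1 iff the zero-start images agree
line-wise, symmetry, additive-shift invariance, range (0, 1]) are
property-tested.

Because the "1 +" offsets are absolute, `eta` is sensitive to the
overall numeric scale of the descriptors. This is inherited from the
printed formulas and deliberately not altered; its consequences appear
under Limitations.

# Synthetic meshes and what passing tests show

The generators provide analytic ground truth: icospheres (`kG = 1/r^2`,
`|kM| = 1/r`), tori (closed forms in the tube angle), a saddle patch
(graph-surface formulas; an exactly symmetric `kM = 0`, `kG = -4`
center), plus seeded vertex noise along normals (topology-preserving at
small sigma) and smooth random radial "blobby" deformations that mimic
the lumpiness of molecular surfaces. All randomness flows through
explicit seeds; the global RNG state is never touched.

These shapes validate curvature convergence, Gauss-Bonnet exactness
(total angle deficit `2*pi*chi` independent of vertex areas), SI
calibration, SGF formula semantics (against a brute-force per-vertex
oracle), descriptor invariances and retrieval ordering. They do not
emulate real protein surfaces' pockets, tunnels, mesh irregularity or
scanner-dependent resolution; passing tests demonstrate correctness of
the computations and their documented invariances, not retrieval
accuracy on real PDB-derived meshes, which additionally depends on the
surface generator used upstream.

# Numerical choices

* Problem sizes: unit tests run on meshes of ~160-2600 vertices;
  convergence tests go to 10242 (subdivision-5 icospheres); K-means
  oracle checks use 50 instances of a few hundred points each, sizes at
  which the exact dynamic program is comfortable.
* Duplicate-vertex merge: grid snapping at the merge tolerance
  (deterministic, order-free).
* Degenerate K-means data (all values equal): centers collapse to that
  value; the farthest-point re-seed loop is bounded so duplicate-heavy
  data cannot cycle.
* Assignment ties go to the lower cluster; boundary relocation uses the
  first minimizing position — both fixed for determinism.
* `eta` is kept at full precision internally; CSV output rounds to 4
  decimals for table display, JSON keeps full precision.
* Dendrograms use `d = 1 - eta`, the simplest monotone map from a
  (0, 1] similarity to a dissimilarity; UPGMA heights are then
  non-decreasing.

# Limitations

* **Scale edge of the umbilic guard.** The guard's absolute floor
  (`max(|k1|, |k2|, 1)`) protects flat regions but means that uniform
  rescaling across the `|k| = 1` line can switch borderline vertices
  between the formula and the limit branch. SI is exactly
  scale-invariant on either side of the line; descriptors of models
  whose curvature spectrum straddles 1 should be compared at a common
  scale (protein surfaces in Angstroms, with curvature radii well above
  1, sit safely on one side).
* **Tie-degenerate fields.** On meshes with exact symmetries a field
  may take few distinct values; if K exceeds that number the K-means
  optimum is non-unique and the descriptor depends legitimately on tie
  resolution. Real surfaces are generic; the invariance guarantees
  assume tie-free fields.
* **Scale sensitivity of `eta`, and degenerate queries.** A perfectly
  uniform field (a discretized sphere classified umbilic everywhere)
  yields a constant descriptor matrix whose zero-start images vanish;
  `eta` against such a query reduces to a function of the other model's
  own row/column spreads and orders candidates by descriptor smallness
  rather than likeness. Retrieval behaves as intended for non-degenerate
  queries (the test suite demonstrates a noisy copy of a lumpy model
  scoring 0.90 against its original versus ~0.6 for decoys) but a
  featureless query cannot be meaningfully ranked against — a direct
  consequence of the absolute offsets in the printed similarity
  formulas combined with the umbilic limit value.
* **Noise versus resolution.** Per-vertex displacement noise enters
  second-derivative estimates as roughly `sigma / h^2` for edge length
  `h`, so even sub-percent noise on a fine mesh dominates discrete
  curvature. This is a property of all local curvature estimators, not
  of this implementation; robustness to measurement noise requires
  smoothing upstream, which this package deliberately does not do.
* Mesh repair (hole filling), PDB-to-surface generation, and
  physico-chemical surface properties are out of scope.
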