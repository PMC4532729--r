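---
title: "Migration patterns on the sphere: geometry, combinatorics and polytopes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Migration patterns on the sphere}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(migpatterns)
```

## The model

A metapopulation of `n` geographically structured populations is represented
by `n` points on the unit sphere.  Because individuals migrate through
neighbouring demes, the natural structure is the Voronoi tessellation under
the great-circle metric: any migration out of a population first crosses the
boundary of its Voronoi cell.  A **migration pattern** is the 4-tuple

\[ M = (G, \Theta, W, T) \]

where `G` is the Voronoi diagram (an embedded multigraph whose faces are the
populations), `W = {w_e}` are gene-flow weights in `(0, 1)` on the edges
(in practice a nondirectional differentiation measure such as
\(F_{ST}\) between the two populations separated by the edge),
`T_i` is the **total load** of population `i` — the sum of the weights on the
boundary of its cell — and `\Theta = {\theta_e}` are the **inner
intersection angles** of the circle family attached to the dual Delaunay
triangulation.  `Theta` pins down the geographical shape of the pattern up
to Möbius transformations of the sphere; `W` carries the genetics.  The two
are deliberately kept independent: there is no accepted functional
relationship between an intersection angle and a differentiation measure,
so the package only offers the occasional `1 - x` bookkeeping convention as
an explicit helper (`complement_convention()`), never implicitly.

## Spherical geometry

`delaunay_triangulate()` uses the brute-force *empty-cap* test: a triple of
points is a Delaunay triangle if and only if all remaining points lie
strictly on one side of the plane through the three points.  All
\(\binom{n}{3}\) triples are examined, an \(O(n^4)\) procedure.  This is a
deliberate design choice rather than a shortcut:

* regional samples (the Sumba example spans under 2 degrees) put all points
  on a near-planar sliver of the sphere, a regime where projected or
  incremental constructions are fragile, while the plane-sidedness test is
  robust;
* the scale of interest (`n` up to a few tens) makes \(O(n^4)\) negligible.

Numerical choices:

* **Sidedness tolerance** `1e-12` on the signed plane distance.  A remaining
  point within tolerance of a candidate plane means four nearly cocircular
  points; the triangulation is ambiguous and the package raises a
  degeneracy error naming the four points instead of silently picking a
  diagonal.
* **Circumcenter sign**: the center of a triangle's circumcircle is the unit
  normal of its plane, signed to point at the pole of the *empty* cap (away
  from the remaining points).  This keeps the empty-circle semantics even
  for circumradii beyond \(\pi/2\), which occur routinely in the clustered
  regime (the far side of the sphere is one huge empty cap).
* **Inner angles** come from the spherical law of cosines applied to the
  triangle (center 1, shared vertex, center 2):
  \(\cos\theta = (\cos D - \cos r_1\cos r_2)/(\sin r_1 \sin r_2)\).
  The arccos argument is clamped into `[-1, 1]` when within `1e-9` of the
  boundary and is an error beyond that.  The tests cross-check this formula
  against an independent tangent-vector computation at the shared vertex.
* Degrees are accepted on input (`[-180, 360]` longitudes normalised);
  radians are used internally; the Earth is the unit sphere — every derived
  quantity is an angle, so no Earth radius is needed.

The primary correctness oracle for the whole geometry stack is **angle
conservation**: for every point set in general position, the inner angles on
the edges incident to a population sum to \(2\pi\).  The test suite checks
this at `1e-6` across uniform and cap-clustered random configurations.

## Circle-pattern (Rivin) conditions

A set of prescribed angles `Theta` is realisable as a Delaunay circle
pattern if and only if

1. around every face of the Voronoi graph (every population), the angles sum
   to exactly \(2\pi\) (`check_rivin_faces()`), and
2. along every simple closed path of the Voronoi graph that is *not* a face
   boundary, the angles sum to strictly more than \(2\pi\)
   (`check_rivin_cycles()`).

Cycle enumeration is exhaustive up to `max_cycle_len` (default 8, exhaustive
enough for graphs of the worked example's size; the count is exponential in
general, so the cap is exposed).  Face boundaries are recognised by their
edge-label sets and excluded even when their sum is exactly \(2\pi\).

Default tolerances: `1e-6` against angles computed by this package, `1e-5`
when validating a table of angles printed to 7 significant figures.  The
upper bound \(\theta < \pi\) is enforced throughout: an inner intersection
angle of two distinct circles is strictly below \(\pi\), and all reference
values obey it.

## The worked example

The shipped fixture (`load_sumba()`) contains eight Sumba populations and 18
F_ST-weighted edges.  From the coordinates alone the package reproduces 12
triangles, 18 edges out of 56 candidate triples, all 18 reference angles to
better than `1e-4` rad, and the eight \(2\pi\) face sums.

One bookkeeping subtlety is worth recording.  The conventional labelling of
the 18 edges was recovered from the reference angle table by matching
recomputed angles (the match is unique; all angles differ by far more than
the rounding).  Under that matching, edge 17 joins **Kodi and Rindi**.  The
stored reference totals for Wunga and Rindi, however, were evidently derived
under an assignment of edge 17 to Wunga: they differ from the
computed-incidence sums by exactly `w17 = 0.00891` (Wunga
`0.16380` vs `0.17271` stored; Rindi `0.05171` vs `0.0428` stored), and the
two errors cancel in the global identity \(\sum_i T_i = 2\sum_e w_e\), which
both versions satisfy.  The package always takes incidence from the
computed triangulation — the face sums close to \(2\pi\) only under that
assignment — so its Wunga and Rindi totals intentionally disagree with the
stored reference values; the acceptance tests document this as an expected
discrepancy rather than masking it.

```{r sumba}
sb <- load_sumba()
pattern <- assemble_pattern(sb$populations, sb$edges)
round(pattern$loads, 5)
max(check_rivin_faces(pattern))
nrow(check_rivin_cycles(pattern, max_cycle_len = 8))
```

## The combinatorial space

Embedded multigraphs are encoded as **combinatorial maps** (rotation
systems): a permutation `sigma` giving the counterclockwise successor of
each dart around its vertex and an involution `alpha` pairing the darts of
each edge.  Faces are the orbits of `sigma(alpha(.))`, and the constructor
enforces connectedness, the Euler relation \(V - E + F = 2\), at least two
vertices, and the no-self-loop rule (a population fully enclosed by another
is excluded from the model).

Equivalence is sphere homeomorphism, which includes reflections, so
`canonical_code()` minimises a breadth-first encoding over all starting
darts *and both orientations*.  The code is a complete invariant at these
sizes and is what all enumeration and transition classification compare.

Three moves connect the space: **contraction** of an edge (refused when it
would collapse the last two vertices or turn a parallel edge into a
self-loop), its inverse **expansion** of a vertex of degree at least four
along a contiguous 2+2-or-larger arc split (the two daughter valences sum to
the original valence plus two), and the **Whitehead move** on an edge of a
cubic map — contraction immediately followed by the only other expansion.

`enumerate_combms(n)` builds the space layer by layer: the cubic layer 0 is
the Whitehead closure of the prism generator `CL_n` (`C_3` for `n = 3`), and
layer `k + 1` consists of all admissible contractions of layer `k`.  Depth
is well defined as `(3n - 6) - E`.  Counting edges from the cubic `3n - 6`
down to the two-vertex graph `C_n` with `n` edges gives a deepest layer at
depth `2n - 6`; a naive count of "moves to the bottom" is sometimes quoted
as `2n - 5`, but the four-face case already shows two contractions (not
three) from either cubic map to `C_4`, so the package uses `2n - 6`
throughout.  For reference: `CombMS(3)` has 1 graph, `CombMS(4)` has 4
(2 cubic + 1 + 1), `CombMS(5)` has 22, `CombMS(6)` has 209.

Expansion moves alone do **not** generate the space: already for `n = 5`,
10 of the 22 graphs cannot be reached from `C_5` by expansions only, while
mixed contraction/expansion sequences reach everything.  The test suite
verifies this by comparing breadth-first closures.

## Linear systems and polytopes

For a labelled migration graph with loads `T`, the **load system**
`build_load_system()` has one variable per edge in `[0, 1]` and one equality
per population: incident variables sum to `T_i`.  The open pattern space
(strict `0 < x < 1`) is represented by the closed polytope plus
`interior_point()`, which maximises the minimum bound slack within the
equality subspace (a Chebyshev-style criterion); an empty relative interior
means no open pattern exists on that graph.  The **angle system**
`build_angle_system()` uses bounds `[0, pi]`, face equalities at \(2\pi\),
and one `>= 2*pi` row per non-facial cycle up to the configurable cap —
with the cap it is an outer approximation of the full circle-pattern
polytope.

No linear-programming package is available in the target environment, so
the package carries a small dense two-phase simplex (Bland's rule, `1e-9`
tolerances); the systems involved have tens of columns at most.  Vertex
enumeration is brute force over active-bound subsets (capped at 24
variables) and is cross-checked in the tests against an exact rational
Gaussian elimination written independently for that purpose.

`build_complex()` glues the load polytopes of labelled cubic maps into the
polytope complex: breadth-first closure under Whitehead moves with labels
inherited (the pivot edge keeps its label), one polytope per distinct
labelled map.  Each move records the contracted graph it factors through;
the corresponding shared facet is `x_e = 0`, and the tests verify as a set
identity that the facet's vertices coincide in both adjacent polytopes.
Nodes are deduplicated by a labelled canonical code that includes the
per-face loads; symmetric labelings that survive the quotient by map
automorphism are retained as distinct coordinate charts (the further
quotient by sphere symmetries is out of scope).  Because each face carries
its population's load, faces are tracked across moves by dart persistence:
every dart except the two pivot darts keeps its face through a Whitehead
move, so majority ownership is exact; an ambiguous correspondence raises an
error rather than guessing.

The labelled complex grows factorially with `n` (labelings of every cubic
map), so `build_complex()` refuses face counts above `n_cap = 6` and guards
the closure with `max_nodes`.

## Dynamics: splits, mergers, and paths

`split_population()` places the two daughters symmetrically at
\(\pm\epsilon/2\) along the bearing great circle.  A one-sided placement
(one daughter at the ancestor, one at distance \(\epsilon\)) would be
equally faithful to the limiting picture; the symmetric choice keeps the
spherical midpoint at the ancestor, which makes `merge_populations()` an
*exact* inverse — a property the tests rely on.  For generic small
\(\epsilon\) the complex gains exactly one vertex, three edges and two
triangles (forced by the Euler relation once one vertex is added), and the
Voronoi side gains one face: populations and faces stay in bijection.

How `W` and `T` transform across a split is genuinely unspecified by the
theory; `split_population(weights = ...)` therefore applies a documented,
overridable convention — each daughter inherits the weight of every
ancestral edge it retains, and edges with no ancestral counterpart
(including the daughter–daughter edge) receive half the smallest weight
that was incident to the ancestor — and the documentation flags this as
extrapolation rather than asserting a model.

`classify_transition()` names the move between two snapshots by canonical
codes (equal codes → `none`; face counts differing by one → `split`/`merge`;
cubic maps related by one move → `whitehead` with the pivot found by
exhaustive search; edge counts differing by one → `contraction`/
`expansion`).  `detect_facet_crossing()` interpolates linearly between
sampled weight vectors within a fixed-graph segment — the theory treats the
path as a continuous curve but prescribes no parametric form, so piecewise
linearity is the minimal assumption — and reports each coordinate's arrival
at 0 or 1, the contraction-eligible events.  States whose per-population
sums drift from the segment's loads are an inconsistent path and an error,
since total flow at each population is constant while the graph is fixed.

## The synthetic generator

`random_points()` emulates two regimes: isotropic points on the whole
sphere (the global null) and area-uniform points inside a spherical cap
(default radius 1 degree, the regional island regime of the worked
example, which stresses the near-coplanar code paths).  It does **not**
emulate coastlines, barriers, spatially correlated weights, or any genetic
model — a green property test therefore establishes the geometric and
combinatorial invariants (counts, \(2\pi\) conservation, duality,
move/inverse identities), not anything about real gene flow.  All
randomness flows through the single integer seed, and the caller's RNG
state is restored afterwards.

## Known limitations

* Triangulation is \(O(n^4)\); enumeration is practical to `n = 8` faces
  and the labelled polytope complex to 6.
* The angle polytope is truncated at `max_cycle_len`; it is exact only when
  the cap reaches the longest non-facial cycle.
* No quotient of the complex by the Möbius group, no directed flows, and no
  estimation of \(F_{ST}\) from genotypes — weights are exogenous inputs.
* Exactly cocircular point quadruples are refused, not perturbed.
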