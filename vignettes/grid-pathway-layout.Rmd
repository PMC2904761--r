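---
title: "Grid layout of pathways under sub-cellular constraints: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grid layout of pathways under sub-cellular constraints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathgrid)
```

## The model

A pathway is an undirected graph whose nodes carry a sub-cellular
localization tag. A layout is an injective assignment `P` of nodes to the
points of an `h × w` integer grid, restricted so that each node sits inside
the compartment region bound to its tag. Regions are rectangles, ovals
(ellipse inequality, boundary inclusive), or annuli — the ring of points
inside an outer boundary but not inside-or-on an inner one — which is how
membranes are modelled: a plasma membrane is a one-unit-wide rectangular
frame, a nuclear membrane an oval ring.

The layout quality is a single scalar cost: spring forces plus crossing
penalties,

$$C(P) = w_a \sum_{(u,v) \in E} F_a(d_{uv}) + w_r \sum_{\{u,v\}} F_r(d_{uv})
 + w_e\,X_{ee}(P) + w_n\,X_{ne}(P) + S(P, l),$$

with Euclidean distances in grid units, $F_a(d) = d^2$, $F_r(d) = 1/d^2$,
$X_{ee}$ the number of edge-edge crossings, $X_{ne}$ the number of node-edge
crossings, and $S$ a surface penalty that is active only in the
dynamic-compartment mode (below). The attraction sum counts each edge once
and the repulsion sum each unordered pair once; the convention matters
because it makes the default weight relation $w_n = 2 w_e$ meaningful as
stated. Whether the original double-sum formulation intends each adjacent
pair once or twice is not recoverable; each-edge-once is declared here, and
any constant factor is absorbed by $w_a$.

Crossing counts are exact and purely combinatorial:

* two edges cross iff the **open interiors** of their segments intersect —
  a proper crossing or a collinear overlap of positive length. Segments
  that merely touch at an endpoint count zero: edge pairs sharing a graph
  endpoint cross unavoidably and uninformatively, and a T-junction's
  touching point is a node, which the node-edge counter charges instead;
* a node-edge crossing is a node lying strictly inside another edge's
  segment.

All predicates are integer orientation tests (exact in doubles far below
$2^{53}$); there is no floating-point geometry in the counters.

## The search

Finding the optimal assignment is a hard combinatorial problem even with
crossings alone, so the optimizer is greedy: at each step it applies the
single (node, vacant admissible grid point) move with the most negative
cost delta, until no move improves the cost by more than the tolerance
(`1e-9`). Because every accepted move strictly decreases a cost that is
bounded below, termination is guaranteed; `max_steps` (default `10·|V|`
accepted moves) is a safety cap only. Ties break lexicographically on
(node id, row, col) so runs are reproducible; the seed only randomizes the
initial layout.

Evaluating all `|V| · h · w` candidate deltas from scratch each step would
be prohibitive. The caches are:

* **repulsion field** — $\mathrm{field}(q) = \sum_u F_r(d(q, P(u)))$ over
  all grid points, with zero-distance self terms dropped so the field is
  finite everywhere; moving one node updates it with one subtraction and
  one addition per grid point, and the repulsion delta of any candidate is
  then an O(1) lookup;
* **attraction deltas** — a move changes these only for the moved node and
  its neighbours (their shared edge lengths are the only ones affected);
  exactly those columns are recomputed;
* **crossing deltas** — per (node, point) integer tables maintained in C++.
  After `v` moves, columns for `v` and its neighbours are rebuilt, and
  every other node's column is adjusted by exactly the terms that involve
  `v`'s node or `v`'s edges at the old versus new geometry (the
  edge-edge interactions between the two nodes' edge sets, the moved node
  on the other's candidate edges, and the other node's candidate point on
  the moved edges). Node-on-segment terms are accumulated by walking the
  1-D lattice ray they live on rather than scanning the whole grid.

The central engineering claim — that after every move the incremental
caches equal a from-scratch rebuild — is asserted wholesale in the test
suite (50 random instances, every accepted move, bit-exact for the integer
tables). Floating-point accumulation drift in the real-valued caches is
bounded by a full recompute every 200 accepted moves; this is cheap
insurance, not a correctness requirement at test sizes.

The two typographically lost attraction-update formulas in the source
material are reconstructed from their stated contract (non-adjacent nodes'
deltas are unchanged by a move) and validated against the recompute oracle
rather than transcribed.

## Compartment dynamics (GDC)

User-drawn compartments are rarely the right size for the nodes they end
up holding. In GDC mode the search interleaves one optimization pass (up
to `|V|` accepted moves) with one compartment update round:

1. **Resize.** For each movable compartment, the spread of its nodes about
   their center of gravity is summarized per axis as `s_v`, `s_h`; the
   default statistic is twice the maximum deviation (a full-extent proxy),
   with twice the mean deviation available behind `spread_method = "mean"` —
   the printed formula is lost in the source text, so the statistic is a
   declared reconstruction with an oracle-checkable contract. If the spread
   fills under 40% of the compartment in **both** axes it shrinks by 0.95;
   if it exceeds 90% in **either** axis it grows by 1/0.95. (The source
   pairs the vertical spread with the compartment *width*; that is treated
   as a typo and spreads are compared dimension-consistently.) Sizes are
   clamped to `[0.6, 1.5] ×` the original: the stated rule only blocks
   shrinking *below* 0.6, which would permit a final 0.95-step past the
   bound, so the bound is enforced as a clamp and a compartment at a bound
   keeps its size.
2. **Reposition.** Candidate centers are grid points within Manhattan
   distance 10 of the (discretized) center of gravity, scanned in order of
   increasing distance with (row, col) tie-break. A candidate is valid if
   every node still satisfies its localization under the new geometry, no
   sibling compartments' bounding rectangles overlap, and the compartment
   stays inside its `within` parent. If nothing is valid the size change is
   reverted and the scan retried; failing that, geometry is left untouched.

The overlap test is the classical corner-in-rectangle check, kept as
formulated even though it misses the cross-shaped overlap of two rectangles
(no corner of either inside the other); `overlap_mode = "strict"` switches
to full interval intersection. Overlap is only meaningful between siblings:
nested compartments (cell inside the canvas, organelles inside the
cytoplasm) overlap by construction, so the rule applies to compartments
sharing a `within` parent, which is exactly the movable organelles in the
bundled scene.

Nodes parked against a compartment surface would veto every resize, so
each node within one grid unit of a movable compartment's surface (a point
whose 4-neighbourhood straddles the boundary) costs $\alpha e^{-\beta l}$,
with $\alpha = 20(w + h)$ by default, $\beta = 0.002$, and `l` the number
of completed update rounds. Early on this is a strong repellent; since it
decays to zero it cannot prevent convergence. In observed runs the final
layouts keep all nodes off the movable surfaces, so the terminal penalty is
exactly zero. With no movable compartment the penalty is identically zero
and GDC reduces — bit-exactly, same seed — to the plain optimizer.

## The spring baseline

`spring_run()` is a standard continuous force-directed embedder with the
same force pair: each node is displaced along its net force, capped by a
step size that cools linearly over the iterations (default 500), clamped
to the canvas, with coincident nodes jittered apart. The exact update rule
of the classical algorithm is not fixed by the source material; only the
force functions are. The baseline deliberately ignores localization. Its
own crossing metrics are measured on the continuous segments; for
like-for-like comparisons with grid layouts, `snap_layout()` rounds the
result to the lattice first (snapping can create coincident nodes and
collinear overlaps, which the exact counters handle).

A practical note from the bundled experiments: whether the unconstrained
grid optimizer or the spring baseline yields fewer crossings is sensitive
to the crossing weights and to how well the baseline is converged — with
`w_e = 10` the two are within a few crossings of each other either way on
84-node synthetic pathways, with `w_e = 50` the grid optimizer tends to
win. The experiment harness reports both rather than asserting a direction.

## Synthetic pathways

`generate_pathway()` emulates curated signalling models at their observed
scales (roughly 53–221 nodes, average degree 2.2–2.5): a preferential
attachment tree plus uniform extra edges gives connectivity and a
heavy-tailed degree sequence; localization tags are drawn i.i.d. from a mix
defaulting to 5% extracellular, 15% plasma membrane, 50% cytoplasm, 20%
nucleus, 10% mitochondria. The bundled scene nests extracellular margin,
membrane ring, cytoplasm (organelles carved out), and movable nucleus and
mitochondria ovals sized so each region comfortably holds its expected node
count. `grid_dims()` implements the square-root sizing rule with
`(h + w)/sqrt(|V|) ≈ 7`, inside the 6.5–11 range of the reference models.

What the generator does *not* emulate: reaction semantics, edge directions,
node glyph sizes, or the near-planarity of hand-curated maps. Tests passing
on these graphs therefore certify the algorithmic contracts (exact
counting, cache equivalence, monotone convergence, constraint satisfaction,
compartment invariants) — not drawing aesthetics on real curated models.

## Numerical choices and problem sizes

* Convergence tolerance `1e-9` on deltas; strictly-decreasing cost traces
  are asserted in tests.
* Oval membership uses the ellipse inequality with a `1e-9` slack so
  boundary points count as inside; annulus regions exclude the inner
  boundary (a width-1 ring is exactly the outline points).
* Degenerate segments (possible after snapping a spring layout) cross
  nothing and contain nothing.
* The test and acceptance workloads use 50-node constrained runs, 84-node
  unconstrained comparisons on a 39 × 29 grid, and 100/50-instance oracle
  sweeps at up to 15 nodes — sizes chosen so the full suite completes in a
  few minutes on one CPU while still exercising every code path at the
  reference models' scale.

## Known limitations

* Single-node moves only: no node-pair swaps, no simulated annealing, so
  the optimizer can stop in local optima that a swap would escape.
* Straight edges only; no bend points.
* Compartments must be placed by the user (or the bundled scene); initial
  automatic placement is out of scope.
* The corner-based overlap test inherits a known false negative (kept for
  fidelity; strict mode available).
* Uniformity of `random_layout()` is per-draw over admissible vacant
  points in a random node order, which is not exactly uniform over all
  injective admissible assignments in pathological geometries.
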