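---
title: "Mechanical tissue simulation with curved cell boundaries: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mechanical tissue simulation with curved cell boundaries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`epitissue` simulates monolayered epithelial tissues in two dimensions. A
cell is a spatial region bounded by straight *inner edges* (walls shared
with neighboring cells) and circular-arc *outer edges* (free boundaries
facing the medium). An isolated cell is a disk; a cell in a confluent sheet
is a polygon; cells at the tissue margin are polygons with one or more arcs.
The underlying physics is soap-film energy minimization: every wall carries
a line tension `eta(i,j)` (free walls `eta(i,0)`), every cell an internal
pressure, and the tissue evolves quasi-statically — at the end of every time
step all vertex forces balance to within a tolerance.

Lengths are measured in units of the nominal cell diameter `d0` (1 unit =
10 µm); the nominal cell area `a0 = pi/4` is the area of a disk of diameter
one. Tensions are measured in an arbitrary force unit with the default wall
tension equal to one; pressures are force per length.

The state is stored on a half-edge mesh: every physical edge is two directed
half-edges with `twin`, `next` and owning-cell pointers, so the neighbors of
a cell are enumerated in time proportional to its number of sides and every
topological event is a local pointer surgery. Exactly three half-edge cycles
pass through every junction vertex; configurations that would create a
higher-degree vertex are resolved immediately by the topological events
below.

### Forces

The force on a junction vertex is the sum over its three incident edges of

* a **tension force**: for an inner edge, magnitude `eta(i,j)` at each
  endpoint directed along the edge toward the other endpoint; for an arc,
  magnitude `eta(i,0)` along the arc tangent in the direction that shortens
  the arc. In the default `constant` scaling the magnitude is `eta` itself
  (wall energy = tension × length, the soap-film convention); the
  alternative `length` scaling multiplies by the edge length.
* a **pressure force** on inner edges only: `(P_i - P_j) |e| / 2` at each
  endpoint along the wall normal, pushing toward the lower-pressure cell.
  Arcs feel no pressure force; the internal pressure of a boundary cell is
  balanced by the curvature of its free boundary, which is the Laplace law
  `P_i = eta(i,0) / r_i` with `r_i` the (signed) arc radius.

The `constant` convention is the one under which the Laplace law, the equal
doublet contact angle `2 acos(eta_in / (2 eta_out))` and the detachment
threshold `eta_in = 2 eta_out` all come out exactly; the package verifies
the doublet angle to a fraction of a degree in its test suite.

### Growth and the quasi-static step

A time step prescribes a signed area change for every cell. The change is
introduced in `k` equal increments (default 20); after each increment the
interior-cell pressures are solved so that the first-order area change of
every fully polygonal cell matches its target. Because vertex forces are
affine in the pressures, this is a linear system; it is symmetric
positive-definite (a Gram matrix of cell-area gradients) and is solved
matrix-free by preconditioned conjugate gradients inside the compiled core.
Boundary-cell pressures follow the Laplace law from their arc radius, and
the shared radius of a cell's arcs relaxes toward the value that restores
the cell's target area (see *Numerical choices*). After the last increment,
iteration continues at constant areas until the largest vertex force drops
below `epsilon` or the iteration budget is spent; non-convergence is
reported in the step report, never thrown.

The signed first-order area change of a cell under a vertex displacement
field — the quantity the pressure solve controls — is
`(sigma/2) * sum over edges of (F_a + F_b) x e` (a cross product per edge).
It is implemented signed, so prescribed shrinkage works the same way as
growth; the test suite checks it against finite differences with the
expected `O(sigma^2)` error decay.

### Topological events

Six primitives cover every topological change of a growing monolayer:

* **contact** (edge insertion): two overlapping free boundaries are joined
  by a new inner edge between the circle intersection points;
* **T1 edge flip**: an inner edge shorter than `t1_length` whose endpoint
  forces are not pulling it open is replaced by a perpendicular edge between
  the two cells that previously met it only at its endpoints. Two margin
  variants exist: a collapsing wall with one endpoint on the tissue boundary
  detaches the two wall cells and gives the third cell a short free
  boundary, and conversely a free arc whose chord collapses (a closing
  boundary wedge) becomes a wall between the two adjacent cells;
* **T2 void removal**: a three-sided void below `t2_area` collapses to a
  single degree-3 vertex;
* **division**: a chord at a given or random orientation, translated until
  the two parts are equal to 0.1%, becomes a new wall; daughter areas sum
  exactly to the mother's at insertion;
* **birth**: a new isolated disk;
* **death**: two-phase apoptosis — prescribed shrinkage followed, below 5%
  of the nominal area, by removal; the neighbors' walls become free
  boundaries that bulge into the hole and mechanics closes it.

Events are detected between relaxation sub-iterations and applied in a fixed
order (contacts, flips, voids, deaths, ascending ids), so identical runs
replay identically.

## Parameters

| parameter | default | units | meaning |
|---|---|---|---|
| `sigma` | 0.01 | d0² per force | relaxation step constant |
| `epsilon` | 1e-3 | force | stationarity threshold on the max vertex force |
| `k` | 20 | — | increments per growth step |
| `t1_length` | 0.05 | d0 | edge length triggering a T1 flip |
| `t2_area` | 1e-3·a0 | d0² | void area triggering a T2 collapse |
| `contact_tol` | 0.02 | d0 | overlap depth triggering a contact |
| `max_iter` | 5000 | — | iteration budget per step |

`contact_tol` is deliberately large enough that a fresh contact edge is
longer than `t1_length`; with a smaller trigger the contact, flip and
detachment events can cycle. The default tension table sets every wall and
free-boundary tension to one, which gives 120° junctions; type-dependent
tensions (e.g. stronger adhesion between like cells) are supplied through
`tension_table()`.

## Numerical choices

* **Relaxation** uses FIRE (fast inertial relaxation engine): semi-implicit
  Euler with velocity mixing and an adaptive time step in
  `[0.02 sigma, 50 sigma]`, quenched whenever a topological event fires.
  Per-vertex displacements are capped at a fraction (20%) of the shortest
  incident element so that stiff features — deep small arcs, short walls —
  advance in small steps without throttling the rest of the tissue; the cap
  also guarantees no element can invert between event checks.
* **Free-boundary bulges** are parameterized by the sagitta of the
  largest-chord arc, which is smooth across the minor/major/inward branches,
  and relax toward the target-area fit under the same displacement cap
  rather than being re-fit instantaneously: the instantaneous fit makes the
  boundary pressure an extremely stiff function of the junction positions
  and sets off oscillations. At stationarity the fit is exact, so the
  Laplace law and the prescribed areas hold together.
* **Inward bulges** (negative arc radius, negative Laplace pressure) arise
  for overfull boundary cells and for cells bulging into the hole left by a
  dead neighbor; cells with a single free boundary may carry arcs spanning
  more than half a circle (lens cells after first contact).
* **Frustrated junctions**: a near-fourfold vertex wants both diagonals
  short; an edge created by a flip is therefore exempt from re-flipping for
  the remainder of the step, and an edge being pulled open is never flipped.
* **Degenerate division planes** (strongly non-convex transients) are
  deferred with a warning and retried at the next step.
* The pure-R mechanics (`assemble_forces()`, `solve_pressures()`,
  `volume_rate()`) is the readable reference; the compiled core is checked
  against it in the tests.

## The bristle patterning model

An epidermis is grown from a two-cell doublet; every cycling cell grows by
`0.1 a0` per step (times a fixed per-cell factor drawn uniformly in
1 ± 0.25, which desynchronizes divisions) and divides at twice its birth
area. Once the tissue exceeds 50 cells, a commitment pass runs every step:
each uncommitted, permissive cell with no bristle within `R` layers (graph
distance on the adjacency graph) becomes a bristle with probability
`p_commit = 0.02`, in seeded random order, and immediately inhibits its
`R`-layer neighborhood. Committed bristles stop growing and dividing. The
five mechanisms differ only in `R` (0 none, 1 contact inhibition, 2–4
soluble-factor inhibition field) and in whether commitment is restricted to
expression stripes.

The inhibition range derives from the steady state of diffusion with linear
degradation, `c(x) = exp(-x sqrt(k_deg / D))`: the reach is the distance
where `c` falls to the response threshold 0.05, the degradation rate is
calibrated once so that `D = 1.2 µm²/s` reaches 10 µm, and reach converts to
layers by dividing by the 10 µm cell diameter (ceiling).

Stripes are *material*: each cell is assigned its band the first time
commitment sees it and daughters inherit the label, so the bands stretch
with the tissue exactly as gene-expression stripes would; with bands fixed
in space, radial growth would carry every committed bristle away from its
midline and the measured alignment would reflect only that drift. The
alignment index is the grand mean over bristles of the per-bristle offset
`d = round(|x - x_mid| / wbar)` from the midline of the bristle's stripe
(drawn through the stripe's own permissive cells, row by row), with `wbar`
the measured mean cell diameter; the fraction with `d = 0` is reported
alongside. The grand-mean normalization (rather than a sum of per-stripe
means) is the reading consistent with the reported statistics. The literal
"count the cells strictly between" variant is available
(`offset_method = "count"`) but on a disordered tissue its metric row
window admits spurious cells and inflates the index.

What the generator does *not* emulate: explicit ac/Dl/N expression dynamics
within stripes (commitment is uniform inside the permissive band), cell
shape changes of committed bristles, and any anisotropy of growth. Passing
tests therefore show that exclusion geometry and band restriction reproduce
the reported pattern statistics, not that the gene circuit itself does.

## The size-control model

Stem (S), progenitor (P) and differentiated (D) cells start as a relaxed
64-cell patch (10 S centered, 16 P around them, 38 D outside). S divide
without limit, P at most twice (second division always symmetric), D never.
Division happens when a cell's area doubles; the division type is sampled
from probabilities with basal value 1/3 each. Growth rates and the two
probability triples are inhibited by the number `N_D` of differentiated
cells within `L` layers through Hill factors `basal / (1 + coeff * N_D)`,
the triples renormalized to sum to one.

Defaults: basal growth `1.0 a0` per step; growth-rate coefficients
`gS = gP = 2`; and, for the division types, the *differentiative* divisions
are inhibited (`hSs = hSa = hPs = hPa = 2`) while self-renewal is not
(`hSr = hPr = 0`). The structure matters: if all probability coefficients
are equal, the renormalized triple never moves and the division-type
feedback is inert. With renewal left free, a stem cell surrounded by many
differentiated neighbors quietly self-renews — no new progenitors, no new
differentiated cells — which is what arrests tissue growth while keeping a
regeneration-competent pool. The feedback's dynamic range is bounded
(`N_D` saturates around 36 at `L = 3`), and the coefficients are chosen
(before any acceptance run) so it separates an early growing phase from an
arrested late phase. The inhibition range `L` then decides the outcome:
at `L = 2`, margin cells never see enough D cells and growth continues; at
`L = 3`, the tissue plateaus with a surviving stem pool; at `L = 4`, growth
is suppressed early and the tissue stays small. Removing the inhibition of
symmetric differentiation lets `S -> (P, P)` dominate at high `N_D` and
depletes the stem pool; removing the inhibition of asymmetric division lets
`S -> (S, P)` dominate, preserving the pool while feeding a persistent
progenitor stream. These comparisons are rank-order properties over seeds,
which is how the tests treat them.

## Problem sizes

The test suite runs its growth experiments at reduced sizes — tissues of a
few hundred to ~800 cells for patterning statistics, 120–150 steps for the
size-control orderings — and the acceptance script grows three seeds per
condition to about 700 cells with a per-step iteration budget of 2500.
Bristle fraction and alignment are intensive statistics and stable in tissue
size at these scales; the size-control checks are rank-order by design.

## Known limitations

* Inner walls are straight; the constant-curvature wall shape is not
  resolved (its curvature is small at moderate pressure differences).
* Multi-arc cells use the minor branch for every arc; a cell whose several
  free boundaries each wrap more than a half circle is not representable.
* The quasi-static contract is enforced up to the per-step iteration
  budget; a step that exhausts it reports non-convergence and the residual
  is relaxed in subsequent steps.
* Stripes deform only through cell motion and division; there is no
  re-specification of bands after the initial assignment.
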