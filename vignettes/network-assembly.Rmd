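---
title: "Coarse-grained self-assembly of collagen-IV-like 2D networks: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coarse-grained self-assembly of collagen-IV-like 2D networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(colweb)
```

## The model

`colweb` simulates the self-assembly of collagen-IV-like molecules into
two-dimensional networks, such as the basement-membrane meshworks of the
ocular lens capsule, and analyses the resulting ring (polygon) structure.

Each molecule is a coarse-grained worm-like chain with patchy-particle
ends: a straight string of beads joined by stiff harmonic bonds
(`U = 1/2 kl (r - r0)^2`), with each adjacent bead triple constrained by a
harmonic angle term (`U = 1/2 k_theta (theta - theta0)^2`, `theta0 = pi`
for a straight chain). The two terminal beads are *heads* - single-bead
stand-ins for the terminal interaction domains (the 7S and NC1 domains are
deliberately merged into one chemistry). Heads attract each other through a
full 12-6 Lennard-Jones potential of depth `eps_hh` and range `sigma_hh`;
body beads repel through the same 12-6 form truncated at `sigma_bb` (purely
repulsive excluded volume); head-body cross terms are identically zero.
Both harmonic terms use the 1/2-prefactor convention - the printed value of
`kl` is only meaningful together with it.

The solvent is implicit: a Langevin thermostat adds a drag `-(m/gamma) v`
and a fluctuation-dissipation-matched Brownian force to the conservative
forces. Two numbers tie the model to thermal physics: `eps_hh` equals
`kB x 300 K` to three significant figures, so heating to 300 K melts every
head-head bond, while at the 30 K base temperature a head bond is worth
about 10 `kB T` and is effectively irreversible - the "thermally
irreversible node formation" regime in which collagen IV networks are
believed to assemble.

## Parameters and their defaults

| symbol | meaning | default | unit |
|---|---|---|---|
| `kl` | bond spring constant | 1.657e-4 | N/m |
| `k_theta` | angle stiffness | 200e-21 | J |
| `theta0` | rest angle (intrinsic curvature) | pi | rad |
| `eps_hh` | head-head well depth | 4.142e-21 | J |
| `sigma_hh` | head-head range | 50 | nm |
| `rc_hh` | head-head cutoff | 150 | nm |
| `eps_bb` | body-body scale | 16.142e-21 | J |
| `sigma_bb` | body-body range (= cutoff) | 137.5 | nm |
| `l_eqm` | molecule rest length | 300 | nm |
| `bond_rest` | per-bond rest length | 60 | nm |
| `m` | bead mass | 1e-21 | kg |
| `dt` | timestep | `2 pi sqrt(m/kl) / 50` (~0.31 ns) | us |
| `gamma` | Langevin damping time | `100 dt` | us |
| `p_target` | barostat pressure | 20 | Pa |
| `lz0` | nominal out-of-plane thickness | 1.5 | nm |

The force-field energy and length scales are the published operating point
of the model. The remaining choices are the package's own and deserve
explanation:

**Bead count per molecule.** Only the end-to-end length (300 nm) is a
physical datum; the discretisation is free. We use five 60-nm bonds
(H-B-B-B-B-H) because that spacing realises the design intent of the
printed `sigma` values. With heads bound at their pair minimum
(`2^(1/6) sigma_hh ~ 56 nm`), the innermost body beads of the molecular
arms meeting at a node sit on a ring whose adjacent spacing is about
160 nm for three arms (outside the 137.5 nm repulsion - easy), 139 nm for
four (marginal) and 122 nm for five (prohibitive): the excluded volume
genuinely "favours k = 3" and caps coordination near four, which matches
the observed coordination statistics. Coarser discretisations (100 nm
beads) leave gaps that admit 5-6 arms per node and produce high-degree
clumps; finer ones (50 nm) make even three arms marginal and stall
assembly. Intramolecular pairs separated by one or two bonds are excluded
from non-bonded interactions; with 60-nm bonds the nearest *included* pair
sits at 180 nm > `sigma_bb`, so a straight molecule is exactly at zero
conservative energy.

**Mass, timestep, damping.** None are physical observables here; they set
the clock. `m = 1e-21` kg gives a bond period of ~15.4 ns, the timestep
resolves it 50-fold, and `gamma = 100 dt` keeps `dt << gamma`. Weaker drag
was tested and *slows* network formation: head capture is
dissipation-limited (a colliding pair must shed ~`eps_hh` within one well
crossing to stick), so the default sits near the efficient-capture regime.

**Langevin discretisation.** The drag-plus-noise force is integrated with
the BAOAB splitting: the Ornstein-Uhlenbeck part (`v -> c v + sqrt(kB T/m
(1 - c^2)) xi`, `c = exp(-dt/gamma)`) is applied exactly between the two
velocity-Verlet half-kicks. A plain impulse-noise discretisation was found
to overheat the stiff bond modes by ~8% and to lag temperature ramps; the
exact OU map keeps the stationary kinetic temperature within the 2%
fluctuation-dissipation contract even for bonded systems.

**Pressure convention.** The 2D system is treated as living in a 3D cell of
nominal thickness `lz0`, so the barostat target "20 Pa" means an in-plane
tension of `p x lz0`. We fix `lz0` at 1.5 nm, the physical width of a
collagen IV triple helix - the natural slab thickness of the quasi-2D
system. As a cross-check, the molecular densities this produces at 20 Pa
(~1.3-1.7e-5 molecules/nm^2) are consistent with the densities implied by
the published mean polygon areas. The barostat itself is a weak-coupling
(Berendsen-type) isotropic rescale with the per-step scale factor clamped
at 2e-4; during this stage temperature is held by a deterministic
velocity-rescale coupling instead of the Langevin thermostat, and once the
stage ends the cell is frozen for good. Only the stationary pressure
matters for its role (picking a physical density), which is why a
weak-coupling barostat suffices.

**Overlap floor.** Non-bonded pairs closer than `0.7 sigma` (a barrier of
~256 `eps`, unreachable dynamically) are evaluated at the floor distance.
This caps the force on pathological initial states without altering any
reachable physics; occurrences are counted and warned about.

## The melt-cool protocol

`run_protocol()` executes: square-grid initialisation (pitch `l_eqm + 100`
nm, molecules horizontal); 4 us of capped-displacement pre-equilibration at
30 K (at most 10 nm of motion per step, mirroring the usual guard against
exploding initial configurations); 36 us of Langevin equilibration at 30 K
- the drive to bond is strong enough that a proto-network forms already
here; 40 us of constant-pressure relaxation at 30 K and 20 Pa; cell
freeze; linear heating to 300 K over 100 us, which melts the proto-network;
and linear cooling back to 30 K over `t_cool` (default 100 us), during
which the network self-assembles. All durations are configurable, and
`duration_scale` shortens every stage proportionally.

A note on the melt criterion: at 300 K the head bonds are thermally
reversible (`eps_hh = kB T`), but an instantaneous snapshot of a liquid at
this density still shows transient head pairs within the 75-nm clustering
cutoff. "Fully melted" therefore manifests as a large majority of
degree-1 nodes with a small, fluctuating population of transient contacts -
not literally 100% - and that is what the tests assert.

## Desk-scale study conditions

The published headline numbers are means over ten replicates of 400
molecules with ~300 us protocols. The package's test suite and acceptance
script run a reduced condition chosen once: 10 x 10 molecules with all
stage durations scaled by 0.5 (0.25 for edge-length observables, which
converge much earlier than the coordination number). Assembly kinetics do
not accelerate with the schedule - the association window at the cold end
of the ramp is what it is - so scaled-down runs systematically
under-coordinate relative to the full protocol (full-duration runs reach
within ~5% of the published mean coordination). Trend comparisons
(cooling-rate, pressure, interaction-strength, tangle-fraction scans) are
robust to this; absolute coordination numbers carry the scale-down bias and
are compared with correspondingly wider tolerances.

## Network extraction and polygon assignment

Nodes are single-linkage clusters of head beads: union-find over head pairs
within `rc = 1.5 sigma_hh = 75 nm` (minimum image), safely above the
head-pair minimum at ~56 nm and below the body scale. Node positions are
periodic circular-mean centroids. Tangle beads (see below) are permanent
crosslinks and enter as their own nodes. Edges are molecule strands between
terminal sites; strands with both ends in one cluster are recorded as
self-loops and excluded; parallel strands collapse into one edge with a
multiplicity that still counts toward the node degree.

Polygons are assigned by Delaunay merging. The node set is triangulated on
the periodic cell (ghost tiling with a safety margin; each periodic face is
kept exactly once, the copy whose centroid lies in the primary cell; a
twin-completeness check guards the margin and triggers a retry with the
full 3x3 tiling). The triangulation must contain every network edge -
networks violating this are rejected, which is the regime restriction under
which the method is defined. Starting from the triangle faces, every
triangulation-only edge is removed one at a time, merging the two faces it
separates; faces are circular linked lists of directed periodic edges and
each removal is an O(1) splice (self-merges split a walk in two, handling
bridges and torus-wrapping regions). The final face set is independent of
the removal order - asserted in the tests - and identical to the faces of
the periodic planar graph as enumerated by an independent half-edge
traversal oracle.

A face counts as a polygon when its boundary, after pruning edges traversed
twice (pendant trees), is a single simple positively-oriented cycle with
zero net cell shift; the complement region of a sparse network and pure
trees are faces but not polygons. An edge is *dangling* exactly when it
does not separate two distinct faces. Two degenerate situations are worth
noting: exactly cocircular node sets (ideal lattices) are disambiguated by
a deterministic, periodicity-preserving jitter of relative size 1e-5 that
affects only the choice of triangulation, never reported coordinates; and
Poisson-Voronoi *vertex graphs* routinely violate the Delaunay-superset
precondition (near-cocircular seeds give arbitrarily short Voronoi edges),
so Voronoi polygon statistics come from the dual construction directly.

## Metrics

* **Shape regularity** `src()`: solidity x balanced repartition x
  convexity. The repartition factor (min/max of the coordinate standard
  deviations) is computed in the polygon's principal-axes frame by default,
  making the score invariant under rigid rotation - a rotated square still
  scores exactly 1, which is the meaning of "regular shapes score 1". The
  pose-dependent raw-frame variant is available as `frame = "raw"`.
  Vertices are used unweighted; simulated edges are straight segments, so
  no edge resampling is needed.
* **Ring statistics** `pn_distribution()`: fractions of polygons by edge
  count, exactly normalised.
* **Assortativity** `assortativity()`: Pearson correlation of polygon edge
  counts over the symmetrised list of adjacent (edge-sharing) polygon
  pairs. A single-size tiling has *undefined* assortativity and is flagged
  `NA`, never silently zero. The 5000-seed Poisson-Voronoi reference value
  is about -0.15.
* **Coordination** `coordination_stats()`: mean degree and second central
  moment `mu2(k)`; `landscape_point()` returns the `(mu2(k), r)` coordinate
  of the network landscape.
* **Averaging convention**: `<SRC>` is polygon-weighted (every polygon
  counts once); whether the original analyses weighted by area is not
  recoverable, and the polygon-weighted mean is the simpler convention.
* **Energy proxy** `upair_k_correlation()`: the head-pair energy and the
  mean coordination number are strongly anti-correlated during assembly
  (each new head contact lowers `Upair` by ~`eps_hh` and raises `<k>`),
  which justifies using `<k>` as a parameter-free proxy for the internal
  energy.

## The maximum-entropy reference model

The entropically ideal polygon distribution maximises Shannon entropy
subject to normalisation, fixed `<n>`, and one further moment constraint
`sum g(n) p_n = const`. The printed form of the third constraint in the
maximum-entropy literature this follows is typographically ambiguous; we
default to `g(n) = 1/n` (the Lemaitre-law constraint) and keep `g`
pluggable (`g(n) = n^2`, `log n`, ...). The solution is the exponential
family `p_n = exp(-l0 - l1 n - l2 g(n))`; multipliers are found by
minimising the convex dual with BFGS from a deterministic spread of starts
(the fit is known to fail for extreme constraint sets, hence the
multi-start and an explicit `converged` flag) and polished by Newton steps
using the analytic covariance Hessian, driving constraint residuals below
1e-10. `fit_maxent()` takes its constraints from an observed distribution,
pools out-of-support sizes into the boundary bins (support 3..20 by
default), and reports the Kullback-Leibler divergence and per-n residuals.
In self-assembled polymer networks the residual signature is diagnostic:
angular strain makes triangles rarer and squares more common than the
entropic prediction, while large flexible polygons follow it closely.

## Idealised nets and tangled molecules

`build_ideal_net()` constructs the two reference structures at their energy
minimum (all bonds unstretched, head clusters at their Lennard-Jones
optimum): a honeycomb (k = 3, one molecule per edge, hexagon side `l_eqm +
2 r_min / sqrt(3)`) and a chain-link-fence square net (k = 4 corners, each
edge two molecules long with a k = 2 mid-edge node, so faces have n = 8 in
node terms). `energy_vs_scale()` stretches them affinely; across a 3 x 3
grid of `kl` and `eps_hh` multipliers the honeycomb's minimum-over-scale
energy per molecule always beats the square net's - with a single head
chemistry the trivalent structure is enthalpically preferred.

Tangled molecules model, in 2D, the lateral 3D entanglement of real
molecules. A tangle site is a TANGLE bead with exactly three bonded
branches (each a 150-nm arm ending in a head; arm beads are spaced 50 nm
since 150 is not a multiple of 60, and the tighter spacing keeps arm
clumping penalised), behaving as a body bead in the force
field but acting as a permanent degree-3 node of the network - this is the
reading under which "tangle points have fixed k = 3" is meaningful. The
one-site template is a three-arm star (a full strand through the crosslink
plus a half strand); the two-site template joins two such sites by a 150-nm
bridge. The published figure fixes only the 150-nm head-to-tangle distance;
the crossing geometry beyond that is schematic, and we use straight
symmetric rest shapes with a free pivot at the tangle site.
`substitute_tangled()` swaps a seeded random fraction of linear molecules
for tangled composites in place (they are deliberately not mass-conserving
replacements - tangled composites carry more head sites, which is also true
of the physical picture they model).

## What the generator does and does not emulate

The synthetic runs reproduce the study conditions: molecule geometry and
interactions, the melt-cool schedule, pressure-set density, replicate
seeding. Passing tests demonstrate that the *model* behaves as published -
they do not validate the model against real basement membranes beyond the
published comparisons. In particular: the simulation is strictly 2D (no
out-of-plane escape or stacking), all heads share one chemistry (real 7S
and NC1 domains bind only their own kind), edges are straight (no curved
laminin-like scaffolding), and image digitisation noise - present in any
experimental network fed through `read_network()` - has no synthetic
counterpart here.

## Known limitations

* Networks whose edges are not a subset of the node Delaunay triangulation
  are rejected rather than analysed; very short edges (nearly coincident
  nodes) are the usual cause.
* Faces that revisit a node (two polygons pinched at a cut vertex) are not
  counted as polygons.
* The minimum-image convention for edge shifts assumes the cell is large
  compared to any edge; tiny periodic fixtures should be built with
  explicit shifts (as the lattice builders do).
* Scaled-down protocols under-coordinate; see "Desk-scale study
  conditions".
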