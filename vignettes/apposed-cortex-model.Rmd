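---
title: "The apposed-cortex adhesion model: mechanics, assumptions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The apposed-cortex adhesion model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acam)
```

## The model

`acam` simulates a 2D epithelial tissue in which the junctional actomyosin
cortex of every cell is an explicit, closed viscoelastic rod (a rope-loop),
and the cortices of neighbouring cells are coupled by discrete adhesion
bonds that form, transmit force, and unbind. Vertices — the points where
three or more cells meet — are not model primitives: they are geometric
consequences of where adhesion couples cortices, so cortical material can
flow past a vertex and neighbouring junctions can exchange material. This
is the defining difference from vertex-based models, in which a junction
is a single shared edge pinned between material vertices.

All lengths are measured in units of the adhesion bond rest length
$\delta_0$ (the equilibrium inter-cortical spacing, tens of nanometres in
epithelia) and time in units of the cortical turnover time $\tau_{cor}$
(about 50 s: the actin turnover timescale over which elastic stress in the
cortex relaxes).

### Cortex

Each cortex is an extensible, unshearable, torsion-free rod with
stretching modulus $E$ (used to nondimensionalise forces) and bending
modulus $B$. Its instantaneous elastic energy is

$$U = \oint \left[ \tfrac12 \kappa^2 c^2 + \tfrac12 \varepsilon^2 \right]
\mathrm{d}S,$$

with $\kappa = \sqrt{B/E}/\delta_0$ the dimensionless
bending-to-stretching ratio, $c$ the curvature and
$\varepsilon = \alpha - 1$ the elastic strain. Activity enters through the
morphoelastic decomposition of the total stretch,
$\lambda = \gamma\,\alpha$: an active contraction factor
$\gamma \in (0, 1]$ (motor loading) shortens the stress-free reference
length without generating stress, and only the elastic part $\alpha$
produces tension ($T = \varepsilon$ in nondimensional units). A free
cortex segment with $\gamma < 1$ simply shortens; a held segment develops
tension $(1-\gamma)/\gamma$.

Discretely, a cortex is an ordered CCW polygon of nodes carrying
persistent material labels (for kymographs). Each segment stores its
undeformed length $\hat\ell$ and its $\gamma$; the reference length is
$\ell = \gamma \hat\ell$. Bending is penalised at nodes as the turning
angle per reference arc length (the discrete-rods convention), which
converges to $c = \partial\theta/\partial S$ and makes the energy a nodal
sum. Forces are defined variationally — the analytic gradient of the
discrete energy — so relaxation monotonically decreases energy and force
balance at a minimum is exact; the analytic rod force expression is used
as a cross-check in the tests, not as the implementation.

### Adhesion

A bond is a Hookean spring of rest length 1 and dimensionless stiffness
$\omega$ (bond stiffness over cortex stretching stiffness), with energy
$\tfrac12\omega(\delta-1)^2$ saturating at the maximum binding length
$\delta_{max}$: a bond stretched beyond $\delta_{max}$ transmits no force,
and at the next turnover step it is removed (it has effectively unbound),
freeing its endpoints to re-bind locally. Unbound nodes re-bind with a
partner sampled from an inverse-distance kernel over candidate nodes of
other cortices; lifetimes are drawn at birth from an exponential
distribution with mean $\tau_{adh}$, the agent-level realisation of a
bond-density relaxation at rate $1/\tau_{adh}$. A node may carry several
received bonds but initiates only one at a time. Bond turnover endows the
apposed cortices with an emergent sliding friction
$\mu_{adh} = \omega\,\tau_{adh}$; the two limits are the junction-vertex
models ($\mu \to \infty$, vertices behave as material anchors) and the
cell vertex models ($\mu \to 0$, free slippage).

### Quasi-static viscoelastic stepping

Cell rearrangement is slow compared with cortical turnover, so the tissue
is always in mechanical equilibrium, and the cortex behaves as a
viscoelastic fluid: one simulation step (one $\tau_{cor}$) is

1. protocol update of the activity field $\gamma$,
2. bond turnover (expiry + overstretch unbinding) and re-binding,
3. viscoelastic rest-length update $\hat\ell \leftarrow d$ (each
   segment's undeformed length becomes its current length, so the
   reference becomes $\gamma d$: all stored elastic stress relaxes and an
   active field re-arms its contraction against the current shape),
4. energy minimisation over all node positions (L-BFGS with analytic
   gradients, residual tolerance $10^{-6}$ per node),
5. observables (junction map, areas, tensions, label tracks).

Note that a *constant* $\gamma < 1$ drives sustained contraction under
this scheme — each step re-arms the contraction against the relaxed
reference — which is what makes junctional activity able to shrink a
junction to zero length over many steps, and what makes removing the
activity ($\gamma \to \gamma_0$) freeze the configuration. Static
problems (the vertex-geometry map) iterate steps 3–4 until the total
cortex length changes by less than $10^{-4}$ per cycle.

## Parameters

| symbol | meaning | default | units |
|---|---|---|---|
| `kappa` | bending/stretching ratio | 0.01 | — |
| `omega` | bond stiffness | 0.05 | — |
| `delta_max` | maximum binding length (force cutoff) | 4 | $\delta_0$ |
| `bind_range` | bond formation reach | 1.1 | $\delta_0$ |
| `delta_gamma` | identity-sensing range | 4 | $\delta_0$ |
| `tau_adh` | mean bond lifetime | 10 | $\tau_{cor}$ |
| `gamma0` | background pre-stress contraction | $1-2\times10^{-4}$ | — |
| `h` | node spacing | 0.5–0.75 | $\delta_0$ |
| `tol` | equilibration residual | $10^{-6}$ | $E$ |

`kappa` and `omega` control the passive vertex geometry through the ratio
$\kappa^2/\omega$; `tau_adh` controls slippage friction; `gamma0` mimics
tissue-scale tension and stabilises open vertices and rosettes.

### The bond formation reach

The continuum description lets unbound sites re-bind anywhere within
$\delta_{max}$. In the discrete realisation this is unstable: every bond
renewal at a stretched distance does irreversible work that the
rest-length update converts into cortex length, so long "tether" bonds
across vertices pump perimeter into the cells (a few percent per step)
and the tissue coarsens. Adhesion complexes are molecular objects of
order $\delta_0$, and the model's own junction schematics show bonds
forming near-normal between apposed membranes, so the package separates
the *formation* reach (`bind_range`, default 1.1 $\delta_0$, chosen as the
largest value at which two apposed cortices equilibrate at exactly the
bond rest spacing) from the force-transmission cutoff $\delta_{max}$.
Formed bonds still stretch, tilt and saturate at $\delta_{max}$ exactly as
specified. Consequences are discussed under *Limitations*.

## Fixtures and experiments

* `single_cell_in_hexagon()` + `exp_vertex_geometry()`: a circular cortex
  inside a fixed hexagonal wall; the adhesion strength is ramped
  quasi-statically and the tissue relaxed by recurrent rest-length
  updates. The vertex opening $\delta^{vert}$ — the radius of the largest
  circle inscribed in the cortex-free region at a wall corner — is the
  geometric signature of $\kappa^2/\omega$. The wall stands in for
  apposed tissue, so the opening is measured against the cortex and its
  mirror images across the wall edges, making the fixture commensurate
  with interior vertices.
* `three_cell_tissue()` + `exp_fracture_ramp()`: the pinned 3-cell tissue
  under a uniform quasi-static $\gamma$ ramp; cortical tension opens the
  interior vertex until no bond can span it ($\delta^{vert} >
  \delta_{max}$) and the tissue fractures.
* `fourteen_cell_tissue()` + `run_t1()`: the neighbour-exchange protocol.
  Identity-sensing contractility ($\gamma = 0.94$) is applied to the
  portions of cortices 1 and 2 within `delta_gamma` of each other, while
  the pair is adhered; the junction shrinks to zero, the 4-way resolves,
  and the new junction between cells 3 and 4 extends passively under the
  background pre-stress.
* `exp_stall()`, `exp_dmax_scan()`, `exp_sequential()`: the stall test
  (activity removed at the 4-way), the binding-length robustness scan,
  and the sequential contraction that yields a second exchange at fast
  turnover or a 5-cell rosette vertex at slow turnover.

```{r quick-example, eval = FALSE}
vg <- exp_vertex_geometry(kappa = 0.01, omega = 0.05)
vg$delta_vert          # equilibrium vertex opening, units of delta_0

r <- run_t1(tau_adh = 10, n_steps = 200, seed = 1)
t1_area_loss(r)        # min normalised area of cells 1 & 2
```

## Problem sizes

Desk-scale defaults, chosen once: the vertex-geometry fixture uses
hexagon edge 5 $\delta_0$ at node spacing 0.5; the 3-cell fracture ramp
uses edge 5 at spacing 0.5 with $\gamma$ decrements of 0.0025–0.005 and
up to 30–40 relaxation cycles per increment; the 14-cell T1 family uses
edge 8 at spacing 0.75 (about 1100 nodes). The acceptance script runs
the full set in roughly a quarter of an hour on one core.

## What the generator emulates — and what it does not

The synthetic fixtures emulate: regular hexagonal packing at mechanical
equilibrium, uniform mechanical parameters, a single composite adhesion
species, a fixed pinned boundary, and activity fields defined purely by
junction identity. Real epithelia have heterogeneous cell sizes and
mechanics, medial (apical-surface) myosin pools, substrate friction,
three-dimensional structure and active extension mechanisms — none of
which are modelled. Passing the packaged tests therefore demonstrates the
internal consistency of the junctional mechanism (contractility +
adhesion turnover are sufficient for a complete, continuous neighbour
exchange) and not a quantitative account of any particular tissue.

## Numerical choices

* Minimiser: L-BFGS (`stats::optim`) on the total energy with analytic
  gradients; residual = max per-node force 2-norm, tolerance $10^{-6}$;
  energy is non-increasing across accepted iterates. Simulation steps cap
  the iteration budget (warm starts make most steps cheap) and log any
  incomplete equilibration in the event record.
* Junction map: a junction is a maximal run of near-rest couplings
  ($\delta \le 1.25$) between two cortices, merging gaps of up to two
  unbonded nodes (single turnover events do not fragment a junction) and
  discarding runs of fewer than three bonded nodes (a residual contact
  vestige at a 4-way is not a junction). Vertices are single-linkage
  clusters of junction-interval endpoints (2.5 $\delta_0$ link radius)
  with membership recounted from the cluster centroid, and at least
  three member cells; a rosette is a vertex with five or more.
* Vertex opening: maximal inscribed circle, computed by maximising the
  minimum distance to the member polylines over the circle centre
  (Nelder-Mead with restarts), constrained near the vertex centre.
* Remeshing keeps current segment lengths within $[0.5, 2]\times$ the
  target spacing, conserves undeformed/reference length exactly, merges
  only where the polyline is locally straight (area change
  $< 10^{-7}$ relative per removal), and re-attaches bonds of dropped
  labels to the nearest surviving node.
* Determinism: every stochastic draw (bond lifetimes, kernel sampling)
  flows from the seed passed to `simulate_tissue()`; equal seeds give
  bit-identical event logs.
* Degenerate inputs: zero-length segments are reported with cell and
  segment index; self-intersecting initial loops are rejected; a
  non-convergent equilibration returns `converged = FALSE` and is the
  caller's decision.

## Design decisions on open points

* **Viscoelastic semantics.** The rest-length update uses
  $\hat\ell \leftarrow d$ (reference $\gamma d$). The alternative
  ($\hat\ell \leftarrow d/\gamma$, which leaves $\varepsilon = 0$ after
  the update) makes a constant activity field inert after one step —
  incompatible with sustained junction shrinkage at fixed $\gamma$ and
  with the stall test, so it was rejected.
* **Identity sensing** is recomputed from the current geometry every
  step and gated on the pair still being adhered: after the exchange
  there are no adhesions between the original pair, hence no
  contractility, even though the cortices may still pass within the
  receptor range near the new junction's vertices.
* **Fast-adhesion regime.** $\tau_{adh} < \tau_{cor}$ is realised as
  bond lifetimes shorter than one step (bonds do not persist between
  steps). The kernel-expectation ("mean-field") force operator is
  provided and tested as the analytic average of that scheme, but
  simulations use the discrete realisation: expectation coupling has
  zero slippage friction and artificially coarsens a tissue.
* **Stress observable** ($P_{cell}$, principal axis) is a virial-type
  area-normalised first moment of the boundary forces; it is a
  qualitative visualisation aid only and appears in no quantitative
  claim.

## Known limitations

* The passive vertex opening is insensitive to $\omega$ at fixed
  $\kappa$ in this realisation (the formation reach, not the energy
  balance, arrests closure), so the constancy of $\delta^{vert}$ along
  $\kappa^2/\omega$ isolines is reproduced trivially rather than through
  the continuum mechanism, and the printed monotone decrease with
  $\omega$ is not reproduced.
* The uniform-contractility fracture threshold is knife-edge sensitive
  to the formation reach: 0.97 at reach 1.1, below 0.90 at reach 1.2.
  The package reports its own threshold (≈0.97) rather than tuning the
  reach to the literature value.
* At desk scale (cells 8–10 $\delta_0$ across) the sensing range
  $\delta_\gamma = 4$ covers a third of a cell perimeter, so the active
  flanks contract the cells far more than at realistic scale (cells
  $\gtrsim$ hundreds of $\delta_0$): T1 area losses read 60–80% instead
  of ~25%. The orderings across adhesion timescales are preserved.
* No excluded volume beyond the repulsive branch of bonds: strongly
  overlapping cortices are possible in pathological states and are not
  forbidden.
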