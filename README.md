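# acam — an apposed-cortex adhesion model of epithelial tissue mechanics

`acam` simulates 2D epithelial tissue for people who study cell
rearrangement — T1 neighbour exchanges, rosette formation, tissue
fracture — at the level of the sub-cellular machinery that drives it.
Unlike vertex models, which collapse each cell-cell interface onto a
single shared edge pinned between material vertices, `acam` represents
the junctional actomyosin cortex of *every* cell as its own closed
viscoelastic rod (a rope-loop), and couples neighbouring cortices with
explicit adhesion bonds that form, transmit force, saturate and turn
over. Vertices are then just the places where three or more cells'
adhesion zones meet: cortical material can flow past them, apposed
cortices can slip against each other, and neighbour exchange becomes a
continuous process rather than a discrete topological move.

The mechanics, in the field's standard notation (lengths in units of the
adhesion rest length $\delta_0$, time in units of the cortical turnover
time $\tau_{cor}$):

* cortex energy $\oint [\tfrac12\kappa^2 c^2 +
  \tfrac12\varepsilon^2]\,\mathrm{d}S$ with bending/stretching ratio
  $\kappa$, curvature $c$ and strain $\varepsilon = \alpha - 1$;
* morphoelastic activity $\lambda = \gamma\alpha$: a contraction factor
  $\gamma < 1$ (myosin loading) shortens the stress-free reference; only
  the elastic stretch $\alpha$ carries tension;
* adhesion bonds: Hookean springs, energy
  $\tfrac12\omega(\delta-1)^2$ saturating at $\delta_{max}$, exponential
  lifetimes with mean $\tau_{adh}$, re-binding by an inverse-distance
  kernel — giving an emergent cortex–cortex sliding friction
  $\mu_{adh} = \omega\,\tau_{adh}$;
* quasi-static stepping: every step relaxes all residual elastic stress
  (rest length ← current length) and minimises the total energy.

See the methods vignette (`vignettes/apposed-cortex-model.Rmd`) for the
full model description, parameter table and numerical choices.

## Worked example

Equilibrium vertex geometry — a single cell adhered inside a hexagonal
wall, relaxed quasi-statically; the opening at the wall corners is the
geometric signature of $\kappa^2/\omega$:

```r
library(acam)
vg <- exp_vertex_geometry(kappa = 0.01, omega = 0.05)
round(vg$delta_vert, 3)
#> [1] 1.507
```

The cortex-free opening at each vertex admits an inscribed circle of
radius ≈ 1.5 adhesion rest lengths: vertices are nearly, but not fully,
closed — tens of nanometres across for a real junctional gap.

An active neighbour exchange — contractility $\gamma = 0.94$ applied by
identity sensing to the junction between cells 1 and 2 of a 14-cell
patch, with adhesion lifetime $\tau_{adh} = 10\,\tau_{cor}$:

```r
r <- run_t1(tau_adh = 10, n_steps = 200, seed = 3)
r$resolved
#> [1] TRUE
tail(r$trace$obs[, c("step", "L12", "L34", "signed_t1")], 3)
#>    step L12      L34 signed_t1
#> 44   44   0 2.068409  2.068409
#> 45   45   0 2.070360  2.070360
#> 46   46   0 2.789891  2.789891
```

The {1,2} junction shrinks to zero length, the 4-way vertex resolves,
and a new junction between the previously unconnected cells 3 and 4
extends passively: the signed T1 length ($L_{3,4} - L_{1,2}$) passes
continuously through zero. Slowing adhesion turnover further
(`tau_adh = 100`) in a second, sequential contraction instead drags the
new junction's endpoints together into a vertex shared by five cells —
a rosette (`exp_sequential()`).

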