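---
title: "Modeling fetal-head descent through the pelvic floor muscle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling fetal-head descent through the pelvic floor muscle}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(pfmsim)
```

## The problem

During the second stage of labor the fetal head passes through the levator
hiatus, stretching the pelvic floor muscle (PFM) far beyond its resting
dimensions.  Where the stress and strain peak, and when, is clinically
relevant: the attachment of the pubococcygeus to the skeleton is where most
postpartum lesions are found.  `pfmsim` models this event at desk scale: a
rigid sphere (the head, at its biparietal diameter, BPD) descends under
gravity through a deformable muscle sheet, and the package reports the
quantities a finite-element study of this process reports — peak equivalent
(von Mises) stress, peak maximum-principal stress and strain with their
occurrence times, end-time values, displacement extrema, and extension
ratios.

Everything is computed in the consistent mm–ton–s–MPa unit system: lengths
in mm, density in ton/mm³, stress in MPa, force in N, energy in mJ, gravity
9810 mm/s².

## The surrogate anatomy

No subject-specific geometry is distributed with the package.  Instead, the
`geometry_synth` layer builds a parametric surrogate of the levator plate: a
sheet ("hammock") over a 70 mm × 60 mm footprint whose bounding box is
exactly 70 × 60 × 40 mm, sagging from a flat outer rim down to an elliptical
urogenital hiatus (default semi-axes 25 × 15 mm).  The key anatomical
features it keeps are:

* the bounding dimensions of the muscle (70 × 60 × 40 mm);
* a hiatus much smaller than any of the simulated heads (80/90/100 mm), so
  passage requires large stretch;
* the hiatus placed anteriorly (default center `(6, 0)` mm), away from the
  skeletal attachment — in vivo the urogenital hiatus opens towards the
  pubic arch while the levator plate attaches posteriorly/laterally;
* a skeletal attachment along one end of the long (X) axis (`select_fixed_rim`,
  default `edges = "xmin"`), with all degrees of freedom fixed there;
* a thin strip (default 6 mm) of tissue adjacent to the attachment excluded
  from the head's contact surface: that tissue is backed by bone, and the
  head slides past the bone rather than loading it frontally.  Without this
  shadow the rigid head, which is wider than the whole muscle, plows
  through tissue that cannot move, which is neither anatomical nor
  numerically meaningful.

What the surrogate does *not* reproduce: the asymmetric, multi-layer sling
of the real levator ani, its fiber directions, neighboring organs, and the
subject-specific bowl shape.  Passing the package's acceptance checks
therefore demonstrates correct mechanics and correct *trends* (peaks grow
with BPD, peaks occur mid-descent, the muscle stretches beyond 100% of its
height), not agreement with subject-specific field values.  One documented
divergence: on this symmetric surrogate the vertical extension ratio
(max u_Z/40) exceeds the horizontal one (u_X span/70) for all three head
sizes, whereas the subject-specific study reports the opposite ordering
(~1.26× vertical vs ~2× horizontal).  The lateral spread of the real sling
is a feature of its asymmetric funnel that a box-bounded parametric sheet
does not recover.

### Meshing

`tetrahedralize()` builds a structured tetrahedral mesh: a graded tensor
grid in the footprint (spacing follows the surface arc length, so the steep
funnel wall is not under-resolved), vertical extrusion through the 6-mm
sheet thickness, and a globally consistent Kuhn six-tet split of every cell.
Cell corners falling inside the hiatus are projected onto its rim; corner
pairs left closer than 0.35 of the target edge are merged (footprint
boundary > rim > interior precedence), which removes sliver prisms along the
rim while preserving the bounding box.  All tets are positively oriented by
construction and the mesh volume is verified in the tests against a
Monte-Carlo volume oracle of the implicit solid (agreement within 5% at the
2 mm resolution, and 3 mm vs 2 mm volumes agree within 5%).

The default resolution is `target_edge = 3` mm (about 16k tets); all
simulation results in the tests and the acceptance script are computed at
3 mm.  The mesher accepts 1–5 mm; mesh-convergence of the *geometry* is
checked in the tests, and finer runs are a one-line change.

## Mechanics

The muscle is isotropic linear elastic in the printed constants
E = 0.2 MPa, ν = 0.4, ρ = 1.12·10⁻⁹ ton/mm³.  Because the tissue undergoes
stretches well above 100% and large rotations, the linear law is applied in
the Green–Lagrange strain measure — the Saint Venant–Kirchhoff (SVK) model:

* E_GL = ½(FᵀF − I), S = λ tr(E_GL) I + 2μ E_GL, σ = F S Fᵀ / det F,

with Lamé constants from (E, ν).  This keeps exactly the two published
constants while making the response objective (rigid rotations produce zero
force, verified to 10⁻⁸ in the tests).  In the small-strain limit the
uniaxial secant modulus reproduces E within 0.5%.

The head is an analytic rigid sphere of diameter D ∈ {80, 90, 100} mm and
density 7.86·10⁻⁹ ton/mm³, giving 3.0 kg at D = 90 (the reported newborn
weight); its printed Young's modulus is deliberately unused.  The sphere
translates vertically only.

### Compression barrier

SVK softens under strong compression and admits element inversion, which a
thin sheet crushed by a rigid body will exercise.  The solver therefore
augments the element energy with a volumetric barrier
W_vol = κ_c/2 (J − 1)² active only for J = det F < 1
(`compression_stiffening`, default κ_c = 3E).  Its force contribution
κ_c (J − 1) cof(F) is well-defined for any F, including inverted states,
and pushes crushed elements back towards J = 1 — mimicking the stiff
compressive response of the corotational small-strain formulations used by
commercial explicit solvers, while leaving tension untouched.  The exported
per-element kernel `element_internal_forces()` is pure SVK; setting
`compression_stiffening = 0` recovers it in the solver.

## Contact and friction

Contact is node-to-analytic-sphere penalty: a contact node penetrating by
δ = R − d receives a radial force kδ.  The default per-node stiffness is
auto-scaled as k = 120 · E · h · (D/90)²: per-node contact load grows like
the head weight (∝D³) over the loaded-node count (∝D), so k ∝ D² holds the
penetration roughly constant across head sizes; the prefactor is set so the
peak penetration stays below the 0.1 mm tolerance on the default surrogate
for all three diameters.  Friction is Coulomb with μ = 0.03, regularized
below a sliding speed of 1 mm/s by a linear viscous law to avoid stick-slip
chatter; the tangential force never exceeds μ|f_n| (verified pointwise).

## Time integration

Central difference (velocity Verlet) with lumped masses.  Three numerical
devices keep the explicit step tractable without distorting the physics —
all are safe here because the muscle's inertia (≈20 g) is three orders of
magnitude below the head's (2–4 kg):

* **Selective mass scaling**: elements whose altitude is below half the
  nominal edge get their mass scaled by (h/2h_e)², lifting their stable
  step to that of a half-edge element.
* **Median mass floor**: nodal masses are floored at the median nodal mass,
  so contact-spring stability is not dictated by boundary slivers.
* **Conservative CFL**: the solver uses a third of the textbook h/c bound
  (the h/c rule underestimates the top eigenfrequency of strongly
  anisotropic lumped tets); in practice the contact-spring bound
  2√(m/k) governs.  The step is re-estimated on the monitor cadence from
  the current maximum stretch, since the SVK tangent stiffens like
  (3λ² − 1)/2, and from the compression-barrier tangent when J < 0.95.

Mass-proportional damping (default 5% of critical at the 1/duration
reference frequency) suppresses low-mode ringing.  An energy ledger tracks
external (gravity) work, kinetic and strain energy, contact-spring storage,
and friction/damping dissipation; the residual stays below 5% of peak work
at every snapshot in the acceptance runs (in practice below 0.5%).
Instability (non-finite or diverging displacements, or more than 10% of
elements inverted) raises a structured `pfm_instability_error`.  Isolated
transient inversions of thin crumpling elements are tolerated — they are
benign for SVK and the ledger stays exact — which is why the bulk solver
does not abort on the first inverted element the way the strict per-element
kernel does.

## Reported quantities

Snapshots are taken at 0, 0.03, …, 0.15 s (six states); a dense monitor
series (~400 samples) carries the scalar peaks, because occurrence times
fall between snapshots.  Peak fields are reported the way a post-processor
draws a contour plot ("nephogram"): per-element invariants are averaged to
nodes with volume weights, and elements with det F ≤ 0.2 (unresolved
sub-element crumpling) are excluded from peak extraction.  Displacement
extrema need no such guard.  Definitions:

* maximum u_Z: largest downward nodal displacement over all nodes and times
  (descent-positive);
* u_X span: largest instantaneous max(u_X) − min(u_X) over nodes;
* extension ratio Z = 100 · max u_Z / height(40), ratio X = 100 · u_X
  span / length(70).

The ratio arithmetic reproduces the published percentages exactly from the
published displacement extrema, with one exception: the printed vertical
ratio for the 80 mm head (128.90%) is inconsistent with its own
displacement (50.358/40 = 125.90%); the implementation computes 125.90% and
does not "correct" towards the printed value.  Similarly, a published
end-time equivalent stress for the 100 mm head exceeds the published peak —
internally inconsistent, flagged in the tests' design, not emulated:
`peak_report()` guarantees end ≤ peak by construction.

## Degenerate inputs and numerical choices

* ν = 0.5 exactly is rejected (incompressible limit of the Lamé form).
* `gap = 0` places the sphere touching, with zero initial force; initial
  penetration is a setup error.
* A node coinciding with the sphere center is a degenerate-contact error.
* Tet orientation is normalized at meshing; zero-volume tets are removed by
  the cleanup pass; remaining volumes are strictly positive or meshing
  fails.
* All simulations are deterministic: reruns are bit-identical, and the
  recorded seed exists for future randomized-anatomy variants, not for the
  solver.

## Problem sizes

The default study (three diameters, 3 mm mesh, 0.15 s) integrates ~16k
elements over ~10⁴ steps per run, a few minutes per diameter on one core.
Unit tests use a 5 mm mesh and shortened durations; the acceptance checks
use the full default study.
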