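# pfmsim

Explicit finite-element simulation of fetal-head descent through the pelvic
floor muscle (PFM) during the second stage of labor.

## The problem

Vaginal delivery stretches the levator ani far beyond its resting
dimensions; where and when the stress and strain peak is where postpartum
lesions concentrate.  `pfmsim` models the event at desk scale: a rigid
sphere representing the fetal head at its biparietal diameter
(BPD ∈ {80, 90, 100} mm) descends under gravity from 23 mm above a
deformable muscle sheet, squeezes through the urogenital hiatus, and the
package reports the mechanical response — exactly the quantities a
finite-element study of this process tabulates.

The package is aimed at biomechanics researchers who need a transparent,
fully scripted, dependency-light re-implementation of this class of
simulation: a parametric anatomy generator, a total-Lagrangian explicit
solver, and table-ready postprocessing, all in R.

## The model

* **Geometry** — a parametric hammock: a 6 mm sheet over a 70 × 60 mm
  footprint sagging to a 70 × 60 × 40 mm bounding box, pierced by an
  anterior elliptical hiatus (semi-axes 25 × 15 mm), meshed with linear
  tetrahedra (default edge 3 mm).  The skeletal attachment fixes one end of
  the long axis.
* **Material** — isotropic linear elastic constants (E = 0.2 MPa, ν = 0.4,
  ρ = 1.12·10⁻⁹ ton/mm³) applied in the Green–Lagrange measure
  (Saint Venant–Kirchhoff), so the response is objective at large rotation
  and stretch: E = ½(FᵀF − I), S = λ tr(E) I + 2μE, σ = F S Fᵀ/det F.
  A volumetric barrier active in compression keeps contact-crushed elements
  from inverting.
* **Head** — analytic rigid sphere, density 7.86·10⁻⁹ ton/mm³ (3.0 kg at
  D = 90), translating vertically under gravity (9810 mm/s² in the
  mm–ton–s–MPa system).
* **Contact** — node-to-sphere penalty with regularized Coulomb friction,
  μ = 0.03.
* **Integration** — central difference with lumped masses, CFL-bounded
  step, energy ledger (work = kinetic + strain + contact + friction +
  damping within 5% at every snapshot; in practice < 0.1%).
* **Outputs** — peak equivalent (von Mises) stress, peak maximum-principal
  stress and strain with occurrence times and end-time values, maximum
  descent u_Z, horizontal span of u_X, and extension ratios
  (100·max u_Z/40, 100·u_X span/70); VTK snapshot series; CSV/JSON metric
  tables; Abaqus INP / Gmsh MSH mesh export.

## Worked example

```r
library(pfmsim)

geo   <- pfm_geometry()                      # 70 x 60 x 40 mm surrogate
mesh  <- tetrahedralize(build_pfm_surrogate(geo), target_edge = 3)
mesh  <- select_fixed_rim(mesh, geo)         # skeletal attachment at one end
sph   <- place_sphere(mesh, diameter = 90)   # 23 mm above the muscle
print(sph)
#> Rigid head sphere: D = 90 mm, mass = 0.003 ton (3 kg), center z = 61.51 mm

run <- run_simulation(mesh, material_params(), sph, simulation_config())
print(run)
#> pfm_run: D = 90 mm, 10985 steps (dt0 = 1.24e-05 s), 6 snapshots
#>   max penetration 0.0500 mm, energy residual 0.00% of peak work

peak_report(run)[, c("bpd", "max_eq_stress", "t_eq_stress",
                     "max_p_strain", "t_p_strain",
                     "ratio_Z_pct", "ratio_X_pct")]
#>   bpd max_eq_stress t_eq_stress max_p_strain t_p_strain ratio_Z_pct ratio_X_pct
#> 1  90      1.077987   0.1145216    0.8024273  0.1136166    234.2739    169.6195
```

Reading: at D = 90 the equivalent stress peaks at 1.08 MPa about 0.115 s
into the 0.15 s descent (three quarters of the simulated interval, after
the head has engaged the hiatus), the largest principal stretch reaches
λ = √(1+2·0.80) ≈ 1.61, and the muscle is stretched to 234% of its height
vertically and 170% of its length horizontally.  Across
D = 80/90/100 the peak stress (0.46 / 1.08 / 2.25 MPa) and peak strain
(0.55 / 0.80 / 1.22) grow monotonically with head size, and every peak
occurs strictly inside the mid-descent window — the qualitative signature
of this delivery model.  Field series for ParaView:

```r
write_snapshot_series(run, mesh, "out/")     # 6 VTK files + .vtk.series index
```

A command-line driver is included
(`inst/exec/pfmsim generate|simulate|sweep|report|verify`), configured by a
YAML file (`inst/extdata/example_config.yaml`).

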