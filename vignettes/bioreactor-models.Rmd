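---
title: "Modeling flow, solute washout and oxygen supply in perfusion hepatocyte bioreactors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling flow, solute washout and oxygen supply in perfusion hepatocyte bioreactors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hepaflow)
```

# The problem

Primary hepatocytes lose metabolic competence within hours in static
culture. Perfusion bioreactors — chambers through which medium is pumped
continuously — can extend viability, but only if three physical
requirements are met simultaneously: the shear stress on the cells must
stay low, a dosed test compound must distribute uniformly on a time scale
short compared with the kinetics being measured, and enough oxygen must
reach every cell to keep the local concentration above the critical level
for hepatocyte survival (about 2.8 µM dissolved O₂).

`hepaflow` provides desk-scale 2D models of three such devices:

* **`realbio`** — a scaffold chamber: a 1-mm porous cell scaffold held
  between two media channels, each with its own inlet and outlet, and with
  gas-permeable membranes on the outer channel walls (total volume 7.0 mL,
  feed 1 mL/min).
* **`fluidizedbed`** — a custom bed of alginate-encapsulated hepatocytes
  (porosity 0.3) held between two 100-µm filters, with media chambers
  below and above (4.8 mL, 1 mL/min); in plan view the chamber is a
  parabolic lens whose maximum width defines three design variants
  (27.3, 22.2 and 16.7 mm).
* **`quasivivo`** — a single chamber with a slanted roof, a 1-mm side
  inlet, a lower offset 2-mm outlet, and beads resting on the floor
  (4.0 mL, 0.5 mL/min).

# Governing equations

Flow is steady, incompressible and laminar (inlet Reynolds numbers are
~10–15):

$$-\mu \nabla^2 \mathbf{u} + \rho(\mathbf{u}\cdot\nabla)\mathbf{u}
  + \nabla P + \frac{\mu}{\kappa}\mathbf{u} = 0,
  \qquad \nabla\cdot\mathbf{u} = 0,$$

with water-like medium properties (µ = 10⁻³ kg/m/s, ρ = 1000 kg/m³) and a
Darcy drag µ/κ active only in homogenized porous regions (scaffold, bead
bed, filters). Permeabilities default to the Kozeny–Carman estimate
κ = d²ε³/(180(1−ε)²) from each region's porosity ε and pore/grain scale d.
Wall shear stress is τ = µ|∂u_t/∂n|.

Dissolved species obey advection–diffusion(–reaction):

$$\frac{\partial c}{\partial t} + \nabla\cdot(-D\nabla c)
  = R - \mathbf{u}\cdot\nabla c .$$

The test compound is conservative (R = 0, D = 10⁻⁸ m²/s). Oxygen
(D = 3×10⁻⁹ m²/s) is consumed by cells at the Michaelis–Menten rate with a
smooth low-oxygen cutoff,

$$R(c) = V_{max}\,\frac{c}{c + k_m}\,\delta(c),$$

where δ is a cubic switch that is 0 below −c_cr, ½ + ¾(c/c_cr) − ¼(c/c_cr)³
on [−c_cr, c_cr] and 1 above; it is C¹ and tolerates the small negative
concentrations a transport discretization can produce, which keeps
low-oxygen steady solves stable (`stepdown_delta()`). Dissolved oxygen at
gas interfaces follows Henry's law, P = K·C with K = 932.4 atm/(mol/L);
air-equilibrated medium carries C₀ = 0.214 mol/m³ (214 µM), which is used
at inlets and membranes and scales linearly with the gas-phase oxygen
fraction. A reference solubility of 0.2 mol/m³ appears in the constant
table for completeness but is not used anywhere.

Key kinetic constants and their units:

| quantity | default | units | note |
|---|---|---|---|
| per-cell O₂ consumption | 0.4 nmol/s per 10⁶ cells | mol/s/cell | saturated rate |
| k_m | 5.6 mmHg → 7.90×10⁻³ | mol/m³ | converted once via Henry's law (`km_to_concentration()`); the conversion is recorded in run metadata because the published sources state only the partial-pressure value |
| c_cr | 2.82×10⁻³ | mol/m³ | critical survival level |
| cell counts | 15, 70, 1.5 ×10⁶ | — | scaffold chamber, bed, single chamber |
| bead loading | 50% v/v, 20-µm cells | — | ~4.8×10⁻² mol/m³/s inside a bead |

Compartment-scale V_max is always derived as
(cell count × per-cell rate) / (reconstructed compartment volume)
(`vmax_from_cells()`), so the total consumption capacity is exact by
construction regardless of how the homogenized compartment is meshed.

# Geometry and meshing

Only a handful of dimensions are device-stated: total volumes (7.0, 4.8,
4.0 mL), port diameters, the 1-mm scaffold, the 100-µm filters and pore
sizes, the bed porosity 0.3, and the plan-view widths of the bed variants.
Everything else (channel heights, lengths, port positions, the roof slant)
is a documented default chosen to satisfy the stated volumes and port
sizes; all defaults live in each builder's `dims` and are overridable.

Two of these choices deserve explanation:

* **Width-averaged fluidized bed.** The bed chamber is a lens in plan
  view. A planar section with a constant extrusion depth cannot represent
  the three width variants or reconstruct the 4.8-mL volume, so the
  section carries the local plan width w(x) as a per-column depth: face
  areas and cell volumes scale with w, making continuity, volumes and the
  volumetric feed rate exact for the true shape.
* **Wedge-shaped distributor/collector chambers.** With flat rectangular
  media chambers, the far (dead-end) corners are stagnant pockets that
  fill only by diffusion; the time to concentration uniformity then
  depends strongly on the diffusion coefficient, contradicting the
  device's reported insensitivity to D, and no practical flow-cell is
  machined with that much dead volume. The default section therefore
  tapers each media chamber from its full height at the port to a thin
  (0.4 mm) residual at the far end — the standard dead-volume-free design
  for tangential-flow modules — which keeps the longitudinal sweep
  velocity roughly constant along the bed. Wedge heights follow from the
  4.8-mL constraint with a 45/55 inlet/outlet split.

Meshes are boundary-fitted structured quadrilateral grids: every region
interface and port end point is a grid line, and between those lines the
spacing is uniform at the requested resolution. A simplicial mesh would
buy no accuracy here — all internal interfaces are axis-aligned — while
the structured layout gives exact region volumes, exact port widths, and
a natural staggered-velocity discretization. Curved boundaries (the roof
slant, the wedge tapers) become cell staircases; their volume error is
second order in the resolution. Sums of metric-weighted cell volumes
reproduce the analytic chamber volumes to within quadrature error, and an
axisymmetric mode (weight 2πr) represents bodies of revolution such as
inlet pipes exactly.

# Numerics

* **Flow** (`solve_flow()`): staggered (MAC) finite volumes; central
  viscous fluxes; at walls the viscous flux uses a one-sided quadratic
  ghost that is exact for parabolic profiles, so plane and pipe Poiseuille
  flow are recovered essentially to solver precision (the remaining
  ~0.1% is the midpoint-rule normalization of the inlet profile).
  Convection is first-order upwind, Picard-linearized; the first sweep is
  a Stokes solve and iteration continues to a relative velocity update of
  10⁻⁸ (configurable). Each sweep solves the full saddle-point system with
  a sparse LU factorization; outlet faces carry a zero ghost pressure,
  which also fixes the pressure level. Inlet profiles are scaled so the
  discrete face fluxes sum exactly to the requested volumetric rate; the
  solver refuses inlet Reynolds numbers above 2000 (outside the laminar
  model's validity).
* **Transport** (`solve_transient_transport()`): cell-centered finite
  volumes sharing the staggered face velocities, so interior fluxes
  telescope and the discrete mass balance closes to rounding error — the
  reported balance numbers are genuine boundary-flux accounts. Advection
  is upwind, diffusion central, stepping implicit Euler (dt = 1 s by
  default) with one factorization per run. Recirculation couples the
  outlet flux to a well-mixed external reservoir (default 2 mL — the
  loop volume is unreported, so this is a labeled assumption) feeding the
  inlet; the update uses the same discrete fluxes, so closed-loop mass is
  conserved exactly.
* **Oxygen** (`solve_oxygen_steady()`): same operator, stationary, with
  the sink linearized as R ≈ V_max δ(c*) c/(c*+k_m) and damped Picard
  iteration (relaxation 0.6, tolerance 10⁻⁸); the denominator is floored
  at 0.1 k_m so transient negative iterates cannot destabilize the
  linearization, and negative concentrations are passed to δ unmodified
  rather than clamped.
* **Beads** (`solve_bead()`): node-centered finite volumes on a uniform
  radial grid with r^s-weighted fluxes (s = 2 sphere, s = 1 cylinder), a
  zero-flux center by construction and a Dirichlet surface; the discrete
  surface flux equals the volume-integrated consumption identically, and
  the solver falls back to mesh doubling if Picard stalls. The zero-order
  closed form C_s − V_max R²/(2(s+1)D) (`zero_order_center()`) serves as
  an independent oracle; with the default kinetics the Michaelis–Menten
  correction at 125 µm is under 1%.

# Criteria with no published definition

* **Uniformity**: "time to a uniform distribution" is quantified as the
  first recorded time at which the *minimum* concentration anywhere in
  the fluid domain reaches 95% of the inlet value and stays there
  (`time_to_uniformity()`, threshold configurable). This is the strictest
  reasonable reading; criteria based on the mean or the outlet cross
  earlier.
* **Equilibration of a sampled outlet curve**
  (`estimate_equilibration_time()`): first sample at ≥95% of the plateau
  (median of the trailing samples — robust to normalization-by-maximum
  under multiplicative noise) holding for 3 consecutive samples.
  Overshoot-then-decline curves, the signature of a fast bypass current
  followed by slow back-mixing, are detected on a median-smoothed copy
  and report the first peak with an `overshoot` flag, since a threshold
  crossing would understate true system equilibration.

# The synthetic washout generator

`washout_model()`/`simulate_washout()` emulate the cell-free validation
experiments: a tracer-loaded reservoir recirculating through the chamber,
with the outlet sampled every minute for 30 min (60 min for the slow
scaffold chamber) and the readout normalized to its maximum. The chamber
is a chain of stirred tanks (plug-like as the chain lengthens) with an
optional fast bypass compartment that reproduces the overshoot shape.
Fluorescence and absorbance readouts are modeled as linear in
concentration — wavelengths are metadata; measurement noise is
multiplicative Gaussian with CV 5% by default (no replicate variance was
published, so this is a documented assumption), seeded and reproducible.

What the generator deliberately does not emulate: instrument drift,
tracer adsorption to tubing, photobleaching, or flow-rate fluctuations of
a peristaltic pump. Passing recovery tests therefore demonstrates that
the estimator tolerates sampling and measurement noise, not that it is
robust to systematic experimental artifacts. Across 100 seeds at CV 5%
the estimator's median absolute bias is within one sampling interval.

# Problem sizes

Default resolutions are 0.4 mm (scaffold chamber, single chamber) and
0.35 mm (bed; its thin filters snap to single cell rows), giving
1 400–2 500 cells per device — enough that the reported metrics change by
well under the acceptance tolerances on refinement, while a full
flow + 30-min transport + oxygen scenario runs in seconds. Transient runs
use dt = 1 s with 0.5-min output cadence; bead profiles use 400 radial
intervals (center concentration converged to ~10⁻⁹ relative); recovery
studies use 100 seeds.

# Known limitations

* **Absolute equilibration times in minutes.** With the flux-consistent
  planar normalization used here (the section carries the full volumetric
  feed), the bed model reaches 95% uniformity in ~9.5 min ≈ 2.0 × V/Q.
  The published planar-model figures imply a different, unstated 2D
  normalization whose inlet velocities are higher than flux-consistent
  values (by ~1.6× for the bed, ~5–8× for the other two devices); in
  dimensionless time t·Q/V the two agree. Comparisons against published
  planar-model minutes should therefore be read with this scale factor in
  mind; the comparison against the *measured* bed equilibration (8 min)
  falls within ±35%.
* **Diffusion-coefficient sensitivity.** At D = 10⁻⁶ m²/s diffusion mixes
  the whole chamber within minutes, pushing the uniformity time toward
  the stirred-tank limit 3·V/Q. The spread across D = 10⁻⁶…10⁻¹⁰ m²/s
  stays below 15% for the default bed geometry, but this is a weaker
  insensitivity than a velocity-inflated 2D model would show (there the
  Péclet number is so high that D is simply irrelevant).
* **3D field values.** Published shear-stress ranges and minimum-oxygen
  values from 3D CAD-faithful simulations are treated as orderings and
  monotonic trends only. The homogenized pore-scale shear estimate
  µ(|u|/ε)/(d/2) inside the bed and the tangential-jump surface shear at
  compartment interfaces land in the right ranges, but pointwise 3D
  values are outside a 2D model's reach.
* **Bed flow patterns.** The reported uneven cross-flow among the
  bed-width variants (stronger near the outlet for the original/oval
  designs, nearer the inlet for the narrow one) is a particle-trajectory
  feature; the Brinkman-homogenized bed forces near-uniform crossing, so
  the package asserts only what the closure supports: uniform crossing
  whose superficial velocity rises as the plan width shrinks.
* **Bead symmetry.** Published 2D and 3D bead results disagree with each
  other at 500 µm; both a cylindrical ("2D section") and a spherical mode
  are exposed, the sphere being the physical default, and only the 250-µm
  value is treated as a quantitative target.
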