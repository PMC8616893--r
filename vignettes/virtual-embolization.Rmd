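---
title: "Virtual AVM embolization: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Virtual AVM embolization: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(avmflow)
```

## The clinical problem

A cerebral arteriovenous malformation (AVM) is a tangle of aberrant vessels
— the *nidus* — that shunts blood from feeding arteries directly into the
venous system without an intervening capillary bed. Endovascular treatment
occludes the *feeders* one by one with a sclerosing agent injected as close
as possible to the nidus. Because the feeders share the nidus as a common
outflow bed, occluding one redistributes flow and pressure into the others;
clinicians therefore care about the *order* of occlusion and about leaving
enough feeders open, at every stage, to preserve venous outflow and avoid
abrupt pressure changes. `avmflow` is a scriptable toolkit for exploring
exactly this question on synthetic anatomy: it enumerates every
blocked/unblocked feeder combination, computes the steady flow for each, and
exports the fields in forms a particle-based visualization can consume.

## The flow model and its assumptions

The package deliberately uses a reduced-order (0D/1D) network model rather
than three-dimensional CFD. Each vessel segment is a rigid straight-walled
tube of radius $r$ and centerline length $L$ carrying fully developed
laminar flow, so its hydraulic resistance is the Hagen–Poiseuille value

$$R = \frac{8 \eta L}{\pi r^4},$$

and the vessel graph becomes a resistor network obeying Kirchhoff's current
law: at every interior node the signed volumetric flows $Q = \Delta p / R$
sum to zero. The boundary conditions are the ones a full CFD study of the
same problem would use: a constant inflow velocity $v_{in}$ imposed at the
single parent-artery inlet as a fixed volumetric inflow $Q_{in} = v_{in}
\cdot \pi r_{in}^2$ (at 0D a velocity profile and a flow rate are
equivalent), and zero pressure at every outlet. Blood is incompressible and
Newtonian with density $\rho = 1055\ \mathrm{kg/m^3}$ and dynamic viscosity
$\eta = 4\ \mathrm{mPa\,s}$. Only $\eta$ enters the steady resistances;
$\rho$ is carried for completeness and future pulsatile work.

Assumptions worth keeping in mind:

* **Steady flow, rigid walls.** No pulsatility, no wall compliance. The
  redistribution *patterns* across embolization variants are the target
  quantity, not instantaneous waveforms.
* **Poiseuille resistance per segment.** Valid for long, roughly straight,
  roughly circular vessels at low Reynolds number; curvature, junction
  losses and non-circular lumina are neglected. Nidus vessels are treated
  like any other segment — no porous-medium surrogate.
* **Full occlusion.** An embolized feeder is removed from the flow graph
  entirely (infinite resistance), not given a large finite resistance. A
  sclerosant occludes completely, and removal keeps the linear system well
  conditioned.

The linear solve eliminates the outlets (pressures pinned to 0 Pa), leaving
a sparse symmetric positive-definite system in the remaining node pressures,
factorized by sparse Cholesky via the Matrix package. The mass-balance
residual, reported with every solution, is checked against $10^{-9}$ of the
inflow in the test suite and sits around $10^{-12}$ in practice.

### Inflow templates and rescaling

Two inflow presets are provided: 0.1 m/s for the simpler, cropped anatomy
template and 0.39 m/s for the complex templates — velocities of the scale
measured by phase-contrast MRI in the Circle of Willis of a healthy adult.
When a reference velocity/area pair is supplied, `scale_inflow()` rescales
flow-preservingly: $v_{case} = v_{ref} A_{ref} / A_{case}$, i.e. the
reference volumetric flow is pushed through the case's inflow cross-section.
The direction of this convention is a documented package choice: it keeps
$Q$ — the quantity the network solver conserves — invariant under the
rescaling.

## The synthetic anatomy generator

Patient imaging is out of scope, so `generate_synthetic_avm()` builds the
*topology* that defines the planning problem: a parent artery from a single
inlet to a branching hub; `n_feeders` artery branches each continuing as a
feeder into a distinct nidus boundary node; the nidus as a random connected
graph (a random spanning tree over points drawn uniformly in a ball,
densified with extra random edges up to a target mean degree, 3 by
default); and `n_drainers` draining veins leaving the venous side of the
nidus, each continuing as a vein to its own outlet. Radii are drawn
uniformly per compartment, with defaults at realistic cerebral calibers
(parent artery 1.2–1.5 mm, feeders 0.3–0.6 mm, nidus vessels 0.1–0.25 mm,
draining veins 0.4–0.8 mm, veins 0.8–1.2 mm) in a ~20 mm working volume.
All randomness flows through one seeded generator, so a config is a
complete, reproducible description of an anatomy.

What the generator does **not** emulate: real nidus angioarchitecture
(intranidal aneurysms, fistulous components), vessel tapering, tortuosity
statistics, or tributary inflow into the venous vasculature. Tests passing
on this anatomy therefore demonstrate the correctness of the *machinery*
(enumeration, conservation, redistribution, file formats), not predictive
accuracy for any patient.

## Embolization semantics

`enumerate_variants(n)` yields all $2^n$ blocked/unblocked combinations in
lexicographic bitstring order, all-open first — with three feeders, the
eight variants that drive eight flow computations. Blocking acts at the
feeder's distal, nidus-side end, where the sclerosant is deposited in
practice; `apply_embolization()` emits an occlusion marker there (axis =
local tangent, radius = feeder radius, length = 10% of the feeder length,
display only) and never mutates its input.

`plan_embolization_order()` encodes the clinical heuristic of starting with
small-diameter, proximally located feeders and closing larger, more distal
feeders later, leaving `keep_open` feeders untouched to preserve venous
outflow. Two deliberate choices are embedded: *diameter sorts before
proximity* (the heuristic names them jointly; a deterministic lexicographic
order is needed, and diameter is the quantity most directly tied to the
flow a feeder carries), and *proximal* is quantified as centerline path
distance from the inlet — a package definition, chosen because it is
well-defined on any connected vessel graph. Ties break on segment id, so
the plan is invariant to the order segments are listed in.

## Velocity-field reconstruction and file formats

For visualization, each embolization variant's 1D solution is expanded onto
a Cartesian grid (0.2 mm step by default): every voxel whose center lies
within one radius of a segment centerline takes that segment's laminar
paraboloid, $v = 2\,\bar v\,(1 - (d/r)^2)$ along the local tangent — twice
the mean velocity on the axis, zero at the wall — and voxels outside every
lumen stay zero. The geometry search (nearest segment, $d/r$, tangent per
voxel) is independent of the variant, so the pipeline computes it once and
reuses it across all $2^n$ fields; a voxel claimed by several segments goes
to the nearest one. The grid-summed cross-sectional flux of the
reconstructed field matches the solved $Q$ to about 1% at a step of $r/5$
(the discretization of the circular cross-section dominates the error).

`resample_points_to_grid()` maps externally simulated point samples (read
from legacy ASCII VTK with `read_vtk_ascii()`) onto the same grid
structure. The kernel is the per-voxel arithmetic mean: deterministic and
order-independent, which nearest-sample rules are not; the interpolation
used by the original conversion pipeline is not documented anywhere, so
the mean is a package choice, not a reconstruction of it.

The VF 3D-texture format is written bit-exactly: magic `"VF_F"`, three
little-endian unsigned 16-bit dimensions, then $n_x n_y n_z$ three-float
little-endian vectors, x index fastest — $10 + 12\,n_x n_y n_z$ bytes in
total. Only the vector-field dialect is implemented (the scalar `"VF_V"`
variant is not needed). A VF file carries no world placement, so
`read_vf()` takes origin/step as arguments.

## The particle engine

The advection engine mirrors the four lifecycle stages of a GPU particle
graph. *Spawn* and *initialize* are folded into `spawn()`: it adds
floor-accumulated `spawn_rate * dt` particles (the fractional remainder
carries over) uniformly over an inlet disc or lumen mask, at age 0, with
velocity looked up at the spawn position; the population cap — 2 million by
default — is enforced by suppressing the excess. *Update* is
`advect_step()`: explicit Euler or classical RK4 over the trilinearly
interpolated field, with edge-clamped sampling; age grows by `dt`. *Output*
is `export_snapshot()`: a legacy VTK point cloud with velocity, speed and
RGB attributes.

Two kill rules keep the population physical: age beyond the configured
lifetime, and landing in a voxel whose stored vector is exactly zero —
i.e. outside the lumen. Nothing in the source material defines wall
behavior; killing avoids particles drifting through vessel walls, at the
cost of some attrition in the partial-volume voxels near the wall. Velocity
color coding clamps speed to `[vmin, vmax]` and maps through piecewise
linear tables with stops at 0, ¼, ½, ¾, 1: rainbow
blue→cyan→green→yellow→red and heated-body black→red→orange→yellow→white.
The exact stop values are package choices (no authoritative table exists
for either scale). The ghosted-view weight $\alpha = \alpha_{min} +
(1-\alpha_{min})(1-|\hat n \cdot \hat v|)^k$ uses area-weighted vertex
normals; degenerate normals fall back to $\alpha_{min}$. Blend modes and
textures are renderer concerns and out of scope — only per-particle and
per-vertex attributes are exported.

## The pipeline and the infeasible-variant rule

`run_pipeline()` chains the stages: generate → enumerate → solve each
variant → reconstruct → write one VF file and one flow-report CSV per
variant (named `variant_<bitstring>` for stable sorting) → optional
particle snapshots → a manifest with MD5 checksums of every artifact.
Identical config and seed reproduce byte-identical outputs.

One boundary case needs a rule: on the generated topology all supply
reaches the nidus through the feeders, so the all-blocked variant has no
open inlet→outlet path and a fixed-inflow solve has no solution. The
pipeline records such variants as *infeasible* in the manifest and still
writes their field — all zeros, which is the physically meaningful
velocity field of a fully occluded AVM — so every variant has a VF file
and the variant set stays complete for downstream visualization. The
solver itself, called directly, raises an explicit "no open outflow path"
error instead; feasibility policy belongs to the orchestration layer, not
to the linear algebra.

## Numerical choices and degenerate inputs

* Voxel membership is decided by the voxel *center*; a voxelization step
  larger than the smallest radius triggers an undersampling warning, not an
  error.
* A zero-length centerline is rejected at segment construction; the
  resistance formula itself degrades gracefully ($L = 0 \Rightarrow R = 0$),
  and the solver refuses zero-resistance segments rather than contracting
  nodes silently.
* Trilinear sampling clamps coordinates to the grid; grids degenerate in an
  axis (a dimension of 1) interpolate correctly in the remaining axes.
* Tube meshes use parallel-transported frames (no twist), one capped tube
  per segment, wound outward (positive signed volume) — a labeled display
  surface, not a unioned watertight model.
* `enumerate_variants()` refuses $n > 24$ feeders; $2^n$ growth makes
  exhaustive enumeration meaningless well before that.

## Problem sizes used by the tests

The test suite and the acceptance script run: the full $2^3$-variant
pipeline on the 3-feeder template at 0.2 mm grid step (~1 s); a
2,000,000-particle spawn+RK4 cycle (~40 s, the dominant cost); conservation
over 100 random networks of 1–6 feeders; a 628-step RK4 revolution on a
41³ rotation field; and flux checks at steps of $r/5$ and $r/10$ on a
20 mm tube. These sizes were chosen to exercise every contract at full
fidelity — the particle capacity check in particular runs at the real 2
million cap, not scaled down.

## Known limitations

No wall shear stress or 3D pressure fields (the 0D model has none), no
non-Newtonian rheology, no pulsatility, no partial occlusion, no real
image segmentation, no EnSight Gold reader (the legacy-VTK intermediate is
the supported entry), and no on-screen rendering — snapshots and fields are
the interface to downstream visualization tools.
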