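# avmflow

Virtual embolization and blood-flow visualization pipelines for cerebral
arteriovenous malformations (AVMs).

An AVM shunts arterial blood through a tangle of aberrant vessels — the
*nidus* — directly into the veins. Treatment occludes the feeding arteries
("feeders") one at a time with a sclerosant injected as close to the nidus
as possible, and because the feeders share the nidus as a common outflow
bed, each occlusion redistributes flow and pressure into the remaining
feeders. Interventional neuroradiologists planning such a treatment want to
see, *before* touching the patient, what every combination of occluded
feeders does to the flow. `avmflow` is a scriptable toolkit for that
question on synthetic anatomy, aimed at researchers building hemodynamic
planning and visualization pipelines: it generates seeded synthetic AVM
vessel networks, enumerates all 2^N blocked/unblocked feeder variants,
solves the steady flow for each, and exports Cartesian velocity fields in
the binary VF 3D-texture format that GPU particle systems (e.g. game-engine
VFX graphs) consume, plus a particle advection engine that mirrors their
spawn/initialize/update/output lifecycle.

## The model

Each vessel segment of radius $r$ and centerline length $L$ is a rigid tube
in fully developed laminar flow, with Hagen–Poiseuille resistance

$$R = \frac{8\eta L}{\pi r^4}, \qquad Q = \frac{\Delta p}{R},$$

and the vessel graph is solved as a Kirchhoff network: flows sum to zero at
every interior node, a constant inflow velocity (0.1 or 0.39 m/s per case
template) enters the parent artery as a fixed volumetric flow
$Q_{in} = v_{in}\,\pi r_{in}^2$, all outlets sit at 0 Pa, and blood is
Newtonian with $\eta = 4$ mPa·s and $\rho = 1055$ kg/m³. Embolization
removes a feeder from the graph (full occlusion). For visualization, each
variant's solution is expanded into a 3D velocity grid with the laminar
paraboloid profile $v = 2\bar v\,(1-(d/r)^2)$ per lumen voxel and written
as a VF file (magic `VF_F`, three uint16 dims, float32 triplets,
x-fastest). See the vignette `vignettes/virtual-embolization.Rmd` for
assumptions, parameter choices and limitations.

## Worked example

```r
library(avmflow)

net <- generate_synthetic_avm(avm_config(n_feeders = 3L, seed = 42L))
net
#> <vascular_network> 21 nodes, 29 segments
#>   segments: artery=4 feeder=3 nidus=18 drainer=2 vein=2
#>   inlets: inlet  outlets: out1, out2

fids <- feeder_ids(net)                      # 3 5 7
base <- solve_flow(net, NULL, fluid_properties(), boundary_conditions(0.1))
base
#> <flow_solution> 29 segments, Q_in = 0.6343 mL/s, residual 2.29e-13

# block feeder 3 (the state bitstring "100"), compare against baseline
st  <- embolization_state(c(TRUE, FALSE, FALSE), fids)
var <- solve_flow(net, st, fluid_properties(), boundary_conditions(0.1))
flow_change_report(net, base, var)
#>   feeder_id Q_baseline Q_variant mean_velocity delta_p rel_change pct_change
#> 1         3   1.08e-07  0.00e+00        0.0000      NA     -1.000     -100.0
#> 5         5   2.88e-08  6.01e-08        0.0818    31.2      1.090      109.0
#> 7         7   4.98e-07  5.74e-07        0.7630   311.6      0.154       15.4

plan_embolization_order(net, keep_open = 1L)
#> <embolization_plan> close 2 feeders in order: 5 -> 7 (keep 1 open)
```

Reading the report: with feeder 3 occluded, its flow is −100% by
definition; the inflow it used to carry (0.108 mL/s of the 0.634 mL/s
total) redistributes into the surviving feeders — the small feeder 5 more
than doubles its flow (+109%), the large feeder 7 gains 15% — exactly the
redistribution effect that makes embolization order clinically relevant.
The plan orders the small-diameter, proximal feeders first and keeps one
open to preserve venous outflow.

The full pipeline — all 8 variants of a 3-feeder case, one VF field and one
flow report each, plus a checksummed manifest — is one call (or
`inst/cli/avmflow pipeline --case case1 --seed 7 --out-dir run/` from a
shell):

```r
man <- run_pipeline(pipeline_config("case1", seed = 7L, out_dir = "run"))
length(man$variants)   # 8, named variant_000 ... variant_111
```

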