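# coronet

Morphometry, hemodynamics and perfusion territories of coronary
arterial networks.

## What this package is for

Quantitative descriptions of the human coronary arterial tree — how
vessels branch, how pressure and flow distribute over hundreds of
thousands of segments, and how much tissue each small artery feeds —
require a computational chain that goes well beyond summary
statistics. `coronet` implements that chain for anyone working with
vascular networks stored as node/segment graphs (e.g. extracted from
imaging cryomicrotome or micro-CT data) or who needs realistic
synthetic arterial trees:

* **Graph model** — nodes with 3D positions, cylindrical segments
  with mean diameter and path length; node classification
  (terminals, bifurcations, trifurcations), arcade/loop counting via
  the cycle-space dimension E − V + C, along-network root proximity,
  and mother/daughter orientation from root proximity or solved flow
  directions.
* **Bifurcation morphometry** — daughter symmetry S = d_S/d_L, area
  growth A = (d_L² + d_S²)/d_M², per-diameter-class summaries, and
  estimation of the scaling exponent γ in d_M^γ = d_L^γ + d_S^γ
  (γ = 2 conserves cross-sectional area; γ = 3 is Murray's law,
  equivalent to constant wall shear stress under Poiseuille flow).
  Under that law, A = (1 + S²)/(1 + S^γ)^(2/γ).
* **Stochastic tree synthesis** — extension of a network to the
  capillary domain (5.0–7.5 μm): per-diameter-class symmetry and
  length-to-diameter distributions drive a binary cascade in which
  daughter diameters satisfy d_L = d_M √(A/(1+S²)), d_S = S·d_L.
* **Hemodynamics** — diameter-dependent in vivo blood viscosity
  (Fåhraeus–Lindqvist effect), Poiseuille conductances
  G = πd⁴/(128 μ l), and a sparse Kirchhoff solve (∑ Q = 0 at every
  junction) with inlet pressure 90 mmHg and a capillary reservoir at
  20 mmHg; loops and trifurcations are handled natively. Derived
  fields: flow, centerline velocity, wall shear stress
  τ = |ΔP|·d/(4l).
* **Distal conductance imputation** — the downstream conductance of
  every segment of an in silico ensemble is computed by one
  reverse-topological sweep; terminals of a measured network then
  receive conductances by window-median, power-law, or stochastic
  draws, and the variability of the resulting hemodynamics is
  quantified (CV, MAD, correlation and slope against the stochastic
  median).
* **Perfusion territories** — Voronoi labeling of myocardial voxels
  by nearest terminal, truncation segments in a diameter band
  (default 100–200 μm), per-territory perfusion in ml/min/g, and
  transmural (subepi/mid/subendo) summaries.

All internal units are SI (m, Pa, m³/s, Pa·s); reporting helpers
convert to μm, mmHg, ml/min and cm/s (1 mmHg = 133.322 Pa).

## Worked example

Build a heart-like synthetic network (400 terminals in a 6.4 mm
slab, 5% arcade loops, 8% trifurcations, 2:1 endo:epi terminal
gradient), impute terminal conductances from an in silico ensemble,
and solve its hemodynamics:

```r
library(coronet)

stats <- reference_statistics()
dom   <- domain_slab(extents = c(6.4e-3, 6.4e-3, 6.4e-3), voxel = 1e-4)
net   <- generate_embedded_network(dom, target_terminals = 400, stats,
                                   loop_fraction = 0.05,
                                   trifurcation_fraction = 0.08,
                                   gradient = 2, seed = 42)
net
#> <vascular_graph>
#>   nodes: 770  segments: 787  roots: 1  loops: 18
#>   diameter range: 30.0 - 253.0 um
#>   terminals: 400  bifurcations: 305  trifurcations: 62

ens   <- generate_ensemble(8, stats, root_diameter_range = c(80e-6, 140e-6),
                           seed = 43)
model <- build_conductance_model(ens, diameter_range = c(25e-6, 400e-6))
model
#> <conductance_model> 4876 pooled segments, window +/- 2.5%
#>   power law: G = 0.098 * d^2.861 (log-log r2 = 0.955)

bc  <- impute_terminal_conductance(net, model, mode = "median")
sol <- solve_pressures(net, bc)
sol
#> <hemodynamic_state>
#>   nodes: 770  segments: 787  terminals: 400
#>   inlet: 90.0 mmHg  capillary: 20.0 mmHg  inflow: 0.894 ml/min
#>   Kirchhoff residual: 2.33e-15 (relative)

estimate_gamma(extract_bifurcations(net), n_boot = 200)
#> Scaling exponent gamma = 3.5284 (robust 3.8421), n = 298
#>   95% bootstrap CI: LS [3.1609, 3.8334], robust [3.8240, 3.8702]
```

Reading the output: the network's 18 loops are arcades (cycle-space
dimension), the pooled conductance model says distal conductance
grows roughly with d^2.9 over the sampled band, the 0.894 ml/min
inflow is the whole slab's supply at a 70 mmHg driving pressure, and
the Kirchhoff residual confirms mass balance at solver precision.
The scaling exponent above 3 reflects the strongly symmetric,
area-growing branching of the microcirculatory fixture.

For perfusion, pass a voxel grid: `slab_grid(dom)` →
`voronoi_assign()` → `truncation_segments()` →
`territory_perfusion()` → `regional_summary()`, or run the whole
chain with `run_pipeline()`.

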