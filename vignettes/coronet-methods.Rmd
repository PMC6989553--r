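---
title: "Models and methods behind coronet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind coronet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`coronet` analyzes and simulates coronary arterial networks: graphs
of nodes (3D positions) and cylindrical segments (mean diameter,
path length). This vignette explains the models, the tunable
parameters and their defaults, the synthetic-data generators and
what they do and do not emulate, and the numerical and design
choices made where the design was genuinely open.

## The graph model

A network is valid when every node is reachable from the root set
and terminal nodes (degree 1) are not roots. Degree-2 nodes are
mid-segmental sampling points, not branch points: `build_network()`
merges each chain of them into one segment whose length is the sum
and whose diameter is the length-weighted mean of the parts. Branch
nodes are classified by degree: 3 = bifurcation, 4 = trifurcation,
≥ 5 = higher-order. Arcades (loops) are counted as the cycle-space
dimension E − V + C, which is exact for any graph and zero for a
tree.

Orientation (which segment end is the "mother" side) is two-pass:
provisional orientation by along-network root proximity, then
optionally re-orientation by the signs of solved flows. The solver
itself is orientation-independent, so this is consistent. Flows
within a relative tolerance of zero (default 1e-12 of the maximum)
fall back to the proximity rule and are flagged; exact proximity
ties go to the lower node id, also flagged, so results are
deterministic and auditable.

## Bifurcation morphometry

At an oriented bifurcation with mother diameter $d_M$ and daughters
$d_L \ge d_S$:

* symmetry $S = d_S / d_L \in (0, 1]$,
* area growth $A = (d_L^2 + d_S^2) / d_M^2$.

If diameters obey a scaling law $d_M^\gamma = d_L^\gamma +
d_S^\gamma$, then $A = (1 + S^2)/(1 + S^\gamma)^{2/\gamma}$: for
$\gamma = 2$, $A \equiv 1$ (area conservation); for $\gamma > 2$, A
increases with symmetry; $\gamma = 3$ (Murray) gives $A = 2^{1/3}$
at $S = 1$ and constant wall shear stress under Poiseuille flow.

**Estimating γ.** The default estimator minimizes the mean squared
normalized residual $(d_M^\gamma - d_L^\gamma -
d_S^\gamma)/d_M^\gamma$, which weights small and large vessels
equally. Different objectives yield different estimates and all are
sensitive to extreme bifurcations, so a robust variant is always
reported: the root of the *median* normalized residual. The two
differ in an important way under measurement noise. Multiplicative
(log-symmetric) diameter noise inflates the expected value of
$(d/d_M)^\gamma$ terms by $e^{\gamma^2\sigma^2}$, biasing the
least-squares estimate low by about 1% at 5% noise — small, but
larger than a bootstrap confidence interval at n = 5000. The median
residual is invariant to symmetric log-scale noise (the median of a
lognormal factor is 1), so its root is median-unbiased; this is the
estimator to use for recovery of a generating exponent from noisy
diameters. Both estimators carry percentile bootstrap CIs (1000
case resamples by default, seeded).

**Area-growth regression.** The linear model A ~ d_M + S is fitted
over a configurable mother-diameter window (default 75–600 μm) with
d_M in millimeters; with diameters spanning only ~0.1–0.6 mm the
raw coefficient scale depends strongly on the unit convention, so
standardized coefficients are reported alongside.

**Diameter classes.** Ten half-open classes, [30,45), …, [150,200),
[200,400) and [400 μm, ∞); a value on a boundary joins the class it
opens. Segments are binned by their own diameter, bifurcations by
the mother's.

**Power laws.** `fit_power_law()` fits $y = a x^\gamma$ by
nonlinear least squares in linear space (Levenberg–Marquardt,
initialized from the log-log regression), with $r^2$ computed in
the space of the fit; a log-log variant is available by flag
because published allometric $r^2$ values are often computed either
way and the two differ.

## Stochastic tree synthesis

`generate_tree()` grows a binary cascade from a root segment.
At each step, for a mother of diameter $d_M$:

1. draw $S$ from the mother's diameter-class symmetry sampler;
2. evaluate (or sample) area growth $A(d_M, S)$;
3. set $d_L = d_M\sqrt{A/(1+S^2)}$ and $d_S = S\,d_L$ — the unique
   inversion of the definitions of S and A;
4. draw each daughter's length from the length-to-diameter sampler
   of the *daughter's own* class.

Branching stops for a segment once its diameter is at or below the
upper capillary bound (default 7.5 μm of the 5.0–7.5 μm capillary
band). Diameters are not clamped to the band, so the achieved
terminal-diameter distribution straddles it from above and is
itself reportable. One guard exists: symmetry draws that would
create a daughter thinner than 2 μm are redrawn (at most 20 times,
then floored), because the in vivo viscosity law is singular at
1.1 μm and hemodynamic quantities are undefined below it; such
draws are vanishingly rare with the default statistics.

The deterministic area-growth mode is the default (daughters "set
to match" the class area-growth relation); a sampled mode
(Gaussian noise around the linear model) is available, since data
only constrain the conditional mean. Whether real daughter
diameters scatter around that relation jointly or independently is
not identifiable from class summaries.

Ensembles (`generate_ensemble()`, default 50 trees with root
diameters uniform in 300–400 μm) derive per-tree sub-seeds from the
master seed by a fixed Lehmer-step scheme, so ensembles are
reproducible and individual trees re-derivable. Root diameters are
drawn uniformly; matching them to observed segment diameters is an
alternative the data do not force.

**Reference statistics.** `reference_statistics()` encodes the
qualitative branching structure of a human coronary network as a
documented fixture: symmetry medians rising from 0.55 in the
largest class to 0.80 in the smallest (Beta samplers whose
dispersion tightens toward small vessels); area growth following
the linear relation $A = 1.13 - 0.66\,d_M[\mathrm{mm}] +
0.34\,S$ (d_M capped at 0.6 mm, clamped to [0.85, 1.8]), which
plateaus near 1 at and above 400 μm and grows toward the
microcirculation; and right-skewed lognormal length-to-diameter
ratios with class medians roughly constant (≈ 5) over 75–200 μm,
shorter in the smallest and the epicardial classes. Below the
lowest class edge (30 μm) the smallest class's samplers are reused
with the symmetry median continued linearly in log-diameter
(slope 0.03 per decade, capped at 0.98) via a power-warp that
preserves the (0,1] support.

With these statistics a full cascade from a 300–400 μm root to the
capillary band contains on the order of 10⁶ segments. The package's
tests and the acceptance script therefore run the same generator at
smaller root diameters (60–200 μm, giving 10³–10⁵ segments per
tree) — a problem-size choice, not a change of mechanism; every
closed-form and conservation property holds at any scale.

**The embedded fixture.** `generate_embedded_network()` builds a
spatially embedded network inside a slab for end-to-end testing:
terminal positions sampled with density increasing linearly along
the transmural axis (a 2:1 endo:epi gradient by default mimics the
subendocardial density excess), a binary tree over the terminals by
recursive bisection (internal nodes at subset centroids), diameters
assigned bottom-up by inverting the area-growth relation, then
requested fractions of trifurcations (a bifurcation contracted into
its parent, path lengths accumulating) and arcade loops (chords
between nearby similar-caliber nodes). Segment lengths always
exceed the Euclidean endpoint distance (tortuosity factor
1.05–1.25). This emulator's contract is statistical structure, not
anatomy: it has no ventricular geometry, no space-filling
optimization, no correlations between successive bifurcations, and
loop chords raise the degree of the nodes they touch (so arcades
and "trifurcations" are not independent counts, exactly as in
skeletonized real networks). Passing tests on it demonstrate the
pipeline's mechanics, not fidelity to any particular heart.

## Hemodynamics

Blood is incompressible and Newtonian per segment, with the
empirical in vivo viscosity law (Fåhraeus–Lindqvist effect) at
fixed discharge hematocrit (default 0.4): with d in micrometers,

$$\mu_{rel} = \Big[1 + (\mu^*_{0.45} - 1)\,
\frac{(1-H_d)^C - 1}{(1-0.45)^C - 1}
\Big(\frac{d}{d-1.1}\Big)^2\Big]
\Big(\frac{d}{d-1.1}\Big)^2$$

with the standard sub-expressions for $\mu^*_{0.45}(d)$ and
$C(d)$. The squared $d/(d-1.1)$ factor appears both inside and
outside the bracket; at $H_d = 0.45$ the large-vessel limit is 3.2
and at zero hematocrit the law collapses to the outer factor
alone. Note the law is not monotone in diameter: at $H_d = 0.4$ it
falls to a minimum near 45–50 μm and then climbs to the
large-vessel plateau — the classic viscosity reduction toward the
microcirculation holds below that minimum, while the thickness of
the exclusion layer dominates in the smallest vessels. The law
yields viscosity *relative to plasma*; absolute viscosity
multiplies by a configurable plasma viscosity (default 1.2 mPa·s,
recorded in run metadata). With pure pressure boundary conditions
all conductances scale by 1/μ_plasma uniformly, so the pressure
field is invariant to this choice — a property the test suite
asserts rather than assumes.

Each segment conducts $G = \pi d^4 / (128 \mu l)$ and carries
$Q = G\,\Delta P$. Conservation of mass at every junction yields a
sparse linear system in the node pressures: root nodes are
Dirichlet-pinned at the inlet pressure (default 90 mmHg), and every
terminal connects to a single virtual capillary reservoir (default
20 mmHg) through its distal conductance — the hybrid
measured-plus-imputed arrangement. An infinite distal conductance
pins the terminal at capillary pressure, which is the natural
boundary for fully synthesized trees. The system is assembled as a
Laplacian over free nodes and solved by `Matrix`'s sparse direct
factorization; the achieved Kirchhoff residual (max node imbalance
relative to the max flow) is stored on the result and asserted
≤ 1e-8 in tests (in practice ~1e-15). Junction losses, vessel
compliance, pulsatility and myocardial contraction are outside the
model.

Wall shear stress is reported as the magnitude $\tau = |\Delta
P|\,d/(4l)$ (identically $32\mu Q/(\pi d^3)$), centerline velocity
as $2Q/(\pi (d/2)^2)$, twice the mean velocity of the parabolic
profile.

**Downstream conductance.** On a tree, the total conductance of the
network distal to each segment (referenced to the capillary
reservoir) is computed in one reverse sweep: terminal segments
contribute their own conductance; an internal segment is its own
conductance in series with the parallel sum of its children. The
sweep is processed level-by-level (hop depth) so it vectorizes;
equality with inlet flow / driving pressure from a full solve to
1e-9 is an acceptance property. On looped graphs the function
refuses to run — the notion is well-defined only on trees, and the
effective conductance must come from a solve.

**Imputation.** `build_conductance_model()` pools (diameter,
downstream conductance) pairs over an ensemble — per-tree log-log
fits vary little, which justifies pooling — fits a power law on the
log-log pooled data, and answers queries by the median of the
window of segments within ±2.5% of the query diameter. The pooled
table is restricted by default in `run_pipeline()` to the 30–400 μm
band over which conductances are imputed; including the capillary
domain would bend the log-log relation (distal conductance becomes
nearly diameter-independent in the smallest vessels) and degrade
the power-law fallback. Three imputation modes: `stochastic`
(independent uniform draw from the window values per terminal —
draws are independent per terminal and per run, the simplest
defensible reading of "a distribution of downstream conductances"),
`median` (window median) and `powerfit`. Empty windows fall back to
the power law and are flagged.

**Variability analysis.** `stochastic_ensemble_analysis()` solves
under n independent stochastic imputations (desk-scale default 200;
1000 available by argument) and reports, per quantity (node
pressure, |flow|, wall shear stress), the median and 95th
percentile across elements of the per-element CV and median
absolute deviation, plus the agreement of each deterministic mode
with the per-element stochastic median: Pearson correlation and the
zero-intercept least-squares slope β — the undefined "agreement"
statistics were pinned to these two standard choices.

## Perfusion territories

Voxels of a myocardial grid are labeled by their Euclidean-nearest
terminal node (exact chunked computation, ties to the lowest
terminal id — no approximate spatial index, so labels are
reproducible bit-for-bit). The truncation segments are the first
segments along each root-to-terminal path whose diameter drops
below the band's upper bound (default 200 μm); segments also below
the lower bound (100 μm) are flagged as below-band but retained, so
inclusive and band-only summaries are both possible. Each
territory is the union of the Voronoi cells of the terminals its
truncation segment feeds; perfusion is the truncation-segment flow
divided by territory mass (volume × tissue density, default
1.05 g/cm³ — a conventional myocardial density, configurable and
recorded). Transmural regions are closed-open depth thirds:
subepicardium [0, ⅓), midmyocardium [⅓, ⅔), subendocardium [⅔, 1].
On looped networks the truncation analysis runs on the
breadth-first spanning subtree from the roots (chords dropped), the
same reduction a flow-ordered collapse would give on arcades with
near-zero chord flow.

## Numerical choices and degenerate inputs

* Sparse solve: direct Cholesky/LU on the free-node Laplacian;
  singular systems (isolated subnetworks) raise an error naming the
  unreachable nodes at validation time.
* Kirchhoff residual and energy balance (segment dissipation plus
  terminal dissipation equals driving power) are computed, not
  assumed; tests require ≤ 1e-8 relative.
* `estimate_gamma` searches γ ∈ [0.5, 8] by golden-section to
  1e-10; an interval without a median-residual sign change falls
  back to minimizing |median residual|.
* Empty diameter classes, empty profile bins and zero-voxel
  territories are emitted as rows with n = 0 and NA statistics, not
  dropped.
* Segments shorter than their diameter (a quality condition on
  extracted networks) are flagged on load, never silently removed.
* All randomized functions take explicit seeds; ensembles and
  stochastic runs derive sub-seeds deterministically, and repeated
  runs are bit-identical.

## Known limitations

* The synthetic fixtures carry no anatomical geometry; regional
  summaries on them validate bookkeeping, not physiology.
* The tree generator draws symmetry independently across
  generations; real networks may have correlated successive
  branchings, which would broaden in silico variability.
* Steady-state Poiseuille flow only: no pulsatility, compliance,
  autoregulation, or junction losses.
* The viscosity law is applied outside its calibration range when
  trees descend below ~3 μm; the 2 μm daughter floor keeps
  evaluations defined but such segments are extrapolations.
* Full-scale ensembles (50 trees from 300–400 μm roots) are
  computationally heavy in plain R; the shipped analyses use
  smaller roots, and all scale-free properties are asserted there.
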