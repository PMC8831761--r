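---
title: "A discrete vascular–porous media model of skin bioheat transfer and perfusion inversion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A discrete vascular–porous media model of skin bioheat transfer and perfusion inversion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
```

hemotherm simulates steady heat and blood transport in a voxelised patch of
perfused tissue and inverts skin-temperature recordings into inlet blood
flow. This vignette is the package's own account of the model: the four
coupled domains and their equations, the parameters that matter, the
numerical choices, what the synthetic data emulate, and the limitations a
user should keep in mind.

## The physical model

Tissue is treated as a porous medium whose liquid phase is the blood in
capillaries (volume fraction $\varepsilon_3$) and whose solid phase is the
tissue itself ($\varepsilon_2 = 1 - \varepsilon_3$). Vessels large enough to
matter individually — arteries, arterioles, veins, venules — are discrete
1-D segments with radii, embedded in the voxel grid. Four temperature fields
are solved simultaneously: $T_1$ on artery segments, $T_2$ in the tissue
phase, $T_3$ in the capillary phase and $T_4$ on vein segments.

**Blood flow.** Flow in the 1-D network follows Poiseuille's law: each
segment has hydraulic conductance $g = \pi R^4 / (8 \mu L)$, and nodal mass
balance gives a sparse linear pressure system per tree. The boundary data
are prescribed volumetric flows: the inlet flow at the artery root and the
exchange flows at terminal (arteriole/venule) nodes. In the capillary
continuum the momentum balance reduces to Darcy's law
$\nabla P = -(\mu / K)\, \mathbf{V}_{Darcy}$, discretised by a cell-centred
finite-volume scheme with harmonic-mean face transmissibilities and no-flux
exterior faces; per-voxel sources $Q_a$ (from artery terminals) and sinks
$Q_v$ (to vein terminals) drive the porous flow.

**Network–porous coupling.** The total inlet flow is distributed to voxels
as perfusion demand and split evenly over each voxel's coupled terminal
nodes ($q_a = Q_a/n$, $q_v = Q_v/m$, where $n$ and $m$ count the terminal
artery and vein nodes in the voxel). The default policy weights voxels by
their count of *reachable* terminals — terminals cut off by a fully
occluded segment receive nothing, which is what makes an occluded inlet
starve its whole downstream territory. Arterial demand and venous return
are assigned on their own voxel sets, so the Darcy phase genuinely carries
blood from arterial to venous coupling sites; a `local_balance` policy
(equal source and sink per voxel, no net capillary drift) is available for
comparison. An alternative policy weights by tissue volume instead of
terminal count. Whatever the policy, every solve certifies the conservation
chain

$$Q_{in} = \textstyle\sum q_a = \sum Q_a = \sum Q_v = \sum q_v = Q_{out}$$

to $10^{-10}$ relative.

**Energy balance.** Each domain's steady balance contains conduction
(central differences; 6-neighbour in the voxel phases, along the tree in
the 1-D domains), advection (first-order upwind on the solved flows, with
flow-weighted mixing at vessel junctions), inter-domain film exchange
$\beta_{x\text{-}y}(T_y - T_x)$, the advected enthalpy of the exchanged
blood (written in donor form — the donor's temperature multiplies the
transferred mass — so the paired terms cancel exactly in the global sum),
metabolic heating $Q_{gen}$ in the tissue phase, and the surface boundary
terms. The assembled system $A\,x = B$ has one row per artery segment,
tissue voxel, capillary voxel and vein segment, and is solved directly or
by a preconditioned Krylov iteration (below).

**Exchange coefficients.** The vessel-wall film coefficient uses the
constant-Nusselt laminar-pipe relation $h = \mathrm{Nu}\, K_b / D$ with
$\mathrm{Nu} = 4$. For a segment sharing lateral area $A$ with a voxel, the
wall exchange splits by volume fraction: $\beta_{1\text{-}2} =
\varepsilon_2 h A$ towards tissue and $\beta_{1\text{-}3} = \varepsilon_3 h
A$ towards capillary blood, so the total is $hA$ with no double counting;
`wall_epsilon_split = FALSE` instead gives the full area to both pairs for
comparison with the literal reading of the exchange definition. The
tissue–capillary exchange inside a voxel uses the capillary-scale film
coefficient and the interfacial area of cylinders of diameter $d_{cap}$ at
volume fraction $\varepsilon_3$: $A_{2\text{-}3} = 4\varepsilon_3 V /
d_{cap}$. With the default $d_{cap} = 8\,\mu m$ this coupling is orders of
magnitude stiffer than voxel conduction, which is physically right (tissue
and capillary blood equilibrate within a voxel) and is the main source of
ill-conditioning the solver has to handle.

**Boundary conditions.** The exposed skin carries a Robin condition
$-K\,\partial T/\partial n = h_{env}(T - T_\infty)$ with a combined
convective + radiative $h_{env} = 8\ \mathrm{W/(m^2 K)}$; all other
boundaries are adiabatic. An imposed flux (the heater) adds to the load on
the heating mask. The arterial inlet enters as an upwind stream at
$T_{inlet} = 37\,^\circ$C: this "advective" inlet conserves energy exactly,
whereas a Dirichlet row on the root element (also available via
`inlet_mode`) discards the root element's own balance; the global audit is
why the advective form is the default. The vein outlet needs no condition —
upwinding makes it pure outflow.

## The phantom and the sensor pad

The built-in phantom is an 18 × 18 × 9 mm all-soft-tissue slab at 0.3 mm
voxels (60 × 60 × 30), sized to the footprint of the flexible heater/sensor
pad it emulates. The heater is an annulus on the top face, inner radius
3.5 mm, outer radius 6.9 mm, driven at 150 W/m² during the heating phase;
the sensor reads the skin temperature at the face centre, inside the
annulus.

One modelling decision deserves emphasis. The device is a contact pad
resting on the skin, so the skin under its footprint cannot exchange heat
with the ambient air; only the uncovered corners of the patch do. The
phantom therefore marks the inscribed disc (radius 9 mm) as *covered*:
covered faces get no Robin exchange, though the ring flux still enters and
the skin temperature is still read there. This cover is not a detail — it
decides the sign of the heated response. With the whole top face exposed, a
surface energy balance caps the heated surface at roughly
$q A_{ring} / (h_{env} A_{top}) \approx 6.4\,^\circ$C above ambient, i.e.
~30 °C — always *below* the 37 °C blood, so more perfusion would *warm* the
heated spot. With the pad in place the trapped ring flux drives the covered
region well above blood temperature at low flow, and perfusion *cools* it:
the heated centre-point temperature then falls steeply between 0 and
0.002 ml/s and flattens beyond — the behaviour the whole inversion protocol
relies on. `device_cover = FALSE` reproduces the fully exposed variant.

## The vessel generator

Trees grow by a rapidly-exploring random tree: sample a point uniformly in
tissue (a uniformly chosen tissue voxel, jittered within the voxel), link
it to the closest existing node or segment, and split a segment when the
closest point falls strictly inside it. Arteries and veins grow as
independent trees from a seed pair — one inlet artery and one outlet vein
entering from opposite faces at mid-depth. Ties go to the lowest segment
id and all randomness flows from one integer seed, so growth is exactly
reproducible. The phantom uses 2000 iterations, after which added segments
no longer move the temperature field appreciably at this domain size;
`surface_mse()` quantifies that convergence between successive growth
stages. Early stopping on a segment-count plateau combined with a terminal
flow threshold is available (`stop=`), but no default threshold is
asserted — the arteriole flow at which growth is "complete" is problem
knowledge.

Radii follow the bifurcation power law $r_p^\gamma = \sum r_c^\gamma$ with
$\gamma = 3$ (Murray's law), implemented as
$r = r_{root} (\ell / \ell_{root})^{1/\gamma}$ where $\ell$ counts the
leaves a segment feeds — this satisfies the law exactly at every junction
and is non-increasing towards the leaves. The root radius default of
0.2 mm (0.4 mm diameter) represents a small subcutaneous feeding artery;
with it, the smallest generated vessel in the 2000-iteration phantom comes
out near 37 µm in diameter, i.e. arteriole scale. No radius-assignment rule
is uniquely "right" here; the rule and its two parameters are exposed.

## Numerical choices

* **Linear solves.** Small systems go through a sparse direct
  factorisation; the Darcy pressure equation and any other symmetric system
  through CHOLMOD Cholesky; large nonsymmetric energy systems through
  ILU(0)-preconditioned BiCGSTAB (compiled in C) with defect-correction
  refinement. Two details matter for accuracy on the stiff
  capillary-exchange coupling: rows are equilibrated by their diagonal, and
  the energy system is solved in offset units $\theta = T - T_\infty$,
  which removes the large common mode that otherwise limits attainable
  precision. Every solve certifies a normwise backward error below
  $10^{-10}$ (residual relative to the larger of the load and solution
  scales) or raises an error.
* **Degenerate elements.** A fully occluded (zero-radius) segment has zero
  conductance, zero wall area and zero exchange; its otherwise
  unconstrained temperature row is slaved to the tissue temperature of a
  voxel it traverses.
* **Voxelisation.** Segment–voxel intersections use exact parametric plane
  crossings, so per-segment intersected lengths sum to the segment length
  to machine precision.
* **Duplicated-term and factor toggles.** The tissue-phase balance is
  assembled with a single tissue–capillary exchange term
  (`double_beta23 = TRUE` reproduces a doubled variant), and the wall film
  coefficient's factor (`wall_h_factor`) covers both readings of the
  Nusselt definition (1 or 2).
* **Temperatures in °C.** All equations are affine in temperature, so the
  offset is harmless, and the energy audit's enthalpy baseline cancels
  because mass is conserved.

Reference physical parameters: blood viscosity 3.5 mPa s, permeability
1.5e-13 m², blood 1050 kg/m³ / 3800 J/(kg K) / 0.50 W/(m K), soft tissue
1270 / 3768 / 0.35, bone 1418 / 2409 / 2.21, metabolic heat 368 W/m³,
$h_{env}$ 8 W/(m² K), ambient 23 °C, inlet blood 37 °C, heater 150 W/m²,
Nu 4, $\varepsilon_3$ 0.05 (a typical capillary volume fraction; no
reference value exists for this parameter, so it is exposed rather than
hidden), capillary diameter 8 µm.

## The measurement protocol and inversion

The protocol is rest (750 s, heater off), heating (1000 s, 150 W/m²),
recovery (1000 s, heater off) — 2750 s in total. Because each phase is long
enough to stabilise, the inversion uses only the mean of the last 100 s of
each phase and steady-state forward solves; no transient heat equation is
needed (and none is implemented).

The forward sweep solves the phantom over inlet flows 0–0.01 ml/s and
ambient temperatures 20–24 °C in both heater states and records the
centre-point skin temperature. The default flow grid is densest below
0.002 ml/s where the heated response is steepest; with it, inverting a
temperature produced by an off-grid forward solve recovers the flow to
better than 1% across the working range. The response surface is fitted per
heater state. The default fit is a shape-preserving monotone cubic spline
in flow at each swept ambient level, blended linearly across ambient — the
steady solution is affine in ambient temperature, so linear blending is
exact, and the monotone spline captures the steep low-flow knee that a
global low-order polynomial cannot (a cubic-in-flow polynomial fit is
available as `method = "poly"`, but over the full 0–0.01 ml/s range it
misses the knee by far more than the 0.05 °C residual bound and is
rejected). Every fit is certified on a dense grid: off-state strictly
increasing in flow and non-decreasing in ambient, on-state strictly
decreasing in flow, residual RMS ≤ 0.05 °C.

Inversion maps each phase's stabilised temperature through the matching
surface (off for rest/recovery, on for heating) by monotone root finding;
temperatures outside the attainable range are clipped to the domain edge
and flagged. The three-phase pattern is classified as `HEALTHY_LIKE`
(recovery returns to within 10% of rest and heating raised the flow),
`DELAYED_EXCEEDING` (recovery at or above the heating flow) or
`DELAYED_PARTIAL` (in between) — the regulation patterns relevant to
screening for impaired vasodilation.

## What the synthetic data do and do not emulate

`synthesize_trace()` builds protocol traces from per-phase steady forward
temperatures joined by first-order exponential relaxation plus Gaussian
sensor noise. The relaxation constant exists only to make the fixtures look
like recordings; the inversion never uses the transient part. Passing the
round-trip tests therefore shows that the *steady* forward model and the
inversion are consistent with each other — it does not validate transient
skin thermodynamics, vasomotion dynamics, subject-specific anatomy (fat
thickness, vessel depth), drift in ambient temperature, or sensor artefacts
such as contact-pressure changes, all of which real recordings contain.
The generator's defaults (noise s.d. 0.05 °C, relaxation 60 s, the protocol
above) are the conditions under which the package's accuracy statements are
made.

## Problem sizes used by the tests

The test-suite and acceptance checks choose resolutions to keep a full run
within minutes while preserving every structural property: the
mass-conservation chain and the smallest-vessel diameter run at the full
0.3 mm phantom with 2000 growth iterations; the energy-balance and
field-structure checks run at 0.6 mm with 2000 iterations; sweeps,
response surfaces and inversion run at 0.9 mm with a 500-iteration network
(the monotone structure of the response is insensitive to this
coarsening, and all conservation checks are resolution-independent). The
spatial field checks use an inlet flow of 0.002 ml/s, inside the steep
sensitive regime of the heated response. Self-convergence is checked by
halving the voxel size (0.9 mm to 0.45 mm) under a fixed network, moving
the centre-point temperature by less than 0.1 °C.

## Known limitations

* Rigid vessels, Newtonian blood at constant viscosity, no pulsatility and
  no autoregulation: the flow problem is linear.
* Steady state only. The protocol's transients are deliberately outside
  scope; only stabilised phase tails are inverted.
* The sensor-pad cover is a binary insulated/exposed split; a finite
  pad-contact resistance would sit between the two variants.
* The generator produces geometrically plausible, space-filling trees, not
  anatomically derived ones; bifurcation angles and fractal measures are
  not tuned.
* Absolute inverted flows are only as meaningful as the phantom geometry
  and parameter set; the pattern classification (relative flows across
  phases) is the robust output.
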