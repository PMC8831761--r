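# hemotherm

Skin temperature tracks skin blood flow, which makes non-invasive thermal
measurements attractive for screening peripheral vascular dysfunction —
e.g. the impaired vasodilation that precedes diabetic foot complications.
Quantifying that link needs a forward model that respects where the blood
actually goes. hemotherm implements a discrete vascular–porous media
bioheat model for exactly that purpose: vessels large enough to matter
(arteries, arterioles, veins, venules) are explicit 1-D segments grown by a
rapidly-exploring random tree inside a voxelised tissue domain, while the
capillary bed is a Darcy porous phase occupying a volume fraction
ε₃ of every voxel. Four temperature fields — arterial T₁, tissue T₂,
capillary T₃, venous T₄ — are coupled by film exchange across vessel walls
(h = Nu·K_b/D, Nu = 4), by the advected enthalpy of the exchanged blood,
and by conduction, and solved as one steady sparse system.

On top of the forward model sits the measurement workflow of a skin
heating test: a contact pad applies a 150 W/m² annular flux to the skin
over a rest (750 s) / heat (1000 s) / recover (1000 s) protocol; forward
sweeps over inlet flow Q ∈ [0, 0.01] ml/s and ambient temperature
T∞ ∈ [20, 24] °C yield two monotone response surfaces
T_skin(Q, T∞) (heater off: increasing in Q; heater on: decreasing in Q);
and each phase's stabilised temperature is inverted through the matching
surface to a per-phase inlet blood flow, classified as `HEALTHY_LIKE`,
`DELAYED_PARTIAL` or `DELAYED_EXCEEDING` according to how the recovery
flow relates to rest and heating.

The package is aimed at researchers in bioheat transfer and thermal
physiology who want a reproducible, fully testable desk-scale
implementation: every solve certifies mass conservation
(inflow = Σq_a = ΣQ_a = ΣQ_v = Σq_v = outflow, to 1e-10) and a global
energy audit, and every stochastic step is driven by one integer seed.

## Worked example

`cmd_demo()` runs the whole pipeline on a coarse (0.9 mm) phantom: grow the
vessel trees, solve the coupled flow and heat problem, sweep and fit the
response surfaces, synthesise a noisy healthy trace and invert it.

```r
library(hemotherm)
cmd_demo("demo_out", seed = 1)
#> grow: 1603 segments, min diameter 58.1 um
#> simulate[off]: centre 36.68 degC, energy imbalance 6.8e-11
#> demo: pattern HEALTHY_LIKE; flows 0.0020/0.0060/0.0021 ml/s
#> # A tibble: 1 x 6
#>   subject Q_rest_ml_s Q_heat_ml_s Q_rec_ml_s pattern      any_extrapolated
#>   <chr>         <dbl>       <dbl>      <dbl> <chr>        <lgl>
#> 1 demo        0.00198     0.00603    0.00206 HEALTHY_LIKE FALSE
```

The trace was synthesised with true flows 0.002 / 0.006 / 0.00205 ml/s and
0.05 °C Gaussian sensor noise; the inversion recovers them to ~2% and the
recovery flow returns to within 10% of rest, so the pattern is classified
healthy. `demo_out/` holds the network (JSON/CSV/VTK), the temperature and
flow fields (VTK + CSV), the balance report, the synthetic trace and the
estimate.

The same pieces compose directly:

```r
ph  <- build_cubic_phantom(voxel_size = 0.9e-3)
net <- grow_rrt(ph$grid, seed_cubic_network(ph$grid), iterations = 500,
                rng_seed = 7) |> assign_radii()
cp  <- couple_network_porous(net, ph$grid, NULL, inlet_flow = 2e-9)
co  <- compute_exchange_coefficients(cp$map, net, ph$grid, tissue_properties())
sys <- assemble_energy_system(ph$grid, net, cp, co,
                              thermal_boundary(q_heat = 150),
                              tissue_properties(), ph$mask)
sol <- solve_temperature(sys)
glance(sol)           # centre-point temperature, field range, energy audit
autoplot(sol)         # skin temperature raster
```

A thin command-line wrapper lives at `inst/cli/hemotherm.R`
(`Rscript hemotherm.R demo --out demo_out`), and
`inst/extdata/example_config.yaml` shows the YAML configuration surface.

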