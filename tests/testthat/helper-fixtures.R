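# Shared fixtures, memoised so expensive objects are built once per run.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixtures)) {
    assign(key, force(expr), envir = .fixtures)
  }
  get(key, envir = .fixtures)
}

# coarse (0.9 mm) phantom with a moderately grown network: the workhorse for
# heat-solver and sweep tests
coarse_phantom <- function() memo("coarse_phantom", build_cubic_phantom(voxel_size = 0.9e-3))

coarse_network <- function() memo("coarse_network", {
  ph <- coarse_phantom()
  assign_radii(grow_rrt(ph$grid, seed_cubic_network(ph$grid), 500, rng_seed = 7))
})

coarse_map <- function() memo("coarse_map", {
  voxelize_segments(coarse_network(), coarse_phantom()$grid)
})

coarse_coeffs <- function() memo("coarse_coeffs", {
  compute_exchange_coefficients(coarse_map(), coarse_network(),
                                coarse_phantom()$grid, tissue_properties())
})

coarse_solve <- function(Q_ml_s, T_amb = 23, q_heat = 0, ...) {
  ph <- coarse_phantom()
  props <- tissue_properties()
  cp <- couple_network_porous(coarse_network(), ph$grid, coarse_map(),
                              inlet_flow = Q_ml_s * 1e-6, props = props)
  sys <- assemble_energy_system(ph$grid, coarse_network(), cp, coarse_coeffs(),
                                thermal_boundary(T_inf = T_amb, q_heat = q_heat),
                                props, ph$mask, ...)
  solve_temperature(sys)
}

# default-grid forward sweep on the coarse phantom (expensive; reused by the
# response-surface, inversion and acceptance tests)
coarse_sweep <- function() memo("coarse_sweep", {
  sweep_forward(coarse_phantom(), coarse_network(), heating = "both",
                props = tissue_properties())
})

coarse_surfaces <- function() memo("coarse_surfaces", {
  tab <- coarse_sweep()
  list(off = fit_response_surface(tab, "off"),
       on = fit_response_surface(tab, "on"))
})

# tiny all-tissue grid with a two-segment artery and vein for dense oracles
tiny_setup <- function(n = 3, voxel = 1e-3, epsilon3 = 0.05) {
  grid <- voxel_grid(array(LABEL_SOFT_TISSUE, dim = c(n, n, n)), voxel,
                     epsilon3 = epsilon3)
  ext <- grid_extent(grid)
  nodes <- tibble::tibble(
    id = 1:6,
    x = c(0.1, 0.45, 0.8, 0.9, 0.55, 0.2) * ext[1],
    y = c(0.5, 0.5, 0.55, 0.5, 0.5, 0.45) * ext[2],
    z = rep(0.4 * ext[3], 6))
  segments <- tibble::tibble(
    id = 1:4, node_a = c(1L, 2L, 4L, 5L), node_b = c(2L, 3L, 5L, 6L),
    radius = c(2e-4, 1.5e-4, 2e-4, 1.5e-4),
    kind = c("ARTERY", "ARTERY", "VEIN", "VEIN"))
  roots <- tibble::tibble(node = c(1L, 4L), kind = c("ARTERY", "VEIN"))
  net <- vessel_network(nodes, segments, roots)
  mask <- extract_skin_mask(grid, policy = "top")
  list(grid = grid, net = net, mask = mask)
}
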