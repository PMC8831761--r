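props <- tissue_properties()

test_that("wall film coefficients follow the Nusselt relation", {
  m <- coarse_map()
  net <- coarse_network()
  co <- compute_exchange_coefficients(m, net, coarse_phantom()$grid, props,
                                      Nu = 4)
  e <- co$entries
  R <- net$segments$radius[match(e$seg_id, net$segments$id)]
  # h = Nu K_b / D: a 100 um diameter vessel at K_b = 0.5 gives 20 kW/(m2 K)
  expect_equal(e$h_wall, 4 * props$K_b / (2 * R), tolerance = 1e-12)
  expect_equal(4 * 0.5 / 100e-6, 20000)
  # epsilon split: the two wall couplings sum to h * A
  expect_equal(e$beta_tissue + e$beta_capillary, e$h_wall * e$area,
               tolerance = 1e-12)
  expect_true(all(e$beta_tissue >= 0 & e$beta_capillary >= 0))
  # zero shared area (occluded radius-0 segment) exchanges nothing
  occ <- apply_stenosis(net, net$segments$id[5], 1)
  m2 <- voxelize_segments(occ, coarse_phantom()$grid)
  co2 <- compute_exchange_coefficients(m2, occ, coarse_phantom()$grid, props)
  e5 <- co2$entries[co2$entries$seg_id == net$segments$id[5], ]
  expect_equal(sum(e5$beta_tissue) + sum(e5$beta_capillary), 0)
})

test_that("uniform conditions give the exact isothermal equilibrium", {
  p0 <- props; p0$Q_gen <- 1e-300
  sol <- local({
    ph <- coarse_phantom()
    cp <- couple_network_porous(coarse_network(), ph$grid, coarse_map(),
                                inlet_flow = 3e-9, props = p0)
    sys <- assemble_energy_system(ph$grid, coarse_network(), cp, coarse_coeffs(),
                                  thermal_boundary(T_inf = 37, T_inlet = 37),
                                  p0, ph$mask)
    solve_temperature(sys)
  })
  allT <- c(sol$T1$temperature, sol$T2[!is.na(sol$T2)],
            sol$T3[!is.na(sol$T3)], sol$T4$temperature)
  expect_equal(range(allT), c(37, 37), tolerance = 1e-9)
})

test_that("metabolic heating balances the surface loss at steady state", {
  # vessel-free balance: all generated heat leaves through the Robin faces
  s <- tiny_setup(n = 3)
  # a tiny inlet keeps the problem assembled the standard way but negligible
  cp <- couple_network_porous(s$net, s$grid, NULL, inlet_flow = 0, props = props)
  co <- compute_exchange_coefficients(voxelize_segments(s$net, s$grid), s$net,
                                      s$grid, props)
  sys <- assemble_energy_system(s$grid, s$net, cp, co,
                                thermal_boundary(T_inf = 20), props, s$mask)
  sol <- solve_temperature(sys)
  interior <- sol$T2[2, 2, 2]
  expect_gt(interior, 20)
  e <- setNames(sol$energy$watts, sol$energy$term)
  vol <- sum(s$grid$labels != LABEL_OUTSIDE) * s$grid$voxel_size^3
  expect_equal(e[["metabolism"]], props$Q_gen * vol, tolerance = 1e-12)
  expect_equal(e[["robin_loss"]], e[["metabolism"]], tolerance = 1e-6)
})

test_that("pure advection transports the inlet temperature downstream", {
  s <- tiny_setup(n = 4)
  p0 <- props; p0$K_b <- 1e-8; p0$Q_gen <- 1e-300  # quench conduction and wall exchange
  cp <- couple_network_porous(s$net, s$grid, NULL, inlet_flow = 1e-8, props = p0)
  co <- compute_exchange_coefficients(voxelize_segments(s$net, s$grid), s$net,
                                      s$grid, p0)
  sys <- assemble_energy_system(s$grid, s$net, cp, co,
                                thermal_boundary(T_inf = 20, T_inlet = 37),
                                p0, s$mask)
  sol <- solve_temperature(sys)
  expect_equal(sol$T1$temperature, rep(37, nrow(sol$T1)), tolerance = 1e-6)
})

test_that("the full solve matches a dense brute-force solve on a tiny grid", {
  s <- tiny_setup(n = 4)
  cp <- couple_network_porous(s$net, s$grid, NULL, inlet_flow = 5e-9,
                              props = props)
  # a milder capillary coupling keeps kappa * eps well below the comparison
  # tolerance; the operator structure under test is unchanged
  co <- compute_exchange_coefficients(voxelize_segments(s$net, s$grid), s$net,
                                      s$grid, props, capillary_diameter = 1e-4)
  sys <- assemble_energy_system(s$grid, s$net, cp, co,
                                thermal_boundary(q_heat = 50), props, s$mask)
  sol <- solve_temperature(sys, method = "ilu_bicgstab")
  A <- as.matrix(sys$A)
  xd <- solve(A, sys$b)
  for (k in 1:3) xd <- xd + solve(A, sys$b - A %*% xd)  # polish the oracle
  got <- c(sol$T1$temperature,
           sol$T2[!is.na(sol$T2)], sol$T3[!is.na(sol$T3)], sol$T4$temperature)
  expect_lt(max(abs(got - xd)) / max(abs(xd)), 1e-12)
})

test_that("the discrete maximum principle holds without sources", {
  p0 <- props; p0$Q_gen <- 1e-300
  ph <- coarse_phantom()
  cp <- couple_network_porous(coarse_network(), ph$grid, coarse_map(),
                              inlet_flow = 2e-9, props = p0)
  sys <- assemble_energy_system(ph$grid, coarse_network(), cp, coarse_coeffs(),
                                thermal_boundary(T_inf = 23, T_inlet = 37),
                                p0, ph$mask)
  sol <- solve_temperature(sys)
  allT <- c(sol$T1$temperature, sol$T2[!is.na(sol$T2)],
            sol$T3[!is.na(sol$T3)], sol$T4$temperature)
  expect_gte(min(allT), 23 - 1e-8)
  expect_lte(max(allT), 37 + 1e-8)
})

test_that("raising ambient temperature or heating never cools any element", {
  get_all <- function(T_inf, q_heat) {
    sol <- coarse_solve(0.002, T_amb = T_inf, q_heat = q_heat)
    c(sol$T1$temperature, sol$T2[!is.na(sol$T2)],
      sol$T3[!is.na(sol$T3)], sol$T4$temperature)
  }
  base <- get_all(21, 0)
  expect_true(all(get_all(23, 0) >= base - 1e-9))
  expect_true(all(get_all(21, 150) >= base - 1e-9))
})

test_that("infinite wall exchange equilibrates vessels with their voxels", {
  s <- tiny_setup(n = 6, voxel = 1e-3)
  cp <- couple_network_porous(s$net, s$grid, NULL, inlet_flow = 3e-9,
                              props = props)
  co_inf <- compute_exchange_coefficients(cp$map, s$net, s$grid, props,
                                          wall_h_factor = 1e6)
  sys <- assemble_energy_system(s$grid, s$net, cp, co_inf,
                                thermal_boundary(), props, s$mask)
  sol <- solve_temperature(sys)
  # every segment's temperature must coincide with the capillary/tissue
  # temperature of the voxels it traverses (area-weighted)
  e <- cp$map$entries
  art <- e[e$kind == "ARTERY" & e$area > 0, ]
  Tvox <- (1 - s$grid$epsilon3[art$vox]) * sol$T2[art$vox] +
    s$grid$epsilon3[art$vox] * sol$T3[art$vox]
  Tseg <- sol$T1$temperature[match(art$seg_id, sol$T1$id)]
  agg <- tapply(seq_len(nrow(art)), art$seg_id, function(i) {
    c(seg = Tseg[i[1]], vox = sum(Tvox[i] * art$area[i]) / sum(art$area[i]))
  })
  dev <- vapply(agg, function(v) abs(v[1] - v[2]), numeric(1))
  expect_lt(max(dev), 0.02)
})

test_that("halving the voxel size barely moves the centre-point temperature", {
  net <- coarse_network()  # grown on the 0.9 mm grid; reused on both grids
  run_at <- function(vx) {
    ph <- build_cubic_phantom(voxel_size = vx)
    cp <- couple_network_porous(net, ph$grid, NULL, inlet_flow = 3e-9,
                                props = props)
    co <- compute_exchange_coefficients(cp$map, net, ph$grid, props)
    sys <- assemble_energy_system(ph$grid, net, cp, co, thermal_boundary(),
                                  props, ph$mask)
    solve_temperature(sys)$center_point
  }
  expect_lt(abs(run_at(0.9e-3) - run_at(0.45e-3)), 0.1)
})

test_that("surface RMS difference matches hand arithmetic", {
  sol <- coarse_solve(0.003)
  expect_equal(surface_mse(sol, sol), 0)
  shifted <- sol
  shifted$skin$temperature <- shifted$skin$temperature + 0.5
  expect_equal(surface_mse(sol, shifted), 0.5, tolerance = 1e-12)
  set.seed(8)
  noisy <- sol
  d <- rnorm(nrow(sol$skin), 0, 0.3)
  noisy$skin$temperature <- sol$skin$temperature + d
  expect_equal(surface_mse(sol, noisy), sqrt(mean(d^2)), tolerance = 1e-12)
  other <- sol
  other$skin <- other$skin[-1, ]
  expect_error(surface_mse(sol, other), "different surface masks")
})

test_that("tidiers summarise a temperature solution", {
  sol <- coarse_solve(0.003)
  g <- glance(sol)
  expect_equal(g$centre_C, sol$center_point)
  expect_lt(g$solve_residual, 1e-10)
  expect_lt(g$energy_rel_imbalance, 0.01)
  expect_equal(nrow(tidy(sol)), nrow(sol$skin))
})
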