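# The forward sweep, surface fitting, inversion and classification. The
# sweep itself is expensive and shared through the fixture helpers.

test_that("the forward sweep has the documented monotone structure", {
  tab <- coarse_sweep()
  for (Ta in unique(tab$T_amb_C)) {
    off <- tab[tab$heating == "off" & tab$T_amb_C == Ta, ]
    off <- off[order(off$Q_ml_s), ]
    expect_true(all(diff(off$T_center_C) > 0))
    on <- tab[tab$heating == "on" & tab$T_amb_C == Ta, ]
    on <- on[order(on$Q_ml_s), ]
    expect_true(all(diff(on$T_center_C) < 0))
    # the largest heated drop sits on the lowest flow interval
    expect_equal(which.min(diff(on$T_center_C)), 1L)
  }
  # off-state temperature rises with ambient temperature at fixed flow
  for (Q in unique(tab$Q_ml_s)) {
    off <- tab[tab$heating == "off" & tab$Q_ml_s == Q, ]
    off <- off[order(off$T_amb_C), ]
    expect_true(all(diff(off$T_center_C) > 0))
  }
})

test_that("zero-flow sweep point matches an independent vessel-free solve", {
  tab <- coarse_sweep()
  t_sweep <- tab$T_center_C[tab$Q_ml_s == 0 & tab$heating == "off" &
                              tab$T_amb_C == 22]
  # vessel-free conduction equilibrium: same phantom, a minimal vessel pair
  # carrying no flow; metabolism against surface loss only
  ph <- coarse_phantom()
  props <- tissue_properties()
  net <- coarse_network()
  cp <- couple_network_porous(net, ph$grid, coarse_map(), inlet_flow = 0,
                              props = props)
  sys <- assemble_energy_system(ph$grid, net, cp, coarse_coeffs(),
                                thermal_boundary(T_inf = 22), props, ph$mask)
  sol <- solve_temperature(sys)
  expect_equal(t_sweep, sol$center_point, tolerance = 1e-9)
  # and the no-perfusion equilibrium sits barely above ambient
  expect_lt(abs(sol$center_point - 22), 4)
})

test_that("surface fitting recovers a known polynomial exactly", {
  Qs <- c(0, 0.002, 0.004, 0.006, 0.008, 0.01)
  Tas <- c(20, 22, 24)
  tab <- expand.grid(Q_ml_s = Qs, T_amb_C = Tas)
  tab$heating <- "off"
  tab$T_center_C <- 25 + 900 * tab$Q_ml_s - 30000 * tab$Q_ml_s^2 +
    0.2 * tab$T_amb_C
  tab <- tibble::as_tibble(tab)
  surf <- fit_response_surface(tab, "off", method = "poly", q_order = 3)
  probe <- expand.grid(Q = seq(0, 0.01, length.out = 23),
                       Ta = seq(20, 24, length.out = 7))
  want <- 25 + 900 * probe$Q - 30000 * probe$Q^2 + 0.2 * probe$Ta
  expect_equal(predict(surf, probe$Q, probe$Ta), want, tolerance = 1e-8)
  expect_lt(surf$residual_rms, 1e-10)
})

test_that("fitted surfaces interpolate the sweep and certify monotonicity", {
  surfs <- coarse_surfaces()
  for (st in c("off", "on")) {
    s <- surfs[[st]]
    tab <- s$table
    expect_lt(max(abs(predict(s, tab$Q_ml_s, tab$T_amb_C) - tab$T_center_C)),
              0.05)
    expect_lt(s$residual_rms, 0.05)
  }
  g <- glance(surfs$off)
  expect_equal(g$Q_max_ml_s, 0.01)
})

test_that("a corrupted sweep table fails the monotonicity certificate", {
  tab <- coarse_sweep()
  bad <- tab[tab$heating == "off", ]
  flip <- which(bad$T_amb_C == 22)[c(3, 4)]
  bad$T_center_C[flip] <- rev(bad$T_center_C[flip])  # break monotonicity
  expect_error(fit_response_surface(bad, "off"), "monoton|increasing")
})

test_that("noise-free inversion recovers flows from true forward solves", {
  surfaces <- coarse_surfaces()
  truth <- c(resting = 0.0027, heating = 0.0055, recovery = 0.0029)
  fw <- sweep_forward(coarse_phantom(), coarse_network(),
                      Q_values = unname(truth), T_amb_values = 21.5,
                      heating = "both", props = tissue_properties())
  Toff <- function(q) fw$T_center_C[fw$heating == "off" & fw$Q_ml_s == q]
  Ton <- function(q) fw$T_center_C[fw$heating == "on" & fw$Q_ml_s == q]
  steady <- c(Toff(truth[1]), Ton(truth[2]), Toff(truth[3]))
  pr <- spas_protocol()
  tt <- seq(1, pr$total_s)
  temp <- ifelse(tt <= 750, steady[1], ifelse(tt <= 1750, steady[2], steady[3]))
  est <- invert_blood_flow(temperature_trace(tt, temp, 21.5, "truth"), surfaces)
  err <- abs(est$phases$Q_ml_s - truth[est$phases$phase]) / truth[est$phases$phase]
  expect_lt(max(err), 0.02)
  expect_false(any(est$phases$extrapolated))
})

test_that("constant traces at a surface value return that flow in all phases", {
  surfaces <- coarse_surfaces()
  Qstar <- 0.004
  pr <- spas_protocol()
  tt <- seq(1, pr$total_s)
  toff <- predict(surfaces$off, Qstar, 22)
  ton <- predict(surfaces$on, Qstar, 22)
  temp <- ifelse(tt > 750 & tt <= 1750, ton, toff)
  est <- invert_blood_flow(temperature_trace(tt, temp, 22, "const"), surfaces)
  expect_equal(est$phases$Q_ml_s, rep(Qstar, 3), tolerance = 1e-6)
})

test_that("noisy traces invert within a few percent (Monte Carlo)", {
  surfaces <- coarse_surfaces()
  truth <- c(resting = 0.0025, heating = 0.006, recovery = 0.0027)
  set.seed(2024)
  errs <- replicate(60, {
    tr <- synthesize_trace(truth, 22.3, surfaces, noise_sd = 0.05,
                           relaxation_tau = 40,
                           rng_seed = sample.int(.Machine$integer.max / 2, 1))
    e <- invert_blood_flow(tr, surfaces)
    max(abs(e$phases$Q_ml_s - truth[e$phases$phase]) / truth[e$phases$phase])
  })
  expect_lt(median(errs), 0.05)
})

test_that("out-of-range temperatures are clipped and flagged", {
  surfaces <- coarse_surfaces()
  pr <- spas_protocol()
  tt <- seq(1, pr$total_s)
  # hotter than the off-state can ever reach: clipped to the upper flow edge
  est <- invert_blood_flow(temperature_trace(tt, rep(39, length(tt)), 22), surfaces)
  expect_true(est$phases$extrapolated[1])
  expect_equal(est$phases$Q_ml_s[1], surfaces$off$domain$Q[2])
})

test_that("pattern classification implements the three rules", {
  mk <- function(q) structure(list(
    phases = tibble::tibble(phase = c("resting", "heating", "recovery"),
                            T_mean_C = 0, T_amb_C = 22, Q_ml_s = q,
                            extrapolated = FALSE),
    pattern = NA, subject_id = "t"), class = "perfusion_estimate")
  expect_equal(classify_pattern(mk(c(0.20, 0.35, 0.21))), "HEALTHY_LIKE")
  expect_equal(classify_pattern(mk(c(0.20, 0.30, 0.32))), "DELAYED_EXCEEDING")
  expect_equal(classify_pattern(mk(c(0.20, 0.30, 0.25))), "DELAYED_PARTIAL")
  expect_warning(cl <- classify_pattern(mk(c(0, 0.3, 0.2))), "undetermined")
  expect_equal(cl, "UNDETERMINED")
})

test_that("synthesised patterns classify as designed", {
  surfaces <- coarse_surfaces()
  for (i in 1:5) {
    q_rest <- runif(1, 0.0015, 0.004)
    q_heat <- q_rest * runif(1, 1.5, 2.5)
    healthy <- c(resting = q_rest, heating = q_heat,
                 recovery = q_rest * runif(1, 0.95, 1.05))
    tr <- synthesize_trace(healthy, 22, surfaces, noise_sd = 0,
                           relaxation_tau = 30, rng_seed = i)
    expect_equal(invert_blood_flow(tr, surfaces)$pattern, "HEALTHY_LIKE")
    delayed <- c(resting = q_rest, heating = q_heat,
                 recovery = q_heat * runif(1, 1.02, 1.2))
    tr2 <- synthesize_trace(delayed, 22, surfaces, noise_sd = 0,
                            relaxation_tau = 30, rng_seed = i)
    expect_equal(invert_blood_flow(tr2, surfaces)$pattern, "DELAYED_EXCEEDING")
  }
})

test_that("trace synthesis is deterministic and settles to steady values", {
  surfaces <- coarse_surfaces()
  q <- c(resting = 0.002, heating = 0.005, recovery = 0.0022)
  t1 <- synthesize_trace(q, 22, surfaces, noise_sd = 0.05, rng_seed = 77)
  t2 <- synthesize_trace(q, 22, surfaces, noise_sd = 0.05, rng_seed = 77)
  expect_identical(t1$temp_C, t2$temp_C)
  # tau -> 0 gives a piecewise-constant trace at the steady temperatures
  t0 <- synthesize_trace(q, 22, surfaces, noise_sd = 0, relaxation_tau = 0)
  expect_equal(unique(t0$temp_C[t0$time_s <= 750]),
               predict(surfaces$off, q[["resting"]], 22))
  # last-100-s means match steady values when tau <= duration / 10
  t3 <- synthesize_trace(q, 22, surfaces, noise_sd = 0, relaxation_tau = 75)
  last <- t3$temp_C[t3$time_s > 1650 & t3$time_s <= 1750]
  expect_lt(abs(mean(last) - predict(surfaces$on, q[["heating"]], 22)), 0.01)
})
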