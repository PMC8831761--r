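props <- tissue_properties()

single_tube <- function(R = 1e-3, L = 1e-2) {
  nodes <- tibble::tibble(id = 1:2, x = c(0, L), y = 0, z = 0)
  segs <- tibble::tibble(id = 1L, node_a = 1L, node_b = 2L, radius = R,
                         kind = "ARTERY")
  vessel_network(nodes, segs, tibble::tibble(node = 1L, kind = "ARTERY"))
}

test_that("a single tube reproduces the closed-form Poiseuille flow", {
  R <- 1e-3; L <- 1e-2; dP <- 100
  net <- single_tube(R, L)
  g <- pi * R^4 / (8 * props$mu * L)
  Q <- g * dP  # flow that produces a 100 Pa drop
  sol <- solve_network_flow(net, inlet_flows = c(ARTERY = Q),
                            terminal_exchange = tibble::tibble(node = 2, q = Q),
                            props = props)
  drop <- sol$node_pressure$pressure[1] - sol$node_pressure$pressure[2]
  expect_equal(drop, dP, tolerance = 1e-10)
  expect_equal(sol$segments$flow[1], pi * R^4 * dP / (8 * props$mu * L),
               tolerance = 1e-10)
  expect_equal(sol$segments$velocity[1], Q / (pi * R^2), tolerance = 1e-10)
})

test_that("zero inlet flow gives zero flow and uniform pressure", {
  net <- single_tube()
  sol <- solve_network_flow(net, c(ARTERY = 0),
                            tibble::tibble(node = 2, q = 0), props)
  expect_equal(sol$segments$flow, 0)
  expect_equal(diff(range(sol$node_pressure$pressure)), 0)
})

test_that("a symmetric bifurcation splits flow exactly in half", {
  nodes <- tibble::tibble(id = 1:4, x = c(0, 1, 2, 2) * 1e-3,
                          y = c(0, 0, 1, -1) * 1e-3, z = 0)
  segs <- tibble::tibble(id = 1:3, node_a = c(1L, 2L, 2L),
                         node_b = c(2L, 3L, 4L),
                         radius = c(2e-4, 1.5e-4, 1.5e-4), kind = "ARTERY")
  net <- vessel_network(nodes, segs, tibble::tibble(node = 1L, kind = "ARTERY"))
  Q <- 1e-8
  sol <- solve_network_flow(net, c(ARTERY = Q),
                            tibble::tibble(node = c(3, 4), q = c(Q / 2, Q / 2)),
                            props)
  expect_equal(sol$segments$flow[2], sol$segments$flow[3], tolerance = 1e-14)
  expect_equal(sol$segments$flow[2], Q / 2, tolerance = 1e-12)
})

test_that("interior node balance holds on a grown tree", {
  net <- coarse_network()
  Q <- 1e-8
  lv <- setdiff(unique(c(net$segments$node_a, net$segments$node_b)), 0)
  cp <- couple_network_porous(net, coarse_phantom()$grid, coarse_map(),
                              inlet_flow = Q, props = props)
  seg <- net$segments
  f <- cp$network_flow$segments$flow
  te <- cp$network_flow$terminal_exchange
  for (k in c("ARTERY", "VEIN")) {
    ks <- which(seg$kind == k)
    nodes_k <- unique(c(seg$node_a[ks], seg$node_b[ks]))
    root <- net$roots$node[net$roots$kind == k]
    for (v in setdiff(nodes_k, root)) {
      net_in <- sum(f[ks][seg$node_b[ks] == v]) - sum(f[ks][seg$node_a[ks] == v])
      q <- te$q[te$node == v & te$kind == k]
      exch <- if (length(q) > 0) (if (k == "ARTERY") -q else q) else 0
      expect_lt(abs(net_in + exch), 1e-12 * Q / 1e-2)
    }
  }
})

test_that("unbalanced boundary conditions are rejected with the imbalance", {
  net <- single_tube()
  expect_error(
    solve_network_flow(net, c(ARTERY = 1e-8),
                       tibble::tibble(node = 2, q = 0.5e-8), props),
    "unbalanced")
})

test_that("terminal exchange distributes evenly within each voxel", {
  m <- coarse_map()
  vc <- m$voxel_counts
  v4 <- vc$vox[vc$n >= 2][1]
  skip_if(is.na(v4), "no multi-terminal voxel in fixture")
  q <- distribute_terminal_exchange(m, tibble::tibble(vox = v4, Q = 4e-9), "ARTERY")
  got <- q$q[q$q != 0]
  expect_equal(length(got), vc$n[vc$vox == v4])
  expect_equal(got, rep(4e-9 / length(got), length(got)))
  # conservation over an arbitrary demand pattern
  demand <- tibble::tibble(vox = vc$vox[vc$n > 0], Q = seq_along(vc$vox[vc$n > 0]) * 1e-12)
  qq <- distribute_terminal_exchange(m, demand, "ARTERY")
  expect_equal(sum(qq$q), sum(demand$Q), tolerance = 1e-15)
  # demand in a voxel without terminals is rejected
  empty <- setdiff(seq_len(prod(m$shape)), vc$vox)[1]
  expect_error(distribute_terminal_exchange(
    m, tibble::tibble(vox = empty, Q = 1e-9), "ARTERY"), "no coupled terminal")
})

test_that("stenosis reduces an isolated tube's flow by the fourth power", {
  R <- 1e-3; L <- 1e-2; dP <- 100
  g0 <- pi * R^4 / (8 * props$mu * L)
  flow_at <- function(net) {
    # impose the same pressure drop by prescribing the flow that yields it
    gk <- pi * net$segments$radius[1]^4 / (8 * props$mu * L)
    Q <- gk * dP
    sol <- solve_network_flow(net, c(ARTERY = Q),
                              tibble::tibble(node = 2, q = Q), props)
    drop <- sol$node_pressure$pressure[1] - sol$node_pressure$pressure[2]
    expect_equal(drop, dP, tolerance = 1e-10)
    sol$segments$flow[1]
  }
  q_full <- flow_at(single_tube(R, L))
  q_half <- flow_at(apply_stenosis(single_tube(R, L), 1L, 0.5))
  expect_equal(q_full / q_half, 16, tolerance = 1e-12)
})

test_that("full occlusion strands the downstream sub-tree", {
  nodes <- tibble::tibble(id = 1:3, x = c(0, 1, 2) * 1e-3, y = 0, z = 0)
  segs <- tibble::tibble(id = 1:2, node_a = c(1L, 2L), node_b = c(2L, 3L),
                         radius = 2e-4, kind = "ARTERY")
  net <- vessel_network(nodes, segs, tibble::tibble(node = 1L, kind = "ARTERY"))
  occ <- apply_stenosis(net, 1L, 1)
  # demanding flow through the occlusion is rejected, naming the sub-tree
  expect_error(solve_network_flow(occ, c(ARTERY = 1e-9),
                                  tibble::tibble(node = 3, q = 1e-9), props),
               "cut off")
  # with no demand, all flows are zero
  sol <- solve_network_flow(occ, c(ARTERY = 0),
                            tibble::tibble(node = 3, q = 0), props)
  expect_equal(sol$segments$flow, c(0, 0))
})

test_that("pressure boundary mode recovers Poiseuille flow from a pressure drop", {
  R <- 1e-3; L <- 1e-2; dP <- 100
  net <- single_tube(R, L)
  sol <- solve_network_flow(net, NULL, NULL, props, bc_mode = "pressure",
                            pressures = list(ARTERY = c(root = dP, terminal = 0)))
  expect_equal(sol$segments$flow[1], pi * R^4 * dP / (8 * props$mu * L),
               tolerance = 1e-12)
  expect_equal(sol$terminal_exchange$q[1], sol$segments$flow[1], tolerance = 1e-12)
  # symmetric Y-tree: both terminals receive the same flow
  nodes <- tibble::tibble(id = 1:4, x = c(0, 1, 2, 2) * 1e-3,
                          y = c(0, 0, 1, -1) * 1e-3, z = 0)
  segs <- tibble::tibble(id = 1:3, node_a = c(1L, 2L, 2L), node_b = c(2L, 3L, 4L),
                         radius = c(2e-4, 1.5e-4, 1.5e-4), kind = "ARTERY")
  y <- vessel_network(nodes, segs, tibble::tibble(node = 1L, kind = "ARTERY"))
  soly <- solve_network_flow(y, NULL, NULL, props, bc_mode = "pressure",
                             pressures = list(ARTERY = c(root = 50, terminal = 0)))
  expect_equal(soly$terminal_exchange$q[1], soly$terminal_exchange$q[2],
               tolerance = 1e-12)
  expect_equal(sum(soly$terminal_exchange$q), soly$segments$flow[1],
               tolerance = 1e-12)
})
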