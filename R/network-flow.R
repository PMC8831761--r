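# Steady 1-D network haemodynamics: Poiseuille conductances and nodal
# pressure solves, per vessel kind.

segment_conductance <- function(network, props) {
  L <- segment_lengths(network)
  pi * network$segments$radius^4 / (8 * props$mu * L)
}

#' Solve steady Poiseuille flow on the vessel network
#'
#' Each vessel kind is solved independently as a linear nodal-pressure
#' system: per-segment conductance `g = pi R^4 / (8 mu L)`, flow
#' `Q = g * (P_a - P_b)`, and mass balance at every node. Boundary data are
#' prescribed volumetric flows: the inlet flow at each root (positive into
#' arteries, out of veins) and the terminal exchange flows at leaf nodes
#' (arterial outflow to the capillary phase, venous inflow from it).
#' Non-terminal nodes exchange nothing. One reference node per connected
#' component is pinned to 0 Pa. Fully occluded (zero-radius) segments carry
#' no flow; a component cut off from its root must carry zero net exchange or
#' the solve is rejected.
#'
#' @param network a [vessel_network()] with radii assigned.
#' @param inlet_flows named numeric, inlet flow per kind in m^3/s, e.g.
#'   `c(ARTERY = 1e-8, VEIN = 1e-8)` (vein value = venous outflow at its
#'   root).
#' @param terminal_exchange tibble with columns `node, q` (m^3/s, positive =
#'   blood leaving an artery / entering a vein at that leaf), or a named
#'   vector keyed by node id. Must sum (per kind) to the kind's inlet flow.
#' @param props a [tissue_properties()].
#' @param bc_mode `"flow"` (default, described above) or `"pressure"`:
#'   prescribe the root pressure and a common terminal pressure per kind and
#'   solve for the flows instead. In pressure mode `inlet_flows` is ignored
#'   and `pressures` supplies the boundary data.
#' @param pressures for `bc_mode = "pressure"`: named list per kind, each a
#'   `c(root = , terminal = )` pair in Pa.
#' @return object of class `network_flow_solution`: tibbles `node_pressure`
#'   (`node, kind, pressure`), `segments`
#'   (`id, kind, flow, velocity, pressure_drop`; flow signed `node_a` ->
#'   `node_b`), and `terminal_exchange` (in pressure mode, the flows that
#'   emerge at the terminals).
#' @export
solve_network_flow <- function(network, inlet_flows, terminal_exchange, props,
                               bc_mode = c("flow", "pressure"),
                               pressures = NULL) {
  bc_mode <- match.arg(bc_mode)
  if (bc_mode == "pressure") {
    return(solve_network_flow_pressure(network, pressures, props))
  }
  seg <- network$segments
  if (any(is.na(seg$radius))) abort("assign radii before solving flow")
  if (is.null(terminal_exchange)) {
    terminal_exchange <- tibble(node = numeric(0), q = numeric(0))
  }
  if (is.numeric(terminal_exchange) && !is.null(names(terminal_exchange))) {
    terminal_exchange <- tibble(node = as.numeric(names(terminal_exchange)),
                                q = as.numeric(terminal_exchange))
  }
  g_all <- segment_conductance(network, props)
  press <- list(); flows <- rep(0, nrow(seg)); texch <- list()
  for (k in unique(seg$kind)) {
    i <- which(seg$kind == k)
    sk <- seg[i, ]
    gk <- g_all[i]
    nodes_k <- sort(unique(c(sk$node_a, sk$node_b)))
    idx <- function(v) match(v, nodes_k)
    nn <- length(nodes_k)
    root <- network$roots$node[network$roots$kind == k][1]
    Q_in <- inlet_flows[[k]] %||% 0
    lv <- leaf_nodes(network, k)
    te <- terminal_exchange[terminal_exchange$node %in% nodes_k, , drop = FALSE]
    if (nrow(te) > 0 && !all(te$node %in% lv)) {
      abort(sprintf("terminal exchange prescribed on non-terminal %s nodes: %s", k,
                    paste(setdiff(te$node, lv), collapse = ", ")))
    }
    s <- numeric(nn)
    sgn <- if (k == "ARTERY") 1 else -1
    s[idx(root)] <- s[idx(root)] + sgn * Q_in
    if (nrow(te) > 0) s[idx(te$node)] <- s[idx(te$node)] - sgn * te$q
    imb <- sum(s)
    tol <- 1e-10 * max(abs(Q_in), max(abs(s)), 1e-300)
    if (abs(imb) > tol) {
      abort(sprintf("%s flow boundary conditions unbalanced by %.3e m^3/s", k, imb))
    }
    live <- gk > 0
    ia <- idx(sk$node_a); ib <- idx(sk$node_b)
    comp <- graph_components(nn, ia[live], ib[live])
    # stranded components must be exchange-free
    for (cmp in setdiff(unique(comp), comp[idx(root)])) {
      members <- nodes_k[comp == cmp]
      if (sum(abs(s[comp == cmp])) > tol) {
        abort(sprintf(
          "%s sub-tree {%s} is cut off from its root by full occlusion but has prescribed flow",
          k, paste(members, collapse = ", ")))
      }
    }
    if (any(abs(tapply(s, comp, sum)) > tol)) {
      abort("flow imbalance within a connected component")
    }
    A <- Matrix::sparseMatrix(
      i = c(ia[live], ib[live], ia[live], ib[live]),
      j = c(ib[live], ia[live], ia[live], ib[live]),
      x = c(-gk[live], -gk[live], gk[live], gk[live]),
      dims = c(nn, nn))
    # pin one reference node per component
    pinned <- vapply(unique(comp), function(cmp) which(comp == cmp)[1], integer(1))
    pinned[match(comp[idx(root)], unique(comp))] <- idx(root)
    keep <- setdiff(seq_len(nn), pinned)
    p <- numeric(nn)
    if (length(keep) > 0 && any(s != 0)) {
      Ar <- A[keep, keep, drop = FALSE]
      p[keep] <- solve_sparse_system(Ar, s[keep], method = "auto")
    }
    press[[k]] <- tibble(node = nodes_k, kind = k, pressure = p)
    flows[i] <- gk * (p[ia] - p[ib])
    texch[[k]] <- tibble(node = if (nrow(te)) te$node else numeric(0),
                         kind = k, q = if (nrow(te)) te$q else numeric(0))
  }
  segs_out <- tibble(
    id = seg$id, kind = seg$kind, flow = flows,
    velocity = ifelse(seg$radius > 0, flows / (pi * seg$radius^2), 0),
    pressure_drop = ifelse(g_all > 0, flows / g_all, 0))
  structure(list(node_pressure = dplyr::bind_rows(press), segments = segs_out,
                 terminal_exchange = dplyr::bind_rows(texch)),
            class = "network_flow_solution")
}

# Pressure-boundary variant: Dirichlet pressures at the root and at every
# leaf of each kind; interior nodes satisfy mass balance; flows follow from
# the conductances.
solve_network_flow_pressure <- function(network, pressures, props) {
  seg <- network$segments
  if (any(is.na(seg$radius))) abort("assign radii before solving flow")
  if (is.null(pressures)) abort("`pressures` is required for bc_mode = 'pressure'")
  g_all <- segment_conductance(network, props)
  press <- list(); flows <- rep(0, nrow(seg)); texch <- list()
  for (k in unique(seg$kind)) {
    pk <- pressures[[k]]
    if (is.null(pk) || !all(c("root", "terminal") %in% names(pk))) {
      abort(sprintf("`pressures$%s` must carry `root` and `terminal` values", k))
    }
    i <- which(seg$kind == k)
    sk <- seg[i, ]
    gk <- g_all[i]
    nodes_k <- sort(unique(c(sk$node_a, sk$node_b)))
    nn <- length(nodes_k)
    ia <- match(sk$node_a, nodes_k); ib <- match(sk$node_b, nodes_k)
    live <- gk > 0
    A <- Matrix::sparseMatrix(
      i = c(ia[live], ib[live], ia[live], ib[live]),
      j = c(ib[live], ia[live], ia[live], ib[live]),
      x = c(-gk[live], -gk[live], gk[live], gk[live]), dims = c(nn, nn))
    root <- network$roots$node[network$roots$kind == k][1]
    lv <- leaf_nodes(network, k)
    fixed <- match(c(root, lv), nodes_k)
    pfix <- c(pk[["root"]], rep(pk[["terminal"]], length(lv)))
    free <- setdiff(seq_len(nn), fixed)
    p <- numeric(nn)
    p[fixed] <- pfix
    if (length(free) > 0) {
      rhs <- -as.numeric(A[free, fixed, drop = FALSE] %*% pfix)
      p[free] <- solve_sparse_system(A[free, free, drop = FALSE], rhs)
    }
    press[[k]] <- tibble(node = nodes_k, kind = k, pressure = p)
    flows[i] <- gk * (p[ia] - p[ib])
    # terminal exchange emerges from the solution: net flow into each leaf
    qlv <- vapply(lv, function(v) {
      sum(flows[i][sk$node_b == v]) - sum(flows[i][sk$node_a == v])
    }, numeric(1))
    if (k == "VEIN") qlv <- -qlv
    texch[[k]] <- tibble(node = lv, kind = k, q = qlv)
  }
  segs_out <- tibble(
    id = seg$id, kind = seg$kind, flow = flows,
    velocity = ifelse(seg$radius > 0, flows / (pi * seg$radius^2), 0),
    pressure_drop = ifelse(g_all > 0, flows / g_all, 0))
  structure(list(node_pressure = dplyr::bind_rows(press), segments = segs_out,
                 terminal_exchange = dplyr::bind_rows(texch)),
            class = "network_flow_solution")
}

# Connected components of an undirected graph on 1..n given edge endpoint
# indices; returns an integer component label per vertex.
graph_components <- function(n, ia, ib) {
  from <- c(ia, ib); to <- c(ib, ia)
  ord <- order(from)
  from <- from[ord]; to <- to[ord]
  ptr <- c(0L, cumsum(tabulate(from, nbins = n)))  # CSR pointers, sorted edges
  lab <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (lab[s] != 0L) next
    cur <- cur + 1L
    lab[s] <- cur
    frontier <- s
    while (length(frontier) > 0) {
      lo <- ptr[frontier] + 1L
      hi <- ptr[frontier + 1L]
      sel <- sequence(pmax(hi - lo + 1L, 0L), from = lo)
      nb <- to[sel]
      nb <- unique(nb[lab[nb] == 0L])
      lab[nb] <- cur
      frontier <- nb
    }
  }
  lab
}

#' Distribute per-voxel exchange flow to coupled terminal nodes
#'
#' Within each voxel the exchanged flow is divided evenly among that voxel's
#' coupled terminal nodes of the requested kind: each of the `n` terminal
#' artery nodes in a voxel receives `Q_a / n` (and correspondingly `Q_v / m`
#' for veins).
#'
#' @param map a [voxelize_segments()] result.
#' @param voxel_Q tibble with columns `vox, Q` (m^3/s per voxel).
#' @param kind `"ARTERY"` or `"VEIN"`.
#' @return tibble `node, q` with one row per receiving terminal node.
#' @export
distribute_terminal_exchange <- function(map, voxel_Q, kind = c("ARTERY", "VEIN")) {
  kind <- match.arg(kind)
  voxel_Q <- voxel_Q[voxel_Q$Q != 0, , drop = FALSE]
  term <- map$terminals[map$terminals$kind == kind, , drop = FALSE]
  cnt <- table(term$vox)
  missing <- setdiff(voxel_Q$vox, as.numeric(names(cnt)))
  if (length(missing) > 0) {
    abort(sprintf("voxels with exchange demand but no coupled terminal %s node: %s",
                  kind, paste(missing, collapse = ", ")))
  }
  n_of <- as.numeric(cnt[as.character(term$vox)])
  q <- voxel_Q$Q[match(term$vox, voxel_Q$vox)] / n_of
  q[is.na(q)] <- 0
  tibble(node = term$node, q = q)
}
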