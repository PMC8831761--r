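#' Couple the 1-D vessel network to the porous capillary phase
#'
#' Distributes the prescribed arterial inlet flow over the tissue as
#' per-voxel exchange demands, splits those demands evenly over each voxel's
#' coupled terminal nodes, and runs both flow solvers. Terminals cut off from
#' their root by a fully occluded segment receive nothing (the demand is
#' assigned over reachable terminals only), so occluding the single inlet
#' zeroes every flow.
#'
#' Perfusion policies (how total inlet flow maps to voxels):
#' * `"terminal_count"` (default): per-voxel arterial demand proportional to
#'   its count of reachable terminal artery nodes, venous return proportional
#'   to reachable terminal vein nodes. The Darcy phase then carries blood
#'   from arterial to venous coupling sites.
#' * `"tissue_volume"`: demand proportional to voxel tissue volume among
#'   voxels holding at least one reachable terminal of the kind.
#' * `"local_balance"`: `Q_v = Q_a` per voxel, restricted to voxels holding
#'   reachable terminals of both kinds (no net Darcy flow).
#'
#' @param network a [vessel_network()] with radii assigned.
#' @param grid a [voxel_grid()].
#' @param map a [voxelize_segments()] result for `network` on `grid` (built
#'   on the fly if `NULL`).
#' @param inlet_flow total arterial inlet flow (m^3/s).
#' @param props a [tissue_properties()].
#' @param perfusion_policy see above.
#' @return list of class `coupled_flow` with elements `network_flow`
#'   ([solve_network_flow()] result), `porous_flow` ([solve_darcy()] result),
#'   `map`, and `balance`, a tibble certifying the conservation chain
#'   root inflow = sum(q_a) = sum(Q_a) = sum(Q_v) = sum(q_v) = root outflow.
#' @export
couple_network_porous <- function(network, grid, map = NULL, inlet_flow,
                                  props = tissue_properties(),
                                  perfusion_policy = c("terminal_count",
                                                       "tissue_volume",
                                                       "local_balance")) {
  perfusion_policy <- match.arg(perfusion_policy)
  stopifnot(inlet_flow >= 0)
  for (k in c("ARTERY", "VEIN")) {
    if (!any(network$segments$kind == k)) {
      abort(sprintf("coupling requires both vessel trees; %s missing", k))
    }
  }
  if (is.null(map)) map <- voxelize_segments(network, grid)
  reach <- list()
  for (k in c("ARTERY", "VEIN")) {
    reach[[k]] <- reachable_terminals(network, k)
  }
  term <- map$terminals
  term$reachable <- term$node %in% c(reach$ARTERY, reach$VEIN)
  art <- term[term$kind == "ARTERY" & term$reachable, ]
  ven <- term[term$kind == "VEIN" & term$reachable, ]
  h3 <- grid$voxel_size^3
  weights <- function(tt) {
    cnt <- dplyr::count(tt, .data$vox)
    switch(perfusion_policy,
           terminal_count = tibble(vox = cnt$vox, w = as.numeric(cnt$n)),
           tissue_volume = tibble(vox = cnt$vox, w = rep(h3, nrow(cnt))),
           local_balance = tibble(vox = cnt$vox, w = as.numeric(cnt$n)))
  }
  if (nrow(art) == 0 || inlet_flow == 0) {
    Qa_tab <- tibble(vox = numeric(0), Q = numeric(0))
    Qv_tab <- Qa_tab
    delivered <- 0
  } else {
    wa <- weights(art)
    wv <- weights(ven)
    if (perfusion_policy == "local_balance") {
      shared <- intersect(wa$vox, wv$vox)
      if (length(shared) == 0) {
        abort("local_balance policy: no voxel holds reachable terminals of both kinds")
      }
      wa <- wa[wa$vox %in% shared, ]
      wv <- wa
    }
    if (nrow(wv) == 0) {
      abort("no reachable terminal vein nodes to return the inlet flow")
    }
    delivered <- inlet_flow
    Qa_tab <- tibble(vox = wa$vox, Q = delivered * wa$w / sum(wa$w))
    Qv_tab <- tibble(vox = wv$vox, Q = delivered * wv$w / sum(wv$w))
  }
  # split voxel demands over coupled (reachable) terminals
  map_reach <- map
  map_reach$terminals <- term[term$reachable, , drop = FALSE]
  qa <- distribute_terminal_exchange(map_reach, Qa_tab, "ARTERY")
  qv <- distribute_terminal_exchange(map_reach, Qv_tab, "VEIN")
  texch <- dplyr::bind_rows(qa, qv)
  nf <- solve_network_flow(network,
                           inlet_flows = c(ARTERY = delivered, VEIN = delivered),
                           terminal_exchange = texch, props = props)
  pf <- solve_darcy(grid,
                    tibble(vox = Qa_tab$vox, Q = Qa_tab$Q),
                    tibble(vox = Qv_tab$vox, Q = Qv_tab$Q), props)
  balance <- tibble(
    quantity = c("root_inflow", "sum_q_a", "sum_Q_a", "sum_Q_v", "sum_q_v",
                 "root_outflow"),
    value = c(delivered, sum(qa$q), sum(Qa_tab$Q), sum(Qv_tab$Q), sum(qv$q),
              root_flow(network, nf, "VEIN")))
  chain_tol <- 1e-10 * max(delivered, 1e-300)
  if (max(abs(balance$value - delivered)) > chain_tol && delivered > 0) {
    abort("mass conservation chain violated in coupled solve")
  }
  structure(list(network_flow = nf, porous_flow = pf, map = map,
                 balance = balance, inlet_flow = inlet_flow,
                 perfusion_policy = perfusion_policy),
            class = "coupled_flow")
}

# Terminal (leaf) nodes of `kind` connected to the root through positive
# conductance (radius > 0) segments.
reachable_terminals <- function(network, kind) {
  seg <- network$segments[network$segments$kind == kind, ]
  live <- seg$radius > 0 & !is.na(seg$radius)
  nodes_k <- sort(unique(c(seg$node_a, seg$node_b)))
  comp <- graph_components(length(nodes_k),
                           match(seg$node_a[live], nodes_k),
                           match(seg$node_b[live], nodes_k))
  root <- network$roots$node[network$roots$kind == kind][1]
  ok <- nodes_k[comp == comp[match(root, nodes_k)]]
  intersect(leaf_nodes(network, kind), ok)
}

# Net flow through the root node of a kind (m^3/s, positive = through-flow).
root_flow <- function(network, nf, kind) {
  root <- network$roots$node[network$roots$kind == kind][1]
  seg <- network$segments
  i <- which(seg$kind == kind & (seg$node_a == root | seg$node_b == root))
  f <- nf$segments$flow[match(seg$id[i], nf$segments$id)]
  sgn <- ifelse(seg$node_a[i] == root, 1, -1)
  if (kind == "ARTERY") sum(sgn * f) else -sum(sgn * f)
}

#' @export
print.coupled_flow <- function(x, ...) {
  cat(sprintf("<coupled_flow> inlet %.4g ml/s, policy %s\n",
              x$inlet_flow * 1e6, x$perfusion_policy))
  print(x$balance)
  invisible(x)
}
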