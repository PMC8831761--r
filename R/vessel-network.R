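#' Vessel network
#'
#' A geometric tree (per vessel kind) of artery or vein segments embedded in
#' the tissue domain. Arteries and veins form independent rooted trees: the
#' artery root is the inlet where blood enters, the vein root the outlet
#' where it leaves. Terminal segments (those with a leaf endpoint) are the
#' arterioles/venules that exchange blood with the capillary (porous) phase.
#'
#' @param nodes tibble with columns `id, x, y, z` (positions in metres).
#' @param segments tibble with columns `id, node_a, node_b, radius, kind`
#'   (`radius` in metres, may be `NA` before [assign_radii()]; `kind` is
#'   `"ARTERY"` or `"VEIN"`).
#' @param roots tibble with columns `node, kind`: one root per vessel kind
#'   present.
#' @return an object of class `vessel_network` with tibbles `nodes`,
#'   `segments` (including a recomputed logical `terminal` column) and
#'   `roots`.
#' @seealso [seed_cubic_network()], [grow_rrt()], [assign_radii()],
#'   [apply_stenosis()]
#' @export
vessel_network <- function(nodes, segments, roots) {
  nodes <- as_tibble(nodes)[, c("id", "x", "y", "z")]
  segments <- as_tibble(segments)
  if (!"radius" %in% names(segments)) segments$radius <- NA_real_
  segments <- segments[, c("id", "node_a", "node_b", "radius", "kind")]
  roots <- as_tibble(roots)[, c("node", "kind")]
  if (anyDuplicated(nodes$id)) abort("duplicate node ids")
  if (anyDuplicated(segments$id)) abort("duplicate segment ids")
  if (!all(segments$kind %in% c("ARTERY", "VEIN"))) {
    abort("segment `kind` must be ARTERY or VEIN")
  }
  if (!all(c(segments$node_a, segments$node_b, roots$node) %in% nodes$id)) {
    abort("segments or roots reference unknown node ids")
  }
  if (any(!is.na(segments$radius) & segments$radius < 0)) {
    abort("segment radii must be non-negative")
  }
  net <- structure(list(nodes = nodes, segments = segments, roots = roots),
                   class = "vessel_network")
  for (k in unique(segments$kind)) {
    if (!any(roots$kind == k)) abort(sprintf("no root declared for kind %s", k))
    check_tree(net, k)
  }
  net$segments <- recompute_terminals(net)
  net
}

#' @export
print.vessel_network <- function(x, ...) {
  for (k in unique(x$segments$kind)) {
    s <- x$segments[x$segments$kind == k, ]
    cat(sprintf("<vessel_network> %s: %d segments, %d terminal; radii %s\n",
                k, nrow(s), sum(s$terminal),
                if (all(is.na(s$radius))) "unassigned" else
                  sprintf("[%.3g, %.3g] mm", min(s$radius, na.rm = TRUE) * 1e3,
                          max(s$radius, na.rm = TRUE) * 1e3)))
  }
  invisible(x)
}

# Connected + acyclic check for one vessel kind, rooted at its declared root.
check_tree <- function(net, kind) {
  seg <- net$segments[net$segments$kind == kind, ]
  if (nrow(seg) == 0) return(invisible(TRUE))
  nodes <- unique(c(seg$node_a, seg$node_b))
  root <- net$roots$node[net$roots$kind == kind][1]
  if (!root %in% nodes) abort(sprintf("%s root is not an endpoint of any segment", kind))
  if (nrow(seg) != length(nodes) - 1) {
    abort(sprintf("%s segments do not form a tree (%d segments, %d nodes)",
                  kind, nrow(seg), length(nodes)))
  }
  # BFS connectivity
  adj <- split(c(seg$node_b, seg$node_a), c(seg$node_a, seg$node_b))
  seen <- structure(logical(length(nodes)), names = nodes)
  queue <- root
  seen[as.character(root)] <- TRUE
  while (length(queue) > 0) {
    v <- queue[[1]]; queue <- queue[-1]
    nb <- adj[[as.character(v)]]
    new <- nb[!seen[as.character(nb)]]
    seen[as.character(new)] <- TRUE
    queue <- c(queue, new)
  }
  if (!all(seen)) abort(sprintf("%s tree is not connected to its root", kind))
  invisible(TRUE)
}

# A segment is terminal iff one endpoint is a non-root leaf of its kind.
recompute_terminals <- function(net) {
  seg <- net$segments
  seg$terminal <- FALSE
  for (k in unique(seg$kind)) {
    i <- seg$kind == k
    deg <- table(c(seg$node_a[i], seg$node_b[i]))
    root <- net$roots$node[net$roots$kind == k]
    leaf <- as.numeric(names(deg))[deg == 1]
    leaf <- setdiff(leaf, root)
    seg$terminal[i] <- seg$node_a[i] %in% leaf | seg$node_b[i] %in% leaf
  }
  seg
}

# Leaf (non-root, degree-1) nodes of one kind.
leaf_nodes <- function(net, kind) {
  seg <- net$segments[net$segments$kind == kind, ]
  deg <- table(c(seg$node_a, seg$node_b))
  root <- net$roots$node[net$roots$kind == kind]
  setdiff(as.numeric(names(deg))[deg == 1], root)
}

segment_lengths <- function(net, seg = net$segments) {
  pa <- net$nodes[match(seg$node_a, net$nodes$id), c("x", "y", "z")]
  pb <- net$nodes[match(seg$node_b, net$nodes$id), c("x", "y", "z")]
  sqrt(rowSums((as.matrix(pb) - as.matrix(pa))^2))
}

#' Seed vessel network for the cubic phantom
#'
#' One inlet artery and one outlet vein at mid-depth, entering from opposite
#' faces of the slab, from which [grow_rrt()] grows the trees.
#'
#' @param grid a [voxel_grid()] (used for its physical extent).
#' @param depth_frac depth of the seed vessels as a fraction of slab height
#'   (0 = bottom, 1 = skin).
#' @return a [vessel_network()] with one artery and one vein segment.
#' @export
seed_cubic_network <- function(grid, depth_frac = 0.5) {
  ext <- grid_extent(grid)
  h <- grid$voxel_size
  z0 <- depth_frac * ext[3]
  nodes <- tibble(
    id = 1:4,
    x = c(h / 2, 0.35 * ext[1], ext[1] - h / 2, 0.65 * ext[1]),
    y = rep(ext[2] / 2, 4),
    z = rep(z0, 4)
  )
  segments <- tibble(
    id = 1:2, node_a = c(1L, 3L), node_b = c(2L, 4L),
    radius = NA_real_, kind = c("ARTERY", "VEIN")
  )
  roots <- tibble(node = c(1L, 3L), kind = c("ARTERY", "VEIN"))
  vessel_network(nodes, segments, roots)
}

#' Assign segment radii by Murray's law
#'
#' Sets the root segment radius and propagates radii towards the leaves under
#' the bifurcation rule `parent^gamma = sum(children^gamma)`, with each
#' child's share proportional to the number of leaves its subtree feeds.
#' Equivalently every segment gets
#' `radius = root_radius * (leaves(segment) / leaves(root))^(1/gamma)`,
#' which satisfies the Murray relation exactly at every bifurcation and is
#' non-increasing from root to leaf.
#'
#' @param network a [vessel_network()]; each kind must form a rooted tree.
#' @param root_radius radius of the root segment (m); scalar, or named vector
#'   with entries `ARTERY`/`VEIN`.
#' @param murray_exponent bifurcation exponent `gamma` (3 = Murray's law).
#' @return the network with radii filled in.
#' @export
assign_radii <- function(network, root_radius = 2e-4, murray_exponent = 3) {
  stopifnot(murray_exponent > 0, all(root_radius > 0))
  seg <- network$segments
  for (k in unique(seg$kind)) {
    rr <- if (length(root_radius) > 1) root_radius[[k]] else root_radius
    i <- which(seg$kind == k)
    sk <- seg[i, ]
    root <- network$roots$node[network$roots$kind == k][1]
    ord <- orient_from_root(sk, root)
    leaves <- leaf_counts(sk, ord)
    total <- leaves[ord$order[1]]  # root segment feeds every leaf
    seg$radius[i] <- rr * (leaves / total)^(1 / murray_exponent)
  }
  network$segments <- seg
  network$segments <- recompute_terminals(network)
  network
}

# Orient a kind's segments away from the root; returns list(order, down)
# where order is a root-first ordering of segment row indices and down[j] is
# the downstream (child-side) node of segment j.
orient_from_root <- function(sk, root) {
  n <- nrow(sk)
  down <- integer(n)
  order <- integer(n)
  touched <- logical(n)
  frontier <- root
  cnt <- 0
  while (length(frontier) > 0) {
    nxt <- numeric(0)
    for (v in frontier) {
      js <- which(!touched & (sk$node_a == v | sk$node_b == v))
      for (j in js) {
        touched[j] <- TRUE
        cnt <- cnt + 1
        order[cnt] <- j
        down[j] <- if (sk$node_a[j] == v) sk$node_b[j] else sk$node_a[j]
        nxt <- c(nxt, down[j])
      }
    }
    frontier <- nxt
  }
  if (cnt != n) abort("segments are not all reachable from the root")
  list(order = order, down = down)
}

# Number of leaves fed by each segment (vector over segment rows).
leaf_counts <- function(sk, ord = NULL, root = NULL) {
  if (is.null(ord)) ord <- orient_from_root(sk, root)
  n <- nrow(sk)
  deg <- table(c(sk$node_a, sk$node_b))
  counts <- numeric(n)
  # children of segment j: segments whose parent-side node is down[j]
  for (j in rev(ord$order)) {
    kids <- which(sk$node_a == ord$down[j] | sk$node_b == ord$down[j])
    kids <- setdiff(kids, j)
    # only true children (those oriented away), i.e. their parent node is down[j]
    kids <- kids[vapply(kids, function(q) {
      up <- if (ord$down[q] == sk$node_a[q]) sk$node_b[q] else sk$node_a[q]
      up == ord$down[j]
    }, logical(1))]
    counts[j] <- if (length(kids) == 0) 1 else sum(counts[kids])
  }
  counts
}

#' Narrow or occlude a vessel segment
#'
#' Scales the radius of one segment by `1 - degree`. Poiseuille conductance
#' falls with the fourth power of radius, so a 50% narrowing reduces the flow
#' through an isolated tube 16-fold at fixed pressure drop; `degree = 1`
#' leaves a zero-radius, zero-conductance (fully occluded) segment and the
#' flow solver then delivers nothing downstream of it.
#'
#' @param network a [vessel_network()].
#' @param segment_id id of the segment to narrow.
#' @param degree stenosis degree in `[0, 1]`.
#' @return the modified network.
#' @export
apply_stenosis <- function(network, segment_id, degree) {
  stopifnot(length(degree) == 1, degree >= 0, degree <= 1)
  j <- match(segment_id, network$segments$id)
  if (is.na(j)) abort(sprintf("unknown segment id %s", segment_id))
  network$segments$radius[j] <- network$segments$radius[j] * (1 - degree)
  network
}

#' Mean distance from tissue voxels to the nearest vessel
#'
#' Space-filling summary used to monitor tree growth: the mean over tissue
#' voxel centres of the Euclidean distance to the closest vessel segment.
#'
#' @param network a [vessel_network()].
#' @param grid a [voxel_grid()].
#' @param kind restrict to one vessel kind, or `NULL` for all segments.
#' @return mean distance in metres.
#' @export
mean_vessel_distance <- function(network, grid, kind = NULL) {
  seg <- network$segments
  if (!is.null(kind)) seg <- seg[seg$kind == kind, ]
  P <- as.matrix(voxel_centres(grid)[, c("x", "y", "z")])
  a <- as.matrix(network$nodes[match(seg$node_a, network$nodes$id), c("x", "y", "z")])
  b <- as.matrix(network$nodes[match(seg$node_b, network$nodes$id), c("x", "y", "z")])
  best <- rep(Inf, nrow(P))
  for (j in seq_len(nrow(seg))) {
    ab <- b[j, ] - a[j, ]
    len2 <- sum(ab^2)
    rel <- sweep(P, 2, a[j, ])
    t <- if (len2 == 0) rep(0, nrow(P)) else pmin(1, pmax(0, rel %*% ab / len2))
    d2 <- rowSums((rel - tcrossprod(t, ab))^2)
    best <- pmin(best, d2)
  }
  mean(sqrt(best))
}
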