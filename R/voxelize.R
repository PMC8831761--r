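#' Map vessel segments onto the voxel grid
#'
#' Traverses each segment through the grid and records, per segment, the
#' voxels it intersects together with the exact intersected length and the
#' lateral wall area `2*pi*R*length` shared with each voxel. Also tallies,
#' per voxel, the number of terminal artery nodes `n` and terminal vein
#' nodes `m` it contains — the coupling counts used to distribute blood
#' exchange between the discrete vessels and the capillary phase.
#'
#' @param network a [vessel_network()] with radii assigned.
#' @param grid a [voxel_grid()]; all nodes must lie inside its extent.
#' @return an object of class `segment_voxel_map`: a list with
#'   * `entries`: tibble `seg_id, kind, terminal, vox, ix, iy, iz, length, area`,
#'   * `terminals`: tibble `node, kind, vox, seg_id` (one row per leaf node),
#'   * `voxel_counts`: tibble `vox, n, m`.
#' @export
voxelize_segments <- function(network, grid) {
  seg <- network$segments
  nodes <- network$nodes
  ext <- grid_extent(grid)
  h <- grid$voxel_size
  d <- grid$shape
  pa <- as.matrix(nodes[match(seg$node_a, nodes$id), c("x", "y", "z")])
  pb <- as.matrix(nodes[match(seg$node_b, nodes$id), c("x", "y", "z")])
  rel_a <- sweep(pa, 2, grid$origin)
  rel_b <- sweep(pb, 2, grid$origin)
  tol <- 1e-9 * max(ext)
  out_a <- which(apply(rel_a, 1, function(p) any(p < -tol | p > ext + tol)))
  out_b <- which(apply(rel_b, 1, function(p) any(p < -tol | p > ext + tol)))
  if (length(out_a) + length(out_b) > 0) {
    bad <- unique(c(seg$node_a[out_a], seg$node_b[out_b]))
    abort(sprintf("nodes outside the grid extent: %s",
                  paste(sort(bad), collapse = ", ")))
  }
  lens <- sqrt(rowSums((rel_b - rel_a)^2))
  if (any(lens == 0)) {
    abort(sprintf("zero-length segments: %s",
                  paste(seg$id[lens == 0], collapse = ", ")))
  }
  res <- vector("list", nrow(seg))
  for (j in seq_len(nrow(seg))) {
    p0 <- rel_a[j, ]; p1 <- rel_b[j, ]
    dp <- p1 - p0
    tcuts <- numeric(0)
    for (ax in 1:3) {
      if (abs(dp[ax]) > 0) {
        k0 <- ceiling(min(p0[ax], p1[ax]) / h + 1e-12)
        k1 <- floor(max(p0[ax], p1[ax]) / h - 1e-12)
        if (k1 >= k0) {
          tcuts <- c(tcuts, ((k0:k1) * h - p0[ax]) / dp[ax])
        }
      }
    }
    tcuts <- sort(unique(pmin(1, pmax(0, tcuts))))
    tt <- unique(c(0, tcuts, 1))
    tmid <- (tt[-1] + tt[-length(tt)]) / 2
    pieces <- length(tmid)
    mid <- matrix(p0, pieces, 3, byrow = TRUE) + tmid %o% dp
    ijk <- pmin(matrix(rep(d, each = pieces), pieces, 3),
                pmax(1L, floor(mid / h) + 1L))
    vox <- ijk[, 1] + d[1] * (ijk[, 2] - 1) + d[1] * d[2] * (ijk[, 3] - 1)
    plen <- diff(tt) * lens[j]
    # merge duplicate voxels (can arise from snapped cuts)
    agg <- rowsum(plen, vox)
    v <- as.numeric(rownames(agg))
    res[[j]] <- tibble(seg_id = seg$id[j], vox = v, length = as.numeric(agg))
  }
  entries <- dplyr::bind_rows(res)
  m <- match(entries$seg_id, seg$id)
  entries$kind <- seg$kind[m]
  entries$terminal <- seg$terminal[m]
  entries$area <- 2 * pi * seg$radius[m] * entries$length
  ijk <- arrayInd(entries$vox, d)
  entries$ix <- ijk[, 1]; entries$iy <- ijk[, 2]; entries$iz <- ijk[, 3]
  entries <- entries[, c("seg_id", "kind", "terminal", "vox", "ix", "iy", "iz",
                         "length", "area")]

  terminals <- terminal_node_table(network, grid)
  vc <- dplyr::count(terminals, .data$vox, .data$kind)
  voxel_counts <- tidyr::pivot_wider(vc, names_from = "kind", values_from = "n",
                                     values_fill = 0L)
  if (!"ARTERY" %in% names(voxel_counts)) voxel_counts$ARTERY <- 0L
  if (!"VEIN" %in% names(voxel_counts)) voxel_counts$VEIN <- 0L
  voxel_counts <- tibble(vox = voxel_counts$vox, n = voxel_counts$ARTERY,
                         m = voxel_counts$VEIN)
  structure(list(entries = entries, terminals = terminals,
                 voxel_counts = voxel_counts, shape = d),
            class = "segment_voxel_map")
}

# One row per leaf node: the voxel containing it and the terminal segment
# ending there.
terminal_node_table <- function(network, grid) {
  seg <- network$segments
  nodes <- network$nodes
  h <- grid$voxel_size
  d <- grid$shape
  rows <- list()
  for (k in unique(seg$kind)) {
    lv <- leaf_nodes(network, k)
    if (length(lv) == 0) next
    sk <- seg[seg$kind == k, ]
    sid <- vapply(lv, function(v) sk$id[which(sk$node_a == v | sk$node_b == v)[1]],
                  numeric(1))
    p <- as.matrix(nodes[match(lv, nodes$id), c("x", "y", "z")])
    rel <- sweep(p, 2, grid$origin)
    ijk <- pmin(matrix(rep(d, each = length(lv)), length(lv), 3),
                pmax(1L, ceiling(rel / h)))
    vox <- ijk[, 1] + d[1] * (ijk[, 2] - 1) + d[1] * d[2] * (ijk[, 3] - 1)
    rows[[k]] <- tibble(node = lv, kind = k, vox = vox, seg_id = sid)
  }
  dplyr::bind_rows(rows)
}

#' @export
print.segment_voxel_map <- function(x, ...) {
  cat(sprintf("<segment_voxel_map> %d segment-voxel entries, %d terminal nodes in %d voxels\n",
              nrow(x$entries), nrow(x$terminals), nrow(x$voxel_counts)))
  invisible(x)
}
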