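# Rapidly-exploring random tree growth of vascular networks.

# Evaluate an expression with a temporarily fixed RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Grow a vessel network by rapidly-exploring random trees
#'
#' Grows each vessel kind's tree independently from its seed structure. One
#' iteration (per kind): draw a point uniformly inside the tissue space (a
#' uniformly chosen tissue voxel, jittered uniformly within the voxel); find
#' the closest existing node or segment by Euclidean distance; link the point
#' to that closest element with a new segment. When the closest point falls
#' strictly inside an existing segment, that segment is split in two at a new
#' node and the link attaches there. Ties between equidistant elements go to
#' the lowest segment id.
#'
#' Growth can stop early when (a) the segment count has changed by less than
#' `plateau_tol` over the trailing `window` fraction of iterations and (b)
#' the flow carried by the smallest vessel under even terminal distribution,
#' `inlet_flow / n_terminals`, has fallen to `min_terminal_flow`. With
#' `stop = NULL` (default) the set number of iterations is always completed.
#'
#' @param grid a [voxel_grid()] providing the tissue sampling space.
#' @param seed_network a [vessel_network()]; every kind in `kinds` must have
#'   at least one segment.
#' @param iterations number of growth iterations per kind (>= 0).
#' @param rng_seed integer seed; identical seeds give identical networks.
#' @param stop optional early-stop criteria:
#'   `list(window = 0.1, plateau_tol = 0.01, min_terminal_flow = , inlet_flow = )`
#'   (flows in m^3/s; the arteriole/venule flow at which growth is considered
#'   complete is problem knowledge, so no default is asserted).
#' @param kinds vessel kinds to grow.
#' @return a [vessel_network()] (radii of new segments unset; call
#'   [assign_radii()]). The per-kind segment counts at checkpoints are
#'   attached as `attr(, "growth_log")`.
#' @export
grow_rrt <- function(grid, seed_network, iterations, rng_seed = NULL,
                     stop = NULL, kinds = c("ARTERY", "VEIN")) {
  stopifnot(iterations >= 0)
  tis_idx <- which(grid$labels != LABEL_OUTSIDE)
  if (length(tis_idx) == 0) abort("grid contains no tissue voxels to sample")
  for (k in kinds) {
    if (!any(seed_network$segments$kind == k)) {
      abort(sprintf("seed network has no %s segments", k))
    }
  }
  ijk <- arrayInd(tis_idx, grid$shape)
  h <- grid$voxel_size
  centres <- sweep((ijk - 0.5) * h, 2, grid$origin, "+")
  log <- list()
  with_seed(rng_seed, {
    nodes <- seed_network$nodes
    segs <- seed_network$segments
    next_node <- max(nodes$id) + 1L
    next_seg <- max(segs$id) + 1L
    for (k in kinds) {
      res <- grow_one_kind(nodes, segs, seed_network$roots, k, iterations,
                           centres, h, next_node, next_seg, stop)
      nodes <- res$nodes; segs <- res$segs
      next_node <- res$next_node; next_seg <- res$next_seg
      log[[k]] <- res$log
    }
    out <- vessel_network(nodes, segs, seed_network$roots)
    attr(out, "growth_log") <- dplyr::bind_rows(log, .id = "kind")
    out
  })
}

grow_one_kind <- function(nodes, segs, roots, kind, iterations, centres, h,
                          next_node, next_seg, stop) {
  mine <- which(segs$kind == kind)
  cap <- length(mine) + 2L * iterations + 8L
  # flat working arrays for speed; sid keeps global segment ids
  ax <- ay <- az <- bx <- by <- bz <- numeric(cap)
  sid <- na_int <- integer(cap)
  nn <- nrow(nodes)
  px <- c(nodes$x, numeric(2L * iterations + 8L))
  py <- c(nodes$y, numeric(2L * iterations + 8L))
  pz <- c(nodes$z, numeric(2L * iterations + 8L))
  pid <- c(nodes$id, integer(2L * iterations + 8L))
  ai <- match(segs$node_a[mine], nodes$id)
  bi <- match(segs$node_b[mine], nodes$id)
  ns <- length(mine)
  ax[1:ns] <- px[ai]; ay[1:ns] <- py[ai]; az[1:ns] <- pz[ai]
  bx[1:ns] <- px[bi]; by[1:ns] <- py[bi]; bz[1:ns] <- pz[bi]
  na_int[1:ns] <- segs$node_a[mine]
  nb_int <- integer(cap); nb_int[1:ns] <- segs$node_b[mine]
  sid[1:ns] <- segs$id[mine]
  nvox <- nrow(centres)
  checkpoints <- unique(c(0L, seq(0L, iterations, by = max(1L, iterations %/% 20L)), iterations))
  log_n <- integer(0); log_it <- integer(0)
  window_counts <- integer(0)
  it_done <- iterations
  eps <- 1e-12
  for (it in seq_len(iterations)) {
    v <- sample.int(nvox, 1L)
    p <- centres[v, ] + (runif(3) - 0.5) * h
    r <- seq_len(ns)
    dx <- bx[r] - ax[r]; dy <- by[r] - ay[r]; dz <- bz[r] - az[r]
    len2 <- dx * dx + dy * dy + dz * dz
    wx <- p[1] - ax[r]; wy <- p[2] - ay[r]; wz <- p[3] - az[r]
    t <- (wx * dx + wy * dy + wz * dz) / pmax(len2, eps)
    t[len2 < eps] <- 0
    t <- pmin(1, pmax(0, t))
    ex <- wx - t * dx; ey <- wy - t * dy; ez <- wz - t * dz
    d2 <- ex * ex + ey * ey + ez * ez
    j <- which.min(d2)  # first minimum = lowest id (rows kept in id order)
    tj <- t[j]
    # decide attachment point: a node, or strictly inside segment j -> split
    snap <- h * 1e-6
    lenj <- sqrt(len2[j])
    tol_t <- if (lenj > 0) snap / lenj else 1
    new_np <- next_node
    px[nn + 1L] <- p[1]; py[nn + 1L] <- p[2]; pz[nn + 1L] <- p[3]
    pid[nn + 1L] <- new_np
    nn <- nn + 1L
    next_node <- next_node + 1L
    if (tj <= tol_t) {
      attach_id <- na_int[j]
      cx <- ax[j]; cy_ <- ay[j]; cz_ <- az[j]
    } else if (tj >= 1 - tol_t) {
      attach_id <- nb_int[j]
      cx <- bx[j]; cy_ <- by[j]; cz_ <- bz[j]
    } else {
      # split segment j at the foot point
      cx <- ax[j] + tj * (bx[j] - ax[j])
      cy_ <- ay[j] + tj * (by[j] - ay[j])
      cz_ <- az[j] + tj * (bz[j] - az[j])
      mid <- next_node
      px[nn + 1L] <- cx; py[nn + 1L] <- cy_; pz[nn + 1L] <- cz_
      pid[nn + 1L] <- mid
      nn <- nn + 1L
      next_node <- next_node + 1L
      # segment j now ends at mid; a new segment carries (mid -> old b)
      ns <- ns + 1L
      ax[ns] <- cx; ay[ns] <- cy_; az[ns] <- cz_
      bx[ns] <- bx[j]; by[ns] <- by[j]; bz[ns] <- bz[j]
      na_int[ns] <- mid; nb_int[ns] <- nb_int[j]
      sid[ns] <- next_seg; next_seg <- next_seg + 1L
      bx[j] <- cx; by[j] <- cy_; bz[j] <- cz_
      nb_int[j] <- mid
      attach_id <- mid
    }
    ns <- ns + 1L
    ax[ns] <- cx; ay[ns] <- cy_; az[ns] <- cz_
    bx[ns] <- p[1]; by[ns] <- p[2]; bz[ns] <- p[3]
    na_int[ns] <- attach_id; nb_int[ns] <- new_np
    sid[ns] <- next_seg; next_seg <- next_seg + 1L
    if (it %in% checkpoints) {
      log_it <- c(log_it, it); log_n <- c(log_n, ns)
      if (!is.null(stop)) {
        window <- stop$window %||% 0.1
        plateau_tol <- stop$plateau_tol %||% 0.01
        w_it <- it - window * iterations
        prev <- log_n[which(log_it >= w_it)[1]]
        plateau <- (ns - prev) / ns < plateau_tol
        flow_ok <- TRUE
        if (!is.null(stop$min_terminal_flow) && !is.null(stop$inlet_flow)) {
          deg <- tabulate(match(c(na_int[1:ns], nb_int[1:ns]), pid[1:nn]), nbins = nn)
          root <- roots$node[roots$kind == kind][1]
          leaves <- sum(deg == 1) - (deg[match(root, pid[1:nn])] == 1)
          flow_ok <- stop$inlet_flow / max(leaves, 1) <= stop$min_terminal_flow
        }
        if (plateau && flow_ok) { it_done <- it; break }
      }
    }
  }
  keep_new <- setdiff(seq_len(nn), seq_len(nrow(nodes)))
  nodes <- dplyr::bind_rows(nodes, tibble(id = pid[keep_new], x = px[keep_new],
                                          y = py[keep_new], z = pz[keep_new]))
  old_other <- segs[segs$kind != kind, ]
  grown <- tibble(id = sid[1:ns], node_a = na_int[1:ns], node_b = nb_int[1:ns],
                  radius = NA_real_, kind = kind)
  # seed segments of this kind keep their radii unless they were split
  keep_r <- match(grown$id, segs$id)
  same_geom <- !is.na(keep_r)
  grown$radius[same_geom] <- segs$radius[keep_r[same_geom]]
  segs <- dplyr::bind_rows(old_other, grown)
  segs <- segs[order(segs$id), ]
  list(nodes = nodes, segs = segs, next_node = next_node, next_seg = next_seg,
       log = tibble(iteration = log_it, segments = log_n, stopped_at = it_done))
}
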