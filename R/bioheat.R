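# Four-domain steady energy balance: 1-D arteries (T1), tissue phase (T2),
# capillary phase (T3), 1-D veins (T4), assembled as one sparse linear
# system. Conduction is discretised centrally (6-neighbour in the voxel
# phases, along-vessel in the 1-D domains), advection with first-order
# upwinding on the solved flows, and the mass-exchange enthalpy terms use
# donor temperatures so that they cancel pairwise in the global energy sum.

#' Assemble the steady four-domain energy system
#'
#' Builds the sparse linear system `A x = b` whose unknowns are the
#' temperatures of every artery segment, tissue voxel, capillary voxel and
#' vein segment. Rows are per-element energy balances containing: conduction
#' (central differences), advection (first-order upwind on the supplied
#' flows, with donor-cell mixing at vessel junctions), inter-domain `beta`
#' exchange, donor-temperature mass-exchange enthalpy, metabolic heat in the
#' tissue phase, Robin (convective + radiative) exchange plus any imposed
#' heating flux on the exposed skin faces, and adiabatic conditions on all
#' other boundaries. The arterial inlet enters as an upwind stream at
#' `T_inlet` (`inlet_mode = "advective"`, energy-conserving) or as a
#' Dirichlet row on the root segments (`inlet_mode = "dirichlet"`).
#'
#' @param grid a [voxel_grid()].
#' @param network a [vessel_network()] with radii.
#' @param flows a [couple_network_porous()] result (or a list with elements
#'   `network_flow`, `porous_flow`, `map`).
#' @param coeffs a [compute_exchange_coefficients()] result.
#' @param boundary a [thermal_boundary()].
#' @param props a [tissue_properties()].
#' @param mask a [extract_skin_mask()] surface mask (its `heating` column
#'   receives `boundary$q_heat`).
#' @param inlet_mode arterial inlet treatment, see above.
#' @param skin_exposure `"weighted"` applies the Robin condition to both
#'   voxel phases weighted by their volume fractions; `"tissue_only"` puts
#'   the whole face on the tissue phase.
#' @param double_beta23 duplicate the tissue-capillary exchange term in the
#'   tissue balance (off by default; provided to reproduce the literal
#'   doubled term).
#' @return object of class `energy_system`: sparse matrix `A`, load `b`, and
#'   an `index`/`meta` pair describing the unknown ordering and the
#'   ingredients of the global energy audit.
#' @export
assemble_energy_system <- function(grid, network, flows, coeffs, boundary,
                                   props, mask,
                                   inlet_mode = c("advective", "dirichlet"),
                                   skin_exposure = c("weighted", "tissue_only"),
                                   double_beta23 = FALSE) {
  inlet_mode <- match.arg(inlet_mode)
  skin_exposure <- match.arg(skin_exposure)
  if (is.null(flows$network_flow) || is.null(flows$porous_flow)) {
    abort("`flows` must carry both the network and porous flow solutions")
  }
  nf <- flows$network_flow
  pf <- flows$porous_flow
  map <- flows$map
  check_node_balance(network, nf)

  seg <- network$segments
  art <- which(seg$kind == "ARTERY")
  ven <- which(seg$kind == "VEIN")
  d <- grid$shape
  tis <- which(grid$labels != LABEL_OUTSIDE)
  n1 <- length(art); n2 <- length(tis); n4 <- length(ven)
  o1 <- 0L; o2 <- n1; o3 <- n1 + n2; o4 <- n1 + 2L * n2
  ntot <- n1 + 2L * n2 + n4
  row1 <- integer(nrow(seg)); row1[art] <- o1 + seq_len(n1)
  row4 <- integer(nrow(seg)); row4[ven] <- o4 + seq_len(n4)
  rowseg <- row1 + row4                      # unknown index per segment row
  vmap <- integer(prod(d))
  vmap[tis] <- seq_len(n2)
  row2 <- function(vox) o2 + vmap[vox]
  row3 <- function(vox) o3 + vmap[vox]

  h <- grid$voxel_size
  V <- h^3
  eps3 <- as.numeric(grid$epsilon3)
  eps2 <- 1 - eps3
  rcb <- props$rho_b * props$c_b
  Ktis <- ifelse(as.numeric(grid$labels) == LABEL_BONE, props$K_bone, props$K_soft)

  ii <- list(); jj <- list(); xx <- list(); nacc <- 0L
  b <- numeric(ntot)
  add <- function(i, j, x) {
    keep <- x != 0
    if (!any(keep)) return(invisible())
    nacc <<- nacc + 1L
    ii[[nacc]] <<- i[keep]; jj[[nacc]] <<- j[keep]; xx[[nacc]] <<- x[keep]
    invisible()
  }
  couple_sym <- function(ri, rj, c) {
    add(ri, ri, c); add(rj, rj, c)
    add(ri, rj, -c); add(rj, ri, -c)
  }
  hmean <- function(a, b_) ifelse(a + b_ > 0, 2 * a * b_ / (a + b_), 0)

  # --- voxel-phase conduction -------------------------------------------
  pairs <- tissue_face_pairs(grid)
  pi_ <- pairs$i; pj_ <- pairs$j
  c2 <- h * hmean(eps2[pi_] * Ktis[pi_], eps2[pj_] * Ktis[pj_])
  couple_sym(row2(pi_), row2(pj_), c2)
  c3 <- h * hmean(eps3[pi_] * props$K_b, eps3[pj_] * props$K_b)
  couple_sym(row3(pi_), row3(pj_), c3)

  # --- capillary advection (upwind on Darcy face flows) ------------------
  fq <- pf$faces$q
  fi <- pf$faces$i; fj <- pf$faces$j
  up <- ifelse(fq >= 0, fi, fj)
  dn <- ifelse(fq >= 0, fj, fi)
  aq <- abs(fq)
  add(row3(up), row3(up), rcb * aq)          # outflow leaves at donor T
  add(row3(dn), row3(up), -rcb * aq)         # and arrives downstream

  # --- vessel <-> capillary mass exchange (donor enthalpy) ---------------
  term <- map$terminals
  texch <- nf$terminal_exchange
  term_q <- texch$q[match(term$node, texch$node)]
  term_q[is.na(term_q)] <- 0
  ta <- term$kind == "ARTERY" & term_q != 0
  tv <- term$kind == "VEIN" & term_q != 0
  # arterial outflow q_a arrives in the capillary voxel at the segment's T
  add(row3(term$vox[ta]), rowseg[match(term$seg_id[ta], seg$id)],
      -rcb * term_q[ta])
  # venous uptake q_v leaves the capillary voxel at its own T
  add(row3(term$vox[tv]), row3(term$vox[tv]), rcb * term_q[tv])

  # --- vessel advection with junction mixing ----------------------------
  segflow <- nf$segments$flow[match(seg$id, nf$segments$id)]
  Q_in <- sum(pmax(0, inlet_flows_of(network, nf, "ARTERY")))
  for (k in c("ARTERY", "VEIN")) {
    ks <- which(seg$kind == k)
    F <- segflow[ks]
    dir <- sign(F)
    Fa <- abs(F)
    upn <- ifelse(dir >= 0, seg$node_a[ks], seg$node_b[ks])
    dnn <- ifelse(dir >= 0, seg$node_b[ks], seg$node_a[ks])
    live <- Fa > 0
    # incoming streams per node: discharging segments, the external inlet,
    # and (veins) capillary uptake at terminal leaves
    streams <- tibble(node = dnn[live], type = "seg",
                      col = rowseg[ks[live]], F = Fa[live],
                      Tfix = NA_real_)
    if (k == "ARTERY") {
      root <- network$roots$node[network$roots$kind == k][1]
      streams <- dplyr::bind_rows(streams,
        tibble(node = root, type = "inlet", col = NA_integer_, F = Q_in,
               Tfix = boundary$T_inlet))
    } else {
      lv <- term[term$kind == "VEIN" & term_q != 0, ]
      qlv <- term_q[term$kind == "VEIN" & term_q != 0]
      if (nrow(lv) > 0) {
        streams <- dplyr::bind_rows(streams,
          tibble(node = lv$node, type = "capillary", col = row3(lv$vox),
                 F = qlv, Tfix = NA_real_))
      }
    }
    streams <- streams[streams$F > 0, , drop = FALSE]
    tot_in <- tapply(streams$F, streams$node, sum)
    # each flowing segment draws from its upstream node's mixture
    draw <- tibble(row = rowseg[ks[live]], node = upn[live], F = Fa[live])
    add(draw$row, draw$row, rcb * draw$F)
    jn <- dplyr::inner_join(draw, streams, by = "node",
                            suffix = c("", "_in"), relationship = "many-to-many")
    if (nrow(jn) > 0) {
      w <- jn$F_in / as.numeric(tot_in[as.character(jn$node)])
      cseg <- jn$type != "inlet"
      add(jn$row[cseg], jn$col[cseg], -rcb * jn$F[cseg] * w[cseg])
      fixed <- !cseg
      if (any(fixed)) {
        bb <- rcb * jn$F[fixed] * w[fixed] * jn$Tfix[fixed]
        b[jn$row[fixed]] <- b[jn$row[fixed]] + bb
      }
    }
  }

  # --- vessel conduction along the tree ---------------------------------
  L <- segment_lengths(network)
  Across <- pi * seg$radius^2
  half <- ifelse(L > 0 & Across > 0, props$K_b * Across / (L / 2), 0)
  for (k in c("ARTERY", "VEIN")) {
    ks <- which(seg$kind == k)
    inc <- tibble(node = c(seg$node_a[ks], seg$node_b[ks]),
                  s = c(ks, ks), half = c(half[ks], half[ks]))
    jn <- dplyr::inner_join(inc, inc, by = "node",
                            relationship = "many-to-many")
    jn <- jn[jn$s.x < jn$s.y, , drop = FALSE]
    if (nrow(jn) > 0) {
      cc <- hmean(jn$half.x, jn$half.y) / 2    # series of the two halves
      couple_sym(rowseg[jn$s.x], rowseg[jn$s.y], cc)
    }
  }

  # --- wall exchange (beta) ---------------------------------------------
  e <- coeffs$entries
  er <- rowseg[match(e$seg_id, seg$id)]
  couple_sym(er, row2(e$vox), e$beta_tissue)
  couple_sym(er, row3(e$vox), e$beta_capillary)
  b23 <- coeffs$beta23$beta * (1 + as.numeric(double_beta23))
  couple_sym(row2(coeffs$beta23$vox), row3(coeffs$beta23$vox), b23)

  # --- skin boundary: Robin + imposed heating ---------------------------
  A_f <- attr(mask, "face_area")
  mvox <- mask$ix + d[1] * (mask$iy - 1L) + d[1] * d[2] * (mask$iz - 1L)
  if (skin_exposure == "weighted") {
    w2f <- eps2[mvox]; w3f <- eps3[mvox]
  } else {
    w2f <- rep(1, length(mvox)); w3f <- rep(0, length(mvox))
  }
  qh <- ifelse(mask$heating, boundary$q_heat, 0)
  covered <- if ("covered" %in% names(mask)) mask$covered else rep(FALSE, nrow(mask))
  rob2 <- boundary$h_env * A_f * w2f * !covered  # no ambient exchange under the pad
  rob3 <- boundary$h_env * A_f * w3f * !covered
  add(row2(mvox), row2(mvox), rob2)
  add(row3(mvox), row3(mvox), rob3)
  b[row2(mvox)] <- b[row2(mvox)] + rob2 * boundary$T_inf + qh * A_f * w2f
  b[row3(mvox)] <- b[row3(mvox)] + rob3 * boundary$T_inf + qh * A_f * w3f

  # --- metabolic heat ----------------------------------------------------
  b[o2 + seq_len(n2)] <- b[o2 + seq_len(n2)] + props$Q_gen * V

  A <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                            dims = c(ntot, ntot))
  # fully occluded (zero-radius, zero-area) segments exchange nothing and
  # would be unconstrained; slave them to the tissue of a voxel they pass
  dg0 <- which(Matrix::diag(A) == 0)
  if (length(dg0) > 0) {
    srow <- match(dg0, rowseg)
    anchor <- vapply(seq_along(dg0), function(q) {
      s <- srow[q]
      if (is.na(s)) abort("unconstrained non-segment unknown in energy system")
      vx <- map$entries$vox[map$entries$seg_id == seg$id[s]][1]
      if (is.na(vx)) NA_integer_ else as.integer(row2(vx))
    }, integer(1))
    A[cbind(dg0, dg0)] <- 1
    ok <- !is.na(anchor)
    if (any(ok)) A[cbind(dg0[ok], anchor[ok])] <- -1
    b[dg0[!ok]] <- boundary$T_inf
  }
  if (inlet_mode == "dirichlet") {
    roots <- network$roots$node[network$roots$kind == "ARTERY"]
    rs <- rowseg[art][seg$node_a[art] %in% roots | seg$node_b[art] %in% roots]
    diag_scale <- mean(abs(Matrix::diag(A)[rs]))
    if (diag_scale == 0) diag_scale <- 1
    A[rs, ] <- 0
    A[cbind(rs, rs)] <- diag_scale
    b[rs] <- diag_scale * boundary$T_inlet
  }
  # vein root exit streams for the energy audit
  vroot <- network$roots$node[network$roots$kind == "VEIN"][1]
  vF <- segflow[ven]
  vdn <- ifelse(vF >= 0, seg$node_b[ven], seg$node_a[ven])
  exit <- vdn == vroot & abs(vF) > 0
  structure(list(
    A = A, b = b,
    index = list(o1 = o1, o2 = o2, o3 = o3, o4 = o4, n1 = n1, n2 = n2,
                 n4 = n4, art = art, ven = ven, tis = tis, rowseg = rowseg,
                 shape = d),
    meta = list(
      boundary = boundary, props = props, grid_voxel = h,
      mask = mask, mask_vox = mvox, rob2 = rob2, rob3 = rob3,
      w2f = w2f, w3f = w3f,
      heat_in = sum(qh * A_f), metab_in = props$Q_gen * V * n2,
      segment_ids = seg$id,
      Q_in = Q_in, rcb = rcb,
      exit_rows = rowseg[ven][exit], exit_F = abs(vF)[exit],
      inlet_mode = inlet_mode)),
    class = "energy_system")
}

# flows arriving at / leaving the root of a kind (positive values)
inlet_flows_of <- function(network, nf, kind) {
  root <- network$roots$node[network$roots$kind == kind][1]
  seg <- network$segments
  i <- which(seg$kind == kind & (seg$node_a == root | seg$node_b == root))
  f <- nf$segments$flow[match(seg$id[i], nf$segments$id)]
  ifelse(seg$node_a[i] == root, f, -f)  # positive = out of the root node
}

check_node_balance <- function(network, nf) {
  seg <- network$segments
  f <- nf$segments$flow[match(seg$id, nf$segments$id)]
  te <- nf$terminal_exchange
  for (k in unique(seg$kind)) {
    ks <- which(seg$kind == k)
    nodes_k <- sort(unique(c(seg$node_a[ks], seg$node_b[ks])))
    net <- numeric(length(nodes_k))
    ia <- match(seg$node_a[ks], nodes_k); ib <- match(seg$node_b[ks], nodes_k)
    net <- net - tapply2(f[ks], ia, length(nodes_k)) +
      tapply2(f[ks], ib, length(nodes_k))
    root <- network$roots$node[network$roots$kind == k][1]
    ri <- match(root, nodes_k)
    inflow <- sum(inlet_flows_of(network, nf, k))
    net[ri] <- net[ri] + inflow  # re-add: root exchanges with outside
    tk <- te[te$kind == k, , drop = FALSE]
    if (nrow(tk) > 0) {
      sgn <- if (k == "ARTERY") -1 else 1
      net[match(tk$node, nodes_k)] <- net[match(tk$node, nodes_k)] + sgn * tk$q
    }
    net[ri] <- 0  # the root's own balance is the global one, checked elsewhere
    scale <- max(abs(f[ks]), 1e-300)
    if (max(abs(net)) > 1e-8 * scale) {
      abort(sprintf("%s flows violate node balance (max residual %.3e m^3/s)",
                    k, max(abs(net))))
    }
  }
  invisible(TRUE)
}

tapply2 <- function(x, g, n) {
  out <- numeric(n)
  s <- tapply(x, g, sum)
  out[as.integer(names(s))] <- s
  out
}
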