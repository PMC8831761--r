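# Cell-centred finite-volume Darcy solve on the tissue voxels.

# 6-neighbourhood of tissue voxels: returns a tibble of unique adjacent
# tissue-voxel pairs (linear indices) with the face axis.
tissue_face_pairs <- function(grid) {
  d <- grid$shape
  tis <- grid$labels != LABEL_OUTSIDE
  lin <- array(seq_len(prod(d)), d)
  sub <- function(dr) {
    switch(dr,
           x = list(A = lin[-d[1], , , drop = FALSE], B = lin[-1, , , drop = FALSE]),
           y = list(A = lin[, -d[2], , drop = FALSE], B = lin[, -1, , drop = FALSE]),
           z = list(A = lin[, , -d[3], drop = FALSE], B = lin[, , -1, drop = FALSE]))
  }
  out <- list()
  for (ax in c("x", "y", "z")) {
    s <- sub(ax)
    ii <- as.vector(s$A); jj <- as.vector(s$B)
    ok <- tis[ii] & tis[jj]
    out[[ax]] <- tibble(i = ii[ok], j = jj[ok], axis = ax)
  }
  dplyr::bind_rows(out)
}

#' Solve Darcy flow in the capillary porous phase
#'
#' Cell-centred finite-volume solve of steady Darcy flow on the tissue
#' voxels: face fluxes `q = T_f (P_i - P_j)` with transmissibility
#' `T_f = (K/mu) A / h` (harmonic mean of `K/mu` across the face), source
#' `Q_a` and sink `Q_v` per voxel, no-flux on every exterior face (the skin
#' condition extends to all boundaries at steady state), and the pressure
#' gauge pinned at one cell per connected tissue component. Requires
#' `sum(Q_a) = sum(Q_v)` per component (steady compatibility for a pure
#' Neumann problem).
#'
#' @param grid a [voxel_grid()].
#' @param Q_a,Q_v per-voxel volumetric source/sink (m^3/s): full arrays /
#'   vectors over all voxels, or tibbles with columns `vox, Q`.
#' @param props a [tissue_properties()].
#' @return object of class `porous_flow_solution`: `pressure` (3-d array, NA
#'   outside tissue), `faces` (tibble `i, j, axis, q, v_darcy`; `q` > 0 flows
#'   from voxel `i` to voxel `j`), `Q_a`, `Q_v` (vectors over all voxels) and
#'   `M13`, `M34` mass-exchange rates (kg/s, `rho_b * Q`).
#' @export
solve_darcy <- function(grid, Q_a, Q_v, props) {
  d <- grid$shape
  nvox <- prod(d)
  to_vec <- function(Q) {
    if (is.data.frame(Q)) {
      v <- numeric(nvox)
      v[Q$vox] <- Q$Q
      v
    } else {
      stopifnot(length(Q) == nvox)
      as.numeric(Q)
    }
  }
  Qa <- to_vec(Q_a); Qv <- to_vec(Q_v)
  tis <- which(grid$labels != LABEL_OUTSIDE)
  if (length(tis) < nvox && (any(Qa[-tis] != 0) || any(Qv[-tis] != 0))) {
    abort("sources prescribed outside tissue")
  }
  src <- Qa - Qv
  scale <- max(abs(Qa), abs(Qv))
  h <- grid$voxel_size
  pairs <- tissue_face_pairs(grid)
  km <- props$K_perm / props$mu
  Tf <- km * h^2 / h  # uniform permeability: harmonic mean = K/mu
  ridx <- integer(nvox); ridx[tis] <- seq_along(tis)
  nt <- length(tis)
  comp <- graph_components(nt, ridx[pairs$i], ridx[pairs$j])
  csum <- tapply(src[tis], comp, sum)
  tol <- if (scale > 0) 1e-10 * scale else 1e-30
  if (any(abs(csum) > tol)) {
    abort(sprintf(
      "unbalanced sources: sum(Q_a) - sum(Q_v) = %.3e m^3/s in a closed region (singular Neumann problem)",
      csum[which.max(abs(csum))]))
  }
  p_t <- numeric(nt)
  if (scale > 0) {
    ia <- ridx[pairs$i]; ja <- ridx[pairs$j]
    A <- Matrix::sparseMatrix(
      i = c(ia, ja, ia, ja), j = c(ja, ia, ia, ja),
      x = c(rep(-Tf, 2 * nrow(pairs)), rep(Tf, 2 * nrow(pairs))),
      dims = c(nt, nt))
    pinned <- vapply(unique(comp), function(cmp) which(comp == cmp)[1], integer(1))
    keep <- setdiff(seq_len(nt), pinned)
    if (length(keep) > 0) {
      As <- methods::as(A[keep, keep, drop = FALSE], "symmetricMatrix")
      p_t[keep] <- as.numeric(Matrix::solve(As, src[tis][keep]))
      resid <- max(abs(A %*% p_t - src[tis])) / max(scale, 1e-300)
      if (resid > 1e-9) abort(sprintf("Darcy solve residual too large: %.3e", resid))
    }
  }
  pressure <- array(NA_real_, d)
  pressure[tis] <- p_t
  q_face <- Tf * (p_t[ridx[pairs$i]] - p_t[ridx[pairs$j]])
  faces <- tibble(i = pairs$i, j = pairs$j, axis = pairs$axis,
                  q = q_face, v_darcy = q_face / h^2)
  structure(list(pressure = pressure, faces = faces, Q_a = Qa, Q_v = Qv,
                 M13 = props$rho_b * Qa, M34 = props$rho_b * Qv,
                 epsilon3 = grid$epsilon3, shape = d),
            class = "porous_flow_solution")
}
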