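#' Solve the assembled energy system
#'
#' Direct or ILU-preconditioned iterative sparse solve of the four-domain
#' energy balance, with the residual certified against the load, the fields
#' unpacked per domain, skin-face temperatures extracted, and a global
#' energy audit (metabolism + imposed heating + arterial advective inflow
#' enthalpy vs. surface Robin loss + venous advective outflow enthalpy).
#'
#' @param system an [assemble_energy_system()] result.
#' @param method passed to the sparse solver (`"auto"` picks direct for
#'   small systems, ILU(0)-BiCGSTAB for large).
#' @return object of class `temperature_solution`:
#'   * `T1`, `T4`: tibbles `id, temperature` per artery/vein segment,
#'   * `T2`, `T3`: 3-d arrays (`NA` outside tissue),
#'   * `skin`: tibble `ix, iy, iz, cx, cy, cz, heating, temperature`,
#'   * `center_point`: skin temperature at the face closest to the exposed
#'     surface centre (inside the heating annulus when one is defined),
#'   * `energy`: tibble of energy-audit terms (W) with the relative
#'     imbalance in `attr(, "relative_imbalance")`,
#'   * `residual`: relative linear-solve residual.
#' @export
solve_temperature <- function(system, method = "auto") {
  A <- system$A; b <- system$b
  x <- tryCatch(
    solve_sparse_system(A, b, method = method,
                        offset = system$meta$boundary$T_inf),
    error = function(e) {
      abort(sprintf("temperature solve failed (%s); the system may be singular: check that every domain is anchored by flow, exchange or a boundary condition", conditionMessage(e)))
    })
  resid <- attr(x, "residual") %||% (max(abs(A %*% x - b)) / max(abs(b)))
  ix <- system$index
  meta <- system$meta
  seg_T <- numeric(length(ix$rowseg))
  seg_T[ix$rowseg > 0] <- x[ix$rowseg[ix$rowseg > 0]]
  d <- ix$shape
  T2 <- array(NA_real_, d); T2[ix$tis] <- x[ix$o2 + seq_len(ix$n2)]
  T3 <- array(NA_real_, d); T3[ix$tis] <- x[ix$o3 + seq_len(ix$n2)]
  mask <- meta$mask
  wsum <- meta$w2f + meta$w3f
  Tskin <- (meta$w2f * T2[meta$mask_vox] + meta$w3f * T3[meta$mask_vox]) / wsum
  skin <- tibble(ix = mask$ix, iy = mask$iy, iz = mask$iz,
                 cx = mask$cx, cy = mask$cy, cz = mask$cz,
                 heating = mask$heating, temperature = Tskin)
  ann <- attr(mask, "annulus")
  centre <- if (!is.null(ann)) ann$centre else c(mean(skin$cx), mean(skin$cy))
  cp <- which.min((skin$cx - centre[1])^2 + (skin$cy - centre[2])^2)
  # energy audit (temperatures in deg C; mass balance makes the offset safe)
  robin_loss <- sum(meta$rob2 * (T2[meta$mask_vox] - meta$boundary$T_inf)) +
    sum(meta$rob3 * (T3[meta$mask_vox] - meta$boundary$T_inf))
  inflow_enth <- meta$rcb * meta$Q_in * meta$boundary$T_inlet
  outflow_enth <- if (length(meta$exit_rows) > 0) {
    sum(meta$rcb * meta$exit_F * x[meta$exit_rows])
  } else 0
  energy <- tibble(
    term = c("metabolism", "imposed_heating", "arterial_inflow",
             "robin_loss", "venous_outflow"),
    watts = c(meta$metab_in, meta$heat_in, inflow_enth,
              robin_loss, outflow_enth))
  total_in <- meta$metab_in + meta$heat_in + inflow_enth
  imbalance <- abs(total_in - robin_loss - outflow_enth) /
    max(abs(total_in), 1e-300)
  attr(energy, "relative_imbalance") <- imbalance
  ids <- meta$segment_ids %||% seq_along(ix$rowseg)
  structure(list(
    T1 = tibble(id = ids[ix$art], temperature = seg_T[ix$art]),
    T2 = T2, T3 = T3,
    T4 = tibble(id = ids[ix$ven], temperature = seg_T[ix$ven]),
    skin = skin, center_point = skin$temperature[cp],
    energy = energy, residual = resid),
    class = "temperature_solution")
}

#' @export
print.temperature_solution <- function(x, ...) {
  rng <- range(x$skin$temperature)
  cat(sprintf("<temperature_solution> skin %.2f-%.2f degC, centre %.2f degC, energy imbalance %.2e\n",
              rng[1], rng[2], x$center_point,
              attr(x$energy, "relative_imbalance")))
  invisible(x)
}

#' Root-mean-square difference between two skin-temperature fields
#'
#' Compares two skin-temperature fields over the same surface mask and
#' returns the root-mean-square difference in deg C — the surface-error
#' summary used to monitor convergence of the vessel-growth iterations.
#'
#' @param field_a,field_b skin tibbles from [solve_temperature()] (or any
#'   data frames with `ix, iy, iz, axis?/temperature` columns over the same
#'   faces), or `temperature_solution` objects.
#' @return RMS difference in deg C.
#' @export
surface_mse <- function(field_a, field_b) {
  get_skin <- function(f) if (inherits(f, "temperature_solution")) f$skin else f
  a <- get_skin(field_a); b_ <- get_skin(field_b)
  if (nrow(a) != nrow(b_) ||
      !all(a$ix == b_$ix & a$iy == b_$iy & a$iz == b_$iz)) {
    abort("skin fields are defined on different surface masks")
  }
  sqrt(mean((a$temperature - b_$temperature)^2))
}
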