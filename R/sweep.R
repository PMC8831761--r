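# Forward sweeps over (inlet flow x ambient temperature) and the fitted
# response surfaces used for inversion.

#' Forward sweep of centre-point skin temperature
#'
#' Runs one steady coupled flow + heat solve per combination of inlet flow,
#' ambient temperature and heating state, and records the centre-point skin
#' temperature (the sensor location inside the heating annulus). This is the
#' forward table from which the response surfaces are fitted.
#'
#' @param phantom a `list(grid, mask)` as returned by
#'   [build_cubic_phantom()].
#' @param network a grown [vessel_network()] with radii (fixed seed, so the
#'   sweep is reproducible).
#' @param Q_values inlet flows in ml/s (>= 0).
#' @param T_amb_values ambient temperatures (deg C).
#' @param heating `"both"`, `"on"` or `"off"`.
#' @param props a [tissue_properties()].
#' @param q_heat heater flux in the on state (W/m^2).
#' @param T_inlet arterial inlet temperature (deg C).
#' @param ... further arguments passed to [compute_exchange_coefficients()].
#' @return a tibble of class `sweep_table` with columns
#'   `Q_ml_s, T_amb_C, heating, T_center_C`.
#' @export
sweep_forward <- function(phantom, network,
                          Q_values = c(0, 5e-4, 7.5e-4, 0.001, 0.00125, 0.0015,
                                       0.00175, 0.002, 0.0025, 0.003, 0.004,
                                       0.005, 0.006, 0.008, 0.01),
                          T_amb_values = c(20, 22, 24),
                          heating = c("both", "on", "off"),
                          props = tissue_properties(), q_heat = 150,
                          T_inlet = 37, ...) {
  heating <- match.arg(heating)
  if (any(Q_values < 0)) abort("inlet flows must be non-negative")
  states <- switch(heating, both = c("off", "on"), on = "on", off = "off")
  map <- voxelize_segments(network, phantom$grid)
  co <- compute_exchange_coefficients(map, network, phantom$grid, props, ...)
  rows <- list()
  k <- 0
  for (Q in Q_values) {
    cp <- couple_network_porous(network, phantom$grid, map,
                                inlet_flow = Q * 1e-6, props = props)
    for (st in states) {
      for (Ta in T_amb_values) {
        bd <- thermal_boundary(T_inf = Ta, T_inlet = T_inlet,
                               q_heat = if (st == "on") q_heat else 0)
        sys <- assemble_energy_system(phantom$grid, network, cp, co, bd,
                                      props, phantom$mask)
        sol <- solve_temperature(sys)
        k <- k + 1
        rows[[k]] <- tibble(Q_ml_s = Q, T_amb_C = Ta, heating = st,
                            T_center_C = sol$center_point)
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("sweep_table", class(out))
  out
}

#' Fit a response surface to a forward sweep
#'
#' Fits the map from (inlet flow, ambient temperature) to centre-point skin
#' temperature for one heating state. Two fit families are available:
#'
#' * `"spline"` (default): a shape-preserving monotone cubic spline in flow
#'   at each swept ambient level, blended linearly across ambient
#'   temperature. This captures the steep low-flow gradient of the heated
#'   state without oscillation and interpolates the sweep exactly.
#' * `"poly"`: least-squares polynomial, `q_order` in flow plus `t_order` in
#'   ambient temperature.
#'
#' The fit is certified on a dense grid inside the swept domain: the
#' off-state surface must increase with flow and with ambient temperature,
#' the on-state surface must decrease with flow, and the fit residual RMS
#' must not exceed `max_residual` — otherwise the fit is rejected with
#' advice to densify the sweep or change the fit family/order.
#'
#' @param table a [sweep_forward()] result (single heating state, or pass
#'   `state` to select one).
#' @param state `"on"` or `"off"`; required when `table` holds both.
#' @param method fit family, see above.
#' @param q_order,t_order polynomial orders for `method = "poly"`.
#' @param max_residual maximum admissible residual RMS (deg C).
#' @return object of class `response_surface` with a [predict()] method
#'   taking `Q_ml_s` and `T_amb_C`.
#' @export
fit_response_surface <- function(table, state = NULL,
                                 method = c("spline", "poly"),
                                 q_order = 3, t_order = 1,
                                 max_residual = 0.05) {
  method <- match.arg(method)
  states <- unique(table$heating)
  if (is.null(state)) {
    if (length(states) > 1) abort("table holds both heating states; pass `state`")
    state <- states
  }
  tab <- table[table$heating == state, , drop = FALSE]
  Qs <- sort(unique(tab$Q_ml_s)); Tas <- sort(unique(tab$T_amb_C))
  if (length(Qs) < 4 || length(Tas) < 3) {
    abort("sweep must cover at least 4 flow values and 3 ambient temperatures")
  }
  if (method == "spline") {
    # one monotone spline per ambient level
    splines <- lapply(Tas, function(Ta) {
      d <- tab[tab$T_amb_C == Ta, ]
      d <- d[order(d$Q_ml_s), ]
      if (any(duplicated(d$Q_ml_s))) abort("duplicate sweep points")
      stats::splinefun(d$Q_ml_s, d$T_center_C, method = "hyman")
    })
    fun <- function(Q, Ta) {
      vals <- vapply(splines, function(f) f(Q), numeric(length(Q)))
      if (is.null(dim(vals))) vals <- matrix(vals, nrow = 1)
      if (length(Tas) == 1) return(vals[, 1])
      ai <- findInterval(Ta, Tas, rightmost.closed = TRUE, all.inside = TRUE)
      w <- (Ta - Tas[ai]) / (Tas[ai + 1] - Tas[ai])
      vals[cbind(seq_len(nrow(vals)), ai)] * (1 - w) +
        vals[cbind(seq_len(nrow(vals)), ai + 1)] * w
    }
    fitted_at <- fun(tab$Q_ml_s, tab$T_amb_C)
  } else {
    fml <- stats::as.formula(sprintf(
      "T_center_C ~ poly(Q_ml_s, %d, raw = TRUE) + poly(T_amb_C, %d, raw = TRUE)",
      q_order, t_order))
    fit <- lm(fml, data = tab)
    fun <- function(Q, Ta) {
      as.numeric(predict(fit, newdata = data.frame(Q_ml_s = Q, T_amb_C = Ta)))
    }
    fitted_at <- fun(tab$Q_ml_s, tab$T_amb_C)
  }
  residual_rms <- sqrt(mean((fitted_at - tab$T_center_C)^2))
  if (residual_rms > max_residual) {
    abort(sprintf(
      "surface fit residual RMS %.3f degC exceeds %.3f: densify the sweep or change the fit (method/order)",
      residual_rms, max_residual))
  }
  # monotonicity certificate on a dense grid
  Qg <- seq(min(Qs), max(Qs), length.out = 201)
  for (Ta in unique(c(Tas, (Tas[-1] + Tas[-length(Tas)]) / 2))) {
    v <- fun(Qg, rep(Ta, length(Qg)))
    dv <- diff(v)
    if (state == "off" && any(dv <= 0)) {
      abort("off-state surface is not strictly increasing in flow: refit with a denser sweep")
    }
    if (state == "on" && any(dv >= 0)) {
      abort("on-state surface is not strictly decreasing in flow: refit with a denser sweep")
    }
  }
  if (state == "off") {
    for (Q in Qg[seq(1, length(Qg), by = 20)]) {
      v <- fun(rep(Q, 41), seq(min(Tas), max(Tas), length.out = 41))
      if (any(diff(v) < 0)) {
        abort("off-state surface is not increasing in ambient temperature")
      }
    }
  }
  structure(list(state = state, method = method, fun = fun,
                 residual_rms = residual_rms,
                 domain = list(Q = range(Qs), T_amb = range(Tas)),
                 table = tab),
            class = "response_surface")
}

#' @export
predict.response_surface <- function(object, Q_ml_s, T_amb_C, ...) {
  Q <- pmin(object$domain$Q[2], pmax(object$domain$Q[1], Q_ml_s))
  Ta <- pmin(object$domain$T_amb[2], pmax(object$domain$T_amb[1], T_amb_C))
  object$fun(Q, Ta)
}

#' @export
print.response_surface <- function(x, ...) {
  cat(sprintf("<response_surface> heating %s, %s fit, residual RMS %.4f degC, Q in [%g, %g] ml/s, T_amb in [%g, %g] degC\n",
              x$state, x$method, x$residual_rms, x$domain$Q[1], x$domain$Q[2],
              x$domain$T_amb[1], x$domain$T_amb[2]))
  invisible(x)
}
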