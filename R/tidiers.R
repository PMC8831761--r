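# broom-style tidiers and ggplot2 autoplot methods for the result objects.

#' Tidy a perfusion estimate
#'
#' @param x a `perfusion_estimate` from [invert_blood_flow()].
#' @param ... unused.
#' @return one row per protocol phase with the inverted flow.
#' @method tidy perfusion_estimate
#' @export
tidy.perfusion_estimate <- function(x, ...) {
  out <- x$phases
  out$subject <- x$subject_id
  out[, c("subject", "phase", "T_mean_C", "T_amb_C", "Q_ml_s", "extrapolated")]
}

#' @rdname tidy.perfusion_estimate
#' @method glance perfusion_estimate
#' @export
glance.perfusion_estimate <- function(x, ...) {
  g <- function(p) x$phases$Q_ml_s[match(p, x$phases$phase)]
  tibble(subject = x$subject_id, Q_rest_ml_s = g("resting"),
         Q_heat_ml_s = g("heating"), Q_rec_ml_s = g("recovery"),
         pattern = x$pattern,
         any_extrapolated = any(x$phases$extrapolated))
}

#' Tidy a fitted response surface
#'
#' @param x a [fit_response_surface()] result.
#' @param ... unused.
#' @return the sweep points with fitted values and residuals.
#' @method tidy response_surface
#' @export
tidy.response_surface <- function(x, ...) {
  out <- x$table
  out$fitted <- predict(x, out$Q_ml_s, out$T_amb_C)
  out$residual <- out$T_center_C - out$fitted
  out
}

#' @rdname tidy.response_surface
#' @method glance response_surface
#' @export
glance.response_surface <- function(x, ...) {
  tibble(state = x$state, method = x$method, residual_rms_C = x$residual_rms,
         Q_min_ml_s = x$domain$Q[1], Q_max_ml_s = x$domain$Q[2],
         T_amb_min_C = x$domain$T_amb[1], T_amb_max_C = x$domain$T_amb[2])
}

#' Tidy a temperature solution
#'
#' @param x a [solve_temperature()] result.
#' @param ... unused.
#' @return the exposed-face skin temperatures as a tibble.
#' @method tidy temperature_solution
#' @export
tidy.temperature_solution <- function(x, ...) x$skin

#' @rdname tidy.temperature_solution
#' @method glance temperature_solution
#' @export
glance.temperature_solution <- function(x, ...) {
  tibble(centre_C = x$center_point,
         skin_min_C = min(x$skin$temperature),
         skin_max_C = max(x$skin$temperature),
         energy_rel_imbalance = attr(x$energy, "relative_imbalance"),
         solve_residual = x$residual)
}

#' Tidy a coupled flow solution
#'
#' @param x a [couple_network_porous()] result.
#' @param ... unused.
#' @return the per-segment flow table.
#' @method tidy coupled_flow
#' @export
tidy.coupled_flow <- function(x, ...) x$network_flow$segments

#' @rdname tidy.coupled_flow
#' @method glance coupled_flow
#' @export
glance.coupled_flow <- function(x, ...) {
  v <- setNames(x$balance$value, x$balance$quantity)
  tibble(inlet_ml_s = x$inlet_flow * 1e6,
         policy = x$perfusion_policy,
         chain_max_rel_dev = max(abs(v - v[["root_inflow"]])) /
           max(v[["root_inflow"]], 1e-300))
}

#' Plot a temperature trace
#'
#' Line plot of the sensor temperature over the protocol, with the heating
#' phase shaded.
#'
#' @param object a [temperature_trace()].
#' @param protocol a [spas_protocol()] for phase shading.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot temperature_trace
#' @export
autoplot.temperature_trace <- function(object, protocol = spas_protocol(), ...) {
  ph <- protocol$phases
  heat <- ph[ph$q_heat_W_m2 > 0, ]
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$time_s, y = .data$temp_C))
  if (nrow(heat) > 0) {
    p <- p + ggplot2::annotate("rect", xmin = heat$start_s, xmax = heat$end_s,
                               ymin = -Inf, ymax = Inf, alpha = 0.12,
                               fill = "red")
  }
  p + ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "sensor temperature (°C)")
}

#' Plot a response surface
#'
#' Centre-point temperature against inlet flow, one curve per swept ambient
#' temperature, with the sweep points overlaid.
#'
#' @param object a [fit_response_surface()] result.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot response_surface
#' @export
autoplot.response_surface <- function(object, ...) {
  Tas <- sort(unique(object$table$T_amb_C))
  Qg <- seq(object$domain$Q[1], object$domain$Q[2], length.out = 101)
  curves <- purrr::map_dfr(Tas, function(Ta) {
    tibble(Q_ml_s = Qg, T_amb_C = Ta,
           T_center_C = predict(object, Qg, rep(Ta, length(Qg))))
  })
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$Q_ml_s, y = .data$T_center_C,
                                       colour = factor(.data$T_amb_C))) +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = object$table) +
    ggplot2::labs(x = "inlet blood flow (ml/s)",
                  y = "centre-point skin temperature (°C)",
                  colour = "ambient (°C)",
                  title = sprintf("heating %s", object$state))
}

#' Plot the skin temperature field
#'
#' Raster of the exposed-surface temperature (top view).
#'
#' @param object a [solve_temperature()] result.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot temperature_solution
#' @export
autoplot.temperature_solution <- function(object, ...) {
  ggplot2::ggplot(object$skin,
                  ggplot2::aes(x = .data$cx * 1e3, y = .data$cy * 1e3,
                               fill = .data$temperature)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(option = "inferno") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)", fill = "T (°C)")
}

#' Plot a vessel network (top view)
#'
#' 2-D projection of the artery (red) and vein (blue) trees with line width
#' proportional to radius.
#'
#' @param object a [vessel_network()].
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot vessel_network
#' @export
autoplot.vessel_network <- function(object, ...) {
  seg <- object$segments
  n <- object$nodes
  df <- tibble(
    x = n$x[match(seg$node_a, n$id)] * 1e3,
    y = n$y[match(seg$node_a, n$id)] * 1e3,
    xend = n$x[match(seg$node_b, n$id)] * 1e3,
    yend = n$y[match(seg$node_b, n$id)] * 1e3,
    kind = seg$kind, radius = seg$radius)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   xend = .data$xend, yend = .data$yend,
                                   colour = .data$kind,
                                   linewidth = .data$radius)) +
    ggplot2::geom_segment(lineend = "round") +
    ggplot2::scale_colour_manual(values = c(ARTERY = "#c0392b", VEIN = "#2e5aac")) +
    ggplot2::scale_linewidth(range = c(0.1, 1.5), guide = "none") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)", colour = NULL)
}
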