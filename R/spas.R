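# The three-phase skin-heating protocol and temperature traces.

#' Three-phase measurement protocol
#'
#' The rest/heat/recover protocol of the skin perfusion assessment: 750 s at
#' rest (no heating), 1000 s with the annular heater at 150 W/m^2, and
#' 1000 s of recovery after power-off — 2750 s in total.
#'
#' @param phases tibble with columns `name, duration_s, q_heat_W_m2`.
#' @return object of class `spas_protocol`.
#' @export
spas_protocol <- function(phases = tibble(
                            name = c("resting", "heating", "recovery"),
                            duration_s = c(750, 1000, 1000),
                            q_heat_W_m2 = c(0, 150, 0))) {
  phases <- as_tibble(phases)
  stopifnot(all(c("name", "duration_s", "q_heat_W_m2") %in% names(phases)))
  if (any(phases$duration_s <= 0)) abort("phase durations must be positive")
  phases$end_s <- cumsum(phases$duration_s)
  phases$start_s <- phases$end_s - phases$duration_s
  structure(list(phases = phases, total_s = sum(phases$duration_s)),
            class = "spas_protocol")
}

#' Temperature trace container
#'
#' A measured (or synthesised) sensor trace over the protocol: sample times,
#' sensor temperature and ambient temperature.
#'
#' @param time_s strictly increasing sample times (s).
#' @param temp_C sensor temperature (deg C).
#' @param ambient_C ambient temperature: scalar or per-sample.
#' @param subject_id optional label.
#' @return a tibble of class `temperature_trace` with columns
#'   `time_s, temp_C, ambient_C`.
#' @export
temperature_trace <- function(time_s, temp_C, ambient_C, subject_id = NA_character_) {
  if (any(diff(time_s) <= 0)) abort("trace times must be strictly increasing")
  if (length(ambient_C) == 1) ambient_C <- rep(ambient_C, length(time_s))
  stopifnot(length(temp_C) == length(time_s), length(ambient_C) == length(time_s))
  out <- tibble(time_s = time_s, temp_C = temp_C, ambient_C = ambient_C)
  attr(out, "subject_id") <- subject_id
  class(out) <- c("temperature_trace", class(out))
  out
}

#' Read / write a temperature trace CSV
#'
#' The CSV dialect has a required header `time_s,temp_C,ambient_C`.
#'
#' @param path CSV file.
#' @param subject_id label attached to the trace (defaults to the file name).
#' @return a [temperature_trace()].
#' @export
read_trace_csv <- function(path, subject_id = basename(path)) {
  if (!file.exists(path)) abort(sprintf("trace file not found: %s", path))
  df <- utils::read.csv(path)
  need <- c("time_s", "temp_C", "ambient_C")
  if (!all(need %in% names(df))) {
    abort(sprintf("trace %s lacks required columns: %s", path,
                  paste(setdiff(need, names(df)), collapse = ", ")))
  }
  bad <- which(!stats::complete.cases(df[need]) |
                 !vapply(seq_len(nrow(df)),
                         function(i) all(is.finite(unlist(df[i, need]))), logical(1)))
  if (length(bad) > 0) {
    abort(sprintf("trace %s has invalid values at rows: %s", path,
                  paste(utils::head(bad, 10), collapse = ", ")))
  }
  nd <- which(diff(df$time_s) <= 0)
  if (length(nd) > 0) {
    abort(sprintf("trace %s times not strictly increasing at rows: %s", path,
                  paste(utils::head(nd + 1, 10), collapse = ", ")))
  }
  temperature_trace(df$time_s, df$temp_C, df$ambient_C, subject_id)
}

#' @rdname read_trace_csv
#' @param trace a [temperature_trace()].
#' @export
write_trace_csv <- function(trace, path) {
  utils::write.csv(as.data.frame(trace[, c("time_s", "temp_C", "ambient_C")]),
                   path, row.names = FALSE)
  invisible(path)
}

#' Synthesise a protocol temperature trace
#'
#' Generates a sensor trace from per-phase steady temperatures of the
#' forward model: within each phase the temperature relaxes exponentially
#' (first-order, time constant `relaxation_tau`) from the previous phase's
#' end value towards the phase's steady value, with optional Gaussian
#' measurement noise. The relaxation exists to make realistic-looking
#' fixtures; the inversion itself only ever uses the stabilised last part of
#' each phase.
#'
#' @param Q_per_phase named flows in ml/s: `c(resting =, heating =,
#'   recovery =)` (names must match the protocol phases).
#' @param T_amb ambient temperature (deg C).
#' @param surfaces list with `off` and `on` [fit_response_surface()] results
#'   (resting/recovery use `off`, heating uses `on`).
#' @param protocol a [spas_protocol()].
#' @param noise_sd Gaussian noise s.d. (deg C).
#' @param relaxation_tau relaxation time constant (s).
#' @param rng_seed integer seed (identical seeds give identical traces).
#' @param dt sample interval (s).
#' @param subject_id label.
#' @return a [temperature_trace()].
#' @export
synthesize_trace <- function(Q_per_phase, T_amb, surfaces,
                             protocol = spas_protocol(), noise_sd = 0,
                             relaxation_tau = 60, rng_seed = NULL, dt = 1,
                             subject_id = "synthetic") {
  ph <- protocol$phases
  if (!all(ph$name %in% names(Q_per_phase))) {
    abort("`Q_per_phase` must be named after every protocol phase")
  }
  if (any(Q_per_phase < 0)) abort("flows must be non-negative")
  steady <- vapply(seq_len(nrow(ph)), function(i) {
    surf <- if (ph$q_heat_W_m2[i] > 0) surfaces$on else surfaces$off
    predict(surf, Q_ml_s = Q_per_phase[[ph$name[i]]], T_amb_C = T_amb)
  }, numeric(1))
  with_seed(rng_seed, {
    tt <- seq(dt, protocol$total_s, by = dt)
    temp <- numeric(length(tt))
    prev <- steady[1]
    for (i in seq_len(nrow(ph))) {
      sel <- tt > ph$start_s[i] & tt <= ph$end_s[i]
      tloc <- tt[sel] - ph$start_s[i]
      decay <- if (relaxation_tau > 0) exp(-tloc / relaxation_tau) else 0
      temp[sel] <- steady[i] + (prev - steady[i]) * decay
      prev <- temp[max(which(sel))]
    }
    if (noise_sd > 0) temp <- temp + rnorm(length(temp), 0, noise_sd)
    temperature_trace(tt, temp, T_amb, subject_id)
  })
}
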