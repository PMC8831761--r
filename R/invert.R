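# Inversion of measured traces to per-phase inlet blood flow, and the
# pattern classification of the three-phase response.

#' Invert a temperature trace to per-phase blood flow
#'
#' For each protocol phase, averages the last 100 s of the sensor
#' temperature (the stabilised tail) and inverts it through the matching
#' response surface — the heater-off surface for the resting and recovery
#' phases, the heater-on surface for the heating phase — by monotone 1-D
#' root finding in flow at the trace's (per-phase mean) ambient temperature.
#' Temperatures outside the surface's range at that ambient are clipped to
#' the domain edge and flagged as extrapolated.
#'
#' @param trace a [temperature_trace()].
#' @param surfaces list with elements `off` and `on`
#'   ([fit_response_surface()] results).
#' @param protocol a [spas_protocol()].
#' @param tail_s averaging window at the end of each phase (s).
#' @return object of class `perfusion_estimate`: tibble `phases`
#'   (`phase, T_mean_C, T_amb_C, Q_ml_s, extrapolated`), the `pattern` class
#'   from [classify_pattern()], and the subject id.
#' @export
invert_blood_flow <- function(trace, surfaces, protocol = spas_protocol(),
                              tail_s = 100) {
  ph <- protocol$phases
  if (max(trace$time_s) < protocol$total_s - 1e-9) {
    abort(sprintf("trace ends at %.0f s but the protocol lasts %.0f s",
                  max(trace$time_s), protocol$total_s))
  }
  rows <- purrr::map_dfr(seq_len(nrow(ph)), function(i) {
    sel <- trace$time_s > ph$end_s[i] - tail_s & trace$time_s <= ph$end_s[i]
    if (!any(sel)) abort(sprintf("no samples in the last %.0f s of phase %s",
                                 tail_s, ph$name[i]))
    Tm <- mean(trace$temp_C[sel])
    Ta <- mean(trace$ambient_C[sel])
    surf <- if (ph$q_heat_W_m2[i] > 0) surfaces$on else surfaces$off
    inv <- invert_surface(surf, Tm, Ta)
    tibble(phase = ph$name[i], T_mean_C = Tm, T_amb_C = Ta,
           Q_ml_s = inv$Q, extrapolated = inv$extrapolated)
  })
  est <- structure(list(phases = rows, pattern = NA_character_,
                        subject_id = attr(trace, "subject_id") %||% NA_character_),
                   class = "perfusion_estimate")
  est$pattern <- classify_pattern(est)
  est
}

# monotone root find of surface(Q, Ta) = T over the swept flow domain
invert_surface <- function(surf, T_target, T_amb) {
  dom <- surf$domain$Q
  f <- function(Q) predict(surf, Q, T_amb) - T_target
  flo <- f(dom[1]); fhi <- f(dom[2])
  if (sign(flo) == sign(fhi)) {
    # target outside the attainable range: report the nearer edge, flagged
    edge <- if (abs(flo) < abs(fhi)) dom[1] else dom[2]
    return(list(Q = edge, extrapolated = TRUE))
  }
  r <- uniroot(f, interval = dom, tol = 1e-12 * max(dom[2], 1))
  list(Q = r$root, extrapolated = FALSE)
}

#' Classify the three-phase blood-flow pattern
#'
#' Applies the flow-regulation pattern rules to per-phase inlet flows:
#' * `HEALTHY_LIKE` — the recovery flow returns to the resting level (within
#'   `healthy_tol`, default 10% of the resting flow) and heating raised the
#'   flow above rest (normal vasodilation and prompt recovery);
#' * `DELAYED_EXCEEDING` — the recovery flow is at or above the heating
#'   flow (strongly delayed down-regulation);
#' * `DELAYED_PARTIAL` — anything else (recovery fell from the heating
#'   level but did not return to rest).
#'
#' @param estimate a `perfusion_estimate` (or any list with a `phases`
#'   tibble containing `phase` and `Q_ml_s`).
#' @param healthy_tol relative tolerance on the recovery-to-rest return.
#' @return a single string, one of the classes above, or `"UNDETERMINED"`
#'   when the resting flow is not positive.
#' @export
classify_pattern <- function(estimate, healthy_tol = 0.10) {
  phs <- estimate$phases
  get <- function(p) phs$Q_ml_s[match(p, phs$phase)]
  q_rest <- get("resting"); q_heat <- get("heating"); q_rec <- get("recovery")
  if (any(is.na(c(q_rest, q_heat, q_rec)))) {
    abort("estimate lacks one of the resting/heating/recovery phases")
  }
  if (q_rest <= 0) {
    warn("resting flow is not positive; pattern undetermined")
    return("UNDETERMINED")
  }
  if (abs(q_rec - q_rest) <= healthy_tol * q_rest && q_heat > q_rest) {
    return("HEALTHY_LIKE")
  }
  if (q_rec >= q_heat) return("DELAYED_EXCEEDING")
  "DELAYED_PARTIAL"
}

#' @export
print.perfusion_estimate <- function(x, ...) {
  cat(sprintf("<perfusion_estimate> subject %s: pattern %s\n",
              x$subject_id, x$pattern))
  print(x$phases)
  invisible(x)
}
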