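# High-level commands behind the command-line interface: each one is
# deterministic under a fixed configuration, writes its outputs plus a
# manifest (config hash, versions), and always emits its balance report.

write_manifest <- function(cfg, out_dir, stage, extra = list()) {
  man <- c(list(stage = stage, config_hash = rlang::hash(unclass(cfg)),
                package_version = as.character(utils::packageVersion("hemotherm")),
                r_version = as.character(getRversion()),
                timestamp = format(Sys.time(), tz = "UTC")), extra)
  jsonlite::write_json(man, file.path(out_dir, sprintf("%s_manifest.json", stage)),
                       auto_unbox = TRUE, digits = NA)
  invisible(man)
}

grow_from_config <- function(cfg, obj) {
  seed_net <- seed_cubic_network(obj$phantom$grid,
                                 depth_frac = cfg$vasculature$seed_depth_frac)
  net <- grow_rrt(obj$phantom$grid, seed_net,
                  iterations = cfg$vasculature$iterations,
                  rng_seed = cfg$seed)
  assign_radii(net, root_radius = cfg$vasculature$root_radius_m,
               murray_exponent = cfg$vasculature$murray_exponent)
}

#' Grow vessel trees from a configuration
#'
#' Builds the phantom, grows artery and vein trees from the default seed
#' structure, assigns radii, and writes the network (JSON, paired CSV, VTK
#' polylines), a growth log of segment counts at checkpoints, and a
#' manifest.
#'
#' @param config a [run_config()], YAML path, or list of overrides.
#' @param out_dir output directory (created if needed).
#' @return the grown [vessel_network()], invisibly.
#' @export
cmd_grow <- function(config = NULL, out_dir = ".") {
  cfg <- run_config(config)
  obj <- config_objects(cfg)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  net <- grow_from_config(cfg, obj)
  write_network_json(net, file.path(out_dir, "network.json"))
  write_network_csv(net, file.path(out_dir, "nodes.csv"),
                    file.path(out_dir, "segments.csv"))
  write_vtk_polylines(net, file.path(out_dir, "network.vtk"))
  log <- attr(net, "growth_log")
  utils::write.csv(log, file.path(out_dir, "growth_log.csv"), row.names = FALSE)
  write_manifest(cfg, out_dir, "grow",
                 list(segments = nrow(net$segments),
                      min_diameter_um = 2e6 * min(net$segments$radius)))
  message(sprintf("grow: %d segments, min diameter %.1f um",
                  nrow(net$segments), 2e6 * min(net$segments$radius)))
  invisible(net)
}

#' Run one coupled flow + temperature simulation
#'
#' Grows (or reads) the network, solves the coupled network/porous blood
#' flow and the four-domain steady energy balance, and writes the fields
#' (VTK structured grid and polylines), the skin temperatures (CSV), the
#' per-segment flow table (CSV), and a balance report carrying both the
#' mass-conservation chain and the global energy audit.
#'
#' @param config a [run_config()], YAML path, or list of overrides.
#' @param out_dir output directory.
#' @param network optional pre-grown [vessel_network()] (grown from config
#'   when `NULL`).
#' @param heating `"on"` or `"off"`.
#' @return list with `flows` (a `coupled_flow`) and `solution` (a
#'   `temperature_solution`), invisibly.
#' @export
cmd_simulate <- function(config = NULL, out_dir = ".", network = NULL,
                         heating = c("off", "on")) {
  heating <- match.arg(heating)
  cfg <- run_config(config)
  obj <- config_objects(cfg)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  net <- network %||% grow_from_config(cfg, obj)
  props <- obj$props
  th <- cfg$thermal
  cp <- couple_network_porous(net, obj$phantom$grid, NULL,
                              inlet_flow = cfg$flow$inlet_flow_ml_s * 1e-6,
                              props = props,
                              perfusion_policy = cfg$flow$perfusion_policy)
  co <- compute_exchange_coefficients(cp$map, net, obj$phantom$grid, props,
                                      Nu = th$Nu, wall_h_factor = th$wall_h_factor,
                                      capillary_diameter = th$capillary_diameter_m,
                                      wall_epsilon_split = th$wall_epsilon_split)
  bd <- thermal_boundary(h_env = th$h_env_W_m2K, T_inf = th$T_inf_C,
                         q_heat = if (heating == "on") th$q_heat_W_m2 else 0,
                         T_inlet = th$T_inlet_C)
  sys <- assemble_energy_system(obj$phantom$grid, net, cp, co, bd, props,
                                obj$phantom$mask,
                                inlet_mode = th$inlet_mode,
                                skin_exposure = th$skin_exposure,
                                double_beta23 = th$double_beta23)
  sol <- solve_temperature(sys)
  # outputs
  d <- obj$phantom$grid$shape
  write_vtk_grid(obj$phantom$grid, file.path(out_dir, "fields.vtk"),
                 cell_data = list(T2 = sol$T2, T3 = sol$T3,
                                  pressure = cp$porous_flow$pressure,
                                  Q_a = cp$porous_flow$Q_a,
                                  Q_v = cp$porous_flow$Q_v))
  segs <- cp$network_flow$segments
  segT <- dplyr::bind_rows(sol$T1, sol$T4)
  write_vtk_polylines(net, file.path(out_dir, "network.vtk"),
                      cell_data = list(flow = segs$flow[match(net$segments$id, segs$id)],
                                       temperature = segT$temperature[match(net$segments$id, segT$id)]))
  utils::write.csv(segs, file.path(out_dir, "segment_flows.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(sol$skin), file.path(out_dir, "skin_temperature.csv"),
                   row.names = FALSE)
  balance <- list(
    mass_chain = as.list(setNames(cp$balance$value, cp$balance$quantity)),
    mass_chain_max_rel_dev = max(abs(cp$balance$value - cp$balance$value[1])) /
      max(cp$balance$value[1], 1e-300),
    energy_terms_W = as.list(setNames(sol$energy$watts, sol$energy$term)),
    energy_rel_imbalance = attr(sol$energy, "relative_imbalance"),
    solve_residual = sol$residual)
  jsonlite::write_json(balance, file.path(out_dir, "balance_report.json"),
                       auto_unbox = TRUE, digits = NA)
  write_manifest(cfg, out_dir, "simulate",
                 list(heating = heating, centre_C = sol$center_point))
  message(sprintf("simulate[%s]: centre %.2f degC, energy imbalance %.1e",
                  heating, sol$center_point,
                  attr(sol$energy, "relative_imbalance")))
  invisible(list(flows = cp, solution = sol))
}

#' Sweep, fit, and invert traces
#'
#' Runs (or re-uses a cached) forward sweep over flow and ambient
#' temperature, fits the off- and on-state response surfaces, inverts each
#' supplied trace into per-phase blood flows, classifies the pattern, and
#' writes a JSON report plus a summary table.
#'
#' @param config a [run_config()], YAML path, or list of overrides.
#' @param traces character vector of trace CSV paths, or a list of
#'   [temperature_trace()] objects.
#' @param out_dir output directory.
#' @param network optional pre-grown network.
#' @return tibble summary (one row per trace), invisibly.
#' @export
cmd_sweep_invert <- function(config = NULL, traces = character(), out_dir = ".",
                             network = NULL) {
  cfg <- run_config(config)
  obj <- config_objects(cfg)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  net <- network %||% grow_from_config(cfg, obj)
  cache <- file.path(out_dir, "sweep_cache.csv")
  key <- rlang::hash(list(unclass(cfg)[c("phantom", "vasculature", "flow",
                                         "properties", "thermal", "sweep")],
                          seed = cfg$seed))
  tab <- NULL
  if (file.exists(cache)) {
    cached <- utils::read.csv(cache)
    if (identical(attr_key <- cached$cache_key[1], key)) {
      tab <- as_tibble(cached[, c("Q_ml_s", "T_amb_C", "heating", "T_center_C")])
      class(tab) <- c("sweep_table", class(tab))
      message("sweep: cache hit, re-using forward table")
    }
  }
  if (is.null(tab)) {
    tab <- sweep_forward(obj$phantom, net, Q_values = cfg$sweep$Q_ml_s,
                         T_amb_values = cfg$sweep$T_amb_C, heating = "both",
                         props = obj$props, q_heat = cfg$thermal$q_heat_W_m2,
                         T_inlet = cfg$thermal$T_inlet_C,
                         Nu = cfg$thermal$Nu,
                         wall_h_factor = cfg$thermal$wall_h_factor,
                         capillary_diameter = cfg$thermal$capillary_diameter_m,
                         wall_epsilon_split = cfg$thermal$wall_epsilon_split)
    out <- as.data.frame(tab)
    out$cache_key <- key
    utils::write.csv(out, cache, row.names = FALSE)
  }
  surfaces <- list(
    off = fit_response_surface(tab, "off", method = cfg$sweep$fit_method,
                               q_order = cfg$sweep$q_order,
                               t_order = cfg$sweep$t_order,
                               max_residual = cfg$sweep$max_residual_C),
    on = fit_response_surface(tab, "on", method = cfg$sweep$fit_method,
                              q_order = cfg$sweep$q_order,
                              t_order = cfg$sweep$t_order,
                              max_residual = cfg$sweep$max_residual_C))
  if (is.character(traces)) traces <- lapply(traces, read_trace_csv)
  results <- lapply(traces, function(tr) {
    invert_blood_flow(tr, surfaces, obj$protocol, tail_s = cfg$invert$tail_s)
  })
  report <- lapply(results, function(est) {
    list(subject = est$subject_id, pattern = est$pattern,
         phases = est$phases)
  })
  jsonlite::write_json(report, file.path(out_dir, "estimates.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  summary <- purrr::map_dfr(results, glance)
  utils::write.csv(as.data.frame(summary), file.path(out_dir, "estimates_summary.csv"),
                   row.names = FALSE)
  write_manifest(cfg, out_dir, "sweep_invert", list(n_traces = length(traces)))
  invisible(summary)
}

#' End-to-end demonstration on a coarse phantom
#'
#' Grows a network, runs heated and unheated simulations, sweeps, fits, and
#' inverts one synthetic healthy trace — all with bundled defaults scaled to
#' a coarse (0.9 mm) phantom so the whole run takes a few minutes.
#'
#' @param out_dir output directory.
#' @param seed integer seed.
#' @return the demo's summary tibble, invisibly.
#' @export
cmd_demo <- function(out_dir = ".", seed = 1L) {
  cfg <- run_config(list(seed = as.integer(seed),
                         phantom = list(voxel_size_m = 0.9e-3),
                         vasculature = list(iterations = 500L)))
  obj <- config_objects(cfg)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  net <- grow_from_config(cfg, obj)
  cmd_grow(cfg, out_dir)
  cmd_simulate(cfg, out_dir, network = net, heating = "off")
  tab <- sweep_forward(obj$phantom, net, Q_values = cfg$sweep$Q_ml_s,
                       T_amb_values = cfg$sweep$T_amb_C, heating = "both",
                       props = obj$props)
  surfaces <- list(off = fit_response_surface(tab, "off"),
                   on = fit_response_surface(tab, "on"))
  tr <- synthesize_trace(c(resting = 0.002, heating = 0.006, recovery = 0.00205),
                         T_amb = 23, surfaces = surfaces, noise_sd = 0.05,
                         rng_seed = seed, subject_id = "demo")
  write_trace_csv(tr, file.path(out_dir, "demo_trace.csv"))
  est <- invert_blood_flow(tr, surfaces)
  jsonlite::write_json(list(subject = "demo", pattern = est$pattern,
                            phases = est$phases),
                       file.path(out_dir, "demo_estimate.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  message(sprintf("demo: pattern %s; flows %s ml/s", est$pattern,
                  paste(sprintf("%.4f", est$phases$Q_ml_s), collapse = "/")))
  invisible(glance(est))
}
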