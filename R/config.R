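# Run configuration: one YAML (or list) carrying every tunable the commands
# use, validated against the known schema, with defaults equal to the model's
# reference settings.

default_config <- function() {
  list(
    schema_version = 1L,
    seed = 1L,
    phantom = list(
      voxel_size_m = 0.3e-3, epsilon3 = 0.05,
      annulus_inner_m = 3.5e-3, annulus_outer_m = 6.9e-3,
      device_cover = TRUE, cover_radius_m = 9e-3),
    vasculature = list(
      iterations = 2000L, root_radius_m = 2e-4, murray_exponent = 3,
      seed_depth_frac = 0.5),
    flow = list(
      inlet_flow_ml_s = 0.005, perfusion_policy = "terminal_count"),
    properties = unclass(tissue_properties()),
    thermal = list(
      h_env_W_m2K = 8.0, T_inf_C = 23, T_inlet_C = 37, q_heat_W_m2 = 150,
      Nu = 4, wall_h_factor = 1, capillary_diameter_m = 8e-6,
      wall_epsilon_split = TRUE, double_beta23 = FALSE,
      inlet_mode = "advective", skin_exposure = "weighted"),
    protocol = list(
      durations_s = c(750, 1000, 1000), q_heat_W_m2 = c(0, 150, 0)),
    sweep = list(
      Q_ml_s = c(0, 5e-4, 7.5e-4, 0.001, 0.00125, 0.0015, 0.00175, 0.002, 0.0025,
                 0.003, 0.004, 0.005, 0.006, 0.008, 0.01),
      T_amb_C = c(20, 22, 24), fit_method = "spline", q_order = 3,
      t_order = 1, max_residual_C = 0.05),
    invert = list(tail_s = 100, healthy_tol = 0.10)
  )
}

#' Load and validate a run configuration
#'
#' Reads a YAML configuration (or takes a list), validates every key against
#' the known schema, and merges it over the defaults. Unknown keys are
#' rejected by name so that typos cannot silently fall back to defaults.
#'
#' @param config path to a YAML file, a list of overrides, or `NULL` for the
#'   defaults.
#' @return the merged configuration list, classed `run_config`.
#' @export
run_config <- function(config = NULL) {
  base <- default_config()
  if (is.null(config)) {
    out <- base
  } else {
    if (is.character(config)) {
      if (!file.exists(config)) abort(sprintf("config file not found: %s", config))
      config <- yaml::read_yaml(config)
    }
    if (!is.list(config)) abort("config must be a YAML file path or a list")
    out <- merge_config(base, config, path = "")
  }
  structure(out, class = c("run_config", "list"))
}

merge_config <- function(base, over, path) {
  unknown <- setdiff(names(over), names(base))
  if (length(unknown) > 0) {
    abort(sprintf("unknown config key(s): %s",
                  paste0(sub("^\\.", "", paste0(path, ".", unknown)),
                         collapse = ", ")))
  }
  for (nm in names(over)) {
    if (is.list(base[[nm]]) && is.list(over[[nm]]) && !is.null(names(base[[nm]]))) {
      base[[nm]] <- merge_config(base[[nm]], over[[nm]], paste0(path, ".", nm))
    } else {
      base[[nm]] <- over[[nm]]
    }
  }
  base
}

config_objects <- function(cfg) {
  props <- do.call(tissue_properties, cfg$properties)
  phantom <- build_cubic_phantom(
    voxel_size = cfg$phantom$voxel_size_m, epsilon3 = cfg$phantom$epsilon3,
    annulus_inner = cfg$phantom$annulus_inner_m,
    annulus_outer = cfg$phantom$annulus_outer_m,
    device_cover = cfg$phantom$device_cover,
    cover_radius = cfg$phantom$cover_radius_m)
  protocol <- spas_protocol(tibble(
    name = c("resting", "heating", "recovery"),
    duration_s = cfg$protocol$durations_s,
    q_heat_W_m2 = cfg$protocol$q_heat_W_m2))
  list(props = props, phantom = phantom, protocol = protocol)
}
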