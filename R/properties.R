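#' Physical tissue and blood properties
#'
#' Container for the physical constants of the model, with defaults from the
#' standard parameter set for perfused soft tissue and bone: blood viscosity
#' 3.5 mPa s, porous-media permeability 1.5e-13 m^2, blood
#' density/heat-capacity/conductivity 1050 kg/m^3, 3800 J/(kg K),
#' 0.50 W/(m K), soft tissue 1270 kg/m^3, 3768 J/(kg K), 0.35 W/(m K), bone
#' 1418 kg/m^3, 2409 J/(kg K), 2.21 W/(m K), and metabolic heat generation
#' 368 W/m^3.
#'
#' @param mu blood dynamic viscosity (Pa s).
#' @param K_perm permeability of the capillary porous phase (m^2).
#' @param rho_b,c_b,K_b blood density (kg/m^3), specific heat (J/(kg K)) and
#'   thermal conductivity (W/(m K)).
#' @param rho_soft,c_soft,K_soft soft-tissue density, specific heat and
#'   conductivity.
#' @param rho_bone,c_bone,K_bone bone density, specific heat and conductivity.
#' @param Q_gen metabolic heat generation (W/m^3).
#' @return a named list of class `tissue_properties`.
#' @export
tissue_properties <- function(mu = 3.5e-3, K_perm = 1.5e-13,
                              rho_b = 1050, c_b = 3800, K_b = 0.50,
                              rho_soft = 1270, c_soft = 3768, K_soft = 0.35,
                              rho_bone = 1418, c_bone = 2409, K_bone = 2.21,
                              Q_gen = 368) {
  p <- list(mu = mu, K_perm = K_perm, rho_b = rho_b, c_b = c_b, K_b = K_b,
            rho_soft = rho_soft, c_soft = c_soft, K_soft = K_soft,
            rho_bone = rho_bone, c_bone = c_bone, K_bone = K_bone,
            Q_gen = Q_gen)
  if (any(unlist(p) <= 0)) abort("all physical properties must be positive")
  structure(p, class = "tissue_properties")
}

#' Thermal boundary conditions
#'
#' @param h_env combined convective + radiative surface heat-transfer
#'   coefficient (W/(m^2 K)); default 8.0.
#' @param T_inf ambient temperature (deg C); default 23.
#' @param q_heat imposed heat flux on the heating mask (W/m^2); 0 when the
#'   heater is off, 150 during the heating phase.
#' @param T_inlet arterial inlet blood temperature (deg C); default 37.
#' @return a named list of class `thermal_boundary`.
#' @export
thermal_boundary <- function(h_env = 8.0, T_inf = 23, q_heat = 0, T_inlet = 37) {
  if (h_env < 0) abort("`h_env` must be >= 0")
  if (q_heat < 0) abort("`q_heat` must be >= 0")
  structure(list(h_env = h_env, T_inf = T_inf, q_heat = q_heat,
                 T_inlet = T_inlet), class = "thermal_boundary")
}
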