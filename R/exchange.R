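#' Vessel-wall and capillary heat-exchange coefficients
#'
#' Computes the inter-domain exchange coefficients `beta` (W/K) from the
#' segment-voxel map. The vessel-wall film coefficient follows the
#' constant-Nusselt laminar-pipe relation `h_wall = factor * Nu * K_b / D`
#' with `Nu = 4` by default (`wall_h_factor = 2` selects the alternative
#' reading with the factor of two in the Nusselt definition). For a
#' segment-voxel pair with shared lateral area `A`, the wall exchange is
#' split between the two porous phases by volume fraction —
#' `beta_tissue = eps2 * h_wall * A`, `beta_capillary = eps3 * h_wall * A` —
#' so the total wall exchange is `h_wall * A` with no double counting
#' (`wall_epsilon_split = FALSE` instead gives the full area to both pairs,
#' the literal reading of the exchange definition). The internal
#' tissue-capillary exchange uses the capillary-scale film coefficient and
#' the capillary interfacial area per voxel, `4 * eps3 * V / d_cap` (surface
#' per volume of cylinders of diameter `d_cap` at volume fraction `eps3`).
#'
#' Fully occluded (zero-radius) segments have zero wall area and exchange
#' nothing; segments with unset (`NA`) radii are rejected.
#'
#' @param map a [voxelize_segments()] result.
#' @param network the matching [vessel_network()].
#' @param grid the matching [voxel_grid()].
#' @param props a [tissue_properties()].
#' @param Nu Nusselt number (default 4, laminar pipe flow).
#' @param wall_h_factor multiplier on `Nu * K_b / D` (1 or 2, see above).
#' @param capillary_diameter representative capillary diameter (m).
#' @param wall_epsilon_split split wall area by volume fraction (default).
#' @return object of class `exchange_coefficients`: `entries` (tibble
#'   `seg_id, kind, vox, area, h_wall, beta_tissue, beta_capillary`),
#'   `beta23` (tibble `vox, beta`), and the settings used.
#' @export
compute_exchange_coefficients <- function(map, network, grid, props, Nu = 4,
                                          wall_h_factor = 1,
                                          capillary_diameter = 8e-6,
                                          wall_epsilon_split = TRUE) {
  seg <- network$segments
  if (any(is.na(seg$radius))) abort("assign radii before computing exchange coefficients")
  e <- map$entries
  R <- seg$radius[match(e$seg_id, seg$id)]
  h_wall <- ifelse(R > 0, wall_h_factor * Nu * props$K_b / (2 * R), 0)
  eps3 <- as.numeric(grid$epsilon3)[e$vox]
  eps2 <- 1 - eps3
  w2 <- if (wall_epsilon_split) eps2 else 1
  w3 <- if (wall_epsilon_split) eps3 else 1
  entries <- tibble(seg_id = e$seg_id, kind = e$kind, vox = e$vox,
                    area = e$area, h_wall = h_wall,
                    beta_tissue = w2 * h_wall * e$area,
                    beta_capillary = w3 * h_wall * e$area)
  tis <- which(grid$labels != LABEL_OUTSIDE)
  V <- grid$voxel_size^3
  h_cap <- wall_h_factor * Nu * props$K_b / capillary_diameter
  a_cap <- 4 * as.numeric(grid$epsilon3)[tis] * V / capillary_diameter
  beta23 <- tibble(vox = tis, beta = h_cap * a_cap)
  structure(list(entries = entries, beta23 = beta23, Nu = Nu,
                 wall_h_factor = wall_h_factor,
                 capillary_diameter = capillary_diameter,
                 wall_epsilon_split = wall_epsilon_split),
            class = "exchange_coefficients")
}
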