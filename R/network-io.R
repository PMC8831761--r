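# Vessel-network and grid I/O: JSON, the two-CSV dialect, and legacy-ASCII
# VTK export for visualisation.

#' Read / write a vessel network as JSON
#'
#' The JSON object carries `nodes` (id, x, y, z), `segments`
#' (id, node_a, node_b, radius, kind, terminal) and `roots` (node, kind).
#'
#' @param network a [vessel_network()].
#' @param path file path.
#' @return `write_network_json()` returns `path` invisibly;
#'   `read_network_json()` returns a [vessel_network()].
#' @export
write_network_json <- function(network, path) {
  jsonlite::write_json(
    list(nodes = network$nodes, segments = network$segments,
         roots = network$roots),
    path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_network_json
#' @export
read_network_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  vessel_network(as_tibble(x$nodes), as_tibble(x$segments), as_tibble(x$roots))
}

#' Read / write a vessel network as paired CSV files
#'
#' `nodes.csv` holds `id,x,y,z`; `segments.csv` holds
#' `id,node_a,node_b,radius,kind,terminal,root` where `root` marks the root
#' node id of each kind on its first segment row.
#'
#' @param network a [vessel_network()].
#' @param nodes_path,segments_path file paths.
#' @return the written paths invisibly, or a [vessel_network()].
#' @export
write_network_csv <- function(network, nodes_path, segments_path) {
  utils::write.csv(network$nodes, nodes_path, row.names = FALSE)
  seg <- network$segments
  seg$root <- NA_integer_
  for (k in unique(seg$kind)) {
    seg$root[which(seg$kind == k)[1]] <- network$roots$node[network$roots$kind == k][1]
  }
  utils::write.csv(seg, segments_path, row.names = FALSE)
  invisible(c(nodes_path, segments_path))
}

#' @rdname write_network_csv
#' @export
read_network_csv <- function(nodes_path, segments_path) {
  nodes <- utils::read.csv(nodes_path)
  seg <- utils::read.csv(segments_path)
  roots <- seg[!is.na(seg$root), c("root", "kind")]
  names(roots)[1] <- "node"
  vessel_network(as_tibble(nodes), as_tibble(seg), as_tibble(roots))
}

#' Export a vessel network as VTK polylines
#'
#' Writes a legacy-ASCII VTK polydata file with one line cell per segment and
#' optional per-segment cell data (radius is always included).
#'
#' @param network a [vessel_network()].
#' @param path output `.vtk` path.
#' @param cell_data named list of per-segment numeric vectors (e.g. flow).
#' @return `path`, invisibly.
#' @export
write_vtk_polylines <- function(network, path, cell_data = list()) {
  nodes <- network$nodes
  seg <- network$segments
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "vessel network", "ASCII",
               "DATASET POLYDATA", sprintf("POINTS %d double", nrow(nodes))), con)
  writeLines(sprintf("%.9g %.9g %.9g", nodes$x, nodes$y, nodes$z), con)
  ia <- match(seg$node_a, nodes$id) - 1L
  ib <- match(seg$node_b, nodes$id) - 1L
  writeLines(sprintf("LINES %d %d", nrow(seg), 3L * nrow(seg)), con)
  writeLines(sprintf("2 %d %d", ia, ib), con)
  cell_data <- c(list(radius = seg$radius,
                      kind = as.numeric(factor(seg$kind, c("ARTERY", "VEIN")))),
                 cell_data)
  writeLines(sprintf("CELL_DATA %d", nrow(seg)), con)
  for (nm in names(cell_data)) {
    writeLines(c(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default"), con)
    writeLines(sprintf("%.9g", replace(cell_data[[nm]], is.na(cell_data[[nm]]), 0)), con)
  }
  invisible(path)
}

#' Export a voxel grid as a VTK structured-points file
#'
#' Legacy-ASCII VTK with tissue labels and the capillary volume fraction as
#' cell data, plus any extra per-voxel fields supplied (full 3-d arrays or
#' vectors over all voxels).
#'
#' @param grid a [voxel_grid()].
#' @param path output `.vtk` path.
#' @param cell_data named list of numeric arrays/vectors with one value per
#'   voxel.
#' @return `path`, invisibly.
#' @export
write_vtk_grid <- function(grid, path, cell_data = list()) {
  d <- grid$shape
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "voxel grid", "ASCII",
               "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d %d", d[1] + 1L, d[2] + 1L, d[3] + 1L),
               sprintf("ORIGIN %.9g %.9g %.9g", grid$origin[1], grid$origin[2],
                       grid$origin[3]),
               sprintf("SPACING %.9g %.9g %.9g", grid$voxel_size,
                       grid$voxel_size, grid$voxel_size),
               sprintf("CELL_DATA %d", prod(d))), con)
  cell_data <- c(list(label = as.numeric(grid$labels),
                      epsilon3 = as.numeric(grid$epsilon3)), cell_data)
  for (nm in names(cell_data)) {
    v <- as.numeric(cell_data[[nm]])
    stopifnot(length(v) == prod(d))
    writeLines(c(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default"), con)
    writeLines(sprintf("%.9g", replace(v, is.na(v), 0)), con)
  }
  invisible(path)
}
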