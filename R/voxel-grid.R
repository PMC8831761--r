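# Tissue label codes used throughout: integer arrays keep the solvers simple,
# the exported constants keep user code readable.

#' Tissue label codes
#'
#' Integer codes used in the `labels` array of a [voxel_grid()]:
#' `LABEL_OUTSIDE` (0), `LABEL_SOFT_TISSUE` (1), `LABEL_BONE` (2).
#'
#' @name tissue-labels
#' @export
LABEL_OUTSIDE <- 0L

#' @rdname tissue-labels
#' @export
LABEL_SOFT_TISSUE <- 1L

#' @rdname tissue-labels
#' @export
LABEL_BONE <- 2L

#' Voxelised tissue domain
#'
#' A regular voxel grid carrying a tissue label and a capillary blood volume
#' fraction per voxel. The capillary (porous) phase occupies fraction
#' `epsilon3` of each tissue voxel and the solid tissue phase the remaining
#' `1 - epsilon3`, so the two fractions always sum to one inside tissue.
#' Outside voxels carry `epsilon3 = 0`.
#'
#' Voxel centres sit at `origin + (index - 0.5) * voxel_size` along each axis
#' (1-based indices); the `z` axis points from the deep boundary towards the
#' skin, so the exposed surface of the cubic phantom is the `z = nz` layer.
#'
#' @param labels integer 3-d array of tissue labels (see [tissue-labels]).
#' @param voxel_size edge length of a voxel in metres.
#' @param epsilon3 capillary blood volume fraction: scalar or array matching
#'   `labels`. Forced to 0 outside tissue.
#' @param origin physical coordinate (m) of the low corner of voxel (1,1,1).
#' @return an object of class `voxel_grid` with fields `labels`, `voxel_size`,
#'   `epsilon3`, `origin`, `shape`.
#' @seealso [build_cubic_phantom()], [import_label_image()],
#'   [extract_skin_mask()]
#' @export
voxel_grid <- function(labels, voxel_size, epsilon3 = 0.05, origin = c(0, 0, 0)) {
  if (!is.array(labels) || length(dim(labels)) != 3) {
    abort("`labels` must be a 3-d integer array")
  }
  storage.mode(labels) <- "integer"
  bad <- setdiff(unique(as.vector(labels)),
                 c(LABEL_OUTSIDE, LABEL_SOFT_TISSUE, LABEL_BONE))
  if (length(bad) > 0) {
    abort(sprintf("unknown tissue labels: %s", paste(bad, collapse = ", ")))
  }
  if (!is.numeric(voxel_size) || length(voxel_size) != 1 || voxel_size <= 0) {
    abort("`voxel_size` must be a single positive length in metres")
  }
  if (length(epsilon3) == 1) {
    eps <- array(as.numeric(epsilon3), dim = dim(labels))
  } else {
    stopifnot(all(dim(epsilon3) == dim(labels)))
    eps <- array(as.numeric(epsilon3), dim = dim(labels))
  }
  if (any(eps < 0 | eps > 1)) abort("`epsilon3` must lie in [0, 1]")
  eps[labels == LABEL_OUTSIDE] <- 0
  structure(
    list(labels = labels, voxel_size = voxel_size, epsilon3 = eps,
         origin = as.numeric(origin), shape = dim(labels)),
    class = "voxel_grid"
  )
}

#' @export
print.voxel_grid <- function(x, ...) {
  n_tis <- sum(x$labels != LABEL_OUTSIDE)
  cat(sprintf("<voxel_grid> %d x %d x %d voxels of %.4g mm; %d tissue (%d soft, %d bone)\n",
              x$shape[1], x$shape[2], x$shape[3], x$voxel_size * 1e3,
              n_tis, sum(x$labels == LABEL_SOFT_TISSUE), sum(x$labels == LABEL_BONE)))
  invisible(x)
}

#' Physical extent of a grid (m)
#' @param grid a [voxel_grid()].
#' @return numeric length-3 vector of physical edge lengths in metres.
#' @export
grid_extent <- function(grid) grid$shape * grid$voxel_size

#' Voxel centre coordinates
#'
#' @param grid a [voxel_grid()].
#' @param which `"tissue"` (default) or `"all"`.
#' @return tibble with columns `ix, iy, iz, x, y, z, label`.
#' @export
voxel_centres <- function(grid, which = c("tissue", "all")) {
  which <- match.arg(which)
  d <- grid$shape
  idx <- if (which == "tissue") which(grid$labels != LABEL_OUTSIDE) else seq_along(grid$labels)
  ijk <- arrayInd(idx, d)
  h <- grid$voxel_size
  tibble(
    ix = ijk[, 1], iy = ijk[, 2], iz = ijk[, 3],
    x = grid$origin[1] + (ijk[, 1] - 0.5) * h,
    y = grid$origin[2] + (ijk[, 2] - 0.5) * h,
    z = grid$origin[3] + (ijk[, 3] - 0.5) * h,
    label = as.vector(grid$labels)[idx]
  )
}

#' Build the cubic skin phantom
#'
#' Constructs the all-soft-tissue 18 x 18 x 9 mm slab used to emulate a patch
#' of skin under an annular contact heater, together with its exposed-surface
#' mask. Only the top (`z = nz`) surface is exposed to the environment; all
#' other boundaries are adiabatic. The annular heating zone on the top face
#' has inner radius 3.5 mm and outer radius 6.9 mm around the face centre: a
#' face belongs to the annulus iff its centre's planar distance from the top
#' face centre lies inside that band.
#'
#' The phantom footprint matches the sensor board itself, which rests flat on
#' the skin during a measurement: the skin under the board (the inscribed
#' disc, radius `cover_radius`) exchanges no heat with the ambient air, and
#' only the uncovered corners carry the Robin (convective + radiative)
#' condition. This cover is what makes the heated centre-point temperature
#' fall with increasing blood flow: the trapped ring flux drives the covered
#' region above blood temperature at low flow, so perfusion cools it, with
#' the steep sensitivity concentrated at the lowest flows. Set
#' `device_cover = FALSE` to expose the whole top face instead (the heated
#' response then rises with flow, because the freely-cooled surface never
#' exceeds blood temperature).
#'
#' @param voxel_size voxel edge (m); must divide both 18 mm and 9 mm exactly.
#' @param epsilon3 capillary blood volume fraction (uniform).
#' @param annulus_inner,annulus_outer heater radii (m).
#' @param device_cover mark the device footprint as covered (insulated from
#'   ambient exchange).
#' @param cover_radius planar radius of the covered footprint (m); default
#'   the inscribed disc of the 18 mm patch.
#' @return list with elements `grid` (a [voxel_grid()]) and `mask`
#'   (a [surface_mask]).
#' @examples
#' ph <- build_cubic_phantom(voxel_size = 0.9e-3)
#' ph$grid$shape  # 20 20 10
#' @export
build_cubic_phantom <- function(voxel_size = 0.3e-3, epsilon3 = 0.05,
                                annulus_inner = 3.5e-3, annulus_outer = 6.9e-3,
                                device_cover = TRUE, cover_radius = 9e-3) {
  ext <- c(18e-3, 18e-3, 9e-3)
  n <- ext / voxel_size
  if (any(abs(n - round(n)) > 1e-9)) {
    res <- ext - round(n) * voxel_size
    abort(sprintf(
      "voxel_size %.6g m does not divide the 18 x 18 x 9 mm phantom evenly (residuals %s m)",
      voxel_size, paste(signif(res[abs(n - round(n)) > 1e-9], 3), collapse = ", ")))
  }
  n <- as.integer(round(n))
  labels <- array(LABEL_SOFT_TISSUE, dim = n)
  grid <- voxel_grid(labels, voxel_size, epsilon3 = epsilon3)
  mask <- extract_skin_mask(grid, policy = "top")
  centre <- grid_extent(grid)[1:2] / 2
  r <- sqrt((mask$cx - centre[1])^2 + (mask$cy - centre[2])^2)
  mask$heating <- r >= annulus_inner & r <= annulus_outer
  mask$covered <- device_cover & r <= cover_radius
  attr(mask, "annulus") <- list(centre = centre, inner = annulus_inner,
                                outer = annulus_outer)
  list(grid = grid, mask = mask)
}

#' Extract the exposed (skin) surface of a voxel grid
#'
#' Lists every tissue-voxel face exposed to the environment, each exactly
#' once. Two exposure policies are supported: `"top"` (only the `z = nz`
#' layer's upper faces, the cubic-phantom convention where all other
#' boundaries are adiabatic) and `"all_outside_adjacent"` (every tissue face
#' adjacent to an OUTSIDE voxel or to the domain boundary, for imported
#' anatomies).
#'
#' @param grid a [voxel_grid()].
#' @param policy exposure policy, see above.
#' @return a `surface_mask`: tibble with voxel indices `ix, iy, iz`, outward
#'   axis `axis` ("x"/"y"/"z"), direction `dir` (+1/-1), face-centre
#'   coordinates `cx, cy, cz`, and a logical `heating` column (all `FALSE`
#'   unless set by a phantom builder). Face area is in `attr(, "face_area")`.
#' @export
extract_skin_mask <- function(grid, policy = c("top", "all_outside_adjacent")) {
  policy <- match.arg(policy)
  d <- grid$shape
  h <- grid$voxel_size
  tis <- grid$labels != LABEL_OUTSIDE
  if (!any(tis)) abort("grid contains no tissue voxels")
  faces <- list()
  if (policy == "top") {
    idx <- which(tis[, , d[3], drop = FALSE], arr.ind = TRUE)
    faces[[1]] <- tibble(ix = idx[, 1], iy = idx[, 2], iz = d[3],
                         axis = "z", dir = 1L)
  } else {
    pad <- function(a) {
      out <- array(FALSE, dim = d + 2)
      out[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- a
      out
    }
    tp <- pad(tis)
    shifts <- list(
      list(axis = "x", dir = -1L, off = c(-1, 0, 0)),
      list(axis = "x", dir = 1L,  off = c(1, 0, 0)),
      list(axis = "y", dir = -1L, off = c(0, -1, 0)),
      list(axis = "y", dir = 1L,  off = c(0, 1, 0)),
      list(axis = "z", dir = -1L, off = c(0, 0, -1)),
      list(axis = "z", dir = 1L,  off = c(0, 0, 1))
    )
    k <- 0
    for (s in shifts) {
      nb <- tp[2:(d[1] + 1) + s$off[1], 2:(d[2] + 1) + s$off[2],
               2:(d[3] + 1) + s$off[3], drop = FALSE]
      dim(nb) <- d
      exposed <- tis & !nb
      if (any(exposed)) {
        idx <- which(exposed, arr.ind = TRUE)
        k <- k + 1
        faces[[k]] <- tibble(ix = idx[, 1], iy = idx[, 2], iz = idx[, 3],
                             axis = s$axis, dir = s$dir)
      }
    }
  }
  out <- dplyr::bind_rows(faces)
  out <- dplyr::arrange(out, .data$axis, .data$dir, .data$iz, .data$iy, .data$ix)
  out$cx <- grid$origin[1] + (out$ix - 0.5) * h + ifelse(out$axis == "x", out$dir * h / 2, 0)
  out$cy <- grid$origin[2] + (out$iy - 0.5) * h + ifelse(out$axis == "y", out$dir * h / 2, 0)
  out$cz <- grid$origin[3] + (out$iz - 0.5) * h + ifelse(out$axis == "z", out$dir * h / 2, 0)
  out$heating <- FALSE
  out$covered <- FALSE
  attr(out, "face_area") <- h^2
  attr(out, "voxel_size") <- h
  attr(out, "policy") <- policy
  class(out) <- c("surface_mask", class(out))
  out
}

#' Import a labelled 3-d image as a voxel grid
#'
#' Reads an integer label image (NIfTI `.nii`/`.nii.gz` via RNifti, or a
#' multi-page TIFF stack via the tiff package) and remaps its labels to the
#' tissue codes. Every label present in the image must appear in `label_map`.
#'
#' @param path image file.
#' @param voxel_size voxel edge in metres.
#' @param label_map named character vector mapping image values to
#'   `"OUTSIDE"`, `"SOFT_TISSUE"` or `"BONE"`, e.g.
#'   `c("0" = "OUTSIDE", "1" = "SOFT_TISSUE", "2" = "BONE")`.
#' @param epsilon3 capillary volume fraction assigned to tissue voxels.
#' @return a [voxel_grid()]; tissue class counts are attached as
#'   `attr(, "class_counts")`.
#' @export
import_label_image <- function(path, voxel_size, label_map, epsilon3 = 0.05) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  if (ext %in% c("nii", "hdr", "img")) {
    if (!requireNamespace("RNifti", quietly = TRUE)) {
      abort("reading NIfTI requires the RNifti package")
    }
    img <- as.array(RNifti::readNifti(path))
  } else if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE)) {
      abort("reading TIFF stacks requires the tiff package")
    }
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    img <- simplify2array(pages)
  } else {
    abort(sprintf("unsupported image format: .%s", ext))
  }
  if (length(dim(img)) != 3) abort("label image must be 3-dimensional")
  vals <- round(as.vector(img))
  known <- as.numeric(names(label_map))
  unknown <- setdiff(unique(vals), known)
  if (length(unknown) > 0) {
    abort(sprintf("image contains labels not covered by `label_map`: %s",
                  paste(sort(unknown), collapse = ", ")))
  }
  codes <- c(OUTSIDE = LABEL_OUTSIDE, SOFT_TISSUE = LABEL_SOFT_TISSUE,
             BONE = LABEL_BONE)
  if (!all(label_map %in% names(codes))) {
    abort("`label_map` values must be OUTSIDE, SOFT_TISSUE or BONE")
  }
  lut <- setNames(codes[label_map], names(label_map))
  labels <- array(as.integer(lut[as.character(vals)]), dim = dim(img))
  grid <- voxel_grid(labels, voxel_size, epsilon3 = epsilon3)
  counts <- table(factor(names(codes)[match(labels, codes)], levels = names(codes)))
  attr(grid, "class_counts") <- counts
  grid
}

#' Write grid labels to a NIfTI image
#'
#' Counterpart of [import_label_image()] for round-tripping voxel labels.
#'
#' @param grid a [voxel_grid()].
#' @param path output `.nii`/`.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_label_image <- function(grid, path) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    abort("writing NIfTI requires the RNifti package")
  }
  img <- RNifti::asNifti(grid$labels)
  RNifti::pixdim(img) <- rep(grid$voxel_size * 1e3, 3)  # NIfTI stores mm
  RNifti::writeNifti(img, path)
  invisible(path)
}
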