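#' Regular 3-D scalar grid
#'
#' The basic volumetric container: a 3-D array of voxel values (relative
#' electron density, unitless with water = 1; or dose) on a regular grid with
#' millimetre spacing. World coordinates are in mm with axes
#' (left-to-right, posterior-to-anterior, inferior-to-superior); the world
#' position of voxel `(i, j, k)` (1-based) is
#' `origin + (c(i, j, k) - 1) * spacing`.
#'
#' @param values numeric 3-D array, finite.
#' @param spacing numeric length-3, voxel spacing in mm, all positive.
#' @param origin numeric length-3, world mm of the center of voxel (1,1,1).
#'   Defaults to centering the grid on the world origin.
#' @return An object of class `image_grid`: a list with elements `values`,
#'   `spacing`, `origin`.
#' @export
image_grid <- function(values, spacing,
                       origin = -(dim(values) - 1) * spacing / 2) {
  stopifnot(is.array(values), length(dim(values)) == 3)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) == 1) spacing <- rep(spacing, 3)
  if (any(spacing <= 0)) stop("spacing must be positive on all axes")
  if (any(dim(values) < 2)) stop("grid too small")
  if (!all(is.finite(values))) stop("grid values must be finite")
  structure(list(values = values, spacing = spacing, origin = origin),
            class = "image_grid")
}

#' @export
print.image_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<image_grid> %d x %d x %d voxels, spacing %s mm, range [%.3g, %.3g]\n",
              d[1], d[2], d[3], paste(signif(x$spacing, 3), collapse = " x "),
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
dim.image_grid <- function(x) dim(x$values)

#' World coordinates of every voxel center along each axis
#' @param grid an `image_grid` or anything with `$spacing`, `$origin` and a dim.
#' @return list of three numeric vectors (x, y, z voxel-center coordinates, mm).
#' @export
grid_axes <- function(grid) {
  d <- dim(grid$values)
  lapply(1:3, function(a) grid$origin[a] + (seq_len(d[a]) - 1) * grid$spacing[a])
}

#' Voxel volume in cc
#' @param spacing length-3 spacing in mm (or an `image_grid`).
#' @export
voxel_cc <- function(spacing) {
  if (inherits(spacing, "image_grid")) spacing <- spacing$spacing
  prod(spacing) / 1000
}

#' Volume of a binary mask in cc
#' @param mask logical array.
#' @param spacing voxel spacing mm (length 3) or an `image_grid`.
#' @export
mask_volume_cc <- function(mask, spacing) sum(mask) * voxel_cc(spacing)

#' Named set of binary masks on a shared grid
#'
#' Holds the segmentation of a phantom: body, left/right lung, ITV, PTV (and,
#' after margin deformation, the deformed aperture-fitting target). All masks
#' share one grid geometry.
#'
#' @param masks named list of logical 3-D arrays of identical dimension.
#' @param spacing,origin grid geometry (as in [image_grid()]).
#' @param check if `TRUE`, verify the clinical nesting invariants
#'   (`itv` within `ptv` within `body`, lungs within `body`) when those masks
#'   are present.
#' @return object of class `structure_set`.
#' @export
structure_set <- function(masks, spacing, origin, check = TRUE) {
  stopifnot(is.list(masks), length(masks) > 0, !is.null(names(masks)))
  d <- dim(masks[[1]])
  for (m in masks) {
    stopifnot(is.logical(m), identical(dim(m), d))
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1) spacing <- rep(spacing, 3)
  ss <- structure(list(masks = masks, spacing = spacing,
                       origin = as.numeric(origin)),
                  class = "structure_set")
  if (check) validate_structures(ss)
  ss
}

validate_structures <- function(ss) {
  m <- ss$masks
  if (!is.null(m$itv) && !is.null(m$ptv) && any(m$itv & !m$ptv))
    stop("invariant violated: itv not contained in ptv")
  if (!is.null(m$ptv) && !is.null(m$body) && any(m$ptv & !m$body))
    stop("invariant violated: ptv not contained in body")
  for (nm in c("lung_left", "lung_right"))
    if (!is.null(m[[nm]]) && !is.null(m$body) && any(m[[nm]] & !m$body))
      stop("invariant violated: ", nm, " not contained in body")
  if (!is.null(m$itv) && !any(m$itv)) stop("itv mask is empty")
  invisible(ss)
}

#' @export
print.structure_set <- function(x, ...) {
  v <- vapply(x$masks, mask_volume_cc, numeric(1), spacing = x$spacing)
  cat("<structure_set>\n")
  for (nm in names(v)) cat(sprintf("  %-10s %8.2f cc\n", nm, v[nm]))
  invisible(x)
}

#' Summarize structure volumes as a tibble
#' @param x a `structure_set`.
#' @param ... unused.
#' @export
tidy.structure_set <- function(x, ...) {
  tibble::tibble(
    structure = names(x$masks),
    n_voxels = vapply(x$masks, sum, numeric(1)),
    volume_cc = vapply(x$masks, mask_volume_cc, numeric(1), spacing = x$spacing)
  )
}

#' Write a phantom (density + masks) to NIfTI files with a JSON manifest
#'
#' @param grid density `image_grid`.
#' @param structures `structure_set` on the same grid.
#' @param dir output directory (created if absent).
#' @param seed optional seed recorded in the manifest.
#' @return invisibly, the manifest as a list.
#' @export
write_phantom <- function(grid, structures, dir, seed = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_nii <- function(arr, path, spacing) {
    img <- RNifti::asNifti(arr * 1, pixdim = spacing)
    RNifti::writeNifti(img, path)
  }
  files <- list(density = file.path(dir, "density.nii.gz"))
  write_nii(grid$values, files$density, grid$spacing)
  vols <- list()
  for (nm in names(structures$masks)) {
    f <- file.path(dir, paste0(nm, ".nii.gz"))
    write_nii(structures$masks[[nm]], f, structures$spacing)
    files[[nm]] <- f
    vols[[nm]] <- mask_volume_cc(structures$masks[[nm]], structures$spacing)
  }
  manifest <- list(files = files, volumes_cc = vols,
                   spacing_mm = grid$spacing, origin_mm = grid$origin,
                   seed = seed)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
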