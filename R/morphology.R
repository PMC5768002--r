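#' Euclidean distance transform in millimetres
#'
#' Distance from each voxel center to the nearest `TRUE` voxel center,
#' honoring anisotropic spacing. An empty mask yields `Inf` everywhere.
#'
#' @param mask logical 3-D array.
#' @param spacing voxel spacing in mm, length 3 (or scalar).
#' @return numeric array of distances (mm), 0 on the mask.
#' @export
distance_mm <- function(mask, spacing) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3)
  if (length(spacing) == 1) spacing <- rep(spacing, 3)
  if (!any(mask)) return(array(Inf, dim(mask)))
  d2 <- edt_sq_cpp(as.logical(mask), as.integer(dim(mask)),
                   as.numeric(spacing))
  array(sqrt(d2), dim(mask))
}

#' Morphological operations in millimetres
#'
#' Dilation/erosion with a Euclidean ball of radius `r_mm` (implemented via
#' the distance transform, so anisotropic spacing is exact); closing is
#' dilation followed by erosion and smooths concavities narrower than the
#' radius.
#'
#' @param mask logical 3-D array.
#' @param r_mm structuring radius in mm (`r_mm = 0` is the identity).
#' @param spacing voxel spacing mm.
#' @return logical array.
#' @export
dilate_mm <- function(mask, r_mm, spacing) {
  if (r_mm <= 0 || !any(mask)) return(mask)
  distance_mm(mask, spacing) <= r_mm
}

#' @rdname dilate_mm
#' @export
erode_mm <- function(mask, r_mm, spacing) {
  if (r_mm <= 0) return(mask)
  if (!any(!mask)) return(mask)
  mask & (distance_mm(!mask, spacing) > r_mm)
}

#' @rdname dilate_mm
#' @export
close_mm <- function(mask, r_mm, spacing) {
  if (r_mm <= 0) return(mask)
  erode_mm(dilate_mm(mask, r_mm, spacing), r_mm, spacing)
}

#' Inner boundary band of a mask
#'
#' Voxels of `mask` lying within `depth_mm` of its surface (distance to the
#' complement at most `depth_mm`).
#' @param mask logical array.
#' @param depth_mm band depth, mm.
#' @param spacing voxel spacing mm.
#' @export
boundary_band <- function(mask, depth_mm, spacing) {
  if (!any(mask) || !any(!mask)) return(mask & FALSE)
  mask & (distance_mm(!mask, spacing) <= depth_mm)
}
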