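# Beam's-eye-view geometry: projection of masks onto the isocenter plane and
# MLC aperture fitting at each arc control point.
#
# Conventions: world axes (x, y, z) = (left-to-right, posterior-to-anterior,
# inferior-to-superior), mm. The gantry rotates in the axial (x, y) plane
# about the isocenter; at gantry angle g (degrees) the source sits at
# iso + SAD * (sin g, cos g, 0), so g = 0 is an anterior beam. In-plane BEV
# axes: the leaf-travel axis ex = (cos g, -sin g, 0) and the leaf-stack axis
# ez = (0, 0, 1); BEV coordinates are scaled to the isocenter plane by the
# divergent magnification SAD / (source-to-voxel depth).

#' Treatment machine geometry
#'
#' @param sad source-axis distance, mm (default 1000, a C-arm linac).
#' @param leaf_width_iso MLC leaf width projected to the isocenter plane, mm.
#' @param n_leaf_pairs number of leaf pairs (stacked along z in the BEV).
#' @param iso isocenter, world mm.
#' @return object of class `beam_geometry`.
#' @export
beam_geometry <- function(sad = 1000, leaf_width_iso = 5, n_leaf_pairs = 60,
                          iso = c(0, 0, 0)) {
  stopifnot(sad > 0, leaf_width_iso > 0, n_leaf_pairs >= 2)
  structure(list(sad = sad, leaf_width_iso = leaf_width_iso,
                 n_leaf_pairs = as.integer(n_leaf_pairs),
                 iso = as.numeric(iso)),
            class = "beam_geometry")
}

#' Arc specification
#'
#' A coplanar arc covering `span` degrees, leaving an unused gap of
#' `360 - span` degrees centered on `gap_center`. The default 340 degree span
#' follows RTOG 0915-style conformal arc practice; the gap is conventionally
#' oriented toward the contralateral lung.
#'
#' @param span arc span, degrees (default 340; 360 gives a full arc).
#' @param spacing control-point spacing, degrees; must divide `span`.
#' @param gap_center gantry angle (degrees) at the middle of the unused gap.
#' @param direction `"CW"` or `"CCW"`.
#' @return object of class `arc_spec`.
#' @export
arc_spec <- function(span = 340, spacing = 2, gap_center = 90,
                     direction = c("CW", "CCW")) {
  direction <- match.arg(direction)
  stopifnot(span > 0, span <= 360, spacing > 0)
  if (abs(span / spacing - round(span / spacing)) > 1e-9)
    stop("control-point spacing must divide the arc span")
  structure(list(span = span, spacing = spacing, gap_center = gap_center,
                 direction = direction),
            class = "arc_spec")
}

#' Gantry angles of an arc
#'
#' Uniformly spaced control-point angles over the span, excluding the gap.
#' For `span < 360` both edges of the gap are included, giving
#' `span / spacing + 1` angles; a full 360 arc gives `360 / spacing` angles.
#'
#' @param spec an [arc_spec()].
#' @return numeric vector of gantry angles in `[0, 360)`, ordered along the
#'   direction of rotation.
#' @export
make_arc <- function(spec) {
  stopifnot(inherits(spec, "arc_spec"))
  if (spec$span >= 360) {
    ang <- seq(0, 360 - spec$spacing, by = spec$spacing)
  } else {
    start <- spec$gap_center + (360 - spec$span) / 2
    ang <- start + seq(0, spec$span, by = spec$spacing)
  }
  ang <- ang %% 360
  if (spec$direction == "CCW") ang <- rev(ang)
  ang
}

bev_basis <- function(gantry_deg) {
  g <- gantry_deg * pi / 180
  list(src_dir = c(sin(g), cos(g), 0),
       ex = c(cos(g), -sin(g), 0),
       ez = c(0, 0, 1))
}

#' Beam's-eye-view projection of a mask
#'
#' Projects every voxel center of the mask through the point source onto the
#' isocenter plane (divergent, SAD-scaled) and marks the pixel receiving each
#' projected center as open.
#'
#' @param mask logical 3-D array (non-empty).
#' @param spacing,origin grid geometry of the mask (mm).
#' @param geometry a [beam_geometry()].
#' @param gantry gantry angle, degrees.
#' @param pitch BEV pixel pitch at the isocenter plane, mm (<= 1).
#' @param pad extra margin around the projected extent, mm.
#' @return object of class `bev_image`: list with `values` (binary matrix,
#'   rows = leaf-travel axis x, cols = leaf-stack axis z), `pitch`, `x0`,
#'   `z0` (mm of the center of pixel \[1, 1\]), and `gantry`.
#' @export
bev_project <- function(mask, spacing, origin, geometry, gantry,
                        pitch = 1, pad = 15) {
  if (!any(mask)) stop("empty target")
  idx <- which(mask, arr.ind = TRUE)
  w <- sweep(sweep(idx - 1, 2, spacing, "*"), 2, origin, "+")
  b <- bev_basis(gantry)
  src <- geometry$iso + geometry$sad * b$src_dir
  rel <- sweep(w, 2, geometry$iso, "-")
  daxis <- geometry$sad - rel %*% b$src_dir  # depth of voxel plane from source
  if (any(daxis <= 0)) stop("mask voxels behind the source")
  magnif <- geometry$sad / as.numeric(daxis)
  xb <- as.numeric(rel %*% b$ex) * magnif
  zb <- as.numeric(rel %*% b$ez) * magnif
  x0 <- floor((min(xb) - pad) / pitch) * pitch
  z0 <- floor((min(zb) - pad) / pitch) * pitch
  nxp <- ceiling((max(xb) + pad - x0) / pitch) + 1
  nzp <- ceiling((max(zb) + pad - z0) / pitch) + 1
  img <- matrix(FALSE, nxp, nzp)
  ix <- pmin(pmax(round((xb - x0) / pitch) + 1, 1), nxp)
  iz <- pmin(pmax(round((zb - z0) / pitch) + 1, 1), nzp)
  img[cbind(ix, iz)] <- TRUE
  structure(list(values = img, pitch = pitch, x0 = x0, z0 = z0,
                 gantry = gantry),
            class = "bev_image")
}

#' Fit MLC leaf positions to a BEV aperture
#'
#' Each leaf pair covers a band of height `leaf_width_iso` along the BEV z
#' axis (leaf boundaries symmetric about z = 0). Within each band the pair
#' opens from the minimum to the maximum open-pixel extent (pixel edges),
#' widened by `margin_mm` on both sides; bands with no open pixel stay
#' closed.
#'
#' @param bev a [bev_project()] result.
#' @param geometry a [beam_geometry()].
#' @param margin_mm aperture margin added to each open edge (may be negative).
#' @return object of class `cp_aperture`: list with `gantry` and `leaves`, a
#'   tibble with columns `pair`, `z_lo`, `z_hi`, `open`, `left`, `right`
#'   (mm at the isocenter plane).
#' @export
fit_mlc <- function(bev, geometry, margin_mm = 0) {
  stopifnot(inherits(bev, "bev_image"))
  if (!any(bev$values)) stop("empty aperture")
  w <- geometry$leaf_width_iso
  npairs <- geometry$n_leaf_pairs
  z_lo <- (seq_len(npairs) - 1 - npairs / 2) * w
  z_hi <- z_lo + w
  op <- which(bev$values, arr.ind = TRUE)
  px <- bev$x0 + (op[, 1] - 1) * bev$pitch
  pz <- bev$z0 + (op[, 2] - 1) * bev$pitch
  band <- floor((pz - z_lo[1]) / w) + 1
  keep <- band >= 1 & band <= npairs
  px <- px[keep]; band <- band[keep]
  left <- rep(NA_real_, npairs)
  right <- rep(NA_real_, npairs)
  if (length(px)) {
    mn <- tapply(px, band, min)
    mx <- tapply(px, band, max)
    bi <- as.integer(names(mn))
    left[bi] <- mn - bev$pitch / 2 - margin_mm
    right[bi] <- mx + bev$pitch / 2 + margin_mm
  }
  open <- !is.na(left) & right > left
  left[!open] <- NA_real_
  right[!open] <- NA_real_
  structure(list(gantry = bev$gantry,
                 leaves = tibble::tibble(pair = seq_len(npairs),
                                         z_lo = z_lo, z_hi = z_hi,
                                         open = open, left = left,
                                         right = right)),
            class = "cp_aperture")
}

#' @export
print.cp_aperture <- function(x, ...) {
  nopen <- sum(x$leaves$open)
  cat(sprintf("<cp_aperture> gantry %.1f deg, %d open leaf pairs, area %.1f cm^2\n",
              x$gantry, nopen, aperture_area_cm2(x)))
  invisible(x)
}

#' Open area of an MLC aperture (cm^2, isocenter plane)
#' @param aperture a `cp_aperture`.
#' @export
aperture_area_cm2 <- function(aperture) {
  lv <- aperture$leaves
  sum((lv$right - lv$left)[lv$open] * (lv$z_hi - lv$z_lo)[lv$open]) / 100
}

#' Serialize apertures to JSON
#' @param apertures list of `cp_aperture`.
#' @param path output path.
#' @export
write_apertures <- function(apertures, path) {
  jsonlite::write_json(
    lapply(apertures, function(a)
      list(gantry = a$gantry,
           leaves = a$leaves[a$leaves$open,
                             c("pair", "z_lo", "z_hi", "left", "right")])),
    path, auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(path)
}

# Rasterize a fitted MLC aperture to a transmission image (0/1) on a pixel
# grid padded enough for penumbra blurring, then optionally blur with a 2-D
# Gaussian of standard deviation sigma_mm (the penumbra model).
rasterize_aperture <- function(aperture, pitch = 1, sigma_mm = 0, pad = NULL) {
  lv <- aperture$leaves[aperture$leaves$open, ]
  if (nrow(lv) == 0) stop("empty aperture")
  if (is.null(pad)) pad <- 5 * sigma_mm + 5
  x0 <- floor((min(lv$left) - pad) / pitch) * pitch
  x1 <- max(lv$right) + pad
  z0 <- floor((min(lv$z_lo) - pad) / pitch) * pitch
  z1 <- max(lv$z_hi) + pad
  nx <- ceiling((x1 - x0) / pitch) + 1
  nz <- ceiling((z1 - z0) / pitch) + 1
  xs <- x0 + (seq_len(nx) - 1) * pitch
  zs <- z0 + (seq_len(nz) - 1) * pitch
  img <- matrix(0, nx, nz)
  for (r in seq_len(nrow(lv))) {
    zi <- which(zs >= lv$z_lo[r] & zs < lv$z_hi[r])
    if (!length(zi)) next
    xi <- which(xs >= lv$left[r] & xs <= lv$right[r])
    img[xi, zi] <- 1
  }
  if (sigma_mm > 0) img <- gaussian_blur2d(img, sigma_mm / pitch)
  list(values = img, pitch = pitch, x0 = x0, z0 = z0)
}

# Separable 2-D Gaussian blur (zero-padded borders), sigma in pixels.
gaussian_blur2d <- function(img, sigma_px) {
  if (sigma_px <= 0) return(img)
  r <- max(1L, ceiling(4 * sigma_px))
  k <- exp(-((-r:r)^2) / (2 * sigma_px^2))
  k <- k / sum(k)
  conv1 <- function(m) {
    # convolve each column with k, zero padding
    nr <- nrow(m)
    out <- matrix(0, nr, ncol(m))
    for (o in -r:r) {
      src <- seq_len(nr) + o
      ok <- src >= 1 & src <= nr
      out[ok, ] <- out[ok, ] + k[o + r + 1] * m[src[ok], ]
    }
    out
  }
  t(conv1(t(conv1(img))))
}
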