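# Synthetic thoracic phantom generation.
#
# The phantom emulates the study conditions of a 20-case early-stage NSCLC
# SBRT cohort: ITV volumes spanning 0.56-69.39 cc (right-skewed, so sampled
# log-uniformly), PTV = ITV + 5 mm isotropic expansion, central/peripheral
# placements in the left or right lung, and fractionations 3x18 / 5x11 /
# 8x7.5 Gy. Densities are typical CT-derived values: body 1.0, lung 0.26,
# tumor 1.0 (relative electron density, water = 1); air outside the body is 0.

ITV_CC_RANGE <- c(0.56, 69.39)

run_seeded <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv()))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Analytic tumor shapes, centered at the origin. Each returns an inside test
# f(x, y, z) plus per-axis half extents (mm). Sizes are solved from the
# requested ITV volume in cc.
tumor_shape <- function(shape, itv_cc, axis_ratio = 3) {
  v_mm3 <- itv_cc * 1000
  switch(shape,
    sphere = {
      r <- (3 * v_mm3 / (4 * pi))^(1 / 3)
      list(inside = function(x, y, z) x^2 + y^2 + z^2 <= r^2,
           extent = c(r, r, r))
    },
    ellipsoid = {
      # prolate along the inferior-superior axis, semi-axes s, s, ratio*s
      s <- (3 * v_mm3 / (4 * pi * axis_ratio))^(1 / 3)
      a <- c(s, s, axis_ratio * s)
      list(inside = function(x, y, z)
             (x / a[1])^2 + (y / a[2])^2 + (z / a[3])^2 <= 1,
           extent = a)
    },
    bilobed = {
      # two overlapping equal spheres along z, centers 1.4 r apart (concave)
      sep_f <- 1.4
      lens <- pi * (4 + sep_f) * (2 - sep_f)^2 / 12  # in units of r^3
      vol_f <- 2 * (4 / 3) * pi - lens               # union volume / r^3
      r <- (v_mm3 / vol_f)^(1 / 3)
      h <- sep_f * r / 2
      list(inside = function(x, y, z)
             (x^2 + y^2 + (z - h)^2 <= r^2) | (x^2 + y^2 + (z + h)^2 <= r^2),
           extent = c(r, r, h + r))
    },
    capped_cylinder = {
      # cylinder of radius rho, half-length 1.5 rho, hemispherical caps
      rho <- (3 * v_mm3 / (13 * pi))^(1 / 3)
      h <- 1.5 * rho
      list(inside = function(x, y, z) {
             r2 <- x^2 + y^2
             (r2 <= rho^2 & abs(z) <= h) |
               (r2 + (abs(z) - h)^2 <= rho^2 & abs(z) > h)
           },
           extent = c(rho, rho, h + rho))
    },
    stop("unknown tumor shape: ", shape)
  )
}

#' Specification of a synthetic thoracic phantom
#'
#' Describes one case: an elliptic body, two elliptic lungs, and a tumor
#' (the ITV) of a given shape and volume placed inside one lung. All lengths
#' in mm, densities relative to water.
#'
#' @param shape one of `"sphere"`, `"ellipsoid"` (3:1 prolate), `"bilobed"`
#'   (two overlapping spheres, concave), `"capped_cylinder"`.
#' @param itv_cc target ITV volume in cc (0.56-69.39 in the emulated cohort).
#' @param laterality `"left"` or `"right"` lung.
#' @param placement `"central"` (near the lung center) or `"peripheral"`.
#' @param center optional explicit tumor center (world mm); when `NULL` the
#'   center is drawn reproducibly from `seed`.
#' @param spacing voxel spacing mm (scalar or length 3). Default 2 mm;
#'   use 3 mm with `n = 64` for a coarse preset.
#' @param grid_n grid size per axis (scalar or length 3). Default 128.
#' @param seed integer; fixes every stochastic choice for this case.
#' @param densities named numeric: `body`, `lung`, `tumor` relative densities.
#' @param axis_ratio long/short axis ratio for the ellipsoid shape.
#' @param ptv_margin_mm isotropic ITV-to-PTV expansion (default 5 mm).
#' @param fractionation a [fractionation_scheme()].
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = "sphere", itv_cc = 7.35,
                         laterality = c("left", "right"),
                         placement = c("peripheral", "central"),
                         center = NULL,
                         spacing = 2, grid_n = 128, seed = 1L,
                         densities = c(body = 1.0, lung = 0.26, tumor = 1.0),
                         axis_ratio = 3, ptv_margin_mm = 5,
                         fractionation = fractionation_scheme(18, 3)) {
  laterality <- match.arg(laterality)
  placement <- match.arg(placement)
  stopifnot(itv_cc > 0, ptv_margin_mm >= 0,
            all(densities > 0), all(densities <= 2))
  if (length(spacing) == 1) spacing <- rep(spacing, 3)
  if (length(grid_n) == 1) grid_n <- rep(grid_n, 3)
  if (any(grid_n < 8)) stop("grid must be at least 8 voxels per axis")
  structure(list(shape = shape, itv_cc = itv_cc, laterality = laterality,
                 placement = placement, center = center,
                 spacing = as.numeric(spacing), n = as.integer(grid_n),
                 seed = as.integer(seed), densities = densities,
                 axis_ratio = axis_ratio, ptv_margin_mm = ptv_margin_mm,
                 fractionation = fractionation,
                 body_semi_axes = c(84, 72, 92),
                 lung_semi_axes = c(34, 48, 70),
                 lung_offset = c(44, 6, 0)),
            class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("<phantom_spec> %s, ITV %.2f cc, %s lung (%s), %g mm voxels, seed %d\n",
              x$shape, x$itv_cc, x$laterality, x$placement,
              x$spacing[1], x$seed))
  invisible(x)
}

#' Serialize a phantom spec to YAML
#' @param spec a `phantom_spec`.
#' @param path file path.
#' @export
write_phantom_spec <- function(spec, path) {
  x <- unclass(spec)
  x$fractionation <- unclass(x$fractionation)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' Fractionation scheme
#' @param dose_per_fraction_gy dose per fraction, Gy.
#' @param n_fractions number of fractions.
#' @return list with `dose_per_fraction_gy`, `n_fractions`, `total_gy`.
#' @export
fractionation_scheme <- function(dose_per_fraction_gy, n_fractions) {
  stopifnot(dose_per_fraction_gy > 0, n_fractions >= 1)
  structure(list(dose_per_fraction_gy = dose_per_fraction_gy,
                 n_fractions = as.integer(n_fractions),
                 total_gy = dose_per_fraction_gy * n_fractions),
            class = "fractionation_scheme")
}

coord_arrays <- function(n, spacing, origin) {
  ax <- lapply(1:3, function(a) origin[a] + (seq_len(n[a]) - 1) * spacing[a])
  list(
    x = array(rep(ax[[1]], times = n[2] * n[3]), n),
    y = array(rep(rep(ax[[2]], each = n[1]), times = n[3]), n),
    z = array(rep(ax[[3]], each = n[1] * n[2]), n)
  )
}

ellipsoid_mask <- function(co, center, semi) {
  ((co$x - center[1]) / semi[1])^2 + ((co$y - center[2]) / semi[2])^2 +
    ((co$z - center[3]) / semi[3])^2 <= 1
}

place_tumor <- function(spec, shp) {
  side <- if (spec$laterality == "left") -1 else 1
  lung_center <- spec$lung_offset * c(side, 1, 1)
  eff <- spec$lung_semi_axes - shp$extent - 2  # 2 mm safety margin
  if (any(eff <= 0)) return(lung_center)
  rho_rng <- if (spec$placement == "central") c(0, 0.3) else c(0.45, 0.75)
  u <- stats::rnorm(3)
  u <- u / sqrt(sum(u^2))
  rho <- stats::runif(1, rho_rng[1], rho_rng[2])
  for (shrink in 0.8^(0:19)) {
    p <- lung_center + u * rho * shrink * eff
    # conservative containment: center offset within the per-axis shrunken lung
    m <- sum(((p - lung_center) / eff)^2)
    if (m <= 1) return(p)
  }
  lung_center
}

#' Build a synthetic thoracic phantom
#'
#' Voxelizes the body, lungs and tumor of a [phantom_spec()] with the
#' center-inclusion rule (a voxel belongs to a mask iff its center lies inside
#' the analytic shape) and derives the PTV as the isotropic Euclidean
#' `ptv_margin_mm` expansion of the ITV, clipped to the grid and body.
#'
#' @param spec a [phantom_spec()].
#' @return list with `grid` (density [image_grid()]) and `structures`
#'   (a [structure_set()] with masks `body`, `lung_left`, `lung_right`,
#'   `itv`, `ptv`).
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  n <- spec$n
  spacing <- spec$spacing
  origin <- -(n - 1) * spacing / 2
  shp <- tumor_shape(spec$shape, spec$itv_cc, spec$axis_ratio)
  if (any(2 * shp$extent / spacing < 3))
    stop("spacing too coarse to resolve tumor (< 3 voxels across)")
  center <- spec$center
  if (is.null(center))
    center <- run_seeded(spec$seed, place_tumor(spec, shp))

  co <- coord_arrays(n, spacing, origin)
  body <- ellipsoid_mask(co, c(0, 0, 0), spec$body_semi_axes)
  lung_l <- ellipsoid_mask(co, spec$lung_offset * c(-1, 1, 1),
                           spec$lung_semi_axes) & body
  lung_r <- ellipsoid_mask(co, spec$lung_offset, spec$lung_semi_axes) & body
  itv <- array(shp$inside(co$x - center[1], co$y - center[2],
                          co$z - center[3]), n)
  if (!any(itv)) stop("ITV empty after voxelization; refine the grid")
  lungs <- lung_l | lung_r
  n_out <- sum(itv & !lungs)
  if (n_out > 0)
    stop(sprintf("tumor outside lung: %d of %d ITV voxels fall outside the lungs (center %s)",
                 n_out, sum(itv), paste(round(center, 1), collapse = ", ")))
  ptv <- (distance_mm(itv, spacing) <= spec$ptv_margin_mm) & body

  dens <- array(0, n)
  dens[body] <- spec$densities[["body"]]
  dens[lungs] <- spec$densities[["lung"]]
  dens[itv] <- spec$densities[["tumor"]]

  grid <- image_grid(dens, spacing, origin)
  structures <- structure_set(
    list(body = body, lung_left = lung_l, lung_right = lung_r,
         itv = itv, ptv = ptv),
    spacing, origin
  )
  list(grid = grid, structures = structures, tumor_center = center,
       spec = spec)
}

#' Sample a cohort of phantom specifications
#'
#' Draws `n` cases emulating the target mix of an early-stage lung SBRT
#' cohort: ITV volumes log-uniform on 0.56-69.39 cc, a mix of shapes with at
#' least one concave (bilobed) target per 5 cases, varied laterality and
#' placement, and fractionation schemes 3x18 / 5x11 / 8x7.5 Gy in roughly
#' 7:8:5 proportion.
#'
#' Volumes are redrawn (from the same log-uniform law, effectively truncated)
#' for cases whose shape would be too thin to resolve at the requested voxel
#' spacing (< 3 voxels across the smallest extent), so every generated case
#' passes [make_phantom()]'s resolution guard.
#'
#' @param n number of cases (>= 1).
#' @param seed integer seed fixing the whole draw.
#' @param ... further arguments passed to [phantom_spec()] (e.g. `spacing`,
#'   `grid_n`).
#' @return list of `phantom_spec` objects.
#' @export
sample_cohort <- function(n, seed = 1L, ...) {
  stopifnot(n >= 1)
  run_seeded(seed, {
    itv_cc <- exp(stats::runif(n, log(ITV_CC_RANGE[1]), log(ITV_CC_RANGE[2])))
    shapes <- sample(c("sphere", "ellipsoid", "bilobed", "capped_cylinder"),
                     n, replace = TRUE)
    # guarantee at least one bilobed target per block of 5 cases
    for (b in seq_len(ceiling(n / 5))) {
      idx <- ((b - 1) * 5 + 1):min(b * 5, n)
      if (!any(shapes[idx] == "bilobed"))
        shapes[sample(idx, 1)] <- "bilobed"
    }
    lat <- sample(c("left", "right"), n, replace = TRUE, prob = c(0.6, 0.4))
    plc <- sample(c("central", "peripheral"), n, replace = TRUE,
                  prob = c(0.35, 0.65))
    fx <- sample(1:3, n, replace = TRUE, prob = c(7, 8, 5) / 20)
    schemes <- list(fractionation_scheme(18, 3), fractionation_scheme(11, 5),
                    fractionation_scheme(7.5, 8))
    lapply(seq_len(n), function(i) {
      sp <- phantom_spec(shape = shapes[i], itv_cc = itv_cc[i],
                         laterality = lat[i], placement = plc[i],
                         seed = (seed * 10007L + i) %% 2147483629L,
                         fractionation = schemes[[fx[i]]], ...)
      resolvable <- function(v)
        all(2 * tumor_shape(sp$shape, v, sp$axis_ratio)$extent / sp$spacing >= 3)
      tries <- 0
      while (!resolvable(sp$itv_cc) && tries < 100) {
        sp$itv_cc <- exp(stats::runif(1, log(ITV_CC_RANGE[1]),
                                      log(ITV_CC_RANGE[2])))
        tries <- tries + 1
      }
      sp
    })
  })
}
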