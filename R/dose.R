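# Simplified arc dose engine.
#
# This is a declared, minimal model -- not a clinical convolution/superposition
# algorithm. Per control point, each voxel receives
#   T(v) * f(r) * exp(-mu_eff * d_eff(v)) * (SAD / dist(source, v))^2
# where T is the MLC aperture transmission at the voxel's BEV position after a
# 2-D Gaussian penumbra blur, f(r) = max(0, 1 - k r) is an unflattened (FFF)
# cone profile in off-axis distance r at the isocenter plane, and d_eff is the
# radiological path length (line integral of relative electron density from
# the body surface to the voxel along the source ray). A plan dose is the
# equally weighted sum over control points (constant dose rate), times the
# plan's normalization scale. The model reproduces the qualitative failure
# modes of conformal arcs (hot shell hugging the PTV, cold tips along the leaf
# stack) without scatter kernels or electron transport.

#' Simplified beam model
#'
#' @param mu_eff effective linear attenuation per mm of water-equivalent
#'   depth (default 0.0046/mm, nominal 6 MV).
#' @param penumbra_sigma Gaussian penumbra width at the isocenter plane, mm.
#' @param fff_k slope of the unflattened radial fluence profile
#'   `f(r) = max(0, 1 - fff_k * r)`, per mm.
#' @return object of class `beam_model`.
#' @export
beam_model <- function(mu_eff = 0.0046, penumbra_sigma = 3.0,
                       fff_k = 0.0015) {
  stopifnot(mu_eff > 0, penumbra_sigma >= 0, fff_k >= 0)
  structure(list(mu_eff = mu_eff, penumbra_sigma = penumbra_sigma,
                 fff_k = fff_k),
            class = "beam_model")
}

#' Dose from a single arc control point
#'
#' @param density density [image_grid()] (relative electron density, zero
#'   outside the body).
#' @param aperture a fitted [fit_mlc()] aperture (`cp_aperture`).
#' @param geometry a [beam_geometry()].
#' @param beam a [beam_model()].
#' @param step ray-marching step, mm; default half the smallest voxel spacing.
#' @param pitch transmission-image pixel pitch, mm.
#' @return dose [image_grid()] (arbitrary units before normalization).
#' @export
compute_cp_dose <- function(density, aperture, geometry, beam,
                            step = NULL, pitch = 1) {
  stopifnot(inherits(density, "image_grid"), inherits(aperture, "cp_aperture"))
  if (is.null(step)) step <- min(density$spacing) / 2
  tr <- rasterize_aperture(aperture, pitch = pitch,
                           sigma_mm = beam$penumbra_sigma)
  b <- bev_basis(aperture$gantry)
  src <- geometry$iso + geometry$sad * b$src_dir
  v <- cp_dose_cpp(as.numeric(density$values), as.integer(dim(density$values)),
                   density$spacing, density$origin,
                   tr$values, tr$x0, tr$z0, tr$pitch,
                   src, geometry$iso, b$ex, b$ez,
                   geometry$sad, beam$mu_eff, beam$fff_k, step, 1e-7)
  image_grid(array(v, dim(density$values)), density$spacing, density$origin)
}

#' Total plan dose
#'
#' Equally weighted sum of per-control-point doses, scaled by the plan's
#' normalization factor.
#'
#' @param density density [image_grid()].
#' @param plan a [plan_dca()] plan.
#' @param beam a [beam_model()].
#' @param step,pitch passed to [compute_cp_dose()].
#' @return dose [image_grid()].
#' @export
compute_plan_dose <- function(density, plan, beam, step = NULL, pitch = 1) {
  stopifnot(inherits(plan, "dca_plan"))
  total <- array(0, dim(density$values))
  for (ap in plan$apertures) {
    cp <- compute_cp_dose(density, ap, plan$geometry, beam,
                          step = step, pitch = pitch)
    total <- total + cp$values
  }
  image_grid(total * plan$normalization_scale / length(plan$apertures),
             density$spacing, density$origin)
}
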