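#' Build a conventional dynamic conformal arc plan
#'
#' At every control point of the arc, the MLC aperture is fitted to the
#' beam's-eye-view projection of the target with the given margin (0 mm by
#' convention for conformal arc SBRT). The isocenter is placed at the
#' target's centroid.
#'
#' @param structures a [structure_set()].
#' @param target_name name of the aperture-fitting target mask (e.g. `"ptv"`).
#' @param arc an [arc_spec()].
#' @param geometry a [beam_geometry()]; its isocenter is replaced by the
#'   target centroid.
#' @param margin_mm MLC margin around the BEV silhouette, mm.
#' @param prescription a [fractionation_scheme()].
#' @param pitch BEV pixel pitch, mm.
#' @return object of class `dca_plan`.
#' @export
plan_dca <- function(structures, target_name = "ptv", arc = arc_spec(),
                     geometry = beam_geometry(), margin_mm = 0,
                     prescription = fractionation_scheme(18, 3), pitch = 1) {
  target <- structures$masks[[target_name]]
  if (is.null(target) || !any(target)) stop("empty target: ", target_name)
  idx <- which(target, arr.ind = TRUE)
  centroid <- structures$origin +
    (colMeans(idx) - 1) * structures$spacing
  geometry$iso <- as.numeric(centroid)
  angles <- make_arc(arc)
  apertures <- lapply(angles, function(g) {
    bev <- bev_project(target, structures$spacing, structures$origin,
                       geometry, g, pitch = pitch)
    fit_mlc(bev, geometry, margin_mm)
  })
  structure(list(arc = arc, geometry = geometry, apertures = apertures,
                 target_name = target_name, prescription = prescription,
                 margin_mm = margin_mm, normalization_scale = 1),
            class = "dca_plan")
}

#' @export
print.dca_plan <- function(x, ...) {
  cat(sprintf("<dca_plan> %d control points over %g deg, target '%s', Rx %g Gy x %d, scale %.4g\n",
              length(x$apertures), x$arc$span, x$target_name,
              x$prescription$dose_per_fraction_gy,
              x$prescription$n_fractions, x$normalization_scale))
  invisible(x)
}

#' Aperture areas of a plan as a tibble
#' @param x a `dca_plan`.
#' @param ... unused.
#' @export
tidy.dca_plan <- function(x, ...) {
  tibble::tibble(
    gantry = vapply(x$apertures, function(a) a$gantry, numeric(1)),
    open_pairs = vapply(x$apertures, function(a) sum(a$leaves$open), numeric(1)),
    area_cm2 = vapply(x$apertures, aperture_area_cm2, numeric(1))
  )
}

#' Normalize a dose grid to target coverage
#'
#' Rescales the dose so that at least `coverage` of the target receives the
#' prescription dose, with the smallest such scale: `scale = rx / D`, where
#' `D` is the `ceiling(coverage * n)`-th largest in-target voxel dose. Dose
#' scaling is linear, so this analytic rescaling is exact; the fraction of
#' target voxels at or above `rx` afterwards lies in
#' `[coverage, coverage + 1/n]` for continuously distributed dose.
#'
#' @param dose dose [image_grid()], positive somewhere in the target.
#' @param target_mask logical array (the ORIGINAL planning target).
#' @param coverage required covered fraction (default 0.95).
#' @param rx prescription dose in the dose grid's unit (default 100, i.e.
#'   normalized dose is expressed in % of prescription).
#' @return list with `dose` (scaled [image_grid()]), `scale`, and
#'   `rx_isodose_level` (`rx` as a fraction of the scaled maximum dose).
#' @export
normalize_to_coverage <- function(dose, target_mask, coverage = 0.95,
                                  rx = 100) {
  stopifnot(inherits(dose, "image_grid"), any(target_mask))
  d <- dose$values[target_mask]
  n <- length(d)
  if (mean(d <= 0) > 1 - coverage) stop("coverage unattainable")
  k <- ceiling(coverage * n)
  dk <- sort(d, decreasing = TRUE)[k]
  if (dk <= 0) stop("coverage unattainable")
  # nudge by 1 ulp-scale so the k-th voxel itself lands at >= rx despite
  # floating-point rounding of the quotient
  scale <- (rx / dk) * (1 + 1e-12)
  scaled <- image_grid(dose$values * scale, dose$spacing, dose$origin)
  list(dose = scaled, scale = scale,
       rx_isodose_level = rx / max(scaled$values))
}

dvh_dx <- function(doses_sorted_desc, x_pct) {
  # dose received by at least x% of the volume, interpolated on sorted doses
  n <- length(doses_sorted_desc)
  as.numeric(quantile(doses_sorted_desc, probs = 1 - x_pct / 100,
                      names = FALSE, type = 7))
}

#' Cumulative dose-volume histogram
#'
#' Cumulative DVH by voxel counting, with ICRU-style statistics computed
#' directly on the sorted in-mask voxel doses (bins are used only for the
#' exported curve; bin width `max(0.1, Dmax/2000)` in the dose unit).
#'
#' @param dose dose [image_grid()].
#' @param mask logical array, non-empty.
#' @param structure name recorded with the curve.
#' @return object of class `dvh`: list with `curve` (tibble `dose`,
#'   `volume_frac`) and `stats` (tibble with `d2`, `d50`, `d98`, `dmax`,
#'   `dmean`), plus `structure` and `n_voxels`. Use [dvh_v()] for Vx.
#' @export
compute_dvh <- function(dose, mask, structure = "structure") {
  if (!any(mask)) stop("empty mask")
  d <- dose$values[mask]
  dmax <- max(d)
  bw <- max(0.1, dmax / 2000)
  edges <- seq(0, dmax + bw, by = bw)
  vol <- vapply(edges, function(e) mean(d >= e), numeric(1))
  sd_desc <- sort(d, decreasing = TRUE)
  structure(list(
    structure = structure,
    n_voxels = length(d),
    curve = tibble::tibble(dose = edges, volume_frac = vol),
    stats = tibble::tibble(
      d2 = dvh_dx(sd_desc, 2), d50 = dvh_dx(sd_desc, 50),
      d98 = dvh_dx(sd_desc, 98), dmax = dmax, dmean = mean(d)),
    doses = sd_desc
  ), class = "dvh")
}

#' Volume fraction receiving at least a dose
#' @param dvh a [compute_dvh()] object.
#' @param x dose threshold (same unit as the DVH).
#' @return fraction of the structure volume with dose >= x.
#' @export
dvh_v <- function(dvh, x) mean(dvh$doses >= x)

#' @export
print.dvh <- function(x, ...) {
  s <- x$stats
  cat(sprintf("<dvh> %s (%d voxels): D2=%.2f D50=%.2f D98=%.2f Dmax=%.2f Dmean=%.2f\n",
              x$structure, x$n_voxels, s$d2, s$d50, s$d98, s$dmax, s$dmean))
  invisible(x)
}

#' @export
tidy.dvh <- function(x, ...) x$curve

#' @export
glance.dvh <- function(x, ...) x$stats

#' Plot a cumulative DVH
#' @param object a `dvh` (or list of them).
#' @param ... unused.
#' @export
autoplot.dvh <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(.data$dose, .data$volume_frac)) +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::labs(x = "Dose", y = "Fractional volume",
                  title = object$structure) +
    ggplot2::theme_minimal()
}

#' Export DVH curves to CSV
#' @param dvhs named list of `dvh` objects.
#' @param path output CSV.
#' @export
write_dvh_csv <- function(dvhs, path) {
  rows <- dplyr::bind_rows(lapply(dvhs, function(d)
    dplyr::mutate(d$curve, structure = d$structure)))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
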