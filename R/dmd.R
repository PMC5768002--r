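# Deformable margin delineation (DMD), automated.
#
# The clinical procedure deforms the aperture-fitting target slice by slice
# by hand: shrink the PTV where the conformal arc plan is hot outside it,
# expand it where the plan is cold inside it, re-plan, and renormalize so the
# prescription still covers 95% of the ORIGINAL PTV. This module replaces the
# manual contouring with a morphological update of the target mask, iterated
# to a tolerance or an iteration cap, keeping the iteration with the best
# conformity index (a manual planner implicitly stops at the best attempt).

#' Parameters of the automated margin deformation
#'
#' @param step_mm deformation step per iteration, mm; `NULL` means one voxel
#'   (the largest spacing component).
#' @param max_iters maximum number of deformation rounds (>= 1).
#' @param stop_tol_cc stop when both the hot and the cold volume are at or
#'   below this, cc.
#' @param smooth_radius_mm morphological closing radius applied to the
#'   deformed target, mm.
#' @param allow_below_itv if `FALSE` (default) the deformed target is forced
#'   to contain the ITV.
#' @return object of class `dmd_params`.
#' @export
dmd_params <- function(step_mm = NULL, max_iters = 10, stop_tol_cc = 0.2,
                       smooth_radius_mm = 2, allow_below_itv = FALSE) {
  stopifnot(is.null(step_mm) || step_mm > 0, max_iters >= 1,
            stop_tol_cc >= 0, smooth_radius_mm >= 0)
  structure(list(step_mm = step_mm, max_iters = as.integer(max_iters),
                 stop_tol_cc = stop_tol_cc,
                 smooth_radius_mm = smooth_radius_mm,
                 allow_below_itv = allow_below_itv),
            class = "dmd_params")
}

#' Classify hot and cold dose regions around the PTV
#'
#' Hot: voxels at or above the prescription dose outside the original PTV
#' (inside the body). Cold: voxels below the prescription dose inside the
#' original PTV.
#'
#' @param dose normalized dose [image_grid()].
#' @param ptv logical mask of the ORIGINAL planning target.
#' @param body logical body mask.
#' @param rx prescription dose in the grid's unit.
#' @return object of class `hot_cold`: list with logical masks `hot`, `cold`
#'   and volumes `hot_cc`, `cold_cc`.
#' @export
find_hot_cold <- function(dose, ptv, body, rx = 100) {
  hot <- (dose$values >= rx) & !ptv & body
  cold <- (dose$values < rx) & ptv
  structure(list(hot = hot, cold = cold,
                 hot_cc = mask_volume_cc(hot, dose$spacing),
                 cold_cc = mask_volume_cc(cold, dose$spacing)),
            class = "hot_cold")
}

#' @export
print.hot_cold <- function(x, ...) {
  cat(sprintf("<hot_cold> hot %.2f cc, cold %.2f cc\n", x$hot_cc, x$cold_cc))
  invisible(x)
}

#' Deform the aperture-fitting target toward the hot/cold pattern
#'
#' Shrinks the current target where hot regions touch its surface (removal
#' restricted to a surface band of depth `step_mm`, so distant hot islands
#' cannot punch holes in the interior) and expands it around cold regions
#' (addition limited to `step_mm` around the cold voxels), then smooths with
#' a morphological closing. The result is clipped to the body and, unless
#' `allow_below_itv`, forced to contain the ITV.
#'
#' @param current logical mask, the current aperture-fitting target.
#' @param regions a [find_hot_cold()] result.
#' @param params a [dmd_params()].
#' @param itv logical ITV mask.
#' @param body logical body mask.
#' @param spacing voxel spacing, mm.
#' @return logical mask, the new target.
#' @export
deform_target <- function(current, regions, params, itv, body, spacing) {
  if (!any(current)) stop("target collapsed")
  step <- params$step_mm
  if (is.null(step)) step <- max(spacing)
  grown <- current | dilate_mm(regions$cold, step, spacing)
  shrink_zone <- dilate_mm(regions$hot, step, spacing) &
    boundary_band(current, step, spacing)
  new <- grown & !shrink_zone
  new <- close_mm(new, params$smooth_radius_mm, spacing)
  new <- new & body
  if (!params$allow_below_itv) new <- new | itv
  if (!any(new)) stop("target collapsed")
  new
}

#' Run the full DCA-DMD loop on one case
#'
#' Iteration 0 is the conventional conformal arc plan on the PTV. Each
#' subsequent iteration classifies hot/cold regions against the ORIGINAL PTV,
#' deforms the aperture-fitting target, re-plans the conformal arc on the
#' deformed target, and renormalizes the dose so the prescription covers 95%
#' of the ORIGINAL PTV. The loop stops when both the hot and cold volumes
#' fall to `stop_tol_cc` or after `max_iters` rounds; the returned plan is
#' the iteration with the best (lowest) conformity index, ties resolved
#' toward fewer iterations. Failures inside the loop (collapsed target,
#' unattainable coverage) return the best previous iteration with a warning
#' flag.
#'
#' @param density density [image_grid()].
#' @param structures a [structure_set()] with `itv`, `ptv`, `body`, lungs.
#' @param arc an [arc_spec()].
#' @param geometry a [beam_geometry()].
#' @param beam a [beam_model()].
#' @param params a [dmd_params()].
#' @param prescription a [fractionation_scheme()].
#' @param coverage coverage fraction of the original PTV (default 0.95).
#' @param rx prescription level of the normalized dose (default 100).
#' @return object of class `dmd_result`: list with `best_plan`, `best_dose`
#'   (normalized), `best_target` (mask), `best_iteration`, `history`
#'   (tibble of per-iteration plan metrics + hot/cold volumes), `warning`
#'   (character or `NA`), and the conventional-arc baseline under
#'   `baseline_dose`.
#' @export
run_dmd <- function(density, structures, arc = arc_spec(),
                    geometry = beam_geometry(), beam = beam_model(),
                    params = dmd_params(),
                    prescription = fractionation_scheme(18, 3),
                    coverage = 0.95, rx = 100) {
  m <- structures$masks
  stopifnot(!is.null(m$itv), !is.null(m$ptv), !is.null(m$body))
  ptv0 <- m$ptv
  spacing <- structures$spacing

  plan_and_eval <- function(target_mask, iter) {
    ss <- structures
    ss$masks$dmd_target <- target_mask
    plan <- plan_dca(ss, "dmd_target", arc, geometry,
                     margin_mm = 0, prescription = prescription)
    raw <- compute_plan_dose(density, plan, beam)
    nrm <- normalize_to_coverage(raw, ptv0, coverage, rx)
    plan$normalization_scale <- nrm$scale
    hc <- find_hot_cold(nrm$dose, ptv0, m$body, rx)
    met <- evaluate_plan(nrm$dose, structures, prescription, rx)
    met <- dplyr::mutate(met, iteration = iter, hot_cc = hc$hot_cc,
                         cold_cc = hc$cold_cc,
                         rx_isodose_level = nrm$rx_isodose_level,
                         target_cc = mask_volume_cc(target_mask, spacing),
                         .before = 1)
    list(plan = plan, dose = nrm$dose, hc = hc, metrics = met,
         target = target_mask)
  }

  iters <- list(plan_and_eval(ptv0, 0L))
  warn <- NA_character_
  target <- ptv0
  for (it in seq_len(params$max_iters)) {
    hc <- iters[[length(iters)]]$hc
    if (hc$hot_cc <= params$stop_tol_cc && hc$cold_cc <= params$stop_tol_cc)
      break
    res <- tryCatch({
      target <- deform_target(target, hc, params, m$itv, m$body, spacing)
      plan_and_eval(target, it)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      warn <- conditionMessage(res)
      break
    }
    iters[[length(iters) + 1]] <- res
  }

  history <- dplyr::bind_rows(lapply(iters, `[[`, "metrics"))
  best <- which.min(history$ci)  # ties: which.min takes the earliest
  structure(list(
    best_plan = iters[[best]]$plan,
    best_dose = iters[[best]]$dose,
    best_target = iters[[best]]$target,
    best_iteration = history$iteration[best],
    baseline_dose = iters[[1]]$dose,
    history = history,
    warning = warn
  ), class = "dmd_result")
}

#' @export
print.dmd_result <- function(x, ...) {
  h <- x$history
  cat(sprintf("<dmd_result> %d iterations, best = iteration %d: CI %.3f (baseline %.3f), coverage %.3f\n",
              nrow(h) - 1, x$best_iteration,
              h$ci[h$iteration == x$best_iteration], h$ci[1],
              h$coverage[h$iteration == x$best_iteration]))
  if (!is.na(x$warning)) cat("  warning: ", x$warning, "\n")
  invisible(x)
}

#' Per-iteration metric history of a DMD run
#' @param x a `dmd_result`.
#' @param ... unused.
#' @export
tidy.dmd_result <- function(x, ...) x$history

#' Best-iteration summary of a DMD run
#' @param x a `dmd_result`.
#' @param ... unused.
#' @export
glance.dmd_result <- function(x, ...) {
  dplyr::mutate(
    x$history[x$history$iteration == x$best_iteration, ],
    baseline_ci = x$history$ci[1],
    warning = x$warning
  )
}

#' Plot the metric trajectory of a DMD run
#' @param object a `dmd_result`.
#' @param metrics character vector of history columns to show.
#' @param ... unused.
#' @export
autoplot.dmd_result <- function(object,
                                metrics = c("ci", "c_delta", "hot_cc",
                                            "cold_cc"), ...) {
  long <- tidyr::pivot_longer(
    object$history[, c("iteration", metrics)],
    -"iteration", names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$iteration, .data$value)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$best_iteration,
                        linetype = "dashed") +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "DMD iteration", y = NULL) +
    ggplot2::theme_minimal()
}
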