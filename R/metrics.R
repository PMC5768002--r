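# Plan-quality indices (RTOG 0915 / Paddick / ICRU suite), computed from a
# coverage-normalized dose grid and the structure set. Isodose volumes are
# voxel-center counts with an inclusive ">=" threshold (consistent with the
# hot-region convention); volumes in cc are count * voxel volume / 1000.

iso_volume_cc <- function(dose, rx, spacing, within = NULL) {
  m <- dose$values >= rx
  if (!is.null(within)) m <- m & within
  mask_volume_cc(m, spacing)
}

#' RTOG conformity index
#'
#' `CI = V_Rx / V_PTV`: the prescription isodose volume (within the body when
#' a body mask is given) over the PTV volume. Ideal value 1, generally > 1.
#'
#' @param dose normalized dose [image_grid()].
#' @param rx prescription dose in the grid's unit.
#' @param ptv logical PTV mask, non-empty.
#' @param body optional logical body mask restricting the isodose volume.
#' @export
conformity_index <- function(dose, rx, ptv, body = NULL) {
  if (!any(ptv)) stop("empty ptv")
  iso_volume_cc(dose, rx, dose$spacing, body) / mask_volume_cc(ptv, dose$spacing)
}

#' Paddick conformity number
#'
#' `CN = TV_PIV^2 / (TV * PIV)` with TV the target volume, PIV the
#' prescription isodose volume and TV_PIV their intersection; the product of
#' coverage and selectivity, ideal value 1.
#'
#' @inheritParams conformity_index
#' @return one-row tibble with `cn`, `tv_cc`, `piv_cc`, `tv_piv_cc`.
#' @export
paddick_cn <- function(dose, rx, ptv, body = NULL) {
  if (!any(ptv)) stop("empty ptv")
  sp <- dose$spacing
  tv <- mask_volume_cc(ptv, sp)
  piv <- iso_volume_cc(dose, rx, sp, body)
  if (piv <= 0) stop("empty prescription isodose volume")
  tv_piv <- mask_volume_cc(ptv & dose$values >= rx, sp)
  tibble::tibble(cn = tv_piv^2 / (tv * piv), tv_cc = tv, piv_cc = piv,
                 tv_piv_cc = tv_piv)
}

#' R50% gradient index
#'
#' Volume of the half-prescription isodose over the PTV volume
#' (intermediate-dose spillage).
#'
#' @inheritParams conformity_index
#' @export
gradient_r50 <- function(dose, rx, ptv, body = NULL) {
  if (!any(ptv)) stop("empty ptv")
  iso_volume_cc(dose, 0.5 * rx, dose$spacing, body) /
    mask_volume_cc(ptv, dose$spacing)
}

#' D2cm: maximum dose 2 cm or further from the PTV
#'
#' Maximum dose (as % of prescription) over body voxels whose Euclidean
#' distance from the PTV is at least 20 mm.
#'
#' @inheritParams conformity_index
#' @param body logical body mask (required).
#' @param distance_mm_min ring distance, mm (default 20).
#' @export
d2cm <- function(dose, rx, ptv, body, distance_mm_min = 20) {
  if (!any(ptv)) stop("empty ptv")
  ring <- body & (distance_mm(ptv, dose$spacing) >= distance_mm_min)
  if (!any(ring)) stop("phantom too small: no body voxels 2 cm from the PTV")
  100 * max(dose$values[ring]) / rx
}

#' Homogeneity index
#'
#' `HI = (D2% - D98%) / D50%` on the PTV dose-volume histogram.
#'
#' @param dvh a [compute_dvh()] of the PTV.
#' @export
homogeneity_index <- function(dvh) {
  s <- dvh$stats
  if (s$d50 <= 0) stop("D50% is zero")
  (s$d2 - s$d98) / s$d50
}

#' External index
#'
#' `C_delta = (V_PI - PTV_PI) / V_PTV`: healthy-tissue volume at or above the
#' prescription isodose, relative to the PTV volume. Ideal value 0.
#'
#' @inheritParams conformity_index
#' @export
external_index <- function(dose, rx, ptv, body = NULL) {
  if (!any(ptv)) stop("empty ptv")
  sp <- dose$spacing
  v_pi <- iso_volume_cc(dose, rx, sp, body)
  ptv_pi <- mask_volume_cc(ptv & dose$values >= rx, sp)
  (v_pi - ptv_pi) / mask_volume_cc(ptv, sp)
}

#' Lung dose metrics
#'
#' V20Gy, V2.5Gy (% of lung volume) and mean lung dose (Gy) on the combined
#' lungs, by default excluding the ITV (the common "lung minus GTV/ITV"
#' convention).
#'
#' @param dose_gy absolute dose [image_grid()] in Gy.
#' @param lung logical mask of both lungs.
#' @param itv logical ITV mask (excluded when `exclude_itv`).
#' @param exclude_itv logical.
#' @return one-row tibble with `lung_v20_pct`, `lung_v2_5_pct`, `mld_gy`.
#' @export
lung_metrics <- function(dose_gy, lung, itv = NULL, exclude_itv = TRUE) {
  m <- lung
  if (exclude_itv && !is.null(itv)) m <- m & !itv
  if (!any(m)) stop("empty lung volume")
  d <- dose_gy$values[m]
  tibble::tibble(lung_v20_pct = 100 * mean(d >= 20),
                 lung_v2_5_pct = 100 * mean(d >= 2.5),
                 mld_gy = mean(d))
}

#' Evaluate all plan-quality indices for one normalized dose
#'
#' @param dose dose [image_grid()] normalized so the prescription level is
#'   `rx` (default 100, i.e. dose in % of prescription).
#' @param structures a [structure_set()] with `body`, `lung_left`,
#'   `lung_right`, `itv`, `ptv`.
#' @param prescription a [fractionation_scheme()] (for absolute lung doses).
#' @param rx prescription level in the dose grid's unit.
#' @param lung_exclude_itv exclude the ITV from the lung volume.
#' @return one-row tibble of class `plan_metrics` with the full index suite.
#' @export
evaluate_plan <- function(dose, structures, prescription, rx = 100,
                          lung_exclude_itv = TRUE) {
  m <- structures$masks
  ptv <- m$ptv; body <- m$body
  dvh <- compute_dvh(dose, ptv, "ptv")
  pad <- paddick_cn(dose, rx, ptv, body)
  dose_gy <- image_grid(dose$values * prescription$total_gy / rx,
                        dose$spacing, dose$origin)
  lung <- lung_metrics(dose_gy, m$lung_left | m$lung_right, m$itv,
                       exclude_itv = lung_exclude_itv)
  out <- tibble::tibble(
    ci = conformity_index(dose, rx, ptv, body),
    cn = pad$cn, tv_cc = pad$tv_cc, piv_cc = pad$piv_cc,
    tv_piv_cc = pad$tv_piv_cc,
    r50 = gradient_r50(dose, rx, ptv, body),
    d2cm_pct = d2cm(dose, rx, ptv, body),
    hi = homogeneity_index(dvh),
    c_delta = external_index(dose, rx, ptv, body),
    d2_pct = 100 * dvh$stats$d2 / rx,
    d50_pct = 100 * dvh$stats$d50 / rx,
    d98_pct = 100 * dvh$stats$d98 / rx,
    dmax_pct = 100 * dvh$stats$dmax / rx,
    dmean_pct = 100 * dvh$stats$dmean / rx,
    coverage = mean(dose$values[ptv] >= rx)
  )
  dplyr::bind_cols(out, lung)
}
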