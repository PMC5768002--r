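#' Benchmark suite of synthetic cases
#'
#' A fixed five-case suite of deliberately non-spherical targets -- a 3:1
#' prolate ellipsoid, a bilobed (concave) target, a capped cylinder, and two
#' cases drawn from the cohort sampler -- optionally extended with further
#' sampled cases. This is the suite used to demonstrate the margin-deformation
#' improvement and the index correlations on synthetic data; the coarse 3 mm /
#' 64-voxel preset keeps a full run tractable on one CPU.
#'
#' @param n_extra additional sampled cases appended after the fixed five.
#' @param seed integer seed (drives the sampled cases and placements).
#' @param spacing,grid_n grid preset passed to every case.
#' @return list of [phantom_spec()]s.
#' @export
benchmark_cohort_specs <- function(n_extra = 0, seed = 1L, spacing = 3,
                                   grid_n = 64) {
  s <- function(k) (seed * 131L + k) %% 2147483629L
  fixed <- list(
    phantom_spec("ellipsoid", itv_cc = 15, axis_ratio = 3,
                 laterality = "left", placement = "peripheral",
                 spacing = spacing, grid_n = grid_n, seed = s(1L),
                 fractionation = fractionation_scheme(18, 3)),
    phantom_spec("bilobed", itv_cc = 10, laterality = "right",
                 placement = "central", spacing = spacing, grid_n = grid_n,
                 seed = s(2L), fractionation = fractionation_scheme(11, 5)),
    phantom_spec("capped_cylinder", itv_cc = 22, laterality = "left",
                 placement = "central", spacing = spacing, grid_n = grid_n,
                 seed = s(3L), fractionation = fractionation_scheme(7.5, 8))
  )
  sampled <- sample_cohort(2, seed = s(4L), spacing = spacing,
                           grid_n = grid_n)
  extra <- if (n_extra > 0)
    sample_cohort(n_extra, seed = s(5L), spacing = spacing, grid_n = grid_n)
  else list()
  c(fixed, sampled, extra)
}
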