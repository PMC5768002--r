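# Cohort-level comparison of planning arms and the accompanying statistics:
# paired Wilcoxon signed-rank tests (exact, tie-aware, for n <= 25) and
# Spearman rank correlations.

#' Paired Wilcoxon signed-rank test
#'
#' Drops zero differences, ranks the absolute differences with average ranks,
#' and computes the two-sided p-value for the positive-rank sum W. For
#' n <= 25 the exact null distribution (signs independently flipped, ranks
#' held fixed -- valid with ties) is built by convolution; above 25 a normal
#' approximation with tie-corrected variance is used. The two-sided p is
#' `P(|W - S/2| >= |w - S/2|)` with S the total rank sum.
#'
#' @param a,b paired numeric vectors of equal length.
#' @param exact_max largest n for which the exact distribution is used.
#' @return one-row tibble with `statistic` (W), `n` (non-zero pairs), `p`,
#'   and `method`.
#' @export
wilcoxon_signed_rank <- function(a, b, exact_max = 25) {
  stopifnot(length(a) == length(b))
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    warning("all paired differences are zero")
    return(tibble::tibble(statistic = 0, n = 0L, p = 1, method = "degenerate"))
  }
  if (n < 2) stop("need at least 2 non-zero paired differences")
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  s_tot <- sum(r)
  if (n <= exact_max) {
    # exact distribution of 2W over integer support via convolution
    w2 <- round(2 * w)
    s2 <- round(2 * s_tot)
    f <- numeric(s2 + 1)  # index = value of 2W, offset 1
    f[1] <- 1
    for (ri in round(2 * r)) {
      g <- numeric(s2 + 1)
      g[1:(s2 + 1 - ri) + ri] <- f[1:(s2 + 1 - ri)]
      f <- (f + g) / 2
    }
    lo <- min(w2, s2 - w2)
    hi <- max(w2, s2 - w2)
    p <- sum(f[seq_len(lo + 1)]) + sum(f[(hi + 1):(s2 + 1)])
    p <- min(1, p)
    method <- "exact"
  } else {
    mu <- s_tot / 2
    sigma <- sqrt(sum(r^2) / 4)
    p <- min(1, 2 * pnorm(-abs(w - mu) / sigma))
    method <- "normal"
  }
  tibble::tibble(statistic = w, n = n, p = p, method = method)
}

#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties.
#'
#' @param x,y numeric vectors, length >= 3, neither constant.
#' @return the correlation coefficient.
#' @export
spearman_rho <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (sd(x) == 0 || sd(y) == 0)
    stop("Spearman correlation undefined for constant input")
  cor(x, y, method = "spearman")
}

#' Run a synthetic cohort through both planning arms
#'
#' Generates `n_cases` phantoms, runs the conventional conformal arc
#' (iteration 0 of the DMD loop) and the DCA-DMD arm on each, and assembles
#' the per-case metrics, arm summaries (mean +/- SD), paired Wilcoxon tests
#' per index, and the Spearman correlations of the external index with CI and
#' the Paddick number over all plans pooled. Individual case failures are
#' logged and excluded.
#'
#' @param n_cases number of cases.
#' @param seed integer seed for the cohort draw.
#' @param specs optional list of [phantom_spec()]s overriding the sampler.
#' @param arc,geometry,beam,params,coverage,rx passed to [run_dmd()].
#' @param out_dir optional directory; when given, writes `cohort.csv`
#'   (per-case metrics), `summary.csv`, `tests.csv` and `correlations.json`.
#' @param ... passed to [sample_cohort()] (e.g. `spacing`, grid `n`).
#' @return object of class `dmd_cohort`: list with tibbles `cases`,
#'   `summary`, `tests`, and `correlations`, plus `failures`.
#' @export
run_cohort <- function(n_cases, seed = 1L, specs = NULL,
                       arc = arc_spec(), geometry = beam_geometry(),
                       beam = beam_model(), params = dmd_params(),
                       coverage = 0.95, rx = 100, out_dir = NULL, ...) {
  if (is.null(specs)) specs <- sample_cohort(n_cases, seed, ...)
  rows <- list()
  failures <- character()
  for (i in seq_along(specs)) {
    res <- tryCatch({
      ph <- make_phantom(specs[[i]])
      dmd <- run_dmd(ph$grid, ph$structures, arc, geometry, beam, params,
                     prescription = specs[[i]]$fractionation,
                     coverage = coverage, rx = rx)
      h <- dmd$history
      dca <- h[1, ]
      best <- h[h$iteration == dmd$best_iteration, ]
      dplyr::bind_rows(
        dplyr::mutate(dca, arm = "DCA", .before = 1),
        dplyr::mutate(best, arm = "DCA-DMD", .before = 1)
      ) |>
        dplyr::mutate(case = i, shape = specs[[i]]$shape,
                      itv_cc = specs[[i]]$itv_cc,
                      dmd_warning = dmd$warning, .before = 1)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, sprintf("case %d: %s", i, conditionMessage(res)))
    } else {
      rows[[length(rows) + 1]] <- res
    }
  }
  if (!length(rows)) stop("all cohort cases failed")
  cases <- dplyr::bind_rows(rows)

  metric_cols <- c("ci", "cn", "r50", "d2cm_pct", "hi", "c_delta",
                   "dmax_pct", "dmean_pct", "d2_pct", "d50_pct", "d98_pct",
                   "coverage", "lung_v20_pct", "lung_v2_5_pct", "mld_gy")
  summary <- cases |>
    tidyr::pivot_longer(dplyr::all_of(metric_cols), names_to = "metric") |>
    dplyr::group_by(.data$arm, .data$metric) |>
    dplyr::summarise(mean = mean(.data$value), sd = sd(.data$value),
                     n = dplyr::n(), .groups = "drop")

  tests <- NULL
  if (length(unique(cases$case)) >= 2) {
    wide <- cases |>
      dplyr::select(dplyr::all_of(c("case", "arm", metric_cols))) |>
      tidyr::pivot_longer(dplyr::all_of(metric_cols), names_to = "metric") |>
      tidyr::pivot_wider(names_from = "arm", values_from = "value")
    tests <- wide |>
      dplyr::group_by(.data$metric) |>
      dplyr::group_modify(function(g, key) {
        if (sum(g$`DCA` - g$`DCA-DMD` != 0) < 2)
          return(tibble::tibble(statistic = 0, n = 0L, p = 1,
                                method = "degenerate"))
        suppressWarnings(wilcoxon_signed_rank(g$`DCA`, g$`DCA-DMD`))
      }) |>
      dplyr::ungroup()
  }

  correlations <- tibble::tibble(
    pair = c("c_delta~ci", "c_delta~cn"),
    rho = c(spearman_rho(cases$c_delta, cases$ci),
            spearman_rho(cases$c_delta, cases$cn)),
    n_plans = nrow(cases)
  )

  out <- structure(list(cases = cases, summary = summary, tests = tests,
                        correlations = correlations, failures = failures,
                        seed = seed),
                   class = "dmd_cohort")
  if (!is.null(out_dir)) write_cohort(out, out_dir)
  out
}

#' Write cohort report files
#' @param cohort a [run_cohort()] result.
#' @param dir output directory.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(cohort$cases, file.path(dir, "cohort.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$summary, file.path(dir, "summary.csv"),
                   row.names = FALSE)
  if (!is.null(cohort$tests))
    utils::write.csv(cohort$tests, file.path(dir, "tests.csv"),
                     row.names = FALSE)
  jsonlite::write_json(cohort$correlations,
                       file.path(dir, "correlations.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  if (length(cohort$failures))
    writeLines(cohort$failures, file.path(dir, "failures.log"))
  invisible(dir)
}

#' @export
print.dmd_cohort <- function(x, ...) {
  n <- length(unique(x$cases$case))
  cat(sprintf("<dmd_cohort> %d cases (%d failures)\n", n, length(x$failures)))
  key <- x$summary[x$summary$metric %in% c("ci", "cn", "c_delta", "r50"), ]
  print(as.data.frame(key), digits = 3)
  invisible(x)
}

#' Per-case, per-arm metrics of a cohort run
#' @param x a `dmd_cohort`.
#' @param ... unused.
#' @export
tidy.dmd_cohort <- function(x, ...) x$cases

#' Arm-level summary of a cohort run
#' @param x a `dmd_cohort`.
#' @param ... unused.
#' @export
glance.dmd_cohort <- function(x, ...) x$summary

#' Box plot of an index across planning arms
#' @param object a `dmd_cohort`.
#' @param metric history column to plot (default `"ci"`).
#' @param ... unused.
#' @export
autoplot.dmd_cohort <- function(object, metric = "ci", ...) {
  ggplot2::ggplot(object$cases,
                  ggplot2::aes(.data$arm, .data[[metric]])) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.08, alpha = 0.6) +
    ggplot2::labs(x = NULL, y = metric) +
    ggplot2::theme_minimal()
}
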