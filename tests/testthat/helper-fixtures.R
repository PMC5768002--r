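# Shared fixtures: small analytic grids and exhaustive per-voxel oracles.

coords_list <- function(n, spacing, origin = -(n - 1) * spacing / 2) {
  ax <- lapply(1:3, function(a) origin[a] + (seq_len(n[a]) - 1) * spacing[a])
  list(
    x = array(rep(ax[[1]], times = n[2] * n[3]), n),
    y = array(rep(rep(ax[[2]], each = n[1]), times = n[3]), n),
    z = array(rep(ax[[3]], each = n[1] * n[2]), n),
    origin = origin
  )
}

sphere_mask <- function(n, spacing, radius, center = c(0, 0, 0),
                        origin = -(n - 1) * spacing / 2) {
  co <- coords_list(n, spacing, origin)
  array((co$x - center[1])^2 + (co$y - center[2])^2 +
          (co$z - center[3])^2 <= radius^2, n)
}

# a random dose grid + nested masks on a small cube, for metric oracles;
# the PTV sits off-center so body voxels beyond the 2 cm ring exist
random_dose_case <- function(seed, n = c(16, 16, 16), spacing = c(3, 3, 3)) {
  set.seed(seed)
  dose <- image_grid(array(runif(prod(n), 0, 150), n), spacing)
  body <- sphere_mask(n, spacing, 40)
  ptv <- sphere_mask(n, spacing, 6, center = c(-7, -7, -7))
  itv <- sphere_mask(n, spacing, 4, center = c(-7, -7, -7))
  lung <- sphere_mask(n, spacing, 12, center = c(5, 5, 5)) & body
  list(dose = dose, body = body, ptv = ptv, itv = itv, lung = lung,
       spacing = spacing)
}

# Exhaustive per-voxel oracles (triple loops, no vectorized shortcuts).
oracle_counts <- function(dose, rx, ptv, body) {
  n <- dim(dose$values)
  piv <- 0; tv <- 0; tv_piv <- 0
  for (i in seq_len(n[1])) for (j in seq_len(n[2])) for (k in seq_len(n[3])) {
    inb <- is.null(body) || body[i, j, k]
    hotv <- dose$values[i, j, k] >= rx && inb
    if (hotv) piv <- piv + 1
    if (ptv[i, j, k]) {
      tv <- tv + 1
      if (dose$values[i, j, k] >= rx) tv_piv <- tv_piv + 1
    }
  }
  vcc <- prod(dose$spacing) / 1000
  list(piv_cc = piv * vcc, tv_cc = tv * vcc, tv_piv_cc = tv_piv * vcc)
}

oracle_d2cm <- function(dose, rx, ptv, body) {
  n <- dim(dose$values)
  sp <- dose$spacing
  pidx <- which(ptv, arr.ind = TRUE)
  best <- -Inf
  for (i in seq_len(n[1])) for (j in seq_len(n[2])) for (k in seq_len(n[3])) {
    if (!body[i, j, k]) next
    d2 <- min((sp[1] * (i - pidx[, 1]))^2 + (sp[2] * (j - pidx[, 2]))^2 +
                (sp[3] * (k - pidx[, 3]))^2)
    if (d2 >= 400) best <- max(best, dose$values[i, j, k])
  }
  100 * best / rx
}

oracle_lung <- function(dose_gy, lung, itv) {
  n <- dim(dose_gy$values)
  vals <- c()
  for (i in seq_len(n[1])) for (j in seq_len(n[2])) for (k in seq_len(n[3]))
    if (lung[i, j, k] && !itv[i, j, k])
      vals <- c(vals, dose_gy$values[i, j, k])
  c(v20 = 100 * mean(vals >= 20), v2_5 = 100 * mean(vals >= 2.5),
    mld = mean(vals))
}

# signed-rank two-sided p by full sign enumeration (n <= ~12)
oracle_signed_rank_p <- function(a, b) {
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  s <- sum(r)
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- signs %*% r
  mean(abs(w_all - s / 2) >= abs(w_obs - s / 2) - 1e-9)
}

# Coarse-preset planning setup used by slow-ish integration tests.
coarse_setup <- function() {
  list(arc = arc_spec(spacing = 10), geometry = beam_geometry(),
       beam = beam_model())
}

tiny_setup <- function() {
  list(arc = arc_spec(spacing = 20), geometry = beam_geometry(),
       beam = beam_model())
}
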