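test_that("arc angles honor span, spacing, gap and direction", {
  a <- make_arc(arc_spec(340, 2, gap_center = 90))
  expect_length(a, 171)
  expect_false(any(a > 80 & a < 100))
  expect_length(make_arc(arc_spec(340, 10, gap_center = 90)), 35)
  cw <- make_arc(arc_spec(340, 10, gap_center = 90, direction = "CW"))
  ccw <- make_arc(arc_spec(340, 10, gap_center = 90, direction = "CCW"))
  expect_identical(ccw, rev(cw))
  expect_error(arc_spec(340, 7), "divide")
  # full arc has no duplicate endpoint
  expect_length(make_arc(arc_spec(360, 10)), 36)
})

test_that("BEV of a centered sphere is a disc of the analytic radius", {
  # integer lattice so a voxel center sits exactly on the 10 mm boundary
  n <- c(33, 33, 33)
  sph <- sphere_mask(n, rep(1, 3), 10, origin = c(-16, -16, -16))
  bev <- bev_project(sph, rep(1, 3), c(-16, -16, -16), beam_geometry(), 0)
  op <- which(bev$values, arr.ind = TRUE)
  r <- sqrt((bev$x0 + (op[, 1] - 1) * bev$pitch)^2 +
              (bev$z0 + (op[, 2] - 1) * bev$pitch)^2)
  expect_gte(max(r), 10.0)
  expect_lte(max(r), 10.2)
})

test_that("a point target projects to one pixel, mirrored at opposed gantries", {
  n <- c(33, 33, 33)
  pt <- array(FALSE, n); pt[17, 17, 17] <- TRUE  # center exactly at the iso
  org <- c(-16, -16, -16)
  b0 <- bev_project(pt, rep(1, 3), org, beam_geometry(), 0)
  b180 <- bev_project(pt, rep(1, 3), org, beam_geometry(), 180)
  expect_equal(sum(b0$values), 1)
  expect_equal(sum(b180$values), 1)
  coord <- function(b) {
    op <- which(b$values, arr.ind = TRUE)
    c(b$x0 + (op[1] - 1) * b$pitch, b$z0 + (op[2] - 1) * b$pitch)
  }
  c0 <- coord(b0); c180 <- coord(b180)
  expect_equal(abs(c0), abs(c180), tolerance = 1e-9)
  expect_equal(c0[2], c180[2], tolerance = 1e-9)  # z not mirrored
})

test_that("sparse masks match the per-voxel ray-projection oracle", {
  set.seed(42)
  geom <- beam_geometry()
  for (rep in 1:5) {
    n <- c(24, 24, 24)
    m <- array(FALSE, n)
    m[cbind(sample(5:20, 3), sample(5:20, 3), sample(5:20, 3))] <- TRUE
    gantry <- runif(1, 0, 360)
    bev <- bev_project(m, rep(2, 3), -(n - 1), geom, gantry)
    # oracle: project each voxel center by hand and rasterize
    g <- gantry * pi / 180
    ex <- c(cos(g), -sin(g), 0); ez <- c(0, 0, 1)
    sdir <- c(sin(g), cos(g), 0)
    idx <- which(m, arr.ind = TRUE)
    w <- sweep((idx - 1) * 2, 2, -(n - 1), "+")
    expected <- matrix(FALSE, nrow(bev$values), ncol(bev$values))
    for (q in seq_len(nrow(w))) {
      rel <- w[q, ]
      daxis <- geom$sad - sum(rel * sdir)
      mag <- geom$sad / daxis
      xb <- sum(rel * ex) * mag; zb <- sum(rel * ez) * mag
      expected[round((xb - bev$x0) / bev$pitch) + 1,
               round((zb - bev$z0) / bev$pitch) + 1] <- TRUE
    }
    expect_identical(bev$values, expected)
  }
})

test_that("parallel-beam limit reproduces the orthographic silhouette", {
  set.seed(7)
  n <- c(20, 20, 20)
  m <- array(runif(prod(n)) < 0.1, n)
  m[10, 10, 10] <- TRUE
  geom <- beam_geometry(sad = 1e6)
  org <- -(n - 1) / 2
  for (gantry in c(0, 90)) {
    bev <- bev_project(m, rep(1, 3), org, geom, gantry, pitch = 0.5)
    op <- which(bev$values, arr.ind = TRUE)
    got <- unique(round(cbind(bev$x0 + (op[, 1] - 1) * bev$pitch,
                              bev$z0 + (op[, 2] - 1) * bev$pitch), 6))
    idx <- which(m, arr.ind = TRUE)
    w <- sweep(idx - 1, 2, org, "+")
    sil <- if (gantry == 0) cbind(w[, 1], w[, 3]) else cbind(-w[, 2], w[, 3])
    sil <- unique(round(sil, 6))
    expect_setequal(apply(got, 1, paste, collapse = ","),
                    apply(sil, 1, paste, collapse = ","))
  }
})

test_that("leaf pairs open to the per-band extrema of a disc", {
  # synthetic disc aperture, radius 10 mm, rasterized at 0.25 mm
  pitch <- 0.25
  xs <- seq(-12, 12, by = pitch); zs <- seq(-12, 12, by = pitch)
  img <- outer(xs, zs, function(x, z) x^2 + z^2 <= 100)
  bev <- structure(list(values = img, pitch = pitch, x0 = xs[1], z0 = zs[1],
                        gantry = 0), class = "bev_image")
  geom <- beam_geometry(leaf_width_iso = 5, n_leaf_pairs = 60)
  ap <- fit_mlc(bev, geom, margin_mm = 0)
  lv <- ap$leaves[ap$leaves$open, ]
  for (q in seq_len(nrow(lv))) {
    zin <- zs[zs >= lv$z_lo[q] & zs < lv$z_hi[q]]
    chord_max <- max(sqrt(pmax(0, 100 - zin^2)))
    expect_equal(lv$right[q], chord_max + pitch / 2, tolerance = pitch)
    expect_equal(lv$left[q], -chord_max - pitch / 2, tolerance = pitch)
  }
  # band [0, 5): opens at least to the midline chord sqrt(100 - 2.5^2)
  band <- lv[lv$z_lo == 0, ]
  expect_gte(band$right, sqrt(100 - 2.5^2))
})

test_that("aperture margin shifts every open edge outward by its value", {
  n <- c(33, 33, 33)
  sph <- sphere_mask(n, rep(1, 3), 10, origin = c(-16, -16, -16))
  bev <- bev_project(sph, rep(1, 3), c(-16, -16, -16), beam_geometry(), 30)
  geom <- beam_geometry()
  a0 <- fit_mlc(bev, geom, 0)
  a2 <- fit_mlc(bev, geom, 2)
  open <- a0$leaves$open
  expect_identical(open, a2$leaves$open)
  expect_equal(a2$leaves$left[open], a0$leaves$left[open] - 2)
  expect_equal(a2$leaves$right[open], a0$leaves$right[open] + 2)
})

test_that("a one-pixel aperture opens one pair of width pitch + 2 margin", {
  img <- matrix(FALSE, 9, 9); img[5, 5] <- TRUE
  bev <- structure(list(values = img, pitch = 1, x0 = -4, z0 = -4,
                        gantry = 0), class = "bev_image")
  geom <- beam_geometry()
  for (margin in c(0, 1.5)) {
    ap <- fit_mlc(bev, geom, margin)
    lv <- ap$leaves[ap$leaves$open, ]
    expect_equal(nrow(lv), 1)
    expect_equal(lv$right - lv$left, 1 + 2 * margin)
  }
})

test_that("fitted aperture area dominates the open-pixel silhouette area", {
  sp <- phantom_spec("bilobed", itv_cc = 12, spacing = 3, grid_n = 64, seed = 8)
  ph <- make_phantom(sp)
  geom <- beam_geometry()
  for (gantry in c(0, 120, 250)) {
    bev <- bev_project(ph$structures$masks$ptv, rep(3, 3),
                       ph$structures$origin, geom, gantry)
    ap <- fit_mlc(bev, geom, 0)
    sil_cm2 <- sum(bev$values) * bev$pitch^2 / 100
    expect_gte(aperture_area_cm2(ap), sil_cm2)
  }
})
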