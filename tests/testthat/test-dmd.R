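test_that("hot/cold classification matches definitions and a brute-force oracle", {
  n <- c(16, 16, 16); spc <- rep(2, 3)
  ptv <- sphere_mask(n, spc, 8)
  body <- sphere_mask(n, spc, 14)
  # uniformly over-dosed PTV, nothing outside: no hot, no cold
  v <- array(0, n); v[ptv] <- 110
  hc <- find_hot_cold(image_grid(v, spc), ptv, body, rx = 100)
  expect_equal(hc$hot_cc, 0)
  expect_equal(hc$cold_cc, 0)
  # dose exactly rx everywhere: hot = body minus ptv (>= is hot), cold empty
  hc2 <- find_hot_cold(image_grid(array(100, n), spc), ptv, body, rx = 100)
  expect_identical(hc2$hot, body & !ptv)
  expect_equal(hc2$cold_cc, 0)
  # random dose vs exhaustive voxel loop
  set.seed(5)
  d <- image_grid(array(runif(prod(n), 0, 200), n), spc)
  hc3 <- find_hot_cold(d, ptv, body, rx = 100)
  hot_o <- array(FALSE, n); cold_o <- array(FALSE, n)
  for (i in 1:16) for (j in 1:16) for (k in 1:16) {
    if (d$values[i, j, k] >= 100 && !ptv[i, j, k] && body[i, j, k])
      hot_o[i, j, k] <- TRUE
    if (d$values[i, j, k] < 100 && ptv[i, j, k]) cold_o[i, j, k] <- TRUE
  }
  expect_identical(hc3$hot, hot_o)
  expect_identical(hc3$cold, cold_o)
  # invariants
  expect_false(any(hc3$hot & ptv))
  expect_true(all(!hc3$cold | ptv))
})

test_that("deformation is a no-op without hot or cold regions", {
  n <- c(32, 32, 32); spc <- rep(3, 3)
  cur <- sphere_mask(n, spc, 15)
  body <- array(TRUE, n)
  itv <- sphere_mask(n, spc, 9)
  empty <- structure(list(hot = array(FALSE, n), cold = array(FALSE, n),
                          hot_cc = 0, cold_cc = 0), class = "hot_cold")
  new <- deform_target(cur, empty, dmd_params(step_mm = 3), itv, body, spc)
  expect_identical(new, cur)
})

test_that("a cold notch drives a local expansion only", {
  n <- c(32, 32, 32); spc <- rep(3, 3)
  cur <- sphere_mask(n, spc, 15)
  body <- array(TRUE, n)
  itv <- sphere_mask(n, spc, 9)
  cold <- array(FALSE, n)
  notch <- which(cur & !sphere_mask(n, spc, 12), arr.ind = TRUE)[1, , drop = FALSE]
  cold[notch] <- TRUE
  hc <- structure(list(hot = array(FALSE, n), cold = cold,
                       hot_cc = 0, cold_cc = voxel_cc(spc)),
                  class = "hot_cold")
  step <- 3
  new <- deform_target(cur, hc, dmd_params(step_mm = step,
                                           smooth_radius_mm = 0),
                       itv, body, spc)
  expect_true(all(cur[new == FALSE] == FALSE))  # superset of current
  added <- which(new & !cur, arr.ind = TRUE)
  if (nrow(added) > 0) {
    d_to_notch <- sqrt(rowSums(sweep(added, 2, as.numeric(notch))^2)) * spc[1]
    expect_true(all(d_to_notch <= step + 1e-9))
  }
})

test_that("an equatorial hot shell shrinks the equator and spares the poles", {
  n <- c(32, 32, 32); spc <- rep(3, 3)
  cur <- sphere_mask(n, spc, 15)
  body <- array(TRUE, n)
  itv <- sphere_mask(n, spc, 6)
  co <- coords_list(n, spc)
  hot <- (!cur) & sphere_mask(n, spc, 18) & (abs(co$z) <= 3)
  hc <- structure(list(hot = hot, cold = array(FALSE, n),
                       hot_cc = mask_volume_cc(hot, spc), cold_cc = 0),
                  class = "hot_cold")
  new <- deform_target(cur, hc, dmd_params(step_mm = 3, smooth_radius_mm = 0),
                       itv, body, spc)
  removed <- cur & !new
  expect_gt(sum(removed), 0)
  # removals confined to a band around the equator
  expect_lte(max(abs(co$z[removed])), 3 + 3 + 1e-9)
  # poles untouched
  poles <- cur & (abs(co$z) > 9)
  expect_true(all(new[poles]))
  # removals stay within one step of the surface
  depth <- distance_mm(!cur, spc)
  expect_lte(max(depth[removed]), 3)
})

test_that("the deformed target always contains the ITV unless allowed otherwise", {
  n <- c(32, 32, 32); spc <- rep(3, 3)
  cur <- sphere_mask(n, spc, 10)
  body <- array(TRUE, n)
  itv <- sphere_mask(n, spc, 9)
  hot <- (!cur) & sphere_mask(n, spc, 16)  # hot shell all around
  hc <- structure(list(hot = hot, cold = array(FALSE, n),
                       hot_cc = mask_volume_cc(hot, spc), cold_cc = 0),
                  class = "hot_cold")
  new <- deform_target(cur, hc, dmd_params(step_mm = 3), itv, body, spc)
  expect_true(all(new[itv]))
  new2 <- deform_target(cur, hc, dmd_params(step_mm = 3,
                                            allow_below_itv = TRUE),
                        itv, body, spc)
  expect_gt(sum(itv & !new2), 0)
})

test_that("the DMD loop honors its iteration contract and is deterministic", {
  sp <- phantom_spec("ellipsoid", itv_cc = 12, spacing = 4, grid_n = 48, seed = 21)
  ph <- make_phantom(sp)
  st <- tiny_setup()
  r1 <- run_dmd(ph$grid, ph$structures, st$arc, st$geometry, st$beam,
                dmd_params(max_iters = 1), prescription = sp$fractionation)
  expect_equal(nrow(r1$history), 2)  # baseline + one deformation
  r2 <- run_dmd(ph$grid, ph$structures, st$arc, st$geometry, st$beam,
                dmd_params(max_iters = 1), prescription = sp$fractionation)
  expect_identical(r1$history, r2$history)
  expect_identical(r1$best_target, r2$best_target)
  # coverage invariant holds on every iteration
  expect_true(all(r1$history$coverage >= 0.95))
  # best iteration never worsens the conformity index
  expect_lte(min(r1$history$ci[r1$history$iteration == r1$best_iteration]),
             r1$history$ci[1])
})

test_that("a loop already at tolerance returns the baseline untouched", {
  sp <- phantom_spec("sphere", itv_cc = 12, spacing = 4, grid_n = 48, seed = 22)
  ph <- make_phantom(sp)
  st <- tiny_setup()
  r <- run_dmd(ph$grid, ph$structures, st$arc, st$geometry, st$beam,
               dmd_params(max_iters = 5, stop_tol_cc = 1e4),
               prescription = sp$fractionation)
  expect_equal(nrow(r$history), 1)
  expect_equal(r$best_iteration, 0L)
  expect_identical(r$best_target, ph$structures$masks$ptv)
})

test_that("successive targets change only near the previous surface", {
  sp <- phantom_spec("bilobed", itv_cc = 12, spacing = 4, grid_n = 48, seed = 23)
  ph <- make_phantom(sp)
  st <- tiny_setup()
  params <- dmd_params(max_iters = 2)
  r <- run_dmd(ph$grid, ph$structures, st$arc, st$geometry, st$beam, params,
               prescription = sp$fractionation)
  # reconstruct iteration-1 target from the loop inputs to check locality
  hc <- find_hot_cold(r$baseline_dose, ph$structures$masks$ptv,
                      ph$structures$masks$body)
  t1 <- deform_target(ph$structures$masks$ptv, hc, params,
                      ph$structures$masks$itv, ph$structures$masks$body,
                      ph$structures$spacing)
  changed <- xor(t1, ph$structures$masks$ptv)
  if (any(changed)) {
    surf_d <- pmin(distance_mm(ph$structures$masks$ptv,
                               ph$structures$spacing),
                   distance_mm(!ph$structures$masks$ptv,
                               ph$structures$spacing))
    step <- max(ph$structures$spacing)
    expect_lte(max(surf_d[changed]),
               step + params$smooth_radius_mm + max(ph$structures$spacing))
  }
  expect_s3_class(tidy(r), "tbl_df")
  expect_true("baseline_ci" %in% names(glance(r)))
  expect_s3_class(autoplot(r), "ggplot")
})
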