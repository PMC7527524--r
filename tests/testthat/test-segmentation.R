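test_that("a two-level sphere is segmented exactly from a centre seed", {
  sp <- c(0.7, 0.7, 0.6)
  d <- c(40, 40, 40)
  ctr <- (d - 1) * sp / 2
  ax <- list(x = (0:39) * sp[1], y = (0:39) * sp[2], z = (0:39) * sp[3])
  r2 <- outer(outer((ax$x - ctr[1])^2, (ax$y - ctr[2])^2, `+`),
              (ax$z - ctr[3])^2, `+`)
  sphere <- r2 <= 8^2
  v <- ot_volume(array(ifelse(sphere, 1, 0), d), sp)
  m <- segment_globe(v, seed_spec(seed = round(ctr / sp) + 1), side = "left")
  expect_identical(m$voxels, sphere)
})

test_that("centroid follows the index-times-spacing convention", {
  sp <- c(0.7, 0.7, 0.6)
  one <- array(FALSE, c(10, 10, 10)); one[4, 5, 6] <- TRUE  # zero-based (3,4,5)
  expect_equal(unclass(centroid_mm(one, sp)),
               c(x = 2.1, y = 2.8, z = 3.0), tolerance = 1e-12)
  cube <- array(FALSE, c(20, 20, 20)); cube[10:12, 10:12, 10:12] <- TRUE
  expect_equal(unclass(centroid_mm(cube, sp)),
               c(x = 7.0, y = 7.0, z = 6.0), tolerance = 1e-12)
})

test_that("centroid equals a brute-force mean over listed voxel coordinates", {
  set.seed(11)
  sp <- c(0.7, 0.7, 0.6)
  for (rep in 1:10) {
    m <- array(FALSE, c(15, 13, 11))
    m[sample(length(m), 50)] <- TRUE
    got <- as.numeric(centroid_mm(m, sp))
    # independent oracle: explicit per-voxel coordinate list
    acc <- c(0, 0, 0); n <- 0
    for (i in 1:15) for (j in 1:13) for (k in 1:11) if (m[i, j, k]) {
      acc <- acc + c((i - 1) * sp[1], (j - 1) * sp[2], (k - 1) * sp[3])
      n <- n + 1
    }
    expect_equal(got, acc / n, tolerance = 1e-13)
  }
})

test_that("centroid shifts exactly with integer-voxel mask translation", {
  set.seed(12)
  sp <- c(0.7, 0.7, 0.6)
  m <- array(FALSE, c(20, 20, 20)); m[5:9, 6:9, 7:10] <- runif(80) > 0.4
  shifted <- oculotrans:::shift3(m, 2, 3, 1)
  expect_equal(as.numeric(centroid_mm(shifted, sp)) - as.numeric(centroid_mm(m, sp)),
               c(2, 3, 1) * sp, tolerance = 1e-12)
})

test_that("mask volume is voxel count times voxel volume", {
  m <- array(FALSE, c(20, 20, 20)); m[1:10, 1:10, 1:10] <- TRUE
  expect_equal(mask_volume_ml(m, c(1, 1, 1)), 1.0)
  expect_error(mask_volume_ml(array(FALSE, c(3, 3, 3)), c(1, 1, 1)), "empty")
})

test_that("phantom globes are segmented with high overlap and accurate volume", {
  ph <- clean_phantom_cr()
  cfg <- ph$truth$config
  v <- ph$volumes$central
  truth <- ph$truth$central$globe_mask_truth$left
  m <- segment_globe(v, seed_spec(), side = "left")
  expect_gte(dice(m$voxels, truth), 0.95)
  vt <- mask_volume_ml(truth, cfg$spacing)
  expect_lte(abs(mask_volume_ml(m) - vt) / vt, 0.05)
})

test_that("segmentation is invariant to intensity rescaling", {
  ph <- clean_phantom_cr()
  v <- ph$volumes$central
  v2 <- v; v2$data <- 2 * v$data
  m1 <- segment_globe(v, seed_spec(), side = "right")
  m2 <- segment_globe(v2, seed_spec(), side = "right")
  expect_identical(m1$voxels, m2$voxels)
})

test_that("a seed in orbital fat is rejected", {
  ph <- clean_phantom_cr()
  cfg <- ph$truth$config
  g <- oculotrans:::phantom_geometry(cfg)
  idx <- round((g$orbit$left$center + c(0, -11, 0)) / cfg$spacing) + 1
  expect_equal(ph$volumes$central$data[idx[1], idx[2], idx[3]], 0.6)
  expect_error(segment_globe(ph$volumes$central, seed_spec(seed = idx),
                             side = "left"),
               "bad seed|leak")
  expect_error(segment_globe(ph$volumes$central,
                             seed_spec(seed = c(2, 2, 2)), side = "left"),
               "background")
})

test_that("pole-vector rotation estimation recovers the gaze angle", {
  c1 <- c(10, 10, 5); p1 <- c(10, 17, 5)
  expect_equal(estimate_rotation_deg(c1, p1, c1, p1, "axial"), 0)
  # analytic 30 deg rotation about z plus a translation: translation cancels
  R <- oculotrans:::euler_matrix(c(0, 0, 30))
  t <- c(0.7, -0.3, 0)
  c2 <- c1 + t; p2 <- c1 + t + as.numeric(R %*% (p1 - c1))
  expect_equal(estimate_rotation_deg(c1, p1, c2, p2, "axial"), 30,
               tolerance = 1e-9)
  expect_error(estimate_rotation_deg(c1, c1, c1, p1, "axial"), "coincides")

  # segmented centroids with the phantom's lens landmark
  ph <- clean_phantom_cr()
  m1 <- centroid_mm(segment_globe(ph$volumes$central, seed_spec(), side = "left"))
  m2 <- centroid_mm(segment_globe(ph$volumes$right, seed_spec(), side = "left"))
  ang <- estimate_rotation_deg(m1, ph$truth$central$eyes$left$lens_mm,
                               m2, ph$truth$right$eyes$left$lens_mm, "axial")
  expect_lt(abs(ang - 30), 1.5)
})
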