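mk_centroid <- function(xyz, side = NULL, gaze = NULL) {
  structure(as.numeric(xyz), names = c("x", "y", "z"), side = side,
            gaze = gaze, class = "centroid_mm")
}

test_that("angle wrapping matches both reporting conventions", {
  expect_equal(wrap_angle(360, "positive"), 0)
  expect_equal(wrap_angle(181, "signed"), -179)
  expect_equal(wrap_angle(228.7, "signed"), -131.3)
  expect_equal(wrap_angle(-131.3, "positive"), 228.7)
  expect_equal(wrap_angle(-4.2, "positive"), 355.8)
  expect_equal(wrap_angle(180, "signed"), 180)
  expect_equal(wrap_angle(c(-350, 10, 370), "signed"), c(10, 10, 10))
})

test_that("horizontal displacement follows the medial/anterior convention with right-eye mirroring", {
  # left eye: 1 mm medial (-x) and 1 mm anterior
  d1 <- horizontal_displacement(mk_centroid(c(5, 5, 5)),
                                mk_centroid(c(4, 6, 5)), side = "left")
  expect_equal(d1$d, sqrt(2), tolerance = 1e-12)
  expect_equal(d1$theta, 45, tolerance = 1e-12)
  # right eye 3-4-5 triangle: dx = +0.3 (medial for the right eye), dy = -0.4
  d2 <- horizontal_displacement(mk_centroid(c(5, 5, 5)),
                                mk_centroid(c(5.3, 4.6, 5)), side = "right")
  expect_equal(d2$d, 0.5, tolerance = 1e-12)
  expect_equal(d2$theta, atan2(-0.4, 0.3) * 180 / pi, tolerance = 1e-9)
  expect_equal(round(d2$theta, 2), -53.13)
  # zero displacement: theta undefined, not 0
  d0 <- horizontal_displacement(mk_centroid(c(5, 5, 5)),
                                mk_centroid(c(5, 5, 7)), side = "left")
  expect_equal(d0$d, 0)
  expect_true(d0$theta_undefined)
  expect_true(is.na(d0$theta))
  expect_equal(d0$out_of_plane_mm, 2)
})

test_that("vertical displacement uses the anterior/up convention without mirroring", {
  dv <- vertical_displacement(mk_centroid(c(5, 5, 5)),
                              mk_centroid(c(5, 5, 5.44)), side = "left")
  expect_equal(dv$d, 0.44, tolerance = 1e-12)
  expect_equal(dv$theta, 90)
  d2 <- vertical_displacement(mk_centroid(c(5, 5, 5)),
                              mk_centroid(c(5, 4.9, 5.1)), side = "right")
  expect_equal(d2$theta, 135, tolerance = 1e-9)
  dr <- vertical_displacement(mk_centroid(c(1, 1, 1)),
                              mk_centroid(c(1, 1 - 0.3, 1 - 0.3)), side = "left")
  expect_equal(dr$theta, -135, tolerance = 1e-9)
})

test_that("displacements match an independent polar-coordinate oracle", {
  set.seed(21)
  for (i in 1:50) {
    delta <- rnorm(3, 0, 0.5)
    side <- sample(c("left", "right"), 1)
    c1 <- mk_centroid(c(10, 10, 10))
    c2 <- mk_centroid(c(10, 10, 10) + delta)
    h <- horizontal_displacement(c1, c2, side)
    du <- if (side == "right") delta[1] else -delta[1]
    zh <- complex(real = du, imaginary = delta[2])
    expect_equal(h$d, Mod(zh), tolerance = 1e-12)
    expect_equal(h$theta, Arg(zh) * 180 / pi, tolerance = 1e-9)
    v <- vertical_displacement(c1, c2, side)
    zv <- complex(real = delta[2], imaginary = delta[3])
    expect_equal(v$d, Mod(zv), tolerance = 1e-12)
    expect_equal(v$theta, Arg(zv) * 180 / pi, tolerance = 1e-9)
    # d does not depend on the angle range
    hp <- horizontal_displacement(c1, c2, side, angle_range = "positive")
    expect_equal(hp$d, h$d)
    expect_true(hp$theta >= 0 && hp$theta < 360)
  }
})

test_that("side bookkeeping is enforced", {
  a <- mk_centroid(c(1, 1, 1), side = "left")
  b <- mk_centroid(c(2, 2, 2), side = "right")
  expect_error(horizontal_displacement(a, b, "left"), "side|eyes")
  expect_error(horizontal_displacement(a, a, "right"), "side")
})

test_that("a mirrored right-eye phantom reproduces the left-eye result exactly", {
  ph <- clean_phantom_cr()
  mirror <- function(v) { v$data <- v$data[dim(v$data)[1]:1, , ]; v }
  cL1 <- centroid_mm(segment_globe(ph$volumes$central, seed_spec(), side = "left"))
  cL2 <- centroid_mm(segment_globe(ph$volumes$right, seed_spec(), side = "left"))
  dL <- horizontal_displacement(cL1, cL2, "left")
  cR1 <- centroid_mm(segment_globe(mirror(ph$volumes$central), seed_spec(),
                                   side = "right"))
  cR2 <- centroid_mm(segment_globe(mirror(ph$volumes$right), seed_spec(),
                                   side = "right"))
  dR <- horizontal_displacement(cR1, cR2, "right")
  expect_equal(dR$d, dL$d, tolerance = 1e-9)
  expect_equal(dR$theta, dL$theta, tolerance = 1e-9)
})

test_that("moving both acquisitions by the same head motion leaves the result unchanged", {
  ph <- clean_phantom_cr()
  base <- end_to_end_displacement(ph$volumes$central, ph$volumes$right,
                                  side = "left")
  ctr <- oculotrans:::volume_center_mm(dim(ph$volumes$central$data),
                                       ph$volumes$central$spacing)
  H <- rigid_transform(rotation = c(0.5, -0.3, 0.8),
                       translation = c(0.8, -0.6, 0.4), center = ctr)
  moved <- end_to_end_displacement(apply_rigid(ph$volumes$central, H),
                                   apply_rigid(ph$volumes$right, H),
                                   side = "left")
  expect_lt(abs(moved$d - base$d), 0.1)
  expect_angle_equal(moved$theta, base$theta, 5)
})
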