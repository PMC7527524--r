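test_that("static mask excludes dilated globes and shrinks monotonically with dilation", {
  ph <- clean_phantom_cr()
  cfg <- ph$truth$config
  v <- ph$volumes$central
  truth <- ph$truth$central$globe_mask_truth

  m0 <- build_static_mask(v, list(), 0)
  expect_true(all(v$data[m0] > 0))       # foreground only
  expect_false(any(m0[v$data == 0]))

  m3 <- build_static_mask(v, truth, 3)
  dil <- oculotrans:::dilate_mm(truth$left | truth$right, 3, cfg$spacing)
  expect_equal(sum(m3 & dil), 0L)

  counts <- vapply(c(0, 1, 3), function(dd)
    sum(build_static_mask(v, truth, dd)), 0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("registering a volume to itself yields the identity", {
  ph <- clean_phantom_cr()
  v <- ph$volumes$central
  sm <- build_static_mask(v, ph$truth$central$globe_mask_truth, 3)
  rep <- register_static(v, v, sm)
  p <- rt_parameters(rep$transform)
  expect_lt(max(abs(p$rotation)), 0.05)
  expect_lt(max(abs(p$translation)), 0.05)
  expect_lt(rep$residual, 1e-4)
  expect_true(rep$pass)
})

test_that("known head motion is recovered within tolerance, noiselessly and with noise", {
  cfg <- desk_config(noise_sd = 0, head_motion = c(rotation = 0, translation = 0),
                     seed = 31)
  ctr <- oculotrans:::volume_center_mm(cfg$grid_shape, cfg$spacing)
  H <- rigid_transform(rotation = c(0.6, -0.5, 1.5),
                       translation = c(1.2, -0.5, 0.7), center = ctr)
  ph <- generate_phantom(cfg, gazes = c("central", "right"),
                         head_motions = list(right = H))
  sm <- build_static_mask(ph$volumes$central,
                          ph$truth$central$globe_mask_truth, 3)
  rep <- register_static(ph$volumes$right, ph$volumes$central, sm)
  want <- rt_parameters(rt_invert(H))
  got <- rt_parameters(rep$transform)
  expect_lt(max(abs(got$rotation - want$rotation)), 0.1)
  expect_lt(max(abs(got$translation - want$translation)), 0.1)

  for (s in c(41, 42)) {
    cfgn <- desk_config(noise_sd = 0.02,
                        head_motion = c(rotation = 0, translation = 0), seed = s)
    phn <- generate_phantom(cfgn, gazes = c("central", "right"),
                            head_motions = list(right = H))
    smn <- build_static_mask(phn$volumes$central,
                             phn$truth$central$globe_mask_truth, 3)
    repn <- register_static(phn$volumes$right, phn$volumes$central, smn)
    gotn <- rt_parameters(repn$transform)
    expect_lt(max(abs(gotn$rotation - want$rotation)), 0.3)
    expect_lt(max(abs(gotn$translation - want$translation)), 0.2)
  }
})

test_that("alignment check passes when aligned, fails at 2 mm offset, and is vacuous at threshold 1", {
  ph <- clean_phantom_cr()
  v <- ph$volumes$central
  sm <- build_static_mask(v, ph$truth$central$globe_mask_truth, 3)
  expect_true(check_alignment(v, v, sm)$pass)
  off <- apply_rigid(v, rigid_transform(translation = c(2, 0, 0)))
  bad <- check_alignment(v, off, sm)
  expect_false(bad$pass)
  expect_gt(bad$residual, 0.02)
  expect_true(check_alignment(v, off, sm, threshold = 1)$pass)
  expect_gte(bad$residual, 0); expect_lte(bad$residual, 1)
})

test_that("registration is symmetric and composes consistently", {
  cfg <- desk_config(noise_sd = 0, head_motion = c(rotation = 0, translation = 0),
                     seed = 51)
  ctr <- oculotrans:::volume_center_mm(cfg$grid_shape, cfg$spacing)
  H1 <- rigid_transform(rotation = c(0.4, 0.6, -0.9),
                        translation = c(-0.8, 0.6, 0.5), center = ctr)
  H2 <- rigid_transform(rotation = c(-0.7, 0.2, 0.8),
                        translation = c(0.9, -0.4, -0.6), center = ctr)
  ph <- generate_phantom(cfg, gazes = c("central", "right", "up"),
                         head_motions = list(right = H1, up = H2))
  A <- ph$volumes$central; B <- ph$volumes$right; C <- ph$volumes$up
  smA <- build_static_mask(A, ph$truth$central$globe_mask_truth, 3)
  smB <- build_static_mask(B, ph$truth$right$globe_mask_truth, 3)

  tBA <- register_static(B, A, smA)$transform
  tAB <- register_static(A, B, smB)$transform
  ps <- rt_parameters(rt_compose(tBA, tAB))
  expect_lt(max(abs(ps$rotation)), 0.1)
  expect_lt(max(abs(ps$translation)), 0.1)

  tCB <- register_static(C, B, smB)$transform
  tCA <- register_static(C, A, smA)$transform
  pc <- rt_parameters(rt_compose(rt_invert(tCA), rt_compose(tBA, tCB)))
  expect_lt(max(abs(pc$rotation)), 0.15)
  expect_lt(max(abs(pc$translation)), 0.15)
})

test_that("a large globe displacement does not perturb the recovered head motion", {
  ctr0 <- oculotrans:::volume_center_mm(c(96, 96, 48), c(0.7, 0.7, 0.6))
  H <- rigid_transform(rotation = c(0.8, -0.4, 1.0),
                       translation = c(0.9, 0.7, -0.5), center = ctr0)
  recover <- function(trans_right) {
    cfg <- desk_config(noise_sd = 0, head_motion = c(rotation = 0, translation = 0),
                       true_translation = list(right = trans_right,
                                               left = c(0.7, 0, 0),
                                               up = c(0, 0, -0.43),
                                               down = c(0, 0, 0.43)),
                       seed = 61)
    ph <- generate_phantom(cfg, gazes = c("central", "right"),
                           head_motions = list(right = H))
    sm <- build_static_mask(ph$volumes$central,
                            ph$truth$central$globe_mask_truth, 3)
    rt_parameters(register_static(ph$volumes$right, ph$volumes$central, sm)$transform)
  }
  small <- recover(c(0, 0, 0))
  big <- recover(c(-2, 0, 0))
  expect_lt(max(abs(small$rotation - big$rotation)), 0.1)
  expect_lt(max(abs(small$translation - big$translation)), 0.1)
})
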