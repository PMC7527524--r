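# construct a sample with exactly the requested mean and SD
sample_with_moments <- function(mean, sd, n) {
  x <- seq_len(n)
  mean + sd * (x - base::mean(x)) / stats::sd(x)
}

test_that("normal 95% CIs reproduce printed summaries and have exact width", {
  elev <- summarize_values(sample_with_moments(0.43, 0.23, 56))
  expect_equal(round(elev$ci_low, 2), 0.37)
  expect_equal(round(elev$ci_high, 2), 0.49)
  depr <- summarize_values(sample_with_moments(0.44, 0.19, 56))
  expect_equal(round(depr$ci_low, 2), 0.39)
  expect_equal(round(depr$ci_high, 2), 0.49)
  # exact width property and degenerate SD
  s <- summarize_values(rnorm(20))
  expect_equal(s$ci_high - s$ci_low, 2 * 1.96 * s$sd / sqrt(s$n), tolerance = 1e-12)
  z <- summarize_values(rep(1.5, 5))
  expect_equal(c(z$ci_low, z$ci_high), c(1.5, 1.5))
  expect_error(summarize_values(1), "at least 2")
})

test_that("direction summaries report arithmetic and circular statistics", {
  same <- summarize_direction(rep(30, 6), "signed")
  expect_equal(same$mean, 30); expect_equal(same$sd, 0)
  expect_equal(same$circ_mean, 30, tolerance = 1e-9)
  expect_equal(same$circ_sd, 0, tolerance = 1e-6)

  anti <- summarize_direction(c(-179, 179), "signed")
  expect_equal(anti$mean, 0)                       # arithmetic mean diverges
  expect_equal(abs(anti$circ_mean), 180, tolerance = 1e-9)

  set.seed(31)
  a <- wrap_angle(rnorm(40, 120, 40), "signed")
  got <- summarize_direction(a, "signed")
  # independent vector-sum oracle in the complex plane
  zbar <- mean(exp(1i * a * pi / 180))
  expect_equal(got$circ_mean, Arg(zbar) * 180 / pi, tolerance = 1e-9)
  expect_equal(got$resultant, Mod(zbar), tolerance = 1e-12)
  expect_equal(got$circ_sd, sqrt(-2 * log(Mod(zbar))) * 180 / pi,
               tolerance = 1e-9)

  expect_error(summarize_direction(c(10, 350), "signed"), "range")
  expect_error(summarize_direction(c(-10, 20), "positive"), "range")
})

test_that("gaze comparison matches the pooled-variance textbook formula", {
  expect_equal(compare_gazes(c(1, 2, 3), c(1, 2, 3)), list(t = 0, p = 1, df = 4),
               tolerance = 1e-12)
  r <- compare_gazes(c(0.5, 0.7, 0.9), c(0.4, 0.6, 0.8))
  sp2 <- (2 * var(c(0.5, 0.7, 0.9)) + 2 * var(c(0.4, 0.6, 0.8))) / 4
  t_hand <- (0.7 - 0.6) / sqrt(sp2 * (1 / 3 + 1 / 3))
  expect_equal(r$t, t_hand, tolerance = 1e-12)
  expect_equal(r$p, 2 * pt(-abs(t_hand), 4), tolerance = 1e-12)
  # sign symmetry
  s1 <- compare_gazes(c(1, 2, 4), c(2, 3, 5))
  s2 <- compare_gazes(c(2, 3, 5), c(1, 2, 4))
  expect_equal(s1$t, -s2$t); expect_equal(s1$p, s2$p)
  # degenerate variance
  expect_equal(compare_gazes(c(2, 2, 2), c(2, 2))$p, 1)
  expect_error(compare_gazes(c(2, 2, 2), c(3, 3)), "undefined")
})

test_that("correlation matches brute force and respects preconditions", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(correlate(x, -2 * x + 1)$R, -1, tolerance = 1e-12)
  set.seed(41)
  a <- rnorm(30); b <- rnorm(30)
  got <- correlate(a, b)
  r_hand <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(got$R, r_hand, tolerance = 1e-12)
  t_hand <- r_hand * sqrt(28 / (1 - r_hand^2))
  expect_equal(got$p, 2 * pt(-abs(t_hand), 28), tolerance = 1e-12)
  # affine invariance up to sign
  expect_equal(correlate(a, 3 * b + 2)$R, got$R, tolerance = 1e-12)
  expect_equal(correlate(a, -0.5 * b)$R, -got$R, tolerance = 1e-12)
  expect_error(correlate(c(1, 2), c(3, 4)), "n >= 3")
  expect_error(correlate(c(1, 2, 3), c(2, 2, 2)), "zero variance")
})

test_that("one-eye selection alternates over a seeded shuffle and is reproducible", {
  rec <- expand.grid(subject = sprintf("S%02d", 1:56),
                     side = c("left", "right"),
                     stringsAsFactors = FALSE)
  sel <- select_one_eye(rec, seed = 7)
  expect_equal(nrow(sel), 56)
  expect_equal(sort(as.integer(table(sel$side))), c(28L, 28L))
  sel2 <- select_one_eye(rec, seed = 7)
  expect_identical(attr(sel, "selection"), attr(sel2, "selection"))
  # two subjects: one right, one left
  small <- select_one_eye(rec[rec$subject %in% c("S01", "S02"), ], seed = 1)
  expect_setequal(small$side, c("left", "right"))
  # missing eye falls back with a warning (a single subject is always
  # assigned the right eye first)
  onesided <- data.frame(subject = "S01", side = "left")
  expect_warning(sel3 <- select_one_eye(onesided, seed = 30), "no right eye")
  expect_equal(nrow(sel3), 1)
  expect_equal(sel3$side, "left")
})

test_that("cohort simulation and tables recover the built-in parameters", {
  rec <- simulate_cohort(n = 200, seed = 5,
                         r_axial = c(abduction = -0.5, adduction = -0.5,
                                     elevation = -0.5, depression = -0.5))
  one <- select_one_eye(rec, seed = 5)
  tabs <- build_tables(one)
  expect_equal(nrow(tabs$table1), 4)
  expect_equal(nrow(tabs$table2), 12)
  ab <- tabs$table2[tabs$table2$gaze == "abduction" &
                    tabs$table2$covariate == "axial_length", ]
  expect_gt(ab$R, -0.6); expect_lt(ab$R, -0.4)
  expect_true(ab$significant)
  d_ab <- tabs$table1[tabs$table1$movement == "abduction", ]
  expect_lt(abs(d_ab$distance_mean - 0.69), 0.08)
  # deterministic re-run
  expect_identical(build_tables(one), tabs)
  expect_identical(simulate_cohort(n = 20, seed = 9), simulate_cohort(n = 20, seed = 9))
})
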