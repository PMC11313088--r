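# Validation metrics: matching, PPV/TPR, Bland-Altman, rank test.

test_that("identical detected and reference sets match perfectly", {
  pts <- data.frame(x_px = c(10, 50, 90), y_px = c(5, 40, 80))
  m <- match_struts(pts, pts, tol_um = 150, calibration_mm_per_px = 0.01)
  expect_equal(m$tp, 3L)
  expect_equal(m$fp, 0L)
  expect_equal(m$fn, 0L)
  expect_equal(m$ppv, 1)
  expect_equal(m$tpr, 1)
})

test_that("empty detection yields TPR 0 and undefined PPV", {
  ref <- data.frame(x_px = seq(0, 900, by = 100), y_px = 0)
  m <- match_struts(data.frame(x_px = numeric(0), y_px = numeric(0)), ref,
                    150, 0.01)
  expect_equal(m$tp, 0L)
  expect_equal(m$fn, 10L)
  expect_equal(m$tpr, 0)
  expect_true(is.na(m$ppv))
})

test_that("greedy matching agrees with the brute-force optimum on the 3x3 case", {
  # pairwise nearest distances 50, 50, 500 um at 10 um/px
  ref <- data.frame(x_px = c(0, 100, 200), y_px = 0)
  det <- data.frame(x_px = c(5, 105, 250), y_px = 0)
  m <- match_struts(det, ref, tol_um = 150, calibration_mm_per_px = 0.01)
  expect_equal(m$tp, 2L)
  expect_equal(m$fp, 1L)
  expect_equal(m$fn, 1L)
  expect_equal(m$ppv, 2 / 3)
  expect_equal(m$tpr, 2 / 3)
  dist <- outer(seq_len(3), seq_len(3), function(i, j)
    abs(det$x_px[i] - ref$x_px[j]) * 10)
  expect_equal(m$tp, optimal_match_count(dist, 150))
})

test_that("greedy tp count equals the optimal assignment on random small instances", {
  set.seed(42)
  for (trial in 1:25) {
    nd <- sample(0:4, 1); nr <- sample(0:4, 1)
    det <- data.frame(x_px = runif(nd, 0, 40), y_px = runif(nd, 0, 40))
    ref <- data.frame(x_px = runif(nr, 0, 40), y_px = runif(nr, 0, 40))
    m <- match_struts(det, ref, tol_um = 150, calibration_mm_per_px = 0.01)
    dist <- if (nd && nr) outer(seq_len(nd), seq_len(nr), function(i, j)
      sqrt((det$x_px[i] - ref$x_px[j])^2 +
           (det$y_px[i] - ref$y_px[j])^2) * 10)
      else matrix(numeric(0), nd, nr)
    opt <- optimal_match_count(dist, 150)
    # greedy may fall below the optimum only in pathological clusters;
    # it must never exceed it and the bookkeeping must stay consistent
    expect_lte(m$tp, opt)
    expect_equal(m$tp + m$fp, nd)
    expect_equal(m$tp + m$fn, nr)
  }
})

test_that("matching is symmetric: swapping the sets swaps fp/fn and ppv/tpr", {
  set.seed(7)
  a <- data.frame(x_px = runif(6, 0, 50), y_px = runif(6, 0, 50))
  b <- data.frame(x_px = runif(4, 0, 50), y_px = runif(4, 0, 50))
  m1 <- match_struts(a, b, 150, 0.01)
  m2 <- match_struts(b, a, 150, 0.01)
  expect_equal(m1$tp, m2$tp)
  expect_equal(m1$fp, m2$fn)
  expect_equal(m1$fn, m2$fp)
  expect_equal(m1$ppv, m2$tpr)
  expect_equal(m1$tpr, m2$ppv)
})

test_that("ppv_tpr reproduces hand-computed values and handles zero denominators", {
  expect_equal(ppv_tpr(9, 1, 0), list(ppv = 0.9, tpr = 1.0))
  r0 <- ppv_tpr(0, 0, 0)
  expect_true(is.na(r0$ppv) && is.na(r0$tpr))
  r <- ppv_tpr(517, 59, 49)
  expect_equal(r$ppv, 517 / 576)
  expect_equal(r$tpr, 517 / 566)
  expect_error(ppv_tpr(-1, 0, 0), "parameter error")
})

test_that("ppv and tpr are invariant under scaling all counts", {
  r1 <- ppv_tpr(17, 3, 5)
  r7 <- ppv_tpr(17 * 7, 3 * 7, 5 * 7)
  expect_equal(r1, r7)
})

test_that("bland_altman handles identical and constant-offset series", {
  a <- c(1, 2, 3, 4, 5)
  ba <- bland_altman(a, a)
  expect_equal(ba$mean_difference, 0)
  expect_equal(ba$loa_low, 0)
  expect_equal(ba$loa_high, 0)
  ba2 <- bland_altman(a + 0.5, a)
  expect_equal(ba2$mean_difference, 0.5)
  expect_equal(ba2$loa_low, 0.5)
  expect_equal(ba2$loa_high, 0.5)
  # constant series: correlation undefined by documented convention
  ba3 <- bland_altman(rep(2, 4), c(1, 2, 3, 4))
  expect_true(is.na(ba3$pearson_r))
})

test_that("bland_altman matches the closed form on a fixed 4-point input", {
  a <- c(1, 2, 3, 4)
  b <- c(1.1, 1.9, 3.2, 3.8)
  d <- a - b
  ba <- bland_altman(a, b)
  m <- sum(d) / 4
  s <- sqrt(sum((d - m)^2) / 3)
  expect_equal(ba$mean_difference, m, tolerance = 1e-12)
  expect_equal(ba$sd_difference, s, tolerance = 1e-12)
  expect_equal(ba$loa_low, m - 1.96 * s, tolerance = 1e-12)
  expect_equal(ba$loa_high, m + 1.96 * s, tolerance = 1e-12)
  expect_equal(ba$pearson_r, cor(a, b), tolerance = 1e-12)
  expect_error(bland_altman(1:3, 1:4), "parameter error")
})

test_that("limits of agreement bracket at least 93% of Gaussian differences", {
  set.seed(11)
  a <- rnorm(1000, 5, 1)
  b <- a + rnorm(1000, 0, 0.4)
  ba <- bland_altman(a, b)
  inside <- mean(ba$differences >= ba$loa_low & ba$differences <= ba$loa_high)
  expect_gte(inside, 0.93)
})

test_that("thickness comparison separates disjoint samples and equates identical ones", {
  same <- thickness_distribution_compare(1:40, 1:40)
  expect_gt(same$p_value, 0.99)
  expect_equal(same$summary_a, same$summary_b)
  apart <- thickness_distribution_compare(1:100, 201:300)
  expect_lt(apart$p_value, 1e-10)
  expect_error(thickness_distribution_compare(numeric(0), 1:3),
               "parameter error")
})

test_that("quartiles follow the linear-interpolation convention", {
  x <- c(10, 20, 30, 40, 50)
  s <- thickness_distribution_compare(x, x)$summary_a
  expect_equal(s$median, 30)
  expect_equal(s$q1, 20)
  expect_equal(s$q3, 40)
})
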