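# Lumen segmentation: binarization, snake, cleanup, area.

test_that("a step-edge wall yields border radii at the step on every A-line", {
  polar <- vessel_polar(rep(100, 360))
  init <- binarize_lumen(polar)
  expect_true(all(abs(init$contour$radii_px - 100) <= 1))
})

test_that("a blank image is a segmentation error", {
  polar <- polar_from_function(function(a, d) 0, 120, 80)
  expect_error(binarize_lumen(polar), "no tissue signal")
})

test_that("an elliptical border is recovered within 2 px on 95% of A-lines", {
  theta <- 2 * pi * (0:359) / 360
  radii <- 120 * 80 / sqrt((80 * cos(theta))^2 + (120 * sin(theta))^2)
  polar <- vessel_polar(radii)
  init <- binarize_lumen(polar)
  err <- abs(init$contour$radii_px - radii)
  expect_gte(mean(err <= 2), 0.95)
})

test_that("the snake is a fixed point on a strong edge", {
  polar <- vessel_polar(rep(100, 360))
  init <- lumen_contour_for_test(rep(100, 360))
  out <- refine_snake(polar, init)
  expect_lt(max(abs(out$radii_px - 100)), 0.5)
})

test_that("with zero smoothness weights each radius climbs to its local gradient maximum", {
  radii <- rep(100, 360)
  polar <- vessel_polar(radii)
  params <- oct_config(snake = list(alpha = 0, beta = 0))$snake
  init <- lumen_contour_for_test(rep(103, 360))
  out <- refine_snake(polar, init, params)
  # independent 1-D oracle: greedy hill climb on the gradient field
  sm <- t(as.matrix(EBImage::gblur(EBImage::Image(t(polar$intensities) / 255),
                                   sigma = 3.0)))
  nd <- ncol(sm)
  Gm <- cbind(0, abs(sm[, 3:nd] - sm[, 1:(nd - 2)]) / 2, 0)
  climb <- function(a, r0) {
    r <- r0 + 1  # 1-based column
    repeat {
      left <- if (r > 1) Gm[a, r - 1] else -Inf
      right <- if (r < nd) Gm[a, r + 1] else -Inf
      if (left > Gm[a, r] && left >= right) r <- r - 1
      else if (right > Gm[a, r]) r <- r + 1
      else return(r - 1)
    }
  }
  oracle <- vapply(1:360, climb, numeric(1), r0 = 103)
  expect_true(all(abs(out$radii_px - oracle) <= 1))
})

test_that("an outward-offset initialization converges back to a circular border", {
  polar <- vessel_polar(rep(100, 360))
  init <- lumen_contour_for_test(rep(105, 360))
  out <- refine_snake(polar, init)
  expect_lt(max(abs(out$radii_px - 100)), 1)
})

test_that("snake energy is non-increasing across iterations", {
  theta <- 2 * pi * (0:359) / 360
  radii <- 100 + 8 * cos(2 * theta)
  polar <- vessel_polar(radii)
  init <- lumen_contour_for_test(rep(100, 360))
  out <- refine_snake(polar, init)
  trace <- attr(out, "energy_trace")
  expect_true(all(diff(trace) <= 1e-9))
})

test_that("postprocessing is a near no-op on smooth contours", {
  theta <- 2 * pi * (0:359) / 360
  radii <- 100 + 6 * cos(theta)
  polar <- vessel_polar(radii)
  contour <- lumen_contour_for_test(radii)
  out <- postprocess_contour(contour, polar)
  expect_lt(max(abs(out$radii_px - radii)), 1.01)
  expect_equal(out$source, "postprocessed")
})

test_that("postprocessing repairs a one-A-line spike and a two-A-line dropout", {
  radii <- rep(100, 360)
  radii[50] <- 120        # outward spike
  radii[200:201] <- 0     # dropout
  polar <- vessel_polar(rep(100, 360))
  out <- postprocess_contour(lumen_contour_for_test(radii), polar)
  expect_lt(abs(out$radii_px[50] - mean(out$radii_px[c(49, 51)])), 2)
  expect_true(all(abs(out$radii_px[200:201] - 100) <= 2))
})

test_that("postprocessed contours satisfy the adjacency smoothness bound", {
  set.seed(4)
  radii <- 100 + cumsum(rnorm(360))
  radii <- radii - mean(radii) + 100
  radii[c(10, 90, 250)] <- radii[c(10, 90, 250)] + 25
  polar <- vessel_polar(pmax(radii, 60))
  out <- postprocess_contour(lumen_contour_for_test(pmax(radii, 60)), polar,
                             smoothness_bound = 15)
  jumps <- abs(diff(c(out$radii_px, out$radii_px[1])))
  expect_lte(max(jumps), 15)
})

test_that("lumen area matches analytic circle and ellipse areas within 1%", {
  polar <- vessel_polar(rep(100, 360))
  circle <- lumen_contour_for_test(rep(100, 360), source = "postprocessed")
  expect_equal(lumen_area(circle, polar, 0.01), pi, tolerance = 0.01)
  theta <- 2 * pi * (0:359) / 360
  radii <- 120 * 80 / sqrt((80 * cos(theta))^2 + (120 * sin(theta))^2)
  ell <- lumen_contour_for_test(radii, source = "postprocessed")
  expect_equal(lumen_area(ell, polar, 0.01), pi * 1.2 * 0.8,
               tolerance = 0.01)
  degenerate <- lumen_contour_for_test(rep(0, 360), source = "postprocessed")
  a0 <- lumen_area(degenerate, polar, 0.01)
  expect_equal(as.numeric(a0), 0)
  expect_true(isTRUE(attr(a0, "degenerate")))
})

test_that("area scales with the square of the calibration", {
  polar <- vessel_polar(rep(90, 360))
  contour <- lumen_contour_for_test(rep(90, 360), source = "postprocessed")
  a1 <- lumen_area(contour, polar, 0.01)
  a2 <- lumen_area(contour, polar, 0.02)
  expect_equal(a2 / a1, 4)
})

test_that("rotation leaves the measured lumen area almost unchanged", {
  spec1 <- phantom_spec(seed = 3, fourier = list(c = c(8, 5), phi = c(0.3, 1.1)),
                        struts = NULL)
  ph1 <- generate_phantom(spec1)
  spec2 <- phantom_spec(seed = 3, fourier = list(c = c(8, 5),
                                                 phi = c(0.3, 1.1) + pi / 3),
                        struts = NULL)
  ph2 <- generate_phantom(spec2)
  r1 <- analyze_frame(ph1$frame_clean)
  r2 <- analyze_frame(ph2$frame_clean)
  expect_lt(abs(r1$lumen_area_mm2 - r2$lumen_area_mm2) / r1$lumen_area_mm2,
            0.01)
})

test_that("segmentation of noise-free phantoms overlaps the truth at Dice >= 0.97", {
  suite <- generate_suite(5, "clean", seed = 42)
  for (ph in suite$phantoms) {
    rec <- analyze_frame(ph$frame_clean)
    expect_null(rec$error)
    expect_gte(lumen_dice(rec$lumen$radii_px, ph$truth$lumen_radii), 0.97)
  }
})
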