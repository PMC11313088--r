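# Stent contour/area, neointimal thickness, coverage classification.

test_that("evenly spaced equal-radius struts give a constant stent contour", {
  struts <- do.call(rbind, lapply(seq(0, 315, by = 45), fake_strut,
                                  anterior_radius_px = 110))
  fit <- fit_stent_contour(struts, 360)
  expect_true(fit$valid)
  expect_true(all(abs(fit$radii_px - 110) < 1e-6))
})

test_that("two struts are insufficient support", {
  struts <- rbind(fake_strut(0, 110), fake_strut(180, 110))
  fit <- fit_stent_contour(struts, 360)
  expect_false(fit$valid)
  expect_match(fit$reason, "insufficient")
})

test_that("struts confined to a small arc invalidate the contour", {
  struts <- do.call(rbind, lapply(c(0, 20, 40, 60), fake_strut,
                                  anterior_radius_px = 110))
  fit <- fit_stent_contour(struts, 360)
  expect_false(fit$valid)
  expect_match(fit$reason, "arc|circumference")
})

test_that("struts sampled from an ellipse interpolate to the analytic ellipse", {
  a_ax <- 130; b_ax <- 100
  alines <- seq(0, 330, by = 30)
  theta <- 2 * pi * alines / 360
  radii <- a_ax * b_ax / sqrt((b_ax * cos(theta))^2 + (a_ax * sin(theta))^2)
  struts <- do.call(rbind, Map(fake_strut, alines, radii))
  fit <- fit_stent_contour(struts, 360)
  th_all <- 2 * pi * (0:359) / 360
  truth <- a_ax * b_ax / sqrt((b_ax * cos(th_all))^2 + (a_ax * sin(th_all))^2)
  expect_true(fit$valid)
  expect_lte(max(abs(fit$radii_px - truth)), 2)
})

test_that("stent area matches analytic circle and ellipse values within 1%", {
  polar <- polar_from_function(function(a, d) 0, 360, 200)
  circ <- fit_stent_contour(do.call(rbind, lapply(seq(0, 315, by = 45),
                                                  fake_strut,
                                                  anterior_radius_px = 110)),
                            360)
  expect_equal(as.numeric(stent_area(circ, polar, 0.01)), pi * 1.1^2,
               tolerance = 0.01)
  a_ax <- 130; b_ax <- 100
  alines <- seq(0, 330, by = 30)
  theta <- 2 * pi * alines / 360
  radii <- a_ax * b_ax / sqrt((b_ax * cos(theta))^2 + (a_ax * sin(theta))^2)
  ell <- fit_stent_contour(do.call(rbind, Map(fake_strut, alines, radii)), 360)
  expect_equal(as.numeric(stent_area(ell, polar, 0.01)), pi * 1.3 * 1.0,
               tolerance = 0.01)
})

test_that("invalid contours report a reason instead of an area", {
  polar <- polar_from_function(function(a, d) 0, 360, 200)
  fit <- fit_stent_contour(fake_strut(0, 100)[0, ], 360)
  sa <- stent_area(fit, polar, 0.01)
  expect_true(is.na(sa))
  expect_match(attr(sa, "reason"), "insufficient")
})

test_that("neointimal thickness is the radial gap, clamped at zero", {
  polar <- polar_from_function(function(a, d) 0, 360, 200)
  lumen <- lumen_contour_for_test(rep(100, 360), "postprocessed")
  expect_equal(neointimal_thickness(lumen, fake_strut(10, 120), polar, 0.01),
               200)
  expect_equal(neointimal_thickness(lumen, fake_strut(10, 100), polar, 0.01),
               0)
  # strut protruding 2 px into the lumen clamps to zero
  expect_equal(neointimal_thickness(lumen, fake_strut(10, 98), polar, 0.01),
               0)
  expect_error(neointimal_thickness(lumen, fake_strut(400, 110), polar, 0.01),
               "geometry error")
})

test_that("coverage labels follow the both-sides rule", {
  n <- 360
  strut <- fake_strut(100, 105, span_lo = 98L, span_width = 5L)
  # tissue on both sides: lumen well anterior of the strut plane
  both <- lumen_contour_for_test(rep(100, n), "postprocessed")
  expect_equal(classify_strut(both, strut)$label, "covered")
  # tissue on one side only
  one <- rep(100, n)
  one[(98 - 3):(98 - 0)] <- 105  # clockwise side pushed to the strut plane
  expect_equal(classify_strut(lumen_contour_for_test(one, "postprocessed"),
                              strut)$label, "uncovered")
  # no tissue anywhere: strut at the lumen border
  bare <- lumen_contour_for_test(rep(105, n), "postprocessed")
  cls <- classify_strut(bare, strut)
  expect_equal(cls$label, "uncovered")
  expect_false(cls$covered_ccw || cls$covered_cw)
})

test_that("side windows wrap across the A-line seam", {
  n <- 360
  strut <- fake_strut(0, 105, span_lo = 358L, span_width = 4L)
  lumen <- lumen_contour_for_test(rep(100, n), "postprocessed")
  expect_equal(classify_strut(lumen, strut)$label, "covered")
})

test_that("adding tissue on a side never flips covered to uncovered", {
  n <- 360
  strut <- fake_strut(100, 105, span_lo = 98L, span_width = 5L)
  for (gap in seq(1, 10, by = 1)) {
    lum <- lumen_contour_for_test(rep(105 - gap, n), "postprocessed")
    lab1 <- classify_strut(lum, strut)$label
    lum2 <- lumen_contour_for_test(rep(105 - gap - 1, n), "postprocessed")
    lab2 <- classify_strut(lum2, strut)$label
    if (lab1 == "covered") expect_equal(lab2, "covered")
  }
})

test_that("measured thickness distribution matches the generating one", {
  suite <- generate_suite(12, "clean", seed = 5)
  meas <- c(); truth <- c()
  for (ph in suite$phantoms) {
    rec <- analyze_frame(ph$frame_clean)
    if (!is.null(rec$error)) next
    meas <- c(meas, rec$struts$thickness_um)
    truth <- c(truth, ph$truth$struts$thickness_um)
  }
  cmpr <- thickness_distribution_compare(meas, truth)
  expect_gt(cmpr$p_value, 0.05)
})
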