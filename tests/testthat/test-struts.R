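# Ring mask, shadow segmentation, profile criteria, strut localization.

test_that("ring mask thickness follows a uniform wall band", {
  polar <- polar_from_function(function(a, d)
    ifelse(d >= 100 & d < 140, 200, 0), 360, 220)
  lumen <- lumen_contour_for_test(rep(100, 360), "postprocessed")
  mask <- build_ring_mask(polar, lumen)
  expect_true(all(abs(mask$thickness_px - 40) <= 3))
})

test_that("ring mask clamps on uniformly bright and on shadowed A-lines", {
  bright <- polar_from_function(function(a, d) 200, 360, 220)
  lumen <- lumen_contour_for_test(rep(100, 360), "postprocessed")
  mb <- build_ring_mask(bright, lumen, max_thickness = 80)
  expect_true(all(mb$thickness_px == 80))
  dark <- polar_from_function(function(a, d) 0, 360, 220)
  md <- build_ring_mask(dark, lumen, min_thickness = 10)
  expect_true(all(md$thickness_px == 10))
})

test_that("eight strut shadows give eight components of the expected span", {
  spec <- phantom_spec(seed = 2, struts = data.frame(
    theta_deg = seq(0, 315, by = 45), thickness_px = 6,
    shadow_alines = 4L, shadow_atten = 0.05))
  ph <- generate_phantom(spec)
  lumen <- segment_lumen(ph$polar)
  mask <- build_ring_mask(ph$polar, lumen)
  comps <- segment_shadows(ph$polar, mask)
  expect_length(comps, 8)
  spans <- vapply(comps, `[[`, integer(1), "span_width")
  expect_true(all(abs(spans - 4) <= 2))
})

test_that("a uniform wall contains no shadow components", {
  polar <- vessel_polar(rep(100, 360))
  lumen <- lumen_contour_for_test(rep(100, 360), "postprocessed")
  mask <- build_ring_mask(polar, lumen)
  comps <- segment_shadows(polar, mask)
  expect_length(comps, 0)
})

test_that("two struts separated by one A-line of wall stay separate or are flagged", {
  spec <- phantom_spec(seed = 2, allow_close = TRUE, struts = data.frame(
    theta_deg = c(90, 95), thickness_px = 6, shadow_alines = 4L,
    shadow_atten = 0.05, bloom_sigma_px = 1.8))
  ph <- generate_phantom(spec)
  lumen <- segment_lumen(ph$polar)
  mask <- build_ring_mask(ph$polar, lumen)
  comps <- segment_shadows(ph$polar, mask)
  struts <- locate_struts(ph$polar, mask, comps)
  expect_true(nrow(struts) == 2 || attr(struts, "merge_events") > 0)
})

test_that("A-line profiles preserve offsets, lengths and constants", {
  polar <- polar_from_function(function(a, d) 77, 360, 220)
  lumen <- lumen_contour_for_test(rep(100, 360), "postprocessed")
  mask <- build_ring_mask(polar, lumen, max_thickness = 50)
  prof <- aline_profile(polar, 10, mask)
  expect_length(prof, mask$thickness_px[11])
  expect_true(all(prof == 77))
  expect_error(aline_profile(polar, 360, mask), "out of range")
})

test_that("a bloom at depth 105 tops the profile at offset 5", {
  polar <- polar_from_function(function(a, d)
    ifelse(d < 100, 2, 100 * exp(-(d - 100) / 30)) +
      250 * exp(-(d - 105)^2 / 4), 360, 220)
  lumen <- lumen_contour_for_test(rep(100, 360), "postprocessed")
  mask <- build_ring_mask(polar, lumen)
  prof <- aline_profile(polar, 50, mask)
  expect_equal(which.max(prof), 105 - attr(prof, "inner_radius_px"))
})

test_that("profile criteria accept a sharp peak with a drop and reject flats and plateaus", {
  expect_null(detect_strut_in_profile(rep(50, 20)))
  # bright peak followed by a clear drop: hand-check both criteria
  p <- c(20, 20, 200, 15, 10, 10, 10, 10)
  expect_equal(detect_strut_in_profile(p), 3L)
  # bright tissue plateau without a drop behind it
  expect_null(detect_strut_in_profile(c(20, 180, 180, 180, 180)))
  expect_error(detect_strut_in_profile(p, drop_fraction = 1.5), "drop_fraction")
})

test_that("raising the height threshold never increases detections", {
  ph <- generate_phantom(phantom_spec(seed = 13, speckle_L = 4))
  lumen <- segment_lumen(ph$polar)
  mask <- build_ring_mask(ph$polar, lumen)
  comps <- segment_shadows(ph$polar, mask)
  counts <- vapply(c(1, 2, 3, 5, 8, 15), function(k) {
    crit <- oct_config(profile = list(k = k))$profile
    nrow(locate_struts(ph$polar, mask, comps, crit))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("struts on a clean phantom localize within 1 A-line and 2 px", {
  spec <- phantom_spec(seed = 8, struts = data.frame(
    theta_deg = seq(0, 324, by = 36), thickness_px = c(0, 3, 6, 12, 25,
                                                       0, 3, 6, 12, 25)))
  ph <- generate_phantom(spec)
  lumen <- segment_lumen(ph$polar)
  mask <- build_ring_mask(ph$polar, lumen)
  comps <- segment_shadows(ph$polar, mask)
  struts <- locate_struts(ph$polar, mask, comps)
  expect_equal(nrow(struts), 10)
  idx <- match(struts$aline_mid, ph$truth$struts$aline)
  # allow cyclic distance for the angular error
  dal <- abs(struts$aline_mid - ph$truth$struts$aline[idx])
  dal <- pmin(dal, 360 - dal)
  expect_true(all(dal <= 1))
  expect_true(all(abs(struts$anterior_radius_px -
                      ph$truth$struts$anterior_radius_px[idx]) <= 2))
})

test_that("strut detection is deterministic and one-per-A-line", {
  ph <- generate_phantom(phantom_spec(seed = 31, speckle_L = 4))
  run <- function() {
    lumen <- segment_lumen(ph$polar)
    mask <- build_ring_mask(ph$polar, lumen)
    comps <- segment_shadows(ph$polar, mask)
    locate_struts(ph$polar, mask, comps)
  }
  s1 <- run(); s2 <- run()
  expect_identical(s1, s2)
  expect_false(any(duplicated(s1$aline_mid)))
})

test_that("a dark wedge without a bloom (calcification-like shadow) yields no strut", {
  polar <- polar_from_function(function(a, d) {
    base <- ifelse(d < 100, 2, 180 * exp(-(d - 100) / 30))
    ifelse(a >= 120 & a <= 124 & d >= 100, base * 0.08, base)
  }, 360, 220)
  lumen <- lumen_contour_for_test(rep(100, 360), "postprocessed")
  mask <- build_ring_mask(polar, lumen)
  comps <- segment_shadows(polar, mask)
  expect_gte(length(comps), 1)
  struts <- locate_struts(polar, mask, comps)
  expect_equal(nrow(struts), 0)
})
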