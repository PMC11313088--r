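# Shared fixture builders. Everything is generated in code at test time.

# Uniform gray RGB frame.
flat_frame <- function(size = 201L, value = 128, calibration = 0.01) {
  px <- array(value, dim = c(size, size, 3L))
  oct_frame(px, 0L, calibration)
}

# Frame with a filled bright circle of given radius at the center.
disc_frame <- function(size = 201L, radius = 50, value = 255,
                       calibration = 0.01) {
  c0 <- (size - 1) / 2
  row <- matrix(0:(size - 1), size, size)
  col <- t(row)
  d <- sqrt((row - c0)^2 + (col - c0)^2)
  m <- ifelse(d <= radius, value, 0)
  px <- array(0, dim = c(size, size, 3L))
  for (ch in 1:3) px[, , ch] <- m
  oct_frame(px, 0L, calibration)
}

# Polar image built directly from a function I(aline_row, depth0based).
polar_from_function <- function(f, n_alines = 360L, n_depth = 200L,
                                calibration = 0.01) {
  I <- outer(seq_len(n_alines), 0:(n_depth - 1L), function(a, d) {
    v <- f(a, d)
    if (length(v) == 1L) rep(v, length(a)) else v
  })
  structure(list(intensities = I, red = I, n_alines = n_alines,
                 n_depth = n_depth, center = c(n_depth, n_depth),
                 radial_step_px = 1, calibration_mm_per_px = calibration,
                 frame_index = 0L),
            class = "oct_polar")
}

# Polar image of a clean vessel: dark lumen to radius r(a), wall beyond with
# exponential falloff.
vessel_polar <- function(radii, n_depth = 200L, wall = 180, falloff = 30,
                         calibration = 0.01) {
  polar_from_function(function(a, d) {
    r <- radii[a]
    ifelse(d < r, 2, wall * exp(-(d - r) / falloff))
  }, n_alines = length(radii), n_depth = n_depth,
  calibration = calibration)
}

# Bare lumen contour for exercising snake/postprocessing/area directly.
lumen_contour_for_test <- function(radii, source = "binarization") {
  structure(list(radii_px = radii, n_alines = length(radii), source = source),
            class = "oct_lumen")
}

# A fabricated strut row in the shape locate_struts() returns.
fake_strut <- function(aline_mid, anterior_radius_px, span_lo = NULL,
                       span_width = 4L, n_alines = 360L) {
  if (is.null(span_lo)) span_lo <- (aline_mid - 1L) %% n_alines
  data.frame(aline_mid = aline_mid, anterior_radius_px = anterior_radius_px,
             peak_intensity = 250, theta_deg = 360 * aline_mid / n_alines,
             x_px = NA_real_, y_px = NA_real_, shadow_id = 1L,
             span_lo = span_lo, span_width = span_width)
}

# Brute-force optimal one-to-one matching count under a distance tolerance
# (independent oracle for the greedy matcher on small instances).
optimal_match_count <- function(dist_um, tol_um) {
  nd <- nrow(dist_um); nr <- ncol(dist_um)
  if (nd == 0L || nr == 0L) return(0L)
  best <- 0L
  # enumerate all injective assignments of detected -> reference
  assign_next <- function(i, used, count) {
    if (count + (nd - i + 1L) <= best) return()
    if (i > nd) { best <<- max(best, count); return() }
    assign_next(i + 1L, used, count)  # leave detection i unmatched
    for (j in seq_len(nr)) {
      if (!used[j] && dist_um[i, j] <= tol_um) {
        used[j] <- TRUE
        assign_next(i + 1L, used, count + 1L)
        used[j] <- FALSE
      }
    }
  }
  assign_next(1L, rep(FALSE, nr), 0L)
  best
}

# Access the package-internal all-strut table for self-match references.
report_strut_table_for_test <- function(report) {
  octcov:::report_strut_table(report)
}
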