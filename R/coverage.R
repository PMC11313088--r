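# Stent contour and area, neointimal thickness, covered/uncovered
# classification.

#' Fit the stent contour through detected struts
#'
#' Periodic monotone-cubic interpolation (Fritsch-Carlson, on a cyclically
#' extended node set) of anterior-edge radius versus angle through the strut
#' midpoints. The contour is only `valid` when at least `min_support` struts
#' span at least `min_arc_deg` of the circumference; otherwise the stent
#' area is not reported -- the failure mode seen when visible struts are
#' confined to a small part of the stent circumference.
#'
#' @param struts an `oct_struts` data.frame (may be empty).
#' @param n_alines number of A-lines of the polar grid.
#' @param min_support minimum number of supporting struts (default 3).
#' @param min_arc_deg minimum angular span of the supports (default 180).
#' @return object of class `oct_stent`: list with `radii_px` (per A-line,
#'   `NA` when invalid), `valid`, `reason`, `support_struts`.
#' @export
fit_stent_contour <- function(struts, n_alines, min_support = 3L,
                              min_arc_deg = 180) {
  n <- as.integer(n_alines)
  invalid <- function(reason)
    structure(list(radii_px = rep(NA_real_, n), valid = FALSE,
                   reason = reason, support_struts = struts),
              class = "oct_stent")
  if (is.null(struts) || nrow(struts) < min_support)
    return(invalid(sprintf("insufficient struts (%d < %d)",
                           if (is.null(struts)) 0L else nrow(struts),
                           min_support)))
  theta <- sort(2 * pi * struts$aline_mid / n)
  gaps <- diff(c(theta, theta[1] + 2 * pi))
  arc_deg <- (2 * pi - max(gaps)) * 180 / pi
  if (arc_deg < min_arc_deg)
    return(invalid(sprintf(
      "struts span only %.0f deg of circumference (< %.0f deg)",
      arc_deg, min_arc_deg)))
  ord <- order(struts$aline_mid)
  th <- 2 * pi * struts$aline_mid[ord] / n
  ra <- struts$anterior_radius_px[ord]
  fun <- splinefun(c(th - 2 * pi, th, th + 2 * pi), rep(ra, 3),
                   method = "monoH.FC")
  radii <- fun(2 * pi * (0:(n - 1L)) / n)
  structure(list(radii_px = pmax(radii, 0), valid = TRUE, reason = NULL,
                 support_struts = struts),
            class = "oct_stent")
}

#' @export
print.oct_stent <- function(x, ...) {
  if (x$valid)
    cat(sprintf("<oct_stent> valid, %d supporting struts\n",
                nrow(x$support_struts)))
  else cat(sprintf("<oct_stent> invalid: %s\n", x$reason))
  invisible(x)
}

#' Stent area
#'
#' Shoelace area of the Cartesian-mapped stent contour, or `NA` with a
#' `reason` attribute when the contour is invalid (a reported status, not
#' an error, so pullback summaries can skip such frames transparently).
#'
#' @param contour an `oct_stent`.
#' @param polar the matching `oct_polar`.
#' @param calibration_mm_per_px positive calibration.
#' @return area in mm^2, or `NA` with attribute `"reason"`.
#' @export
stent_area <- function(contour, polar,
                       calibration_mm_per_px = polar$calibration_mm_per_px) {
  stopifnot(inherits(contour, "oct_stent"))
  if (!contour$valid)
    return(structure(NA_real_, reason = contour$reason))
  poly <- map_contour_to_cartesian(contour$radii_px, polar)
  shoelace_area(poly) * calibration_mm_per_px^2
}

#' Neointimal thickness of one strut
#'
#' Radial (along the A-line) distance from the lumen contour to the strut's
#' anterior edge, clamped at zero for struts protruding into the lumen (a
#' negative tissue thickness has no physical meaning; the side flags decide
#' such a strut's label).
#'
#' @param lumen a postprocessed `oct_lumen`.
#' @param strut one row of an `oct_struts` data.frame.
#' @param polar the matching `oct_polar`.
#' @param calibration_mm_per_px positive calibration.
#' @return thickness in micrometres.
#' @export
neointimal_thickness <- function(lumen, strut, polar,
                                 calibration_mm_per_px =
                                   polar$calibration_mm_per_px) {
  stopifnot(inherits(lumen, "oct_lumen"))
  mid <- strut$aline_mid
  if (mid < 0 || mid >= lumen$n_alines)
    stop("geometry error: aline_mid out of range")
  gap_px <- max(0, strut$anterior_radius_px - lumen$radii_px[mid + 1L])
  gap_px * polar$radial_step_px * calibration_mm_per_px * 1000
}

#' Covered/uncovered classification of one strut
#'
#' The strut shadow hides tissue directly behind the strut, so coverage is
#' judged laterally: on each side, over `side_window_alines` A-lines just
#' beyond the shadow span, the strut's anterior-edge radius is compared with
#' the lumen contour. A side counts as covered when the median radial gap
#' (strut radius minus lumen radius) is at least `min_cover_px`. A strut is
#' `covered` only when both sides are; tissue on one side only, or none,
#' makes it `uncovered`.
#'
#' @param lumen a postprocessed `oct_lumen`.
#' @param strut one row of an `oct_struts` data.frame.
#' @param side_window_alines lateral window width (default 3); windows wrap
#'   cyclically.
#' @param min_cover_px minimum radial gap counting as tissue (default 2:
#'   the lumen boundary and the anterior edge each carry a half-pixel
#'   boundary convention, so a bare strut measures a gap of one pixel --
#'   two pixels is the smallest gap distinguishable from quantization).
#' @return data.frame with `covered_ccw`, `covered_cw`, `label`.
#' @export
classify_strut <- function(lumen, strut, side_window_alines = 3L,
                           min_cover_px = 2) {
  stopifnot(inherits(lumen, "oct_lumen"))
  n <- lumen$n_alines
  lo <- strut$span_lo            # 0-based first A-line of the shadow span
  w <- strut$span_width
  ccw_lines <- (lo + w + 0:(side_window_alines - 1L)) %% n
  cw_lines <- (lo - 1L - 0:(side_window_alines - 1L)) %% n
  gap <- function(lines)
    median(strut$anterior_radius_px - lumen$radii_px[lines + 1L])
  covered_ccw <- gap(ccw_lines) >= min_cover_px
  covered_cw <- gap(cw_lines) >= min_cover_px
  data.frame(covered_ccw = covered_ccw, covered_cw = covered_cw,
             label = if (covered_ccw && covered_cw) "covered" else "uncovered")
}
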