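# Cartesian <-> polar resampling. All detection operates in the polar
# (A-line x depth) domain; the convention shared across the package is:
#   theta_a = 2*pi*a / n_alines for A-line a = 0 .. n_alines-1,
#   A-line 0 points along +x (3 o'clock), angle increases counter-clockwise
#   on the displayed image (rows grow downward, so y = center_row - d*sin).
# Pixel coordinates are 0-based (row, col).

#' Resample an OCT frame into polar coordinates
#'
#' Samples the frame's grayscale luminance (and, separately, its red
#' channel) along `n_alines` radial scan lines centered on the catheter
#' position. Sample `(a, d)` is the interpolated source value at
#' `center + d * radial_step * (cos theta_a, sin theta_a)`; positions
#' outside the raster are 0.
#'
#' @param frame an [oct_frame()].
#' @param n_alines number of A-lines (>= 90); default 360, one per degree.
#' @param n_depth number of radial samples (>= 64); default the inscribed
#'   radius of the frame around the catheter center.
#' @param radial_step_px source pixels per depth sample (default 1).
#' @param interpolation `"bilinear"` (default) or `"nearest"`.
#' @return an object of class `oct_polar`: list with `intensities` and
#'   `red` (`n_alines` x `n_depth` matrices, 0-255), `n_alines`, `n_depth`,
#'   `center` (0-based row, col of the source frame), `radial_step_px`,
#'   `calibration_mm_per_px` and `frame_index` carried over from the frame.
#' @seealso [to_cartesian()], [map_contour_to_cartesian()]
#' @export
to_polar <- function(frame, n_alines = 360L, n_depth = NULL,
                     radial_step_px = 1, interpolation = "bilinear") {
  stopifnot(inherits(frame, "oct_frame"))
  n_alines <- as.integer(n_alines)
  if (n_alines < 90L) stop("n_alines must be >= 90")
  h <- dim(frame$pixels)[1]; w <- dim(frame$pixels)[2]
  cr <- frame$catheter_center[1]; cc <- frame$catheter_center[2]
  if (cr < 0 || cr > h - 1 || cc < 0 || cc > w - 1)
    stop("geometry error: catheter center outside raster")
  if (is.null(n_depth))
    n_depth <- floor(min(cr, cc, h - 1 - cr, w - 1 - cc) / radial_step_px)
  n_depth <- as.integer(n_depth)
  if (n_depth < 64L) stop("n_depth must be >= 64")

  gray <- 0.299 * frame$pixels[, , 1] + 0.587 * frame$pixels[, , 2] +
          0.114 * frame$pixels[, , 3]
  red <- frame$pixels[, , 1]

  theta <- 2 * pi * (0:(n_alines - 1L)) / n_alines
  d <- (0:(n_depth - 1L)) * radial_step_px
  # sample grid (1-based for the matrices)
  rows <- (cr + 1) - outer(sin(theta), d)
  cols <- (cc + 1) + outer(cos(theta), d)
  if (identical(interpolation, "nearest")) {
    rows <- round(rows); cols <- round(cols)
  } else if (!identical(interpolation, "bilinear")) {
    stop("interpolation must be 'bilinear' or 'nearest'")
  }
  ints <- matrix(bilinear_sample(gray, as.vector(rows), as.vector(cols)),
                 n_alines, n_depth)
  reds <- matrix(bilinear_sample(red, as.vector(rows), as.vector(cols)),
                 n_alines, n_depth)
  structure(list(intensities = ints, red = reds,
                 n_alines = n_alines, n_depth = n_depth,
                 center = c(cr, cc), radial_step_px = radial_step_px,
                 calibration_mm_per_px = frame$calibration_mm_per_px,
                 frame_index = frame$frame_index),
            class = "oct_polar")
}

#' Resample a polar image back to Cartesian coordinates
#'
#' Inverse of [to_polar()] with the stored center and radial step. Pixels
#' outside the sampled annulus are 0.
#'
#' @param polar an `oct_polar` object.
#' @param out_height,out_width output raster size; defaults reproduce a
#'   raster just covering the sampled disk around the stored center.
#' @param channel `"intensities"` (default) or `"red"`.
#' @return a numeric `out_height` x `out_width` matrix (0-255).
#' @export
to_cartesian <- function(polar, out_height = NULL, out_width = NULL,
                         channel = c("intensities", "red")) {
  stopifnot(inherits(polar, "oct_polar"))
  channel <- match.arg(channel)
  img <- polar[[channel]]
  n <- polar$n_alines; nd <- polar$n_depth
  step <- polar$radial_step_px
  cr <- polar$center[1]; cc <- polar$center[2]
  rmax <- (nd - 1) * step
  if (is.null(out_height)) out_height <- ceiling(cr + rmax) + 1L
  if (is.null(out_width)) out_width <- ceiling(cc + rmax) + 1L

  row0 <- rep(0:(out_height - 1L), times = out_width)
  col0 <- rep(0:(out_width - 1L), each = out_height)
  dx <- col0 - cc
  dy <- cr - row0
  d <- sqrt(dx * dx + dy * dy) / step
  theta <- atan2(dy, dx) %% (2 * pi)
  a <- theta * n / (2 * pi)

  out <- numeric(out_height * out_width)
  ok <- d <= (nd - 1)
  if (any(ok)) {
    av <- a[ok]; dv <- d[ok]
    a0 <- floor(av); fa <- av - a0
    d0 <- pmin(floor(dv), nd - 2L); d0 <- pmax(d0, 0L); fd <- dv - d0
    r1 <- (a0 %% n) + 1L
    r2 <- ((a0 + 1L) %% n) + 1L
    c1 <- d0 + 1L; c2 <- d0 + 2L
    v <- img[cbind(r1, c1)] * (1 - fa) * (1 - fd) +
         img[cbind(r2, c1)] * fa       * (1 - fd) +
         img[cbind(r1, c2)] * (1 - fa) * fd +
         img[cbind(r2, c2)] * fa       * fd
    out[ok] <- v
  }
  matrix(out, out_height, out_width)
}

#' Map a per-A-line radius contour into frame pixel coordinates
#'
#' @param radii_px one radial position per A-line (depth samples, all >= 0).
#' @param polar the `oct_polar` carrying center and radial step.
#' @return closed polygon as an `n_alines` x 2 matrix of 0-based
#'   `(x_px, y_px)` vertices (closure is implicit: last joins first).
#' @export
map_contour_to_cartesian <- function(radii_px, polar) {
  stopifnot(inherits(polar, "oct_polar"))
  n <- polar$n_alines
  if (length(radii_px) != n)
    stop("geometry error: need one radius per A-line")
  if (any(!is.finite(radii_px)) || any(radii_px < 0))
    stop("geometry error: radii must be finite and non-negative")
  theta <- 2 * pi * (0:(n - 1L)) / n
  r <- radii_px * polar$radial_step_px
  cbind(x_px = polar$center[2] + r * cos(theta),
        y_px = polar$center[1] - r * sin(theta))
}

#' @export
print.oct_polar <- function(x, ...) {
  cat(sprintf("<oct_polar> %d A-lines x %d depth samples, step %.3g px, center (%.1f, %.1f)\n",
              x$n_alines, x$n_depth, x$radial_step_px,
              x$center[1], x$center[2]))
  invisible(x)
}
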