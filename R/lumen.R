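# Lumen segmentation: binarization seed, cyclic radial snake, morphological
# cleanup, area. The contour is parameterized as one radius per A-line
# (star-shaped around the catheter), which makes the active-contour energy
# well-posed and matches how analysts trace a lumen.

lumen_contour <- function(radii_px, source) {
  structure(list(radii_px = radii_px, n_alines = length(radii_px),
                 source = source),
            class = "oct_lumen")
}

#' @export
print.oct_lumen <- function(x, ...) {
  cat(sprintf("<oct_lumen> %d A-lines, source '%s', radius %.1f-%.1f px\n",
              x$n_alines, x$source, min(x$radii_px), max(x$radii_px)))
  invisible(x)
}

#' Initial lumen contour by binarization
#'
#' Thresholds the polar image (Otsu by default) and, scanning outward along
#' each A-line, takes the start of the first above-threshold run of at least
#' `min_run` samples as the lumen border -- the first bright tissue beyond
#' the dark lumen. A-lines with no qualifying run (guidewire shadows) are
#' filled by cyclic linear interpolation from their neighbours.
#'
#' @param polar an `oct_polar`.
#' @param threshold_method `"otsu"` or `"fixed"`.
#' @param fixed_value threshold (0-255) when `threshold_method = "fixed"`.
#' @param min_run minimum run length in depth samples (default 3), skipping
#'   isolated bright noise before the wall.
#' @return list with `binary` (logical matrix) and `contour`
#'   (an `oct_lumen` with source `"binarization"`).
#' @export
binarize_lumen <- function(polar, threshold_method = c("otsu", "fixed"),
                           fixed_value = NULL, min_run = 3L) {
  stopifnot(inherits(polar, "oct_polar"))
  threshold_method <- match.arg(threshold_method)
  img <- polar$intensities
  thr <- if (threshold_method == "fixed") {
    if (is.null(fixed_value)) stop("configuration error: fixed_value required")
    fixed_value
  } else {
    if (max(img) <= min(img))
      stop("segmentation error: no tissue signal (flat image)")
    255 * EBImage::otsu(EBImage::Image(t(img) / 255), range = c(0, 1))
  }
  bin <- img > thr
  n <- polar$n_alines
  radii <- rep(NA_real_, n)
  for (a in seq_len(n)) {
    r <- rle(bin[a, ])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    hit <- which(r$values & r$lengths >= min_run)
    if (length(hit)) radii[a] <- starts[hit[1]] - 1L  # 0-based depth
  }
  if (all(is.na(radii)))
    stop("segmentation error: no tissue signal")
  radii <- fill_cyclic_na(radii)
  list(binary = bin, contour = lumen_contour(radii, "binarization"))
}

#' Refine a lumen contour with a cyclic radial active contour
#'
#' Minimizes, over per-A-line radii r (cyclic in a),
#' \deqn{E = \sum_a \alpha (r_{a+1}-r_a)^2 + \beta (r_{a+1}-2r_a+r_{a-1})^2
#'   - w_{edge} G(a, r_a)}
#' where G is the radial intensity-gradient magnitude (normalized to
#' \[0, 1\]). Minimization is cyclic coordinate descent over a 3-coloring of
#' the A-lines with a small candidate move set scaled by `gamma`; each
#' accepted move strictly decreases the energy, so the energy trace is
#' non-increasing by construction. Iteration stops when the mean absolute
#' radial move per sweep falls below `convergence_tol` or at `max_iter`
#' (non-convergence logs a warning and returns the best iterate).
#'
#' @param polar an `oct_polar`.
#' @param init an `oct_lumen` initial contour.
#' @param params list of snake parameters (see [oct_config()] section
#'   `snake`): `alpha`, `beta`, `gamma`, `w_edge`, `max_iter`,
#'   `convergence_tol`.
#' @return an `oct_lumen` with source `"snake_refined"`; the per-sweep
#'   energy is attached as attribute `"energy_trace"`.
#' @export
refine_snake <- function(polar, init, params = oct_config()$snake) {
  stopifnot(inherits(polar, "oct_polar"), inherits(init, "oct_lumen"))
  if (params$max_iter < 1L || params$max_iter > 10000L)
    stop("max_iter must be in [1, 10000]")
  n <- polar$n_alines; nd <- polar$n_depth
  alpha <- params$alpha; beta <- params$beta
  w_edge <- params$w_edge; gamma <- params$gamma

  # radial gradient magnitude of the smoothed image, range [0, 1]; the
  # blur width sets the capture range of the edge force
  sm <- t(as.matrix(EBImage::gblur(EBImage::Image(t(polar$intensities) / 255),
                                   sigma = 3.0)))
  G <- cbind(0, abs(sm[, 3:nd] - sm[, 1:(nd - 2)]) / 2, 0)
  if (max(G) > 0) G <- G / max(G)

  gsamp <- function(rows, r) {
    # linear interpolation of G along depth at radius r (0-based depth)
    x <- pmin(pmax(r + 1, 1), nd)
    x0 <- pmin(floor(x), nd - 1)
    f <- x - x0
    G[cbind(rows, x0)] * (1 - f) + G[cbind(rows, x0 + 1)] * f
  }
  idx_wrap <- function(i) ((i - 1L) %% n) + 1L
  local_energy <- function(rows, v, r) {
    rm2 <- r[idx_wrap(rows - 2L)]; rm1 <- r[idx_wrap(rows - 1L)]
    rp1 <- r[idx_wrap(rows + 1L)]; rp2 <- r[idx_wrap(rows + 2L)]
    alpha * ((v - rm1)^2 + (rp1 - v)^2) +
      beta * ((rm2 - 2 * rm1 + v)^2 + (rm1 - 2 * v + rp1)^2 +
              (v - 2 * rp1 + rp2)^2) -
      w_edge * gsamp(rows, v)
  }
  total_energy <- function(r) {
    rp1 <- r[c(2:n, 1L)]; rm1 <- r[c(n, 1:(n - 1L))]
    sum(alpha * (rp1 - r)^2 + beta * (rp1 - 2 * r + rm1)^2 -
        w_edge * gsamp(seq_len(n), r))
  }

  r <- pmin(pmax(init$radii_px, 0), nd - 1)
  deltas <- gamma * c(-10, -5, -2, -1, 1, 2, 5, 10)
  trace <- numeric(0)
  converged <- FALSE
  for (iter in seq_len(params$max_iter)) {
    moved <- 0
    for (color in 0:2) {
      rows <- which((seq_len(n) - 1L) %% 3L == color)
      e0 <- local_energy(rows, r[rows], r)
      best_v <- r[rows]; best_e <- e0
      for (d in deltas) {
        v <- pmin(pmax(r[rows] + d, 0), nd - 1)
        e <- local_energy(rows, v, r)
        upd <- e < best_e - 1e-12
        best_v[upd] <- v[upd]; best_e[upd] <- e[upd]
      }
      moved <- moved + sum(abs(best_v - r[rows]))
      r[rows] <- best_v
    }
    trace <- c(trace, total_energy(r))
    if (moved / n < params$convergence_tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("snake did not converge within max_iter; returning best iterate")
  out <- lumen_contour(r, "snake_refined")
  attr(out, "energy_trace") <- trace
  out
}

#' Morphological cleanup of a lumen contour
#'
#' Rasterizes the enclosed region in the polar domain, applies closing then
#' opening with a disk (filling narrow dropouts and shaving one-A-line
#' spikes), discards connected components smaller than `min_blob_px`,
#' re-extracts the boundary per A-line, and enforces the adjacency
#' smoothness bound with a cyclic running median.
#'
#' @param contour an `oct_lumen`.
#' @param polar the `oct_polar` the contour lives in.
#' @param min_blob_px minimum component area kept (default 20).
#' @param closing_radius disk radius for closing/opening (default 2). The
#'   disk sets the smallest angular feature the contour can represent:
#'   radius 2 repairs one-A-line spikes and two-A-line dropouts while
#'   keeping genuine features such as a bare-sided coverage step.
#' @param smoothness_bound maximum allowed adjacent-radius jump, px.
#' @return an `oct_lumen` with source `"postprocessed"`.
#' @export
postprocess_contour <- function(contour, polar, min_blob_px = 20L,
                                closing_radius = 2L, smoothness_bound = 15) {
  stopifnot(inherits(contour, "oct_lumen"), inherits(polar, "oct_polar"))
  n <- polar$n_alines; nd <- polar$n_depth
  r <- pmin(pmax(contour$radii_px, 0), nd - 1)
  mask <- outer(r, 0:(nd - 1L), function(ri, d) d < ri)
  mask[, 1] <- TRUE  # the catheter center is always inside the lumen
  pad <- closing_radius + 1L
  padded <- rbind(mask[(n - pad + 1L):n, , drop = FALSE], mask,
                  mask[1:pad, , drop = FALSE])
  kern <- EBImage::makeBrush(2L * closing_radius + 1L, "disc")
  m <- EBImage::opening(EBImage::closing(padded * 1, kern), kern)
  m <- m[(pad + 1L):(pad + n), , drop = FALSE] > 0.5
  m[, 1] <- TRUE
  lab <- EBImage::bwlabel(m * 1)
  keep <- which(tabulate(lab[lab > 0]) >= min_blob_px)
  center_lab <- unique(lab[, 1])
  keep <- union(keep, center_lab[center_lab > 0])
  m <- matrix(lab %in% keep, n, nd)
  if (!any(m)) stop("segmentation error: empty region after cleaning")
  count0 <- pmax(pmin(ceiling(r), nd), 1)  # inside-samples of the input
  radii <- numeric(n)
  for (a in seq_len(n)) {
    row <- m[a, ]
    stop_at <- which(!row)
    count <- if (length(stop_at)) stop_at[1] - 1L else nd
    # where the morphology left the A-line untouched keep the input's
    # sub-pixel radius; where it repaired a defect the boundary lies
    # between the last inside and first outside sample (half-pixel
    # convention) -- rasterization alone must not quantize the contour
    radii[a] <- if (count == count0[a]) r[a] else count - 0.5
  }
  radii[radii <= 0] <- NA
  if (all(is.na(radii))) stop("segmentation error: empty region after cleaning")
  radii <- fill_cyclic_na(radii)
  # enforce smoothness: replace outliers w.r.t. the cyclic running median
  for (pass in 1:20) {
    med <- cyclic_median_filter(radii, 5L)
    bad <- abs(radii - med) > smoothness_bound
    if (!any(bad)) break
    radii[bad] <- med[bad]
  }
  lumen_contour(radii, "postprocessed")
}

#' Lumen area
#'
#' Area of the Cartesian-mapped contour polygon (shoelace formula) scaled by
#' the squared calibration. Computing on the Cartesian polygon rather than
#' counting polar pixels avoids angular-sampling bias.
#'
#' @param contour an `oct_lumen` (expected `"postprocessed"`).
#' @param polar the matching `oct_polar`.
#' @param calibration_mm_per_px positive calibration.
#' @return area in mm^2; a degenerate all-zero contour returns 0 with
#'   attribute `degenerate = TRUE`.
#' @export
lumen_area <- function(contour, polar,
                       calibration_mm_per_px = polar$calibration_mm_per_px) {
  stopifnot(inherits(contour, "oct_lumen"))
  if (calibration_mm_per_px <= 0) stop("calibration must be positive")
  if (all(contour$radii_px == 0))
    return(structure(0, degenerate = TRUE))
  poly <- map_contour_to_cartesian(contour$radii_px, polar)
  shoelace_area(poly) * calibration_mm_per_px^2
}

#' Dice overlap of two lumen contours
#'
#' Area-weighted Dice coefficient of the star-shaped regions described by
#' two per-A-line radius vectors on the same polar grid (each wedge
#' contributes r^2, the polar area element).
#'
#' @param radii_a,radii_b per-A-line radii in depth samples.
#' @return Dice coefficient in \[0, 1\].
#' @export
lumen_dice <- function(radii_a, radii_b) {
  stopifnot(length(radii_a) == length(radii_b))
  2 * sum(pmin(radii_a, radii_b)^2) / (sum(radii_a^2) + sum(radii_b^2))
}

#' Segment the lumen of a polar image (binarize + snake + cleanup)
#'
#' Convenience wrapper running [binarize_lumen()], [refine_snake()] and
#' [postprocess_contour()] with the given configuration.
#'
#' @param polar an `oct_polar`.
#' @param config an [oct_config()].
#' @return an `oct_lumen` with source `"postprocessed"`.
#' @export
segment_lumen <- function(polar, config = oct_config()) {
  init <- binarize_lumen(polar, config$lumen$threshold_method,
                         config$lumen$fixed_value, config$lumen$min_run)
  snk <- refine_snake(polar, init$contour, config$snake)
  postprocess_contour(snk, polar, config$post$min_blob_px,
                      config$post$closing_radius,
                      config$post$smoothness_bound)
}
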