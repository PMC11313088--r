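# Strut detection: adaptive ring mask over the vessel wall, strut-shadow
# segmentation on the red channel, per-A-line intensity-profile criteria,
# and strut localization at the midpoint of the anterior edge.

#' Build the adaptive ring mask over the vessel wall
#'
#' For each A-line the mask starts at the lumen border and extends to the
#' depth at which the (smoothed) wall signal has decayed below fraction `f`
#' of that A-line's peak wall intensity, clamped to
#' `[min_thickness, max_thickness]`; A-lines with no wall signal (below
#' `signal_floor`) clamp to `min_thickness`. The thickness profile is
#' median-filtered across A-lines (window 5).
#'
#' @param polar an `oct_polar`.
#' @param lumen a postprocessed `oct_lumen`.
#' @param f intensity fraction defining the outer edge (default 0.1).
#' @param min_thickness,max_thickness clamps in depth samples.
#' @param signal_floor gray level below which an A-line counts as shadowed.
#' @return object of class `oct_ring`: list with `inner_radii_px` (the
#'   lumen radii) and `thickness_px` (integer per A-line).
#' @export
build_ring_mask <- function(polar, lumen, f = 0.1, min_thickness = 10L,
                            max_thickness = 80L, signal_floor = 8) {
  stopifnot(inherits(polar, "oct_polar"), inherits(lumen, "oct_lumen"))
  n <- polar$n_alines; nd <- polar$n_depth
  inner <- round(lumen$radii_px)
  if (all(inner + min_thickness >= nd - 1L))
    stop("mask error: lumen touches the image edge on every A-line")
  thick <- integer(n)
  for (a in seq_len(n)) {
    lo <- inner[a] + 2L  # first column beyond the border (depth inner+1)
    if (lo > nd) { thick[a] <- min_thickness; next }
    prof <- polar$intensities[a, lo:nd]
    np <- length(prof)
    smwin <- min(5L, np)
    sm <- stats::filter(prof, rep(1 / smwin, smwin), sides = 2)
    sm[is.na(sm)] <- prof[is.na(sm)]
    peak <- max(sm); pk <- which.max(sm)
    if (peak < signal_floor) { thick[a] <- min_thickness; next }
    below <- which(sm < f * peak & seq_len(np) > pk)
    thick[a] <- if (length(below)) below[1] else max_thickness
  }
  thick <- pmin(pmax(thick, min_thickness), max_thickness)
  # the wall extent varies smoothly with angle; narrow dips are strut
  # shadows truncating their own A-lines, so inflate them from neighbours
  # (cyclic running max, window 9) before the median smoothing
  h <- 4L
  tp <- c(tail(thick, h), thick, head(thick, h))
  thick <- vapply(seq_len(n), function(i) max(tp[i:(i + 2L * h)]), numeric(1))
  thick <- as.integer(round(cyclic_median_filter(thick, 5L)))
  thick <- pmin(thick, nd - 1L - inner)
  thick <- pmax(thick, 1L)
  structure(list(inner_radii_px = lumen$radii_px, thickness_px = thick),
            class = "oct_ring")
}

# Logical n_alines x n_depth matrix of ring-mask membership.
ring_mask_matrix <- function(mask, n_depth) {
  inner <- round(mask$inner_radii_px)
  outer(seq_along(inner), 0:(n_depth - 1L),
        function(a, d) d > inner[a] & d <= inner[a] + mask$thickness_px[a])
}

#' Segment strut shadows within the ring mask
#'
#' Fixed pipeline on the red channel restricted to the mask: 3x3 median
#' filter, Gaussian smoothing (`sigma`), adaptive threshold against the
#' local mean over a `window` x `window` box (pixels *below* local mean +
#' `offset` are shadow -- strut shadows are dark), morphological opening
#' then closing (disk radius 1), connected components. Components smaller
#' than `min_area_px` are discarded; components spanning more than
#' `max_span` A-lines are split at local width minima (each split is
#' counted as a merge event in the `"split_events"` attribute).
#'
#' @param polar an `oct_polar`.
#' @param mask an `oct_ring`.
#' @param sigma Gaussian smoothing sigma (default 1).
#' @param window local-mean window in px (odd, default 31).
#' @param offset threshold offset in gray levels (default -10).
#' @param min_area_px minimum component area (default 6).
#' @param max_span maximum component span in A-lines (default 20).
#' @param merge_flag_span span (A-lines) beyond which an unsplittable
#'   component is flagged as a possible merge of adjacent struts
#'   (default 9: the largest plausible single-strut footprint).
#' @param use_red use the red channel (default); otherwise grayscale.
#' @return list of shadow components (class `oct_shadows`), each with
#'   `rows` (1-based A-line rows), `pixels` (m x 2 matrix of row, col),
#'   `area_px`, `span_lo`/`span_hi`/`span_width` (cyclic, 1-based rows).
#' @export
segment_shadows <- function(polar, mask, sigma = 1.0, window = 31L,
                            offset = -10, min_area_px = 6L, max_span = 20L,
                            merge_flag_span = 9L, use_red = TRUE) {
  stopifnot(inherits(polar, "oct_polar"), inherits(mask, "oct_ring"))
  n <- polar$n_alines; nd <- polar$n_depth
  mm <- ring_mask_matrix(mask, nd)
  if (!any(mm)) stop("mask error: empty ring mask")
  img <- (if (use_red) polar$red else polar$intensities) / 255

  med <- EBImage::medianFilter(t(img), 1L)           # 3x3
  sm <- as.matrix(EBImage::gblur(EBImage::Image(med), sigma = sigma))
  box <- matrix(1 / window^2, window, window)
  localmean <- as.matrix(EBImage::filter2(EBImage::Image(sm), box,
                                          boundary = "circular"))
  shadow <- t(sm < localmean + offset / 255) & mm

  pad <- 3L
  padded <- rbind(shadow[(n - pad + 1L):n, , drop = FALSE], shadow,
                  shadow[1:pad, , drop = FALSE]) * 1
  kern <- EBImage::makeBrush(3L, "disc")
  cleaned <- EBImage::closing(EBImage::opening(padded, kern), kern)
  shadow <- cleaned[(pad + 1L):(pad + n), , drop = FALSE] > 0.5

  lab <- EBImage::bwlabel(shadow * 1)
  nlab <- max(lab)
  if (nlab == 0) return(structure(list(), class = "oct_shadows",
                                  split_events = 0L))
  # merge labels that touch across the cyclic row seam (8-connectivity)
  parent <- seq_len(nlab)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (j in seq_len(nd)) {
    a <- lab[1L, j]
    if (a == 0) next
    for (dj in -1:1) {
      jj <- j + dj
      if (jj < 1 || jj > nd) next
      b <- lab[n, jj]
      if (b > 0) {
        ra <- find(a); rb <- find(b)
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
      }
    }
  }
  roots <- vapply(seq_len(nlab), find, integer(1))
  lab[lab > 0] <- roots[lab[lab > 0]]

  split_events <- 0L
  comps <- list()
  make_comp <- function(px) {
    span <- cyclic_span(px[, 1], n)
    list(rows = sort(unique(px[, 1])), pixels = px,
         area_px = nrow(px), span_lo = span$lo, span_hi = span$hi,
         span_width = span$width)
  }
  add_comp <- function(px) {
    # recursively split components that are wider than max_span, or that
    # show a pronounced interior width minimum (two shadows joined by a
    # thin neck -- the near-adjacent-strut merge case), at that minimum
    comp <- make_comp(px)
    if (nrow(px) < min_area_px) return(invisible())
    seqrows <- cyclic_seq(comp$span_lo, comp$span_hi, n)
    counts <- vapply(seqrows, function(rr) sum(px[, 1] == rr), numeric(1))
    cut_rel <- NA_integer_
    if (comp$span_width > max_span) {
      interior <- 2:(length(seqrows) - 1L)
      cut_rel <- interior[which.min(counts[interior])]
    } else if (comp$span_width >= 7L) {
      # only consider necks with at least 3 full rows on each side
      interior <- 4:(length(seqrows) - 3L)
      dips <- interior[counts[interior] <= 0.4 * median(counts)]
      if (length(dips)) cut_rel <- dips[which.min(counts[dips])]
    }
    if (is.na(cut_rel)) {
      comps[[length(comps) + 1L]] <<- comp
      return(invisible())
    }
    first <- seqrows[1:(cut_rel - 1L)]
    px_a <- px[px[, 1] %in% first, , drop = FALSE]
    px_b <- px[!px[, 1] %in% first, , drop = FALSE]
    if (nrow(px_a) == 0 || nrow(px_b) == 0) {
      comps[[length(comps) + 1L]] <<- comp
      return(invisible())
    }
    split_events <<- split_events + 1L
    add_comp(px_a); add_comp(px_b)
  }
  for (id in sort(unique(lab[lab > 0]))) {
    px <- which(lab == id, arr.ind = TRUE)
    colnames(px) <- c("row", "col")
    if (nrow(px) < min_area_px) next
    add_comp(px)
  }
  # components wider than a single strut's plausible footprint that the
  # dip rule could not split are still flagged as possible merges
  wide <- sum(vapply(comps, `[[`, integer(1), "span_width") >=
                merge_flag_span)
  structure(comps, class = "oct_shadows",
            split_events = split_events + wide)
}

#' Intensity profile of one A-line within the ring mask
#'
#' Grayscale intensities from just beyond the lumen border to the mask's
#' outer edge on that A-line. Element `j` of the profile sits at depth
#' offset `j` beyond the (rounded) inner radius, i.e. absolute depth
#' `inner + j`; the inner radius is attached as attribute
#' `"inner_radius_px"`.
#'
#' @param polar an `oct_polar`.
#' @param aline 0-based A-line index.
#' @param mask an `oct_ring`.
#' @param despeckle apply the depth-wise median-of-3 plus light Gaussian
#'   despeckling before extraction (default `FALSE`: raw intensities).
#' @return numeric vector of length `thickness_px[aline]`.
#' @export
aline_profile <- function(polar, aline, mask, despeckle = FALSE) {
  n <- polar$n_alines
  if (aline < 0 || aline >= n) stop("aline out of range")
  src <- if (despeckle) despeckle_depthwise(polar$intensities)
         else polar$intensities
  profile_from_matrix(src, aline + 1L, mask, polar$n_depth)
}

profile_from_matrix <- function(src, row, mask, n_depth) {
  inner <- round(mask$inner_radii_px[row])
  t_px <- mask$thickness_px[row]
  cols <- (inner + 2L):(inner + 1L + t_px)  # depths inner+1 .. inner+t
  cols <- cols[cols <= n_depth]
  prof <- src[row, cols]
  attr(prof, "inner_radius_px") <- inner
  prof
}

# Speckle suppression along depth only, so the angular footprint of
# neighbouring struts is never smeared together. The median of 3 preserves
# monotone ramps (hence edges) exactly; the optional Gaussian is used for
# the detection decisions, never for edge placement.
med3_depthwise <- function(I) {
  nd <- ncol(I)
  a <- I[, c(1L, 1:(nd - 1L))]
  b <- I[, c(2:nd, nd)]
  a + I + b - pmax(a, I, b) - pmin(a, I, b)
}

despeckle_depthwise <- function(I) {
  med <- med3_depthwise(I)
  k <- exp(-(-3:3)^2 / 2)
  k <- k / sum(k)
  sm <- t(apply(med, 1L, function(v)
    as.numeric(stats::filter(v, k, sides = 2))))
  sm[is.na(sm)] <- med[is.na(sm)]
  sm
}

#' Single-strut peak test on an A-line profile
#'
#' Candidates are the strongest local maxima of the profile, examined in
#' decreasing order of intensity (ties break to the smallest depth) -- a
#' strut bloom is not always the brightest sample on its A-line, e.g. under
#' thick neointima the tissue surface can outshine it, so a global
#' intensity rule is impractical and the slope of the profile decides. A
#' candidate is accepted iff (a) its peak exceeds `baseline + k * spread`,
#' with baseline and spread the median and MAD of the profile outside the
#' candidate's own contiguous footprint (robust to the peak itself), and
#' (b) the intensity falls below `drop_fraction * peak` within
#' `drop_window_px` samples behind the peak -- the "bright peak followed by
#' a clear drop" signature that separates a strut bloom (shadow behind)
#' from a bright tissue plateau. The first candidate passing both wins, so
#' at most one strut per A-line.
#'
#' @param profile numeric A-line profile (length >= 3), as returned by
#'   [aline_profile()].
#' @param k height threshold in robust spreads (default 3).
#' @param drop_fraction fraction of the peak the signal must fall below.
#' @param drop_window_px how far behind the peak to look for the drop.
#' @param max_candidates how many local maxima to examine (default 3);
#'   candidates dimmer than half the profile maximum are never considered.
#' @return the accepted peak's depth offset (same convention as the profile
#'   indices) or `NULL` when no strut is present.
#' @export
detect_strut_in_profile <- function(profile, k = 3.0, drop_fraction = 0.25,
                                    drop_window_px = 15L,
                                    max_candidates = 3L) {
  np <- length(profile)
  if (np < 3L) return(NULL)
  if (drop_fraction <= 0 || drop_fraction >= 1) stop("drop_fraction in (0,1)")
  if (drop_window_px < 1L) stop("drop_window_px >= 1")
  p <- as.numeric(profile)
  lagp <- c(-Inf, p[-np])
  leadp <- c(p[-1], -Inf)
  cand <- which(p >= lagp & p >= leadp & p >= 0.5 * max(p))
  cand <- cand[order(-p[cand], cand)]
  cand <- cand[seq_len(min(length(cand), max_candidates))]
  for (i in cand) {
    peak <- p[i]
    # background statistics exclude the candidate bloom's own footprint
    # (the contiguous run >= drop_fraction * peak around the peak);
    # otherwise a wide bloom over a deep shadow inflates the spread and
    # masks itself
    lo <- i
    while (lo > 1L && p[lo - 1L] >= drop_fraction * peak) lo <- lo - 1L
    hi <- i
    while (hi < np && p[hi + 1L] >= drop_fraction * peak) hi <- hi + 1L
    background <- p[-(lo:hi)]
    if (!length(background)) next
    baseline <- median(background)
    spread <- mad(background)
    if (!(peak > baseline + k * spread)) next
    if (i >= np) next  # nothing behind the peak, no drop evidence
    behind <- p[(i + 1L):min(i + drop_window_px, np)]
    if (min(behind) < drop_fraction * peak) return(i)
  }
  NULL
}

#' Localize struts from shadow components
#'
#' Runs [detect_strut_in_profile()] on every A-line of each shadow
#' component. A component yields a strut iff at least `min_hit_alines`
#' profiles accept. Ghost peaks (accepted peaks much deeper than the most
#' anterior accepted peak of the same component, the "multiplied strut in
#' the shadow" artifact) are discarded via `ghost_margin_px`. The strut
#' position is the midpoint of the anterior edge: the anterior edge on each
#' accepting A-line is the anterior end of the contiguous run of samples
#' >= 50% of the peak (peak minus the anterior half-width of the bloom),
#' and `aline_mid` is the cyclic median of the accepting A-lines. At most
#' one strut per A-line is returned.
#'
#' @param polar an `oct_polar`.
#' @param mask an `oct_ring`.
#' @param components an `oct_shadows` list from [segment_shadows()].
#' @param criteria list with `k`, `drop_fraction`, `drop_window_px`
#'   (see [oct_config()] section `profile`).
#' @param min_hit_alines minimum accepting A-lines per component
#'   (default 2: an isolated single-line acceptance is overwhelmingly a
#'   speckle artifact).
#' @param ghost_margin_px depth margin for ghost-peak rejection.
#' @return data.frame of class `oct_struts`: `aline_mid` (0-based),
#'   `anterior_radius_px`, `peak_intensity`, `theta_deg`, `x_px`, `y_px`,
#'   `shadow_id`, `span_lo` (0-based), `span_width`. Attribute
#'   `"merge_events"` carries the count of oversized-component splits.
#' @export
locate_struts <- function(polar, mask, components,
                          criteria = oct_config()$profile,
                          min_hit_alines = 2L, ghost_margin_px = 10) {
  stopifnot(inherits(polar, "oct_polar"), inherits(mask, "oct_ring"))
  n <- polar$n_alines
  empty <- data.frame(aline_mid = integer(0), anterior_radius_px = numeric(0),
                      peak_intensity = numeric(0), theta_deg = numeric(0),
                      x_px = numeric(0), y_px = numeric(0),
                      shadow_id = integer(0), span_lo = integer(0),
                      span_width = integer(0))
  out <- empty
  src_det <- despeckle_depthwise(polar$intensities)
  src_edge <- med3_depthwise(polar$intensities)
  for (ci in seq_along(components)) {
    comp <- components[[ci]]
    acc_row <- integer(0); acc_peak <- numeric(0)
    acc_radius <- numeric(0); acc_edge <- numeric(0)
    acc_clamped <- logical(0)
    for (row in comp$rows) {
      prof <- profile_from_matrix(src_det, row, mask, polar$n_depth)
      i <- detect_strut_in_profile(prof, criteria$k, criteria$drop_fraction,
                                   criteria$drop_window_px)
      if (is.null(i)) next
      inner <- attr(prof, "inner_radius_px")
      # edge placement on the ramp-preserving median-filtered profile:
      # re-center the peak locally, then walk toward the lumen while the
      # profile is strictly falling and stays >= 50% of the peak -- the
      # walk stops at the 50% crossing or at the dip separating the bloom
      # from the (brighter) tissue above it
      pe <- profile_from_matrix(src_edge, row, mask, polar$n_depth)
      win <- max(1L, i - 2L):min(length(pe), i + 2L)
      ie <- win[which.max(pe[win])]
      peak <- pe[[ie]]
      # walk anteriorly down the bloom flank; the edge is where the flank
      # ends: at the 50% crossing, at a dip (profile rising again toward
      # the brighter tissue), or where the slope collapses to under a
      # quarter of the steepest step seen (the bloom merging into the
      # gentle border ramp of thin coverage)
      j <- ie
      max_step <- 0
      while (j > 1L) {
        ahead <- pe[[j - 1L]]
        if (ahead < 0.5 * peak) break
        if (ahead >= pe[[j]]) break
        step <- pe[[j]] - ahead
        if (pe[[j]] <= 0.9 * peak && step < 0.25 * max_step) break
        max_step <- max(max_step, step)
        j <- j - 1L
      }
      acc_row <- c(acc_row, row)
      acc_peak <- c(acc_peak, peak)
      acc_radius <- c(acc_radius, inner + i)
      # the edge lies on the boundary between sample j-1 and sample j; a
      # walk that ran into the profile start found no interior edge
      acc_edge <- c(acc_edge, inner + j - 0.5)
      acc_clamped <- c(acc_clamped, j == 1L)
    }
    if (!length(acc_row)) next
    # majority vote on the peak depth: ghost peaks (deeper duplicates in
    # the shadow) and stray tissue-surface acceptances on shadow-edge
    # lines both sit far from the median accepted radius
    keep <- abs(acc_radius - median(acc_radius)) <= ghost_margin_px
    acc_row <- acc_row[keep]; acc_peak <- acc_peak[keep]
    acc_radius <- acc_radius[keep]; acc_edge <- acc_edge[keep]
    acc_clamped <- acc_clamped[keep]
    if (length(acc_row) < min_hit_alines) next
    # lines whose walk hit the profile start carry no edge information of
    # their own; ignore them unless every line clamped (bare strut at the
    # border)
    edge_pool <- if (any(!acc_clamped)) acc_edge[!acc_clamped] else acc_edge
    rel <- (acc_row - comp$span_lo) %% n
    mid_rel <- sort(rel)[ceiling(length(rel) / 2)]
    pick <- which.min(abs(rel - mid_rel))
    mid_row <- acc_row[pick]
    out <- rbind(out, data.frame(
      aline_mid = mid_row - 1L,
      # median over accepting A-lines: single shadow-edge lines that read
      # the neighbouring tissue surface instead of the bloom cannot drag
      # the strut position
      anterior_radius_px = median(edge_pool),
      peak_intensity = max(acc_peak),
      theta_deg = 360 * (mid_row - 1L) / n,
      x_px = NA_real_, y_px = NA_real_,
      shadow_id = ci,
      span_lo = comp$span_lo - 1L,
      span_width = comp$span_width))
  }
  if (nrow(out)) {
    # one strut per A-line: on collision keep the brighter peak
    out <- out[order(out$aline_mid, -out$peak_intensity), ]
    out <- out[!duplicated(out$aline_mid), ]
    theta <- 2 * pi * out$aline_mid / n
    r <- out$anterior_radius_px * polar$radial_step_px
    out$x_px <- polar$center[2] + r * cos(theta)
    out$y_px <- polar$center[1] - r * sin(theta)
    rownames(out) <- NULL
  }
  structure(out, class = c("oct_struts", "data.frame"),
            merge_events = attr(components, "split_events") %||% 0L)
}
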