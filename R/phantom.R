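# Synthetic OCT phantom generator with exact ground truth. The generative
# geometry is polar: a dark lumen inside a Fourier-shaped border, a tissue
# band with exponential depth falloff, metallic struts as Gaussian blooms
# whose 50% leading edge sits at the strut's anterior surface, radially
# trailing shadows, multiplicative gamma speckle, and optional guidewire
# shadow and colored overlay marks. The Cartesian frame is derived through
# the package's own inverse transform, which doubles as a regression test of
# the transform pair.

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Phantom specification
#'
#' Parameters of one synthetic OCT frame. The lumen border is the Fourier
#' radius function r(theta) = r0 + sum_k c_k cos(k theta + phi_k)
#' (K <= 4, |c_k| <= 0.15 r0). Struts are given per row of `struts`:
#' angular position, coverage thickness in px (the neointima over the
#' strut), bloom width (Gaussian sigma, px), bloom peak intensity, shadow
#' attenuation factor in \[0, 0.2\], shadow angular footprint in A-lines,
#' and optionally `uncovered_side` (`NA`, `"ccw"` or `"cw"`) to emulate
#' one-sided coverage. Speckle is multiplicative unit-mean gamma noise with
#' shape `speckle_L` (0 disables it).
#'
#' @param n_alines,n_depth polar grid size.
#' @param r0 mean lumen radius, px.
#' @param fourier list with `c` and `phi` (harmonic amplitudes/phases).
#' @param wall_intensity peak wall gray level at the border.
#' @param falloff_px exponential depth-attenuation constant of the wall.
#' @param lumen_bg residual gray level inside the lumen.
#' @param struts data.frame, one row per strut (see Details).
#' @param speckle_L gamma shape of the multiplicative speckle (0 = none).
#' @param guidewire `NULL` or `list(theta_deg, span_deg)`.
#' @param overlay_marks `FALSE`, `TRUE` (default corner marks) or a list of
#'   `list(row0, col0, h, w, rgb)` blocks.
#' @param calibration_mm_per_px calibration attached to the frame.
#' @param seed RNG seed for the speckle.
#' @param frame_index index attached to the frame.
#' @param allow_close skip the minimum strut separation check (used to
#'   construct the known near-adjacent-strut failure mode).
#' @return object of class `oct_phantom_spec`.
#' @export
phantom_spec <- function(n_alines = 360L, n_depth = 300L, r0 = 100,
                         fourier = list(c = numeric(0), phi = numeric(0)),
                         wall_intensity = 180, falloff_px = 30,
                         lumen_bg = 2, struts = default_phantom_struts(),
                         speckle_L = 0, guidewire = NULL,
                         overlay_marks = FALSE,
                         calibration_mm_per_px = 0.01, seed = 1L,
                         frame_index = 0L, allow_close = FALSE) {
  k <- length(fourier$c)
  if (k > 4L) stop("spec error: at most 4 Fourier harmonics")
  if (k && any(abs(fourier$c) > 0.15 * r0))
    stop("spec error: |c_k| must be <= 0.15 * r0")
  theta <- 2 * pi * (0:(n_alines - 1L)) / n_alines
  r <- rep(r0, n_alines)
  for (j in seq_len(k)) r <- r + fourier$c[j] * cos(j * theta + fourier$phi[j])
  if (any(r <= 0)) stop("spec error: lumen radius must stay positive")
  if (!is.null(struts) && nrow(struts)) {
    if (is.null(struts$bloom_sigma_px)) struts$bloom_sigma_px <- 2
    if (is.null(struts$bloom_peak)) struts$bloom_peak <- 250
    if (is.null(struts$shadow_atten)) struts$shadow_atten <- 0.1
    if (is.null(struts$shadow_alines)) struts$shadow_alines <- 4L
    if (is.null(struts$uncovered_side)) struts$uncovered_side <- NA_character_
    if (any(struts$thickness_px < 0)) stop("spec error: thickness_px >= 0")
    if (any(struts$shadow_atten < 0 | struts$shadow_atten > 0.2))
      stop("spec error: shadow_atten in [0, 0.2]")
    al <- sort(round(struts$theta_deg / 360 * n_alines)) %% n_alines
    if (nrow(struts) > 1L && !allow_close) {
      gaps <- diff(c(al, al[1] + n_alines))
      if (any(gaps < 8))
        stop("spec error: strut positions closer than the 8 A-line minimum")
    }
    hw <- struts$bloom_sigma_px * sqrt(2 * log(2))
    a_idx <- (round(struts$theta_deg / 360 * n_alines) %% n_alines) + 1L
    if (any(r[a_idx] + struts$thickness_px + 2 * hw +
            struts$bloom_sigma_px >= n_depth))
      stop("spec error: strut deeper than the polar grid")
  }
  structure(list(n_alines = as.integer(n_alines),
                 n_depth = as.integer(n_depth), r0 = r0, fourier = fourier,
                 wall_intensity = wall_intensity, falloff_px = falloff_px,
                 lumen_bg = lumen_bg, struts = struts,
                 speckle_L = speckle_L, guidewire = guidewire,
                 overlay_marks = overlay_marks,
                 calibration_mm_per_px = calibration_mm_per_px,
                 seed = as.integer(seed), frame_index = as.integer(frame_index),
                 allow_close = allow_close),
            class = "oct_phantom_spec")
}

#' @rdname phantom_spec
#' @export
default_phantom_struts <- function() {
  data.frame(theta_deg = seq(0, 315, by = 45),
             thickness_px = c(0, 3, 6, 12, 25, 6, 3, 0),
             bloom_sigma_px = 2, bloom_peak = 250,
             shadow_atten = 0.1, shadow_alines = 4L,
             uncovered_side = NA_character_)
}

#' Generate one synthetic OCT frame with ground truth
#'
#' Renders the phantom in polar coordinates per its spec, derives the
#' Cartesian RGB frame through [to_cartesian()], and computes the ground
#' truth analytically from the generating parameters: true lumen radii,
#' true strut positions/anterior radii/thicknesses with covered/uncovered
#' labels (covered iff the generating thickness is >= 1 px on both sides),
#' and true lumen/stent areas. Identical seeds give bit-identical output.
#'
#' @param spec an [phantom_spec()].
#' @return list with `frame` (overlay-marked when requested),
#'   `frame_clean`, `polar`, `truth` (class `oct_phantom_truth`) and
#'   `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "oct_phantom_spec"))
  n <- spec$n_alines; nd <- spec$n_depth
  theta <- 2 * pi * (0:(n - 1L)) / n
  r_base <- rep(spec$r0, n)
  for (j in seq_along(spec$fourier$c))
    r_base <- r_base + spec$fourier$c[j] * cos(j * theta + spec$fourier$phi[j])

  struts <- spec$struts
  r_true <- r_base
  side_window <- 3L
  if (!is.null(struts) && nrow(struts)) {
    # one-sided coverage: push the lumen border down to the strut plane on
    # the uncovered side so no tissue sits above the strut there
    for (s in seq_len(nrow(struts))) {
      us <- struts$uncovered_side[s]
      if (is.na(us) || struts$thickness_px[s] < 1) next
      a_s <- round(struts$theta_deg[s] / 360 * n) %% n
      wsh <- struts$shadow_alines[s]
      half <- (wsh - 1L) %/% 2L
      offs <- if (us == "ccw") (wsh - half):(wsh - half + side_window + 1L)
              else -(half + 1L):-(half + side_window + 2L)
      rows <- ((a_s + offs) %% n) + 1L
      r_true[rows] <- r_base[rows] + struts$thickness_px[s]
    }
  }

  D <- matrix(rep(0:(nd - 1L), each = n), n, nd)
  R <- matrix(r_true, n, nd)
  # partial-volume border: sample d covers [d-0.5, d+0.5), so the border
  # sample mixes lumen and wall and the intensity ramp centers exactly at
  # the generating radius
  w <- pmin(pmax(D + 0.5 - R, 0), 1)
  I <- (1 - w) * spec$lumen_bg +
    w * spec$wall_intensity * exp(-pmax(D - R, 0) / spec$falloff_px)

  truth_struts <- NULL
  if (!is.null(struts) && nrow(struts)) {
    for (s in seq_len(nrow(struts))) {
      a_s <- round(struts$theta_deg[s] / 360 * n) %% n
      t_px <- struts$thickness_px[s]
      sig <- struts$bloom_sigma_px[s]
      hw <- sig * sqrt(2 * log(2))
      wsh <- struts$shadow_alines[s]
      half <- (wsh - 1L) %/% 2L
      shadow_rows <- ((a_s + (-half):(wsh - 1L - half)) %% n) + 1L
      # shadow: attenuate everything behind the bloom
      for (row in shadow_rows) {
        dc <- r_true[row] + t_px + hw
        behind <- D[row, ] > dc + hw
        I[row, behind] <- I[row, behind] * struts$shadow_atten[s]
      }
      # bloom: Gaussian blob whose 50% leading edge is the anterior surface
      sig_a <- max(wsh / 2.355, 0.7)
      ext <- ceiling(3 * sig_a)
      bloom_rows <- ((a_s + (-ext):ext) %% n) + 1L
      da <- (-ext):ext
      for (bi in seq_along(bloom_rows)) {
        row <- bloom_rows[bi]
        dc <- r_true[row] + t_px + hw
        amp <- struts$bloom_peak[s] * exp(-da[bi]^2 / (2 * sig_a^2))
        prof <- amp * exp(-(D[row, ] - dc)^2 / (2 * sig^2))
        I[row, ] <- pmax(I[row, ], prof)
      }
    }
    a_idx <- (round(struts$theta_deg / 360 * n) %% n)
    label <- ifelse(struts$thickness_px >= 1 & is.na(struts$uncovered_side),
                    "covered", "uncovered")
    truth_struts <- data.frame(
      aline = a_idx,
      anterior_radius_px = r_true[a_idx + 1L] + struts$thickness_px,
      thickness_px = struts$thickness_px,
      thickness_um = struts$thickness_px * spec$calibration_mm_per_px * 1000,
      label = label)
  }

  if (!is.null(spec$guidewire)) {
    lo <- round((spec$guidewire$theta_deg - spec$guidewire$span_deg / 2) /
                  360 * n)
    hi <- round((spec$guidewire$theta_deg + spec$guidewire$span_deg / 2) /
                  360 * n)
    rows <- (lo:hi %% n) + 1L
    I[rows, D[1, ] > 5] <- I[rows, D[1, ] > 5] * 0.03
  }

  if (spec$speckle_L > 0) {
    I <- with_seed(spec$seed,
                   I * matrix(rgamma(n * nd, shape = spec$speckle_L,
                                     rate = spec$speckle_L), n, nd))
  }
  I <- pmin(pmax(I, 0), 255)

  polar <- structure(list(intensities = I, red = I, n_alines = n,
                          n_depth = nd, center = c(nd, nd),
                          radial_step_px = 1,
                          calibration_mm_per_px = spec$calibration_mm_per_px,
                          frame_index = spec$frame_index),
                     class = "oct_polar")
  gray <- to_cartesian(polar, 2L * nd + 1L, 2L * nd + 1L)
  px <- array(0, dim = c(2L * nd + 1L, 2L * nd + 1L, 3L))
  px[, , 1] <- gray; px[, , 2] <- gray; px[, , 3] <- gray
  frame_clean <- oct_frame(px, spec$frame_index, spec$calibration_mm_per_px,
                           c(nd, nd))
  frame <- frame_clean
  marks <- spec$overlay_marks
  if (isTRUE(marks)) marks <- default_overlay_marks(2L * nd + 1L, 2L * nd + 1L)
  if (is.list(marks) && length(marks)) {
    for (mk in marks) {
      rows <- (mk$row0 + 1L):(mk$row0 + mk$h)
      cols <- (mk$col0 + 1L):(mk$col0 + mk$w)
      for (ch in 1:3) px[rows, cols, ch] <- mk$rgb[ch]
    }
    frame <- oct_frame(px, spec$frame_index, spec$calibration_mm_per_px,
                       c(nd, nd))
  }

  if (!is.null(truth_struts)) {
    th <- 2 * pi * truth_struts$aline / n
    truth_struts$x_px <- nd + truth_struts$anterior_radius_px * cos(th)
    truth_struts$y_px <- nd - truth_struts$anterior_radius_px * sin(th)
  }
  lum_poly <- cbind(nd + r_true * cos(theta), nd - r_true * sin(theta))
  true_lumen_area <- shoelace_area(lum_poly) * spec$calibration_mm_per_px^2
  true_stent_area <- NA_real_
  if (!is.null(truth_struts) && nrow(truth_struts) >= 3L) {
    fit <- fit_stent_contour(
      data.frame(aline_mid = truth_struts$aline,
                 anterior_radius_px = truth_struts$anterior_radius_px),
      n)
    sa <- stent_area(fit, polar, spec$calibration_mm_per_px)
    true_stent_area <- as.numeric(sa)
  }
  truth <- structure(list(lumen_radii = r_true, struts = truth_struts,
                          lumen_area_mm2 = true_lumen_area,
                          stent_area_mm2 = true_stent_area,
                          calibration_mm_per_px = spec$calibration_mm_per_px),
                     class = "oct_phantom_truth")
  list(frame = frame, frame_clean = frame_clean, polar = polar,
       truth = truth, spec = spec)
}

default_overlay_marks <- function(h, w) {
  list(list(row0 = 4L, col0 = 4L, h = 12L, w = 60L, rgb = c(255, 255, 0)),
       list(row0 = h - 20L, col0 = w - 84L, h = 12L, w = 70L,
            rgb = c(0, 255, 255)))
}

#' Generate a randomized phantom suite
#'
#' Draws `n_frames` phantom specs at the given difficulty and renders them.
#' `"clean"` is noise-free; `"speckle"` adds the default multiplicative
#' speckle (gamma shape 4); `"hard"` additionally includes guidewire
#' shadows, overlay marks, thin (1-2 px) coverage, a near-adjacent strut
#' pair, and one frame whose struts are confined to under 180 degrees of
#' arc. Coverage thicknesses are drawn from the
#' \{0, 3, 6, 12, 25\} px strata (0-250 um at the default 0.01 mm/px).
#' The manifest records every spec for exact replay; two calls with the
#' same seed are identical.
#'
#' @param n_frames number of frames (>= 1).
#' @param difficulty `"clean"`, `"speckle"` or `"hard"`.
#' @param seed integer seed.
#' @return list with `phantoms` (list of [generate_phantom()] results) and
#'   `manifest` (list of specs), plus `difficulty` and `seed`.
#' @export
generate_suite <- function(n_frames, difficulty = c("clean", "speckle", "hard"),
                           seed = 1L) {
  difficulty <- match.arg(difficulty)
  stopifnot(n_frames >= 1L)
  manifest <- with_seed(seed, {
    lapply(seq_len(n_frames), function(i) {
      r0 <- runif(1, 80, 130)
      K <- sample(0:3, 1)
      fourier <- list(c = if (K) runif(K, 0, 0.08) * r0 else numeric(0),
                      phi = if (K) runif(K, 0, 2 * pi) else numeric(0))
      limited_arc <- difficulty == "hard" && i == 1L
      close_pair <- difficulty == "hard" && i %% 3L == 0L
      n_struts <- if (limited_arc) 4L else sample(6:10, 1)
      repeat {
        al <- if (limited_arc) sort(sample(0:119, n_struts))
              else sort(sample(0:359, n_struts))
        gaps <- diff(c(al, al[1] + 360L))
        if (all(gaps >= 8L)) break
      }
      if (close_pair) al <- c(al, (al[1] + 5L) %% 360L)
      ns <- length(al)
      strata <- if (difficulty == "hard") c(0, 1, 2, 3, 6, 12, 25)
                else c(0, 3, 6, 12, 25)
      struts <- data.frame(
        theta_deg = al * 360 / 360,
        thickness_px = sample(strata, ns, replace = TRUE),
        bloom_sigma_px = runif(ns, 1.6, 2.2),
        bloom_peak = runif(ns, 230, 255),
        shadow_atten = runif(ns, 0.05, 0.15),
        shadow_alines = sample(3:5, ns, replace = TRUE),
        uncovered_side = NA_character_)
      guidewire <- NULL
      if (difficulty == "hard" && i %% 2L == 0L) {
        gw_theta <- runif(1, 0, 360)
        ok <- all(pmin(abs(gw_theta - struts$theta_deg),
                       360 - abs(gw_theta - struts$theta_deg)) > 25)
        if (ok) guidewire <- list(theta_deg = gw_theta, span_deg = 18)
      }
      phantom_spec(
        r0 = r0, fourier = fourier,
        struts = struts,
        speckle_L = if (difficulty == "clean") 0 else 4,
        guidewire = guidewire,
        overlay_marks = difficulty == "hard",
        seed = (seed %% 65536L) * 32000L + i,
        frame_index = i - 1L,
        allow_close = close_pair)
    })
  })
  list(phantoms = lapply(manifest, generate_phantom),
       manifest = manifest, difficulty = difficulty, seed = seed)
}
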