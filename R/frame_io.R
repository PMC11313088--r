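# Frame containers, overlay removal, and pullback reading.

#' OCT frame container
#'
#' One Cartesian RGB cross-section plus its calibration and index within the
#' pullback. Pixel values are numeric 0-255; coordinates are 0-based
#' (row, col) with row increasing downward.
#'
#' @param pixels height x width x 3 numeric array, 0-255 per channel;
#'   height and width must be >= 64.
#' @param frame_index integer >= 0, position within the pullback.
#' @param calibration_mm_per_px positive isotropic calibration.
#' @param catheter_center 0-based `(row, col)` of the imaging catheter;
#'   default the raster center.
#' @return an object of class `oct_frame`.
#' @export
oct_frame <- function(pixels, frame_index = 0L, calibration_mm_per_px,
                      catheter_center = NULL) {
  if (length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stop("format error: pixels must be a height x width x 3 RGB array")
  h <- dim(pixels)[1]; w <- dim(pixels)[2]
  if (h < 64L || w < 64L) stop("format error: frame smaller than 64 px")
  if (!is.numeric(calibration_mm_per_px) || length(calibration_mm_per_px) != 1L ||
      !is.finite(calibration_mm_per_px) || calibration_mm_per_px <= 0)
    stop("configuration error: calibration_mm_per_px must be a positive number")
  frame_index <- as.integer(frame_index)
  if (frame_index < 0L) stop("frame_index must be >= 0")
  if (is.null(catheter_center)) catheter_center <- c((h - 1) / 2, (w - 1) / 2)
  if (catheter_center[1] < 0 || catheter_center[1] > h - 1 ||
      catheter_center[2] < 0 || catheter_center[2] > w - 1)
    stop("geometry error: catheter_center outside raster")
  structure(list(pixels = pixels, frame_index = frame_index,
                 calibration_mm_per_px = calibration_mm_per_px,
                 catheter_center = catheter_center),
            class = "oct_frame")
}

#' @export
print.oct_frame <- function(x, ...) {
  cat(sprintf("<oct_frame> #%d  %dx%d px, %.4g mm/px\n", x$frame_index,
              dim(x$pixels)[1], dim(x$pixels)[2], x$calibration_mm_per_px))
  invisible(x)
}

#' Overlay mask specification
#'
#' Vendor exports stamp colored markers and text over the frame; these are
#' removed with per-pixel color rules before any analysis. A rule is a
#' predicate on the three channel values plus a replacement strategy.
#' The default single rule targets saturated (non-gray) pixels --
#' `max(R,G,B) - min(R,G,B) > 60` -- since OCT tissue signal in vendor
#' exports is near-gray, and zero-fills them (overlays sit over the dark
#' lumen or outer field).
#'
#' @param rules list of rules; each a list with `predicate`
#'   (`function(r, g, b)` returning a logical vector) and `strategy`
#'   (`"zero_fill"` or `"radial_inpaint"`).
#' @return an object of class `oct_overlay_spec`.
#' @export
overlay_mask_spec <- function(rules = list(list(
    predicate = function(r, g, b) {
      pmax(r, g, b) - pmin(r, g, b) > 60
    },
    strategy = "zero_fill"))) {
  if (!length(rules)) stop("configuration error: at least one color rule required")
  for (rule in rules) {
    if (!is.function(rule$predicate)) stop("each rule needs a predicate function")
    if (!rule$strategy %in% c("zero_fill", "radial_inpaint"))
      stop("strategy must be 'zero_fill' or 'radial_inpaint'")
  }
  structure(list(rules = rules), class = "oct_overlay_spec")
}

#' Remove colored overlay markers from a frame
#'
#' Every pixel matching a color rule is replaced according to the rule's
#' strategy (`zero_fill` sets it to black; `radial_inpaint` copies the
#' nearest non-matching pixel walking inward along the ray toward the
#' catheter center). Non-matching pixels are untouched, so the operation is
#' idempotent.
#'
#' @param frame an [oct_frame()].
#' @param spec an [overlay_mask_spec()].
#' @return a new `oct_frame` of identical dimensions.
#' @export
remove_overlays <- function(frame, spec = overlay_mask_spec()) {
  stopifnot(inherits(frame, "oct_frame"))
  if (!inherits(spec, "oct_overlay_spec")) stop("spec must be an overlay_mask_spec")
  px <- frame$pixels
  h <- dim(px)[1]; w <- dim(px)[2]
  r <- px[, , 1]; g <- px[, , 2]; b <- px[, , 3]
  for (rule in spec$rules) {
    m <- rule$predicate(as.vector(r), as.vector(g), as.vector(b))
    m <- matrix(as.logical(m), h, w)
    m[is.na(m)] <- FALSE
    if (!any(m)) next
    if (rule$strategy == "zero_fill") {
      r[m] <- 0; g[m] <- 0; b[m] <- 0
    } else {
      idx <- which(m, arr.ind = TRUE)
      cr <- frame$catheter_center[1] + 1
      cc <- frame$catheter_center[2] + 1
      for (i in seq_len(nrow(idx))) {
        p <- idx[i, ]
        v <- c(cr, cc) - p
        len <- sqrt(sum(v^2))
        if (len < 1) { r[p[1], p[2]] <- 0; g[p[1], p[2]] <- 0; b[p[1], p[2]] <- 0; next }
        v <- v / len
        q <- p
        for (s in seq_len(ceiling(len))) {
          cand <- round(p + v * s)
          if (cand[1] < 1 || cand[1] > h || cand[2] < 1 || cand[2] > w) break
          if (!m[cand[1], cand[2]]) { q <- cand; break }
        }
        r[p[1], p[2]] <- r[q[1], q[2]]
        g[p[1], p[2]] <- g[q[1], q[2]]
        b[p[1], p[2]] <- b[q[1], q[2]]
      }
    }
  }
  px[, , 1] <- r; px[, , 2] <- g; px[, , 3] <- b
  oct_frame(px, frame$frame_index, frame$calibration_mm_per_px,
            frame$catheter_center)
}

#' Read an OCT pullback
#'
#' Reads either a multi-frame RGB DICOM file or a directory of single-frame
#' PNG/TIFF images (sorted by filename). Calibration is taken from the DICOM
#' pixel-spacing tag when present, otherwise from `calibration_override`;
#' having neither is an error, never a silent default.
#'
#' @param path DICOM file or directory of PNG/TIFF frames.
#' @param calibration_override optional positive mm-per-pixel value.
#' @return list of [oct_frame()] objects with contiguous indices from 0.
#' @export
read_pullback <- function(path, calibration_override = NULL) {
  if (!file.exists(path)) stop("I/O error: no such file or directory: ", path)
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.(png|tif|tiff)$",
                             ignore.case = TRUE, full.names = TRUE))
    if (!length(files)) stop("I/O error: no PNG/TIFF frames in ", path)
    if (is.null(calibration_override))
      stop("configuration error: calibration_mm_per_px unavailable; ",
           "single-image input requires calibration_override")
    frames <- vector("list", length(files))
    for (i in seq_along(files)) {
      img <- if (grepl("\\.png$", files[i], ignore.case = TRUE))
        png::readPNG(files[i]) else tiff::readTIFF(files[i])
      if (length(dim(img)) == 2L) stop("format error: non-RGB image: ", files[i])
      if (dim(img)[3] > 3L) img <- img[, , 1:3]
      frames[[i]] <- oct_frame(img * 255, i - 1L, calibration_override)
    }
    return(frames)
  }
  dc <- read_dicom_rgb(path)
  calib <- dc$pixel_spacing_mm %||% calibration_override
  if (is.null(calib))
    stop("configuration error: calibration_mm_per_px unavailable; DICOM has ",
         "no PixelSpacing tag and no calibration_override was given")
  lapply(seq_len(dc$n_frames), function(i)
    oct_frame(dc$frames[[i]], i - 1L, calib))
}

#' Write a pullback as multi-frame RGB DICOM
#'
#' Companion writer for [read_pullback()]; emits explicit-VR little-endian
#' DICOM with the tags the reader consumes (rows, columns, number of frames,
#' pixel spacing, interleaved 8-bit RGB pixel data). Intended for fixtures
#' and phantom suites; round-trips frame count, pixels and calibration
#' exactly.
#'
#' @param frames list of [oct_frame()]s of identical size and calibration.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pullback_dicom <- function(frames, path) {
  stopifnot(length(frames) >= 1L)
  write_dicom_rgb(lapply(frames, `[[`, "pixels"),
                  frames[[1]]$calibration_mm_per_px, path)
  invisible(path)
}
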