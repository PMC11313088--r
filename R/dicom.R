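# Minimal multi-frame RGB DICOM support (explicit VR little endian).
#
# No DICOM package ships with this toolchain, and the package only needs the
# handful of tags relevant to vendor OCT exports: rows, columns, number of
# frames, samples per pixel, photometric interpretation, pixel spacing, and
# the interleaved 8-bit pixel data. The writer emits exactly the tags the
# reader consumes; anything else in a file is parsed generically and skipped.

TRANSFER_SYNTAX_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
SOP_CLASS_SECONDARY_CAPTURE <- "1.2.840.10008.5.1.4.1.1.7"

uint16_le <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
uint32_le <- function(x) {
  x <- as.numeric(x)
  as.raw(c(x %% 256, (x %/% 256) %% 256, (x %/% 65536) %% 256,
           (x %/% 16777216) %% 256))
}

pad_even <- function(bytes, pad = as.raw(0)) {
  if (length(bytes) %% 2L) c(bytes, pad) else bytes
}

# One explicit-VR data element.
dicom_element <- function(group, element, vr, value_bytes) {
  long_form <- vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")
  header <- c(uint16_le(group), uint16_le(element), charToRaw(vr))
  if (long_form) {
    c(header, as.raw(c(0, 0)), uint32_le(length(value_bytes)), value_bytes)
  } else {
    if (length(value_bytes) > 65534) stop("value too long for short-form VR")
    c(header, uint16_le(length(value_bytes)), value_bytes)
  }
}

dicom_string <- function(group, element, vr, s) {
  pad <- if (vr == "UI") as.raw(0) else charToRaw(" ")
  dicom_element(group, element, vr, pad_even(charToRaw(s), pad))
}

dicom_us <- function(group, element, x) {
  dicom_element(group, element, "US", uint16_le(x))
}

# Write a list of height x width x 3 arrays (0-255) as one multi-frame file.
write_dicom_rgb <- function(pixel_arrays, pixel_spacing_mm, path) {
  h <- dim(pixel_arrays[[1]])[1]
  w <- dim(pixel_arrays[[1]])[2]
  n <- length(pixel_arrays)
  for (px in pixel_arrays)
    if (!identical(dim(px), c(h, w, 3L)) && !identical(dim(px), as.integer(c(h, w, 3))))
      stop("all frames must share dimensions height x width x 3")

  # interleaved RGB, row-major within each frame
  pixel_bytes <- as.raw(unlist(lapply(pixel_arrays, function(px) {
    v <- as.integer(round(aperm(px, c(3L, 2L, 1L))))
    pmin(pmax(v, 0L), 255L)
  }), use.names = FALSE))
  pixel_bytes <- pad_even(pixel_bytes)

  meta_body <- c(
    dicom_element(0x0002, 0x0001, "OB", as.raw(c(0, 1))),
    dicom_string(0x0002, 0x0002, "UI", SOP_CLASS_SECONDARY_CAPTURE),
    dicom_string(0x0002, 0x0003, "UI", "1.2.826.0.1.3680043.10.424.1"),
    dicom_string(0x0002, 0x0010, "UI", TRANSFER_SYNTAX_EXPLICIT_LE),
    dicom_string(0x0002, 0x0012, "UI", "1.2.826.0.1.3680043.10.424")
  )
  meta <- c(dicom_element(0x0002, 0x0000, "UL", uint32_le(length(meta_body))),
            meta_body)

  spacing <- sprintf("%.8g\\%.8g", pixel_spacing_mm, pixel_spacing_mm)
  dataset <- c(
    dicom_string(0x0008, 0x0016, "UI", SOP_CLASS_SECONDARY_CAPTURE),
    dicom_string(0x0008, 0x0018, "UI", "1.2.826.0.1.3680043.10.424.1"),
    dicom_us(0x0028, 0x0002, 3),
    dicom_string(0x0028, 0x0004, "CS", "RGB"),
    dicom_us(0x0028, 0x0006, 0),
    dicom_string(0x0028, 0x0008, "IS", as.character(n)),
    dicom_us(0x0028, 0x0010, h),
    dicom_us(0x0028, 0x0011, w),
    dicom_string(0x0028, 0x0030, "DS", spacing),
    dicom_us(0x0028, 0x0100, 8),
    dicom_us(0x0028, 0x0101, 8),
    dicom_us(0x0028, 0x0102, 7),
    dicom_us(0x0028, 0x0103, 0),
    dicom_element(0x7FE0, 0x0010, "OB", pixel_bytes)
  )

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(c(meta, dataset), con)
  invisible(path)
}

# Generic explicit-VR little-endian element walk; returns the tags of
# interest. Errors on files that are not DICM or not explicit VR LE.
read_dicom_rgb <- function(path) {
  bytes <- readBin(path, raw(), n = file.info(path)$size)
  if (length(bytes) < 140 || rawToChar(bytes[129:132]) != "DICM")
    stop("format error: not a DICOM file (missing DICM magic): ", path)
  pos <- 133L
  u16 <- function(i) as.integer(bytes[i]) + 256L * as.integer(bytes[i + 1L])
  u32 <- function(i) as.numeric(bytes[i]) + 256 * as.numeric(bytes[i + 1L]) +
    65536 * as.numeric(bytes[i + 2L]) + 16777216 * as.numeric(bytes[i + 3L])
  tags <- list()
  while (pos + 7L <= length(bytes)) {
    group <- u16(pos); element <- u16(pos + 2L)
    vr <- rawToChar(bytes[(pos + 4L):(pos + 5L)])
    if (!grepl("^[A-Z]{2}$", vr))
      stop("format error: implicit-VR or corrupt DICOM not supported")
    if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
      len <- u32(pos + 8L)
      val_start <- pos + 12L
    } else {
      len <- u16(pos + 6L)
      val_start <- pos + 8L
    }
    if (len == 4294967295) stop("format error: undefined-length elements not supported")
    value <- if (len > 0) bytes[val_start:(val_start + len - 1L)] else raw(0)
    key <- sprintf("%04x,%04x", group, element)
    tags[[key]] <- list(vr = vr, value = value)
    pos <- val_start + len
    if (group == 0x7FE0 && element == 0x0010) break
  }
  str_val <- function(key) {
    t <- tags[[key]]
    if (is.null(t)) return(NULL)
    v <- t$value
    trimws(rawToChar(v[v != as.raw(0)]))
  }
  us_val <- function(key) {
    t <- tags[[key]]
    if (is.null(t)) return(NULL)
    as.integer(t$value[1]) + 256L * as.integer(t$value[2])
  }
  photometric <- str_val("0028,0004")
  samples <- us_val("0028,0002") %||% 1L
  if (is.null(photometric) || photometric != "RGB" || samples != 3L)
    stop("format error: non-RGB DICOM payload (photometric ",
         photometric %||% "<missing>", ", samples ", samples, ")")
  rows <- us_val("0028,0010"); cols <- us_val("0028,0011")
  n_frames <- as.integer(str_val("0028,0008") %||% "1")
  spacing <- str_val("0028,0030")
  pixel_spacing_mm <- if (is.null(spacing)) NULL else
    as.numeric(strsplit(spacing, "\\\\")[[1]][1])
  pix <- tags[["7fe0,0010"]]
  if (is.null(pix)) stop("format error: no pixel data")
  need <- rows * cols * 3L * n_frames
  pv <- as.integer(pix$value[seq_len(need)])
  frames <- vector("list", n_frames)
  per <- rows * cols * 3L
  for (i in seq_len(n_frames)) {
    chunk <- pv[((i - 1L) * per + 1L):(i * per)]
    frames[[i]] <- aperm(array(chunk, dim = c(3L, cols, rows)), c(3L, 2L, 1L))
  }
  list(frames = frames, n_frames = n_frames, rows = rows, cols = cols,
       pixel_spacing_mm = pixel_spacing_mm)
}
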