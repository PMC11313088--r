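# End-to-end orchestration: per-frame analysis, pullback reports, and
# validation against reference annotations.

REPORT_SCHEMA <- "octcov-report-v1"

#' Analyze a single OCT frame
#'
#' Runs the full stage chain: overlay removal, polar transform, lumen
#' segmentation (binarize + snake + cleanup), ring mask, strut-shadow
#' segmentation, strut localization, stent contour/area, and per-strut
#' thickness and coverage classification.
#'
#' @param frame an [oct_frame()].
#' @param config an [oct_config()].
#' @return a per-frame record: list with `frame_index`, `lumen`
#'   (`oct_lumen`), `lumen_area_mm2`, `struts` (data.frame with
#'   `thickness_um`, `covered_ccw`, `covered_cw`, `label` appended),
#'   `stent_area_mm2` (`NA` with `stent_reason` when the contour is
#'   invalid), counts, `merge_events`, and -- when a stage failed --
#'   `error = list(stage, message)` with all later fields `NULL`.
#' @export
analyze_frame <- function(frame, config = oct_config()) {
  rec <- list(frame_index = frame$frame_index, error = NULL)
  stage <- "overlay_removal"
  out <- tryCatch({
    if (isTRUE(config$io$remove_overlays))
      frame <- remove_overlays(frame, overlay_mask_spec())
    stage <- "polar_transform"
    polar <- to_polar(frame, config$polar$n_alines, config$polar$n_depth,
                      config$polar$radial_step_px,
                      config$polar$interpolation)
    stage <- "lumen_segmentation"
    lumen <- segment_lumen(polar, config)
    la <- lumen_area(lumen, polar)
    stage <- "ring_mask"
    mask <- build_ring_mask(polar, lumen, config$ring$f,
                            config$ring$min_thickness,
                            config$ring$max_thickness,
                            config$ring$signal_floor)
    stage <- "shadow_segmentation"
    comps <- segment_shadows(polar, mask, config$shadow$sigma,
                             config$shadow$window, config$shadow$offset,
                             config$shadow$min_area_px,
                             config$shadow$max_span,
                             config$shadow$merge_flag_span,
                             config$shadow$use_red)
    stage <- "strut_localization"
    struts <- locate_struts(polar, mask, comps, config$profile,
                            config$struts$min_hit_alines,
                            config$struts$ghost_margin_px)
    stage <- "coverage_analysis"
    stent <- fit_stent_contour(struts, polar$n_alines,
                               config$coverage$min_support,
                               config$coverage$min_arc_deg)
    sa <- stent_area(stent, polar)
    merge_events <- attr(struts, "merge_events") %||% 0L
    if (nrow(struts)) {
      extra <- do.call(rbind, lapply(seq_len(nrow(struts)), function(i) {
        st <- struts[i, ]
        cls <- classify_strut(lumen, st, config$coverage$side_window_alines,
                              config$coverage$min_cover_px)
        cbind(data.frame(thickness_um =
                           neointimal_thickness(lumen, st, polar)), cls)
      }))
      struts <- cbind(as.data.frame(struts), extra)
    } else {
      struts <- cbind(as.data.frame(struts),
                      data.frame(thickness_um = numeric(0),
                                 covered_ccw = logical(0),
                                 covered_cw = logical(0),
                                 label = character(0)))
    }
    list(lumen = lumen,
         polar_geom = list(n_alines = polar$n_alines,
                           n_depth = polar$n_depth,
                           center = polar$center,
                           calibration_mm_per_px = polar$calibration_mm_per_px),
         lumen_area_mm2 = as.numeric(la),
         struts = struts,
         stent_valid = stent$valid,
         stent_area_mm2 = as.numeric(sa),
         stent_reason = if (stent$valid) NA_character_ else stent$reason,
         merge_events = merge_events)
  }, error = function(e) {
    rec$error <<- list(stage = stage, message = conditionMessage(e))
    NULL
  })
  if (is.null(out)) return(rec)
  rec <- c(rec["frame_index"], out, list(error = NULL))
  rec$n_struts <- nrow(rec$struts)
  rec$n_covered <- sum(rec$struts$label == "covered")
  rec$n_uncovered <- sum(rec$struts$label == "uncovered")
  rec
}

#' Analyze a full pullback
#'
#' Applies [analyze_frame()] to every frame of a pullback, isolating
#' failures per frame (a frame failing at any stage is recorded with the
#' failing stage and reason and excluded from the summary rather than
#' aborting the run). When `out_dir` is given, writes deterministic
#' outputs: per-strut and per-frame CSVs (schema string in the header
#' comment line), a JSON summary, and the resolved configuration as YAML.
#'
#' @param input a DICOM file path, a directory of PNG/TIFF frames, or a
#'   list of [oct_frame()] objects.
#' @param config an [oct_config()].
#' @param out_dir optional output directory (created if missing).
#' @return object of class `oct_report`: list with `frames` (records),
#'   `summary`, `config`, `config_hash`, `version`, `schema`.
#' @export
analyze_pullback <- function(input, config = oct_config(), out_dir = NULL) {
  frames <- if (is.character(input))
    read_pullback(input, config$io$calibration_override)
  else if (is.list(input) && all(vapply(input, inherits, logical(1),
                                        "oct_frame"))) input
  else stop("I/O error: input must be a path or a list of oct_frame objects")

  records <- lapply(frames, analyze_frame, config = config)
  ok <- !vapply(records, function(r) !is.null(r$error), logical(1))
  total <- sum(vapply(records[ok], `[[`, numeric(1), "n_struts"))
  covered <- sum(vapply(records[ok], `[[`, numeric(1), "n_covered"))
  uncovered <- sum(vapply(records[ok], `[[`, numeric(1), "n_uncovered"))
  summary <- list(
    n_frames = length(records),
    n_frames_analyzed = sum(ok),
    n_frames_failed = sum(!ok),
    total_struts = total,
    covered = covered,
    uncovered = uncovered,
    pct_uncovered = if (total > 0) 100 * uncovered / total else NA_real_,
    lumen_area_mm2 = vapply(records, function(r)
      r$lumen_area_mm2 %||% NA_real_, numeric(1)),
    stent_area_mm2 = vapply(records, function(r)
      r$stent_area_mm2 %||% NA_real_, numeric(1)))
  report <- structure(
    list(frames = records, summary = summary, config = config,
         config_hash = config_hash(config),
         version = as.character(packageVersion("octcov")),
         schema = REPORT_SCHEMA),
    class = "oct_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.oct_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<oct_report> %d frames (%d analyzed, %d failed)\n",
              s$n_frames, s$n_frames_analyzed, s$n_frames_failed))
  cat(sprintf("  struts: %d total, %d covered, %d uncovered (%.1f%% uncovered)\n",
              s$total_struts, s$covered, s$uncovered,
              s$pct_uncovered %||% NA))
  invisible(x)
}

# All-strut table of a report (one row per strut, frame_index prepended).
report_strut_table <- function(report) {
  rows <- lapply(report$frames, function(r) {
    if (!is.null(r$error) || is.null(r$struts) || !nrow(r$struts)) return(NULL)
    cbind(frame_index = r$frame_index, as.data.frame(r$struts))
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(frame_index = integer(0), aline_mid = integer(0),
                      anterior_radius_px = numeric(0),
                      peak_intensity = numeric(0), theta_deg = numeric(0),
                      x_px = numeric(0), y_px = numeric(0),
                      shadow_id = integer(0), span_lo = integer(0),
                      span_width = integer(0), thickness_um = numeric(0),
                      covered_ccw = logical(0), covered_cw = logical(0),
                      label = character(0))
  rownames(out) <- NULL
  out
}

write_report <- function(report, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  write_atomic <- function(writer, path) {
    tmp <- paste0(path, ".tmp")
    writer(tmp)
    file.rename(tmp, path)
  }
  struts <- report_strut_table(report)
  frames <- do.call(rbind, lapply(report$frames, function(r) data.frame(
    frame_index = r$frame_index,
    analyzed = is.null(r$error),
    failed_stage = if (is.null(r$error)) NA_character_ else r$error$stage,
    failure_reason = if (is.null(r$error)) NA_character_ else r$error$message,
    lumen_area_mm2 = r$lumen_area_mm2 %||% NA_real_,
    stent_area_mm2 = r$stent_area_mm2 %||% NA_real_,
    stent_reason = r$stent_reason %||% NA_character_,
    n_struts = r$n_struts %||% NA_integer_,
    n_covered = r$n_covered %||% NA_integer_,
    n_uncovered = r$n_uncovered %||% NA_integer_)))
  write_csv_schema <- function(df, path) {
    con <- file(path, "w")
    writeLines(paste0("# schema: ", report$schema, " config: ",
                      report$config_hash), con)
    write.csv(df, con, row.names = FALSE)
    close(con)
  }
  write_atomic(function(p) write_csv_schema(struts, p),
               file.path(out_dir, "struts.csv"))
  write_atomic(function(p) write_csv_schema(frames, p),
               file.path(out_dir, "frames.csv"))
  write_atomic(function(p) jsonlite::write_json(
    c(report$summary[c("n_frames", "n_frames_analyzed", "n_frames_failed",
                       "total_struts", "covered", "uncovered",
                       "pct_uncovered")],
      list(schema = report$schema, config_hash = report$config_hash,
           version = report$version)),
    p, auto_unbox = TRUE, digits = NA, na = "null"),
    file.path(out_dir, "summary.json"))
  write_atomic(function(p) write_config(report$config, p),
               file.path(out_dir, "config.yaml"))
  invisible(out_dir)
}

#' Validate a pullback report against reference annotations
#'
#' Matches detected struts against reference strut positions frame by frame
#' and pools the confusion counts over the pullback -- for all struts and
#' separately for the uncovered-only and covered-only subsets (label-aware
#' matching). When the reference carries frame-level areas, Bland-Altman
#' agreement for lumen and stent area is reported; when it carries
#' per-strut thicknesses, the thickness distributions are compared.
#'
#' @param report an `oct_report`.
#' @param reference a CSV path or data.frame with columns `frame_index`,
#'   `x_px`, `y_px`, `label`, and optionally `thickness_um`; frame-level
#'   reference areas may be supplied in `frame_areas` (data.frame with
#'   `frame_index`, `lumen_area_mm2`, `stent_area_mm2`).
#' @param config an [oct_config()] (matching tolerance).
#' @param frame_areas optional frame-level reference areas (see above).
#' @return list with pooled `oct_match` reports (`all`, `uncovered`,
#'   `covered`), `per_frame` counts, optional `lumen_area_agreement`,
#'   `stent_area_agreement`, `thickness_comparison`.
#' @export
validate_against_reference <- function(report, reference,
                                       config = oct_config(),
                                       frame_areas = NULL) {
  stopifnot(inherits(report, "oct_report"))
  if (is.character(reference)) {
    if (!file.exists(reference)) stop("I/O error: no such file: ", reference)
    reference <- read.csv(reference, comment.char = "#",
                          stringsAsFactors = FALSE)
  }
  needed <- c("frame_index", "x_px", "y_px", "label")
  missing_cols <- setdiff(needed, names(reference))
  if (length(missing_cols) || !nrow(reference))
    stop("format error: reference must be non-empty with columns ",
         paste(needed, collapse = ", "),
         if (length(missing_cols)) paste0(" (missing: ",
                                          paste(missing_cols, collapse = ", "),
                                          ")"))
  detected <- report_strut_table(report)
  calibs <- unlist(lapply(report$frames, function(r)
    r$polar_geom$calibration_mm_per_px))
  calib_mm <- if (length(calibs)) calibs[1] else
    report$config$io$calibration_override %||%
    stop("configuration error: no calibration available for matching")

  frames_idx <- sort(unique(c(detected$frame_index, reference$frame_index)))
  pool <- function(det, ref) {
    tp <- 0L; fp <- 0L; fn <- 0L
    per <- lapply(frames_idx, function(fi) {
      d <- det[det$frame_index == fi, , drop = FALSE]
      r <- ref[ref$frame_index == fi, , drop = FALSE]
      m <- match_struts(d, r, config$matching$tol_um, calib_mm)
      tp <<- tp + m$tp; fp <<- fp + m$fp; fn <<- fn + m$fn
      data.frame(frame_index = fi, tp = m$tp, fp = m$fp, fn = m$fn)
    })
    rates <- ppv_tpr(tp, fp, fn)
    list(match = structure(list(tp = tp, fp = fp, fn = fn,
                                ppv = rates$ppv, tpr = rates$tpr,
                                pairs = NULL), class = "oct_match"),
         per_frame = do.call(rbind, per))
  }
  all_pool <- pool(detected, reference)
  unc <- pool(detected[detected$label == "uncovered", , drop = FALSE],
              reference[reference$label == "uncovered", , drop = FALSE])
  cov <- pool(detected[detected$label == "covered", , drop = FALSE],
              reference[reference$label == "covered", , drop = FALSE])
  out <- list(all = all_pool$match, uncovered = unc$match,
              covered = cov$match, per_frame = all_pool$per_frame)
  if (!is.null(frame_areas)) {
    fr <- do.call(rbind, lapply(report$frames, function(r) data.frame(
      frame_index = r$frame_index,
      lumen_area_mm2 = r$lumen_area_mm2 %||% NA_real_,
      stent_area_mm2 = r$stent_area_mm2 %||% NA_real_)))
    merged <- merge(fr, frame_areas, by = "frame_index",
                    suffixes = c("_alg", "_ref"))
    okl <- stats::complete.cases(merged[c("lumen_area_mm2_alg",
                                          "lumen_area_mm2_ref")])
    if (sum(okl) >= 2)
      out$lumen_area_agreement <- bland_altman(
        merged$lumen_area_mm2_alg[okl], merged$lumen_area_mm2_ref[okl])
    oks <- stats::complete.cases(merged[c("stent_area_mm2_alg",
                                          "stent_area_mm2_ref")])
    if (sum(oks) >= 2)
      out$stent_area_agreement <- bland_altman(
        merged$stent_area_mm2_alg[oks], merged$stent_area_mm2_ref[oks])
  }
  if ("thickness_um" %in% names(reference) &&
      nrow(detected) && any(!is.na(reference$thickness_um)))
    out$thickness_comparison <- thickness_distribution_compare(
      detected$thickness_um, reference$thickness_um[!is.na(reference$thickness_um)])
  out
}
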