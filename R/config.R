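#' Pipeline configuration
#'
#' Builds the full, validated configuration for [analyze_pullback()] and the
#' individual pipeline stages. Every tunable of the pipeline lives here;
#' passing an unknown key is an error, so a config file cannot silently
#' misspell an option. The resolved configuration (defaults filled in) is
#' written next to the outputs of every pullback analysis.
#'
#' Sections and defaults:
#' \describe{
#'   \item{polar}{`n_alines` (360, one A-line per degree), `n_depth`
#'     (`NULL` = inscribed radius of the frame), `radial_step_px` (1),
#'     `interpolation` ("bilinear" or "nearest").}
#'   \item{lumen}{`threshold_method` ("otsu" or "fixed"), `fixed_value`,
#'     `min_run` (3 depth samples), `border_convention`
#'     ("first_bright": the first above-threshold run marks the lumen
#'     border, the reading consistent with dark-lumen OCT physics).}
#'   \item{snake}{`alpha` (0.1, elasticity), `beta` (0.05, rigidity),
#'     `gamma` (0.1, step size px), `w_edge` (1.0), `max_iter` (500),
#'     `convergence_tol` (0.05 px mean move).}
#'   \item{post}{`min_blob_px` (20), `closing_radius` (2),
#'     `smoothness_bound` (15 px max adjacent radius jump).}
#'   \item{ring}{`f` (0.1 intensity fraction), `min_thickness` (10),
#'     `max_thickness` (80), `signal_floor` (8 gray levels).}
#'   \item{shadow}{`sigma` (1.0), `window` (31), `offset` (-10 gray
#'     levels), `min_area_px` (6), `max_span` (20 A-lines),
#'     `merge_flag_span` (9 A-lines: wider components are flagged as
#'     possible strut merges),
#'     `use_red` (TRUE; FALSE falls back to grayscale).}
#'   \item{profile}{`k` (3.0, height threshold in robust spreads),
#'     `drop_fraction` (0.25), `drop_window_px` (15).}
#'   \item{struts}{`min_hit_alines` (2), `ghost_margin_px` (10).}
#'   \item{coverage}{`min_support` (3 struts), `min_arc_deg` (180),
#'     `side_window_alines` (3), `min_cover_px` (2).}
#'   \item{matching}{`tol_um` (150).}
#'   \item{io}{`remove_overlays` (TRUE), `calibration_override` (NULL),
#'     `write_overlays` (FALSE).}
#' }
#'
#' @param ... named overrides; nested sections are merged, e.g.
#'   `oct_config(snake = list(alpha = 0.2))`.
#' @return a named list of sections with class `"oct_config"`.
#' @export
#' @examples
#' cfg <- oct_config(profile = list(k = 2.5))
#' cfg$profile$k
oct_config <- function(...) {
  defaults <- list(
    polar = list(n_alines = 360L, n_depth = NULL, radial_step_px = 1,
                 interpolation = "bilinear"),
    lumen = list(threshold_method = "otsu", fixed_value = NULL,
                 min_run = 3L, border_convention = "first_bright"),
    snake = list(alpha = 0.1, beta = 0.05, gamma = 0.1, w_edge = 1.0,
                 max_iter = 500L, convergence_tol = 0.05),
    post = list(min_blob_px = 20L, closing_radius = 2L,
                smoothness_bound = 15),
    ring = list(f = 0.1, min_thickness = 10L, max_thickness = 80L,
                signal_floor = 8),
    shadow = list(sigma = 1.0, window = 31L, offset = -10,
                  min_area_px = 6L, max_span = 20L,
                  merge_flag_span = 9L, use_red = TRUE),
    profile = list(k = 3.0, drop_fraction = 0.25, drop_window_px = 15L),
    struts = list(min_hit_alines = 2L, ghost_margin_px = 10),
    coverage = list(min_support = 3L, min_arc_deg = 180,
                    side_window_alines = 3L, min_cover_px = 2),
    matching = list(tol_um = 150),
    io = list(remove_overlays = TRUE, calibration_override = NULL,
              write_overlays = FALSE),
    seed = 1L
  )
  over <- list(...)
  if (length(over) && (is.null(names(over)) || any(names(over) == "")))
    stop("all configuration overrides must be named")
  for (key in names(over)) {
    if (!key %in% names(defaults))
      stop("unknown configuration key: '", key, "'")
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]]))) {
      sub <- over[[key]]
      if (!is.list(sub)) stop("section '", key, "' must be a named list")
      bad <- setdiff(names(sub), names(defaults[[key]]))
      if (length(bad))
        stop("unknown configuration key", if (length(bad) > 1) "s", ": '",
             paste0(key, "$", bad, collapse = "', '"), "'")
      defaults[[key]] <- modifyList(defaults[[key]], sub)
    } else {
      defaults[[key]] <- over[[key]]
    }
  }
  structure(defaults, class = "oct_config")
}

#' Read / write a configuration as YAML
#'
#' The resolved configuration written by [analyze_pullback()] round-trips
#' through these helpers; unknown keys in the file are rejected by
#' [oct_config()].
#'
#' @param path file path.
#' @param config an `oct_config` object.
#' @return `read_config` returns an `oct_config`; `write_config` returns
#'   `path` invisibly.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(oct_config, raw)
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "oct_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# Stable fingerprint of a resolved configuration.
config_hash <- function(config) {
  string_hash(yaml::as.yaml(unclass(config)))
}
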