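#' Pipeline configuration
#'
#' Collects every tunable of the pipeline with its default. Unknown names are
#' rejected, so configs are forward-compatible typo-safe.
#'
#' @param ... named overrides of the defaults listed below.
#' @return A named list of class `pipeline_config` with fields:
#'   `max_depth_mm` (1500), `kernel_px` (7), `ws` (8), `low_hz` (0.08),
#'   `high_hz` (0.5), `filter_order` (4), `min_distance_s` (2),
#'   `min_prominence_frac` (0.3), `window_cycles` (5), `loa_multiplier`
#'   (1.96), `detector` ("oracle"), `detect_max_frames` (150), `seed` (1).
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    max_depth_mm = 1500, kernel_px = 7, ws = 8,
    low_hz = 0.08, high_hz = 0.5, filter_order = 4,
    min_distance_s = 2.0, min_prominence_frac = 0.3,
    window_cycles = 5, loa_multiplier = 1.96,
    detector = "oracle", detect_max_frames = 150, seed = 1L,
    rois = "thorax,abdomen"
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown) > 0)
    stop_validation(paste("unknown config key(s):", paste(unknown, collapse = ", ")))
  defaults[names(overrides)] <- overrides
  structure(defaults, class = "pipeline_config")
}

#' Write / read a pipeline configuration as a flat key=value file
#'
#' @param config a [pipeline_config()].
#' @param path file path.
#' @return `read_config` returns a [pipeline_config()]; `write_config`
#'   returns `path` invisibly.
#' @export
write_config <- function(config, path) {
  writeLines(sprintf("%s=%s", names(config),
                     vapply(config, function(v) format(v, digits = 15), character(1))),
             path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- vapply(kv, `[`, character(1), 1)
  vals <- vapply(kv, function(p) paste(p[-1], collapse = "="), character(1))
  args <- lapply(seq_along(keys), function(i) {
    if (keys[i] %in% c("detector", "rois")) vals[i]
    else if (keys[i] %in% c("kernel_px", "ws", "window_cycles", "detect_max_frames", "seed"))
      as.integer(vals[i])
    else as.numeric(vals[i])
  })
  names(args) <- keys
  do.call(pipeline_config, args)
}

#' Run the full breathing-analysis pipeline on an RGB-D sequence
#'
#' Executes, in order: background masking and closing refinement, face
#' detection (with retries over frames), ROI placement from the face box,
#' per-ROI mean-depth extraction, normalization, moving-average smoothing,
#' zero-phase band-pass filtering, inhalation-peak detection, and
#' breath-by-breath plus windowed tachograms. When `out_dir` is given, all
#' intermediate series, both tachograms per ROI, and a run log (config,
#' detector used, detection frame, stage warnings) are written as CSV/text.
#'
#' @param input a [frame_sequence()] or the path of a sequence container
#'   (read lazily).
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory.
#' @param detector optional detector function; by default chosen from
#'   `config$detector` (`"oracle"` uses the sequence annotations, `"blob"`
#'   the color-segmentation detector).
#' @return List with `face`, `detect_frame`, `rois`, `raw`, `filtered`
#'   (named lists of [depth_series()]), `tachogram`, `windowed` (named lists
#'   of tachograms), `mean_br` (named numeric), and `log` (character).
#' @export
run_pipeline <- function(input, config = pipeline_config(), out_dir = NULL,
                         detector = NULL) {
  seq <- if (is.character(input)) read_sequence(input, lazy = TRUE) else input
  log <- c(sprintf("config: %s", paste(sprintf("%s=%s", names(config),
                                               vapply(config, format, character(1))),
                                       collapse = " ")))
  logw <- function(expr, stage) {
    withCallingHandlers(expr, warning = function(w) {
      log <<- c(log, sprintf("[%s] warning: %s", stage, conditionMessage(w)))
      invokeRestart("muffleWarning")
    })
  }

  if (is.null(detector)) {
    detector <- switch(config$detector,
      oracle = {
        if (is.null(seq$annotations) || is.null(seq$annotations$face_box))
          stop_detection("oracle detector requested but the sequence has no face annotation")
        oracle_detector(seq$annotations)
      },
      blob = skin_blob_detector(),
      stop_validation(sprintf("unknown detector '%s'", config$detector)))
  }
  loc <- locate_face(seq, detector, max_frames = config$detect_max_frames,
                     max_depth_mm = config$max_depth_mm, kernel_px = config$kernel_px)
  log <- c(log, sprintf("face detected on frame %d at (%g,%g) %gx%g [detector=%s]",
                        loc$frame, loc$face$x, loc$face$y, loc$face$w, loc$face$h,
                        config$detector))
  rois <- logw(compute_rois(loc$face, seq$height, seq$width), "roi")
  keep <- trimws(strsplit(config$rois, ",", fixed = TRUE)[[1]])
  if (!all(keep %in% names(rois)))
    stop_validation(sprintf("unknown ROI name(s) in config: %s",
                            paste(setdiff(keep, names(rois)), collapse = ", ")))
  rois <- rois[keep]
  for (r in rois)
    log <- c(log, sprintf("ROI %s: [%d,%d)x[%d,%d)", r$name, r$x0, r$x1, r$y0, r$y1))

  raw <- logw(extract_mean_depth(seq, rois, max_depth_mm = config$max_depth_mm),
              "extract")
  filtered <- lapply(raw, function(s) {
    f <- logw(condition_series(s, ws = config$ws, low_hz = config$low_hz,
                               high_hz = config$high_hz, order = config$filter_order),
              "filter")
    # sign convention: inhalation moves the chest wall toward the camera,
    # i.e. depth decreases; flip so inhalation appears as signal maxima
    f$values <- -f$values
    f
  })
  tachos <- lapply(filtered, function(s) {
    p <- detect_breath_peaks(s, min_distance_s = config$min_distance_s,
                             min_prominence_frac = config$min_prominence_frac)
    tachogram_from_peaks(p)
  })
  windowed <- lapply(tachos, function(t)
    logw(window_average_br(t, n_cycles = config$window_cycles), "window"))
  mbr <- vapply(tachos, mean_br, numeric(1))
  log <- c(log, sprintf("mean BR %s: %.3f breaths/min", names(mbr), mbr))

  res <- list(face = loc$face, detect_frame = loc$frame, rois = rois,
              raw = raw, filtered = filtered, tachogram = tachos,
              windowed = windowed, mean_br = mbr, log = log)
  if (!is.null(out_dir)) write_pipeline_outputs(res, out_dir)
  res
}

write_series_csv <- function(s, path) {
  utils::write.csv(data.frame(time_s = sprintf("%.6f", s$times),
                              value = sprintf("%.9g", s$values)),
                   path, row.names = FALSE, quote = FALSE)
}

write_tachogram_csv <- function(t, path) {
  utils::write.csv(data.frame(breath_index = t$breath_index,
                              time_s = sprintf("%.6f", t$time_s),
                              br_bpm = sprintf("%.6f", t$br_bpm)),
                   path, row.names = FALSE, quote = FALSE)
}

#' Read a tachogram CSV written by the pipeline
#' @param path CSV with columns `breath_index,time_s,br_bpm`.
#' @return A tachogram data.frame.
#' @export
read_tachogram <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("breath_index", "time_s", "br_bpm") %in% names(df)))
    stop_format("tachogram CSV must have columns breath_index,time_s,br_bpm")
  structure(df[c("breath_index", "time_s", "br_bpm")],
            class = c("tachogram", "data.frame"))
}

write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(res$raw)) {
    write_series_csv(res$raw[[nm]], file.path(out_dir, sprintf("%s_raw.csv", nm)))
    write_series_csv(res$filtered[[nm]], file.path(out_dir, sprintf("%s_filtered.csv", nm)))
    write_tachogram_csv(res$tachogram[[nm]], file.path(out_dir, sprintf("%s_tachogram.csv", nm)))
    write_tachogram_csv(res$windowed[[nm]], file.path(out_dir, sprintf("%s_windowed.csv", nm)))
  }
  writeLines(res$log, file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}

#' Write a debug overlay image of mask and ROI boxes
#'
#' Renders the color frame with masked pixels blacked out and the face box
#' and ROI rectangles drawn as bright outlines; a quick visual check of the
#' geometry stage.
#'
#' @param seq a [frame_sequence()].
#' @param res a [run_pipeline()] result.
#' @param path output PNG path.
#' @param frame which frame to render (default the detection frame).
#' @return `path`, invisibly.
#' @export
write_debug_overlay <- function(seq, res, path, frame = res$detect_frame) {
  f <- get_frame(seq, frame, color = TRUE)
  mask <- mask_background(f)
  img <- if (is.null(f$color)) array(200, c(seq$height, seq$width, 3)) else f$color
  for (ch in 1:3) img[, , ch][mask] <- 0
  draw_box <- function(img, x0, y0, x1, y1, rgb) {
    rows <- (y0 + 1):y1; cols <- (x0 + 1):x1
    for (ch in 1:3) {
      img[c(min(rows), max(rows)), cols, ch] <- rgb[ch]
      img[rows, c(min(cols), max(cols)), ch] <- rgb[ch]
    }
    img
  }
  fb <- res$face
  img <- draw_box(img, round(fb$x), round(fb$y), round(fb$x + fb$w),
                  round(fb$y + fb$h), c(255, 255, 0))
  for (r in res$rois) img <- draw_box(img, r$x0, r$y0, r$x1, r$y1, c(0, 255, 0))
  png::writePNG(img / 255, path)
  invisible(path)
}
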