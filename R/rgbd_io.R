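#' Construct a single RGB-D frame
#'
#' @param depth numeric H x W matrix of depth values in integer millimetres;
#'   0 means the sensor returned no measurement (null depth). Values must be
#'   whole numbers in `[0, 65535]` so they can be stored losslessly as 16-bit
#'   integers.
#' @param color H x W x 3 array of 8-bit color values in `[0, 255]`, or `NULL`
#'   when only the depth channel is available (the depth pipeline never needs
#'   color after the face has been located).
#' @param timestamp frame time in seconds.
#' @param index ordinal frame index (1-based).
#' @return An object of class `depth_frame`.
#' @export
depth_frame <- function(depth, color = NULL, timestamp, index) {
  if (!is.matrix(depth)) stop_format("depth must be an H x W matrix")
  if (any(!is.finite(depth))) stop_format("depth contains non-finite values")
  if (any(depth < 0)) stop_format("depth values must be non-negative")
  if (any(depth >= 65536)) stop_validation("depth value >= 2^16 cannot be represented in 16 bits")
  if (!is.null(color)) {
    if (length(dim(color)) != 3L || dim(color)[3] != 3L)
      stop_format("color must be an H x W x 3 array")
    if (!all(dim(color)[1:2] == dim(depth)))
      stop_format("color and depth must share the same H x W")
  }
  structure(
    list(depth = depth, color = color,
         timestamp = as.numeric(timestamp), index = as.integer(index)),
    class = "depth_frame"
  )
}

#' Construct an RGB-D frame sequence
#'
#' A sequence either holds all frames in memory (`frames`) or renders/reads
#' them on demand through `frame_fun` (lazy backend). The lazy backend is what
#' makes minute-long 640x480 recordings tractable: downstream stages stream
#' one frame at a time.
#'
#' @param frames list of [depth_frame()] objects (materialized backend).
#' @param frame_fun function `(k, color = TRUE)` returning frame `k`
#'   (lazy backend). Exactly one of `frames` / `frame_fun` must be given.
#' @param timestamps numeric vector of frame times in seconds, strictly
#'   increasing.
#' @param nominal_fps nominal frame rate in Hz.
#' @param width,height frame size in pixels.
#' @param annotations optional annotation list (oracle face box, ground-truth
#'   breathing parameters); see [write_annotations()].
#' @return An object of class `frame_sequence`.
#' @export
frame_sequence <- function(frames = NULL, frame_fun = NULL, timestamps,
                           nominal_fps, width, height, annotations = NULL) {
  if (is.null(frames) == is.null(frame_fun))
    stop_validation("exactly one of frames / frame_fun must be supplied")
  timestamps <- as.numeric(timestamps)
  if (length(timestamps) < 1L) stop_validation("sequence must contain at least one frame")
  if (any(diff(timestamps) <= 0))
    stop_validation("timestamps must be strictly increasing")
  if (!is.null(frames)) {
    if (length(frames) != length(timestamps))
      stop_validation("frames and timestamps lengths differ")
    for (f in frames) {
      if (!inherits(f, "depth_frame")) stop_format("frames must be depth_frame objects")
      if (!all(dim(f$depth) == c(height, width)))
        stop_format(sprintf("frame %d has shape %dx%d, expected %dx%d",
                            f$index, nrow(f$depth), ncol(f$depth), height, width))
    }
  }
  structure(
    list(frames = frames, frame_fun = frame_fun, timestamps = timestamps,
         nominal_fps = as.numeric(nominal_fps), width = as.integer(width),
         height = as.integer(height), annotations = annotations),
    class = "frame_sequence"
  )
}

#' Number of frames in a sequence
#' @param seq a [frame_sequence()].
#' @return integer frame count.
#' @export
n_frames <- function(seq) length(seq$timestamps)

#' Fetch one frame from a sequence
#'
#' @param seq a [frame_sequence()].
#' @param k frame index (1-based).
#' @param color if `FALSE`, a lazy backend may skip rendering/reading the
#'   color channel (the returned frame then has `color = NULL`).
#' @return A [depth_frame()].
#' @export
get_frame <- function(seq, k, color = TRUE) {
  k <- as.integer(k)
  if (k < 1L || k > n_frames(seq)) stop_validation(sprintf("frame index %d out of range", k))
  if (!is.null(seq$frames)) return(seq$frames[[k]])
  seq$frame_fun(k, color = color)
}

#' @export
print.frame_sequence <- function(x, ...) {
  cat(sprintf("<frame_sequence> %d frames, %dx%d px, %.6g s, nominal %.3g fps (%s)\n",
              n_frames(x), x$width, x$height,
              diff(range(x$timestamps)), x$nominal_fps,
              if (is.null(x$frames)) "lazy" else "in memory"))
  invisible(x)
}

# ---- 16-bit grayscale PNG encoder -------------------------------------------
# png/EBImage only write 8-bit PNGs, so the 16-bit depth channel gets its own
# minimal encoder: grayscale, filter type 0, one zlib IDAT (memCompress emits
# RFC-1950 zlib streams). Decoding is delegated to png::readPNG, which handles
# 16-bit, giving an independent check on the writer.

uint32_be <- function(n) writeBin(as.integer(n), raw(), size = 4L, endian = "big")

png_chunk <- function(type, data) {
  body <- c(charToRaw(type), data)
  crc_hex <- formatC(digest::digest(body, algo = "crc32", serialize = FALSE),
                     width = 8, flag = "0")
  crc <- as.raw(strtoi(substring(crc_hex, c(1, 3, 5, 7), c(2, 4, 6, 8)), 16L))
  c(uint32_be(length(data)), body, crc)
}

write_png16 <- function(mat, path) {
  h <- nrow(mat); w <- ncol(mat)
  v <- matrix(as.integer(t(mat)), nrow = w)     # column k = scanline k, row-major
  bytes <- matrix(0L, nrow = 2L * w + 1L, ncol = h)
  bytes[seq(2L, 2L * w, by = 2L), ] <- v %/% 256L
  bytes[seq(3L, 2L * w + 1L, by = 2L), ] <- v %% 256L   # row 1 = filter byte 0
  ihdr <- c(uint32_be(w), uint32_be(h), as.raw(c(16L, 0L, 0L, 0L, 0L)))
  idat <- memCompress(as.raw(as.vector(bytes)), "gzip")
  con <- file(path, "wb"); on.exit(close(con))
  writeBin(as.raw(c(0x89, 0x50, 0x4e, 0x47, 0x0d, 0x0a, 0x1a, 0x0a)), con)
  writeBin(png_chunk("IHDR", ihdr), con)
  writeBin(png_chunk("IDAT", idat), con)
  writeBin(png_chunk("IEND", raw(0)), con)
  invisible(path)
}

read_png16 <- function(path) {
  round(png::readPNG(path) * 65535)
}

depth_name <- function(i) sprintf("depth_%06d.png", i)
color_name <- function(i) sprintf("color_%06d.png", i)

# ---- annotation sidecar -----------------------------------------------------
# Flat (key,value) CSV. Numeric vectors (e.g. ground-truth peak times) are
# serialized as ";"-joined strings.

flatten_annotations <- function(ann) {
  out <- list()
  if (!is.null(ann$face_box)) {
    fb <- ann$face_box
    out[c("face.x", "face.y", "face.w", "face.h")] <-
      as.character(c(fb$x, fb$y, fb$w, fb$h))
  }
  for (nm in names(ann$rois)) {
    for (p in names(ann$rois[[nm]])) {
      v <- ann$rois[[nm]][[p]]
      out[[paste("roi", nm, p, sep = ".")]] <-
        paste(format(v, digits = 15, trim = TRUE, scientific = FALSE), collapse = ";")
    }
  }
  out
}

unflatten_annotations <- function(keys, values) {
  ann <- list(face_box = NULL, rois = list())
  fb <- match(c("face.x", "face.y", "face.w", "face.h"), keys)
  if (!any(is.na(fb)))
    ann$face_box <- face_box(as.numeric(values[fb[1]]), as.numeric(values[fb[2]]),
                             as.numeric(values[fb[3]]), as.numeric(values[fb[4]]))
  roi_keys <- grep("^roi\\.", keys)
  for (i in roi_keys) {
    parts <- strsplit(keys[i], ".", fixed = TRUE)[[1]]
    nm <- parts[2]; p <- paste(parts[-(1:2)], collapse = ".")
    ann$rois[[nm]][[p]] <- as.numeric(strsplit(values[i], ";", fixed = TRUE)[[1]])
  }
  ann
}

#' Write / read the annotation sidecar
#'
#' Annotations carry the oracle face box and per-ROI ground-truth breathing
#' parameters of a synthetic sequence as a flat `key,value` CSV, keeping
#' oracle data out of the image payload.
#'
#' @param ann annotation list (`face_box` plus `rois`, a named list of
#'   parameter lists).
#' @param path file path of `annotations.csv`.
#' @return `read_annotations` returns the annotation list; `write_annotations`
#'   returns `path` invisibly.
#' @export
write_annotations <- function(ann, path) {
  fl <- flatten_annotations(ann)
  utils::write.csv(data.frame(key = names(fl), value = unlist(fl, use.names = FALSE),
                              stringsAsFactors = FALSE),
                   path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_annotations
#' @export
read_annotations <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  unflatten_annotations(df$key, df$value)
}

# ---- sequence container -----------------------------------------------------

#' Read an RGB-D sequence from its directory container
#'
#' The container holds `depth_NNNNNN.png` (16-bit grayscale, value = depth in
#' millimetres), `color_NNNNNN.png` (8-bit RGB), `timestamps.csv`
#' (`index,time_s`) and an optional `annotations.csv`. Frames are ordered by
#' the CSV index column, not by directory listing.
#'
#' @param path container directory.
#' @param lazy if `TRUE`, frames are read from disk on demand instead of being
#'   loaded up front (recommended for minute-long recordings).
#' @param nominal_fps nominal frame rate; by default inferred from the median
#'   timestamp interval.
#' @return A [frame_sequence()].
#' @export
read_sequence <- function(path, lazy = FALSE, nominal_fps = NULL) {
  ts_path <- file.path(path, "timestamps.csv")
  if (!file.exists(ts_path)) stop_format(sprintf("missing timestamps.csv in %s", path))
  ts <- utils::read.csv(ts_path)
  if (!all(c("index", "time_s") %in% names(ts)))
    stop_format("timestamps.csv must have columns index,time_s")
  ts <- ts[order(ts$index), , drop = FALSE]
  if (any(diff(ts$time_s) <= 0))
    stop_validation("timestamps.csv: times are not strictly increasing")
  for (i in ts$index) {
    for (f in c(depth_name(i), color_name(i)))
      if (!file.exists(file.path(path, f)))
        stop_format(sprintf("missing frame file %s in %s", f, path))
  }
  if (is.null(nominal_fps)) nominal_fps <- 1 / stats::median(diff(ts$time_s))

  first <- read_png16(file.path(path, depth_name(ts$index[1])))
  height <- nrow(first); width <- ncol(first)

  load_one <- function(k, color = TRUE) {
    i <- ts$index[k]
    depth <- read_png16(file.path(path, depth_name(i)))
    if (!all(dim(depth) == c(height, width)))
      stop_format(sprintf("frame file %s has shape %dx%d, expected %dx%d",
                          depth_name(i), nrow(depth), ncol(depth), height, width))
    col <- NULL
    if (color) {
      col <- round(png::readPNG(file.path(path, color_name(i))) * 255)
      if (length(dim(col)) == 2L) col <- array(col, c(dim(col), 3L))  # grayscale fallback
    }
    depth_frame(depth, col, ts$time_s[k], i)
  }

  ann_path <- file.path(path, "annotations.csv")
  ann <- if (file.exists(ann_path)) read_annotations(ann_path) else NULL

  if (lazy) {
    frame_sequence(frame_fun = load_one, timestamps = ts$time_s,
                   nominal_fps = nominal_fps, width = width, height = height,
                   annotations = ann)
  } else {
    frames <- lapply(seq_len(nrow(ts)), load_one)
    frame_sequence(frames = frames, timestamps = ts$time_s,
                   nominal_fps = nominal_fps, width = width, height = height,
                   annotations = ann)
  }
}

#' Write an RGB-D sequence to the directory container
#'
#' Depth is stored losslessly as 16-bit integers (millimetres); the roundtrip
#' through [read_sequence()] is bit-exact on depth and color and exact to the
#' CSV precision (6 decimals) on timestamps.
#'
#' @param seq a [frame_sequence()].
#' @param path output directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_sequence <- function(seq, path) {
  if (n_frames(seq) == 0L) stop_validation("cannot write a 0-frame sequence")
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  for (k in seq_len(n_frames(seq))) {
    f <- get_frame(seq, k, color = TRUE)
    if (any(f$depth >= 65536) || any(f$depth < 0))
      stop_validation(sprintf("frame %d: depth out of 16-bit range", f$index))
    if (any(f$depth != floor(f$depth)))
      stop_validation(sprintf("frame %d: depth must be whole millimetres for lossless storage", f$index))
    write_png16(f$depth, file.path(path, depth_name(f$index)))
    col <- f$color
    if (is.null(col)) col <- array(0, c(seq$height, seq$width, 3L))
    png::writePNG(col / 255, file.path(path, color_name(f$index)))
  }
  idx <- vapply(seq_len(n_frames(seq)),
                function(k) get_frame(seq, k, color = FALSE)$index, integer(1))
  ts <- data.frame(index = idx, time_s = sprintf("%.6f", seq$timestamps))
  utils::write.csv(ts, file.path(path, "timestamps.csv"), row.names = FALSE, quote = FALSE)
  if (!is.null(seq$annotations))
    write_annotations(seq$annotations, file.path(path, "annotations.csv"))
  invisible(path)
}

#' Validate a frame sequence, reporting (not raising) problems
#'
#' Checks frame-interval jitter against the nominal rate, the fraction of
#' null-depth (dropout) pixels per frame, and the declared resolution.
#'
#' @param seq a [frame_sequence()].
#' @param jitter_frac tolerated relative deviation of any frame interval from
#'   `1/nominal_fps` (default 20%).
#' @param dropout_frac tolerated per-frame fraction of null-depth pixels
#'   (default 10%).
#' @return Character vector of warnings; empty if the sequence looks clean.
#' @export
validate_sequence <- function(seq, jitter_frac = 0.2, dropout_frac = 0.1) {
  warnings <- character(0)
  nominal <- 1 / seq$nominal_fps
  iv <- diff(seq$timestamps)
  bad <- which(abs(iv - nominal) > jitter_frac * nominal)
  if (length(bad) > 0)
    warnings <- c(warnings, sprintf(
      "frame-interval jitter exceeds %.0f%% of nominal for %d interval(s) (worst at frame %d: %.4f s vs %.4f s)",
      100 * jitter_frac, length(bad), bad[which.max(abs(iv[bad] - nominal))],
      iv[bad[which.max(abs(iv[bad] - nominal))]], nominal))
  for (k in seq_len(n_frames(seq))) {
    f <- get_frame(seq, k, color = FALSE)
    if (!all(dim(f$depth) == c(seq$height, seq$width))) {
      warnings <- c(warnings, sprintf("frame %d resolution %dx%d differs from declared %dx%d",
                                      f$index, nrow(f$depth), ncol(f$depth),
                                      seq$height, seq$width))
      next
    }
    frac0 <- mean(f$depth == 0)
    if (frac0 > dropout_frac)
      warnings <- c(warnings, sprintf("frame %d: %.1f%% null-depth pixels (> %.0f%%)",
                                      f$index, 100 * frac0, 100 * dropout_frac))
  }
  warnings
}
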