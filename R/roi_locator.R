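#' Face bounding box
#'
#' Pixel coordinates use the image convention: origin at the top-left corner,
#' x rightward (columns), y downward (rows), 0-based.
#'
#' @param x,y upper-left corner of the box, pixels.
#' @param w,h box width and height, pixels (must be positive).
#' @return An object of class `face_box`.
#' @export
face_box <- function(x, y, w, h) {
  if (w <= 0 || h <= 0) stop_geometry("face box must have positive width and height")
  structure(list(x = as.numeric(x), y = as.numeric(y),
                 w = as.numeric(w), h = as.numeric(h)), class = "face_box")
}

#' Rectangular region of interest
#'
#' Half-open pixel rectangle `[x0, x1) x [y0, y1)`, 0-based, origin top-left.
#'
#' @param name region label (e.g. `"thorax"`).
#' @param x0,y0 upper-left corner (inclusive).
#' @param x1,y1 lower-right corner (exclusive).
#' @return An object of class `roi`.
#' @export
roi <- function(name, x0, y0, x1, y1) {
  if (x1 <= x0 || y1 <= y0)
    stop_geometry(sprintf("ROI '%s' is empty: [%g,%g)x[%g,%g)", name, x0, x1, y0, y1))
  structure(list(name = name, x0 = as.integer(x0), y0 = as.integer(y0),
                 x1 = as.integer(x1), y1 = as.integer(y1)), class = "roi")
}

# 1-based row/column index ranges of an ROI inside an R matrix
roi_rows <- function(r) (r$y0 + 1L):r$y1
roi_cols <- function(r) (r$x0 + 1L):r$x1

#' Mask the scene background by depth
#'
#' Pixels farther than `max_depth_mm` from the camera, and null-depth pixels
#' (value 0, no sensor return), are masked out so only the subject remains.
#' Depth values themselves are never altered; the mask only classifies pixels.
#'
#' @param frame a [depth_frame()] or a depth matrix in millimetres.
#' @param max_depth_mm background distance threshold (default 1500 mm).
#' @return Logical H x W matrix; `TRUE` = masked (excluded).
#' @export
mask_background <- function(frame, max_depth_mm = 1500) {
  depth <- if (inherits(frame, "depth_frame")) frame$depth else frame
  depth > max_depth_mm | depth == 0
}

#' Refine a background mask by morphological closing
#'
#' Applies a closing (dilate, then erode, square structuring element) to the
#' unmasked region: interior holes smaller than the kernel — typical depth
#' speckle — are absorbed into the subject while the outer contour is
#' restored. Idempotent away from image borders.
#'
#' @param mask logical matrix from [mask_background()] (`TRUE` = masked).
#' @param kernel_px odd kernel side length, `>= 3` (default 7).
#' @return Refined logical mask of the same shape.
#' @export
refine_mask_closing <- function(mask, kernel_px = 7) {
  kernel_px <- as.integer(kernel_px)
  if (kernel_px < 3L || kernel_px %% 2L == 0L)
    stop_validation("kernel_px must be odd and >= 3")
  fg <- matrix(as.numeric(!mask), nrow(mask), ncol(mask))
  brush <- EBImage::makeBrush(kernel_px, shape = "box")
  closed <- EBImage::closing(fg, brush)
  !(closed > 0.5)
}

#' Compute thoracic and abdominal ROIs from the face bounding box
#'
#' With a face box at `(x, y)` of size `w x h` in a frame of height `H`, the
#' regions are placed at fixed multiples of the face height above the bottom
#' edge of the frame:
#' \deqn{thorax = [x, x+w) \times [H - 2h,\; H - 3h/2)}
#' \deqn{abdomen = [x, x+w) \times [H - 5h/6,\; H - h/3)}
#' Both regions have width `w` and height `h/2` (area `w*h/2`), scaling with
#' the subject's apparent size so the placement adapts to any distance within
#' the working range. Fractional coordinates are rounded to the nearest
#' integer (ties away from zero). Regions partially outside the frame are
#' clipped with a warning; once computed, the ROIs stay fixed for the whole
#' sequence.
#'
#' @param face a [face_box()].
#' @param frame_height,frame_width frame size in pixels.
#' @return Named list with `thorax` and `abdomen` [roi()] objects.
#' @export
compute_rois <- function(face, frame_height, frame_width) {
  if (face$h <= 0 || face$w <= 0) stop_geometry("degenerate face box (zero width or height)")
  H <- frame_height
  if (H - 2 * face$h < 0)
    stop_geometry("face too large for frame: thorax region would start above the frame")
  mk <- function(name, y0, y1) {
    x0 <- round_half_up(face$x); x1 <- round_half_up(face$x + face$w)
    y0 <- round_half_up(y0); y1 <- round_half_up(y1)
    cx0 <- max(x0, 0); cy0 <- max(y0, 0)
    cx1 <- min(x1, frame_width); cy1 <- min(y1, H)
    if (cx1 <= cx0 || cy1 <= cy0)
      stop_geometry(sprintf("ROI '%s' lies entirely outside the frame", name))
    if (cx0 != x0 || cy0 != y0 || cx1 != x1 || cy1 != y1)
      warning(sprintf("ROI '%s' clipped to frame bounds", name), call. = FALSE)
    roi(name, cx0, cy0, cx1, cy1)
  }
  list(
    thorax  = mk("thorax",  H - 2 * face$h,     H - 3 * face$h / 2),
    abdomen = mk("abdomen", H - 5 * face$h / 6, H - face$h / 3)
  )
}

# ---- face detection ---------------------------------------------------------
# FaceDetector interface: a function (color, mask) -> face_box or NULL.
# The detector only ever sees the person: masked pixels are blacked out first.

#' Oracle face detector from sequence annotations
#'
#' Returns the annotated face box regardless of image content; used for
#' synthetic scenes where a cartoon face would defeat appearance-based
#' detectors, and to test the pipeline independently of detection quality.
#'
#' @param annotations annotation list of the sequence (with `face_box`).
#' @return A detector function `(color, mask) -> face_box | NULL`.
#' @export
oracle_detector <- function(annotations) {
  box <- annotations$face_box
  function(color, mask) box
}

#' Skin-tone blob face detector
#'
#' Appearance-based detector for the color stream: after background blackout
#' it labels connected components of skin-like pixels (`R > 140`, `R > G > B`)
#' and returns the bounding box of the largest one, or `NULL` if no component
#' exceeds `min_px` pixels. Works on the synthetic scenes produced by
#' [synthesize_sequence()]; real-world use would substitute a trained
#' detector behind the same interface.
#'
#' @param min_px minimum component size in pixels.
#' @return A detector function `(color, mask) -> face_box | NULL`.
#' @export
skin_blob_detector <- function(min_px = 100) {
  function(color, mask) {
    if (is.null(color)) return(NULL)
    r <- color[, , 1]; g <- color[, , 2]; b <- color[, , 3]
    skin <- r > 140 & r > g & g > b & !mask
    if (!any(skin)) return(NULL)
    lab <- EBImage::bwlabel(matrix(as.numeric(skin), nrow(skin), ncol(skin)))
    sizes <- tabulate(lab[lab > 0])
    best <- which.max(sizes)
    if (sizes[best] < min_px) return(NULL)
    idx <- which(lab == best, arr.ind = TRUE)
    y0 <- min(idx[, 1]) - 1L; y1 <- max(idx[, 1])
    x0 <- min(idx[, 2]) - 1L; x1 <- max(idx[, 2])
    face_box(x0, y0, x1 - x0, y1 - y0)
  }
}

#' Detect the face in a single masked color frame
#'
#' Masked pixels are blacked out before the detector runs, so detection sees
#' the person alone in the scene.
#'
#' @param color H x W x 3 color array (0-255), or `NULL`.
#' @param mask logical background mask (`TRUE` = masked).
#' @param detector a detector function, e.g. [oracle_detector()] or
#'   [skin_blob_detector()].
#' @return A [face_box()] or `NULL` if no face was found.
#' @export
detect_face <- function(color, mask, detector) {
  if (!is.null(color)) {
    blacked <- color
    blacked[, , 1][mask] <- 0; blacked[, , 2][mask] <- 0; blacked[, , 3][mask] <- 0
    color <- blacked
  }
  detector(color, mask)
}

#' Locate the face in a sequence, retrying over frames
#'
#' Runs background masking, closing refinement and [detect_face()] on
#' successive frames until a face is found or the frame budget is exhausted
#' (an unbounded search is rejected by design).
#'
#' @param seq a [frame_sequence()].
#' @param detector detector function.
#' @param max_frames retry budget (default 150 frames, i.e. 10 s at 15 fps).
#' @param max_depth_mm background threshold passed to [mask_background()].
#' @param kernel_px closing kernel passed to [refine_mask_closing()].
#' @return List with `face` ([face_box()]), `frame` (index where detection
#'   succeeded), and `mask` (refined mask of that frame).
#' @export
locate_face <- function(seq, detector, max_frames = 150,
                        max_depth_mm = 1500, kernel_px = 7) {
  budget <- min(max_frames, n_frames(seq))
  for (k in seq_len(budget)) {
    f <- get_frame(seq, k, color = TRUE)
    mask <- refine_mask_closing(mask_background(f, max_depth_mm), kernel_px)
    box <- detect_face(f$color, mask, detector)
    if (!is.null(box)) return(list(face = box, frame = k, mask = mask))
  }
  stop_detection(sprintf("no face detected in frames 1-%d", budget))
}
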