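# Small-scene helpers: 160x120 frames keep unit tests fast while exercising
# the same geometry as full 640x480 recordings (face box scales with frame).

tiny_scene_config <- function(duration_s = 30, noise_sigma_mm = 0,
                              dropout_prob = 0, timing_jitter_frac = 0,
                              seed = 1, width = 160, height = 120, ...) {
  scene_config(duration_s = duration_s, noise_sigma_mm = noise_sigma_mm,
               dropout_prob = dropout_prob, timing_jitter_frac = timing_jitter_frac,
               seed = seed, width = width, height = height, ...)
}

tiny_sequence <- function(rate_bpm = 15, duration_s = 30, amplitude_mm = 4,
                          both_rois = FALSE, profile = NULL, ...) {
  if (is.null(profile)) profile <- breathing_profile(rate_bpm, amplitude_mm)
  profiles <- if (both_rois) list(thorax = profile, abdomen = profile)
              else list(thorax = profile)
  synthesize_sequence(tiny_scene_config(duration_s = duration_s, ...), profiles,
                      materialize = FALSE)
}

# hand-built sequence from a list of depth matrices (color = mid gray)
frames_from_depth <- function(depths, fps = 15) {
  h <- nrow(depths[[1]]); w <- ncol(depths[[1]])
  frames <- lapply(seq_along(depths), function(k) {
    depth_frame(depths[[k]], array(128, c(h, w, 3)), (k - 1) / fps, k)
  })
  frame_sequence(frames = frames, timestamps = (seq_along(depths) - 1) / fps,
                 nominal_fps = fps, width = w, height = h)
}

# raw mean-depth series computed directly from a displacement model, skipping
# rendering; used where the property under test lives in the signal chain
raw_series_from_profile <- function(profile, duration_s, fps = 15,
                                    subject_mm = 1000, quantize = TRUE) {
  t <- seq(0, duration_s, by = 1 / fps)
  v <- subject_mm - breathing_displacement(t, profile)
  if (quantize) v <- round(v)
  depth_series("thorax", t, v, "raw", fps)
}

# brute-force box morphology on logical foreground matrices (test oracle)
brute_box_filter <- function(fg, k, op) {
  r <- (k - 1) %/% 2
  h <- nrow(fg); w <- ncol(fg)
  out <- matrix(FALSE, h, w)
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      win <- fg[max(1, i - r):min(h, i + r), max(1, j - r):min(w, j + r)]
      out[i, j] <- op(win)
    }
  }
  out
}
brute_closing <- function(fg, k) {
  brute_box_filter(brute_box_filter(fg, k, any), k, all)
}

box_iou <- function(a, b) {
  ix <- max(0, min(a$x + a$w, b$x + b$w) - max(a$x, b$x))
  iy <- max(0, min(a$y + a$h, b$y + b$h) - max(a$y, b$y))
  inter <- ix * iy
  inter / (a$w * a$h + b$w * b$h - inter)
}
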