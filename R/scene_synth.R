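#' Breathing profile of a synthetic subject
#'
#' Describes the chest-wall displacement waveform of one body region. The
#' base model is a sinusoid `d(t) = A * sin(2*pi*(rate/60)*t + phase)`;
#' options add a second harmonic (20% is a realistic asymmetry between
#' inhalation and exhalation), breath-to-breath interval jitter (each cycle
#' duration drawn uniformly within `+-interval_jitter_frac` of the nominal
#' period), and apnea episodes. Inside a central-apnea (CA) episode the
#' amplitude is multiplied by a small factor (< 0.2); inside an obstructive
#' apnea (OA) episode by a factor > 1 with an added phase shift, emulating
#' paradoxical thoraco-abdominal motion.
#'
#' The band the downstream filter passes is 4.8-30 breaths/min; rates outside
#' it are allowed here (to synthesize out-of-band stress cases) but trigger a
#' warning.
#'
#' @param rate_bpm breathing rate, breaths per minute.
#' @param amplitude_mm peak displacement in millimetres (default 4, a typical
#'   chest-wall excursion comfortably above the \eqn{\sim}2.5 mm depth
#'   sensitivity of a structured-light camera at 1 m).
#' @param phase_rad initial phase in radians.
#' @param episodes list of episodes, each a list with `start_s`, `duration_s`,
#'   `kind` (`"CA"` or `"OA"`), `amplitude_factor`, `phase_shift_rad`.
#' @param harmonic2_frac relative amplitude of the 2nd harmonic (default 0).
#' @param interval_jitter_frac breath-to-breath cycle-length jitter fraction
#'   (default 0 = metronomic).
#' @return An object of class `breathing_profile`.
#' @export
breathing_profile <- function(rate_bpm, amplitude_mm = 4, phase_rad = 0,
                              episodes = list(), harmonic2_frac = 0,
                              interval_jitter_frac = 0) {
  if (amplitude_mm < 0) stop_validation("amplitude_mm must be non-negative")
  if (rate_bpm <= 0) stop_validation("rate_bpm must be positive")
  if (rate_bpm < 4.8 || rate_bpm > 30)
    warning(sprintf("rate %.3g bpm is outside the 4.8-30 bpm pass band", rate_bpm),
            call. = FALSE)
  if (length(episodes) > 1) {
    ss <- vapply(episodes, `[[`, numeric(1), "start_s")
    ee <- ss + vapply(episodes, `[[`, numeric(1), "duration_s")
    o <- order(ss)
    if (any(ss[o][-1] < ee[o][-length(ee)]))
      stop_validation("episodes must not overlap")
  }
  structure(list(rate_bpm = rate_bpm, amplitude_mm = amplitude_mm,
                 phase_rad = phase_rad, episodes = episodes,
                 harmonic2_frac = harmonic2_frac,
                 interval_jitter_frac = interval_jitter_frac,
                 cycles = NULL),
            class = "breathing_profile")
}

# Draw the realized cycle table (onsets/durations) for a jittered profile and
# the ground-truth inhalation peak times over [0, duration_s]. Uses the
# current RNG state; callers seed it.
realize_breathing <- function(profile, duration_s) {
  period <- 60 / profile$rate_bpm
  j <- profile$interval_jitter_frac
  if (j > 0) {
    n_max <- ceiling(duration_s / (period * (1 - j))) + 2L
    durs <- period * (1 + runif(n_max, -j, j))
    onsets <- c(0, cumsum(durs))[seq_len(n_max)]
    keep <- onsets < duration_s     # last kept cycle may extend past the end
    profile$cycles <- list(onset = onsets[keep], duration = durs[keep])
  }
  profile$gt_peak_times <- gt_peak_times(profile, duration_s)
  profile
}

# cycle-phase u(t): fractional number of completed breathing cycles
cycle_phase <- function(t, profile) {
  if (is.null(profile$cycles)) {
    (profile$rate_bpm / 60) * t
  } else {
    on <- profile$cycles$onset; du <- profile$cycles$duration
    i <- findInterval(t, on)                  # 1-based cycle index
    i <- pmin(pmax(i, 1L), length(on))
    (i - 1) + (t - on[i]) / du[i]
  }
}

# Inhalation-peak times of the fundamental over [0, duration_s]: solutions of
# 2*pi*u + phase = pi/2 + 2*pi*k.
gt_peak_times <- function(profile, duration_s) {
  u_star <- ((0.25 - profile$phase_rad / (2 * pi)) %% 1)
  if (is.null(profile$cycles)) {
    period <- 60 / profile$rate_bpm
    t <- (u_star + 0:ceiling(duration_s / period)) * period
  } else {
    on <- profile$cycles$onset; du <- profile$cycles$duration
    t <- on + u_star * du
  }
  t[t >= 0 & t <= duration_s]
}

#' Chest-wall displacement at given times
#'
#' Evaluates the displacement model of a [breathing_profile()] (positive =
#' toward the camera, i.e. inhalation brings the chest wall closer, reducing
#' measured depth).
#'
#' @param t time(s) in seconds (vectorized).
#' @param profile a [breathing_profile()] (realized or not; an unrealized
#'   profile with interval jitter is evaluated at its nominal rate).
#' @return Displacement(s) in millimetres.
#' @export
breathing_displacement <- function(t, profile) {
  u <- cycle_phase(t, profile)
  amp <- rep(profile$amplitude_mm, length(t))
  dphi <- numeric(length(t))
  for (ep in profile$episodes) {
    inside <- t >= ep$start_s & t < ep$start_s + ep$duration_s
    amp[inside] <- amp[inside] * ep$amplitude_factor
    if (!is.null(ep$phase_shift_rad)) dphi[inside] <- ep$phase_shift_rad
  }
  theta <- 2 * pi * u + profile$phase_rad + dphi
  d <- sin(theta)
  if (profile$harmonic2_frac > 0) d <- d + profile$harmonic2_frac * sin(2 * theta)
  amp * d
}

#' Scene configuration for the synthetic RGB-D generator
#'
#' Defaults reproduce the nominal recording conditions the pipeline targets:
#' a seated subject ~1 m from the camera, background beyond the 1.5 m masking
#' distance, 640x480 frames at 15 fps, per-pixel depth noise of 2.5 mm
#' (the expected sensitivity of the depth module at 1 m), 1% null-depth
#' dropout, and 5% frame-timing jitter.
#'
#' @param duration_s recording length in seconds.
#' @param subject_distance_mm distance of the body surface (default 1000).
#' @param background_distance_mm background plane distance; must exceed
#'   1500 mm so the background mask removes it (default 2500).
#' @param fps nominal frame rate (default 15).
#' @param width,height frame size in pixels (defaults 640x480).
#' @param noise_sigma_mm per-pixel Gaussian depth noise SD (default 2.5).
#' @param dropout_prob probability that a pixel returns null depth
#'   (default 0.01).
#' @param timing_jitter_frac frame-timestamp jitter as a fraction of the
#'   frame interval (default 0.05).
#' @param face_box oracle [face_box()] placed in the upper part of the image.
#' @param seed integer RNG seed; every random element of the scene derives
#'   from it.
#' @return An object of class `scene_config`.
#' @export
scene_config <- function(duration_s, subject_distance_mm = 1000,
                         background_distance_mm = 2500, fps = 15,
                         width = 640, height = 480, noise_sigma_mm = 2.5,
                         dropout_prob = 0.01, timing_jitter_frac = 0.05,
                         face_box = NULL, seed = 1L) {
  if (background_distance_mm <= 1500)
    stop_validation("background_distance_mm must exceed the 1500 mm masking distance")
  if (subject_distance_mm >= 1500)
    stop_validation("subject_distance_mm must be below the 1500 mm masking distance")
  if (is.null(face_box)) {
    # face box scaled to the frame: centered, upper quarter, 1/8 x 1/4 of frame
    w <- round(width / 8); h <- round(height / 4)
    face_box <- face_box(round(width / 2 - w / 2), round(height / 8), w, h)
  }
  structure(list(duration_s = duration_s,
                 subject_distance_mm = subject_distance_mm,
                 background_distance_mm = background_distance_mm,
                 fps = fps, width = as.integer(width), height = as.integer(height),
                 noise_sigma_mm = noise_sigma_mm, dropout_prob = dropout_prob,
                 timing_jitter_frac = timing_jitter_frac,
                 face_box = face_box, seed = as.integer(seed)),
            class = "scene_config")
}

frame_seed <- function(seed, k) {
  (as.numeric(seed) %% 65536) * 32749 + 7919 * k
}

with_preserved_rng <- function(code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  code
}

#' Synthesize an annotated RGB-D breathing sequence
#'
#' Renders, per frame: a background plane; a body silhouette (head ellipse
#' plus torso rectangle) at the subject distance; within each named ROI
#' footprint (placed from the oracle face box exactly as the pipeline places
#' them) a depth of `subject_distance - d(t)` so that inhalation moves the
#' surface toward the camera; Gaussian per-pixel depth noise; integer
#' quantization to millimetres; and a random fraction of null-depth dropout
#' pixels. Frame times are `k/fps` plus uniform jitter. The color channel
#' carries a skin-toned patch at the face box so appearance-based detection
#' is possible. The oracle face box and all ground-truth breathing
#' parameters (including exact inhalation peak times) are stored in the
#' sequence annotations.
#'
#' Generation is deterministic: the same configuration and seed produce a
#' bit-identical sequence, regardless of frame access order.
#'
#' @param config a [scene_config()].
#' @param profiles named list of [breathing_profile()]s; names must be among
#'   `thorax`, `abdomen`.
#' @param materialize if `FALSE`, return a lazy sequence that renders frames
#'   on demand (recommended beyond a few seconds of footage).
#' @return An annotated [frame_sequence()].
#' @export
synthesize_sequence <- function(config, profiles, materialize = TRUE) {
  stopifnot(inherits(config, "scene_config"))
  if (is.null(names(profiles)) || !all(names(profiles) %in% c("thorax", "abdomen")))
    stop_validation("profiles must be named with ROI names among {thorax, abdomen}")
  H <- config$height; W <- config$width
  fb <- config$face_box
  # geometry error if a footprint does not fit; clipping is reported again
  # (and logged) when the analysis pipeline recomputes the ROIs
  rois <- suppressWarnings(compute_rois(fb, H, W))
  rois <- rois[names(profiles)]

  n <- max(1L, floor(config$duration_s * config$fps))
  seq_parts <- with_preserved_rng({
    set.seed(config$seed)
    jit <- if (config$timing_jitter_frac > 0)
      runif(n, -config$timing_jitter_frac, config$timing_jitter_frac) / config$fps
    else numeric(n)
    times <- (seq_len(n) - 1L) / config$fps + jit
    times[1] <- max(times[1], 0)
    realized <- lapply(profiles[sort(names(profiles))], realize_breathing,
                       duration_s = config$duration_s)
    list(times = times, realized = realized[names(profiles)])
  })
  times <- seq_parts$times
  realized <- seq_parts$realized

  ann <- list(face_box = fb, rois = lapply(realized, function(p) {
    list(rate_bpm = p$rate_bpm, amplitude_mm = p$amplitude_mm,
         phase_rad = p$phase_rad, interval_jitter_frac = p$interval_jitter_frac,
         gt_peak_times = p$gt_peak_times)
  }))

  # static depth template: background + head ellipse + torso rectangle
  template <- matrix(config$background_distance_mm, H, W)
  cx <- fb$x + fb$w / 2; cy <- fb$y + fb$h / 2
  rx <- fb$w * 0.7; ry <- fb$h * 0.7
  ys <- matrix(0:(H - 1), H, W); xs <- matrix(0:(W - 1), H, W, byrow = TRUE)
  head_px <- ((xs - cx) / rx)^2 + ((ys - cy) / ry)^2 <= 1
  torso_rows <- max(1L, round(fb$y + fb$h)):H
  torso_cols <- max(1L, round(cx - 1.5 * fb$w)):min(W, round(cx + 1.5 * fb$w))
  template[head_px] <- config$subject_distance_mm
  template[torso_rows, torso_cols] <- config$subject_distance_mm

  color_template <- array(40, c(H, W, 3))
  for (ch in 1:3) {
    pl <- color_template[, , ch]
    pl[head_px] <- c(60, 45, 35)[ch]
    pl[torso_rows, torso_cols] <- c(90, 110, 160)[ch]
    pl[max(1, round(fb$y) + 1):min(H, round(fb$y + fb$h)),
       max(1, round(fb$x) + 1):min(W, round(fb$x + fb$w))] <- c(230, 180, 120)[ch]
    color_template[, , ch] <- pl
  }

  npix <- H * W
  render <- function(k, color = TRUE) {
    depth <- template
    for (nm in names(realized)) {
      d <- breathing_displacement(times[k], realized[[nm]])
      r <- rois[[nm]]
      depth[roi_rows(r), roi_cols(r)] <- config$subject_distance_mm - d
    }
    with_preserved_rng({
      set.seed(frame_seed(config$seed, k))
      if (config$noise_sigma_mm > 0)
        depth <- depth + rnorm(npix) * config$noise_sigma_mm
      depth <- round(depth)
      if (config$noise_sigma_mm > 0 && min(depth) < 0) depth[depth < 0] <- 0
      if (config$dropout_prob > 0) {
        ndrop <- stats::rbinom(1L, npix, config$dropout_prob)
        if (ndrop > 0) depth[sample.int(npix, ndrop)] <- 0
      }
    })
    # constructor checks skipped: the renderer guarantees the frame invariants
    structure(list(depth = depth, color = if (color) color_template else NULL,
                   timestamp = times[k], index = k),
              class = "depth_frame")
  }

  if (materialize) {
    frame_sequence(frames = lapply(seq_len(n), render), timestamps = times,
                   nominal_fps = config$fps, width = W, height = H,
                   annotations = ann)
  } else {
    frame_sequence(frame_fun = render, timestamps = times,
                   nominal_fps = config$fps, width = W, height = H,
                   annotations = ann)
  }
}

#' Ground-truth tachogram from sequence annotations
#'
#' Converts the annotated ground-truth inhalation peak times of a synthetic
#' sequence into a breath-by-breath tachogram comparable to the pipeline's
#' estimate.
#'
#' @param annotations annotation list of a synthetic sequence.
#' @param roi_name which ROI's ground truth to use.
#' @return A tachogram (see [tachogram_from_peaks()]).
#' @export
gt_tachogram <- function(annotations, roi_name) {
  pt <- annotations$rois[[roi_name]]$gt_peak_times
  if (is.null(pt) || length(pt) < 2)
    stop_validation(sprintf("no ground-truth peak times for ROI '%s'", roi_name))
  tachogram_from_peaks(peak_list(pt, numeric(0)))
}
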