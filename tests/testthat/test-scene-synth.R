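test_that("breathing displacement follows the stated waveform", {
  p <- breathing_profile(15, amplitude_mm = 4)
  expect_equal(breathing_displacement(0, p), 0)
  # quarter period of a 15 bpm breath at t = 1 s: full amplitude
  expect_equal(breathing_displacement(1, p), 4 * sin(2 * pi * 0.25))
  # vectorized, periodic
  t <- seq(0, 8, by = 0.1)
  expect_equal(breathing_displacement(t, p), 4 * sin(2 * pi * (15 / 60) * t))

  # central apnea damps the amplitude inside the episode only
  pca <- breathing_profile(15, 4, episodes = list(
    list(start_s = 10, duration_s = 10, kind = "CA",
         amplitude_factor = 0.1, phase_shift_rad = 0)))
  tin <- seq(10, 19.9, by = 0.05)
  expect_true(all(abs(breathing_displacement(tin, pca)) <= 0.4 + 1e-12))
  expect_equal(breathing_displacement(5, pca), breathing_displacement(5, p))

  # obstructive apnea: amplified and phase-shifted
  poa <- breathing_profile(15, 4, episodes = list(
    list(start_s = 10, duration_s = 10, kind = "OA",
         amplitude_factor = 1.5, phase_shift_rad = pi)))
  expect_equal(breathing_displacement(12, poa),
               1.5 * 4 * sin(2 * pi * 0.25 * 12 + pi))

  expect_error(breathing_profile(15, episodes = list(
    list(start_s = 0, duration_s = 10, kind = "CA", amplitude_factor = 0.1),
    list(start_s = 5, duration_s = 10, kind = "OA", amplitude_factor = 2))),
    "overlap", class = "db_validation_error")
})

test_that("frame count, determinism, and static scenes behave as declared", {
  # 60 s at 15 fps -> 900 frames (lazy: no rendering needed to count)
  seq60 <- synthesize_sequence(scene_config(duration_s = 60, seed = 1),
                               list(thorax = breathing_profile(16)),
                               materialize = FALSE)
  expect_equal(n_frames(seq60), 900)

  # same seed + config -> bit-identical frames, any access order
  a <- tiny_sequence(duration_s = 1, noise_sigma_mm = 2.5, dropout_prob = 0.01,
                     timing_jitter_frac = 0.05, seed = 9)
  b <- tiny_sequence(duration_s = 1, noise_sigma_mm = 2.5, dropout_prob = 0.01,
                     timing_jitter_frac = 0.05, seed = 9)
  expect_identical(get_frame(a, 7)$depth, get_frame(b, 7)$depth)
  expect_identical(get_frame(a, 2)$depth, get_frame(b, 2)$depth)
  expect_identical(a$timestamps, b$timestamps)
  c <- tiny_sequence(duration_s = 1, noise_sigma_mm = 2.5, seed = 10)
  expect_false(identical(get_frame(a, 2)$depth, get_frame(c, 2)$depth))

  # flat profile, no noise: every frame identical
  flat <- tiny_sequence(duration_s = 0.5, profile = breathing_profile(15, amplitude_mm = 0))
  expect_identical(get_frame(flat, 1)$depth, get_frame(flat, n_frames(flat))$depth)
})

test_that("noiseless thorax mean depth swings peak-to-peak by twice the amplitude", {
  seq <- tiny_sequence(rate_bpm = 15, duration_s = 30, amplitude_mm = 4)
  rois <- compute_rois(seq$annotations$face_box, seq$height, seq$width)
  raw <- extract_mean_depth(seq, rois["thorax"])$thorax
  expect_equal(diff(range(raw$values)), 8)
})

test_that("ground-truth rate is recoverable from the noiseless series spectrum", {
  dur <- 30; rate <- 12
  seq <- tiny_sequence(rate_bpm = rate, duration_s = dur)
  rois <- compute_rois(seq$annotations$face_box, seq$height, seq$width)
  raw <- extract_mean_depth(seq, rois["thorax"])$thorax
  v <- raw$values - mean(raw$values)
  sp <- Mod(fft(v))[2:(length(v) %/% 2)]
  f_peak <- (which.max(sp)) / (length(v) / 15)   # Hz
  expect_lt(abs(f_peak - rate / 60), 1 / dur)
})

test_that("background masking removes every background pixel", {
  seq <- tiny_sequence(duration_s = 0.5, noise_sigma_mm = 2.5, dropout_prob = 0.01,
                       seed = 3)
  f <- get_frame(seq, 1)
  mask <- mask_background(f)
  # corners are background plane (2500 mm); must all be masked
  expect_true(all(mask[1:5, 1:5]))
  expect_true(all(mask[1:5, (seq$width - 4):seq$width]))
  # and no unmasked pixel is beyond the threshold or null
  expect_true(all(f$depth[!mask] > 0 & f$depth[!mask] <= 1500))
})

test_that("breath-interval jitter produces cycles within the stated band", {
  p <- breathing_profile(18, interval_jitter_frac = 0.03)
  set.seed(5)
  r <- depthbreath:::realize_breathing(p, 60)
  iv <- diff(r$gt_peak_times)
  expect_true(all(iv >= (60 / 18) * 0.93 & iv <= (60 / 18) * 1.07))
  expect_equal(length(r$gt_peak_times), 18, tolerance = 0.1)
})

test_that("ROI footprints that do not fit the frame are a geometry error", {
  expect_error(
    synthesize_sequence(
      tiny_scene_config(duration_s = 0.5,
                        face_box = face_box(10, 5, 40, 70)),  # h too large for H=120
      list(thorax = breathing_profile(15))),
    class = "db_geometry_error")
})
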