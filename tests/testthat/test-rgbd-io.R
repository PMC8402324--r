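test_that("container roundtrip is bit-exact on depth and color, 6-decimal on timestamps", {
  set.seed(11)
  h <- 16; w <- 20
  depths <- lapply(1:3, function(k) {
    m <- matrix(sample(0:65535, h * w, replace = TRUE), h, w)
    m[1, 1] <- 0; m[h, w] <- 65535
    m
  })
  frames <- lapply(1:3, function(k) {
    col <- array(sample(0:255, h * w * 3, replace = TRUE), c(h, w, 3))
    depth_frame(depths[[k]], col, c(0, 0.066712, 0.133254)[k], k)
  })
  seq <- frame_sequence(frames = frames, timestamps = c(0, 0.066712, 0.133254),
                        nominal_fps = 15, width = w, height = h,
                        annotations = list(face_box = face_box(3, 1, 5, 4),
                                           rois = list(thorax = list(rate_bpm = 15))))
  dir <- withr::local_tempdir()
  write_sequence(seq, dir)
  back <- read_sequence(dir)

  for (k in 1:3) {
    expect_true(all(get_frame(back, k)$depth == depths[[k]]))
    expect_true(all(get_frame(back, k)$color == frames[[k]]$color))
  }
  expect_equal(back$timestamps, seq$timestamps, tolerance = 1e-9)
  expect_equal(back$annotations$face_box$w, 5)
  expect_equal(back$annotations$rois$thorax$rate_bpm, 15)

  # lazy reading returns the same frames
  lazy <- read_sequence(dir, lazy = TRUE)
  expect_true(all(get_frame(lazy, 2)$depth == depths[[2]]))
})

test_that("the 16-bit depth encoder agrees with an independent decoder", {
  set.seed(4)
  m <- matrix(sample(0:65535, 30 * 25, replace = TRUE), 30, 25)
  path <- withr::local_tempfile(fileext = ".png")
  depthbreath:::write_png16(m, path)
  decoded <- round(png::readPNG(path) * 65535)
  expect_true(all(decoded == m))
})

test_that("missing or malformed container pieces raise named errors", {
  seq <- tiny_sequence(duration_s = 0.2)
  seq <- frame_sequence(frames = lapply(1:3, function(k) get_frame(seq, k)),
                        timestamps = seq$timestamps[1:3], nominal_fps = 15,
                        width = seq$width, height = seq$height)
  dir <- withr::local_tempdir()
  write_sequence(seq, dir)

  file.remove(file.path(dir, "depth_000002.png"))
  expect_error(read_sequence(dir), "depth_000002.png", class = "db_format_error")

  write_sequence(seq, dir)  # restore
  ts <- read.csv(file.path(dir, "timestamps.csv"))
  ts$time_s <- c(0, 0.0667, 0.05)
  write.csv(ts, file.path(dir, "timestamps.csv"), row.names = FALSE)
  expect_error(read_sequence(dir), "strictly increasing", class = "db_validation_error")
})

test_that("degenerate writes are rejected", {
  expect_error(frame_sequence(frames = list(), timestamps = numeric(0),
                              nominal_fps = 15, width = 4, height = 4),
               class = "db_validation_error")
  expect_error(depth_frame(matrix(70000, 2, 2), NULL, 0, 1),
               "2\\^16", class = "db_validation_error")
  f <- depth_frame(matrix(10.5, 2, 2), NULL, 0, 1)
  seq <- frame_sequence(frames = list(f, depth_frame(matrix(10.5, 2, 2), NULL, 0.07, 2)),
                        timestamps = c(0, 0.07), nominal_fps = 15, width = 2, height = 2)
  expect_error(write_sequence(seq, withr::local_tempdir()),
               "whole millimetres", class = "db_validation_error")
})

test_that("reading orders frames by CSV index, not file order", {
  seq <- tiny_sequence(duration_s = 0.3, rate_bpm = 12)
  seq <- frame_sequence(frames = lapply(1:4, function(k) get_frame(seq, k)),
                        timestamps = seq$timestamps[1:4], nominal_fps = 15,
                        width = seq$width, height = seq$height)
  dir <- withr::local_tempdir()
  write_sequence(seq, dir)
  ts <- read.csv(file.path(dir, "timestamps.csv"))
  write.csv(ts[c(3, 1, 4, 2), ], file.path(dir, "timestamps.csv"), row.names = FALSE)
  back <- read_sequence(dir)
  expect_equal(vapply(1:4, function(k) get_frame(back, k)$index, integer(1)), 1:4)
  expect_lt(max(abs(back$timestamps - seq$timestamps)), 1e-6)  # CSV precision
})

test_that("validate_sequence reports jitter, dropout, and resolution mismatches", {
  clean <- tiny_sequence(duration_s = 1)
  expect_length(validate_sequence(clean), 0)

  # alternating short/long frame intervals: 50% deviation from nominal
  n <- 10
  times <- cumsum(c(0, rep(c(0.5, 1.5) / 15, length.out = n - 1)))
  jittered <- frame_sequence(frames = lapply(1:n, function(k) {
    depth_frame(matrix(1000, 4, 4), NULL, times[k], k)
  }), timestamps = times, nominal_fps = 15, width = 4, height = 4)
  expect_match(validate_sequence(jittered), "jitter", all = FALSE)

  half0 <- matrix(1000, 4, 4); half0[1:2, ] <- 0
  dropout <- frame_sequence(frames = list(
    depth_frame(matrix(1000, 4, 4), NULL, 0, 1),
    depth_frame(half0, NULL, 1 / 15, 2)),
    timestamps = c(0, 1 / 15), nominal_fps = 15, width = 4, height = 4)
  expect_match(validate_sequence(dropout), "null-depth", all = FALSE)
})
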