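test_that("mean-depth extraction averages valid ROI pixels only", {
  mk <- function(vals) matrix(vals, 2, 2)   # whole frame is the ROI
  r <- roi("test", 0, 0, 2, 2)
  uniform <- frames_from_depth(list(mk(1000), mk(1000)))
  expect_equal(extract_mean_depth(uniform, list(r))$test$values, c(1000, 1000))

  halves <- frames_from_depth(list(mk(c(900, 900, 1100, 1100)), mk(1000)))
  expect_equal(extract_mean_depth(halves, list(r))$test$values[1], 1000)

  with_nulls <- frames_from_depth(list(mk(c(1000, 1000, 0, 0)), mk(1000)))
  expect_equal(extract_mean_depth(with_nulls, list(r))$test$values[1], 1000)

  # pixels beyond the background threshold excluded too
  with_bg <- frames_from_depth(list(mk(c(998, 1002, 2500, 2500)), mk(1000)))
  expect_equal(extract_mean_depth(with_bg, list(r))$test$values[1], 1000)
})

test_that("fully-occluded frames are interpolated; chronic occlusion is an error", {
  depths <- lapply(seq(0, 1000), function(k) matrix(1000 + (k %% 3), 2, 2))
  depths[[11]] <- matrix(0, 2, 2)
  seq <- frames_from_depth(depths)
  r <- roi("test", 0, 0, 2, 2)
  s <- extract_mean_depth(seq, list(r))$test
  expect_true(all(is.finite(s$values)))
  # interpolated between neighbours 10 and 12
  expect_equal(s$values[11], mean(c(s$values[10], s$values[12])))

  mostly0 <- lapply(1:10, function(k) matrix(if (k > 4) 0 else 1000, 2, 2))
  expect_error(extract_mean_depth(frames_from_depth(mostly0), list(r)),
               class = "db_acquisition_error")
})

test_that("extraction handles many ROIs consistently", {
  set.seed(31)
  depths <- lapply(1:20, function(k) matrix(sample(900:1100, 400, TRUE), 20, 20))
  seq <- frames_from_depth(depths)
  rois <- lapply(1:10, function(i) roi(paste0("r", i), (i - 1) * 2, 0, i * 2, 20))
  all10 <- extract_mean_depth(seq, rois)
  expect_length(all10, 10)
  for (i in c(1, 5, 10)) {
    single <- extract_mean_depth(seq, rois[i])
    expect_equal(all10[[paste0("r", i)]]$values, single[[paste0("r", i)]]$values)
  }
})

test_that("normalization gives zero mean and unit population scale", {
  fs <- 15
  s <- depth_series("t", c(0, 1 / fs), c(-1, 1), "raw", fs)
  expect_equal(normalize_series(s)$values, c(-1, 1))

  const <- depth_series("t", 0:9 / fs, rep(1000, 10), "raw", fs)
  expect_equal(normalize_series(const)$values, rep(0, 10))

  set.seed(2)
  x <- depth_series("t", 0:99 / fs, 1000 + rnorm(100), "raw", fs)
  nx <- normalize_series(x)$values
  expect_equal(mean(nx), 0, tolerance = 1e-9)
  expect_equal(sqrt(mean(nx^2)), 1, tolerance = 1e-9)
})

test_that("causal moving average matches its defining recursion", {
  fs <- 15
  s <- depth_series("t", 0:3 / fs, c(1, 3, 5, 7), "raw", fs)
  expect_equal(moving_average(s, 2)$values, c(1, 2, 4, 6))
  expect_equal(moving_average(s, 1)$values, c(1, 3, 5, 7))
  expect_equal(moving_average(s, 8)$values, cumsum(c(1, 3, 5, 7)) / 1:4)
  const <- depth_series("t", 0:9 / fs, rep(4, 10), "raw", fs)
  expect_equal(moving_average(const, 8)$values, rep(4, 10))
  # timestamps unchanged
  expect_equal(moving_average(s, 2)$times, s$times)
})

test_that("band-pass rejects DC and stop-band, passes mid-band at unity", {
  fs <- 15
  t <- seq(0, 120, by = 1 / fs)
  mk <- function(v) depth_series("t", t, v, "smoothed", fs)
  central <- t >= 30 & t <= 90

  dc <- bandpass_filter(mk(rep(5, length(t))))
  expect_lt(max(abs(dc$values)), 1e-6 * 5)

  mid <- bandpass_filter(mk(sin(2 * pi * 0.25 * t)))
  amp <- max(abs(mid$values[central]))
  expect_gt(amp, 0.9); expect_lt(amp, 1.1)

  slow <- suppressWarnings(bandpass_filter(mk(sin(2 * pi * 0.01 * t))))
  expect_lt(max(abs(slow$values[central])), 0.1)
})

test_that("smoothing and band-pass are jointly linear", {
  fs <- 15
  t <- seq(0, 60, by = 1 / fs)
  set.seed(8)
  x <- sin(2 * pi * 0.2 * t) + 0.3 * rnorm(length(t))
  chain <- function(v) bandpass_filter(moving_average(
    depth_series("t", t, v, "normalized", fs), 8))$values
  expect_equal(chain(3.7 * x), 3.7 * chain(x), tolerance = 1e-6)
})

test_that("band-pass is zero-phase; the full chain delays peaks uniformly", {
  fs <- 15
  t <- seq(0, 120, by = 1 / fs)
  x <- sin(2 * pi * 0.25 * t)
  peaks_of <- function(s) detect_breath_peaks(s, min_distance_s = 2)$peak_times
  input_peaks <- seq(1, 119, by = 4)   # analytic maxima of the 0.25 Hz sinusoid

  bp <- bandpass_filter(depth_series("t", t, x, "smoothed", fs))
  bp_peaks <- peaks_of(bp)
  interior <- bp_peaks > 10 & bp_peaks < 110
  shifts <- vapply(bp_peaks[interior],
                   function(p) min(abs(p - input_peaks)), numeric(1))
  expect_lt(max(shifts), 1 / fs)       # < 1 sample

  raw <- depth_series("t", t, 1000 - 4 * x, "raw", fs)
  full <- condition_series(raw)
  full$values <- -full$values          # inhalation sign convention
  fp <- peaks_of(full)
  fi <- fp > 10 & fp < 110
  fshift <- vapply(fp[fi], function(p) {
    d <- p - input_peaks; d[which.min(abs(d))]
  }, numeric(1))
  # constant group delay of the causal ws=8 moving average: (ws-1)/2 samples
  expect_lt(max(fshift) - min(fshift), 1 / fs)
  expect_equal(mean(fshift), 3.5 / fs, tolerance = 0.3 / fs)
})

test_that("interpolated short gaps barely move the estimated breath rate", {
  prof <- breathing_profile(16)
  mk_seq <- function(gap_at = NULL) {
    depths <- lapply(0:899, function(k) {
      matrix(round(1000 - breathing_displacement(k / 15, prof)), 2, 2)
    })
    if (!is.null(gap_at)) for (k in gap_at) depths[[k]] <- matrix(0, 2, 2)
    frames_from_depth(depths)
  }
  r <- roi("test", 0, 0, 2, 2)
  br_of <- function(seq) {
    s <- condition_series(extract_mean_depth(seq, list(r))$test)
    s$values <- -s$values
    mean_br(tachogram_from_peaks(detect_breath_peaks(s)))
  }
  expect_lt(abs(br_of(mk_seq(300:302)) - br_of(mk_seq())), 0.1)
})

test_that("stage contracts are enforced", {
  fs <- 15
  s <- depth_series("t", 0:99 / fs, rnorm(100), "raw", fs)
  expect_error(bandpass_filter(s), class = "db_validation_error")
  expect_error(normalize_series(moving_average(s)), class = "db_validation_error")
  short <- depth_series("t", 0:29 / fs, rnorm(30), "smoothed", fs)
  expect_warning(bandpass_filter(short), "transient")
})
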