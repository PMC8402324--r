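#' Per-ROI depth time series
#'
#' @param roi_name region label.
#' @param times sample times in seconds, strictly increasing.
#' @param values millimetres for stage `"raw"`, dimensionless afterwards.
#' @param stage one of `"raw"`, `"normalized"`, `"smoothed"`, `"bandpassed"`.
#' @param fs_nominal nominal sampling rate in Hz.
#' @return An object of class `depth_series`.
#' @export
depth_series <- function(roi_name, times, values,
                         stage = c("raw", "normalized", "smoothed", "bandpassed"),
                         fs_nominal) {
  stage <- match.arg(stage)
  if (length(times) != length(values)) stop_validation("times and values lengths differ")
  if (length(times) < 2) stop_validation("series must have at least 2 samples")
  if (any(diff(times) <= 0)) stop_validation("series times must be strictly increasing")
  if (any(!is.finite(values))) stop_validation("series values must be finite")
  structure(list(roi_name = roi_name, times = as.numeric(times),
                 values = as.numeric(values), stage = stage,
                 fs_nominal = as.numeric(fs_nominal)),
            class = "depth_series")
}

#' @export
print.depth_series <- function(x, ...) {
  cat(sprintf("<depth_series> '%s' [%s], %d samples over %.4g s @ %.3g Hz nominal\n",
              x$roi_name, x$stage, length(x$values), diff(range(x$times)), x$fs_nominal))
  invisible(x)
}

#' Extract per-ROI mean-depth breathing signals from a sequence
#'
#' For every frame, the mean depth over each ROI's pixels is computed and
#' stored with the frame timestamp, excluding background-masked and
#' null-depth pixels. This is the whole acquisition step: constant work per
#' sample, so any number of regions can be tracked simultaneously in real
#' time. Frames in which every ROI pixel is invalid are recorded as missing
#' and filled by linear interpolation; an ROI invalid in more than half of
#' the frames aborts the acquisition.
#'
#' @param seq a [frame_sequence()].
#' @param rois list of [roi()] objects.
#' @param max_depth_mm per-frame background threshold (default 1500 mm).
#' @return Named list of raw [depth_series()], one per ROI.
#' @export
extract_mean_depth <- function(seq, rois, max_depth_mm = 1500) {
  if (length(rois) < 1) stop_validation("at least one ROI is required")
  n <- n_frames(seq)
  vals <- matrix(NA_real_, n, length(rois))
  for (r in rois) {
    if (r$x1 > seq$width || r$y1 > seq$height || r$x0 < 0 || r$y0 < 0)
      stop_geometry(sprintf("ROI '%s' extends outside the frame", r$name))
  }
  for (k in seq_len(n)) {
    depth <- get_frame(seq, k, color = FALSE)$depth
    for (j in seq_along(rois)) {
      px <- depth[roi_rows(rois[[j]]), roi_cols(rois[[j]])]
      ok <- px > 0 & px <= max_depth_mm
      if (any(ok)) vals[k, j] <- mean(px[ok])
    }
  }
  out <- list()
  for (j in seq_along(rois)) {
    v <- vals[, j]
    miss <- is.na(v)
    if (mean(miss) > 0.5)
      stop_acquisition(sprintf(
        "ROI '%s' had no valid pixels in %.0f%% of frames; acquisition discarded",
        rois[[j]]$name, 100 * mean(miss)))
    if (any(miss))
      v <- stats::approx(seq$timestamps[!miss], v[!miss], xout = seq$timestamps,
                         rule = 2)$y
    out[[rois[[j]]$name]] <-
      depth_series(rois[[j]]$name, seq$timestamps, v, "raw", seq$nominal_fps)
  }
  out
}

#' Normalize a raw series to zero mean and unit scale
#'
#' Subtracts the mean and divides by the (population) standard deviation,
#' reducing transitory states when the series is filtered next. A constant
#' series maps to all zeros. Breath-rate estimation is scale-invariant, so
#' the unit-variance convention is cosmetic but fixed for reproducibility.
#'
#' @param s raw [depth_series()].
#' @return Normalized [depth_series()].
#' @export
normalize_series <- function(s) {
  if (s$stage != "raw") stop_validation("normalize_series expects a raw series")
  x <- s$values
  sdev <- sqrt(mean((x - mean(x))^2))
  y <- if (sdev == 0) rep(0, length(x)) else (x - mean(x)) / sdev
  depth_series(s$roi_name, s$times, y, "normalized", s$fs_nominal)
}

#' Causal moving-average smoothing
#'
#' `y(n) = (x(n) + x(n-1) + ... + x(n-(ws-1))) / ws`: the causal mean of the
#' last `ws` samples. For the first `ws - 1` samples an expanding window
#' (mean of the samples available so far) is used. Timestamps are unchanged;
#' the filter's constant group delay of `(ws-1)/2` samples shifts every
#' extremum equally and therefore cancels in all breath-interval quantities.
#'
#' @param s a [depth_series()] (stage `"normalized"` or `"raw"`).
#' @param ws window length in samples (default 8; at 15 fps this smooths
#'   sensor noise while leaving the 0.08-0.5 Hz breathing band nearly
#'   untouched).
#' @return Smoothed [depth_series()].
#' @export
moving_average <- function(s, ws = 8) {
  ws <- as.integer(ws)
  if (ws < 1L) stop_validation("ws must be >= 1")
  x <- s$values; n <- length(x)
  cs <- cumsum(x)
  y <- numeric(n)
  head_n <- seq_len(min(ws, n))
  y[head_n] <- cs[head_n] / head_n                    # expanding window edge
  if (n > ws) {
    idx <- (ws + 1L):n
    y[idx] <- (cs[idx] - cs[idx - ws]) / ws
  }
  depth_series(s$roi_name, s$times, y, "smoothed", s$fs_nominal)
}

#' Zero-phase Butterworth band-pass filtering
#'
#' Resamples the series onto a uniform grid at the nominal rate (timestamps
#' of a real recording jitter around the nominal frame interval), then
#' applies a Butterworth band-pass forward and backward (`signal::filtfilt`),
#' so the net phase is zero and the time location of breathing peaks and
#' troughs is preserved. The default band of 0.08-0.5 Hz corresponds to
#' 4.8-30 breaths/min.
#'
#' @param s smoothed [depth_series()].
#' @param low_hz,high_hz band edges in Hz (defaults 0.08 and 0.5).
#' @param order Butterworth prototype order (default 4).
#' @return Band-passed [depth_series()] on the uniform time grid.
#' @export
bandpass_filter <- function(s, low_hz = 0.08, high_hz = 0.5, order = 4) {
  if (s$stage != "smoothed")
    stop_validation("bandpass_filter expects a smoothed series (apply moving_average first)")
  dur <- diff(range(s$times))
  if (dur < 3 / low_hz)
    warning(sprintf("series of %.3g s is shorter than 3 low-band periods (%.3g s); output is transient-dominated",
                    dur, 3 / low_hz), call. = FALSE)
  fs <- s$fs_nominal
  tu <- seq(s$times[1], s$times[length(s$times)], by = 1 / fs)
  xu <- stats::approx(s$times, s$values, xout = tu, rule = 2)$y
  xu <- xu - mean(xu)   # remove DC exactly; it is outside the pass band anyway
  bf <- signal::butter(order, c(low_hz, high_hz) / (fs / 2), type = "pass")
  # odd-reflection padding suppresses the forward-backward startup transient
  # (time constant ~ 1/(2*pi*low_hz)) at both ends
  n <- length(xu)
  p <- min(n - 1L, ceiling(3 * fs / low_hz))
  xp <- c(2 * xu[1] - xu[(p + 1):2], xu, 2 * xu[n] - xu[(n - 1):(n - p)])
  yp <- signal::filtfilt(bf, xp)
  yu <- yp[(p + 1):(p + n)]
  depth_series(s$roi_name, tu, yu, "bandpassed", fs)
}

#' Run the full signal-conditioning chain on a raw series
#'
#' Normalization, causal moving average, and zero-phase band-pass, in that
#' order.
#'
#' @param s raw [depth_series()].
#' @param ws moving-average window (samples).
#' @param low_hz,high_hz,order band-pass parameters.
#' @return Band-passed [depth_series()].
#' @export
condition_series <- function(s, ws = 8, low_hz = 0.08, high_hz = 0.5, order = 4) {
  bandpass_filter(moving_average(normalize_series(s), ws = ws),
                  low_hz = low_hz, high_hz = high_hz, order = order)
}
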