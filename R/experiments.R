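#' Forced-rate validation study on synthetic recordings
#'
#' Emulates a metronome-paced single-ROI validation: a batch of 60-s
#' recordings, each with the thorax driven at a known forced rate, is run
#' through the full pipeline with the default configuration and the
#' estimated mean breath rate is compared to the forced rate by RMSE.
#'
#' The forced-rate schedule (12-25 breaths/min, several rates repeated)
#' mirrors a typical forced-breathing protocol; recording `i` uses seed
#' `base_seed * 1000 + i` so the whole batch is reproducible from one seed.
#'
#' @param base_seed integer seed for the batch.
#' @param duration_s recording length (default 60).
#' @param rates_bpm forced rates, one per recording (default: 17 recordings
#'   over 12, 14, 15, 16, 18, 20, 22 breaths/min).
#' @param amplitude_mm chest displacement amplitude (default 4).
#' @param config [pipeline_config()] used for estimation.
#' @param verbose print per-recording progress.
#' @return List with `results` (data.frame `recording`, `forced_bpm`,
#'   `estimated_bpm`) and `rmse_bpm`.
#' @export
simulate_forced_rate_study <- function(base_seed = 1,
                                       duration_s = 60,
                                       rates_bpm = c(12, 12, 14, 14, 15, 15, 15,
                                                     16, 16, 18, 18, 18, 12, 12,
                                                     20, 22, 22),
                                       amplitude_mm = 4,
                                       config = pipeline_config(rois = "thorax"),
                                       verbose = FALSE) {
  base_seed <- as.numeric(base_seed) %% 1e6
  est <- numeric(length(rates_bpm))
  for (i in seq_along(rates_bpm)) {
    cfg <- scene_config(duration_s = duration_s, seed = base_seed * 1000 + i)
    seq <- synthesize_sequence(cfg,
                               list(thorax = breathing_profile(rates_bpm[i],
                                                               amplitude_mm = amplitude_mm)),
                               materialize = FALSE)
    est[i] <- run_pipeline(seq, config)$mean_br[["thorax"]]
    if (verbose)
      message(sprintf("recording %2d: forced %.3g bpm -> estimated %.3f bpm",
                      i, rates_bpm[i], est[i]))
  }
  results <- data.frame(recording = seq_along(rates_bpm),
                        forced_bpm = rates_bpm, estimated_bpm = est)
  list(results = results, rmse_bpm = rmse(est, rates_bpm))
}

#' Two-ROI agreement study on synthetic recordings
#'
#' Emulates a natural-breathing validation against a reference: a batch of
#' 60-s two-ROI (thorax + abdomen) recordings at base rates spread uniformly
#' over 8-29 breaths/min with breath-to-breath interval jitter. Estimated
#' breath events are paired with the generator's ground-truth event times;
#' per recording and ROI, the mean breath-by-breath rate of the paired
#' estimate and reference are compared by RMSE, and likewise after both
#' tachograms are smoothed with a sliding window of `window_cycles`
#' inhalation-exhalation cycles (step 1 cycle).
#'
#' @param base_seed integer seed for the batch.
#' @param n number of recordings (default 20).
#' @param duration_s recording length (default 60).
#' @param rate_range_bpm base-rate range covered uniformly (default 8-29).
#' @param interval_jitter_frac breath-interval jitter (default 0.03).
#' @param amplitude_mm chest displacement amplitude (default 4).
#' @param window_cycles window length for the smoothed comparison (default 5).
#' @param config [pipeline_config()] used for estimation.
#' @param verbose print per-recording progress.
#' @return List with `results` (one row per recording x ROI: paired means of
#'   estimate and reference, breath-by-breath and windowed), `rmse_breath_bpm`
#'   and `rmse_windowed_bpm`.
#' @export
simulate_two_roi_study <- function(base_seed = 1, n = 20, duration_s = 60,
                                   rate_range_bpm = c(8, 29),
                                   interval_jitter_frac = 0.03,
                                   amplitude_mm = 4, window_cycles = 5,
                                   config = pipeline_config(),
                                   verbose = FALSE) {
  base_seed <- as.numeric(base_seed) %% 1e6
  rates <- seq(rate_range_bpm[1], rate_range_bpm[2], length.out = n)
  rows <- list()
  for (i in seq_len(n)) {
    cfg <- scene_config(duration_s = duration_s, seed = base_seed * 1000 + i)
    prof <- breathing_profile(rates[i], amplitude_mm = amplitude_mm,
                              interval_jitter_frac = interval_jitter_frac)
    seq <- synthesize_sequence(cfg, list(thorax = prof, abdomen = prof),
                               materialize = FALSE)
    res <- run_pipeline(seq, config)
    for (nm in names(res$tachogram)) {
      gt <- gt_tachogram(seq$annotations, nm)
      pb <- pair_breaths(res$tachogram[[nm]], gt)
      vw <- window_average_br(res$tachogram[[nm]], n_cycles = window_cycles)
      gw <- window_average_br(gt, n_cycles = window_cycles)
      pw <- pair_breaths(vw, gw)
      rows[[length(rows) + 1L]] <- data.frame(
        recording = i, roi = nm, rate_bpm = rates[i],
        mean_vs = mean(pb$pairs$br_vs), mean_gt = mean(pb$pairs$br_gt),
        mean_vs_win = mean(pw$pairs$br_vs), mean_gt_win = mean(pw$pairs$br_gt))
    }
    if (verbose)
      message(sprintf("recording %2d: base rate %.3g bpm done", i, rates[i]))
  }
  results <- do.call(rbind, rows)
  list(results = results,
       rmse_breath_bpm = rmse(results$mean_vs, results$mean_gt),
       rmse_windowed_bpm = rmse(results$mean_vs_win, results$mean_gt_win))
}
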