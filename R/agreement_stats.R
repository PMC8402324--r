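#' Pair estimated breaths with reference breaths by time
#'
#' Bland-Altman analysis needs paired observations; breath events of the
#' camera estimate (VS) and the reference (GT) are matched greedily by
#' nearest timestamps: candidate pairs are considered in order of increasing
#' time difference, and each entry is used at most once. Pairs farther apart
#' than `tol_s` are rejected; unmatched entries on either side are counted
#' and excluded.
#'
#' @param vs estimated tachogram.
#' @param gt reference tachogram.
#' @param tol_s pairing tolerance in seconds; default half the median
#'   reference breath interval.
#' @return An object of class `paired_breaths`: data.frame `pairs`
#'   (`time_s`, `br_vs`, `br_gt`) plus unmatched counts.
#' @export
pair_breaths <- function(vs, gt, tol_s = NULL) {
  if (nrow(vs) < 1 || nrow(gt) < 1) stop_validation("both tachograms must be non-empty")
  if (is.null(tol_s)) {
    tol_s <- if (nrow(gt) >= 2) stats::median(diff(gt$time_s)) / 2
             else stats::median(60 / gt$br_bpm) / 2
  }
  cand <- expand.grid(i = seq_len(nrow(gt)), j = seq_len(nrow(vs)))
  cand$dt <- abs(gt$time_s[cand$i] - vs$time_s[cand$j])
  cand <- cand[cand$dt <= tol_s, , drop = FALSE]
  cand <- cand[order(cand$dt), , drop = FALSE]
  used_i <- logical(nrow(gt)); used_j <- logical(nrow(vs))
  pi <- integer(0); pj <- integer(0)
  for (r in seq_len(nrow(cand))) {
    i <- cand$i[r]; j <- cand$j[r]
    if (!used_i[i] && !used_j[j]) {
      used_i[i] <- TRUE; used_j[j] <- TRUE
      pi <- c(pi, i); pj <- c(pj, j)
    }
  }
  if (length(pi) == 0) stop_validation("no breath pairs within tolerance")
  o <- order(gt$time_s[pi])
  structure(list(
    pairs = data.frame(time_s = gt$time_s[pi][o],
                       br_vs = vs$br_bpm[pj][o],
                       br_gt = gt$br_bpm[pi][o]),
    n_unmatched_vs = sum(!used_j),
    n_unmatched_gt = sum(!used_i),
    tol_s = tol_s), class = "paired_breaths")
}

#' Bland-Altman agreement between paired breath rates
#'
#' Differences `d_i = br_vs - br_gt` give the bias (mean difference) and the
#' limits of agreement `bias +- multiplier * sd(d)` (sample SD, n-1). The
#' conventional multiplier 1.96 spans 95% of differences under normality;
#' it is a parameter so other coverages can be produced.
#'
#' @param p a [pair_breaths()] result.
#' @param multiplier limits-of-agreement multiplier (default 1.96).
#' @return An `agreement_report`: `bias`, `loa_low`, `loa_high`,
#'   `loa_multiplier`, `rmse` (breath-level, over the same pairs), `n`,
#'   unmatched counts, and a `points` data.frame (`mean`, `diff`) for
#'   plotting.
#' @export
bland_altman <- function(p, multiplier = 1.96) {
  d <- p$pairs$br_vs - p$pairs$br_gt
  n <- length(d)
  if (n < 2) stop_validation("Bland-Altman needs at least 2 pairs")
  bias <- mean(d); s <- stats::sd(d)
  structure(list(
    bias = bias, loa_low = bias - multiplier * s, loa_high = bias + multiplier * s,
    loa_multiplier = multiplier,
    rmse = rmse(p$pairs$br_vs, p$pairs$br_gt),
    n = n, n_unmatched_vs = p$n_unmatched_vs, n_unmatched_gt = p$n_unmatched_gt,
    points = data.frame(mean = (p$pairs$br_vs + p$pairs$br_gt) / 2, diff = d)),
    class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("<agreement_report> n=%d  bias=%.3f  LoA [%.3f, %.3f] (x%.3g)  RMSE=%.3f breaths/min\n",
              x$n, x$bias, x$loa_low, x$loa_high, x$loa_multiplier, x$rmse))
  if (x$n_unmatched_vs + x$n_unmatched_gt > 0)
    cat(sprintf("  unmatched: %d estimate, %d reference\n",
                x$n_unmatched_vs, x$n_unmatched_gt))
  invisible(x)
}

#' Root-mean-squared error between estimates and reference values
#'
#' `sqrt(mean((estimate - truth)^2))`, in breaths/min when applied to breath
#' rates. Used both at breath level and at experiment level (one mean rate
#' per recording).
#'
#' @param estimates,truths equal-length numeric vectors.
#' @return Non-negative scalar.
#' @export
rmse <- function(estimates, truths) {
  if (length(estimates) != length(truths))
    stop_validation("rmse: estimates and truths differ in length")
  if (length(estimates) < 1) stop_validation("rmse: empty input")
  sqrt(mean((estimates - truths)^2))
}

#' Full agreement report between two tachograms
#'
#' Convenience wrapper: [pair_breaths()] then [bland_altman()].
#'
#' @param vs,gt estimated and reference tachograms.
#' @param tol_s pairing tolerance (see [pair_breaths()]).
#' @param multiplier limits-of-agreement multiplier.
#' @return An `agreement_report`.
#' @export
compare_tachograms <- function(vs, gt, tol_s = NULL, multiplier = 1.96) {
  bland_altman(pair_breaths(vs, gt, tol_s), multiplier)
}

#' Bland-Altman plot
#'
#' @param report an `agreement_report`.
#' @param ... passed to [graphics::plot()].
#' @return The report, invisibly.
#' @export
plot_bland_altman <- function(report, ...) {
  graphics::plot(report$points$mean, report$points$diff,
                 xlab = "Mean of estimate and reference [breaths/min]",
                 ylab = "Difference (estimate - reference) [breaths/min]",
                 pch = 19, col = grDevices::adjustcolor("steelblue", 0.6), ...)
  graphics::abline(h = report$bias, lty = 1)
  graphics::abline(h = c(report$loa_low, report$loa_high), lty = 2)
  invisible(report)
}
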