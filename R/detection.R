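#' Threshold-crossing onset detection on a feature signal
#'
#' Scans the windows whose end time lies strictly after `search_start_s`
#' (a window's energy is only available once the window completes, so the
#' detection time is the window END) and reports the first window with
#' `u_n >= threshold`. Latency is `max(0, detect_time - onset_s)`; the clamp
#' matters when the scan is started before the onset. A seizure not detected
#' within `fn_cutoff_s` seconds of the onset (default 5 s) counts as a false
#' negative.
#'
#' @param sig A `feature_signal` (see [project_feature()]).
#' @param threshold Detection threshold (feature units), > 0.
#' @param onset_s Annotated onset, seconds, in the signal's time base.
#' @param search_start_s Where the scan begins; defaults to the onset.
#' @param fn_cutoff_s False-negative latency cutoff, seconds.
#' @return A list: `detected`, `detect_time_s`, `latency_s` (NA when not
#'   detected), `is_fn`.
#' @export
detect_onset <- function(sig, threshold, onset_s,
                         search_start_s = onset_s, fn_cutoff_s = 5) {
  stopifnot(inherits(sig, "feature_signal"))
  if (!length(sig$values)) stop("empty feature signal")
  if (threshold <= 0) stop("`threshold` must be positive")
  ends <- sig$window_start_s + sig$window_len_s
  elig <- which(ends > search_start_s)
  hit <- elig[sig$values[elig] >= threshold]
  if (!length(hit)) {
    return(list(detected = FALSE, detect_time_s = NA_real_,
                latency_s = NA_real_, is_fn = TRUE))
  }
  detect_time <- ends[hit[1]]
  latency <- max(0, detect_time - onset_s)
  list(detected = TRUE, detect_time_s = detect_time, latency_s = latency,
       is_fn = latency > fn_cutoff_s)
}

#' False-positive window rate on non-seizure data
#'
#' Percentage of windows whose feature value strictly exceeds the threshold
#' (detection itself uses `>=`; the strict inequality here fixes the
#' boundary so that a threshold placed exactly on an observed value does not
#' count that value as a false positive).
#'
#' @param sig A `feature_signal` from annotation-free data.
#' @param threshold Threshold in feature units.
#' @return FP rate in percent (0-100).
#' @export
false_positive_rate <- function(sig, threshold) {
  stopifnot(inherits(sig, "feature_signal"))
  if (!length(sig$values)) stop("no windows: empty feature signal")
  100 * mean(sig$values > threshold)
}

#' Threshold achieving a target false-positive rate
#'
#' The smallest observed feature value whose FP rate is at or below the
#' target: the `ceiling((1 - target) * W)`-th order statistic of the
#' non-seizure feature values (exact and deterministic; no continuous grid).
#'
#' @param sig Non-seizure `feature_signal`.
#' @param target_fp Target FP rate as a fraction (default 0.05).
#' @return Threshold in feature units.
#' @export
threshold_for_fp <- function(sig, target_fp = 0.05) {
  stopifnot(inherits(sig, "feature_signal"))
  if (target_fp <= 0 || target_fp >= 1) stop("`target_fp` must be in (0, 1)")
  u <- sig$values
  if (!length(u)) stop("no windows: empty feature signal")
  th <- sort(u)[ceiling((1 - target_fp) * length(u))]
  stopifnot(false_positive_rate(sig, th) <= 100 * target_fp)
  th
}

#' Largest threshold still detecting within a target latency
#'
#' The maximum feature value over the windows ending within
#' `(onset_s, onset_s + target_lat_s]`: at this threshold the onset is still
#' detected with latency at most `target_lat_s`; any higher threshold is
#' not crossed by those windows.
#'
#' @param sig Seizure `feature_signal`.
#' @param onset_s Annotated onset, seconds.
#' @param target_lat_s Target latency, seconds (default 2).
#' @return Threshold in feature units.
#' @export
threshold_for_latency <- function(sig, onset_s, target_lat_s = 2) {
  stopifnot(inherits(sig, "feature_signal"))
  ends <- sig$window_start_s + sig$window_len_s
  elig <- ends > onset_s & ends <= onset_s + target_lat_s
  if (!any(elig)) {
    stop("no analysis window ends within (", onset_s, ", ",
         onset_s + target_lat_s, "] s")
  }
  max(sig$values[elig])
}

#' Calibrate the operating threshold from training seizures
#'
#' For each training seizure the candidate threshold is the arithmetic mean
#' of the threshold at the target FP rate (from non-seizure data) and the
#' threshold at the target latency (from that seizure). The operating
#' threshold `Th_1` is the median of the candidates (mean of the central two
#' for an even count).
#'
#' @param train_sigs List of seizure `feature_signal`s (training set).
#' @param onsets Numeric vector of per-seizure onsets, seconds.
#' @param nonseizure_sig Non-seizure `feature_signal` used for the FP side.
#' @param fp_target Target FP fraction (default 0.05).
#' @param lat_target_s Target latency, seconds (default 2).
#' @param scales Scale factors for subsequent sweeps.
#' @return A `threshold_calibration`: per-seizure table (`th_fp`, `th_lat`,
#'   `candidate`), `th_fp`, `th1`, `scales`.
#' @export
calibrate <- function(train_sigs, onsets, nonseizure_sig,
                      fp_target = 0.05, lat_target_s = 2,
                      scales = c(0.2, 0.5, 0.8, 1.0, 1.2, 1.5, 2.0)) {
  if (!length(train_sigs)) stop("need at least one training seizure")
  stopifnot(length(train_sigs) == length(onsets))
  th_fp <- threshold_for_fp(nonseizure_sig, fp_target)
  th_lat <- mapply(function(sig, on) threshold_for_latency(sig, on,
                                                           lat_target_s),
                   train_sigs, onsets)
  per <- data.frame(th_fp = th_fp, th_lat = th_lat,
                    candidate = (th_fp + th_lat) / 2)
  structure(
    list(per_seizure = per, th_fp = th_fp,
         th1 = stats::median(per$candidate), scales = scales),
    class = "threshold_calibration"
  )
}

#' @export
print.threshold_calibration <- function(x, ...) {
  cat(sprintf("<threshold_calibration> %d seizures, th1 = %.4g (th_fp = %.4g)\n",
              nrow(x$per_seizure), x$th1, x$th_fp))
  invisible(x)
}

#' Performance indices across scaled thresholds
#'
#' Evaluates FP (on held-out non-seizure data), FN%, and mean latency over
#' the test seizures at every multiple of the operating threshold. Mean
#' latency averages the seizures for which a crossing exists anywhere in the
#' clip; seizures crossing later than the FN cutoff still count as FN but
#' their latency is reported in the mean.
#'
#' @param test_sigs List of test-seizure `feature_signal`s.
#' @param onsets Per-seizure onsets, seconds.
#' @param nonseizure_sig Held-out non-seizure `feature_signal`.
#' @param th1 Operating threshold.
#' @param scales Scale factors (default the 0.2 ... 2.0 sweep).
#' @param fn_cutoff_s False-negative cutoff, seconds.
#' @return Data frame: `scale`, `threshold`, `fp_pct`, `fn_pct`,
#'   `mean_latency_s`, `n_detected`.
#' @export
evaluate_at_scales <- function(test_sigs, onsets, nonseizure_sig, th1,
                               scales = c(0.2, 0.5, 0.8, 1.0, 1.2, 1.5, 2.0),
                               fn_cutoff_s = 5) {
  if (th1 <= 0) stop("`th1` must be positive")
  rows <- lapply(scales, function(s) {
    th <- s * th1
    outs <- mapply(function(sig, on) {
      detect_onset(sig, th, on, fn_cutoff_s = fn_cutoff_s)
    }, test_sigs, onsets, SIMPLIFY = FALSE)
    lat <- vapply(outs, function(o) o$latency_s, 0)
    det <- vapply(outs, function(o) o$detected, TRUE)
    data.frame(scale = s, threshold = th,
               fp_pct = false_positive_rate(nonseizure_sig, th),
               fn_pct = 100 * mean(vapply(outs, function(o) o$is_fn, TRUE)),
               mean_latency_s = if (any(det)) mean(lat[det]) else NA_real_,
               n_detected = sum(det))
  })
  do.call(rbind, rows)
}

#' Stable threshold range of one seizure
#'
#' The range from the threshold meeting the target FP rate (lower end, from
#' non-seizure data) up to the threshold still meeting the target latency
#' (upper end, from the seizure). A wide range means the feature tolerates
#' threshold miscalibration; the width is clamped at zero when no stable
#' range exists.
#'
#' @param seizure_sig Seizure `feature_signal`.
#' @param onset_s Annotated onset, seconds.
#' @param nonseizure_sig Non-seizure `feature_signal`.
#' @param fp_target Target FP fraction.
#' @param lat_target_s Target latency, seconds.
#' @return List `low`, `high`, `width`.
#' @export
stable_range <- function(seizure_sig, onset_s, nonseizure_sig,
                         fp_target = 0.05, lat_target_s = 2) {
  low <- threshold_for_fp(nonseizure_sig, fp_target)
  high <- threshold_for_latency(seizure_sig, onset_s, lat_target_s)
  list(low = low, high = high, width = max(0, high - low))
}

#' Rank features by stable-range width
#'
#' Rank 1 is the widest range; ties receive the mean of the tied rank
#' positions.
#'
#' @param widths Named numeric vector of per-feature widths for one seizure.
#' @return Numeric vector of ranks (same names).
#' @export
rank_features <- function(widths) {
  if (length(widths) < 2) stop("need at least two features to rank")
  rank(-widths, ties.method = "average")
}

#' Aggregate per-seizure feature ranks
#'
#' @param rank_matrix Seizures x features matrix of ranks (rows as returned
#'   by [rank_features()]).
#' @return Data frame: `feature`, `mean_rank`, `sd_rank`,
#'   `first_rank_count` (ties at the top each count).
#' @export
aggregate_ranks <- function(rank_matrix) {
  stopifnot(is.matrix(rank_matrix), !is.null(colnames(rank_matrix)))
  row_min <- apply(rank_matrix, 1, min)
  data.frame(
    feature = colnames(rank_matrix),
    mean_rank = colMeans(rank_matrix),
    sd_rank = apply(rank_matrix, 2, stats::sd),
    first_rank_count = colSums(rank_matrix == row_min),
    row.names = NULL
  )
}

#' Normalize a feature signal against its threshold
#'
#' `u_n / th`: values above 1 flag false-positive windows, which makes
#' signals with different scales directly comparable when screening
#' artifacts.
#'
#' @param sig A `feature_signal`.
#' @param th Threshold, > 0.
#' @return A `feature_signal` with normalized values.
#' @export
normalize_against_threshold <- function(sig, th) {
  stopifnot(inherits(sig, "feature_signal"))
  if (th <= 0) stop("`th` must be positive")
  sig$values <- sig$values / th
  sig$feature_name <- paste0(sig$feature_name, "_norm")
  sig
}
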