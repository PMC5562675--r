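test_that("onset detection reports first crossing, latency, and FN status", {
  sig <- make_signal(c(0, 0, 3, 0, 0, 0))    # windows end at 1, 2, 3, ... s
  out <- detect_onset(sig, threshold = 2, onset_s = 0)
  expect_true(out$detected)
  expect_equal(out$detect_time_s, 3)
  expect_equal(out$latency_s, 3)
  expect_false(out$is_fn)

  # nothing crosses: a false negative with undefined latency
  none <- detect_onset(sig, threshold = 10, onset_s = 0)
  expect_false(none$detected)
  expect_true(none$is_fn)
  expect_true(is.na(none$latency_s))

  # crossing later than the 5 s cutoff: detected but still FN
  late <- make_signal(c(0, 0, 0, 0, 0, 0, 7))
  out_late <- detect_onset(late, 5, onset_s = 0)
  expect_true(out_late$detected)
  expect_true(out_late$is_fn)
  expect_equal(out_late$latency_s, 7)

  # scanning from before the onset clamps pre-onset crossings to latency 0
  pre <- make_signal(c(9, 0, 0, 0, 9, 0))
  out_pre <- detect_onset(pre, 5, onset_s = 3, search_start_s = 0)
  expect_equal(out_pre$detect_time_s, 1)
  expect_equal(out_pre$latency_s, 0)

  expect_error(detect_onset(make_signal(numeric()), 1, 0), "empty")
  expect_error(detect_onset(sig, 0, 0), "positive")
})

test_that("false positive rate counts strictly-above windows", {
  sig <- make_signal(c(1, 2, 3, 4))
  expect_equal(false_positive_rate(sig, 10), 0)
  expect_equal(false_positive_rate(sig, 0), 100)
  expect_equal(false_positive_rate(sig, 2), 50)   # boundary value excluded
  set.seed(41)
  u <- rlnorm(500)
  s <- make_signal(u)
  for (th in stats::quantile(u, c(0.1, 0.5, 0.9))) {
    expect_equal(false_positive_rate(s, th), 100 * sum(u > th) / 500)
  }
})

test_that("FP threshold is the exact order statistic meeting the target", {
  sig <- make_signal(1:100)
  expect_equal(threshold_for_fp(sig, 0.05), 95)
  expect_equal(threshold_for_fp(make_signal(rep(7, 10)), 0.05), 7)
  # brute-force scan oracle over all observed candidate thresholds
  set.seed(42)
  for (i in 1:50) {
    u <- rlnorm(sample(50:200, 1))
    s <- make_signal(u)
    got <- threshold_for_fp(s, 0.05)
    cand <- sort(u)
    ok <- cand[vapply(cand, function(v) mean(u > v) <= 0.05, TRUE)]
    expect_equal(got, min(ok))
    expect_lte(false_positive_rate(s, got), 5)
  }
})

test_that("latency threshold is the max over windows ending in the target", {
  # only the window ending at 4 s lies in (3, 5]
  sig <- make_signal(c(9, 9, 9, 7, 1, 1))
  expect_equal(threshold_for_latency(sig, onset_s = 3), 7)
  sig2 <- make_signal(c(0, 0, 0, 3, 9, 1))
  expect_equal(threshold_for_latency(sig2, onset_s = 3), 9)
  expect_error(threshold_for_latency(sig, onset_s = 6.5), "ends within")

  # scan oracle: the result detects within target, one step higher fails
  set.seed(43)
  for (i in 1:50) {
    u <- rlnorm(30)
    s <- make_signal(u)
    onset <- sample(3:20, 1)
    th <- threshold_for_latency(s, onset, target_lat_s = 2)
    hit <- detect_onset(s, th, onset)
    expect_true(hit$detected)
    expect_lte(hit$latency_s, 2)
    above <- detect_onset(s, th * (1 + 1e-9), onset)
    expect_true(!above$detected || above$latency_s > 2)
  }
})

test_that("calibration averages the two targets and takes the median", {
  ns <- make_signal(rep(1, 40))               # th_fp = 1 exactly
  mk <- function(peak) make_signal(c(0, peak, peak, 0, 0))
  # candidates (1+1)/2, (1+3)/2, (1+17)/2 = 1, 2, 9 -> median 2
  cal <- calibrate(list(mk(1), mk(3), mk(17)), c(0, 0, 0), ns)
  expect_equal(cal$per_seizure$candidate, c(1, 2, 9))
  expect_equal(cal$th1, 2)
  # even count: mean of the central two
  cal4 <- calibrate(list(mk(1), mk(5), mk(9), mk(13)), rep(0, 4), ns)
  expect_equal(cal4$th1, 4)
  # a single seizure is its own median
  cal1 <- calibrate(list(mk(9)), 0, ns)
  expect_equal(cal1$th1, cal1$per_seizure$candidate)
})

test_that("scaled-threshold evaluation is monotone in the expected directions", {
  ds <- small_dataset()
  series <- lapply(ds$seizures, function(s) band_energy_series(s$recording))
  ns <- band_energy_series(ds$nonseizure)
  sigs <- lapply(series, subband_feature, band_name = "beta")
  ns_sig <- subband_feature(ns, "beta")
  onsets <- vapply(ds$seizures, function(s) s$annotation$onset_s, 0)
  cal <- calibrate(sigs[1:6], onsets[1:6], ns_sig)
  ev <- evaluate_at_scales(sigs[7:12], onsets[7:12], ns_sig, cal$th1)
  expect_equal(nrow(ev), 7)
  expect_false(is.unsorted(rev(ev$fp_pct)))
  expect_false(is.unsorted(ev$fn_pct))
  # a low threshold detects everything
  expect_equal(ev$fn_pct[ev$scale == 0.2], 0)
})

test_that("stable ranges clamp at zero and match their two solvers", {
  ns <- make_signal(rep(2, 40))
  sz <- make_signal(c(0, 9, 9, 0))
  r <- stable_range(sz, 0, ns)
  expect_equal(r$low, 2)
  expect_equal(r$high, 9)
  expect_equal(r$width, 7)
  expect_equal(r$low, threshold_for_fp(ns, 0.05))
  expect_equal(r$high, threshold_for_latency(sz, 0, 2))
  weak <- make_signal(c(0, 1, 1, 0))
  expect_equal(stable_range(weak, 0, ns)$width, 0)
})

test_that("feature ranking follows width order with averaged ties", {
  expect_equal(unname(rank_features(c(3, 2, 1))), c(1, 2, 3))
  expect_equal(unname(rank_features(c(2, 2, 1))), c(1.5, 1.5, 3))
  set.seed(44)
  rm <- t(replicate(50, rank_features(
    stats::setNames(runif(7), paste0("f", 1:7)))))
  agg <- aggregate_ranks(rm)
  # brute-force sort oracle for the mean ranks
  expect_equal(agg$mean_rank, unname(colMeans(rm)))
  expect_equal(sum(agg$first_rank_count), 50)  # no ties among runif draws
  expect_true(all(agg$mean_rank >= 1 & agg$mean_rank <= 7))
  # top ties each count as a first rank
  tied <- rbind(rank_features(c(5, 5, 1)), rank_features(c(1, 5, 9)))
  colnames(tied) <- c("a", "b", "c")
  expect_equal(aggregate_ranks(tied)$first_rank_count, c(1, 1, 1))
})

test_that("threshold-normalized signals flag FP windows at 1", {
  sig <- make_signal(c(2, 4, 8))
  expect_equal(normalize_against_threshold(sig, 4)$values, c(0.5, 1, 2))
  expect_equal(normalize_against_threshold(make_signal(rep(0, 3)), 2)$values,
               rep(0, 3))
  expect_error(normalize_against_threshold(sig, 0), "positive")
  set.seed(45)
  u <- rlnorm(200)
  s <- make_signal(u)
  th <- threshold_for_fp(s, 0.1)
  norm <- normalize_against_threshold(s, th)
  expect_equal(100 * mean(norm$values > 1), false_positive_rate(s, th))
})
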