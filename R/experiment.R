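#' Experiment configuration
#'
#' Parameters of the full seven-feature comparison: random train/test split,
#' the two eigenfeatures plus the five single-band comparators, the scaled
#' threshold sweep, the FP/latency targets, and the training-set-size sweep.
#'
#' @param split_seed Seed of the random 50/50 split (and of the size sweep's
#'   resampling).
#' @param train_fraction Fraction of seizures assigned to training.
#' @param scales Threshold scale factors; must include 1.
#' @param fp_target Target FP fraction for calibration (default 0.05).
#' @param lat_target_s Target latency for calibration, seconds (default 2).
#' @param fn_cutoff_s False-negative cutoff, seconds (default 5).
#' @param initial_len_s Initial-segment length for `e_i`, seconds.
#' @param sweep_sizes Training-set sizes for the eigenvector stability sweep.
#' @param sweep_repeats Resampling repeats per size.
#' @param channel Channel used for analysis.
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(split_seed = 1, train_fraction = 0.5,
                              scales = c(0.2, 0.5, 0.8, 1.0, 1.2, 1.5, 2.0),
                              fp_target = 0.05, lat_target_s = 2,
                              fn_cutoff_s = 5, initial_len_s = 5,
                              sweep_sizes = c(10, 20, 30, 50),
                              sweep_repeats = 20, channel = 1) {
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("`train_fraction` must be in (0, 1)")
  }
  if (!any(abs(scales - 1) < 1e-12)) stop("`scales` must include 1.0")
  structure(
    list(split_seed = split_seed, train_fraction = train_fraction,
         scales = scales, fp_target = fp_target,
         lat_target_s = lat_target_s, fn_cutoff_s = fn_cutoff_s,
         initial_len_s = initial_len_s, sweep_sizes = sweep_sizes,
         sweep_repeats = sweep_repeats, channel = channel),
    class = "experiment_config"
  )
}

#' Random train/test split of a dataset
#'
#' Uniform partition without replacement, deterministic per seed; tags each
#' seizure `"train"` or `"test"`.
#'
#' @param dataset An `annotated_dataset`.
#' @param seed Split seed.
#' @param fraction Training fraction.
#' @return The dataset with `split` tags set.
#' @export
split_train_test <- function(dataset, seed = 1, fraction = 0.5) {
  stopifnot(inherits(dataset, "annotated_dataset"))
  n <- length(dataset$seizures)
  if (n < 2) stop("need at least 2 seizures to split")
  n_train <- round(fraction * n)
  if (n_train < 1 || n_train >= n) {
    stop("`fraction` leaves an empty train or test side")
  }
  set.seed(seed)
  train_idx <- sample.int(n, n_train)
  for (i in seq_len(n)) {
    dataset$seizures[[i]]$split <- if (i %in% train_idx) "train" else "test"
  }
  dataset
}

feature_names <- function() {
  c("delta", "theta", "alpha", "beta", "gamma", "u_i", "u_w")
}

# band-energy series of every clip plus the calibration / held-out halves
# of the non-seizure recording (halved by time, so the FP threshold is never
# evaluated on the windows it was fitted to)
prepare_series <- function(dataset, cfg) {
  series <- lapply(dataset$seizures, function(s) {
    band_energy_series(s$recording, channel = cfg$channel)
  })
  ns <- band_energy_series(dataset$nonseizure, channel = cfg$channel)
  W <- nrow(ns$energies)
  half <- W %/% 2
  list(series = series,
       ns_cal = subset_series(ns, seq_len(half)),
       ns_held = subset_series(ns, (half + 1):W))
}

feature_signal_for <- function(series, feature, ei, ew) {
  switch(feature,
         u_i = project_feature(series, ei),
         u_w = project_feature(series, ew),
         subband_feature(series, feature))
}

#' Run the full feature comparison
#'
#' Trains `e_i` (initial 5 s) and `e_w` (whole seizure) on the training
#' seizures, calibrates a per-feature operating threshold `Th_1` (each of
#' the seven features lives on its own scale), evaluates FP / FN / latency
#' at every scaled threshold on the test seizures and held-out non-seizure
#' data, computes per-test-seizure stable threshold ranges, and ranks the
#' features by range width.
#'
#' @param dataset A split `annotated_dataset` (see [split_train_test()]);
#'   an unsplit dataset is split with `cfg$split_seed`.
#' @param cfg An [experiment_config()].
#' @return A `comparison_report` list: `ei`, `ew`, `angle_deg`, `th1` per
#'   feature, `grid` (feature x scale indices), `rank_matrix`, `ranks`
#'   (aggregated), `widths`, `config`, `n_train`, `n_test`.
#' @export
run_comparison <- function(dataset, cfg = experiment_config()) {
  stopifnot(inherits(dataset, "annotated_dataset"))
  splits <- vapply(dataset$seizures, function(s) s$split, "")
  if (!any(splits == "train")) {
    dataset <- split_train_test(dataset, cfg$split_seed, cfg$train_fraction)
    splits <- vapply(dataset$seizures, function(s) s$split, "")
  }
  prep <- prepare_series(dataset, cfg)
  anns <- lapply(dataset$seizures, function(s) s$annotation)
  tr <- which(splits == "train")
  te <- which(splits == "test")

  ei <- train_eigenfeature(prep$series[tr], anns[tr], mode = "initial",
                           initial_len_s = cfg$initial_len_s)
  ew <- train_eigenfeature(prep$series[tr], anns[tr], mode = "whole")

  onsets <- vapply(anns, function(a) a$onset_s, 0)
  grid <- list()
  th1 <- stats::setNames(numeric(length(feature_names())), feature_names())
  widths <- matrix(NA_real_, nrow = length(te),
                   ncol = length(feature_names()),
                   dimnames = list(NULL, feature_names()))
  for (f in feature_names()) {
    sigs <- lapply(prep$series, feature_signal_for, feature = f,
                   ei = ei, ew = ew)
    ns_cal_sig <- feature_signal_for(prep$ns_cal, f, ei, ew)
    ns_held_sig <- feature_signal_for(prep$ns_held, f, ei, ew)
    cal <- calibrate(sigs[tr], onsets[tr], ns_cal_sig,
                     fp_target = cfg$fp_target,
                     lat_target_s = cfg$lat_target_s, scales = cfg$scales)
    th1[f] <- cal$th1
    ev <- evaluate_at_scales(sigs[te], onsets[te], ns_held_sig, cal$th1,
                             scales = cfg$scales,
                             fn_cutoff_s = cfg$fn_cutoff_s)
    grid[[f]] <- cbind(feature = f, ev)
    widths[, f] <- vapply(seq_along(te), function(j) {
      stable_range(sigs[[te[j]]], onsets[te[j]], ns_cal_sig,
                   fp_target = cfg$fp_target,
                   lat_target_s = cfg$lat_target_s)$width
    }, 0)
  }
  rank_matrix <- t(apply(widths, 1, rank_features))
  structure(
    list(ei = ei, ew = ew, angle_deg = eigenvector_angle(ei, ew),
         th1 = th1, grid = do.call(rbind, grid),
         widths = widths, rank_matrix = rank_matrix,
         ranks = aggregate_ranks(rank_matrix),
         config = cfg, n_train = length(tr), n_test = length(te),
         sim_seed = dataset$config$seed),
    class = "comparison_report"
  )
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("<comparison_report> %d train / %d test seizures\n",
              x$n_train, x$n_test))
  cat(sprintf("  angle(e_i, e_w) = %.1f deg\n", x$angle_deg))
  at1 <- x$grid[abs(x$grid$scale - 1) < 1e-12, ]
  for (i in seq_len(nrow(at1))) {
    cat(sprintf("  %-6s FP %5.2f%%  FN %5.1f%%  Lat %s s  mean rank %.2f\n",
                at1$feature[i], at1$fp_pct[i], at1$fn_pct[i],
                formatC(at1$mean_latency_s[i], format = "f", digits = 2),
                x$ranks$mean_rank[match(at1$feature[i], x$ranks$feature)]))
  }
  invisible(x)
}

#' Training-set-size sensitivity of the eigenfeatures
#'
#' For each size, repeatedly resamples that many training seizures (without
#' replacement), retrains `e_i` and `e_w`, and reports the component-wise
#' mean and standard deviation of each eigenvector across repeats.
#'
#' @param dataset A split `annotated_dataset`.
#' @param cfg An [experiment_config()].
#' @param sizes Training-set sizes; default from `cfg`.
#' @param repeats Resamples per size; default from `cfg`.
#' @return Data frame: `mode`, `size`, `band`, `mean`, `sd`.
#' @export
sample_size_sweep <- function(dataset, cfg = experiment_config(),
                              sizes = cfg$sweep_sizes,
                              repeats = cfg$sweep_repeats) {
  stopifnot(inherits(dataset, "annotated_dataset"))
  splits <- vapply(dataset$seizures, function(s) s$split, "")
  if (!any(splits == "train")) {
    dataset <- split_train_test(dataset, cfg$split_seed, cfg$train_fraction)
    splits <- vapply(dataset$seizures, function(s) s$split, "")
  }
  tr <- which(splits == "train")
  if (max(sizes) > length(tr)) {
    stop("sweep size ", max(sizes), " exceeds the training pool of ",
         length(tr))
  }
  # window pools per training seizure, computed once
  pools <- lapply(dataset$seizures[tr], function(s) {
    series <- band_energy_series(s$recording, channel = cfg$channel)
    list(
      initial = series$energies[
        select_segment_windows(series, s$annotation$onset_s,
                               s$annotation$offset_s, mode = "initial",
                               initial_len_s = cfg$initial_len_s), ,
        drop = FALSE],
      whole = series$energies[
        select_segment_windows(series, s$annotation$onset_s,
                               s$annotation$offset_s, mode = "whole"), ,
        drop = FALSE]
    )
  })
  seeds <- derive_seeds(cfg$split_seed, length(sizes) * repeats)
  out <- list()
  for (si in seq_along(sizes)) {
    sz <- sizes[si]
    es <- list(initial = matrix(0, repeats, 5), whole = matrix(0, repeats, 5))
    for (r in seq_len(repeats)) {
      set.seed(seeds[(si - 1) * repeats + r])
      pick <- sample(length(pools), sz)
      for (mode in c("initial", "whole")) {
        acc <- accumulate_second_moment(lapply(pools[pick], `[[`, mode))
        es[[mode]][r, ] <- dominant_eigenvector(acc)$e
      }
    }
    for (mode in c("initial", "whole")) {
      out[[length(out) + 1]] <- data.frame(
        mode = if (mode == "initial") "e_i" else "e_w",
        size = sz, band = band_names(),
        mean = colMeans(es[[mode]]),
        sd = apply(es[[mode]], 2, stats::sd))
    }
  }
  do.call(rbind, out)
}

#' Write the comparison report to disk
#'
#' Emits `fig5_grid.csv` (feature x scale performance indices),
#' `fig6_ranks.csv` (mean rank with sd), `fig7_firstranks.csv` (first-rank
#' counts), the two trained model JSON files, and `manifest.json`
#' (seeds, config hash, eigenvector angle). Re-rendering the same report
#' reproduces the files byte for byte.
#'
#' @param report A `comparison_report`.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
render_report <- function(report, out_dir) {
  stopifnot(inherits(report, "comparison_report"))
  ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create '", out_dir, "'")
  utils::write.csv(report$grid, file.path(out_dir, "fig5_grid.csv"),
                   row.names = FALSE)
  utils::write.csv(report$ranks[, c("feature", "mean_rank", "sd_rank")],
                   file.path(out_dir, "fig6_ranks.csv"), row.names = FALSE)
  utils::write.csv(report$ranks[, c("feature", "first_rank_count")],
                   file.path(out_dir, "fig7_firstranks.csv"),
                   row.names = FALSE)
  hash <- config_hash(report$config)
  save_model(report$ei, file.path(out_dir, "model_initial.json"),
             config_hash = hash)
  save_model(report$ew, file.path(out_dir, "model_whole.json"),
             config_hash = hash)
  jsonlite::write_json(
    list(sim_seed = report$sim_seed, split_seed = report$config$split_seed,
         config_hash = hash, angle_deg = report$angle_deg,
         th1 = as.list(report$th1),
         n_train = report$n_train, n_test = report$n_test),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(out_dir)
}

#' Simulate, split, compare, and render in one call
#'
#' @param sim_cfg A [sim_config()].
#' @param exp_cfg An [experiment_config()].
#' @param out_dir Optional output directory for [render_report()].
#' @return The `comparison_report`.
#' @export
run_experiment <- function(sim_cfg = sim_config(),
                           exp_cfg = experiment_config(), out_dir = NULL) {
  dataset <- simulate_dataset(sim_cfg)
  dataset <- split_train_test(dataset, exp_cfg$split_seed,
                              exp_cfg$train_fraction)
  report <- run_comparison(dataset, exp_cfg)
  if (!is.null(out_dir)) render_report(report, out_dir)
  report
}
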