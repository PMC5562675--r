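test_that("background noise has the right length, seed, and 1/f spectrum", {
  cfg <- sim_config(theta_rhythm_uV = 0)
  bg <- simulate_background(30, cfg, seed = 5)
  expect_equal(nrow(bg$samples), 30 * 200)
  bg2 <- simulate_background(30, cfg, seed = 5)
  expect_identical(bg$samples, bg2$samples)
  expect_false(identical(bg$samples,
                         simulate_background(30, cfg, seed = 6)$samples))

  # periodogram regression oracle: log-log slope in 2-50 Hz near -1
  slope_of <- function(rec) {
    x <- get_channel(rec)
    n <- length(x)
    P <- Mod(stats::fft(x))^2
    f <- (0:(n - 1)) * rec$fs / n
    sel <- f >= 2 & f <= 50
    unname(stats::coef(stats::lm(log(P[sel]) ~ log(f[sel])))[2])
  }
  expect_lt(abs(slope_of(simulate_background(600, cfg, seed = 5)) + 1), 0.3)
  # the intermittent theta rhythm does not break the broadband slope
  expect_lt(abs(slope_of(simulate_background(600, sim_config(), seed = 5)) + 1),
            0.3)
})

test_that("simulated seizures are beta-dominant early and theta-dominant late", {
  for (seed in 1:4) {
    prof <- seizure_profile(duration_s = 30)
    burst <- simulate_seizure(prof, fs = 200, seed = seed)
    expect_equal(length(burst$samples), 30 * 200)
    expect_equal(burst$annotation$offset_s, 30)
    ser <- band_energy_series(recording(burst$samples, fs = 200))
    first5 <- colSums(ser$energies[1:4, , drop = FALSE])
    expect_equal(names(which.max(first5)), "beta")
    late <- colSums(ser$energies[20:28, , drop = FALSE])
    expect_equal(names(which.max(late)), "theta")
  }
})

test_that("artifact injection is additive, seeded, and class-faithful", {
  cfg <- sim_config(theta_rhythm_uV = 0)
  bg <- simulate_background(120, cfg, seed = 9)

  silent <- artifact_spec(spike_rate_per_min = 0, line_rate_per_min = 0,
                          movement_rate_per_min = 0)
  expect_identical(inject_artifacts(bg, silent, seed = 1)$samples,
                   bg$samples)

  # 60 Hz bursts: the gamma cap at 55 Hz keeps almost all added energy
  # out of the five bands
  lines_only <- artifact_spec(spike_rate_per_min = 0,
                              movement_rate_per_min = 0,
                              line_rate_per_min = 6)
  withl <- inject_artifacts(bg, lines_only, seed = 2)
  expect_gt(max(abs(withl$samples - bg$samples)), 1)  # bursts were added
  s0 <- band_energy_series(bg)
  s1 <- band_energy_series(withl)
  tot <- function(rec) {
    apply(window_partition(rec)$windows, 2,
          function(w) 400 * sum(diff(w)^2))
  }
  added_band <- sum(s1$energies) - sum(s0$energies)
  added_total <- sum(tot(withl)) - sum(tot(bg))
  expect_lt(added_band / added_total, 0.02)
})

test_that("spike counts follow the configured Poisson rate", {
  zero <- recording(rep(0, 1200 * 200), fs = 200)   # 20 min of silence
  spikes_only <- artifact_spec(spike_rate_per_min = 2,
                               line_rate_per_min = 0,
                               movement_rate_per_min = 0)
  out <- get_channel(inject_artifacts(zero, spikes_only, seed = 7))
  # count clusters of excursions above half the minimum spike amplitude;
  # a biphasic spike has two lobes, so merge excursions within 0.3 s
  idx <- which(abs(out) > 0.5 * 0.7 * 300)
  starts <- sum(diff(c(-Inf, idx)) > 0.3 * 200)
  lambda <- 2 * 20
  bounds <- stats::qpois(c(0.005, 0.995), lambda)
  expect_gte(starts, bounds[1])
  expect_lte(starts, bounds[2])
})

test_that("dataset generation is annotated, margin-padded, and deterministic", {
  ds <- small_dataset()
  expect_length(ds$seizures, 12)
  for (s in ds$seizures) {
    dur <- s$annotation$offset_s - s$annotation$onset_s
    expect_gte(dur, 10)
    expect_lte(dur, 60)
    expect_equal(s$annotation$onset_s, 60)
    expect_equal(duration(s$recording), 60 + dur + 60)
  }
  expect_equal(duration(ds$nonseizure), 900)

  ds2 <- simulate_dataset(sim_config(seed = 42, n_seizures = 12,
                                     nonseizure_duration_s = 900))
  expect_identical(ds$seizures[[3]]$recording$samples,
                   ds2$seizures[[3]]$recording$samples)
  expect_identical(ds$nonseizure$samples, ds2$nonseizure$samples)
})

test_that("exported EDF payloads are byte-identical across runs", {
  cfg <- sim_config(seed = 8, n_seizures = 2, nonseizure_duration_s = 120)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  export_dataset(simulate_dataset(cfg), d1)
  export_dataset(simulate_dataset(cfg), d2)
  files <- list.files(d1)
  expect_true(all(c("seizure_001.edf", "seizure_001_annotations.csv",
                    "nonseizure.edf", "manifest.json") %in% files))
  for (f in files) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  }
  # the exported files parse back into the same data
  back <- read_recording(file.path(d1, "seizure_001.edf"))
  expect_equal(back$fs, 200)
  ann <- read_annotations(file.path(d1, "seizure_001_annotations.csv"))
  expect_equal(ann$onset_s, 60)
})
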