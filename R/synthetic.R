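# Synthetic annotated EEG with the statistical structure the detector
# assumes: 1/f background with an intermittent theta rhythm, seizures whose
# first seconds are beta-dominant and whose later phase is theta-dominant
# (on the post-difference-filter energy scale the analysis pipeline sees),
# and the three non-seizure artifact classes (interictal spikes, 60 Hz line
# bursts, slow movement transients).

# frequency axis of an n-point DFT, folded to [0, fs/2]
fft_freqs <- function(n, fs) {
  k <- 0:(n - 1)
  pmin(k, n - k) * fs / n
}

# white noise shaped in the frequency domain by `gain(f)`, unit variance
shaped_noise <- function(n, fs, gain_fun) {
  w <- stats::rnorm(n)
  G <- gain_fun(fft_freqs(n, fs))
  y <- Re(stats::fft(stats::fft(w) * G, inverse = TRUE)) / n
  s <- stats::sd(y)
  if (s == 0) rep(0, n) else y / s
}

# 1/f (power exponent -1) noise; flat below f0 to keep the variance finite
pink_noise <- function(n, fs, f0 = 0.5) {
  shaped_noise(n, fs, function(f) 1 / sqrt(pmax(f, f0)))
}

# random-phase narrowband component: Gaussian spectral bump centred mid-band
narrowband_noise <- function(n, fs, low_hz, high_hz) {
  fc <- (low_hz + high_hz) / 2
  sigma <- (high_hz - low_hz) / 6
  shaped_noise(n, fs, function(f) exp(-0.5 * ((f - fc) / sigma)^2))
}

# gain of the first-difference filter at frequency f
diff_filter_gain <- function(f, fs) 2 * abs(sin(pi * f / fs))

band_centers <- function(bands = eeg_bands()) {
  stats::setNames((bands$low_hz + bands$high_hz) / 2, bands$name)
}

# sub-seeds derived from one root seed (documented substream scheme:
# `n` draws from sample.int under the root seed)
derive_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1, n)
}

#' Seizure morphology profile
#'
#' Describes one synthetic seizure: duration, the length of the onset phase,
#' per-phase band weights, and the amplitude build-up. Weights are expressed
#' on the post-difference-filter energy scale (the scale on which band
#' dominance is described and measured); the synthesizer divides each band's
#' raw amplitude by the difference-filter gain at the band center so that
#' the analysis pipeline sees the stated proportions. Defaults: onset
#' beta-dominant (beta 1.0, alpha 0.6, delta/theta 0.3, gamma 0.2), late
#' phase theta-dominant (theta 1.0, gamma 0.6, alpha 0.4, beta/delta 0.3).
#'
#' @param duration_s Seizure duration, seconds (>= 10 for training
#'   inclusion; >= onset_phase_len_s).
#' @param onset_phase_len_s Length of the onset phase, seconds (default 5).
#' @param onset_weights,late_weights Named 5-vectors of nonnegative band
#'   amplitude weights (post-filter scale).
#' @param ramp_s Onset build-up time, seconds.
#' @param amplitude_uV Base band amplitude (post-filter scale), microvolts
#'   RMS per unit weight.
#' @param sustain_gain Amplitude multiplier reached by the end of the onset
#'   phase and sustained through the late phase (rhythmic build-up).
#' @param transition_s Crossfade length between onset and late weights.
#' @return A `seizure_profile` list.
#' @export
seizure_profile <- function(duration_s = 30, onset_phase_len_s = 5,
                            onset_weights = c(delta = 0.3, theta = 0.3,
                                              alpha = 0.6, beta = 1.0,
                                              gamma = 0.2),
                            late_weights = c(delta = 0.3, theta = 1.0,
                                             alpha = 0.4, beta = 0.3,
                                             gamma = 0.6),
                            ramp_s = 1, amplitude_uV = 25,
                            sustain_gain = 1.5, transition_s = 2) {
  if (duration_s < onset_phase_len_s) {
    stop("`duration_s` must be at least `onset_phase_len_s`")
  }
  if (any(onset_weights < 0) || any(late_weights < 0)) {
    stop("band weights must be nonnegative")
  }
  nm <- band_names()
  stopifnot(all(nm %in% names(onset_weights)), all(nm %in% names(late_weights)))
  structure(
    list(duration_s = duration_s, onset_phase_len_s = onset_phase_len_s,
         onset_weights = onset_weights[nm], late_weights = late_weights[nm],
         ramp_s = ramp_s, amplitude_uV = amplitude_uV,
         sustain_gain = sustain_gain, transition_s = transition_s),
    class = "seizure_profile"
  )
}

#' Artifact specification for non-seizure data
#'
#' Rates are per minute; event times are Poisson. The three classes mirror
#' what contaminates chronic rodent recordings: interictal spikes (brief
#' biphasic transients), 60 Hz line-noise bursts, and large slow movement
#' transients (0.5-3 Hz).
#'
#' @param spike_rate_per_min,spike_width_ms,spike_amplitude_uV Interictal
#'   spike rate, width, and peak amplitude.
#' @param line_rate_per_min,line_duration_s,line_amplitude_uV 60 Hz burst
#'   rate, length, and amplitude.
#' @param movement_rate_per_min,movement_duration_s,movement_amplitude_uV
#'   Movement transient rate, length, and amplitude.
#' @return An `artifact_spec` list.
#' @export
artifact_spec <- function(spike_rate_per_min = 2, spike_width_ms = 60,
                          spike_amplitude_uV = 300,
                          line_rate_per_min = 0.5, line_duration_s = 1,
                          line_amplitude_uV = 50,
                          movement_rate_per_min = 0.5,
                          movement_duration_s = 2,
                          movement_amplitude_uV = 400) {
  spec <- list(spike_rate_per_min = spike_rate_per_min,
               spike_width_ms = spike_width_ms,
               spike_amplitude_uV = spike_amplitude_uV,
               line_rate_per_min = line_rate_per_min,
               line_duration_s = line_duration_s,
               line_amplitude_uV = line_amplitude_uV,
               movement_rate_per_min = movement_rate_per_min,
               movement_duration_s = movement_duration_s,
               movement_amplitude_uV = movement_amplitude_uV)
  if (any(unlist(spec) < 0)) stop("artifact rates/amplitudes must be >= 0")
  structure(spec, class = "artifact_spec")
}

#' Simulation configuration
#'
#' Bundles every knob of the dataset generator. One root `seed` fixes every
#' sample: sub-seeds for each seizure clip, the non-seizure recording, and
#' each artifact stream are drawn from it up front.
#'
#' @param seed Root seed (integer).
#' @param fs Sampling rate, Hz.
#' @param n_seizures Number of peri-ictal clips.
#' @param duration_range_s Seizure durations are drawn uniformly over whole
#'   seconds in this range (the 10 s floor is the training inclusion
#'   criterion).
#' @param pre_s,post_s Peri-ictal margins, seconds.
#' @param nonseizure_duration_s Length of the dedicated non-seizure
#'   recording (default 1.5 h).
#' @param interictal_gap_s Minimum separation between seizures and
#'   non-seizure sampling in the emulated recordings (clips are generated
#'   independently, honoring the gap by construction).
#' @param background_sd_uV 1/f background amplitude.
#' @param white_sd_uV Broadband sensor-noise floor.
#' @param theta_rhythm_uV RMS amplitude of the intermittent background
#'   theta rhythm when active.
#' @param amplitude_jitter_sdlog Per-seizure lognormal amplitude jitter.
#' @param band_jitter_sdlog Per-seizure, per-band lognormal weight jitter
#'   (redrawn when it would break beta dominance of the pooled onset
#'   energies).
#' @param profile Base [seizure_profile()] (its `duration_s` is overridden
#'   per seizure).
#' @param artifacts An [artifact_spec()].
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1, fs = 200, n_seizures = 100,
                       duration_range_s = c(10, 60), pre_s = 60, post_s = 60,
                       nonseizure_duration_s = 5400,
                       interictal_gap_s = 3600,
                       background_sd_uV = 20, white_sd_uV = 3,
                       theta_rhythm_uV = 40,
                       amplitude_jitter_sdlog = 0.15,
                       band_jitter_sdlog = 0.2,
                       profile = seizure_profile(),
                       artifacts = artifact_spec()) {
  if (interictal_gap_s < 3600) {
    stop("`interictal_gap_s` must be at least 3600 s ",
         "(non-seizure data at least 1 h away from seizures)")
  }
  structure(
    list(seed = seed, fs = fs, n_seizures = n_seizures,
         duration_range_s = duration_range_s, pre_s = pre_s, post_s = post_s,
         nonseizure_duration_s = nonseizure_duration_s,
         interictal_gap_s = interictal_gap_s,
         background_sd_uV = background_sd_uV, white_sd_uV = white_sd_uV,
         theta_rhythm_uV = theta_rhythm_uV,
         amplitude_jitter_sdlog = amplitude_jitter_sdlog,
         band_jitter_sdlog = band_jitter_sdlog,
         profile = profile, artifacts = artifacts),
    class = "sim_config"
  )
}

#' Simulate non-seizure background EEG
#'
#' 1/f-shaped noise (power spectral exponent about -1) plus a white noise
#' floor plus an intermittent narrowband theta rhythm whose slow amplitude
#' modulation emulates behavioral state changes. Deterministic per seed.
#'
#' @param duration_s Length, seconds.
#' @param cfg A [sim_config()].
#' @param seed Seed for this stream.
#' @return A single-channel [recording()].
#' @export
simulate_background <- function(duration_s, cfg = sim_config(), seed = 1) {
  if (duration_s <= 0) stop("`duration_s` must be positive")
  set.seed(seed)
  n <- round(duration_s * cfg$fs)
  x <- cfg$background_sd_uV * pink_noise(n, cfg$fs) +
    cfg$white_sd_uV * stats::rnorm(n)
  if (cfg$theta_rhythm_uV > 0) {
    t <- (seq_len(n) - 1) / cfg$fs
    period <- stats::runif(1, 30, 60)
    phase <- stats::runif(1, 0, 2 * pi)
    env <- (0.5 * (1 + sin(2 * pi * t / period + phase)))^2
    x <- x + cfg$theta_rhythm_uV * env *
      narrowband_noise(n, cfg$fs, 5.5, 8)
  }
  recording(x, fs = cfg$fs, channel_labels = "EEG1")
}

seizure_envelopes <- function(profile, fs, n) {
  t <- (seq_len(n) - 1) / fs
  # amplitude build-up: 0 -> 1 over ramp_s (raised cosine), then -> sustain
  # by the end of the onset phase, held through the late phase
  ramp <- ifelse(t >= profile$ramp_s, 1,
                 0.5 * (1 - cos(pi * t / profile$ramp_s)))
  grow <- ifelse(t <= profile$ramp_s, 1,
          ifelse(t >= profile$onset_phase_len_s, profile$sustain_gain,
                 1 + (profile$sustain_gain - 1) *
                   (t - profile$ramp_s) /
                   (profile$onset_phase_len_s - profile$ramp_s)))
  # crossfade of band weights centred on the end of the onset phase
  h <- profile$transition_s / 2
  u <- (t - profile$onset_phase_len_s + h) / profile$transition_s
  cf <- ifelse(u <= 0, 0, ifelse(u >= 1, 1, 0.5 * (1 - cos(pi * u))))
  # short taper at the seizure end
  tail_s <- 0.5
  taper <- ifelse(t > profile$duration_s - tail_s,
                  0.5 * (1 - cos(pi * (profile$duration_s - t) / tail_s)), 1)
  list(gain = ramp * grow * pmax(taper, 0), crossfade = cf)
}

#' Simulate one seizure burst
#'
#' The burst is a sum of five random-phase narrowband components (one per
#' band, centred mid-band) whose amplitude envelopes follow the profile's
#' per-phase weights with a smooth onset ramp, a build-up to the sustained
#' ictal amplitude, and a crossfade from onset to late-phase weights.
#'
#' @param profile A [seizure_profile()].
#' @param fs Sampling rate, Hz.
#' @param seed Seed for this seizure's stream.
#' @return List: `samples` (numeric vector) and `annotation` (one row,
#'   spanning the burst).
#' @export
simulate_seizure <- function(profile, fs = 200, seed = 1) {
  stopifnot(inherits(profile, "seizure_profile"))
  set.seed(seed)
  n <- round(profile$duration_s * fs)
  env <- seizure_envelopes(profile, fs, n)
  bands <- eeg_bands()
  centers <- band_centers(bands)
  x <- numeric(n)
  for (i in seq_len(nrow(bands))) {
    b <- bands$name[i]
    comp <- narrowband_noise(n, fs, bands$low_hz[i], bands$high_hz[i])
    w_t <- profile$onset_weights[b] * (1 - env$crossfade) +
      profile$late_weights[b] * env$crossfade
    amp <- profile$amplitude_uV * w_t * env$gain /
      diff_filter_gain(centers[b], fs)
    x <- x + amp * comp
  }
  list(samples = x,
       annotation = seizure_annotations(0, profile$duration_s))
}

#' Inject artifacts into a recording
#'
#' Adds interictal spikes (biphasic transients), 60 Hz line-noise bursts,
#' and slow high-amplitude movement transients at Poisson event times.
#' The annotations are unchanged: artifacts are part of the non-seizure
#' signal the detector must reject.
#'
#' @param rec A single-channel [recording()].
#' @param spec An [artifact_spec()].
#' @param seed Seed for the artifact stream.
#' @return The recording with artifacts added.
#' @export
inject_artifacts <- function(rec, spec = artifact_spec(), seed = 1) {
  stopifnot(inherits(rec, "eeg_recording"), inherits(spec, "artifact_spec"))
  set.seed(seed)
  fs <- rec$fs
  x <- get_channel(rec, 1)
  n <- length(x)
  dur_min <- n / fs / 60

  add_events <- function(x, rate_per_min, make_shape) {
    k <- stats::rpois(1, rate_per_min * dur_min)
    if (k == 0) return(x)
    centers <- sort(stats::runif(k, 0, n / fs))
    for (tc in centers) {
      shape <- make_shape()
      i0 <- round(tc * fs) - length(shape) %/% 2
      idx <- seq_along(shape) + i0
      keep <- idx >= 1 & idx <= n
      x[idx[keep]] <- x[idx[keep]] + shape[keep]
    }
    x
  }

  # biphasic spike: derivative-of-Gaussian, width = spike_width_ms
  if (spec$spike_rate_per_min > 0) {
    x <- add_events(x, spec$spike_rate_per_min, function() {
      w <- spec$spike_width_ms / 1000
      tt <- seq(-w, w, by = 1 / fs)
      s <- -tt * exp(-0.5 * (tt / (w / 4))^2)
      s / max(abs(s)) * spec$spike_amplitude_uV * stats::runif(1, 0.7, 1.3)
    })
  }
  # 60 Hz burst under a Hann envelope
  if (spec$line_rate_per_min > 0) {
    x <- add_events(x, spec$line_rate_per_min, function() {
      m <- round(spec$line_duration_s * fs)
      tt <- (seq_len(m) - 1) / fs
      hann <- 0.5 * (1 - cos(2 * pi * seq_len(m) / (m + 1)))
      spec$line_amplitude_uV * sqrt(2) *
        sin(2 * pi * 60 * tt + stats::runif(1, 0, 2 * pi)) * hann
    })
  }
  # slow movement transient, random frequency 0.5-3 Hz
  if (spec$movement_rate_per_min > 0) {
    x <- add_events(x, spec$movement_rate_per_min, function() {
      m <- round(spec$movement_duration_s * fs)
      tt <- (seq_len(m) - 1) / fs
      f <- stats::runif(1, 0.5, 3)
      hann <- 0.5 * (1 - cos(2 * pi * seq_len(m) / (m + 1)))
      spec$movement_amplitude_uV *
        sin(2 * pi * f * tt + stats::runif(1, 0, 2 * pi)) * hann
    })
  }
  recording(x, fs = fs, channel_labels = rec$channel_labels,
            start_time_s = rec$start_time_s)
}

# per-seizure jitters; redrawn until beta keeps its pooled onset-energy
# dominance (post-filter scale), which the feature contrast relies on
draw_band_jitter <- function(onset_weights, sdlog, max_tries = 100) {
  nm <- names(onset_weights)
  for (i in seq_len(max_tries)) {
    j <- stats::setNames(stats::rlnorm(length(nm), 0, sdlog), nm)
    energies <- (onset_weights * j)^2
    if (names(which.max(energies)) == "beta") return(j)
  }
  stats::setNames(rep(1, length(nm)), nm)
}

#' Simulate a full annotated dataset
#'
#' `n_seizures` peri-ictal clips (background + seizure burst + artifacts,
#' 60 s margins on both sides) plus one dedicated non-seizure recording
#' (default 1.5 h) with the same background statistics and artifacts.
#' Deterministic per the root seed. Per-seizure realism: the overall ictal
#' amplitude and each band weight carry lognormal jitter, so the
#' second-moment matrix is full rank and seizures differ in composition
#' while every onset stays beta-dominant.
#'
#' @param cfg A [sim_config()].
#' @return An `annotated_dataset`: `seizures` (list of
#'   `list(recording, annotation, split)`), `nonseizure` recording, `config`.
#' @export
simulate_dataset <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  seeds <- derive_seeds(cfg$seed, 4 * cfg$n_seizures + 3)
  set.seed(seeds[1])
  durations <- sample(seq(cfg$duration_range_s[1], cfg$duration_range_s[2]),
                      cfg$n_seizures, replace = TRUE)
  set.seed(seeds[2])
  amp_jit <- stats::rlnorm(cfg$n_seizures, 0, cfg$amplitude_jitter_sdlog)

  seizures <- vector("list", cfg$n_seizures)
  for (i in seq_len(cfg$n_seizures)) {
    s_bg <- seeds[3 + (i - 1) * 4 + 1]
    s_sz <- seeds[3 + (i - 1) * 4 + 2]
    s_ar <- seeds[3 + (i - 1) * 4 + 3]
    s_jt <- seeds[3 + (i - 1) * 4 + 4]
    set.seed(s_jt)
    jit <- draw_band_jitter(cfg$profile$onset_weights, cfg$band_jitter_sdlog)
    prof <- cfg$profile
    prof$duration_s <- durations[i]
    prof$amplitude_uV <- prof$amplitude_uV * amp_jit[i]
    prof$onset_weights <- prof$onset_weights * jit
    prof$late_weights <- prof$late_weights * jit
    clip_len <- cfg$pre_s + durations[i] + cfg$post_s
    bg <- simulate_background(clip_len, cfg, seed = s_bg)
    burst <- simulate_seizure(prof, fs = cfg$fs, seed = s_sz)
    x <- get_channel(bg, 1)
    i0 <- round(cfg$pre_s * cfg$fs)
    x[i0 + seq_along(burst$samples)] <- x[i0 + seq_along(burst$samples)] +
      burst$samples
    rec <- inject_artifacts(
      recording(x, fs = cfg$fs, channel_labels = "EEG1"),
      cfg$artifacts, seed = s_ar)
    seizures[[i]] <- list(
      recording = rec,
      annotation = seizure_annotations(cfg$pre_s, cfg$pre_s + durations[i]),
      split = "none"
    )
  }
  ns <- simulate_background(cfg$nonseizure_duration_s, cfg,
                            seed = seeds[3])
  ns <- inject_artifacts(ns, cfg$artifacts,
                         seed = seeds[3 + 4 * cfg$n_seizures])
  structure(
    list(seizures = seizures, nonseizure = ns, config = cfg),
    class = "annotated_dataset"
  )
}

#' @export
print.annotated_dataset <- function(x, ...) {
  cat(sprintf("<annotated_dataset> %d seizure clips + %.1f h non-seizure @ %g Hz\n",
              length(x$seizures), duration(x$nonseizure) / 3600,
              x$config$fs))
  invisible(x)
}

#' Export a dataset as EDF + annotation CSV files
#'
#' Writes `seizure_###.edf` with `seizure_###_annotations.csv` sidecars,
#' `nonseizure.edf`, and `manifest.json` (seed, config hash). Byte-identical
#' across runs with the same configuration.
#'
#' @param dataset An `annotated_dataset`.
#' @param dir Output directory (created if needed).
#' @param physical_range EDF physical scale, microvolts.
#' @return `dir`, invisibly.
#' @export
export_dataset <- function(dataset, dir, physical_range = 4000) {
  stopifnot(inherits(dataset, "annotated_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(dataset$seizures)) {
    s <- dataset$seizures[[i]]
    base <- file.path(dir, sprintf("seizure_%03d", i))
    write_recording(s$recording, paste0(base, ".edf"),
                    physical_range = physical_range)
    write_annotations(s$annotation, paste0(base, "_annotations.csv"))
  }
  write_recording(dataset$nonseizure, file.path(dir, "nonseizure.edf"),
                  physical_range = physical_range)
  jsonlite::write_json(
    list(seed = dataset$config$seed,
         n_seizures = length(dataset$seizures),
         config_hash = config_hash(dataset$config)),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(dir)
}

# md5 of the deparsed configuration (deterministic provenance tag)
config_hash <- function(cfg) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(cfg), f)
  unname(tools::md5sum(f))
}
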