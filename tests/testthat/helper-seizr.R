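# Shared fixtures and independent oracles. Everything is generated in code;
# the heavier simulated datasets are cached per session.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# small annotated dataset for unit tests (12 clips, 15 min non-seizure)
small_dataset <- function() {
  cached("small_dataset", simulate_dataset(
    sim_config(seed = 42, n_seizures = 12, nonseizure_duration_s = 900)))
}

# full study-sized dataset (100 clips, 1.5 h non-seizure) for the
# acceptance-grade end-to-end checks
default_dataset <- function() {
  cached("default_dataset", simulate_dataset(sim_config(seed = 1)))
}

default_report <- function() {
  cached("default_report",
         run_comparison(split_train_test(default_dataset(), seed = 1,
                                         fraction = 0.5),
                        experiment_config(split_seed = 1)))
}

sine_recording <- function(freq_hz, duration_s = 10, fs = 200, amp = 1) {
  t <- seq(0, duration_s - 1 / fs, by = 1 / fs)
  recording(amp * sin(2 * pi * freq_hz * t), fs = fs)
}

# direct O(N^2) DFT-summation oracle for band energies (independent of fft)
band_energy_oracle <- function(window, fs, bands = eeg_bands()) {
  d <- diff(window)
  N <- length(window)
  d <- c(d, rep(0, N - length(d)))
  n <- 0:(N - 1)
  X <- vapply(0:(N %/% 2), function(k) {
    sum(d * exp(-2i * pi * k * n / N))
  }, complex(1))
  f <- (0:(N %/% 2)) * fs / N
  p <- Mod(X)^2
  e <- vapply(seq_len(nrow(bands)), function(i) {
    if (i == nrow(bands)) {
      sum(p[f >= bands$low_hz[i] & f <= bands$high_hz[i]])
    } else {
      sum(p[f >= bands$low_hz[i] & f < bands$high_hz[i]])
    }
  }, 0)
  names(e) <- bands$name
  e
}

# iterative oracle for the dominant eigenpair of a symmetric PSD matrix:
# power-iteration warm-up, then Rayleigh-quotient iteration (cubic
# convergence, robust to small eigengaps); independent of eigen()
power_iteration_oracle <- function(C, iters = 10000) {
  p <- ncol(C)
  v <- rep(1 / sqrt(p), p)
  for (i in seq_len(min(iters, 500))) {
    w <- as.numeric(C %*% v)
    nw <- sqrt(sum(w^2))
    if (nw == 0) return(list(e = v, lambda = 0))
    v <- w / nw
  }
  for (i in 1:25) {
    mu <- as.numeric(t(v) %*% C %*% v)
    w <- tryCatch(solve(C - mu * diag(p), v), error = function(e) NULL)
    if (is.null(w)) break                      # singular shift: converged
    v <- as.numeric(w) / sqrt(sum(w^2))
    if (sqrt(sum((C %*% v - mu * v)^2)) <= 1e-14 * max(abs(C))) break
  }
  if (v[which.max(abs(v))] < 0) v <- -v
  list(e = v, lambda = as.numeric(t(v) %*% C %*% v))
}

random_psd <- function(p = 5) {
  A <- matrix(stats::rnorm(p * p), p)
  crossprod(A)
}

# axis angle between two directions; the chord/asin form stays accurate for
# tiny angles where acos of the dot product hits its precision floor
angle_deg <- function(a, b) {
  a <- a / sqrt(sum(a^2))
  b <- b / sqrt(sum(b^2))
  if (sum(a * b) < 0) b <- -b
  2 * asin(min(1, sqrt(sum((a - b)^2)) / 2)) * 180 / pi
}

make_signal <- function(values, start_s = seq_along(values) - 1,
                        window_len_s = 1, name = "u") {
  structure(list(values = values, window_start_s = start_s,
                 window_len_s = window_len_s, feature_name = name),
            class = "feature_signal")
}
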