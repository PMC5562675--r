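#' Default EEG subband definitions
#'
#' The five conventional EEG bands as used throughout the package:
#' delta 1-4, theta 4-8, alpha 8-13, beta 13-25, gamma 25-55 Hz. Frequencies
#' below 1 Hz are excluded (offset/drift noise) and the gamma band stops at
#' 55 Hz to keep 60 Hz line interference out. Band membership is lower-edge
#' inclusive, upper-edge exclusive, except that 55 Hz itself belongs to gamma.
#'
#' @return A data frame with columns `name`, `low_hz`, `high_hz`.
#' @export
eeg_bands <- function() {
  data.frame(
    name = c("delta", "theta", "alpha", "beta", "gamma"),
    low_hz = c(1, 4, 8, 13, 25),
    high_hz = c(4, 8, 13, 25, 55),
    stringsAsFactors = FALSE
  )
}

band_names <- function(bands = eeg_bands()) bands$name

check_bands <- function(bands) {
  stopifnot(is.data.frame(bands),
            all(c("name", "low_hz", "high_hz") %in% names(bands)))
  if (any(bands$high_hz <= bands$low_hz)) stop("band edges must increase")
  if (nrow(bands) > 1 &&
      any(bands$low_hz[-1] < bands$high_hz[-nrow(bands)])) {
    stop("bands must be disjoint and ordered")
  }
  bands
}

#' First-difference filter
#'
#' `y(n) = x(n + 1) - x(n)`. EEG magnitude falls roughly as 1/f; the
#' difference filter (gain `2 sin(pi f / fs)`, rising with frequency)
#' counteracts that tilt before the spectral decomposition.
#'
#' @param x Numeric vector, length >= 2.
#' @return Numeric vector of length `length(x) - 1`.
#' @export
difference_filter <- function(x) {
  if (length(x) < 2) stop("difference filter needs at least 2 samples")
  diff(x)
}

#' Partition a recording into analysis windows
#'
#' Windows of `window_len_s` seconds spaced `hop_s` apart (defaults 2 s and
#' 1 s, i.e. 50% overlap). A trailing partial window is discarded. Window
#' timing is 0-based and half-open: a window starting at `t` covers
#' `[t, t + window_len_s)`.
#'
#' @param rec An [recording()] or a numeric vector (then `fs` is required).
#' @param window_len_s,hop_s Window length and hop, seconds.
#' @param channel Channel selection for multi-channel recordings.
#' @param fs Sampling rate when `rec` is a bare vector.
#' @return List with `windows` (samples x W matrix), `start_s`, and the
#'   window parameters.
#' @export
window_partition <- function(rec, window_len_s = 2, hop_s = 1,
                             channel = NULL, fs = NULL) {
  if (hop_s <= 0) stop("`hop_s` must be positive")
  if (window_len_s <= 0) stop("`window_len_s` must be positive")
  if (inherits(rec, "eeg_recording")) {
    x <- get_channel(rec, channel)
    fs <- rec$fs
    t0 <- rec$start_time_s
  } else {
    if (is.null(fs)) stop("`fs` is required for bare numeric input")
    x <- as.numeric(rec)
    t0 <- 0
  }
  n_win <- round(fs * window_len_s)
  n_hop <- round(fs * hop_s)
  n <- length(x)
  if (n < n_win) {
    return(list(windows = matrix(numeric(), nrow = n_win, ncol = 0),
                start_s = numeric(), window_len_s = window_len_s,
                hop_s = hop_s, fs = fs))
  }
  W <- (n - n_win) %/% n_hop + 1
  starts <- (seq_len(W) - 1) * n_hop
  idx <- outer(seq_len(n_win), starts, `+`)
  list(windows = matrix(x[idx], nrow = n_win, ncol = W),
       start_s = t0 + starts / fs,
       window_len_s = window_len_s, hop_s = hop_s, fs = fs)
}

#' Subband energies of one analysis window
#'
#' The raw window is difference-filtered, zero-padded back to `n_fft` points
#' (default: the original window length, keeping the bin spacing at
#' `fs / N`), transformed with an unnormalized forward DFT, and `|X[k]|^2`
#' is summed over the one-sided bins falling in each band. No taper is
#' applied.
#'
#' @param window Numeric vector of raw samples (e.g. 400 at the defaults).
#' @param fs Sampling rate, Hz.
#' @param bands Band definition table, see [eeg_bands()].
#' @param n_fft DFT length; defaults to `length(window)`.
#' @return Named numeric vector of five nonnegative energies.
#' @export
band_energy <- function(window, fs, bands = eeg_bands(),
                        n_fft = length(window)) {
  bands <- check_bands(bands)
  df <- fs / n_fft
  if (df > min(bands$high_hz - bands$low_hz)) {
    stop("frequency resolution ", df, " Hz is coarser than the narrowest ",
         "band; use a longer window")
  }
  d <- difference_filter(window)
  d <- c(d, rep(0, n_fft - length(d)))
  X <- stats::fft(d)
  k <- 0:(n_fft %/% 2)               # one-sided bins
  f <- k * df
  p <- Mod(X[k + 1])^2
  e <- vapply(seq_len(nrow(bands)), function(i) {
    hi_inclusive <- i == nrow(bands)  # 55 Hz itself stays in gamma
    sel <- if (hi_inclusive) f >= bands$low_hz[i] & f <= bands$high_hz[i]
           else f >= bands$low_hz[i] & f < bands$high_hz[i]
    sum(p[sel])
  }, 0)
  names(e) <- bands$name
  e
}

#' Subband energy series of a recording
#'
#' Applies [band_energy()] to every window of the default 2 s / 1 s-hop
#' partition, yielding the per-window five-component energy vectors that all
#' downstream features are built from.
#'
#' @inheritParams window_partition
#' @param bands Band definition table.
#' @return A `band_energy_series` object: `energies` (W x 5 matrix),
#'   `window_start_s`, window parameters, `fs`, `bands`.
#' @export
band_energy_series <- function(rec, channel = NULL, window_len_s = 2,
                               hop_s = 1, bands = eeg_bands(), fs = NULL) {
  wp <- window_partition(rec, window_len_s = window_len_s, hop_s = hop_s,
                         channel = channel, fs = fs)
  W <- ncol(wp$windows)
  energies <- matrix(0, nrow = W, ncol = nrow(bands),
                     dimnames = list(NULL, bands$name))
  for (i in seq_len(W)) {
    energies[i, ] <- band_energy(wp$windows[, i], fs = wp$fs, bands = bands)
  }
  structure(
    list(energies = energies, window_start_s = wp$start_s,
         window_len_s = window_len_s, hop_s = hop_s, fs = wp$fs,
         bands = bands),
    class = "band_energy_series"
  )
}

#' @export
print.band_energy_series <- function(x, ...) {
  cat(sprintf("<band_energy_series> %d windows of %g s (hop %g s) @ %g Hz\n",
              nrow(x$energies), x$window_len_s, x$hop_s, x$fs))
  invisible(x)
}

#' @export
as.data.frame.band_energy_series <- function(x, ...) {
  cbind(data.frame(window_start_s = x$window_start_s),
        as.data.frame(x$energies))
}

#' Keep a subset of windows of a band-energy series
#' @param series A `band_energy_series`.
#' @param idx Integer or logical window indices.
#' @return A `band_energy_series` restricted to `idx`.
#' @export
subset_series <- function(series, idx) {
  stopifnot(inherits(series, "band_energy_series"))
  series$energies <- series$energies[idx, , drop = FALSE]
  series$window_start_s <- series$window_start_s[idx]
  series
}

#' Export / import a band-energy series as CSV
#'
#' Columns: `window_start_s`, `delta`, `theta`, `alpha`, `beta`, `gamma`.
#' @param series A `band_energy_series`.
#' @param path CSV path.
#' @export
write_band_series <- function(series, path) {
  utils::write.csv(as.data.frame(series), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_band_series
#' @param window_len_s,hop_s,fs Window metadata (not stored in the CSV).
#' @export
read_band_series <- function(path, window_len_s = 2, hop_s = 1, fs = 200) {
  df <- utils::read.csv(path)
  bands <- eeg_bands()
  structure(
    list(energies = as.matrix(df[, bands$name, drop = FALSE]),
         window_start_s = df$window_start_s,
         window_len_s = window_len_s, hop_s = hop_s, fs = fs, bands = bands),
    class = "band_energy_series"
  )
}
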