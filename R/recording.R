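#' Construct an EEG recording
#'
#' A recording holds one or more equally long sampled channels (in microvolts),
#' the sampling rate, channel labels, and the time (in seconds) of the first
#' sample. All analysis in this package operates on a single channel at a
#' time; multi-channel recordings require an explicit channel selection.
#'
#' @param samples Numeric vector (single channel) or matrix with one column
#'   per channel, in microvolts.
#' @param fs Sampling rate in Hz (default 200, the rate assumed throughout
#'   for simulated data).
#' @param channel_labels Character vector of channel names; defaults to
#'   `"EEG1"`, `"EEG2"`, ...
#' @param start_time_s Time offset of the first sample, seconds.
#'
#' @return An object of class `eeg_recording`.
#' @export
#' @examples
#' rec <- recording(sin(2 * pi * 10 * seq(0, 2, by = 1 / 200)), fs = 200)
#' duration(rec)
recording <- function(samples, fs = 200, channel_labels = NULL,
                      start_time_s = 0) {
  if (is.vector(samples)) samples <- matrix(as.numeric(samples), ncol = 1)
  if (!is.matrix(samples)) stop("`samples` must be a vector or matrix")
  storage.mode(samples) <- "double"
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0) {
    stop("`fs` must be a single positive number")
  }
  if (is.null(channel_labels)) {
    channel_labels <- paste0("EEG", seq_len(ncol(samples)))
  }
  if (length(channel_labels) != ncol(samples)) {
    stop("one channel label per column is required")
  }
  structure(
    list(samples = samples, fs = fs,
         channel_labels = as.character(channel_labels),
         start_time_s = as.numeric(start_time_s)),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channel(s) x %d samples @ %g Hz (%.2f s, t0 = %g s)\n",
              ncol(x$samples), nrow(x$samples), x$fs, duration(x),
              x$start_time_s))
  cat("  channels:", paste(x$channel_labels, collapse = ", "), "\n")
  invisible(x)
}

#' Recording duration in seconds
#' @param rec An `eeg_recording`.
#' @return Duration in seconds (`n_samples / fs`).
#' @export
duration <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  nrow(rec$samples) / rec$fs
}

#' Extract one channel as a numeric vector
#'
#' @param rec An `eeg_recording`.
#' @param channel Channel index or label. Required (no default) when the
#'   recording has more than one channel.
#' @return Numeric vector of samples.
#' @export
get_channel <- function(rec, channel = NULL) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (is.null(channel)) {
    if (ncol(rec$samples) > 1) {
      stop("recording has ", ncol(rec$samples),
           " channels; select one explicitly with `channel`")
    }
    channel <- 1L
  }
  if (is.character(channel)) {
    idx <- match(channel, rec$channel_labels)
    if (is.na(idx)) stop("no channel labelled '", channel, "'")
    channel <- idx
  }
  rec$samples[, channel]
}

#' Construct seizure annotations
#'
#' Annotations mark seizure spans in recording time. They are kept as a plain
#' data frame with columns `onset_s`, `offset_s`, `label`, sorted by onset.
#' Overlapping seizures are rejected.
#'
#' @param onset_s,offset_s Numeric vectors of onset/offset times in seconds.
#' @param label Optional character vector of labels (recycled).
#' @return A data frame of annotations sorted by `onset_s`.
#' @export
seizure_annotations <- function(onset_s = numeric(), offset_s = numeric(),
                                label = "seizure") {
  if (length(onset_s) != length(offset_s)) {
    stop("`onset_s` and `offset_s` must have equal length")
  }
  ann <- data.frame(onset_s = as.numeric(onset_s),
                    offset_s = as.numeric(offset_s),
                    label = if (length(onset_s)) {
                      rep_len(as.character(label), length(onset_s))
                    } else character(),
                    stringsAsFactors = FALSE)
  validate_annotations(ann)
}

validate_annotations <- function(ann) {
  required <- c("onset_s", "offset_s", "label")
  if (!all(required %in% names(ann))) {
    stop("annotations need columns ", paste(required, collapse = ", "))
  }
  bad <- which(ann$offset_s <= ann$onset_s)
  if (length(bad)) {
    stop("annotation row ", bad[1], ": offset_s (", ann$offset_s[bad[1]],
         ") must exceed onset_s (", ann$onset_s[bad[1]], ")")
  }
  ann <- ann[order(ann$onset_s), , drop = FALSE]
  rownames(ann) <- NULL
  if (nrow(ann) > 1) {
    ov <- which(ann$onset_s[-1] < ann$offset_s[-nrow(ann)])
    if (length(ov)) {
      stop("annotations overlap: row ", ov[1], " (offset ",
           ann$offset_s[ov[1]], " s) and row ", ov[1] + 1, " (onset ",
           ann$onset_s[ov[1] + 1], " s)")
    }
  }
  ann
}

#' Clip the peri-ictal segment around one seizure
#'
#' Extracts the segment from `pre_s` seconds before the annotated onset until
#' `post_s` seconds after the annotated offset (default 60 s on each side),
#' clamped to the recording bounds. The annotation is re-expressed in
#' clip-local time.
#'
#' @param rec An `eeg_recording`.
#' @param ann A one-row annotation data frame (or a row of one).
#' @param pre_s,post_s Margins in seconds before onset / after offset.
#' @return A list with elements `recording` (the clip, `start_time_s = 0`)
#'   and `annotation` (one-row data frame in clip-local seconds).
#' @export
clip_peri_ictal <- function(rec, ann, pre_s = 60, post_s = 60) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (is.data.frame(ann)) {
    if (nrow(ann) != 1) stop("`ann` must be a single annotation row")
    onset <- ann$onset_s
    offset <- ann$offset_s
    label <- ann$label
  } else {
    stop("`ann` must be a one-row annotation data frame")
  }
  t0 <- rec$start_time_s
  t1 <- t0 + duration(rec)
  if (onset < t0 || offset > t1) {
    stop("annotation [", onset, ", ", offset, "] s lies outside recording [",
         t0, ", ", t1, "] s")
  }
  lo <- max(onset - pre_s, t0)
  hi <- min(offset + post_s, t1)
  # seconds -> sample indices: floor for the start (visual onset precision)
  i0 <- floor((lo - t0) * rec$fs) + 1
  i1 <- floor((hi - t0) * rec$fs)
  i1 <- min(i1, nrow(rec$samples))
  clip <- recording(rec$samples[i0:i1, , drop = FALSE], fs = rec$fs,
                    channel_labels = rec$channel_labels, start_time_s = 0)
  local_ann <- data.frame(onset_s = onset - lo, offset_s = offset - lo,
                          label = label, stringsAsFactors = FALSE)
  list(recording = clip, annotation = local_ann)
}
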