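# Minimal EDF (European Data Format) codec: fixed 256-byte ASCII header,
# one 256-byte signal header per channel, data records of 16-bit little-endian
# integers. Physical values are mapped linearly onto the digital range.
# Only continuous, equal-rate signals are supported, which is all this
# package produces.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = width, flag = "-")
}

# choose a data-record layout: 1 s records when the sample count divides
# evenly, otherwise a single record holding everything (fractional record
# duration, permitted by the format's ASCII duration field)
edf_record_layout <- function(n_samples, fs) {
  if (n_samples %% fs == 0) {
    list(n_records = n_samples %/% fs, samples_per_record = fs,
         record_duration_s = 1)
  } else {
    list(n_records = 1L, samples_per_record = n_samples,
         record_duration_s = n_samples / fs)
  }
}

write_edf <- function(rec, path, physical_range = 1000) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (!all(is.finite(rec$samples))) {
    stop("cannot write EDF: recording contains non-finite samples")
  }
  if (max(abs(rec$samples)) > physical_range) {
    stop("samples exceed the EDF physical range of +/-", physical_range,
         " uV; increase `physical_range`")
  }
  ns <- ncol(rec$samples)
  n <- nrow(rec$samples)
  lay <- edf_record_layout(n, rec$fs)
  dig_max <- 32767L

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8),                             # version
    edf_pad("X X X X", 80),                      # patient id (anonymous)
    edf_pad("Startdate X X X X", 80),            # recording id
    edf_pad("01.01.00", 8),                      # start date
    edf_pad("00.00.00", 8),                      # start time
    edf_pad(256 * (1 + ns), 8),                  # header bytes
    edf_pad("", 44),                             # reserved
    edf_pad(lay$n_records, 8),
    edf_pad(format(lay$record_duration_s, digits = 7), 8),
    edf_pad(ns, 4)
  )
  sig <- paste0(
    paste(vapply(rec$channel_labels, edf_pad, "", width = 16), collapse = ""),
    paste(rep(edf_pad("AgAgCl electrode", 80), ns), collapse = ""),
    paste(rep(edf_pad("uV", 8), ns), collapse = ""),
    paste(rep(edf_pad(-physical_range, 8), ns), collapse = ""),
    paste(rep(edf_pad(physical_range, 8), ns), collapse = ""),
    paste(rep(edf_pad(-dig_max, 8), ns), collapse = ""),
    paste(rep(edf_pad(dig_max, 8), ns), collapse = ""),
    paste(rep(edf_pad("", 80), ns), collapse = ""),   # prefilter
    paste(rep(edf_pad(lay$samples_per_record, 8), ns), collapse = ""),
    paste(rep(edf_pad("", 32), ns), collapse = "")    # reserved
  )
  writeChar(paste0(hdr, sig), con, eos = NULL)

  scale <- dig_max / physical_range
  digital <- round(rec$samples * scale)
  storage.mode(digital) <- "integer"
  for (r in seq_len(lay$n_records)) {
    rows <- ((r - 1) * lay$samples_per_record + 1):(r * lay$samples_per_record)
    # channel-sequential within each record
    writeBin(as.integer(digital[rows, ]), con, size = 2, endian = "little")
  }
  invisible(path)
}

read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) {
    trimws(readChar(con, width, useBytes = TRUE))
  }
  rd(8); rd(80); rd(80); rd(8); rd(8)
  header_bytes <- as.integer(rd(8))
  rd(44)
  n_records <- as.integer(rd(8))
  record_duration <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1) stop("malformed EDF header in '", path,
                                "': bad signal count at byte 252")
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  for (i in seq_len(ns)) rd(80)                      # transducer
  for (i in seq_len(ns)) rd(8)                       # physical dim
  phys_min <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  phys_max <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  dig_min <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  dig_max <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  for (i in seq_len(ns)) rd(80)                      # prefilter
  spr <- vapply(seq_len(ns), function(i) as.integer(rd(8)), 0L)
  for (i in seq_len(ns)) rd(32)                      # reserved
  if (length(unique(spr)) != 1) {
    stop("EDF '", path, "': differing per-signal rates are not supported")
  }
  seek(con, header_bytes)
  total <- n_records * sum(spr)
  raw16 <- readBin(con, "integer", n = total, size = 2, signed = TRUE,
                   endian = "little")
  if (length(raw16) != total) {
    stop("malformed EDF '", path, "': expected ", total,
         " samples after byte ", header_bytes, ", got ", length(raw16))
  }
  samples <- matrix(0, nrow = n_records * spr[1], ncol = ns)
  pos <- 0
  for (r in seq_len(n_records)) {
    for (s in seq_len(ns)) {
      rows <- ((r - 1) * spr[1] + 1):(r * spr[1])
      samples[rows, s] <- raw16[(pos + 1):(pos + spr[s])]
      pos <- pos + spr[s]
    }
  }
  for (s in seq_len(ns)) {
    gain <- (phys_max[s] - phys_min[s]) / (dig_max[s] - dig_min[s])
    samples[, s] <- phys_min[s] + (samples[, s] - dig_min[s]) * gain
  }
  fs <- spr[1] / record_duration
  recording(samples, fs = fs, channel_labels = labels, start_time_s = 0)
}
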