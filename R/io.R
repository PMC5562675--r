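#' Read an EEG recording from EDF or CSV
#'
#' The CSV dialect is one header row; column 1 is either a time column in
#' seconds (named `time` or `time_s`, from which the sampling rate is
#' inferred) or a bare sample index, in which case `fs` must be supplied;
#' remaining columns are channels in microvolts. EDF files carry their rate
#' and labels in the header.
#'
#' @param path File path.
#' @param format `"edf"`, `"csv"`, or `"auto"` (by file extension).
#' @param fs Sampling rate override, required for index-style CSV files.
#' @return An [recording()] object.
#' @export
read_recording <- function(path, format = c("auto", "edf", "csv"), fs = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: '", path, "'")
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     edf = "edf", csv = "csv",
                     stop("cannot guess format of '", path,
                          "'; pass `format` explicitly"))
  }
  if (format == "edf") return(read_edf(path))
  df <- utils::read.csv(path, check.names = FALSE)
  if (ncol(df) < 2) {
    stop("CSV recording '", path,
         "' needs a time/index column plus at least one channel column")
  }
  first <- names(df)[1]
  if (tolower(first) %in% c("time", "time_s", "t")) {
    tcol <- df[[1]]
    if (nrow(df) < 2) stop("CSV recording '", path, "' has fewer than 2 rows")
    dt <- stats::median(diff(tcol))
    fs_inferred <- 1 / dt
    if (!is.null(fs) && abs(fs - fs_inferred) > 1e-6 * fs) {
      stop("`fs` (", fs, ") disagrees with the time column (", fs_inferred, ")")
    }
    fs <- fs_inferred
    start_time_s <- tcol[1]
  } else {
    if (is.null(fs)) {
      stop("CSV '", path, "' has an index column and no time column; ",
           "the sampling rate is unknown - pass `fs` (CLI: --fs)")
    }
    start_time_s <- 0
  }
  recording(as.matrix(df[, -1, drop = FALSE]), fs = fs,
            channel_labels = names(df)[-1], start_time_s = start_time_s)
}

#' Write an EEG recording to EDF or CSV
#'
#' EDF output uses 16-bit samples over a symmetric physical range (default
#' +/-1000 uV, comfortable headroom for rodent epidural EEG), so values
#' round-trip to within `physical_range / 2^15`. CSV output is exact.
#'
#' @param rec An [recording()] object.
#' @param path Output path.
#' @param format `"edf"`, `"csv"`, or `"auto"` (by extension).
#' @param physical_range EDF physical scale in microvolts.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, format = c("auto", "edf", "csv"),
                            physical_range = 1000) {
  stopifnot(inherits(rec, "eeg_recording"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     edf = "edf", csv = "csv",
                     stop("cannot guess format of '", path,
                          "'; pass `format` explicitly"))
  }
  if (!all(is.finite(rec$samples))) {
    stop("recording contains non-finite samples")
  }
  if (format == "edf") {
    write_edf(rec, path, physical_range = physical_range)
  } else {
    t <- rec$start_time_s + (seq_len(nrow(rec$samples)) - 1) / rec$fs
    df <- data.frame(time_s = t)
    for (j in seq_len(ncol(rec$samples))) df[[rec$channel_labels[j]]] <-
        rec$samples[, j]
    utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}

#' Read / write seizure annotations
#'
#' Annotation sidecars are CSV files with columns `onset_s`, `offset_s`,
#' `label`. Reading sorts by onset and rejects overlapping or inverted rows.
#'
#' @param path CSV file path.
#' @return `read_annotations`: a data frame of annotations (possibly empty).
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("file not found: '", path, "'")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("onset_s", "offset_s") %in% names(df))) {
    stop("annotation CSV '", path, "' needs columns onset_s, offset_s, label")
  }
  if (is.null(df$label)) df$label <- "seizure"
  validate_annotations(df[, c("onset_s", "offset_s", "label")])
}

#' @rdname read_annotations
#' @param ann Annotation data frame.
#' @export
write_annotations <- function(ann, path) {
  ann <- validate_annotations(ann)
  utils::write.csv(ann, path, row.names = FALSE)
  invisible(path)
}
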