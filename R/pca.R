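#' Select seizure windows for eigenfeature training
#'
#' Returns the indices of the analysis windows that lie entirely inside the
#' chosen training segment of one seizure: either the initial
#' `initial_len_s` seconds after the annotated onset (`mode = "initial"`,
#' default 5 s, i.e. 4 windows at the 2 s / 1 s defaults) or the whole
#' seizure span (`mode = "whole"`). Partial windows are dropped.
#'
#' @param series A [band_energy_series()].
#' @param onset_s,offset_s Seizure bounds in the series' time base, seconds.
#' @param mode `"initial"` or `"whole"`.
#' @param initial_len_s Length of the initial segment, seconds.
#' @return Integer vector of window indices.
#' @export
select_segment_windows <- function(series, onset_s, offset_s,
                                   mode = c("initial", "whole"),
                                   initial_len_s = 5) {
  stopifnot(inherits(series, "band_energy_series"))
  mode <- match.arg(mode)
  if (offset_s - onset_s < series$window_len_s) {
    stop("seizure of ", offset_s - onset_s,
         " s is shorter than one analysis window")
  }
  starts <- series$window_start_s
  ends <- starts + series$window_len_s
  hi <- if (mode == "initial") onset_s + initial_len_s else offset_s
  idx <- which(starts >= onset_s - 1e-9 & ends <= hi + 1e-9)
  if (!length(idx)) {
    stop("no complete window inside [", onset_s, ", ", hi, "] s")
  }
  idx
}

#' Pooled second-moment matrix of subband-energy vectors
#'
#' Accumulates `C = (1/N) * sum_n X_n X_n^T` over all contributing windows,
#' pooled across seizures (a single sum, not a mean of per-seizure
#' matrices). The energy vectors are not mean-centered by default: the
#' dominant eigenvector of the raw second moment is the principal direction
#' of the ictal energy itself. Set `center = TRUE` for a conventional
#' covariance (sensitivity studies only).
#'
#' @param x A W x 5 energy matrix, a `band_energy_series`, or a list of
#'   either (rows are pooled).
#' @param center Subtract the pooled mean first? Default `FALSE`.
#' @return A list with `C` (5 x 5 symmetric PSD matrix) and `n` (window
#'   count), class `second_moment`.
#' @export
accumulate_second_moment <- function(x, center = FALSE) {
  as_mat <- function(z) {
    if (inherits(z, "band_energy_series")) z$energies
    else if (is.matrix(z)) z
    else matrix(as.numeric(z), nrow = 1)
  }
  X <- if (is.list(x) && !inherits(x, "band_energy_series")) {
    do.call(rbind, lapply(x, as_mat))
  } else {
    as_mat(x)
  }
  if (!nrow(X)) stop("no windows to accumulate")
  if (center) X <- sweep(X, 2, colMeans(X))
  C <- crossprod(X) / nrow(X)
  C <- (C + t(C)) / 2
  structure(list(C = C, n = nrow(X)), class = "second_moment")
}

#' Dominant eigenvector of a pooled second-moment matrix
#'
#' Solves `C e = lambda e` and returns the eigenpair with maximal
#' eigenvalue. Because `C` is entrywise nonnegative (outer products of
#' nonnegative energy vectors), the dominant eigenvector has an
#' entrywise-nonnegative representative (Perron); the sign is fixed by
#' making the largest-magnitude component positive. If the top two
#' eigenvalues tie to within `1e-10` (relative), a warning is emitted and
#' the first eigenpair returned by the symmetric solver is kept.
#'
#' @param C A 5 x 5 symmetric PSD matrix or a `second_moment` object.
#' @param segment_mode Optional tag, `"initial_5s"` or `"whole"`.
#' @return An `eigen_feature`: unit vector `e`, eigenvalue `lambda`,
#'   `segment_mode`, `n_windows`, band names.
#' @export
dominant_eigenvector <- function(C, segment_mode = NA_character_) {
  n_windows <- NA_integer_
  if (inherits(C, "second_moment")) {
    n_windows <- C$n
    C <- C$C
  }
  stopifnot(is.matrix(C), nrow(C) == ncol(C))
  if (max(abs(C - t(C))) > 1e-8 * max(abs(C), 1e-300)) {
    stop("`C` must be symmetric")
  }
  ev <- eigen(C, symmetric = TRUE)
  scale <- max(abs(ev$values), .Machine$double.xmin)
  if (length(ev$values) > 1 &&
      (ev$values[1] - ev$values[2]) <= 1e-10 * scale) {
    warning("top two eigenvalues tie within tolerance; ",
            "keeping the first eigenpair deterministically")
  }
  e <- ev$vectors[, 1]
  if (e[which.max(abs(e))] < 0) e <- -e
  structure(
    list(e = e, lambda = ev$values[1], segment_mode = segment_mode,
         n_windows = n_windows,
         bands = colnames(C) %||% band_names()),
    class = "eigen_feature"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.eigen_feature <- function(x, ...) {
  cat(sprintf("<eigen_feature> mode=%s lambda=%.4g n=%s\n",
              x$segment_mode, x$lambda,
              ifelse(is.na(x$n_windows), "?", x$n_windows)))
  print(stats::setNames(round(x$e, 4), x$bands))
  invisible(x)
}

#' Train an eigenfeature from training seizures
#'
#' Convenience wrapper: selects the segment windows of every training
#' seizure, pools them into one second-moment matrix, and extracts the
#' dominant eigenvector.
#'
#' @param series_list List of [band_energy_series()], one per seizure clip.
#' @param annotations List (or data frame rows) of per-clip annotations in
#'   clip-local time.
#' @param mode `"initial"` or `"whole"`.
#' @param initial_len_s Initial-segment length, seconds.
#' @return An `eigen_feature`.
#' @export
train_eigenfeature <- function(series_list, annotations,
                               mode = c("initial", "whole"),
                               initial_len_s = 5) {
  mode <- match.arg(mode)
  pools <- mapply(function(series, ann) {
    idx <- select_segment_windows(series, ann$onset_s, ann$offset_s,
                                  mode = mode, initial_len_s = initial_len_s)
    series$energies[idx, , drop = FALSE]
  }, series_list, annotations, SIMPLIFY = FALSE)
  acc <- accumulate_second_moment(pools)
  dominant_eigenvector(
    acc, segment_mode = if (mode == "initial") "initial_5s" else "whole")
}

#' Project a band-energy series onto an eigenfeature
#'
#' The detection feature `u_n = e . X_n` per window: the energy component
#' along the principal ictal energy direction.
#'
#' @param series A [band_energy_series()].
#' @param feat An `eigen_feature` (or bare numeric weight vector).
#' @param feature_name Name recorded on the resulting signal.
#' @return A `feature_signal`: `values`, `window_start_s`, `window_len_s`,
#'   `feature_name`.
#' @export
project_feature <- function(series, feat, feature_name = NULL) {
  stopifnot(inherits(series, "band_energy_series"))
  e <- if (inherits(feat, "eigen_feature")) feat$e else as.numeric(feat)
  if (length(e) != ncol(series$energies)) {
    stop("weight vector length ", length(e), " does not match ",
         ncol(series$energies), " bands")
  }
  if (is.null(feature_name)) {
    feature_name <- if (inherits(feat, "eigen_feature")) {
      switch(feat$segment_mode, initial_5s = "u_i", whole = "u_w", "u")
    } else "u"
  }
  structure(
    list(values = as.numeric(series$energies %*% e),
         window_start_s = series$window_start_s,
         window_len_s = series$window_len_s,
         feature_name = feature_name),
    class = "feature_signal"
  )
}

#' Single-subband comparator feature
#'
#' One component of the energy vector as a detection feature, equivalent to
#' projecting onto a one-hot weight vector.
#'
#' @param series A [band_energy_series()].
#' @param band_name One of `"delta"`, `"theta"`, `"alpha"`, `"beta"`,
#'   `"gamma"`.
#' @return A `feature_signal`.
#' @export
subband_feature <- function(series, band_name) {
  stopifnot(inherits(series, "band_energy_series"))
  if (!band_name %in% colnames(series$energies)) {
    stop("unknown band '", band_name, "'")
  }
  structure(
    list(values = as.numeric(series$energies[, band_name]),
         window_start_s = series$window_start_s,
         window_len_s = series$window_len_s,
         feature_name = band_name),
    class = "feature_signal"
  )
}

#' @export
print.feature_signal <- function(x, ...) {
  cat(sprintf("<feature_signal> %s: %d windows\n", x$feature_name,
              length(x$values)))
  invisible(x)
}

#' Angle between two feature eigenvectors, in degrees
#'
#' `acos` of the normalized dot product, reported as the axis angle
#' `min(theta, 180 - theta)` in `[0, 90]` degrees (an eigenvector and its
#' negation are the same feature).
#'
#' @param e1,e2 `eigen_feature` objects or numeric vectors.
#' @return Angle in degrees.
#' @export
eigenvector_angle <- function(e1, e2) {
  v1 <- if (inherits(e1, "eigen_feature")) e1$e else as.numeric(e1)
  v2 <- if (inherits(e2, "eigen_feature")) e2$e else as.numeric(e2)
  n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
  if (n1 == 0 || n2 == 0) stop("cannot take the angle with a zero vector")
  acos(min(1, abs(sum(v1 * v2)) / (n1 * n2))) * 180 / pi
}

#' Save / load a trained eigenfeature model
#'
#' The model file is JSON: band definitions, the unit weight vector `e`, its
#' eigenvalue, the training segment mode, the number of pooled windows, and
#' a configuration hash for provenance.
#'
#' @param feat An `eigen_feature`.
#' @param path JSON path.
#' @param config_hash Optional provenance string.
#' @export
save_model <- function(feat, path, config_hash = NA_character_) {
  stopifnot(inherits(feat, "eigen_feature"))
  obj <- list(bands = eeg_bands(), e = feat$e, lambda = feat$lambda,
              segment_mode = feat$segment_mode, n_windows = feat$n_windows,
              config_hash = config_hash)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(e = as.numeric(obj$e), lambda = as.numeric(obj$lambda),
         segment_mode = obj$segment_mode,
         n_windows = as.integer(obj$n_windows),
         bands = obj$bands$name),
    class = "eigen_feature"
  )
}
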