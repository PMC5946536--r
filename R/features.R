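#' Time-domain sEMG features
#'
#' The four classic time-domain features used for windowed sEMG pattern
#' recognition: mean absolute value (MAV), waveform length (WL), number of
#' zero crossings (ZC) and number of slope-sign changes (SSC). MAV and WL
#' are in mV; ZC and SSC are counts. ZC and SSC take a deadband `eps` (mV)
#' below which a crossing or slope change is ignored; `eps = 0` recovers the
#' textbook definitions.
#'
#' Conventions: a zero crossing at junction k requires a strictly negative
#' sign product `x[k] * x[k+1] < 0` (exact zeros never count) and
#' `|x[k] - x[k+1]| >= eps`. A slope-sign change at interior sample k
#' requires `(x[k]-x[k-1]) * (x[k]-x[k+1]) > 0` and the larger of the two
#' adjacent steps to be at least `eps`.
#'
#' @param x numeric vector, one channel of one analysis window, in mV.
#' @param eps deadband in mV (>= 0); default 0.01.
#' @return `mav()` and `waveform_length()` return a scalar in mV;
#'   `zero_crossings()` and `slope_sign_changes()` return an integer count.
#' @export
mav <- function(x) {
  if (length(x) < 1L) stop("parameter error: empty window")
  mean(abs(x))
}

#' @rdname mav
#' @export
waveform_length <- function(x) {
  if (length(x) < 2L) stop("parameter error: window length must be >= 2")
  sum(abs(diff(x)))
}

#' @rdname mav
#' @export
zero_crossings <- function(x, eps = 0.01) {
  if (length(x) < 2L) stop("parameter error: window length must be >= 2")
  if (eps < 0) stop("parameter error: eps must be >= 0")
  a <- x[-length(x)]
  b <- x[-1L]
  sum(a * b < 0 & abs(a - b) >= eps)
}

#' @rdname mav
#' @export
slope_sign_changes <- function(x, eps = 0.01) {
  if (length(x) < 3L) stop("parameter error: window length must be >= 3")
  if (eps < 0) stop("parameter error: eps must be >= 0")
  left <- x[2:(length(x) - 1L)] - x[1:(length(x) - 2L)]
  right <- x[2:(length(x) - 1L)] - x[3:length(x)]
  sum(left * right > 0 & pmax(abs(left), abs(right)) >= eps)
}

#' Feature vector of one multichannel analysis window
#'
#' Concatenates the four time-domain features per channel, in channel order:
#' `Ch1_MAV, Ch1_WL, Ch1_ZC, Ch1_SSC, Ch2_MAV, ...`. The per-channel MAV
#' components are also attached as attribute `mav_by_channel`, since the
#' threshold-switch post-processing needs them by channel.
#'
#' @param w numeric matrix, window samples x channels (mV); column names are
#'   used as channel labels.
#' @param eps deadband in mV for ZC/SSC.
#' @return named numeric vector of length `4 * ncol(w)` with attribute
#'   `mav_by_channel`.
#' @export
extract_features <- function(w, eps = 0.01) {
  w <- as.matrix(w)
  labels <- colnames(w)
  if (is.null(labels)) labels <- paste0("Ch", seq_len(ncol(w)))
  blocks <- lapply(seq_len(ncol(w)), function(j) {
    x <- w[, j]
    c(mav(x), waveform_length(x), zero_crossings(x, eps),
      slope_sign_changes(x, eps))
  })
  v <- unlist(blocks)
  names(v) <- as.vector(t(outer(labels, c("MAV", "WL", "ZC", "SSC"),
                                paste, sep = "_")))
  attr(v, "mav_by_channel") <- stats::setNames(
    vapply(blocks, `[`, numeric(1L), 1L), labels)
  v
}

#' Feature matrix over the analysis windows of a recording
#'
#' Windows the recording (see [window_grid()]), extracts the time-domain
#' feature vector of every window, and returns the stacked feature matrix
#' together with the per-window, per-channel MAV needed by the
#' threshold-switch post-processing.
#'
#' @param rec an [emg_recording] (already band-pass filtered if desired).
#' @inheritParams window_grid
#' @param eps ZC/SSC deadband in mV.
#' @return list with `x` (windows x features matrix), `mav` (windows x
#'   channels MAV matrix, mV), `window_start` (0-based sample offsets),
#'   `window_samples`, `step`.
#' @export
feature_matrix <- function(rec, window_ms = 137.6, overlap_frac = 0.5,
                           eps = 0.01) {
  g <- window_grid(nrow(rec$samples), rec$fs, window_ms, overlap_frac)
  nw <- length(g$start)
  nc <- ncol(rec$samples)
  x <- matrix(0, nw, 4L * nc)
  mv <- matrix(0, nw, nc, dimnames = list(NULL, rec$channel_labels))
  for (i in seq_len(nw)) {
    w <- rec$samples[(g$start[i] + 1L):(g$start[i] + g$length), ,
                     drop = FALSE]
    f <- extract_features(w, eps)
    if (i == 1L) colnames(x) <- names(f)
    x[i, ] <- f
    mv[i, ] <- attr(f, "mav_by_channel")
  }
  if (nw == 0L)
    colnames(x) <- as.vector(t(outer(rec$channel_labels,
                                     c("MAV", "WL", "ZC", "SSC"),
                                     paste, sep = "_")))
  list(x = x, mav = mv, window_start = g$start,
       window_samples = g$length, step = g$step)
}

#' Write a feature matrix as CSV
#'
#' One row per window, feature columns named `ChK_MAV/WL/ZC/SSC`, plus a
#' leading `window_start` column of 0-based sample offsets.
#'
#' @param fm result of [feature_matrix()].
#' @param path output file path.
#' @export
write_features <- function(fm, path) {
  utils::write.csv(cbind(data.frame(window_start = fm$window_start),
                         as.data.frame(fm$x)),
                   path, row.names = FALSE)
  invisible(path)
}
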