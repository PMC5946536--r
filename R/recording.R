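#' Default motion set and channel layout
#'
#' The five-motion control scheme used throughout the package: channels
#' Ch1 to Ch5 drive hand close, hand open, wrist rotation, elbow flexion
#' and elbow extension respectively.
#'
#' @return `default_motions()` returns a character vector of the five motion
#'   names in channel order; `default_motion_map()` returns a named character
#'   vector mapping channel labels (`Ch1`..`Ch5`) to motion names.
#' @export
default_motions <- function() {
  c("hand close", "hand open", "wrist rotation", "elbow flexion",
    "elbow extension")
}

#' @rdname default_motions
#' @export
default_motion_map <- function() {
  stats::setNames(default_motions(), paste0("Ch", 1:5))
}

#' Multichannel sEMG recording
#'
#' Container for a multichannel surface-EMG recording. Amplitudes are in mV
#' throughout the package. Sample offsets in annotations (and in windows
#' derived from a recording) are 0-based with half-open `[start, end)`
#' intervals, matching the on-disk sidecar format.
#'
#' @param samples numeric matrix, one column per channel, one row per sample,
#'   in mV.
#' @param fs sampling rate in Hz (> 0).
#' @param channel_labels character vector of channel names; defaults to the
#'   column names of `samples`, or `Ch1..ChK`.
#' @param motion_map optional named character vector mapping channel label to
#'   motion name; must be a bijection between the channels and the motion set.
#' @param annotations optional data.frame with columns `motion`, `start`,
#'   `end` (0-based half-open sample intervals) and optionally `phase`
#'   (`"steady"` or `"transient"`). Intervals must lie inside the recording;
#'   intervals of the same phase must not overlap.
#'
#' @return an object of class `emg_recording`.
#' @export
emg_recording <- function(samples, fs, channel_labels = NULL,
                          motion_map = NULL, annotations = NULL) {
  samples <- as.matrix(samples)
  storage.mode(samples) <- "double"
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("config error: `fs` must be a single positive number (Hz)")
  fs <- as.numeric(fs)
  if (is.null(channel_labels)) {
    channel_labels <- colnames(samples)
    if (is.null(channel_labels))
      channel_labels <- paste0("Ch", seq_len(ncol(samples)))
  }
  if (length(channel_labels) != ncol(samples))
    stop("format error: ", length(channel_labels), " channel labels for ",
         ncol(samples), " data columns")
  colnames(samples) <- channel_labels
  if (!is.null(motion_map)) {
    motion_map <- unlist(motion_map)
    if (is.null(names(motion_map)) || !all(names(motion_map) %in% channel_labels))
      stop("config error: motion_map names must be channel labels")
    if (anyDuplicated(motion_map) || anyDuplicated(names(motion_map)))
      stop("config error: motion_map must be a bijection between channels and motions")
  }
  if (!is.null(annotations)) {
    annotations <- as.data.frame(annotations)
    req <- c("motion", "start", "end")
    if (!all(req %in% names(annotations)))
      stop("format error: annotations need columns motion, start, end")
    if (!"phase" %in% names(annotations)) annotations$phase <- "steady"
    with(annotations, {
      if (any(start < 0) || any(end > nrow(samples)) || any(end <= start))
        stop("format error: annotation intervals must lie within the recording")
    })
    ann <- annotations[order(annotations$start), ]
    for (ph in unique(ann$phase)) {
      a <- ann[ann$phase == ph, ]
      if (nrow(a) > 1L && any(a$start[-1L] < a$end[-nrow(a)]))
        stop("format error: overlapping ", ph, " annotation intervals")
    }
  }
  structure(list(samples = samples, fs = fs,
                 channel_labels = channel_labels,
                 motion_map = motion_map, annotations = annotations),
            class = "emg_recording")
}

#' @export
print.emg_recording <- function(x, ...) {
  n <- nrow(x$samples)
  cat(sprintf("<emg_recording> %d channels x %d samples (%.2f s at %g Hz)\n",
              ncol(x$samples), n, n / x$fs, x$fs))
  cat("  channels:", paste(x$channel_labels, collapse = ", "), "\n")
  if (!is.null(x$motion_map))
    cat("  motions: ",
        paste(names(x$motion_map), x$motion_map, sep = " -> ",
              collapse = "; "), "\n", sep = "")
  if (!is.null(x$annotations))
    cat("  annotations:", nrow(x$annotations), "intervals\n")
  invisible(x)
}

#' @export
plot.emg_recording <- function(x, channels = x$channel_labels, ...) {
  t <- (seq_len(nrow(x$samples)) - 1L) / x$fs
  k <- length(channels)
  op <- graphics::par(mfrow = c(k, 1), mar = c(2, 4, 1, 1))
  on.exit(graphics::par(op))
  for (ch in channels) {
    graphics::plot(t, x$samples[, ch], type = "l", xlab = "time (s)",
                   ylab = paste0(ch, " (mV)"), ...)
    if (!is.null(x$annotations)) {
      a <- x$annotations[x$annotations$phase == "steady", , drop = FALSE]
      graphics::abline(v = a$start / x$fs, col = "grey60", lty = 2)
    }
  }
  invisible(x)
}

#' Duration of a recording in seconds
#' @param rec an [emg_recording].
#' @return duration in seconds (samples / fs).
#' @export
duration_s <- function(rec) nrow(rec$samples) / rec$fs

#' Read / write a recording with its JSON sidecar
#'
#' The recording file is comma-delimited text with one header row of channel
#' labels and one row per sample (amplitudes in mV, `.` decimal). The sidecar
#' is JSON with keys `fs_hz`, `channel_labels`, `motion_map` and optional
#' `annotations` (list of `{motion, start, end, phase}`, 0-based half-open).
#'
#' @param path path to the CSV sample file.
#' @param sidecar path to the JSON sidecar.
#' @return `read_recording()` returns an [emg_recording];
#'   `write_recording()` invisibly returns `path`.
#' @export
read_recording <- function(path, sidecar) {
  meta <- jsonlite::fromJSON(sidecar, simplifyVector = TRUE)
  if (is.null(meta$fs_hz) || !is.numeric(meta$fs_hz) || meta$fs_hz <= 0)
    stop("config error: sidecar must supply a positive fs_hz")
  dat <- utils::read.csv(path, check.names = FALSE)
  if (nrow(dat) == 0L) stop("format error: empty recording file")
  if (!all(vapply(dat, is.numeric, logical(1L))))
    stop("format error: non-numeric (ragged?) columns in recording file")
  labels <- meta$channel_labels
  if (is.null(labels)) labels <- names(dat)
  if (length(labels) != ncol(dat))
    stop("format error: ", ncol(dat), " data columns but ", length(labels),
         " channel labels in sidecar")
  ann <- meta$annotations
  if (!is.null(ann) && length(ann)) ann <- as.data.frame(ann) else ann <- NULL
  mm <- meta$motion_map
  if (!is.null(mm)) mm <- unlist(mm)
  emg_recording(as.matrix(dat), fs = meta$fs_hz, channel_labels = labels,
                motion_map = mm, annotations = ann)
}

#' @rdname read_recording
#' @param rec an [emg_recording] to write.
#' @export
write_recording <- function(rec, path, sidecar) {
  utils::write.csv(as.data.frame(rec$samples), path, row.names = FALSE)
  meta <- list(fs_hz = rec$fs, channel_labels = rec$channel_labels)
  if (!is.null(rec$motion_map)) meta$motion_map <- as.list(rec$motion_map)
  if (!is.null(rec$annotations)) meta$annotations <- rec$annotations
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# Butterworth band-pass of a samples matrix; zero-phase or causal.
bandpass_matrix <- function(x, fs, low_hz, high_hz, order = 4L,
                            mode = c("zero-phase", "causal")) {
  mode <- match.arg(mode)
  if (!is.numeric(low_hz) || !is.numeric(high_hz) ||
      low_hz <= 0 || high_hz <= low_hz)
    stop("parameter error: need 0 < low_hz < high_hz")
  if (high_hz >= fs / 2)
    stop("parameter error: high cutoff ", high_hz,
         " Hz must be below Nyquist (", fs / 2, " Hz)")
  bf <- signal::butter(order, c(low_hz, high_hz) / (fs / 2), type = "pass")
  apply(x, 2L, function(col) {
    if (mode == "zero-phase") signal::filtfilt(bf, col)
    else as.numeric(signal::filter(bf, col))
  })
}

#' Band-pass filter a recording
#'
#' 4th-order Butterworth band-pass applied per channel. The offline mode is
#' zero-phase (forward-backward); the streaming mode is causal single-pass.
#' Length and all metadata are preserved.
#'
#' @param rec an [emg_recording].
#' @param low_hz,high_hz band edges in Hz; `0 < low_hz < high_hz < fs/2`.
#' @param mode `"zero-phase"` (default, offline) or `"causal"` (streaming).
#' @param order filter order (default 4).
#' @return a filtered [emg_recording].
#' @export
bandpass <- function(rec, low_hz = 80, high_hz = 400,
                     mode = c("zero-phase", "causal"), order = 4L) {
  y <- bandpass_matrix(rec$samples, rec$fs, low_hz, high_hz,
                       order = order, mode = match.arg(mode))
  colnames(y) <- rec$channel_labels
  emg_recording(y, rec$fs, rec$channel_labels, rec$motion_map,
                rec$annotations)
}

#' Overlapping analysis-window grid
#'
#' Window length in samples is `round(window_ms * fs / 1000)` and the step is
#' `round(length * (1 - overlap_frac))`; at 1860 Hz the default 137.6 ms /
#' 50\% grid gives 256-sample windows stepping by 128. Trailing partial
#' windows are discarded.
#'
#' @param n_samples number of samples available.
#' @param fs sampling rate in Hz.
#' @param window_ms window duration in milliseconds (default 137.6).
#' @param overlap_frac fractional overlap between consecutive windows
#'   (default 0.5).
#' @return a list with `start` (integer vector of 0-based window starts,
#'   possibly empty), `length` (window length in samples) and `step`.
#' @export
window_grid <- function(n_samples, fs, window_ms = 137.6,
                        overlap_frac = 0.5) {
  if (window_ms <= 0 || overlap_frac < 0 || overlap_frac >= 1)
    stop("parameter error: window_ms > 0 and 0 <= overlap_frac < 1 required")
  len <- as.integer(round(window_ms * fs / 1000))
  step <- as.integer(round(len * (1 - overlap_frac)))
  if (len < 1L || step < 1L)
    stop("parameter error: window or step shorter than one sample")
  if (n_samples < len)
    return(list(start = integer(0), length = len, step = step))
  list(start = seq.int(0L, n_samples - len, by = step),
       length = len, step = step)
}

#' Extract the analysis windows of a recording
#'
#' @param rec an [emg_recording].
#' @inheritParams window_grid
#' @return a list of per-window sample matrices (length x channels), with the
#'   window grid attached as attributes `start`, `length`, `step`.
#' @export
window_iter <- function(rec, window_ms = 137.6, overlap_frac = 0.5) {
  g <- window_grid(nrow(rec$samples), rec$fs, window_ms, overlap_frac)
  wins <- lapply(g$start, function(s)
    rec$samples[(s + 1L):(s + g$length), , drop = FALSE])
  attributes(wins) <- c(attributes(wins), g[c("start", "length", "step")])
  wins
}
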