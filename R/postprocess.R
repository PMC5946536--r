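#' Output token for the prosthesis staying still
#'
#' `STILL` is an output token produced by post-processing, never a trained
#' classifier class.
#' @export
STILL <- "STILL"

#' Per-motion MAV threshold configuration
#'
#' Holds one amplitude threshold (mV) per motion for the MAV-based threshold
#' switches. `st_thresholds()` returns the standard set (ST) used in the
#' motivating TMR case: 0.2 mV for hand close, hand open, elbow flexion and
#' elbow extension (Ch1/Ch2/Ch4/Ch5) and 0.1 mV for wrist rotation (Ch3).
#' `derive_thresholds()` scales a configuration, e.g. 0.8 for the lower set
#' (LT) and 1.2 for the higher set (HT).
#'
#' @param thresholds named numeric vector, motion -> threshold in mV (> 0).
#' @param name configuration label (e.g. `"ST"`, `"LT"`, `"HT"`).
#' @return a `threshold_config` object.
#' @export
threshold_config <- function(thresholds, name = "custom") {
  thresholds <- unlist(thresholds)
  if (is.null(names(thresholds)) || any(names(thresholds) == ""))
    stop("config error: thresholds must be named by motion")
  if (!is.numeric(thresholds) || any(!is.finite(thresholds)) ||
      any(thresholds <= 0))
    stop("config error: every threshold must be a positive number (mV)")
  structure(list(thresholds = thresholds, name = name),
            class = "threshold_config")
}

#' @rdname threshold_config
#' @export
st_thresholds <- function() {
  threshold_config(stats::setNames(c(0.2, 0.2, 0.1, 0.2, 0.2),
                                   default_motions()),
                   name = "ST")
}

#' @rdname threshold_config
#' @param cfg a `threshold_config` to scale.
#' @param factor positive scale factor applied to every threshold.
#' @export
derive_thresholds <- function(cfg, factor,
                              name = sprintf("%s x %g", cfg$name, factor)) {
  if (!is.numeric(factor) || length(factor) != 1L || factor <= 0)
    stop("parameter error: factor must be a single positive number")
  threshold_config(cfg$thresholds * factor, name = name)
}

#' @export
print.threshold_config <- function(x, ...) {
  cat(sprintf("<threshold_config> %s\n", x$name))
  print(x$thresholds)
  invisible(x)
}

#' Read a threshold configuration from YAML or JSON
#'
#' The file maps motion names to thresholds in mV, either flat or under a
#' `thresholds` key, with an optional `name` key.
#'
#' @param path YAML or JSON file.
#' @return a `threshold_config`.
#' @export
read_thresholds <- function(path) {
  obj <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::fromJSON(path) else yaml::read_yaml(path)
  if (!is.null(obj$thresholds))
    threshold_config(obj$thresholds, name = obj$name %||% "custom")
  else
    threshold_config(obj)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' MAV-based threshold switch for one decision
#'
#' The improved pattern-recognition post-processing: a classified motion is
#' emitted only when the MAV of that motion's designated channel exceeds its
#' preset threshold, `D = V - T > 0` (strictly); otherwise the prosthesis
#' stays still. This discriminates the steady state from the transient
#' state, whose low-amplitude windows are the main source of
#' misclassification.
#'
#' @param c motion label classified by the pattern recognizer.
#' @param mav_by_motion named numeric vector of window MAVs in mV, indexed
#'   by motion (each motion's designated channel).
#' @param cfg a [threshold_config()] covering `c`.
#' @return list with `output` (`c` or `STILL`), `D` (`V - T`, mV), `V`, `T`.
#' @export
threshold_switch <- function(c, mav_by_motion, cfg) {
  if (!c %in% names(cfg$thresholds))
    stop("config error: no threshold configured for motion '", c, "'")
  if (!c %in% names(mav_by_motion))
    stop("config error: no MAV supplied for motion '", c, "'")
  V <- unname(mav_by_motion[[c]])
  T <- unname(cfg$thresholds[[c]])
  D <- V - T
  list(output = if (D > 0) c else STILL, D = D, V = V, T = T)
}

#' Majority-vote smoothing of a decision stream
#'
#' Each decision is replaced by the modal label of the last `L` raw
#' decisions (fewer at the start of the stream, current decision included).
#' Ties are resolved in favour of the previous output when it is among the
#' tied labels, otherwise by label order.
#'
#' @param stream character vector of raw class labels.
#' @param L queue length (>= 1); `L = 1` returns the stream unchanged.
#' @param labels label order used for tie-breaks; defaults to
#'   `sort(unique(stream))`.
#' @return character vector of smoothed labels, same length as `stream`.
#' @export
majority_vote <- function(stream, L, labels = sort(unique(stream))) {
  if (!is.numeric(L) || length(L) != 1L || L < 1)
    stop("parameter error: queue length L must be >= 1")
  L <- as.integer(L)
  n <- length(stream)
  out <- character(n)
  prev <- NA_character_
  for (t in seq_len(n)) {
    q <- stream[max(1L, t - L + 1L):t]
    cnt <- table(factor(q, levels = labels))
    top <- names(cnt)[cnt == max(cnt)]
    out[t] <- if (!is.na(prev) && prev %in% top) prev else top[1L]
    prev <- out[t]
  }
  out
}

#' Run the full windowed classification pipeline on a recording
#'
#' Band-pass filters the recording, extracts the time-domain feature vector
#' of every analysis window, classifies each window with the fitted LDA, and
#' applies the selected post-processing: none (raw pattern recognition),
#' majority vote of queue length `L`, or the MAV-based threshold switches.
#' The MAV recorded for each window is that of the classified motion's
#' designated channel, computed from the same band-pass-filtered window the
#' features came from.
#'
#' @param rec an [emg_recording] whose `motion_map` covers the model labels.
#' @param model an `emg_lda` fitted on the same feature layout.
#' @param mode `"none"`, `"vote"` or `"threshold"`.
#' @param L majority-vote queue length (used when `mode = "vote"`).
#' @param thresholds a [threshold_config()] (used when `mode = "threshold"`).
#' @param band band-pass edges in Hz applied before feature extraction,
#'   or `NULL` if `rec` is already filtered.
#' @inheritParams window_grid
#' @param eps ZC/SSC deadband in mV.
#' @return a `decision_stream`: data.frame with columns `window_start`
#'   (0-based samples), `raw_class`, `mav_mv`, `output`, and attributes
#'   `fs`, `window_samples`, `step`, `mode`.
#' @export
run_pipeline <- function(rec, model, mode = c("none", "vote", "threshold"),
                         L = 5L, thresholds = NULL, band = c(80, 400),
                         window_ms = 137.6, overlap_frac = 0.5, eps = 0.01) {
  mode <- match.arg(mode)
  if (is.null(rec$motion_map))
    stop("config error: recording has no motion_map")
  if (!all(model$labels %in% rec$motion_map))
    stop("config error: model labels not covered by the recording motion_map")
  if (!is.null(band))
    rec <- bandpass(rec, band[1L], band[2L])
  fm <- feature_matrix(rec, window_ms, overlap_frac, eps)
  if (!identical(colnames(fm$x), model$feature_names))
    stop("config error: feature layout of recording does not match model")
  nw <- nrow(fm$x)
  raw <- if (nw) predict(model, fm$x) else character(0)
  # designated channel per motion (inverse of the channel -> motion map)
  chan_of <- stats::setNames(names(rec$motion_map), rec$motion_map)
  v <- if (nw) fm$mav[cbind(seq_len(nw), match(chan_of[raw],
                                               colnames(fm$mav)))]
       else numeric(0)
  out <- switch(mode,
    none = raw,
    vote = majority_vote(raw, L, labels = model$labels),
    threshold = {
      if (is.null(thresholds))
        stop("config error: mode 'threshold' needs a threshold_config")
      if (!all(model$labels %in% names(thresholds$thresholds)))
        stop("config error: thresholds missing for some motions")
      ifelse(v - thresholds$thresholds[raw] > 0, raw, STILL)
    })
  ds <- data.frame(window_start = fm$window_start, raw_class = raw,
                   mav_mv = v, output = unname(out),
                   stringsAsFactors = FALSE)
  structure(ds, fs = rec$fs, window_samples = fm$window_samples,
            step = fm$step, mode = mode,
            class = c("decision_stream", "data.frame"))
}

#' Write / read a decision stream as CSV
#'
#' Columns: `window_start`, `raw_class`, `mav_mv`, `output`. The sampling
#' rate and window geometry are carried in a JSON comment-free sidecar-less
#' way: they are re-supplied on read.
#'
#' @param ds a `decision_stream`.
#' @param path CSV file path.
#' @export
write_stream <- function(ds, path) {
  utils::write.csv(as.data.frame(ds), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_stream
#' @param fs,window_samples,step window geometry to re-attach.
#' @export
read_stream <- function(path, fs = NULL, window_samples = NULL,
                        step = NULL) {
  ds <- utils::read.csv(path, stringsAsFactors = FALSE)
  structure(ds, fs = fs, window_samples = window_samples, step = step,
            class = c("decision_stream", "data.frame"))
}

#' @export
print.decision_stream <- function(x, ...) {
  cat(sprintf("<decision_stream> %d windows, mode = %s\n", nrow(x),
              attr(x, "mode") %||% "?"))
  tab <- table(x$output)
  cat("  outputs:", paste(names(tab), tab, sep = ": ", collapse = "; "),
      "\n")
  invisible(x)
}
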