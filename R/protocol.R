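#' Training-session labeling plan
#'
#' The classifier training protocol: each motion is attempted in turn for
#' `per_motion_s` seconds (default 7 s, 35 s for the five-motion session);
#' the first `trim_head_s` seconds of each segment are cut to avoid the
#' transient state and only the last `keep_s` seconds are labeled and used
#' for training (defaults 4 s cut / 3 s kept).
#'
#' @param motion_order the motions in session order; each configured motion
#'   exactly once.
#' @param per_motion_s segment duration per motion in seconds.
#' @param trim_head_s leading seconds discarded per segment.
#' @param keep_s trailing seconds kept per segment;
#'   `trim_head_s + keep_s <= per_motion_s`.
#' @return a `session_plan` object.
#' @export
session_plan <- function(motion_order = default_motions(), per_motion_s = 7,
                         trim_head_s = 4, keep_s = 3) {
  if (anyDuplicated(motion_order))
    stop("protocol error: motion_order must list each motion once")
  if (trim_head_s + keep_s > per_motion_s + 1e-9)
    stop("protocol error: trim_head_s + keep_s must be <= per_motion_s")
  structure(list(motion_order = motion_order, per_motion_s = per_motion_s,
                 trim_head_s = trim_head_s, keep_s = keep_s),
            class = "session_plan")
}

#' @export
print.session_plan <- function(x, ...) {
  cat(sprintf(
    "<session_plan> %d motions x %g s (cut %g s, keep %g s) = %g s total\n",
    length(x$motion_order), x$per_motion_s, x$trim_head_s, x$keep_s,
    x$per_motion_s * length(x$motion_order)))
  invisible(x)
}

#' Read a session plan from YAML
#' @param path YAML file with keys `motion_order`, `per_motion_s`,
#'   `trim_head_s`, `keep_s` (missing keys take the defaults).
#' @return a [session_plan()].
#' @export
read_session_plan <- function(path) {
  y <- yaml::read_yaml(path)
  session_plan(motion_order = y$motion_order %||% default_motions(),
               per_motion_s = y$per_motion_s %||% 7,
               trim_head_s = y$trim_head_s %||% 4,
               keep_s = y$keep_s %||% 3)
}

#' Extract the labeled training set of a session recording
#'
#' Applies the labeling protocol to a training-session recording: for each
#' motion segment the head is discarded, the kept tail is windowed on the
#' standard analysis grid, features are extracted, and every window is
#' labeled with the segment's motion. At 1860 Hz a kept 3 s tail is 5580
#' samples and yields 42 windows per motion (256-sample windows, step 128).
#'
#' @param rec an [emg_recording] covering the full plan duration.
#' @param plan a [session_plan()].
#' @param band band-pass edges in Hz applied before feature extraction
#'   (`NULL` to skip).
#' @inheritParams feature_matrix
#' @return list with `x` (feature matrix), `y` (motion labels),
#'   `window_start` (0-based offsets into the full recording).
#' @export
extract_training_set <- function(rec, plan, band = c(80, 400),
                                 window_ms = 137.6, overlap_frac = 0.5,
                                 eps = 0.01) {
  need <- plan$per_motion_s * length(plan$motion_order)
  if (duration_s(rec) < need - 1e-9)
    stop("protocol error: recording (", round(duration_s(rec), 2),
         " s) shorter than the plan (", need, " s)")
  if (!is.null(band)) rec <- bandpass(rec, band[1L], band[2L])
  keep_n <- as.integer(round(plan$keep_s * rec$fs))
  xs <- list(); ys <- list(); ws <- list()
  for (k in seq_along(plan$motion_order)) {
    seg_start <- (k - 1L) * plan$per_motion_s
    from <- as.integer(round((seg_start + plan$trim_head_s) * rec$fs))
    seg <- emg_recording(
      rec$samples[(from + 1L):(from + keep_n), , drop = FALSE],
      rec$fs, rec$channel_labels)
    fm <- feature_matrix(seg, window_ms, overlap_frac, eps)
    xs[[k]] <- fm$x
    ys[[k]] <- rep(plan$motion_order[k], nrow(fm$x))
    ws[[k]] <- fm$window_start + from
  }
  list(x = do.call(rbind, xs), y = unlist(ys),
       window_start = unlist(ws))
}

#' Average-MAV grid over assessment sessions
#'
#' The rehabilitation-progress analysis: for each assessment session the
#' MAV of every channel is computed over each motion's annotated steady
#' hold, and the grid entry (motion, channel) is the average across
#' sessions. With the five-motion scheme this is the 5 x 5 grid whose
#' principal diagonal should dominate each column when the sEMG signals are
#' independent; coupled signals show strong off-diagonal mass.
#'
#' @param recordings list of annotated [emg_recording]s (one per session);
#'   each must annotate a steady hold for every motion.
#' @param motions motion (row) order; defaults to the motion_map order of
#'   the first recording.
#' @param band optional band-pass edges applied before the MAV.
#' @return a `mav_grid`: motions x channels matrix (mV) with attributes
#'   `n_sessions` and `motion_map`.
#' @export
mav_grid <- function(recordings, motions = NULL, band = NULL) {
  if (!length(recordings)) stop("protocol error: no sessions supplied")
  r1 <- recordings[[1L]]
  if (is.null(motions))
    motions <- if (!is.null(r1$motion_map)) unname(r1$motion_map)
               else unique(r1$annotations$motion)
  channels <- r1$channel_labels
  acc <- matrix(0, length(motions), length(channels),
                dimnames = list(motions, channels))
  for (rec in recordings) {
    if (!is.null(band)) rec <- bandpass(rec, band[1L], band[2L])
    ann <- rec$annotations
    if (is.null(ann)) stop("protocol error: session without annotations")
    ann <- ann[ann$phase == "steady", , drop = FALSE]
    for (m in motions) {
      a <- ann[ann$motion == m, , drop = FALSE]
      if (!nrow(a))
        stop("protocol error: session missing a steady hold for '", m, "'")
      seg <- do.call(rbind, lapply(seq_len(nrow(a)), function(i)
        rec$samples[(a$start[i] + 1L):a$end[i], , drop = FALSE]))
      acc[m, ] <- acc[m, ] + colMeans(abs(seg))
    }
  }
  structure(acc / length(recordings), n_sessions = length(recordings),
            motion_map = r1$motion_map, class = c("mav_grid", "matrix"))
}

#' @export
print.mav_grid <- function(x, ...) {
  cat(sprintf("<mav_grid> average MAV (mV) over %d session(s)\n",
              attr(x, "n_sessions")))
  print(round(unclass(x), 4L))
  invisible(x)
}

#' Grey-scale plot of a MAV grid
#'
#' Rows are intended motions, columns channels; darker means larger average
#' MAV. Normalization is per grid (global maximum scales to black).
#'
#' @param x a [mav_grid()].
#' @param ... passed to [graphics::image()].
#' @export
plot.mav_grid <- function(x, ...) {
  m <- unclass(x)
  z <- t(m[rev(seq_len(nrow(m))), , drop = FALSE])
  graphics::image(seq_len(ncol(m)), seq_len(nrow(m)), z,
                  col = grDevices::grey.colors(64, start = 1, end = 0),
                  zlim = c(0, max(m)), axes = FALSE, xlab = "channel",
                  ylab = "intended motion", ...)
  graphics::axis(1L, seq_len(ncol(m)), colnames(m))
  graphics::axis(2L, seq_len(nrow(m)), rev(rownames(m)), las = 2L)
  graphics::box()
  invisible(x)
}

#' Write a MAV grid as a labeled CSV matrix
#' @param g a [mav_grid()].
#' @param path output CSV path.
#' @export
write_mav_grid <- function(g, path) {
  utils::write.csv(as.data.frame(unclass(g)), path, row.names = TRUE)
  invisible(path)
}

#' Per-motion channel-independence score
#'
#' Quantifies how well each motion's designated channel is dominated by its
#' intended motion: for motion `m` with designated channel `c(m)`, the
#' score is `grid[m, c(m)] / max over other motions m' of grid[m', c(m)]`.
#' Scores above 1 mean amplitude-based control could separate that motion;
#' scores at or below 1 mean the channel is coupled. An all-zero column
#' gives `NA`; a column active only for its intended motion gives `Inf`.
#'
#' @param g a [mav_grid()].
#' @param motion_map channel -> motion map; defaults to the one stored in
#'   the grid.
#' @return named numeric vector, one score per motion.
#' @export
independence_score <- function(g, motion_map = attr(g, "motion_map")) {
  if (is.null(motion_map))
    stop("config error: independence_score needs a motion_map")
  m <- unclass(g)
  chan_of <- stats::setNames(names(motion_map), motion_map)
  vapply(rownames(m), function(mo) {
    col <- m[, chan_of[[mo]]]
    own <- col[[mo]]
    rest <- max(col[setdiff(names(col), mo)])
    if (own == 0 && rest == 0) NA_real_
    else if (rest == 0) Inf
    else own / rest
  }, numeric(1L))
}
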