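#' Default motion-by-channel coupling matrix
#'
#' Steady-state envelope amplitudes (mV, rows = motions, columns = channels)
#' emulating the coupled-sEMG situation after TMR in which amplitude-only
#' control fails. Each motion's designated channel carries a 0.30 mV
#' envelope (0.15 mV for wrist rotation, whose reinnervated site is weaker),
#' the anatomically paired channels are strongly co-activated at 0.8 of the
#' column diagonal (hand close with elbow flexion across the two biceps
#' heads; hand open with elbow extension across the two triceps heads), and
#' every remaining off-diagonal entry carries 0.2 of the column diagonal as
#' background co-contraction.
#'
#' @param diag_mv designated-channel envelope amplitudes in mV, one per
#'   motion in channel order.
#' @param strong,weak coupling fractions for paired and background
#'   co-activation.
#' @return 5 x 5 numeric matrix with motion row names and channel column
#'   names.
#' @export
default_coupling <- function(diag_mv = c(0.30, 0.30, 0.15, 0.30, 0.30),
                             strong = 0.8, weak = 0.2) {
  motions <- default_motions()
  channels <- paste0("Ch", 1:5)
  m <- outer(rep(1, 5L), diag_mv) * weak
  diag(m) <- diag_mv
  pairs <- rbind(c(1L, 4L), c(4L, 1L), c(2L, 5L), c(5L, 2L))
  m[pairs] <- strong * diag_mv[pairs[, 2L]]
  dimnames(m) <- list(motions, channels)
  m
}

#' Simulator configuration
#'
#' Describes the synthetic coupled-sEMG generator: each channel is an
#' amplitude envelope multiplying a unit-RMS band-limited Gaussian carrier,
#' plus white baseline noise. Envelopes ramp linearly over `transient_s`
#' at motion onset, hold at `level x coupling[motion, channel]`, and decay
#' over `transient_s` after the hold, so the recording contains the
#' transient and steady states the post-processing must discriminate.
#'
#' @param fs sampling rate in Hz (default 1860, the real-time control rate).
#' @param motions motion labels (default the five-motion scheme).
#' @param channel_labels channel names, same length as motions.
#' @param coupling motions x channels envelope matrix in mV; defaults to
#'   [default_coupling()].
#' @param transient_s onset/offset ramp duration in seconds (default 0.4).
#' @param noise_mv baseline white-noise RMS in mV (default 0.02, > 0).
#' @param carrier_band carrier band edges in Hz (default 80-400).
#' @param seed optional integer; when set, [simulate_emg()] is fully
#'   reproducible and leaves the caller's RNG state untouched.
#' @return a `sim_config` object.
#' @export
sim_config <- function(fs = 1860, motions = default_motions(),
                       channel_labels = paste0("Ch", seq_along(motions)),
                       coupling = default_coupling(), transient_s = 0.4,
                       noise_mv = 0.02, carrier_band = c(80, 400),
                       seed = NULL) {
  coupling <- as.matrix(coupling)
  if (any(coupling < 0)) stop("parameter error: coupling entries must be >= 0")
  if (transient_s < 0) stop("parameter error: transient_s must be >= 0")
  if (noise_mv <= 0) stop("parameter error: noise_mv must be > 0")
  if (nrow(coupling) != length(motions) ||
      ncol(coupling) != length(channel_labels))
    stop("parameter error: coupling must be motions x channels")
  dimnames(coupling) <- list(motions, channel_labels)
  structure(list(fs = fs, motions = motions,
                 channel_labels = channel_labels, coupling = coupling,
                 transient_s = transient_s, noise_mv = noise_mv,
                 carrier_band = carrier_band, seed = seed),
            class = "sim_config")
}

#' Motion schedule (simulation ground truth)
#'
#' Ordered motion attempts: each entry ramps up at `onset_s` over the
#' configured transient duration, holds for `hold_s` at `level` times the
#' configured envelope, then decays. `REST` entries are implicit: any time
#' not covered by an entry is rest. Entries must be chronological and
#' non-overlapping (the decay tail may overlap the next ramp, as when a
#' subject switches directly between motions).
#'
#' @param motion character vector of motion labels.
#' @param onset_s numeric vector of ramp-start times in seconds.
#' @param hold_s numeric vector of steady-hold durations in seconds.
#' @param level contraction level multipliers (> = 0), default 1.
#' @return a `motion_schedule` data.frame.
#' @export
motion_schedule <- function(motion, onset_s, hold_s, level = 1) {
  n <- length(motion)
  level <- rep_len(level, n)
  if (any(level < 0)) stop("parameter error: negative contraction level")
  if (any(hold_s < 0) || any(onset_s < 0))
    stop("parameter error: negative onset or hold")
  if (is.unsorted(onset_s, strictly = TRUE))
    stop("parameter error: entries must be chronological")
  sched <- data.frame(motion = motion, onset_s = onset_s, hold_s = hold_s,
                      level = level, stringsAsFactors = FALSE)
  class(sched) <- c("motion_schedule", "data.frame")
  sched
}

#' Default assessment schedule
#'
#' One attempt per motion, each held for about 5 s at a moderate level of
#' effort with a rest between attempts — the weekly-assessment protocol
#' shape used to probe coupling.
#'
#' @param motions motion labels in the order attempted.
#' @param hold_s steady-hold duration (default 5 s).
#' @param rest_s rest between attempts (default 10 s).
#' @param transient_s ramp duration, used to space entries (default 0.4 s).
#' @param lead_s rest before the first attempt (default 1 s).
#' @return a [motion_schedule()].
#' @export
assessment_schedule <- function(motions = default_motions(), hold_s = 5,
                                rest_s = 10, transient_s = 0.4,
                                lead_s = 1) {
  span <- 2 * transient_s + hold_s + rest_s
  motion_schedule(motions,
                  onset_s = lead_s + span * (seq_along(motions) - 1L),
                  hold_s = hold_s)
}

# Trapezoidal envelope on the simulation time grid (seconds -> level).
ramp_envelope <- function(t, onset, transient, hold) {
  up_end <- onset + transient
  hold_end <- up_end + hold
  down_end <- hold_end + transient
  e <- numeric(length(t))
  if (transient > 0) {
    i <- t >= onset & t < up_end
    e[i] <- (t[i] - onset) / transient
    i <- t >= hold_end & t < down_end
    e[i] <- 1 - (t[i] - hold_end) / transient
  }
  e[t >= up_end & t < hold_end] <- 1
  e
}

#' Simulate a coupled multichannel sEMG recording
#'
#' Each channel is `envelope(t) * carrier(t) + noise(t)`: the carrier is an
#' independent unit-RMS Gaussian process band-limited to the configured
#' band, the envelope sums the trapezoidal contributions of every scheduled
#' motion through the coupling matrix, and the baseline noise is white
#' Gaussian with RMS `noise_mv`. During a steady hold the expected MAV of a
#' channel with envelope amplitude `a` is `sqrt(a^2 + noise^2) * sqrt(2/pi)`
#' (the mean absolute value of a Gaussian). Ground-truth annotations mark
#' every ramp as `transient` and every hold as `steady`.
#'
#' @param cfg a [sim_config()].
#' @param sched a [motion_schedule()]; every motion must exist in the
#'   coupling matrix.
#' @param duration override total duration in seconds; defaults to the end
#'   of the last decay plus one second of trailing rest.
#' @return an annotated [emg_recording] with the channel -> motion map
#'   taken from the configuration.
#' @export
simulate_emg <- function(cfg, sched, duration = NULL) {
  if (!all(sched$motion %in% cfg$motions))
    stop("parameter error: schedule motion missing from coupling matrix: ",
         paste(setdiff(sched$motion, cfg$motions), collapse = ", "))
  ends <- sched$onset_s + 2 * cfg$transient_s + sched$hold_s
  if (nrow(sched) > 1L &&
      any(sched$onset_s[-1L] < (sched$onset_s + cfg$transient_s +
                                sched$hold_s)[-nrow(sched)]))
    stop("parameter error: overlapping schedule entries")
  if (is.null(duration)) duration <- max(ends) + 1
  n <- as.integer(round(duration * cfg$fs))
  if (!is.null(cfg$seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                        globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(cfg$seed)
  }
  t <- (seq_len(n) - 1L) / cfg$fs
  nc <- length(cfg$channel_labels)
  env <- matrix(0, n, nc)
  for (i in seq_len(nrow(sched))) {
    shape <- ramp_envelope(t, sched$onset_s[i], cfg$transient_s,
                           sched$hold_s[i])
    amp <- sched$level[i] * cfg$coupling[sched$motion[i], ]
    env <- env + outer(shape, amp)
  }
  x <- matrix(0, n, nc, dimnames = list(NULL, cfg$channel_labels))
  for (j in seq_len(nc)) {
    carrier <- bandpass_matrix(matrix(stats::rnorm(n), ncol = 1L), cfg$fs,
                               cfg$carrier_band[1L], cfg$carrier_band[2L])
    carrier <- carrier / stats::sd(carrier)
    x[, j] <- env[, j] * carrier + stats::rnorm(n, sd = cfg$noise_mv)
  }
  s <- function(sec) as.integer(round(pmin(pmax(sec, 0), duration) * cfg$fs))
  next_onset <- c(sched$onset_s[-1L], Inf)
  ann <- do.call(rbind, lapply(seq_len(nrow(sched)), function(i) {
    on <- sched$onset_s[i]; tr <- cfg$transient_s; h <- sched$hold_s[i]
    # decay clipped at the next onset so annotations never overlap when a
    # subject switches directly from one motion to the next
    data.frame(motion = sched$motion[i],
               start = s(c(on, on + tr, on + tr + h)),
               end = s(c(on + tr, on + tr + h,
                         min(on + 2 * tr + h, next_onset[i]))),
               phase = c("transient", "steady", "transient"),
               stringsAsFactors = FALSE)
  }))
  ann <- ann[ann$end > ann$start, ]
  rownames(ann) <- NULL
  emg_recording(x, cfg$fs, cfg$channel_labels,
                motion_map = stats::setNames(cfg$motions,
                                             cfg$channel_labels),
                annotations = ann)
}

#' Read simulator configuration / motion schedule from YAML
#'
#' `read_sim_config()` accepts keys `fs`, `motions`, `channel_labels`,
#' `coupling` (list of rows), `transient_s`, `noise_mv`, `carrier_band`,
#' `seed`; missing keys take the [sim_config()] defaults.
#' `read_motion_schedule()` expects a list of entries with `motion`,
#' `onset_s`, `hold_s` and optional `level`.
#'
#' @param path YAML file.
#' @return a [sim_config()] or [motion_schedule()].
#' @export
read_sim_config <- function(path) {
  y <- yaml::read_yaml(path)
  motions <- y$motions %||% default_motions()
  cfg <- sim_config(
    fs = y$fs %||% 1860,
    motions = motions,
    channel_labels = y$channel_labels %||% paste0("Ch",
                                                  seq_along(motions)),
    coupling = if (!is.null(y$coupling))
      do.call(rbind, y$coupling) else default_coupling(),
    transient_s = y$transient_s %||% 0.4,
    noise_mv = y$noise_mv %||% 0.02,
    carrier_band = unlist(y$carrier_band %||% c(80, 400)),
    seed = y$seed)
  cfg
}

#' @rdname read_sim_config
#' @export
read_motion_schedule <- function(path) {
  y <- yaml::read_yaml(path)
  entries <- y$entries %||% y
  motion_schedule(
    motion = vapply(entries, `[[`, character(1L), "motion"),
    onset_s = vapply(entries, `[[`, numeric(1L), "onset_s"),
    hold_s = vapply(entries, `[[`, numeric(1L), "hold_s"),
    level = vapply(entries, function(e) e$level %||% 1, numeric(1L)))
}

#' Simulate a classifier training session
#'
#' Realizes a [session_plan()]: the motions are attempted back-to-back,
#' each segment ramping up at its start and holding to the segment end
#' (the decay spills into the head of the next segment, which the labeling
#' protocol cuts anyway). The recording is exactly the plan duration: 35 s
#' for the default five-motion, 7 s-per-motion plan.
#'
#' @param cfg a [sim_config()].
#' @param plan a [session_plan()].
#' @return an annotated [emg_recording] of the plan duration.
#' @export
make_training_session <- function(cfg, plan) {
  k <- length(plan$motion_order)
  onsets <- plan$per_motion_s * (seq_len(k) - 1L)
  sched <- motion_schedule(plan$motion_order, onsets,
                           hold_s = plan$per_motion_s - cfg$transient_s)
  simulate_emg(cfg, sched, duration = plan$per_motion_s * k)
}
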