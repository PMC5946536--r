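#' Score a decision stream against simulation ground truth
#'
#' Classifies every analysis window as steady, transient or rest from the
#' annotated ground-truth intervals and computes offline control metrics.
#' A window overlapping any transient interval, or straddling an interval
#' boundary, counts as transient (conservative, since the transient state
#' is where misclassification concentrates); a window fully inside a steady
#' hold is steady; a window touching no interval is rest.
#'
#' Metrics: `steady_accuracy` is the fraction of steady windows whose
#' output equals the held motion; `transient_error_rate` is the fraction of
#' transient windows emitting a *wrong* motion (neither `STILL` nor a
#' motion active in that window); `still_rate_transient` is the fraction of
#' transient windows emitting `STILL`. The confusion table counts steady
#' windows by true motion (rows) against outputs (motions plus `STILL`).
#'
#' @param ds a `decision_stream` from [run_pipeline()] (needs attributes
#'   `fs` and `window_samples`, or pass them explicitly).
#' @param truth an annotated [emg_recording] (the simulated input) or its
#'   annotations data.frame.
#' @param fs,window_samples time base of the stream; default from `ds`.
#' @return a `stream_metrics` object: list with `steady_accuracy`,
#'   `transient_error_rate`, `still_rate_transient`, `confusion`,
#'   `n_windows` (named total/steady/transient/rest counts).
#' @export
score_stream <- function(ds, truth, fs = attr(ds, "fs"),
                         window_samples = attr(ds, "window_samples")) {
  ann <- if (inherits(truth, "emg_recording")) truth$annotations else truth
  if (is.null(ann)) stop("parameter error: truth carries no annotations")
  if (is.null(fs) || is.null(window_samples))
    stop("parameter error: stream time base (fs, window_samples) unknown")
  motions <- unique(ann$motion)
  n <- nrow(ds)
  phase <- character(n)
  steady_motion <- rep(NA_character_, n)
  allowed <- vector("list", n)
  st <- ann[ann$phase == "steady", , drop = FALSE]
  tr <- ann[ann$phase == "transient", , drop = FALSE]
  for (i in seq_len(n)) {
    w0 <- ds$window_start[i]
    w1 <- w0 + window_samples            # half-open [w0, w1)
    over_st <- st[st$start < w1 & st$end > w0, , drop = FALSE]
    over_tr <- tr[tr$start < w1 & tr$end > w0, , drop = FALSE]
    inside_st <- over_st[over_st$start <= w0 & over_st$end >= w1, ,
                         drop = FALSE]
    if (nrow(over_tr) || (nrow(over_st) && !nrow(inside_st))) {
      phase[i] <- "transient"
      allowed[[i]] <- unique(c(over_tr$motion, over_st$motion))
    } else if (nrow(inside_st)) {
      phase[i] <- "steady"
      steady_motion[i] <- inside_st$motion[1L]
    } else {
      phase[i] <- "rest"
    }
  }
  is_st <- phase == "steady"
  is_tr <- phase == "transient"
  out <- ds$output
  steady_accuracy <- if (any(is_st))
    mean(out[is_st] == steady_motion[is_st]) else NA_real_
  wrong_tr <- vapply(which(is_tr), function(i)
    out[i] != STILL && !(out[i] %in% allowed[[i]]), logical(1L))
  transient_error_rate <- if (any(is_tr)) mean(wrong_tr) else NA_real_
  still_rate_transient <- if (any(is_tr))
    mean(out[is_tr] == STILL) else NA_real_
  confusion <- table(
    truth = factor(steady_motion[is_st], levels = motions),
    output = factor(out[is_st], levels = c(motions, STILL)))
  structure(list(steady_accuracy = steady_accuracy,
                 transient_error_rate = transient_error_rate,
                 still_rate_transient = still_rate_transient,
                 confusion = confusion,
                 n_windows = c(total = n, steady = sum(is_st),
                               transient = sum(is_tr),
                               rest = sum(phase == "rest"))),
            class = "stream_metrics")
}

#' @export
print.stream_metrics <- function(x, ...) {
  cat("<stream_metrics>\n")
  cat(sprintf("  steady accuracy:       %.3f  (%d steady windows)\n",
              x$steady_accuracy, x$n_windows[["steady"]]))
  cat(sprintf("  transient error rate:  %.3f  (%d transient windows)\n",
              x$transient_error_rate, x$n_windows[["transient"]]))
  cat(sprintf("  STILL rate, transient: %.3f\n", x$still_rate_transient))
  invisible(x)
}

#' ARAT condition totals from the motivating TMR case study
#'
#' Published total scores of the modified Action Research Arm Test (eight
#' tasks, each scored 0-3 and averaged over three trials) for one
#' transhumeral TMR amputee under seven control conditions: raw pattern
#' recognition (`Control`), majority vote with queue lengths 3/5/10
#' (`L3`/`L5`/`L10`) and MAV threshold switches with the lower/standard/
#' higher threshold sets (`LT`/`ST`/`HT`). These observer-rated totals are
#' inputs to the score arithmetic, not quantities the package computes.
#'
#' @return named numeric vector of condition totals.
#' @export
arat_condition_totals <- function() {
  c(Control = 9.3, L3 = 11, L5 = 11, L10 = 13,
    LT = 14.7, ST = 16, HT = 14.7)
}

#' Percentage increase of condition totals over a baseline
#'
#' `100 * (total - baseline_total) / baseline_total` for every condition.
#'
#' @param scores named numeric vector of per-condition totals (including
#'   the baseline).
#' @param baseline name of the baseline condition (default `"Control"`).
#' @return named numeric vector of percentages for the non-baseline
#'   conditions.
#' @export
percent_increase <- function(scores, baseline = "Control") {
  if (!baseline %in% names(scores))
    stop("parameter error: baseline '", baseline, "' not among scores")
  b <- scores[[baseline]]
  if (!is.finite(b) || b <= 0)
    stop("parameter error: baseline total must be > 0")
  rest <- scores[setdiff(names(scores), baseline)]
  100 * (rest - b) / b
}

#' Aggregate per-task ARAT trial scores into condition totals
#'
#' Each task is scored 0-3 per trial; the final task score is the mean of
#' its trials and a condition's total is the sum of final task scores.
#'
#' @param scores data.frame with columns `condition`, `task`, `score`
#'   (one row per trial; scores in 0..3).
#' @return named numeric vector of condition totals.
#' @export
arat_totals <- function(scores) {
  if (!all(c("condition", "task", "score") %in% names(scores)))
    stop("format error: need columns condition, task, score")
  if (any(!scores$score %in% 0:3))
    stop("format error: task scores must be integers in 0..3")
  per_task <- stats::aggregate(score ~ condition + task, scores, mean)
  tot <- stats::aggregate(score ~ condition, per_task, sum)
  stats::setNames(tot$score, tot$condition)
}
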