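#' Event detection configuration
#'
#' @param w odd moving-average window length in frames.
#' @param threshold probability threshold; frames with smoothed value
#'   strictly above it seed events. `NULL` means "select from training data"
#'   (see [select_specificity_threshold()]); [detect_events()] itself
#'   requires a concrete value.
#' @param min_duration minimum event length in frames (applied after
#'   merging).
#' @param merge_gap events separated by at most this many frames are merged.
#' @return A list of class `event_detection_config`.
#' @export
event_detection_config <- function(w = 5L, threshold = NULL,
                                   min_duration = 1L, merge_gap = 0L) {
  w <- as.integer(w)
  if (w < 1L || w %% 2L == 0L) stop_invalid("'w' must be odd and >= 1")
  if (!is.null(threshold))
    check_number(threshold, "threshold", min = 0, max = 1)
  min_duration <- as.integer(min_duration)
  merge_gap <- as.integer(merge_gap)
  if (min_duration < 1L) stop_invalid("'min_duration' must be >= 1")
  if (merge_gap < 0L) stop_invalid("'merge_gap' must be >= 0")
  structure(list(w = w, threshold = threshold, min_duration = min_duration,
                 merge_gap = merge_gap), class = "event_detection_config")
}

#' Default detection config for a given frame rate
#'
#' Window of 5 frames, minimum event duration 0.3 s, merge gap 0.5 s,
#' threshold left to specificity-first selection on training data.
#'
#' @param fps frames per second.
#' @param threshold optional concrete threshold.
#' @export
default_detection_config <- function(fps, threshold = NULL) {
  event_detection_config(w = 5L, threshold = threshold,
                         min_duration = max(1L, round(0.3 * fps)),
                         merge_gap = round(0.5 * fps))
}

#' Centered moving average with shrinking edges
#'
#' @param trace a [probability_trace()] or numeric vector.
#' @param w odd window length, at most the trace length; at the edges the
#'   window shrinks to the available frames. `w = 1` is the identity.
#' @return Numeric vector of the same length (a [probability_trace()] when
#'   the input was one).
#' @export
moving_average <- function(trace, w = 5L) {
  x <- trace_values(trace)
  w <- as.integer(w)
  if (w < 1L || w %% 2L == 0L) stop_invalid("'w' must be odd and >= 1")
  if (w > length(x)) stop_invalid("'w' exceeds trace length")
  half <- (w - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  n <- length(x)
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  out <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  if (inherits(trace, "probability_trace"))
    probability_trace(pmin(pmax(out, 0), 1), trace$fps, trace$video_id)
  else out
}

#' Bound attack events in a smoothed probability trace
#'
#' Three rules, in order: (1) maximal runs of frames strictly above the
#' threshold become candidate events; (2) candidates separated by at most
#' `merge_gap` frames are merged; (3) merged candidates shorter than
#' `min_duration` frames are discarded. Merging precedes the duration filter
#' so fragmented bouts are not discarded piecewise.
#'
#' @param trace smoothed [probability_trace()] (or numeric vector plus
#'   `fps`).
#' @param config an [event_detection_config()] with a concrete `threshold`.
#' @param fps frame rate, required when `trace` is a bare vector.
#' @return An [event_set()] of 0-based closed frame intervals.
#' @export
detect_events <- function(trace, config, fps = NULL) {
  x <- trace_values(trace)
  if (inherits(trace, "probability_trace")) fps <- trace$fps
  if (is.null(fps)) stop_invalid("'fps' required for a bare numeric trace")
  if (is.null(config$threshold))
    stop_invalid("config carries no threshold; select one first")
  if (any(x < 0 | x > 1)) stop_invalid("trace values must lie in [0, 1]")
  above <- x > config$threshold
  if (!any(above))
    return(event_set(fps = fps, n_frames = length(x)))
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  s <- starts[r$values] - 1L   # 0-based
  e <- ends[r$values] - 1L
  # merge runs separated by <= merge_gap
  if (length(s) > 1L) {
    ms <- s[1L]; me <- e[1L]; out_s <- integer(); out_e <- integer()
    for (i in 2L:length(s)) {
      if (s[i] - me - 1L <= config$merge_gap) me <- e[i]
      else { out_s <- c(out_s, ms); out_e <- c(out_e, me); ms <- s[i]; me <- e[i] }
    }
    s <- c(out_s, ms); e <- c(out_e, me)
  }
  keep <- (e - s + 1L) >= config$min_duration
  event_set(s[keep], e[keep], fps = fps, n_frames = length(x))
}

#' Cumulative attack duration of an event set
#'
#' The primary resident-intruder readout: total seconds covered by detected
#' attack events, `sum((end - start + 1) / fps)` over closed frame intervals.
#'
#' @param events an [event_set()].
#' @return Seconds (0 for an empty set).
#' @export
cumulative_attack_duration <- function(events) {
  if (!inherits(events, "event_set")) stop_invalid("not an event_set")
  if (!nrow(events)) return(0)
  sum(events$end_frame - events$start_frame + 1) / attr(events, "fps")
}

#' Session summary from detected events
#'
#' @param events an [event_set()].
#' @param video_id session identifier.
#' @param config the [event_detection_config()] used (echoed).
#' @return A list of class `session_summary`: video id, cumulative attack
#'   duration (s), number of events, config.
#' @export
session_summary <- function(events, video_id = NULL, config = NULL) {
  structure(list(video_id = video_id,
                 cumulative_attack_duration_s =
                   cumulative_attack_duration(events),
                 n_events = nrow(events),
                 config = config),
            class = "session_summary")
}

#' @export
print.session_summary <- function(x, ...) {
  cat(sprintf("session '%s': %d attack events, cumulative duration %.2f s\n",
              x$video_id %||% "?", x$n_events,
              x$cumulative_attack_duration_s))
  invisible(x)
}

#' Precision/recall/F1 of detected events against ground truth
#'
#' A predicted event matches a truth event when their intersection covers at
#' least `min_overlap` of the truth event; matching is one-to-one and greedy
#' in temporal order. Empty sets follow the conventions precision = 1 with no
#' predictions and recall = 1 with no truth.
#'
#' @param predicted,truth [event_set()] objects on the same frame axis.
#' @param min_overlap required fraction of the truth event covered, in
#'   `(0, 1]`.
#' @return A list: `precision`, `recall`, `f1`, `n_matched`.
#' @export
event_match_metrics <- function(predicted, truth, min_overlap = 0.5) {
  check_number(min_overlap, "min_overlap", min = 0, max = 1,
               strict_min = TRUE)
  np <- nrow(predicted); nt <- nrow(truth)
  used <- logical(np)
  matched_truth <- 0L
  for (i in seq_len(nt)) {
    tlen <- truth$end_frame[i] - truth$start_frame[i] + 1L
    for (j in seq_len(np)) {
      if (used[j]) next
      ov <- min(truth$end_frame[i], predicted$end_frame[j]) -
        max(truth$start_frame[i], predicted$start_frame[j]) + 1L
      if (ov >= min_overlap * tlen && ov > 0L) {
        used[j] <- TRUE
        matched_truth <- matched_truth + 1L
        break
      }
    }
  }
  precision <- if (np == 0L) 1 else sum(used) / np
  recall <- if (nt == 0L) 1 else matched_truth / nt
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  list(precision = precision, recall = recall, f1 = f1,
       n_matched = matched_truth)
}
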