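#' Frame-level ROC AUC (Mann-Whitney formulation)
#'
#' Equals the probability that a randomly chosen positive outranks a randomly
#' chosen negative, with ties counted 1/2. Invariant to strictly monotone
#' transforms of the scores.
#'
#' @param scores numeric score per frame (higher = more attack-like).
#' @param labels 0/1 per frame; both classes must be present.
#' @return AUC in `[0, 1]`.
#' @examples
#' roc_auc(c(0.9, 0.8, 0.4, 0.3), c(1, 0, 1, 0))  # 0.75
#' @export
roc_auc <- function(scores, labels) {
  scores <- trace_values(scores)
  labels <- as.integer(labels)
  if (length(scores) != length(labels) || !all(labels %in% c(0L, 1L)))
    stop_invalid("scores and 0/1 labels must have equal length")
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L)
    stop_invalid("both classes must be present to compute ROC AUC")
  r <- rank(scores)  # average ranks handle ties as 1/2 wins
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Specificity-first decision threshold
#'
#' Returns the smallest threshold (decision rule: `score > threshold` is a
#' detection) whose specificity on the given data reaches `min_specificity`,
#' i.e. the most sensitive operating point subject to a false-positive floor.
#' This mirrors a specificity-first operating policy for rare events, where
#' false positives are costlier than missed frames.
#'
#' @param scores numeric scores.
#' @param labels 0/1 labels, both classes present.
#' @param min_specificity required specificity in `(0, 1]` (0 is accepted and
#'   returns a threshold below all scores).
#' @return A list: `threshold`, achieved `specificity` and `sensitivity`.
#' @export
select_specificity_threshold <- function(scores, labels,
                                         min_specificity = 0.999) {
  scores <- trace_values(scores)
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L)) || length(scores) != length(labels))
    stop_invalid("scores and 0/1 labels must have equal length")
  if (min_specificity > 1)
    stop_invalid("min_specificity cannot exceed 1")
  neg <- scores[labels == 0L]; pos <- scores[labels == 1L]
  if (!length(neg) || !length(pos))
    stop_invalid("both classes must be present")
  cand <- c(min(scores) - 1, sort(unique(scores)))
  spec <- vapply(cand, function(th) mean(neg <= th), 0)
  ok <- which(spec >= min_specificity)
  th <- cand[ok[1L]]  # smallest qualifying threshold = max sensitivity
  list(threshold = th,
       specificity = spec[ok[1L]],
       sensitivity = mean(pos > th))
}

#' Duration-calibrated event threshold
#'
#' Chooses the detection threshold that makes the bounded events reproduce
#' the reference (human-scored) cumulative attack duration of the training
#' sessions as closely as possible: for each candidate threshold the full
#' smooth-and-detect chain runs on every training trace, and the threshold
#' minimizing the absolute log-ratio of total detected to total true
#' duration wins (ties go to the higher, more specific threshold). This is
#' the operating point for faithful duration scoring; use
#' [select_specificity_threshold()] instead when false positives must be
#' suppressed at the cost of sensitivity.
#'
#' @param traces list of [probability_trace()] objects for the training
#'   sessions.
#' @param truth_events list of ground-truth [event_set()] objects, parallel
#'   to `traces`.
#' @param config an [event_detection_config()] providing `w`, `merge_gap`,
#'   `min_duration` (its threshold field is ignored).
#' @param candidates candidate thresholds to scan.
#' @return A list: `threshold`, `detected_s`, `truth_s`, `ratio` at the
#'   selected threshold.
#' @export
select_duration_threshold <- function(traces, truth_events, config,
                                      candidates = seq(0.05, 0.95,
                                                       by = 0.05)) {
  if (length(traces) != length(truth_events) || !length(traces))
    stop_invalid("need parallel non-empty lists of traces and truth events")
  truth_s <- sum(vapply(truth_events, cumulative_attack_duration, 0))
  if (truth_s <= 0) stop_invalid("training sessions contain no true events")
  smoothed <- lapply(traces, moving_average, w = config$w)
  det <- vapply(candidates, function(th) {
    cfg <- event_detection_config(config$w, th, config$min_duration,
                                  config$merge_gap)
    sum(vapply(smoothed, function(tr)
      cumulative_attack_duration(detect_events(tr, cfg)), 0))
  }, 0)
  err <- abs(log(pmax(det, 1e-9) / truth_s))
  best <- which(err == min(err))
  best <- best[length(best)]  # tie-break: the more specific threshold
  list(threshold = candidates[best], detected_s = det[best],
       truth_s = truth_s, ratio = det[best] / truth_s)
}
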