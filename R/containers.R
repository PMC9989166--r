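#' Video session container
#'
#' Holds a grayscale (or RGB) frame sequence with its frame rate and, when
#' available, per-frame binary aggression labels. Frames are stored as a
#' numeric array on the 8-bit scale (0--255): `H x W x T` for grayscale or
#' `H x W x 3 x T` for RGB.
#'
#' @param frames numeric array, `H x W x T` (grayscale) or `H x W x 3 x T`.
#' @param fps frames per second (positive).
#' @param id optional character identifier.
#' @param labels optional integer vector of per-frame labels in \{0, 1\},
#'   one per frame.
#' @return An object of class `video_session`.
#' @export
video_session <- function(frames, fps, id = NULL, labels = NULL) {
  if (!is.array(frames) || !(length(dim(frames)) %in% c(3L, 4L)))
    stop_invalid("'frames' must be an H x W x T or H x W x 3 x T array")
  check_number(fps, "fps", min = 0, strict_min = TRUE)
  nt <- dim(frames)[length(dim(frames))]
  if (!is.null(labels)) {
    labels <- as.integer(labels)
    if (length(labels) != nt || !all(labels %in% c(0L, 1L)))
      stop_invalid("'labels' must be 0/1 with one entry per frame")
  }
  structure(list(frames = frames, fps = fps, id = id, labels = labels),
            class = "video_session")
}

#' @export
print.video_session <- function(x, ...) {
  d <- dim(x$frames)
  nt <- d[length(d)]
  cat(sprintf("video_session '%s': %d frames %dx%d @ %g fps (%.1f s)%s\n",
              x$id %||% "?", nt, d[1], d[2], x$fps, nt / x$fps,
              if (is.null(x$labels)) "" else
                sprintf(", %d labeled attack frames", sum(x$labels))))
  invisible(x)
}

n_frames <- function(video) {
  d <- dim(video$frames)
  d[length(d)]
}

#' Attack event set
#'
#' A set of non-overlapping closed frame intervals (0-based) marking attack
#' bouts, together with the frame rate needed to express them in seconds.
#'
#' @param start_frame,end_frame integer vectors of equal length; 0-based
#'   closed interval bounds with `start_frame <= end_frame`.
#' @param fps frames per second.
#' @param n_frames optional total frame count of the underlying session; when
#'   given, intervals must lie within `[0, n_frames - 1]`.
#' @return A data frame of class `event_set` with columns `start_frame`,
#'   `end_frame` and attributes `fps`, `n_frames`.
#' @export
event_set <- function(start_frame = integer(), end_frame = integer(),
                      fps, n_frames = NULL) {
  start_frame <- as.integer(start_frame)
  end_frame <- as.integer(end_frame)
  if (length(start_frame) != length(end_frame))
    stop_invalid("start/end vectors must have equal length")
  check_number(fps, "fps", min = 0, strict_min = TRUE)
  o <- order(start_frame)
  start_frame <- start_frame[o]; end_frame <- end_frame[o]
  if (any(start_frame < 0L)) stop_invalid("event frames must be >= 0")
  if (any(end_frame < start_frame)) stop_invalid("event end before start")
  if (length(start_frame) > 1L &&
      any(start_frame[-1L] <= end_frame[-length(end_frame)]))
    stop_invalid("event intervals overlap")
  if (!is.null(n_frames) && length(end_frame) &&
      max(end_frame) > n_frames - 1L)
    stop_invalid("event interval exceeds frame range")
  structure(data.frame(start_frame = start_frame, end_frame = end_frame),
            fps = fps, n_frames = n_frames,
            class = c("event_set", "data.frame"))
}

#' @export
print.event_set <- function(x, ...) {
  cat(sprintf("event_set: %d events @ %g fps, total %.2f s\n",
              nrow(x), attr(x, "fps"), cumulative_attack_duration(x)))
  if (nrow(x)) print.data.frame(x, ...)
  invisible(x)
}

# 0/1 indicator vector of length n from an event set.
events_to_indicator <- function(events, n) {
  lab <- integer(n)
  for (i in seq_len(nrow(events)))
    lab[(events$start_frame[i] + 1L):(events$end_frame[i] + 1L)] <- 1L
  lab
}

#' Per-frame attack probability trace
#'
#' @param p numeric vector of per-frame probabilities in `[0, 1]`.
#' @param fps frames per second.
#' @param video_id optional source video identifier.
#' @return Object of class `probability_trace`.
#' @export
probability_trace <- function(p, fps, video_id = NULL) {
  p <- as.numeric(p)
  if (anyNA(p) || any(p < 0) || any(p > 1))
    stop_invalid("probabilities must lie in [0, 1]")
  check_number(fps, "fps", min = 0, strict_min = TRUE)
  structure(list(p = p, fps = fps, video_id = video_id),
            class = "probability_trace")
}

#' @export
print.probability_trace <- function(x, ...) {
  cat(sprintf("probability_trace '%s': %d frames @ %g fps, mean p = %.4f\n",
              x$video_id %||% "?", length(x$p), x$fps, mean(x$p)))
  invisible(x)
}

trace_values <- function(trace) {
  if (inherits(trace, "probability_trace")) trace$p else as.numeric(trace)
}
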