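#' Convert an RGB frame to grayscale
#'
#' Uses the ITU-R BT.601 luma weights (0.299, 0.587, 0.114), the standard
#' convention for 8-bit video. A single-channel input passes through
#' unchanged.
#'
#' @param frame numeric matrix (`H x W`, already grayscale) or array
#'   (`H x W x 3`, RGB on the 0--255 scale).
#' @return `H x W` numeric matrix.
#' @examples
#' red <- array(0, c(2, 2, 3)); red[, , 1] <- 255
#' round(to_grayscale(red))  # 76
#' @export
to_grayscale <- function(frame) {
  if (is.matrix(frame)) return(frame)
  if (is.array(frame) && length(dim(frame)) == 3L) {
    if (dim(frame)[3] == 1L) return(frame[, , 1L])
    if (dim(frame)[3] == 3L)
      return(0.299 * frame[, , 1L] + 0.587 * frame[, , 2L] +
             0.114 * frame[, , 3L])
  }
  stop_invalid("expected an H x W matrix or H x W x 3 RGB array")
}

# grayscale frames of a session as an H x W x T array
session_gray <- function(video) {
  d <- dim(video$frames)
  if (length(d) == 3L) return(video$frames)
  nt <- d[4]
  out <- array(0, c(d[1], d[2], nt))
  for (t in seq_len(nt)) out[, , t] <- to_grayscale(video$frames[, , , t])
  out
}

#' Build temporal-difference channel stacks
#'
#' Rebuilds the classifier input not as color channels but as motion
#' channels: channel 1 is the current grayscale frame, and channel `1 + i` is
#' the signed difference between the current frame and the frame `lags[i]`
#' steps earlier. Frames earlier than a lag get a zero-filled channel, so a
#' video's first frame always has all-zero difference channels.
#'
#' @param gray_frames `H x W x T` numeric array of grayscale frames.
#' @param lags strictly increasing positive integer lags (default `c(1, 2)`).
#' @return `H x W x C x T` array with `C = length(lags) + 1`.
#' @export
build_difference_stack <- function(gray_frames, lags = c(1L, 2L)) {
  if (!is.array(gray_frames) || length(dim(gray_frames)) != 3L ||
      dim(gray_frames)[3] < 1L)
    stop_invalid("'gray_frames' must be a non-empty H x W x T array")
  lags <- as.integer(lags)
  if (length(lags) < 1L || any(lags < 1L) || any(diff(lags) <= 0))
    stop_invalid("'lags' must be strictly increasing integers >= 1")
  d <- dim(gray_frames); h <- d[1]; w <- d[2]; nt <- d[3]
  out <- array(0, c(h, w, length(lags) + 1L, nt))
  out[, , 1L, ] <- gray_frames
  for (i in seq_along(lags)) {
    l <- lags[i]
    if (l < nt)
      out[, , i + 1L, (l + 1L):nt] <-
        gray_frames[, , (l + 1L):nt] - gray_frames[, , 1L:(nt - l)]
  }
  out
}
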