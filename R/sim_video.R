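#' Parameters for the synthetic resident-intruder video generator
#'
#' Defaults emulate the defining features of the training recordings: a
#' top-view arena with a light-coated resident and a dark-coated intruder on a
#' mid-gray background, and rare short attack bouts during which the two
#' animals are in close contact and move with high-frequency jitter. With the
#' default bout rate and duration, the expected fraction of attack-labeled
#' frames is about 1.7%, i.e. attacks are on the order of 1% of the footage.
#'
#' @param width_px,height_px frame size in pixels.
#' @param fps frames per second.
#' @param duration_s session length in seconds.
#' @param resident_intensity,intruder_intensity,background_intensity 8-bit
#'   grayscale levels; must satisfy resident > background > intruder.
#' @param blob_radius_px animal blob radius in pixels.
#' @param walk_speed baseline locomotion, px per frame.
#' @param attack_rate expected attack bouts per minute (Poisson rate).
#' @param bout_duration_s length-2 numeric `(min, max)` of uniform bout
#'   durations in seconds.
#' @param attack_jitter per-frame high-frequency displacement (px, sd) applied
#'   to both animals during a bout.
#' @param contact_distance_px maximum center-to-center separation during a
#'   bout.
#' @param noise_sd additive Gaussian pixel noise (8-bit units).
#' @param min_bouts minimum number of scheduled bouts (ignored when
#'   `attack_rate = 0`). The default of 1 emulates the selection of training
#'   recordings that contain at least one aggression event; set to 0 for an
#'   unconditioned Poisson schedule.
#' @param seed random seed.
#' @return A list of class `sim_video_params`.
#' @export
sim_video_params <- function(width_px = 64L, height_px = 64L, fps = 15,
                             duration_s = 120,
                             resident_intensity = 230,
                             intruder_intensity = 40,
                             background_intensity = 130,
                             blob_radius_px = 5,
                             walk_speed = 1.5,
                             attack_rate = 0.5,
                             bout_duration_s = c(1, 3),
                             attack_jitter = 3,
                             contact_distance_px = 8,
                             noise_sd = 4,
                             min_bouts = 1L,
                             seed = 1L) {
  p <- list(width_px = as.integer(width_px), height_px = as.integer(height_px),
            fps = fps, duration_s = duration_s,
            resident_intensity = resident_intensity,
            intruder_intensity = intruder_intensity,
            background_intensity = background_intensity,
            blob_radius_px = blob_radius_px, walk_speed = walk_speed,
            attack_rate = attack_rate, bout_duration_s = bout_duration_s,
            attack_jitter = attack_jitter,
            contact_distance_px = contact_distance_px,
            noise_sd = noise_sd, min_bouts = as.integer(min_bouts),
            seed = seed)
  validate_sim_video_params(p)
  class(p) <- "sim_video_params"
  p
}

validate_sim_video_params <- function(p) {
  check_number(p$width_px, "width_px", min = 8)
  check_number(p$height_px, "height_px", min = 8)
  check_number(p$fps, "fps", min = 0, strict_min = TRUE)
  check_number(p$duration_s, "duration_s", min = 0, strict_min = TRUE)
  check_number(p$attack_rate, "attack_rate", min = 0)
  check_number(p$bout_duration_s, "bout_duration_s", min = 0,
               strict_min = TRUE, len = 2L)
  if (p$bout_duration_s[2] < p$bout_duration_s[1])
    stop_invalid("bout_duration_s must be (min, max) with min <= max")
  check_number(p$walk_speed, "walk_speed", min = 0)
  check_number(p$attack_jitter, "attack_jitter", min = 0)
  check_number(p$contact_distance_px, "contact_distance_px", min = 0)
  check_number(p$noise_sd, "noise_sd", min = 0)
  check_number(p$min_bouts, "min_bouts", min = 0)
  if (!(p$resident_intensity > p$background_intensity &&
        p$background_intensity > p$intruder_intensity))
    stop_invalid("need resident_intensity > background_intensity > intruder_intensity")
  invisible(p)
}

# Poisson-process bout starts, thinned so bouts never overlap (0.5 s guard
# gap keeps distinct events separable by the detector's merge rule). With
# min_bouts > 0 the schedule is conditioned on at least that many accepted
# bouts (zero-truncated Poisson via rejection), emulating recordings selected
# for containing aggression events.
schedule_bouts <- function(rate_per_min, dur_range, total_s, guard_s = 0.5,
                           min_bouts = 0L) {
  if (rate_per_min <= 0)
    return(data.frame(start_s = numeric(), end_s = numeric()))
  for (try in seq_len(1000L)) {
    out <- schedule_bouts_once(rate_per_min, dur_range, total_s, guard_s)
    if (nrow(out) >= min_bouts) return(out)
  }
  stop_invalid("could not schedule the requested minimum number of bouts")
}

schedule_bouts_once <- function(rate_per_min, dur_range, total_s, guard_s) {
  n_cand <- stats::rpois(1L, rate_per_min * total_s / 60)
  if (n_cand == 0L) return(data.frame(start_s = numeric(), end_s = numeric()))
  starts <- sort(stats::runif(n_cand, 0, total_s))
  durs <- stats::runif(n_cand, dur_range[1], dur_range[2])
  keep_s <- numeric(); keep_e <- numeric(); last_end <- -Inf
  for (i in seq_len(n_cand)) {
    if (starts[i] > last_end + guard_s && starts[i] + durs[i] <= total_s) {
      keep_s <- c(keep_s, starts[i])
      keep_e <- c(keep_e, starts[i] + durs[i])
      last_end <- starts[i] + durs[i]
    }
  }
  data.frame(start_s = keep_s, end_s = keep_e)
}

# Project a point onto the admissible box [r, W-r] x [r, H-r].
clamp_pos <- function(pos, w, h, r) {
  c(min(max(pos[1], r), w - r), min(max(pos[2], r), h - r))
}

#' Simulate a resident-intruder session video with ground-truth bouts
#'
#' Two blobs (light resident, dark intruder) perform independent bounded
#' random walks with reflecting arena edges; during scheduled attack bouts the
#' intruder is kept within `contact_distance_px` of the resident and both
#' receive high-frequency jitter. Blobs are rendered as discs with smooth
#' (logistic) edges over a uniform background, plus additive Gaussian noise,
#' quantized to 8 bits. The returned event set is the exact ground truth of
#' the schedule; a frame is labeled aggressive iff it lies inside a bout.
#'
#' @param params a [sim_video_params()] object.
#' @param id identifier stored in the returned session.
#' @return A list with elements `video` (a [video_session()] with per-frame
#'   labels), `events` (the ground-truth [event_set()]) and `tracks` (a
#'   per-frame matrix of the true blob centers: res_x, res_y, intr_x,
#'   intr_y), so the contact geometry of labeled frames can be audited.
#' @examples
#' out <- simulate_ri_video(sim_video_params(duration_s = 10, seed = 42))
#' out$video
#' out$events
#' @export
simulate_ri_video <- function(params = sim_video_params(), id = "sim") {
  validate_sim_video_params(params)
  p <- params
  with_seed(p$seed, {
    nt <- as.integer(round(p$duration_s * p$fps))
    w <- p$width_px; h <- p$height_px; r <- p$blob_radius_px
    bouts <- schedule_bouts(p$attack_rate, p$bout_duration_s, p$duration_s,
                            min_bouts = p$min_bouts)
    # frame f (0-based) covers time [f, f+1)/fps; closed frame intervals
    sf <- floor(bouts$start_s * p$fps)
    ef <- pmin(ceiling(bouts$end_s * p$fps) - 1, nt - 1L)
    keep <- ef >= sf
    ev <- event_set(sf[keep], ef[keep], fps = p$fps, n_frames = nt)
    labels <- events_to_indicator(ev, nt)

    # random-walk state: position + persistent heading per animal
    res <- c(stats::runif(1, r, w - r), stats::runif(1, r, h - r))
    intr <- c(stats::runif(1, r, w - r), stats::runif(1, r, h - r))
    th_res <- stats::runif(1, 0, 2 * pi)
    th_intr <- stats::runif(1, 0, 2 * pi)

    tracks <- matrix(0, nt, 4,
                     dimnames = list(NULL, c("res_x", "res_y",
                                             "intr_x", "intr_y")))
    xg <- matrix(rep(seq_len(w), each = h), h, w)   # column index = x
    yg <- matrix(rep(seq_len(h), times = w), h, w)  # row index = y
    frames <- array(0, dim = c(h, w, nt))
    edge <- 0.8  # px, softness of the logistic disc edge

    step_walk <- function(pos, th) {
      th <- th + stats::rnorm(1, 0, 0.4)
      pos2 <- pos + p$walk_speed * c(cos(th), sin(th))
      # reflect at walls
      if (pos2[1] < r || pos2[1] > w - r) th <- pi - th
      if (pos2[2] < r || pos2[2] > h - r) th <- -th
      list(pos = clamp_pos(pos2, w, h, r), th = th)
    }

    for (t in seq_len(nt)) {
      s <- step_walk(res, th_res); res <- s$pos; th_res <- s$th
      if (labels[t] == 1L) {
        # attack: both animals jitter, intruder pinned near the resident
        res <- clamp_pos(res + stats::rnorm(2, 0, p$attack_jitter), w, h, r)
        ang <- stats::runif(1, 0, 2 * pi)
        d <- stats::runif(1, 0, p$contact_distance_px)
        intr <- clamp_pos(res + d * c(cos(ang), sin(ang)), w, h, r)
      } else {
        s <- step_walk(intr, th_intr); intr <- s$pos; th_intr <- s$th
      }
      tracks[t, ] <- c(res, intr)
      m_res <- stats::plogis(-(sqrt((xg - res[1])^2 + (yg - res[2])^2) - r) / edge)
      m_int <- stats::plogis(-(sqrt((xg - intr[1])^2 + (yg - intr[2])^2) - r) / edge)
      img <- p$background_intensity * (1 - m_res) + p$resident_intensity * m_res
      img <- img * (1 - m_int) + p$intruder_intensity * m_int
      if (p$noise_sd > 0) img <- img + stats::rnorm(h * w, 0, p$noise_sd)
      frames[, , t] <- round(pmin(pmax(img, 0), 255))
    }
    list(video = video_session(frames, p$fps, id = id, labels = labels),
         events = ev, tracks = tracks)
  })
}
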