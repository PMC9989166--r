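#' Parameters for the synthetic three-chamber trajectory generator
#'
#' Arena geometry defaults to the standard sociability cage: a 40.5 x 60 cm
#' floor split into three compartments along the long axis, with one wired
#' cylinder (radius 5 cm) centered in each lateral compartment.
#'
#' @param arena_w_cm,arena_l_cm arena floor size (width x length, cm).
#' @param cylinder_radius_cm cylinder radius (cm).
#' @param sample_rate_hz tracker sampling rate.
#' @param phase_duration_s recorded phase length in seconds; `NULL` uses the
#'   protocol default (300 s habituation, 600 s tests).
#' @param preference_weights length-2 non-negative weights; the long-run dwell
#'   time near cylinder 1 vs cylinder 2 is proportional to them.
#' @param speed_cm_s locomotion speed of the body center.
#' @param seed random seed.
#' @return A list of class `sim_tct_params`.
#' @export
sim_tct_params <- function(arena_w_cm = 40.5, arena_l_cm = 60,
                           cylinder_radius_cm = 5, sample_rate_hz = 25,
                           phase_duration_s = NULL,
                           preference_weights = c(1, 1),
                           speed_cm_s = 6, seed = 1L) {
  p <- list(arena_w_cm = arena_w_cm, arena_l_cm = arena_l_cm,
            cylinder_radius_cm = cylinder_radius_cm,
            sample_rate_hz = sample_rate_hz,
            phase_duration_s = phase_duration_s,
            preference_weights = preference_weights,
            speed_cm_s = speed_cm_s, seed = seed)
  check_number(p$arena_w_cm, "arena_w_cm", min = 0, strict_min = TRUE)
  check_number(p$arena_l_cm, "arena_l_cm", min = 0, strict_min = TRUE)
  check_number(p$cylinder_radius_cm, "cylinder_radius_cm", min = 0,
               strict_min = TRUE)
  check_number(p$sample_rate_hz, "sample_rate_hz", min = 0, strict_min = TRUE)
  if (!is.null(p$phase_duration_s))
    check_number(p$phase_duration_s, "phase_duration_s", min = 0,
                 strict_min = TRUE)
  check_number(p$preference_weights, "preference_weights", min = 0, len = 2L)
  if (sum(p$preference_weights) <= 0)
    stop_invalid("preference_weights must not be all zero")
  check_number(p$speed_cm_s, "speed_cm_s", min = 0)
  class(p) <- "sim_tct_params"
  p
}

tct_phases <- c("habituation", "test1", "test2", "test3")

# Stimulus identity of (cylinder1, cylinder2) per phase before
# counterbalancing. Habituation cylinders are empty.
phase_stimuli <- function(phase) {
  switch(phase,
         habituation = NULL,
         test1 = c("stimulus1", "object"),
         test2 = c("stimulus1", "stimulus2"),   # familiar vs unfamiliar
         test3 = c("stimulus1", "stimulus3"),
         stop_invalid(sprintf("unknown phase '%s'", phase)))
}

#' Zone geometry of the three-chamber arena
#'
#' @param arena_w_cm,arena_l_cm arena floor size.
#' @param cylinder_radius_cm cylinder radius (5 cm for a 10 cm diameter
#'   cylinder).
#' @param proximity_margin_cm proximity band beyond the cylinder wall within
#'   which the nose counts as exploring (2.5 cm in the standard protocol).
#' @param phase one of `"habituation"`, `"test1"`, `"test2"`, `"test3"`.
#' @param counterbalanced if `TRUE`, the stimulus assignment of the two
#'   cylinders is swapped (side counterbalancing across subjects).
#' @return A list of class `zone_set`: cylinder centers (cylinder 1 in the
#'   compartment nearer y = 0), radius, margin, compartment boundaries along
#'   the long axis, and the per-phase stimulus assignment.
#' @export
zone_set <- function(arena_w_cm = 40.5, arena_l_cm = 60,
                     cylinder_radius_cm = 5, proximity_margin_cm = 2.5,
                     phase = "test1", counterbalanced = FALSE) {
  if (!phase %in% tct_phases)
    stop_invalid(sprintf("unknown phase '%s'", phase))
  check_number(proximity_margin_cm, "proximity_margin_cm", min = 0,
               strict_min = TRUE)
  check_flag(counterbalanced, "counterbalanced")
  b <- arena_l_cm / 3
  stim <- phase_stimuli(phase)
  if (!is.null(stim) && counterbalanced) stim <- rev(stim)
  structure(list(
    arena_w_cm = arena_w_cm, arena_l_cm = arena_l_cm,
    centers = list(c(arena_w_cm / 2, b / 2),
                   c(arena_w_cm / 2, arena_l_cm - b / 2)),
    cylinder_radius_cm = cylinder_radius_cm,
    proximity_margin_cm = proximity_margin_cm,
    compartment_bounds = c(0, b, 2 * b, arena_l_cm),
    phase = phase,
    stimuli = stim,
    counterbalanced = counterbalanced
  ), class = "zone_set")
}

#' @export
print.zone_set <- function(x, ...) {
  cat(sprintf("zone_set [%s]: arena %.1f x %.1f cm, cylinders r=%g cm at (%g, %g) / (%g, %g), margin %g cm\n",
              x$phase, x$arena_w_cm, x$arena_l_cm, x$cylinder_radius_cm,
              x$centers[[1]][1], x$centers[[1]][2],
              x$centers[[2]][1], x$centers[[2]][2], x$proximity_margin_cm))
  if (!is.null(x$stimuli))
    cat(sprintf("  cylinder1 = %s, cylinder2 = %s%s\n", x$stimuli[1],
                x$stimuli[2],
                if (x$counterbalanced) " (counterbalanced)" else ""))
  invisible(x)
}

#' Tracked three-point trajectory
#'
#' @param time_s strictly increasing sample times.
#' @param nose,center,tail two-column matrices of (x, y) coordinates in cm.
#' @return A data frame of class `tracked_trajectory` with columns `time_s`,
#'   `nose_x_cm`, `nose_y_cm`, `center_x_cm`, `center_y_cm`, `tail_x_cm`,
#'   `tail_y_cm`.
#' @export
tracked_trajectory <- function(time_s, nose, center, tail) {
  n <- length(time_s)
  nose <- matrix(nose, ncol = 2); center <- matrix(center, ncol = 2)
  tail <- matrix(tail, ncol = 2)
  if (nrow(nose) != n || nrow(center) != n || nrow(tail) != n)
    stop_invalid("trajectory fields must have equal length")
  if (n > 1 && any(diff(time_s) <= 0))
    stop_invalid("time_s must be strictly increasing")
  structure(data.frame(time_s = time_s,
                       nose_x_cm = nose[, 1], nose_y_cm = nose[, 2],
                       center_x_cm = center[, 1], center_y_cm = center[, 2],
                       tail_x_cm = tail[, 1], tail_y_cm = tail[, 2]),
            class = c("tracked_trajectory", "data.frame"))
}

#' Simulate a three-chamber test trajectory
#'
#' The body center follows a waypoint walk: it alternates travel segments
#' (toward a random waypoint in the center compartment) with dwell segments
#' orbiting just outside a cylinder wall. Which cylinder is visited is chosen
#' by a deficit scheduler so that accumulated near-cylinder dwell time tracks
#' `preference_weights`. The nose leads the body center by 2 cm along the
#' heading and the tail base trails it by 2.5 cm, as in three-point tracking.
#'
#' @param params a [sim_tct_params()] object.
#' @param phase one of `"habituation"`, `"test1"`, `"test2"`, `"test3"`.
#' @param counterbalanced stimulus-side counterbalancing flag passed to
#'   [zone_set()].
#' @return A list with elements `trajectory` (a [tracked_trajectory()]) and
#'   `zones` (a [zone_set()]).
#' @export
simulate_tct_session <- function(params = sim_tct_params(),
                                 phase = "test1", counterbalanced = FALSE) {
  if (!is.character(phase) || length(phase) != 1L || !phase %in% tct_phases)
    stop_invalid(sprintf("unknown phase '%s'", paste(phase, collapse = ",")))
  p <- params
  zones <- zone_set(p$arena_w_cm, p$arena_l_cm, p$cylinder_radius_cm,
                    phase = phase, counterbalanced = counterbalanced)
  dur <- p$phase_duration_s %||% if (phase == "habituation") 300 else 600
  dt <- 1 / p$sample_rate_hz
  n <- as.integer(round(dur * p$sample_rate_hz))
  wts <- p$preference_weights / sum(p$preference_weights)

  with_seed(p$seed, {
    pos <- c(p$arena_w_cm / 2, p$arena_l_cm / 2)
    heading <- stats::runif(1, 0, 2 * pi)
    centers <- matrix(0, n, 2)
    step <- p$speed_cm_s * dt
    dwell <- c(0, 0)               # accumulated near-cylinder time
    orbit_r <- p$cylinder_radius_cm + 1.5
    margin <- 1.5                  # wall margin for waypoints

    state <- "travel"
    goal <- pos
    dwell_left <- 0
    visit_next <- TRUE             # alternate cylinder visits with wandering
    target_cyl <- 1L

    new_goal <- function() {
      if (visit_next) {
        # visit the cylinder whose dwell share lags its preference most
        share <- if (sum(dwell) > 0) dwell / sum(dwell) else c(0, 0)
        target_cyl <<- which.max(wts - share)
        cc <- zones$centers[[target_cyl]]
        ang <- stats::runif(1, 0, 2 * pi)
        state <<- "approach"
        goal <<- cc + orbit_r * c(cos(ang), sin(ang))
      } else {
        state <<- "travel"
        goal <<- c(stats::runif(1, margin, p$arena_w_cm - margin),
                   stats::runif(1, p$arena_l_cm / 3 + margin,
                                2 * p$arena_l_cm / 3 - margin))
      }
      visit_next <<- !visit_next
    }
    new_goal()

    for (i in seq_len(n)) {
      if (step == 0) { centers[i, ] <- pos; next }
      if (state == "dwell") {
        cc <- zones$centers[[target_cyl]]
        ang <- atan2(pos[2] - cc[2], pos[1] - cc[1]) + step / orbit_r
        pos <- cc + orbit_r * c(cos(ang), sin(ang))
        dwell[target_cyl] <- dwell[target_cyl] + dt
        dwell_left <- dwell_left - dt
        if (dwell_left <= 0) new_goal()
      } else {
        d <- goal - pos
        dist <- sqrt(sum(d^2))
        if (dist <= step) {
          pos <- goal
          if (state == "approach") {
            state <- "dwell"
            dwell_left <- stats::runif(1, 8, 14)
          } else new_goal()
        } else {
          dir <- d / dist
          wob <- stats::rnorm(1, 0, 0.3)
          dir <- c(cos(wob) * dir[1] - sin(wob) * dir[2],
                   sin(wob) * dir[1] + cos(wob) * dir[2])
          pos <- pos + step * dir
        }
      }
      pos[1] <- min(max(pos[1], 0.5), p$arena_w_cm - 0.5)
      pos[2] <- min(max(pos[2], 0.5), p$arena_l_cm - 0.5)
      centers[i, ] <- pos
    }

    # heading from motion; stationary samples keep the previous heading
    dx <- c(0, diff(centers[, 1])); dy <- c(0, diff(centers[, 2]))
    hd <- atan2(dy, dx)
    moving <- (dx != 0 | dy != 0)
    if (!any(moving)) hd[] <- heading else {
      hd[!moving] <- NA
      if (is.na(hd[1])) hd[1] <- heading
      hd <- zoo_locf(hd)
    }
    nose <- centers + 2.0 * cbind(cos(hd), sin(hd))
    tail <- centers - 2.5 * cbind(cos(hd), sin(hd))
    traj <- tracked_trajectory(seq_len(n) * dt, nose, centers, tail)
    list(trajectory = traj, zones = zones)
  })
}

# last-observation-carried-forward for internal NA runs
zoo_locf <- function(x) {
  idx <- cumsum(!is.na(x))
  x[!is.na(x)][pmax(idx, 1L)]
}
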