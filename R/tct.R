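#' Time spent in proximity of a cylinder
#'
#' A sample counts as "in proximity" when the nose point lies within
#' `proximity_margin_cm` of the cylinder wall, i.e. at most
#' `cylinder_radius_cm + proximity_margin_cm` from the cylinder center
#' (boundary inclusive). Each sample contributes its preceding inter-sample
#' interval (left-Riemann attribution; the first sample contributes the
#' following interval). Samples with missing coordinates are dropped.
#'
#' @param traj a [tracked_trajectory()].
#' @param zones a [zone_set()].
#' @param cylinder_id 1 or 2.
#' @return Seconds of proximity.
#' @export
proximity_time <- function(traj, zones, cylinder_id) {
  if (!nrow(traj)) stop_invalid("empty trajectory")
  if (!(cylinder_id %in% c(1L, 2L))) stop_invalid("cylinder_id must be 1 or 2")
  tt <- traj$time_s
  if (nrow(traj) > 1 && any(diff(tt) <= 0))
    stop_invalid("time_s must be strictly increasing")
  dt <- if (nrow(traj) > 1) c(diff(tt)[1L], diff(tt)) else 0
  cc <- zones$centers[[cylinder_id]]
  d <- sqrt((traj$nose_x_cm - cc[1])^2 + (traj$nose_y_cm - cc[2])^2)
  inside <- d <= zones$cylinder_radius_cm + zones$proximity_margin_cm
  inside[is.na(inside)] <- FALSE
  sum(dt[inside])
}

#' Locomotion as body-center path length
#'
#' Sum of Euclidean distances between consecutive body-center samples, in cm.
#' Segments with a missing endpoint are skipped.
#'
#' @param traj a [tracked_trajectory()].
#' @param point which tracked point to use (default body center).
#' @return Path length in cm (0 with a warning for a single sample).
#' @export
path_length <- function(traj, point = c("center", "nose", "tail")) {
  point <- match.arg(point)
  if (nrow(traj) < 2L) {
    warning("fewer than 2 samples; path length is 0")
    return(0)
  }
  x <- traj[[paste0(point, "_x_cm")]]
  y <- traj[[paste0(point, "_y_cm")]]
  seg <- sqrt(diff(x)^2 + diff(y)^2)
  sum(seg, na.rm = TRUE)
}

#' Per-phase three-chamber summary
#'
#' Computes both cylinders' proximity times and the locomotion of the phase,
#' then maps cylinder sides to stimulus identities using the zone set's
#' (possibly counterbalanced) assignment. Habituation has no stimuli, so only
#' per-cylinder times are reported.
#'
#' @param traj a [tracked_trajectory()].
#' @param zones a [zone_set()] carrying the phase's stimulus assignment.
#' @param phase optional phase label; must agree with `zones$phase` when
#'   given.
#' @return A list of class `phase_summary`: `phase`, `proximity_s` (named
#'   per-cylinder vector), `stimulus_s` (named per-stimulus vector, absent
#'   for habituation), `locomotion_cm`.
#' @export
phase_summary <- function(traj, zones, phase = NULL) {
  phase <- phase %||% zones$phase
  if (!identical(phase, zones$phase))
    stop_invalid(sprintf("zone set is for phase '%s', not '%s'",
                         zones$phase, phase))
  prox <- c(cylinder1 = proximity_time(traj, zones, 1L),
            cylinder2 = proximity_time(traj, zones, 2L))
  stim <- NULL
  if (!is.null(zones$stimuli)) {
    stim <- as.numeric(prox)
    names(stim) <- zones$stimuli
  }
  structure(list(phase = phase, proximity_s = prox, stimulus_s = stim,
                 locomotion_cm = path_length(traj)),
            class = "phase_summary")
}

#' @export
print.phase_summary <- function(x, ...) {
  cat(sprintf("phase_summary [%s]: locomotion %.0f cm\n", x$phase,
              x$locomotion_cm))
  cat(sprintf("  cylinder1 %.1f s, cylinder2 %.1f s\n",
              x$proximity_s[1], x$proximity_s[2]))
  if (!is.null(x$stimulus_s))
    cat(sprintf("  %s\n", paste(sprintf("%s %.1f s", names(x$stimulus_s),
                                        x$stimulus_s), collapse = ", ")))
  invisible(x)
}
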