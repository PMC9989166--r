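# Plain-text interchange formats: one-line-header CSVs for tables, JSON for
# zone geometry and reports, lossless multi-frame TIFF + JSON sidecar for
# video sessions.

read_csv_checked <- function(path, required_cols) {
  if (!file.exists(path)) stop_invalid(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(required_cols, names(df))
  if (length(missing))
    stop_invalid(sprintf("%s: missing column(s) %s", path,
                         paste(missing, collapse = ", ")))
  df
}

#' Read and write video sessions
#'
#' Sessions are stored as lossless 8-bit multi-frame grayscale TIFF stacks
#' with a JSON sidecar (`<path>.json`) carrying fps, id and per-frame labels,
#' so a written session reads back bit-identically.
#'
#' @param session a [video_session()].
#' @param path TIFF file path.
#' @return `read_video` returns a [video_session()]; `write_video` returns
#'   `path` invisibly.
#' @export
write_video <- function(session, path) {
  frames <- session$frames
  if (length(dim(frames)) != 3L)
    stop_invalid("only grayscale sessions are serialized")
  lst <- lapply(seq_len(dim(frames)[3]), function(t) frames[, , t] / 255)
  tiff::writeTIFF(lst, path, bits.per.sample = 8L, compression = "none")
  meta <- list(fps = session$fps, id = session$id, labels = session$labels)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_video
#' @export
read_video <- function(path) {
  if (!file.exists(path)) stop_invalid(sprintf("file not found: %s", path))
  lst <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(lst)) lst <- list(lst)
  h <- nrow(lst[[1]]); w <- ncol(lst[[1]])
  frames <- array(0, c(h, w, length(lst)))
  for (t in seq_along(lst)) frames[, , t] <- round(lst[[t]] * 255)
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar))
    stop_invalid(sprintf("missing video sidecar: %s", sidecar))
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  video_session(frames, fps = meta$fps, id = meta$id,
                labels = if (length(meta$labels)) meta$labels else NULL)
}

#' Read and write per-frame label files
#'
#' CSV with columns `frame_index` (0-based) and `label` in \{0, 1\}.
#'
#' @param labels integer 0/1 vector.
#' @param path CSV path.
#' @export
write_labels <- function(labels, path) {
  utils::write.csv(data.frame(frame_index = seq_along(labels) - 1L,
                              label = as.integer(labels)),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_labels
#' @export
read_labels <- function(path) {
  df <- read_csv_checked(path, c("frame_index", "label"))
  bad <- which(!df$label %in% c(0L, 1L))
  if (length(bad))
    stop_invalid(sprintf("%s: label out of {0,1} at row %d", path, bad[1L]))
  df$label[order(df$frame_index)]
}

#' Read and write probability traces
#'
#' CSV with columns `frame_index`, `probability` plus the frame rate.
#'
#' @param trace a [probability_trace()].
#' @param path CSV path.
#' @export
write_trace <- function(trace, path) {
  utils::write.csv(data.frame(frame_index = seq_along(trace$p) - 1L,
                              probability = trace$p,
                              fps = trace$fps),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  df <- read_csv_checked(path, c("frame_index", "probability", "fps"))
  if (any(df$probability < 0 | df$probability > 1))
    stop_invalid(sprintf("%s: probability out of [0,1] at row %d", path,
                         which(df$probability < 0 | df$probability > 1)[1L]))
  probability_trace(df$probability[order(df$frame_index)], fps = df$fps[1L])
}

#' Read and write event sets
#'
#' CSV with columns `start_frame`, `end_frame` (0-based closed intervals)
#' plus derived `start_s`, `end_s`, `duration_s`.
#'
#' @param events an [event_set()].
#' @param path CSV path.
#' @export
write_events <- function(events, path) {
  fps <- attr(events, "fps")
  utils::write.csv(data.frame(
    start_frame = events$start_frame, end_frame = events$end_frame,
    start_s = events$start_frame / fps,
    end_s = (events$end_frame + 1) / fps,
    duration_s = (events$end_frame - events$start_frame + 1) / fps,
    fps = fps), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @param n_frames optional frame count bound for validation.
#' @export
read_events <- function(path, n_frames = NULL) {
  df <- read_csv_checked(path, c("start_frame", "end_frame", "fps"))
  event_set(df$start_frame, df$end_frame, fps = df$fps[1L],
            n_frames = n_frames)
}

#' Read and write tracked trajectories
#'
#' CSV with columns `time_s`, `nose_x_cm`, `nose_y_cm`, `center_x_cm`,
#' `center_y_cm`, `tail_x_cm`, `tail_y_cm`.
#'
#' @param traj a [tracked_trajectory()].
#' @param path CSV path.
#' @export
write_trajectory <- function(traj, path) {
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  cols <- c("time_s", "nose_x_cm", "nose_y_cm", "center_x_cm",
            "center_y_cm", "tail_x_cm", "tail_y_cm")
  df <- read_csv_checked(path, cols)
  if (nrow(df) > 1 && any(diff(df$time_s) <= 0))
    stop_invalid(sprintf("%s: time_s not strictly increasing at row %d",
                         path, which(diff(df$time_s) <= 0)[1L] + 1L))
  tracked_trajectory(df$time_s, cbind(df$nose_x_cm, df$nose_y_cm),
                     cbind(df$center_x_cm, df$center_y_cm),
                     cbind(df$tail_x_cm, df$tail_y_cm))
}

#' Read and write zone geometry
#'
#' JSON document with cylinder centers, radius, proximity margin,
#' compartment boundaries and stimulus assignment.
#'
#' @param zones a [zone_set()].
#' @param path JSON path.
#' @export
write_zones <- function(zones, path) {
  jsonlite::write_json(unclass(zones), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_zones
#' @export
read_zones <- function(path) {
  if (!file.exists(path)) stop_invalid(sprintf("file not found: %s", path))
  z <- jsonlite::read_json(path, simplifyVector = TRUE)
  zs <- zone_set(z$arena_w_cm, z$arena_l_cm, z$cylinder_radius_cm,
                 z$proximity_margin_cm, phase = z$phase,
                 counterbalanced = isTRUE(z$counterbalanced))
  zs$centers <- if (is.matrix(z$centers))
    lapply(seq_len(nrow(z$centers)), function(i) as.numeric(z$centers[i, ]))
  else lapply(z$centers, as.numeric)
  zs
}

#' Read and write cohort tables
#'
#' CSV with columns `animal_id`, `genotype`, `age_months`, `treatment`,
#' `session`, `attack_duration_s`.
#'
#' @param table a `cohort_table` data frame.
#' @param path CSV path.
#' @export
write_cohort <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  cols <- c("animal_id", "genotype", "age_months", "treatment", "session",
            "attack_duration_s")
  df <- read_csv_checked(path, cols)
  if (!nrow(df)) stop_invalid(sprintf("%s: empty cohort table", path))
  if (any(df$attack_duration_s < 0))
    stop_invalid(sprintf("%s: negative duration at row %d", path,
                         which(df$attack_duration_s < 0)[1L]))
  key <- paste(df$animal_id, df$age_months, df$treatment, df$session)
  if (anyDuplicated(key))
    stop_invalid(sprintf("%s: duplicated session at row %d", path,
                         anyDuplicated(key)))
  class(df) <- c("cohort_table", "data.frame")
  df
}
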