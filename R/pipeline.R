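#' Pipeline configuration
#'
#' A nested list describing an end-to-end run: how many synthetic sessions to
#' simulate (or which files to load), training settings, detection settings
#' and output location. Round-trips losslessly through YAML.
#'
#' @param out_dir output directory for all artifacts.
#' @param n_train_videos number of synthetic training sessions.
#' @param n_score_videos number of additional sessions scored end-to-end.
#' @param video list of [sim_video_params()] overrides (name/value pairs).
#' @param training list of [training_config()] overrides.
#' @param detection list of [event_detection_config()] overrides
#'   (`min_specificity` sets the specificity floor for threshold selection).
#' @param seed global seed; per-stage seeds are derived from it by fixed
#'   offsets.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, n_train_videos = 4L,
                            n_score_videos = 2L, video = list(),
                            training = list(), detection = list(),
                            seed = 1L) {
  structure(list(out_dir = out_dir,
                 n_train_videos = as.integer(n_train_videos),
                 n_score_videos = as.integer(n_score_videos),
                 video = video, training = training, detection = detection,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Write / read a pipeline configuration as YAML
#' @param config a [pipeline_config()].
#' @param path YAML file path.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop_invalid(sprintf("file not found: %s", path))
  cfg <- yaml::read_yaml(path)
  do.call(pipeline_config, cfg)
}

#' Run the full resident-intruder scoring pipeline
#'
#' Simulates labeled training sessions, trains the frame classifier with
#' leave-one-video-out validation, selects the specificity-first threshold on
#' the training predictions, then scores fresh sessions end-to-end
#' (predict, smooth, detect, summarize) and writes every artifact plus a
#' machine-readable JSON run report. Identical config and seed reproduce
#' identical artifacts.
#'
#' @param config a [pipeline_config()].
#' @return The run report, invisibly (also written to
#'   `<out_dir>/report.json`).
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) stop_invalid("not a pipeline_config")
  if (config$n_train_videos < 2L)
    stop_invalid("need at least 2 training videos")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  vp_base <- do.call(sim_video_params, config$video)
  train_videos <- list(); train_truth <- list()
  for (i in seq_len(config$n_train_videos)) {
    vp <- vp_base; vp$seed <- derive_seed(config$seed, i)
    sim <- simulate_ri_video(vp, id = sprintf("train_%02d", i))
    train_videos[[i]] <- sim$video
    train_truth[[i]] <- sim$events
    write_video(sim$video,
                file.path(config$out_dir, sprintf("train_%02d.tif", i)))
    write_events(sim$events,
                 file.path(config$out_dir, sprintf("train_%02d_truth.csv", i)))
  }

  tc_args <- config$training
  tc_args$seed <- tc_args$seed %||% derive_seed(config$seed, 500L)
  tc <- do.call(training_config, tc_args)
  fit <- train_frame_classifier(train_videos, tc)
  save_model(fit$model, file.path(config$out_dir, "model"))
  utils::write.csv(fit$fold_metrics,
                   file.path(config$out_dir, "fold_metrics.csv"),
                   row.names = FALSE)

  mode <- config$detection$threshold_mode %||% "duration"
  min_spec <- config$detection$min_specificity %||% 0.999
  det_args <- config$detection
  det_args$min_specificity <- NULL; det_args$threshold_mode <- NULL
  det_base <- if (length(det_args))
    do.call(event_detection_config, det_args)
  else default_detection_config(vp_base$fps)

  train_traces <- lapply(train_videos, predict_probabilities,
                         model = fit$model)
  if (mode == "specificity") {
    thr <- select_specificity_threshold(
      unlist(lapply(train_traces, `[[`, "p")),
      unlist(lapply(train_videos, function(v) v$labels)), min_spec)
  } else {
    thr <- select_duration_threshold(train_traces, train_truth, det_base)
  }
  det <- event_detection_config(det_base$w, thr$threshold,
                                det_base$min_duration, det_base$merge_gap)

  sessions <- list()
  for (i in seq_len(config$n_score_videos)) {
    vp <- vp_base; vp$seed <- derive_seed(config$seed, 1000L + i)
    sim <- simulate_ri_video(vp, id = sprintf("score_%02d", i))
    trace <- predict_probabilities(fit$model, sim$video)
    write_trace(trace, file.path(config$out_dir, sprintf("score_%02d_trace.csv", i)))
    sm <- moving_average(trace, det$w)
    ev <- detect_events(sm, det)
    write_events(ev, file.path(config$out_dir, sprintf("score_%02d_events.csv", i)))
    m <- event_match_metrics(ev, sim$events, min_overlap = 0.5)
    sessions[[i]] <- list(
      video_id = sim$video$id,
      truth_duration_s = cumulative_attack_duration(sim$events),
      detected_duration_s = cumulative_attack_duration(ev),
      n_events = nrow(ev), recall = m$recall, precision = m$precision)
  }

  report <- list(
    seed = config$seed,
    package_version = as.character(utils::packageVersion("ethoscore")),
    n_train_videos = config$n_train_videos,
    mean_holdout_auc = fit$mean_auc,
    fold_auc = fit$fold_metrics$auc,
    threshold = thr$threshold,
    threshold_mode = mode,
    detection = list(w = det$w, min_duration = det$min_duration,
                     merge_gap = det$merge_gap),
    sessions = sessions)
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(report)
}
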