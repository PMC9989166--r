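# Smoothing, event bounding, session scoring, event matching.

test_that("moving average shrinks its window at the edges", {
  expect_equal(moving_average(c(0, 1, 0, 1, 0), 3),
               c(0.5, 1 / 3, 2 / 3, 1 / 3, 0.5))
  x <- runif(20)
  expect_equal(moving_average(x, 1), x)
  expect_equal(moving_average(rep(0.3, 10), 7), rep(0.3, 10))
  expect_error(moving_average(x, 4), "odd")
  expect_error(moving_average(x, 21), "exceeds")
  tr <- probability_trace(x, fps = 10)
  sm <- moving_average(tr, 5)
  expect_s3_class(sm, "probability_trace")
  expect_equal(sm$fps, 10)
})

test_that("event bounding applies threshold, merge and duration rules in order", {
  cfg <- event_detection_config(w = 1L, threshold = 0.5, min_duration = 2L,
                                merge_gap = 1L)
  ev <- detect_events(c(0, 0, 1, 1, 1, 0, 0, 1, 0, 0), cfg, fps = 10)
  expect_equal(ev$start_frame, 2L)
  expect_equal(ev$end_frame, 4L)

  # merging bridges a small gap before the duration filter
  cfg2 <- event_detection_config(w = 1L, threshold = 0.5, min_duration = 4L,
                                 merge_gap = 2L)
  ev2 <- detect_events(c(1, 1, 0, 0, 1, 1, 0, 0, 0), cfg2, fps = 10)
  expect_equal(as.integer(ev2$start_frame), 0L)
  expect_equal(as.integer(ev2$end_frame), 5L)

  expect_equal(nrow(detect_events(rep(0, 10),
                                  event_detection_config(1L, 0.5), fps = 5)),
               0L)
  expect_error(event_detection_config(w = 4L), "odd")
  expect_error(event_detection_config(w = 1L, min_duration = 0L),
               "min_duration")
})

test_that("an indicator trace recovers its own events exactly", {
  truth <- event_set(c(3L, 20L, 50L), c(10L, 22L, 80L), fps = 15,
                     n_frames = 100L)
  ind <- rep(0, 100)
  for (i in seq_len(nrow(truth)))
    ind[(truth$start_frame[i] + 1):(truth$end_frame[i] + 1)] <- 1
  cfg <- event_detection_config(w = 1L, threshold = 0.5, min_duration = 1L,
                                merge_gap = 0L)
  got <- detect_events(ind, cfg, fps = 15)
  expect_equal(got$start_frame, truth$start_frame)
  expect_equal(got$end_frame, truth$end_frame)

  # idempotence: re-encoding and re-detecting returns the same set
  ind2 <- rep(0, 100)
  for (i in seq_len(nrow(got)))
    ind2[(got$start_frame[i] + 1):(got$end_frame[i] + 1)] <- 1
  again <- detect_events(ind2, cfg, fps = 15)
  expect_equal(as.data.frame(again), as.data.frame(got))
})

test_that("raising the threshold never increases detected duration", {
  set.seed(11)
  x <- pmin(pmax(stats::filter(runif(300), rep(1 / 5, 5), sides = 2), 0), 1)
  x[is.na(x)] <- 0
  cfg <- function(th) event_detection_config(w = 1L, threshold = th,
                                             min_duration = 1L,
                                             merge_gap = 0L)
  durs <- vapply(seq(0, 0.9, by = 0.1), function(th)
    cumulative_attack_duration(detect_events(as.numeric(x), cfg(th),
                                             fps = 10)), 0)
  expect_true(all(diff(durs) <= 1e-12))
})

test_that("cumulative attack duration sums closed frame intervals", {
  expect_equal(cumulative_attack_duration(event_set(fps = 30)), 0)
  expect_equal(cumulative_attack_duration(
    event_set(0L, 29L, fps = 30, n_frames = 30L)), 1.0)
  expect_equal(cumulative_attack_duration(
    event_set(c(2L, 10L), c(4L, 19L), fps = 10)), 1.3)
  s <- session_summary(event_set(c(2L, 10L), c(4L, 19L), fps = 10), "v")
  expect_equal(s$cumulative_attack_duration_s, 1.3)
  expect_equal(s$n_events, 2L)
})

test_that("event matching follows the overlap and empty-set conventions", {
  t1 <- event_set(0L, 9L, fps = 10, n_frames = 50L)
  same <- event_match_metrics(t1, t1, 0.5)
  expect_equal(same$precision, 1); expect_equal(same$recall, 1)
  expect_equal(same$f1, 1)

  disj <- event_match_metrics(event_set(20L, 29L, fps = 10), t1, 0.5)
  expect_equal(disj$precision, 0); expect_equal(disj$recall, 0)

  half <- event_match_metrics(event_set(0L, 4L, fps = 10), t1, 0.5)
  expect_equal(half$precision, 1); expect_equal(half$recall, 1)

  under <- event_match_metrics(event_set(0L, 3L, fps = 10), t1, 0.5)
  expect_equal(under$recall, 0)

  none <- event_match_metrics(event_set(fps = 10), t1, 0.5)
  expect_equal(none$precision, 1); expect_equal(none$recall, 0)
  expect_equal(event_match_metrics(t1, event_set(fps = 10), 0.5)$recall, 1)
})

test_that("event sets reject malformed intervals", {
  expect_error(event_set(5L, 3L, fps = 10), "end before start")
  expect_error(event_set(c(0L, 3L), c(4L, 8L), fps = 10), "overlap")
  expect_error(event_set(0L, 99L, fps = 10, n_frames = 50L), "range")
})
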