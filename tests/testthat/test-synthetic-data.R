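# Synthetic generators: resident-intruder videos, three-chamber
# trajectories, cohort tables.

test_that("video generator honours the no-attack and determinism contracts", {
  p <- sim_video_params(duration_s = 5, attack_rate = 0, seed = 3L)
  out <- simulate_ri_video(p)
  expect_equal(nrow(out$events), 0L)
  expect_true(all(out$video$labels == 0L))

  p2 <- tiny_video_params(seed = 11, duration_s = 10)
  a <- simulate_ri_video(p2)
  b <- simulate_ri_video(p2)
  expect_identical(a$video$frames, b$video$frames)
  expect_identical(as.data.frame(a$events), as.data.frame(b$events))

  expect_error(sim_video_params(fps = 0), "fps")
  expect_error(sim_video_params(duration_s = -1), "duration_s")
  expect_error(sim_video_params(background_intensity = 250),
               "resident_intensity")
})

test_that("attack-labeled frames satisfy the contact-distance ground truth", {
  out <- simulate_ri_video(tiny_video_params(seed = 21, duration_s = 60))
  lab <- out$video$labels
  expect_gt(sum(lab), 0)
  d <- sqrt((out$tracks[, "res_x"] - out$tracks[, "intr_x"])^2 +
            (out$tracks[, "res_y"] - out$tracks[, "intr_y"])^2)
  expect_true(all(d[lab == 1L] <= tiny_video_params(1)$contact_distance_px + 1e-9))
  # labels agree with the returned intervals
  ind <- integer(length(lab))
  for (i in seq_len(nrow(out$events)))
    ind[(out$events$start_frame[i] + 1):(out$events$end_frame[i] + 1)] <- 1L
  expect_identical(ind, lab)
})

test_that("attack-frame prevalence is near 1% when the rate is tuned for it", {
  # 0.3 bouts/min x 2 s mean duration = 1% of frames; six 10-min sessions
  frac <- vapply(1:6, function(i) {
    p <- sim_video_params(width_px = 32L, height_px = 32L,
                          blob_radius_px = 3, duration_s = 600,
                          attack_rate = 0.3, seed = 100 + i)
    mean(simulate_ri_video(p)$video$labels)
  }, 0)
  expect_gte(mean(frac), 0.005)
  expect_lte(mean(frac), 0.02)
})

test_that("three-chamber generator produces balanced dwell under equal weights", {
  s <- simulate_tct_session(sim_tct_params(phase_duration_s = 6000, seed = 5),
                            phase = "test1")
  p1 <- proximity_time(s$trajectory, s$zones, 1L)
  p2 <- proximity_time(s$trajectory, s$zones, 2L)
  expect_gt(p1, 0); expect_gt(p2, 0)
  expect_lt(abs(p1 - p2) / ((p1 + p2) / 2), 0.10)
})

test_that("three-chamber generator respects speed, phase and geometry contracts", {
  s0 <- simulate_tct_session(sim_tct_params(speed_cm_s = 0,
                                            phase_duration_s = 20, seed = 2),
                             phase = "habituation")
  expect_equal(path_length(s0$trajectory), 0)
  expect_null(s0$zones$stimuli)
  expect_error(simulate_tct_session(sim_tct_params(), phase = "test9"),
               "phase")
  # trajectory stays inside the arena (tracking-noise tolerance for the nose)
  s <- simulate_tct_session(sim_tct_params(phase_duration_s = 120, seed = 8),
                            phase = "test2")
  expect_true(all(s$trajectory$center_x_cm >= 0 &
                  s$trajectory$center_x_cm <= 40.5))
  expect_true(all(s$trajectory$center_y_cm >= 0 &
                  s$trajectory$center_y_cm <= 60))
})

test_that("preference weights shift stimulus-side dwell", {
  s <- simulate_tct_session(sim_tct_params(phase_duration_s = 1200,
                                           preference_weights = c(3, 1),
                                           seed = 6), phase = "test1")
  ps <- phase_summary(s$trajectory, s$zones)
  expect_gt(ps$stimulus_s[["stimulus1"]], ps$stimulus_s[["object"]])
})

test_that("cohort generator obeys zero injection, determinism and validation", {
  p <- sim_cohort_params(n_per_genotype = 4L, zero_prob = 1, seed = 2L)
  expect_true(all(simulate_cohort(p)$attack_duration_s == 0))
  p2 <- sim_cohort_params(n_per_genotype = 4L, seed = 7L)
  expect_identical(simulate_cohort(p2), simulate_cohort(p2))
  expect_error(sim_cohort_params(n_per_genotype = 1L), "n_per_genotype")
  co <- simulate_cohort(sim_cohort_params(n_per_genotype = 6L, seed = 1L))
  expect_true(all(co$attack_duration_s >= 0 & co$attack_duration_s <= 600))
  # one row per animal x age x treatment
  expect_false(anyDuplicated(co[c("animal_id", "age_months", "treatment")]) > 0)
})

test_that("cohort log-scale marginals converge to the configured effects", {
  p <- sim_cohort_params(n_per_genotype = 10000L, ages_months = c(4L, 6L),
                         genotype_effect = 0.8, onset_age_months = 5L,
                         zero_prob = 0, crossover_age_months = 0L, seed = 31L)
  co <- simulate_cohort(p)
  lv <- log(co$attack_duration_s)
  sd_tot <- sqrt(0.6^2 + 0.5^2)
  # pre-onset: both genotypes at baseline
  m4 <- mean(lv[co$age_months == 4])
  expect_lt(abs(m4 - log(15)), 3 * sd_tot / sqrt(sum(co$age_months == 4)))
  # post-onset genotype contrast
  d6 <- mean(lv[co$age_months == 6 & co$genotype == "SAMP8"]) -
    mean(lv[co$age_months == 6 & co$genotype == "SAMR1"])
  expect_lt(abs(d6 - 0.8), 3 * sd_tot * sqrt(2 / 10000))
})
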