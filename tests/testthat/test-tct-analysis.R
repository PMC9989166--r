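# Three-chamber readouts: proximity geometry, locomotion, phase summaries.

test_that("proximity time follows the wall-margin geometry", {
  z <- zone_set(phase = "test1")
  cc <- z$centers[[1]]
  n <- 61
  # nose parked 6 cm from the cylinder center: 1 cm from the wall, inside
  tr <- line_trajectory(0:60, rep(cc[1] + 6, n), rep(cc[2], n))
  expect_equal(proximity_time(tr, z, 1L), 61)  # 60 s + leading interval
  # 10 cm from center: 5 cm from the wall, outside the 2.5 cm margin
  tr2 <- line_trajectory(0:60, rep(cc[1] + 10, n), rep(cc[2], n))
  expect_equal(proximity_time(tr2, z, 1L), 0)
  # exactly on the 7.5 cm boundary: inclusive
  tr3 <- line_trajectory(0:10, rep(cc[1] + 7.5, 11), rep(cc[2], 11))
  expect_equal(proximity_time(tr3, z, 1L), 11)
  # all samples at the arena center reach neither lateral cylinder
  mid <- line_trajectory(0:30, rep(40.5 / 2, 31), rep(30, 31))
  expect_equal(proximity_time(mid, z, 1L), 0)
  expect_equal(proximity_time(mid, z, 2L), 0)
})

test_that("alternating in/out dwell integrates to half the session", {
  z <- zone_set(phase = "test1")
  cc <- z$centers[[1]]
  tt <- seq(0.1, 100, by = 0.1)
  inside <- (floor((seq_along(tt) - 1) / 50) %% 2) == 0  # 5 s in, 5 s out
  x <- ifelse(inside, cc[1] + 6, cc[1] + 20)
  tr <- line_trajectory(tt, x, rep(cc[2], length(tt)))
  expect_lte(abs(proximity_time(tr, z, 1L) - 50), 0.1 + 1e-9)
})

test_that("proximity time is monotone in the margin and errors on bad time", {
  z <- zone_set(phase = "test1")
  cc <- z$centers[[1]]
  set.seed(2)
  tr <- line_trajectory(1:50, cc[1] + runif(50, 0, 15), rep(cc[2], 50))
  margins <- c(0.5, 1.5, 2.5, 4, 6)
  times <- vapply(margins, function(m) {
    zz <- zone_set(proximity_margin_cm = m, phase = "test1")
    proximity_time(tr, zz, 1L)
  }, 0)
  expect_true(all(diff(times) >= 0))
  bad <- tr; bad$time_s <- rev(bad$time_s)
  expect_error(proximity_time(bad, z, 1L), "increasing")
})

test_that("path length matches closed-form geometry", {
  tr <- line_trajectory(c(0, 1), c(0, 3), c(0, 4))
  expect_equal(path_length(tr), 5)
  still <- line_trajectory(0:5, rep(2, 6), rep(3, 6))
  expect_equal(path_length(still), 0)
  # circle perimeter within 1% at 1000 samples
  th <- seq(0, 2 * pi, length.out = 1001)
  circ <- line_trajectory(seq_along(th), 10 + 5 * cos(th), 10 + 5 * sin(th))
  expect_lt(abs(path_length(circ) - 2 * pi * 5) / (2 * pi * 5), 0.01)
  expect_warning(pl <- path_length(line_trajectory(1, 2, 3)), "2 samples")
  expect_equal(pl, 0)
})

test_that("path length is invariant under rigid motions", {
  set.seed(4)
  x <- cumsum(rnorm(100)); y <- cumsum(rnorm(100))
  tr <- line_trajectory(1:100, x, y)
  a <- 0.7
  xr <- cos(a) * x - sin(a) * y + 12
  yr <- sin(a) * x + cos(a) * y - 3
  expect_equal(path_length(line_trajectory(1:100, xr, yr)), path_length(tr))
})

test_that("missing samples are dropped from dwell and path sums", {
  z <- zone_set(phase = "test1")
  cc <- z$centers[[1]]
  tr <- line_trajectory(1:10, rep(cc[1] + 6, 10), rep(cc[2], 10))
  tr$nose_x_cm[4] <- NA
  expect_equal(proximity_time(tr, z, 1L), 9)
  tr$center_x_cm[4] <- NA
  expect_equal(path_length(tr), 0)
})

test_that("phase summaries relabel cylinders per counterbalancing", {
  sim <- simulate_tct_session(sim_tct_params(phase_duration_s = 300,
                                             seed = 12), phase = "test1")
  ps <- phase_summary(sim$trajectory, sim$zones)
  zf <- zone_set(phase = "test1", counterbalanced = TRUE)
  psf <- phase_summary(sim$trajectory, zf)
  # per-cylinder times unchanged, stimulus labels swapped
  expect_equal(psf$proximity_s, ps$proximity_s)
  expect_equal(psf$stimulus_s[["stimulus1"]], ps$stimulus_s[["object"]])
  expect_equal(psf$stimulus_s[["object"]], ps$stimulus_s[["stimulus1"]])
  expect_equal(sum(psf$stimulus_s), sum(psf$proximity_s))

  hab <- simulate_tct_session(sim_tct_params(phase_duration_s = 60,
                                             seed = 3), "habituation")
  ph <- phase_summary(hab$trajectory, hab$zones)
  expect_null(ph$stimulus_s)
  expect_named(ph$proximity_s, c("cylinder1", "cylinder2"))
  expect_error(phase_summary(hab$trajectory, hab$zones, phase = "test1"),
               "phase")
})

test_that("the two proximity zones are disjoint in time", {
  sim <- simulate_tct_session(sim_tct_params(phase_duration_s = 600,
                                             seed = 19), phase = "test2")
  p1 <- proximity_time(sim$trajectory, sim$zones, 1L)
  p2 <- proximity_time(sim$trajectory, sim$zones, 2L)
  expect_lte(p1 + p2, 600 + 1)
})
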