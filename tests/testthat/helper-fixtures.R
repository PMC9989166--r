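# Small, fast synthetic fixtures shared across test files. Everything is
# generated in code; nothing is read from disk except the bundled toy cohort.

# Low-resolution video parameters for quick classifier exercises (not the
# full-scale study conditions; those live in the acceptance tests).
tiny_video_params <- function(seed, duration_s = 30, attack_rate = 4) {
  sim_video_params(width_px = 32L, height_px = 32L, fps = 15,
                   duration_s = duration_s, blob_radius_px = 3,
                   attack_rate = attack_rate, bout_duration_s = c(0.5, 1.5),
                   contact_distance_px = 5, seed = seed)
}

tiny_training_config <- function(seed = 1L, epochs = 10L) {
  training_config(epochs = epochs, filters = c(4L, 8L, 16L),
                  input_pool = 2L, seed = seed)
}

toy_cohort_path <- function() {
  system.file("extdata", "toy_cohort.csv", package = "ethoscore")
}

# straight-line trajectory builder
line_trajectory <- function(time_s, x, y) {
  tracked_trajectory(time_s, cbind(x, y), cbind(x, y), cbind(x, y))
}
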