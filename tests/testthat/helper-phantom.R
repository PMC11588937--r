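# Compact phantom used throughout the tests: same band anatomy as the default,
# scaled to a 96 x 128 frame at 10 fps so propagation tests stay fast.
small_phantom_config <- function(...) {
  args <- utils::modifyList(
    list(image_height = 96L, image_width = 128L, frame_rate = 10,
         rest1_s = 4, exercise_s = 4, rest2_s = 2,
         rest_thickness = c(OE = 12, OI = 14, TrA = 9),
         speckle_sigma = 0.05, seed = 1L),
    list(...))
  do.call(phantom_config, args)
}

small_cohort_config <- function() {
  list(image_height = 96L, image_width = 128L, frame_rate = 10,
       rest1_s = 4, exercise_s = 4, rest2_s = 2,
       rest_thickness = c(OE = 12, OI = 14, TrA = 9),
       speckle_sigma = 0.05)
}

# Synthetic measurement series with gaussian measurement noise, for classifier
# tests that do not need mask geometry.
make_series <- function(rest_th, ex_th, rest_com, ex_com,
                        n_rest1 = 40, n_ex = 40, n_rest2 = 16, sd = 0.3,
                        muscle = "TrA", seed = 1) {
  set.seed(seed)
  n <- n_rest1 + n_ex + n_rest2
  phase <- c(rep("rest1", n_rest1), rep("exercise", n_ex), rep("rest2", n_rest2))
  th <- c(rnorm(n_rest1, rest_th, sd), rnorm(n_ex, ex_th, sd),
          rnorm(n_rest2, rest_th, sd))
  com <- c(rnorm(n_rest1, rest_com, sd), rnorm(n_ex, ex_com, sd),
           rnorm(n_rest2, rest_com, sd))
  structure(data.frame(frame = seq_len(n) - 1L, phase = phase, muscle = muscle,
                       thickness_px = th, com_px = com,
                       stringsAsFactors = FALSE),
            frame_rate = 10, image_width = 128L,
            class = c("measurement_series", "data.frame"))
}
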