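test_that("phase schedule converts durations to contiguous frame ranges", {
  ph <- phase_schedule(phantom_config(frame_rate = 20))
  expect_equal(ph$start, c(0, 200, 400))
  expect_equal(ph$end, c(200, 400, 480))
  expect_equal(attr(ph, "n_frames"), 480L)

  ph1 <- phase_schedule(small_phantom_config(frame_rate = 1, rest1_s = 1,
                                             exercise_s = 1, rest2_s = 1))
  expect_equal(ph1$start, 0:2)
  expect_equal(ph1$end, 1:3)

  # fractional fps: boundaries by round-half-even on cumulative seconds * fps
  ph75 <- phase_schedule(phantom_config(frame_rate = 7.5))
  expect_equal(ph75$end, round(7.5 * c(10, 20, 24)))
  expect_equal(attr(ph75, "n_frames"), 180L)

  expect_error(phase_schedule(small_phantom_config(rest1_s = 0, exercise_s = 0,
                                                   rest2_s = 0)),
               "empty schedule")
})

test_that("config validation rejects ambiguous and overflowing geometries", {
  expect_error(small_phantom_config(thickening_factor = c(OE = 1, OI = 1, TrA = 1.05)),
               "ambiguous")
  expect_error(small_phantom_config(lateral_shift = c(OE = 0, OI = 0, TrA = -2)),
               "ambiguous")
  expect_error(small_phantom_config(rest_thickness = c(OE = 30, OI = 30, TrA = 30)),
               "geometry overflow")
  expect_error(small_phantom_config(thickening_factor = c(OE = 4, OI = 4, TrA = 4)),
               "geometry overflow")
  expect_error(small_phantom_config(frame_rate = 0), "frame_rate")
  expect_error(small_phantom_config(speckle_sigma = 1.5), "speckle_sigma")
})

test_that("no-dynamics phantom is static with all-relaxed truth", {
  sim <- simulate_sequence(small_phantom_config(rest1_s = 1, exercise_s = 1,
                                                rest2_s = 1, speckle_sigma = 0))
  expect_false(any(sim$truth$contracted))
  for (t in 2:dim(sim$masks)[3]) {
    expect_identical(sim$masks[, , t], sim$masks[, , 1])
    expect_identical(sim$video[, , t], sim$video[, , 1])
  }
})

test_that("thickening scales mask thickness; rest2 returns to rest geometry", {
  sim <- simulate_sequence(small_phantom_config(
    thickening_factor = c(OE = 1, OI = 1, TrA = 1.5), speckle_sigma = 0))
  ph <- sim$truth$phases
  mid <- floor((ph$start[2] + ph$end[2]) / 2) + 1L   # mid-exercise, 1-based
  expect_lt(abs(muscle_thickness(sim$masks[, , mid], 3) - 1.5 * 9), 1)
  expect_lt(abs(muscle_thickness(sim$masks[, , mid], 1) - 12), 1)
  # with zero speckle every rest1 frame is identical and rest2 equals rest1
  expect_identical(sim$masks[, , 5], sim$masks[, , 1])
  expect_identical(sim$video[, , 5], sim$video[, , 1])
  last <- dim(sim$masks)[3]
  expect_identical(sim$masks[, , last], sim$masks[, , 1])
  expect_identical(sim$video[, , last], sim$video[, , 1])
})

test_that("identical seeds are bit-identical; seeds differ only in texture/speckle", {
  cfg7 <- small_phantom_config(rest1_s = 1, exercise_s = 1, rest2_s = 1, seed = 7)
  cfg8 <- small_phantom_config(rest1_s = 1, exercise_s = 1, rest2_s = 1, seed = 8)
  a <- simulate_sequence(cfg7)
  b <- simulate_sequence(cfg7)
  c <- simulate_sequence(cfg8)
  expect_identical(a$video, b$video)
  expect_identical(a$masks, b$masks)
  expect_false(identical(a$video, c$video))
  expect_identical(a$masks, c$masks)   # clean geometry does not depend on seed
})

test_that("clean masks are exclusive, connected, hole-free, of configured thickness", {
  sim <- simulate_sequence(small_phantom_config(
    thickening_factor = c(OE = 1.3, OI = 1, TrA = 1.4),
    lateral_shift = c(OE = 0, OI = 0, TrA = -5),
    rest1_s = 1, exercise_s = 1, rest2_s = 1))
  h_rest <- c(12, 14, 9)
  for (t in seq(1, dim(sim$masks)[3], by = 7)) {
    m <- sim$masks[, , t]
    for (lab in muscle_labels()) {
      bw <- m == lab
      cc <- EBImage::bwlabel(bw)
      expect_equal(max(cc), 1)                                   # connected
      expect_equal(sum(as.matrix(EBImage::fillHull(bw * 1)) > 0),
                   sum(bw))                                      # no holes
    }
  }
  # configured rest thickness at every interior column, within 1 px
  m0 <- sim$masks[, , 1]
  for (lab in muscle_labels()) {
    cnt <- colSums(m0 == lab)
    interior <- which(cnt > 0)
    interior <- interior[-c(1, length(interior))]
    expect_true(all(abs(cnt[interior] - h_rest[lab]) <= 1))
  }
})

test_that("transducer drift shifts the clean masks of all muscles equally", {
  base <- simulate_sequence(small_phantom_config(rest1_s = 1, exercise_s = 1,
                                                 rest2_s = 1, speckle_sigma = 0))
  drift <- simulate_sequence(small_phantom_config(rest1_s = 1, exercise_s = 1,
                                                  rest2_s = 1, speckle_sigma = 0,
                                                  drift_px = 6,
                                                  drift_onset_s = 1))
  n <- dim(base$masks)[3]
  for (lab in muscle_labels()) {
    com0 <- lateral_center_of_mass(base$masks[, , 1], lab)
    com_pre <- lateral_center_of_mass(drift$masks[, , 5], lab)
    com_post <- lateral_center_of_mass(drift$masks[, , n], lab)
    expect_lt(abs(com_pre - com0), 0.6)            # before onset: no drift
    expect_lt(abs(com_post - (com0 + 6)), 0.6)     # after ramp: full drift
  }
})

test_that("phantom cohort labels match the configured ground truth", {
  ch <- phantom_cohort(n_videos = 2L, seed = 5L, config = small_cohort_config())
  expect_length(ch$sims, 2)
  expect_equal(nrow(ch$labels), 6)
  for (v in 1:2) {
    truth <- ch$sims[[v]]$truth$contracted
    lab <- ch$labels[ch$labels$video == v, ]
    expect_equal(unname(truth[lab$muscle]), lab$contracted)
  }
  # identical seed reproduces the cohort exactly
  ch2 <- phantom_cohort(n_videos = 2L, seed = 5L, config = small_cohort_config())
  expect_identical(ch$sims[[1]]$video, ch2$sims[[1]]$video)
  expect_identical(ch$labels, ch2$labels)
})
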