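# a textured test frame pair: the small phantom's first frame
flow_fixture <- local({
  sim <- NULL
  function() {
    if (is.null(sim))
      sim <<- simulate_sequence(small_phantom_config(
        rest1_s = 1, exercise_s = 1, rest2_s = 1,
        thickening_factor = c(OE = 1.3, OI = 1, TrA = 1.3),
        lateral_shift = c(OE = 0, OI = 0, TrA = -5), seed = 3))
    sim
  }
})

test_that("dense flow is zero for identical frames and recovers translation", {
  sim <- flow_fixture()
  f1 <- sim$video[, , 1]
  m1 <- sim$masks[, , 1]

  fl0 <- dense_flow(f1, f1, ref_mask = m1)
  expect_lt(mean(abs(fl0$u)) + mean(abs(fl0$v)), 0.1)

  f2 <- f1
  f2[, 4:ncol(f1)] <- f1[, 1:(ncol(f1) - 3)]   # shift right by 3 px
  fl <- dense_flow(f1, f2, ref_mask = m1)
  expect_lt(abs(median(fl$u) - 3), 0.5)
  expect_lt(abs(median(fl$v)), 0.5)
})

test_that("featureless frames give a zero field with a warning", {
  z <- matrix(0.5, 64, 64)
  expect_warning(fl <- dense_flow(z, z), "featureless")
  expect_equal(max(abs(fl$u)), 0)
  expect_equal(max(abs(fl$v)), 0)
  expect_error(dense_flow(matrix(0, 4, 4), matrix(0, 5, 5)), "same shape")
})

test_that("warping follows the flow and drops out-of-frame mass", {
  sim <- flow_fixture()
  m <- sim$masks[, , 1]
  h <- nrow(m); w <- ncol(m)
  zero <- list(u = matrix(0, h, w), v = matrix(0, h, w))

  # zero flow: near-idempotent after one smoothing pass (a handful of pixels
  # at undulation crests may keep flickering under smooth+binarize)
  w1 <- warp_mask(m, zero)
  w2 <- warp_mask(w1, zero)
  w3 <- warp_mask(w2, zero)
  expect_lt(mean(w3 != w2), 5e-4)
  for (lab in muscle_labels()) {
    expect_gt(dice(m == lab, w1 == lab), 0.98)
    expect_gt(dice(m == lab, w3 == lab), 0.98)
  }

  # uniform +3 column shift: interior pixels shifted exactly
  shift3 <- list(u = matrix(3, h, w), v = matrix(0, h, w))
  ws <- warp_mask(m, shift3)
  ref <- matrix(0L, h, w)
  ref[, 4:w] <- m[, 1:(w - 3)]
  interior <- 10:(w - 10)
  sm_ref <- warp_mask(ref, zero)   # same smoothing as the warped mask
  expect_gt(dice(ws[, interior] > 0, sm_ref[, interior] > 0), 0.995)

  # flow pushing the mask fully outside the frame empties the labels
  big <- list(u = matrix(2 * w, h, w), v = matrix(0, h, w))
  expect_true(all(warp_mask(m, big) == 0))
})

test_that("postprocess keeps the best component, fills holes, is idempotent", {
  prev <- matrix(0L, 30, 30)
  prev[5:15, 5:15] <- 1L

  m <- matrix(0L, 30, 30)
  m[6:14, 6:14] <- 1L        # large component overlapping prev
  m[25:27, 25:27] <- 1L      # small spurious component
  m[10, 10] <- 0L            # interior hole
  pp <- postprocess_mask(m, prev)
  expect_equal(pp[26, 26], 0L)                    # small component removed
  expect_equal(pp[10, 10], 1L)                    # hole filled
  expect_identical(postprocess_mask(pp, prev), pp)

  # equal-area tie: the component overlapping the previous mask wins
  tie <- matrix(0L, 30, 30)
  tie[6:10, 6:10] <- 1L      # overlaps prev
  tie[20:24, 20:24] <- 1L    # same area, no overlap
  pt <- postprocess_mask(tie, prev)
  expect_true(all(pt[6:10, 6:10] == 1L))
  expect_true(all(pt[20:24, 20:24] == 0L))

  # empty label stays empty; other labels untouched
  m2 <- matrix(0L, 30, 30); m2[3:8, 3:8] <- 2L
  expect_identical(postprocess_mask(m2, prev), m2)
})

test_that("reference selection maximizes correlation with recency tie-break", {
  sim <- flow_fixture()
  expect_equal(select_reference_frame(1, 0L, sim$video), 0)

  # frame t is a pixel-identical copy of frame 10 -> 10 wins
  video <- sim$video[, , 1:13]
  video[, , 13] <- video[, , 11]        # 0-based frame 12 == frame 10
  sel <- select_reference_frame(12, 0:11, video)
  expect_equal(sel, 10)

  # after the exercise, a resting-geometry candidate is selected, not a
  # late-exercise one (recovery behaviour)
  ph <- sim$truth$phases
  t_rest2 <- ph$start[3] + 1                       # early rest2 frame
  sel2 <- select_reference_frame(t_rest2, 0:(t_rest2 - 1), sim$video)
  plateau <- (ph$start[2] + 6):(ph$end[2] - 6)     # full-contraction frames
  expect_false(sel2 %in% plateau)

  expect_error(select_reference_frame(0, integer(0), sim$video), "t must be")
  expect_error(select_reference_frame(3, c(2L), sim$video), "candidates")
})

test_that("propagation is deterministic and cycle-robust on a low-noise phantom", {
  sim <- simulate_sequence(small_phantom_config(
    rest1_s = 1, exercise_s = 1, rest2_s = 1, speckle_sigma = 0.02,
    thickening_factor = c(OE = 1.3, OI = 1, TrA = 1.3), seed = 9))
  fw <- propagate(sim$video, sim$masks[, , 1])
  fw2 <- propagate(sim$video, sim$masks[, , 1])
  expect_identical(fw, fw2)

  n <- dim(sim$video)[3]
  rev_video <- sim$video[, , n:1]
  bw <- propagate(rev_video, sim$masks[, , n])
  dd <- vapply(seq_len(n), function(t) {
    min(vapply(muscle_labels(), function(lab)
      dice(fw[, , t] == lab, bw[, , n - t + 1] == lab), numeric(1)))
  }, numeric(1))
  expect_gte(min(dd), 0.8)
})
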