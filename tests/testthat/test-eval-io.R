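test_that("dice matches its definition with the empty-empty convention", {
  r <- matrix(0L, 10, 10); r[2:5, 2:5] <- 1L
  expect_equal(dice(r, r), 1)
  y <- matrix(0L, 10, 10); y[7:9, 7:9] <- 1L
  expect_equal(dice(r, y), 0)
  # |R| = 4, |Y| = 4, |R & Y| = 2
  a <- matrix(0L, 5, 5); a[1, 1:4] <- 1L
  b <- matrix(0L, 5, 5); b[1, 3:5] <- 1L; b[2, 5] <- 1L
  expect_equal(dice(a, b), 0.5)
  expect_equal(dice(matrix(0L, 3, 3), matrix(0L, 3, 3)), 1)
  expect_equal(dice(a, b), dice(b, a))
  expect_error(dice(matrix(0, 3, 3), matrix(0, 4, 4)), "same shape")

  # growing Y towards R (Y subset of R) never decreases dice
  prev <- -Inf
  for (k in 1:4) {
    y2 <- matrix(0L, 10, 10); y2[2:(1 + k), 2:5] <- 1L
    d <- dice(r, y2)
    expect_gte(d, prev)
    prev <- d
  }
})

test_that("classification report counts muscle- and subject-level accuracy", {
  rep1 <- classification_report(rep("contracted", 6), rep("contracted", 6),
                                subject = rep(1:2, each = 3))
  expect_equal(rep1$muscle_accuracy, 1)
  expect_equal(rep1$subject_accuracy, 1)

  pred <- c("contracted", "relaxed", "relaxed", "contracted", "relaxed", "contracted")
  ref <- c("contracted", "relaxed", "contracted", "relaxed", "relaxed", "contracted")
  rep2 <- classification_report(pred, ref, subject = rep(c("A", "B"), each = 3))
  expect_equal(rep2$muscle_accuracy, 4 / 6)
  expect_equal(rep2$subject_accuracy, 0)

  expect_error(classification_report(character(0), character(0), character(0)),
               "empty")
  expect_error(classification_report(pred, ref[1:3], rep("A", 6)), "aligned")
})

test_that("video, mask, measurement and parameter files round-trip losslessly", {
  sim <- simulate_sequence(small_phantom_config(rest1_s = 0.5, exercise_s = 0.5,
                                                rest2_s = 0.5, seed = 2))
  td <- withr::local_tempdir()

  vf <- file.path(td, "v.tif")
  write_video_stack(sim$video, vf)
  expect_identical(read_video_stack(vf), sim$video)

  mf <- file.path(td, "m.tif")
  write_mask_stack(sim$masks, mf)
  expect_identical(read_mask_stack(mf), sim$masks)
  bad <- sim$masks; bad[1, 1, 1] <- 7L
  expect_error(write_mask_stack(bad, mf), "unknown label")

  ser <- extract_series(sim$masks, sim$truth$phases)
  ser$thickness_px[3] <- NA   # missing cells must survive the round-trip
  cf <- file.path(td, "meas.csv")
  write_measurements(ser, cf)
  ser2 <- read_measurements(cf, frame_rate = 10)
  expect_equal(ser2$thickness_px, ser$thickness_px)
  expect_equal(ser2$com_px, ser$com_px)
  expect_equal(ser2$phase, ser$phase)
  expect_true(is.na(ser2$thickness_px[3]))

  pf <- file.path(td, "p.json")
  write_params(classifier_params(), pf)
  p <- read_params(pf)
  expect_equal(c(p$t_th, p$t_com, p$d_th, p$d_com), c(24.5, 25.5, -1, 6))

  ff <- file.path(td, "ph.json")
  write_phases(sim$truth$phases, ff)
  ph2 <- read_phases(ff)
  expect_equal(ph2$start, sim$truth$phases$start)
  expect_equal(ph2$end, sim$truth$phases$end)
  expect_equal(attr(ph2, "frame_rate"), 10)
  writeLines('{"frame_rate": 10}', ff)
  expect_error(read_phases(ff), "missing phase metadata")
})

test_that("the command-line interface chains simulate, measure and classify", {
  td <- withr::local_tempdir()
  cfg <- file.path(td, "cfg.yaml")
  yaml::write_yaml(list(image_height = 96L, image_width = 128L, frame_rate = 5,
                        rest1_s = 1, exercise_s = 1, rest2_s = 1,
                        rest_thickness = list(OE = 12, OI = 14, TrA = 9),
                        thickening_factor = list(OE = 1, OI = 1, TrA = 1.5),
                        transition_s = 0.2, speckle_sigma = 0.02), cfg)
  out <- file.path(td, "sim")
  expect_message(rusi_cli(c("simulate", "--config", cfg, "--seed", "4",
                            "--out", out)), "phantom written")
  expect_true(file.exists(file.path(out, "video.tif")))

  meas <- file.path(td, "meas.csv")
  suppressMessages(rusi_cli(c("measure", "--masks", file.path(out, "masks.tif"),
             "--phases", file.path(out, "phases.json"), "--out", meas)))
  expect_true(file.exists(meas))

  res <- file.path(td, "result.json")
  suppressMessages(rusi_cli(c("classify", "--meas", meas, "--out", res)))
  cls <- jsonlite::read_json(res, simplifyVector = TRUE)
  expect_equal(cls$label[cls$muscle == "TrA"], "contracted")
  expect_equal(cls$label[cls$muscle == "OE"], "relaxed")

  rt <- file.path(td, "rt.json")
  suppressMessages(rusi_cli(c("realtime", "--meas", meas,
             "--phases", file.path(out, "phases.json"), "--out", rt)))
  expect_true(file.exists(rt))

  ev <- file.path(td, "ev.json")
  suppressMessages(rusi_cli(c("evaluate", "--pred", file.path(out, "masks.tif"),
             "--ref", file.path(out, "masks.tif"), "--out", ev)))
  expect_equal(jsonlite::read_json(ev, simplifyVector = TRUE)$TrA$median, 1)

  expect_error(rusi_cli(character(0)), "usage")
  expect_error(rusi_cli(c("classify", "--meas", meas)), "--out")
})
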