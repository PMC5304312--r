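# Rendered corneal deformation sequences and their ground-truth consistency.

test_that("apex displacement matches the injected peak deformation", {
  r <- small_render(truth = synthetic_truth(vibration_amp_um = 0, seed = 42),
                    noise_sd = 0)
  rows <- attr(r$truth, "contour_rows")
  apex <- round(attr(r$truth, "apex_col"))
  disp_px <- max(rows[, apex] - rows[1, apex])
  # 1.04 mm at 20 um/px = 52 px, plus whole-eye motion where it overlaps
  expect_gt(disp_px, 52 - 1)
  apex_only <- rows[, apex] - rows[1, apex]
  # at the deformation peak the eye motion ramp is still ~0
  i_pk <- which.min(abs((0:139) * 0.231 - (7.47 + 21.54) / 2))
  expect_equal(apex_only[i_pk], 1.04 / 0.02, tolerance = 0.5)
})

test_that("zero-deformation truth renders a static sequence", {
  tru <- synthetic_truth(max_deformation_mm = 0, vibration_amp_um = 0,
                         eye_motion_mm = 0)
  r <- render_deformation_sequence(tru, rows = 120, cols = 288,
                                   apex_row_px = 25, central_cols = 80,
                                   noise_sd = 0)
  for (i in c(2, 70, 140))
    expect_identical(r$frames$frames[, , i], r$frames$frames[, , 1])
})

test_that("injected vibration appears at the right spectral frequency", {
  tru <- synthetic_truth(vibration_hz = 416, vibration_amp_um = 40, seed = 8)
  r <- small_render(truth = tru, noise_sd = 0)
  rows <- attr(r$truth, "contour_rows")
  apex <- round(attr(r$truth, "apex_col"))
  sig <- rows[, apex] * 0.02   # mm
  prof <- make_profile(sig)
  expect_equal(vibration_frequency(prof), 416, tolerance = 15 / 416)
})

test_that("rendered truth is self-consistent: flatness crossings at the injected applanations", {
  r <- small_render(noise_sd = 0)
  scale_mm <- r$frames$pixel_scale_um / 1000
  rows <- attr(r$truth, "contour_rows")
  flat <- apply(rows, 1, function(y)
    tonopulse:::central_flatness_mm(y * scale_mm, 80))
  prof <- make_profile(rep(0, nrow(rows)), flatness = flat)
  app <- applanation_times(prof)
  expect_equal(unname(app["w1_ms"]), r$truth$applanation1_ms, tolerance = 0.231 / 7.47)
  expect_equal(unname(app["w2_ms"]), r$truth$applanation2_ms, tolerance = 0.231 / 21.54)
})

test_that("geometry outside the frame is rejected before rendering", {
  tru <- synthetic_truth(max_deformation_mm = 3, eye_motion_mm = 2)
  expect_error(render_deformation_sequence(tru, rows = 120, cols = 288,
                                           apex_row_px = 25),
               "outside the frame")
})

test_that("frame sequences round-trip through a per-frame image directory", {
  tru <- synthetic_truth(max_deformation_mm = 0, vibration_amp_um = 0,
                         eye_motion_mm = 0)
  r <- render_deformation_sequence(tru, rows = 60, cols = 100, n_frames = 3,
                                   apex_row_px = 15, central_cols = 40,
                                   flatness_threshold_mm = 0.001,
                                   noise_sd = 0)
  dir <- withr::local_tempdir()
  write_frame_dir(r$frames, dir, format = "png")
  back <- read_frame_dir(dir)
  expect_equal(dim(back$frames), dim(r$frames$frames))
  expect_equal(back$frame_interval_us, 231)
  expect_equal(back$pixel_scale_um, 20)
  expect_lt(max(abs(back$frames - r$frames$frames)), 1 / 255)
})
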