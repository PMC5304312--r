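# Contour extraction: median filter, edge detection, completion, decomposition.

test_that("3x3 median filter: constants, artefact removal, exact median", {
  const <- matrix(7.3, 10, 12)
  expect_equal(median_filter_frame(const), const)

  hot <- matrix(0.2, 20, 20)
  hot[10, 11] <- 1   # single-pixel artefact on a flat background
  expect_equal(median_filter_frame(hot), matrix(0.2, 20, 20))

  patch <- matrix(c(9, 2, 7, 4, 5, 6, 3, 8, 1), 3, 3)
  expect_equal(median_filter_frame(patch)[2, 2], 5)

  # brute-force cross-check with edge replication on a random image
  set.seed(2)
  img <- matrix(runif(30 * 25), 30, 25)
  ref <- img
  for (i in 1:30) for (j in 1:25) {
    ri <- pmin(pmax((i - 1):(i + 1), 1), 30)
    rj <- pmin(pmax((j - 1):(j + 1), 1), 25)
    ref[i, j] <- median(img[ri, rj])
  }
  expect_equal(median_filter_frame(img), ref)
  expect_error(median_filter_frame(matrix(1, 2, 5)), "3x3")
})

test_that("edge detection finds a sharp band boundary to sub-pixel accuracy", {
  img <- matrix(0.1, 200, 80)
  img[100:130, ] <- 0.9   # top boundary between rows 99 and 100
  det <- detect_corneal_edge(img)
  expect_true(all(det$valid))
  expect_true(all(abs(det$rows - 100) <= 0.5))
})

test_that("occluded columns are flagged invalid and completed by the polynomial", {
  r <- small_render(noise_sd = 0)
  frame <- r$frames$frames[, , 1]
  occ <- 120:149
  frame[, occ] <- 0.08   # 30-column occlusion
  det <- detect_corneal_edge(median_filter_frame(frame))
  expect_gte(sum(!det$valid[occ]), 28)  # interior of the gap undetectable
  comp <- complete_contour(det$rows, det$valid)
  truth <- attr(r$truth, "contour_rows")[1, ]
  expect_true(all(abs(comp$rows[occ] - truth[occ]) < 0.5))
  expect_true(all(comp$filled[!det$valid]))
})

test_that("contours on noiseless and noisy renders track the truth", {
  tru <- synthetic_truth(vibration_amp_um = 0, eye_motion_mm = 0.2, seed = 2)
  truth_rows <- NULL
  for (noise in c(0, 0.02)) {
    r <- small_render(truth = tru, noise_sd = noise)
    cont <- extract_contours(r$frames)
    truth_rows <- attr(r$truth, "contour_rows")
    err <- abs(cont$y - truth_rows)
    if (noise == 0) {
      expect_lt(max(err), 0.5)    # sub-pixel recovery everywhere
    } else {
      expect_lt(mean(err), 1)     # within the +/-1 px detection error budget
    }
  }
})

test_that("polynomial completion is exact in-class and rejects sparse input", {
  n <- 1:200
  x <- (n - 100.5) / 100
  poly5 <- 80 + 5 * x - 12 * x^2 + 3 * x^3 + 6 * x^4 - 2 * x^5
  valid <- rep(TRUE, 200); valid[60:110] <- FALSE
  comp <- complete_contour(replace(poly5, !valid, NA), valid)
  expect_equal(comp$rows, poly5, tolerance = 1e-8)

  parab <- 90 + 20 * x^2
  valid2 <- rep(TRUE, 200); valid2[80:120] <- FALSE
  comp2 <- complete_contour(replace(parab, !valid2, NA), valid2)
  expect_true(all(abs(comp2$rows - parab) < 0.1))

  expect_error(complete_contour(replace(poly5, 12:200, NA),
                                c(rep(TRUE, 11), rep(FALSE, 189))),
               "valid columns")
  # valid points spanning less than half the window are also rejected
  vspan <- rep(FALSE, 200); vspan[1:60] <- TRUE
  expect_error(complete_contour(replace(poly5, 61:200, NA), vspan), "span")
})

test_that("polynomial completion is idempotent", {
  n <- 1:150
  x <- (n - 75.5) / 75
  base <- 70 + 10 * x^2 - 4 * x^4
  valid <- rep(TRUE, 150); valid[40:70] <- FALSE
  comp <- complete_contour(replace(base, !valid, NA), valid)
  again <- complete_contour(comp$rows, rep(TRUE, 150))
  expect_identical(again$rows, comp$rows)
  expect_false(any(again$filled))
})

test_that("decomposition separates rigid shifts from corneal reaction", {
  rest <- 50 + 0.002 * (1:200 - 100.5)^2
  y <- rbind(rest, rest + 10, rest + 10)   # pure 0.2 mm whole-eye shift
  dec <- decompose_response(make_contour_set(y))
  expect_equal(dec$eye_motion, c(0, 0.2, 0.2), tolerance = 1e-12)
  expect_lt(max(abs(dec$corneal_reaction)), 1e-12)

  # pure central indentation: eye motion stays 0, apex reaction is injected
  bump <- 8 * exp(-((1:200) - 100.5)^2 / (2 * 15^2))
  y2 <- rbind(rest, rest + bump)
  dec2 <- decompose_response(make_contour_set(y2))
  expect_lt(abs(dec2$eye_motion[2]), 1e-6)
  expect_equal(max(dec2$corneal_reaction[2, ]), max(bump) * 0.02,
               tolerance = 1e-6)

  # frame 1 is its own reference
  expect_equal(dec2$corneal_reaction[1, ], rep(0, 200))
})

test_that("decomposition additivity: a constant rigid shift moves only eye_motion", {
  r <- small_render(noise_sd = 0)
  cont <- extract_contours(r$frames)
  dec <- decompose_response(cont)
  shifted <- cont
  shifted$y <- cont$y + 3          # +3 px on every frame including the rest frame
  shifted$y[1, ] <- cont$y[1, ]    # keep the resting reference
  dec_s <- decompose_response(shifted)
  expect_equal(dec_s$eye_motion[-1], dec$eye_motion[-1] + 3 * 0.02,
               tolerance = 1e-10)
  expect_equal(dec_s$corneal_reaction, dec$corneal_reaction, tolerance = 1e-10)
})

test_that("pure rendered indentation recovers the injected apex amplitude", {
  tru <- synthetic_truth(vibration_amp_um = 0, eye_motion_mm = 0, seed = 13)
  r <- small_render(truth = tru, noise_sd = 0)
  cont <- extract_contours(r$frames)
  dec <- decompose_response(cont)
  expect_lt(max(abs(dec$eye_motion)), 0.01)
  expect_equal(max(dec$corneal_reaction), 1.04, tolerance = 0.02 / 1.04)
})

test_that("unusable frames are flagged instead of crashing the stack", {
  r <- small_render(noise_sd = 0)
  frames <- r$frames$frames[, , 1:5]
  frames[, , 3] <- 0.08   # featureless frame
  fs <- frame_sequence(frames)
  cont <- extract_contours(fs)
  expect_false(cont$frame_ok[3])
  expect_true(all(cont$frame_ok[-3]))
  # losing the resting frame is fatal for decomposition
  frames2 <- r$frames$frames[, , 1:5]
  frames2[, , 1] <- 0.08
  cont2 <- extract_contours(frame_sequence(frames2))
  expect_error(decompose_response(cont2), "resting reference")
})
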