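# Synthetic data generators: pulse traces, IOP readings, cohorts.

test_that("zero-jitter pulse trace is periodic with the requested rate", {
  tr <- generate_pulse_trace(84, 5, jitter_frac = 0, seed = 1)
  peaks <- attr(tr, "truth_peaks_s")
  expect_equal(diff(peaks), rep(60 / 84, length(peaks) - 1), tolerance = 1e-10)
  b <- detect_beats(tr)
  # detected systolic spacing matches the 714.3 ms beat period
  expect_true(all(abs(diff(b$peak_times_s) - 60 / 84) < 0.002))
  # phase at any detected peak is 0 (the origin convention)
  for (pk in b$peak_times_s[2:4])
    expect_lt(min(phase_at(tr, pk, b), 360 - phase_at(tr, pk, b)), 1)
})

test_that("per-beat jitter stays within the requested fraction", {
  tr <- generate_pulse_trace(84, 6, jitter_frac = 0.04, seed = 7)
  periods <- diff(attr(tr, "truth_peaks_s"))
  expect_true(all(abs(diff(periods)) <= 0.04 * mean(periods)))
})

test_that("trigger is placed at the requested cardiac phase", {
  for (phi in c(0, 90, 200, 345)) {
    tr <- generate_pulse_trace(84, 6, jitter_frac = 0, trigger_phase_deg = phi,
                               seed = 5)
    b <- detect_beats(tr)
    got <- phase_at(tr, tr$trigger_time_s, b)
    expect_lt(abs(angle_diff_deg(got, phi)), 1)
  }
})

test_that("pulse rate outside the device range is rejected", {
  expect_error(generate_pulse_trace(10, 10), "device range")
  expect_error(generate_pulse_trace(300, 10), "device range")
  expect_error(generate_pulse_trace(84, 1), "at least 3 beats")
})

test_that("IOP readings follow the cosine modulation model", {
  flat <- synthetic_truth(iop_baseline_mmHg = 15.25, iop_mod_amp_mmHg = 0,
                          noise_sd_mmHg = 0)
  expect_equal(generate_iop_readings(flat, c(0, 45, 270)),
               rep(15.25, 3))
  tru <- synthetic_truth(iop_baseline_mmHg = 15, iop_mod_amp_mmHg = 1,
                         phase_offset_deg = 60, noise_sd_mmHg = 0)
  expect_equal(generate_iop_readings(tru, 60), 16.0)   # cosine maximum
  expect_equal(generate_iop_readings(tru, 240), 14.0)  # opposite phase
  # noiseless argmax over a fine grid sits exactly at the offset
  grid <- seq(0, 359.5, by = 0.5)
  expect_equal(grid[which.max(generate_iop_readings(tru, grid))], 60)
  expect_error(generate_iop_readings(tru, 400), "\\[0, 360\\)")
})

test_that("synthetic truth enforces its invariants", {
  expect_error(synthetic_truth(applanation1_ms = 22, applanation2_ms = 21),
               "applanation1_ms")
  expect_error(synthetic_truth(applanation2_ms = 40), "applanation")
  expect_error(synthetic_truth(vibration_hz = 50), "vibration_hz")
  expect_error(synthetic_truth(vibration_hz = 3000), "vibration_hz")
  expect_error(synthetic_truth(max_deformation_mm = -1), ">= 0")
})

test_that("cohort generation: size, even phasing, determinism", {
  co <- generate_cohort(10, 6, seed = 3)
  expect_equal(nrow(co$records), 60)
  expect_equal(length(co$truths), 10)
  expect_true(all(co$records$w6_deg %in% seq(0, 330, 30)))

  # exact even phasing: binned phases pairwise >= 30 deg apart
  cfg0 <- cohort_config(phase_jitter_sd_deg = 0)
  co0 <- generate_cohort(4, 6, config = cfg0, seed = 9)
  for (v in 1:4) {
    bins <- sort(co0$records$w6_deg[co0$records$subject == v])
    gaps <- diff(c(bins, bins[1] + 360))
    expect_true(all(gaps >= 30))
  }

  # bit-identical regeneration under the same seed
  expect_identical(generate_cohort(5, 6, seed = 11)$records,
                   generate_cohort(5, 6, seed = 11)$records)
  expect_error(generate_cohort(5, 2), "at least 3")
})
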