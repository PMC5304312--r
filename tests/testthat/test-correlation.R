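# Phase-shift correlation scan, significance, rejection, summaries.

test_that("pearson_r: exact cases and agreement with stats::cor", {
  expect_equal(pearson_r(1:6, 2 * (1:6) + 1), 1)
  expect_equal(pearson_r(1:6, -(1:6)), -1)
  # frozen value computed by hand from the defining sums (14.5 / 17.5)
  expect_equal(pearson_r(1:6, c(2, 1, 4, 3, 6, 5)), 0.8285714285714286,
               tolerance = 1e-12)
  set.seed(3)
  for (i in 1:20) {
    x <- rnorm(sample(3:40, 1)); y <- rnorm(length(x))
    expect_equal(pearson_r(x, y), cor(x, y), tolerance = 1e-12)
  }
  expect_error(pearson_r(rep(1, 5), 1:5), "undefined correlation")
  expect_error(pearson_r(1:2, 1:2), "at least 3")
})

test_that("shift_phase wraps correctly", {
  expect_equal(shift_phase(350, 30), 20)
  expect_equal(shift_phase(c(0, 120, 350), 0), c(0, 120, 350))
  expect_equal(shift_phase(c(0, 120, 350), 360), c(0, 120, 350))
  expect_error(shift_phase(400, 0), "\\[0, 360\\)")
})

test_that("scan recovers a noiseless cosine modulation at its offset", {
  th <- c(0, 60, 120, 180, 240, 300)
  for (off in c(0, 40, 60, 170, 310)) {
    tru <- synthetic_truth(phase_offset_deg = off, noise_sd_mmHg = 0)
    s <- scan_phase_shifts(generate_iop_readings(tru, th), th)
    expect_equal(s$phi_max_deg, off)
    expect_equal(s$r_max, 1, tolerance = 1e-9)
    expect_equal(wrap_deg(s$phi_min_deg - s$phi_max_deg), 180)
    expect_equal(s$r_min, -1, tolerance = 1e-9)
  }
})

test_that("linear-mode self-correlation peaks at the inverse shift", {
  th <- c(0, 60, 120, 180, 240, 300)
  delta <- 110
  w <- shift_phase(th, delta)
  s <- scan_phase_shifts(w, th, mode = "linear")
  # feature IS the phase shifted by delta: r = 1 exactly when the scan
  # applies the same shift (other shifts that keep the wrap pattern intact
  # tie at r = 1; the argmax then breaks toward the smallest such shift)
  expect_equal(s$r[s$phi_grid_deg == delta], 1, tolerance = 1e-12)
  expect_equal(s$r_max, 1, tolerance = 1e-12)
  expect_lte(s$phi_max_deg, delta)
})

test_that("antisymmetry r(phi + 180) = -r(phi) holds for arbitrary features", {
  set.seed(8)
  grid <- seq(0, 350, 10)
  for (i in 1:10) {
    th <- wrap_deg(runif(1, 0, 60) + (0:5) * 60)
    w <- rnorm(6)
    s <- scan_phase_shifts(w, th, grid)
    flipped <- s$r[match(wrap_deg(grid + 180), grid)]
    expect_equal(flipped, -s$r, tolerance = 1e-12)
  }
})

test_that("shift-equivariance: rotating all phases moves the argmax with them", {
  set.seed(9)
  th <- wrap_deg(17 + (0:5) * 60)
  w <- rnorm(6) + cospi((th - 80) / 180)
  s0 <- scan_phase_shifts(w, th)
  for (delta in c(30, 120, 250)) {
    s1 <- scan_phase_shifts(w, shift_phase(th, delta))
    expect_equal(s1$phi_max_deg, wrap_deg(s0$phi_max_deg + delta))
    expect_equal(s1$r_max, s0$r_max, tolerance = 1e-12)
  }
})

test_that("scan preconditions and tie-breaking", {
  expect_error(scan_phase_shifts(1:2, c(0, 30)), "at least 3")
  expect_error(scan_phase_shifts(1:4, c(0, 0, 0, 30)), "distinct")
  # constant feature: correlation undefined at every shift
  expect_error(scan_phase_shifts(rep(5, 6), c(0, 60, 120, 180, 240, 300)),
               "undefined correlation")
})

test_that("significance follows Student's t on K - 2 df", {
  expect_equal(correlation_significance(0, 10), 1)
  expect_lt(correlation_significance(0.95, 6), 0.05)
  # r = 0.811 at K = 6 sits essentially at the p = 0.05 boundary
  expect_equal(correlation_significance(0.811, 6), 0.05, tolerance = 0.05)
  expect_lt(abs(correlation_significance(0.811, 6) - 0.05), 0.002)
  expect_equal(correlation_significance(1, 5), 0)
  expect_equal(correlation_significance(-1, 5), 0)
  # cross-check against cor.test on a concrete sample
  set.seed(4)
  x <- rnorm(8); y <- x + rnorm(8)
  ct <- cor.test(x, y)
  expect_equal(correlation_significance(unname(ct$estimate), 8), ct$p.value,
               tolerance = 1e-10)
})

test_that("outlier rejection presets retain the documented subject counts", {
  ext <- reference_correlation_extrema()
  thick <- reject_outliers(ext, "thick")
  expect_equal(sum(thick$retained), 9)
  expect_false(thick$retained[ext$subject == 6])
  strict <- reject_outliers(ext, "strict")
  expect_equal(sum(strict$retained), 7)
  expect_equal(sort(ext$subject[!strict$retained]), c(4, 6, 7))
  all_in <- reject_outliers(ext, min_abs_r = 0)
  expect_true(all(all_in$retained))
  expect_error(reject_outliers(ext, min_abs_r = 1.5), "empty retained set")
})

test_that("feature summary reproduces the reference single-subject aggregates", {
  t1 <- reference_subject1_features()
  t1$subject <- 1
  summ <- summarize_features(t1)
  expect_equal(summ$w5_mmHg_mean, 15.25)
  expect_equal(summ$w5_mmHg_sd, 0.61, tolerance = 0.01)
  expect_equal(summ$w1_ms_mean, 7.47, tolerance = 0.001)
  # population mode uses the 1/N denominator
  summ_pop <- summarize_features(t1, std_mode = "population")
  expect_equal(summ_pop$w5_mmHg_sd,
               summ$w5_mmHg_sd * sqrt(5 / 6), tolerance = 1e-12)
})

test_that("cohort summary pools retained correlations and flags significance", {
  co <- generate_cohort(6, 6, seed = 15)
  scan <- scan_cohort(co$records)
  summ <- cohort_summary(co$records, scan)
  expect_s3_class(summ, "cohort_summary")
  expect_equal(nrow(summ$features), 6)
  expect_true(summ$pooled$n_retained <= 6)
  expect_true(all(summ$extrema$r_max >= -1 & summ$extrema$r_max <= 1))
  expect_equal(summ$iop_nonsync_spread_mmHg, max(summ$features$w5_mmHg_sd))
  # single retained subject: sample sd undefined and flagged as NA
  one <- cohort_summary(co$records[co$records$subject == 1, ],
                        list(scans = scan$scans[1],
                             extrema = scan$extrema[1, ]))
  expect_true(is.na(one$pooled$r_max_sd_sample))
})

test_that("circular mean behaves on wrapped angle sets", {
  expect_equal(circular_mean_deg(c(350, 10)), 0)
  expect_equal(circular_mean_deg(c(80, 100)), 90)
  expect_true(is.na(circular_mean_deg(c(0, 180))))
  # matches the naive mean away from the wrap point
  set.seed(1)
  x <- runif(50, 100, 140)
  expect_equal(circular_mean_deg(x), mean(x), tolerance = 0.5)
})
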