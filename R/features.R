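# Measurement features w(1)..w(6).
#
#   w(1) first applanation time (ms)    w(4) corneal vibration frequency (Hz)
#   w(2) second applanation time (ms)   w(5) IOP, device-reported (mmHg)
#   w(3) maximum corneal deformation (mm)  w(6) pulse-phase bin at trigger (deg)

#' Build a deformation profile from a response decomposition
#'
#' Reduces the per-column corneal reaction to the two time series the
#' feature extractors need: the apex reaction amplitude and the central
#' flatness.  The apex signal is averaged over a small column neighbourhood
#' to suppress pixel-level detection noise; the flatness statistic is the
#' RMS deviation of a quadratic fit to the central-region contour from its
#' best straight line (the quadratic fit rejects per-column noise that would
#' otherwise saturate the micrometre-scale flatness threshold).
#'
#' @param decomp a [decompose_response()] result.
#' @param contours the matching `contour_set` (supplies the raw contour for
#'   the flatness statistic).
#' @param apex_col apex column; `NULL` locates it as the column of maximum
#'   reaction (restricted to the central third) at the frame of maximum
#'   overall reaction.
#' @param apex_halfwidth columns averaged on each side of the apex.
#' @param central_cols width (columns) of the central flatness window.
#' @return object of class `deformation_profile`: list with `time_ms`,
#'   `apex_mm`, `vib_mm` (wide-average apex signal for the vibration
#'   stage), `central_flatness` (mm), `apex_col`, `frame_ok`.
#' @export
deformation_profile <- function(decomp, contours, apex_col = NULL,
                                apex_halfwidth = 5, central_cols = 150) {
  stopifnot(inherits(decomp, "response_decomposition"))
  rx <- decomp$corneal_reaction
  I <- nrow(rx); N <- ncol(rx)
  if (is.null(apex_col)) {
    central_third <- seq.int(floor(N / 3), ceiling(2 * N / 3))
    pk_frame <- which.max(apply(rx[, central_third, drop = FALSE], 1,
                                function(z) max(z, na.rm = TRUE)))
    apex_col <- central_third[which.max(rx[pk_frame, central_third])]
  }
  cols <- max(1, apex_col - apex_halfwidth):min(N, apex_col + apex_halfwidth)
  apex_mm <- rowMeans(rx[, cols, drop = FALSE])
  scale_mm <- decomp$pixel_scale_um / 1000
  # Wider, Gaussian-weighted apex signal for the vibration stage: the
  # corneal vibration has a millimetre-scale footprint, so averaging over
  # +/- 1 mm (weight sd 0.5 mm) trades a few percent of amplitude for a
  # several-fold reduction in per-frame detection noise.
  half_w <- round(1 / scale_mm)
  wcols <- max(1, apex_col - half_w):min(N, apex_col + half_w)
  wts <- exp(-((wcols - apex_col) * scale_mm)^2 / (2 * 0.5^2))
  vib_mm <- as.vector(rx[, wcols, drop = FALSE] %*% wts) / sum(wts)
  flat <- vapply(seq_len(I), function(i) {
    if (!decomp$frame_ok[i]) return(NA_real_)
    central_flatness_mm(contours$y[i, ] * scale_mm, central_cols)
  }, numeric(1))
  structure(
    list(time_ms = (seq_len(I) - 1) * decomp$frame_interval_us / 1000,
         apex_mm = apex_mm,
         vib_mm = vib_mm,
         central_flatness = flat,
         apex_col = apex_col,
         frame_ok = decomp$frame_ok),
    class = "deformation_profile")
}

#' Applanation times from the central-flatness series
#'
#' The first applanation `w(1)` is the first time the central flatness drops
#' below the threshold (the cornea passes through geometric flatness on the
#' way in); the second applanation `w(2)` is the last time it rises back
#' above the threshold after the deformation peak (flat again on the way
#' out).  Crossings are located by linear interpolation between frames, so
#' the result is not quantized to the 231 us frame interval.
#'
#' @param profile a [deformation_profile()].
#' @param flatness_threshold_mm applanation criterion (default 5 um).
#' @param smooth_window odd Savitzky-Golay window (frames) applied to the
#'   flatness series before crossing detection; the quadratic smoother is
#'   exact on the locally linear approach to the crossing, so it suppresses
#'   frame-to-frame noise without biasing the crossing time.  `0` disables.
#' @return named numeric `c(w1_ms, w2_ms)`.
#' @export
applanation_times <- function(profile, flatness_threshold_mm = 0.005,
                              smooth_window = 5) {
  f <- profile$central_flatness
  t <- profile$time_ms
  if (smooth_window >= 3 && !anyNA(f) && length(f) > smooth_window)
    f <- pmax(signal::sgolayfilt(f, p = 2, n = smooth_window), 0)
  ok <- !is.na(f)
  below <- which(ok & f < flatness_threshold_mm)
  if (length(below) == 0)
    stopf("no applanation: central flatness never crosses %.4g mm",
          flatness_threshold_mm)
  i1 <- below[1]
  w1 <- if (i1 == 1) t[1] else
    t[i1 - 1] + (t[i1] - t[i1 - 1]) *
      (f[i1 - 1] - flatness_threshold_mm) / (f[i1 - 1] - f[i1])
  i2 <- below[length(below)]
  w2 <- if (i2 >= length(f)) t[length(f)] else
    t[i2] + (t[i2 + 1] - t[i2]) *
      (flatness_threshold_mm - f[i2]) / (f[i2 + 1] - f[i2])
  if (w2 <= w1)
    stopf("no applanation: flatness crossing pattern degenerate")
  c(w1_ms = w1, w2_ms = w2)
}

#' Maximum corneal deformation
#'
#' Maximum of the apex reaction with parabolic sub-frame refinement over the
#' three frames around the discrete maximum.  By default the
#' high-frequency corneal vibration riding on the apex is removed first by
#' Savitzky-Golay smoothing (cubic, 21-frame window), so the reported
#' maximum is that of the deformation pulse itself, not pulse + vibration;
#' the smoother reproduces polynomials up to degree 3 exactly, so smooth
#' profiles are unaffected.
#'
#' @param profile a [deformation_profile()].
#' @param vibration_reject smooth out the >100 Hz vibration before peak
#'   picking.
#' @return maximum deformation `w(3)` in mm.
#' @export
max_deformation <- function(profile, vibration_reject = TRUE) {
  a <- profile$apex_mm
  if (length(a) == 0) stopf("empty profile")
  if (vibration_reject && length(a) >= 21)
    a <- signal::sgolayfilt(a, p = 3, n = 21)
  i <- which.max(a)
  if (i == 1 || i == length(a)) return(a[i])
  parabolic_refine(a[i - 1], a[i], a[i + 1])$value
}

#' Corneal vibration frequency (> 100 Hz)
#'
#' Detrends the apex signal in two steps - a low-order polynomial fit
#' (default degree 4) followed by subtraction of a Savitzky-Golay smooth
#' (cubic, 21-frame window) - then applies a Hann taper, zero-pads at least
#' 4x, and returns the frequency of the largest magnitude-spectrum peak
#' above `lowcut_hz`, sharpened by parabolic bin interpolation.  The
#' polynomial alone cannot follow the compactly supported deformation
#' pulse, whose spectral leakage extends past 100 Hz and would otherwise
#' mask micrometre-scale vibrations; the smoothing subtraction acts as a
#' high-pass with an effective cutoff near 250 Hz while leaving any
#' constant, linear or cubic trend exactly removed.  The sampling rate
#' follows from the 231 us frame interval (about 4329 Hz).  A peak must
#' exceed `floor_factor` times the median spectral magnitude above the
#' cutoff and correspond to an apex amplitude of at least `min_amp_um`
#' (the practical detection limit given the 20 um/px resolution);
#' otherwise no vibration is reported.
#'
#' @param profile a [deformation_profile()].
#' @param lowcut_hz lower edge of the search band (default 100 Hz).
#' @param detrend_degree polynomial degree removed before the FFT.
#' @param sg_window Savitzky-Golay window length (odd; `0` disables the
#'   smoothing subtraction).
#' @param pad_factor zero-padding factor (>= 4).
#' @param floor_factor peak-to-median noise-floor factor.
#' @param min_amp_um minimum detectable vibration amplitude (um).
#' @return vibration frequency `w(4)` in Hz.
#' @export
vibration_frequency <- function(profile, lowcut_hz = 100,
                                detrend_degree = 4, sg_window = 21,
                                pad_factor = 4,
                                floor_factor = 6, min_amp_um = 2) {
  a <- profile$vib_mm %||% profile$apex_mm
  n <- length(a)
  if (n < 64) stopf("need at least 64 frames for spectral analysis")
  dt_s <- (profile$time_ms[2] - profile$time_ms[1]) / 1000
  fs <- 1 / dt_s
  x <- seq_len(n)
  X <- outer((x - mean(x)) / (n / 2), 0:detrend_degree, `^`)
  resid_raw <- a - lm.fit(X, a)$fitted.values
  resid <- resid_raw
  if (sg_window >= 5 && sg_window < n)
    resid <- resid - signal::sgolayfilt(resid, p = 3, n = sg_window)
  hann <- 0.5 - 0.5 * cospi(2 * (x - 1) / (n - 1))
  nfft <- 2^ceiling(log2(pad_factor * n))
  mag_of <- function(sig) {
    abs(fft(c(sig * hann, rep(0, nfft - n))))[seq_len(nfft %/% 2)]
  }
  spec <- mag_of(resid)
  freq <- (seq_len(nfft %/% 2) - 1) * fs / nfft
  band <- which(freq > lowcut_hz)
  i <- band[which.max(spec[band])]
  noise_floor <- median(spec[band])
  # amplitude estimate: Hann coherent gain is sum(hann)/2 per unit amplitude
  amp_um <- spec[i] / (sum(hann) / 2) * 1000
  if (spec[i] < floor_factor * noise_floor || amp_um < min_amp_um)
    stopf("no vibration detected above %g Hz", lowcut_hz)
  # The smoothing subtraction has a rippled response around several hundred
  # hertz that can tilt the spectral lobe; the final frequency is therefore
  # refined on the polynomial-only residual, restricted to a narrow band
  # around the detected peak where the slow-pulse leakage is negligible.
  spec_raw <- mag_of(resid_raw)
  local <- which(freq > max(lowcut_hz, freq[i] - 50) & freq < freq[i] + 50)
  j <- local[which.max(spec_raw[local])]
  if (j > 1 && j < length(spec_raw)) {
    ref <- parabolic_refine(spec_raw[j - 1], spec_raw[j], spec_raw[j + 1])
    freq[j] + ref$offset * fs / nfft
  } else {
    freq[j]
  }
}

#' Assemble and validate a feature vector
#'
#' Enforces the feature invariants: `w1 < w2`, `w3 > 0`, `w4 > 100` Hz
#' (strict), `w6` on the 30-degree bin grid.  `w5` is the device-reported
#' IOP, passed through untouched - it is never image-derived.
#'
#' @param w1_ms,w2_ms applanation times (ms).
#' @param w3_mm maximum deformation (mm).
#' @param w4_hz vibration frequency (Hz).
#' @param iop_mmHg device IOP reading, becomes `w5_mmHg`.
#' @param phase_bin_deg binned pulse phase from [bin_phase()], becomes
#'   `w6_deg`.
#' @return one-row `data.frame` with columns `w1_ms..w6_deg`.
#' @export
assemble_feature_vector <- function(w1_ms, w2_ms, w3_mm, w4_hz, iop_mmHg,
                                    phase_bin_deg) {
  if (!(w1_ms < w2_ms)) stopf("rejected: w1 (%.3f) must precede w2 (%.3f)", w1_ms, w2_ms)
  if (!(w3_mm > 0)) stopf("rejected: w3 must be positive")
  if (!(w4_hz > 100)) stopf("rejected: w4 must exceed 100 Hz (got %g)", w4_hz)
  if (!(phase_bin_deg %in% seq(0, 330, 30)))
    stopf("rejected: w6 must be a 30-degree bin in 0..330")
  data.frame(w1_ms = w1_ms, w2_ms = w2_ms, w3_mm = w3_mm, w4_hz = w4_hz,
             w5_mmHg = iop_mmHg, w6_deg = phase_bin_deg)
}

#' Extract image-derived features from a frame sequence
#'
#' Convenience wrapper: contours, decomposition, deformation profile, then
#' `w(1)..w(4)`.
#'
#' @param fs a [frame_sequence()].
#' @param low_frac,high_frac edge-detection thresholds.
#' @param peripheral_frac whole-eye estimation window.
#' @param central_cols,flatness_threshold_mm applanation criterion.
#' @param ... passed to [vibration_frequency()].
#' @return list with `w1_ms`, `w2_ms`, `w3_mm`, `w4_hz` (NA when no
#'   vibration is detected), plus the intermediate `profile`.
#' @export
extract_sequence_features <- function(fs, low_frac = 0.1, high_frac = 0.3,
                                      peripheral_frac = 0.1,
                                      central_cols = 150,
                                      flatness_threshold_mm = 0.005, ...) {
  contours <- extract_contours(fs, low_frac, high_frac)
  decomp <- decompose_response(contours, peripheral_frac)
  profile <- deformation_profile(decomp, contours, central_cols = central_cols)
  app <- applanation_times(profile, flatness_threshold_mm)
  w4 <- tryCatch(vibration_frequency(profile, ...), error = function(e) NA_real_)
  list(w1_ms = unname(app["w1_ms"]), w2_ms = unname(app["w2_ms"]),
       w3_mm = max_deformation(profile), w4_hz = w4, profile = profile)
}
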