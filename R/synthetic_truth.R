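# Ground truth for one synthetic measurement.

#' Ground truth for a synthetic tonometry measurement
#'
#' Bundles every quantity the synthetic renderer and IOP generator need, so
#' that downstream recovery can be checked against known values.  Defaults
#' are the package's documented study conditions: applanations at 7.47 and
#' 21.54 ms, 1.04 mm maximum deformation, a 416 Hz corneal vibration of
#' 20 um, 0.3 mm whole-eye retraction, and an IOP modulated by the cardiac
#' phase as `baseline + amp * cos(phase - phase_offset)` with the IOP maximum
#' lagging the finger-pulse systolic peak by 60 degrees.
#'
#' @param applanation1_ms,applanation2_ms first/second applanation times (ms);
#'   must satisfy `0 < t1 < t2 <` total sequence duration (32.34 ms minus one
#'   frame at the default time base).
#' @param max_deformation_mm peak corneal reaction amplitude at the apex (mm).
#' @param vibration_hz frequency of the superimposed corneal vibration (Hz);
#'   must exceed 100 Hz and stay below the Nyquist limit of the frame rate
#'   (about 2164 Hz at 231 us/frame).
#' @param vibration_amp_um vibration amplitude at the apex (um).
#' @param eye_motion_mm peak whole-eye retraction reached after the
#'   deformation peak (mm).
#' @param iop_baseline_mmHg subject baseline IOP (mmHg).
#' @param iop_mod_amp_mmHg amplitude of the cardiac IOP modulation (mmHg).
#' @param phase_offset_deg cardiac phase (deg) at which the IOP is maximal,
#'   measured from the finger-pulse systolic peak.
#' @param noise_sd_mmHg Gaussian noise added to IOP readings (mmHg).
#' @param seed integer seed used wherever this truth drives randomness.
#' @return object of class `synthetic_truth` (a validated list).
#' @export
synthetic_truth <- function(applanation1_ms = 7.47,
                            applanation2_ms = 21.54,
                            max_deformation_mm = 1.04,
                            vibration_hz = 416,
                            vibration_amp_um = 20,
                            eye_motion_mm = 0.3,
                            iop_baseline_mmHg = 12,
                            iop_mod_amp_mmHg = 0.75,
                            phase_offset_deg = 60,
                            noise_sd_mmHg = 0.25,
                            seed = 1L) {
  total_ms <- 139 * 0.231
  nyquist_hz <- 1e6 / 231 / 2
  if (!(applanation1_ms > 0 && applanation1_ms < applanation2_ms &&
        applanation2_ms < total_ms))
    stopf("need 0 < applanation1_ms < applanation2_ms < %.2f ms", total_ms)
  if (!(vibration_hz > 100 && vibration_hz < nyquist_hz))
    stopf("vibration_hz must lie in (100, %.0f) Hz", nyquist_hz)
  amps <- c(max_deformation_mm, vibration_amp_um, eye_motion_mm,
            iop_mod_amp_mmHg, noise_sd_mmHg)
  if (any(amps < 0)) stopf("amplitudes and noise levels must be >= 0")
  structure(
    list(applanation1_ms = applanation1_ms,
         applanation2_ms = applanation2_ms,
         max_deformation_mm = max_deformation_mm,
         vibration_hz = vibration_hz,
         vibration_amp_um = vibration_amp_um,
         eye_motion_mm = eye_motion_mm,
         iop_baseline_mmHg = iop_baseline_mmHg,
         iop_mod_amp_mmHg = iop_mod_amp_mmHg,
         phase_offset_deg = wrap_deg(phase_offset_deg),
         noise_sd_mmHg = noise_sd_mmHg,
         seed = as.integer(seed)),
    class = "synthetic_truth")
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf(
    paste0("<synthetic_truth> applanations %.2f/%.2f ms, peak %.2f mm, ",
           "vibration %g Hz @ %g um, eye motion %g mm\n",
           "  IOP %.2f + %.2f cos(phase - %g deg) mmHg, noise sd %.2f, seed %d\n"),
    x$applanation1_ms, x$applanation2_ms, x$max_deformation_mm,
    x$vibration_hz, x$vibration_amp_um, x$eye_motion_mm,
    x$iop_baseline_mmHg, x$iop_mod_amp_mmHg, x$phase_offset_deg,
    x$noise_sd_mmHg, x$seed))
  invisible(x)
}

#' Generate IOP readings under the cardiac-phase modulation model
#'
#' The generative model the correlation analysis assumes: each reading is
#' `baseline + amp * cos(phase - phase_offset) + N(0, noise_sd)`, so the
#' noiseless maximum occurs exactly at `phase = phase_offset`.
#'
#' @param truth a [synthetic_truth()] supplying baseline, modulation
#'   amplitude, phase offset and noise level.
#' @param phases_deg cardiac phases (deg, in `[0, 360)`) at which readings
#'   are taken.
#' @param seed optional integer seed for the noise; defaults to the truth's.
#' @return numeric vector of IOP readings (mmHg), one per phase.
#' @export
generate_iop_readings <- function(truth, phases_deg, seed = NULL) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (any(phases_deg < 0 | phases_deg >= 360))
    stopf("phases_deg must lie in [0, 360)")
  iop <- truth$iop_baseline_mmHg +
    truth$iop_mod_amp_mmHg * cospi((phases_deg - truth$phase_offset_deg) / 180)
  if (truth$noise_sd_mmHg > 0) {
    set.seed(seed %||% truth$seed)
    iop <- iop + rnorm(length(phases_deg), 0, truth$noise_sd_mmHg)
  }
  iop
}
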