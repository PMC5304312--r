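# Synthetic pulse-oximeter traces.
#
# Only the cardiac *phase* enters the downstream analysis, so the waveform
# model is deliberately simple: a periodic von-Mises-shaped pulse (fundamental
# plus harmonics) with a time warp that makes the systolic upstroke fast and
# the decay slow.  The systolic peak sits exactly at phase 0 of each beat.

#' Construct a pulse trace
#'
#' @param samples amplitude samples in percent (`[0, 100]`), uniformly spaced.
#' @param sample_rate_hz sampling rate (Hz).
#' @param trigger_time_s time of the tonometer trigger within the trace (s).
#' @return object of class `pulse_trace`.
#' @export
pulse_trace <- function(samples, sample_rate_hz, trigger_time_s) {
  if (any(samples < 0 | samples > 100))
    stopf("pulse samples must lie in [0, 100] percent")
  dur <- (length(samples) - 1) / sample_rate_hz
  if (trigger_time_s < 0 || trigger_time_s > dur)
    stopf("trigger_time_s must lie inside the trace (0..%.2f s)", dur)
  structure(
    list(samples = as.numeric(samples),
         sample_rate_hz = sample_rate_hz,
         trigger_time_s = trigger_time_s),
    class = "pulse_trace")
}

#' @export
print.pulse_trace <- function(x, ...) {
  cat(sprintf("<pulse_trace> %d samples @ %g Hz (%.2f s), trigger at %.3f s\n",
              length(x$samples), x$sample_rate_hz,
              (length(x$samples) - 1) / x$sample_rate_hz, x$trigger_time_s))
  invisible(x)
}

# Periodic pulse waveform on beat fraction u in [0, 1): von Mises bump with
# peak exactly at u = 0, asymmetrised by a monotone time warp (fast upstroke
# just before the peak, slow decay after it).
pulse_waveform <- function(u, kappa = 3, skew = 0.45) {
  u <- u %% 1
  w <- u - skew * (1 - cospi(2 * u)) / (2 * pi)   # warp'(u) = 1 - skew*sin(2*pi*u)
  exp(kappa * (cospi(2 * w) - 1))
}

#' Generate a synthetic pulse-oximeter trace
#'
#' Produces a quasi-periodic finger-pulse waveform with per-beat period
#' jitter and places the tonometer trigger at a requested cardiac phase.
#' Phase 0 is the systolic peak.  With `jitter_frac = j`, per-beat periods
#' are drawn uniformly in `mean * (1 +/- j/2)`, so successive periods differ
#' by at most `j` of the mean (the documented device-level rate variability
#' is 4 percent).
#'
#' @param rate_bpm pulse rate in beats per minute; the emulated device range
#'   is 20-254 bpm.
#' @param duration_s trace length (s); must span at least 3 beats.
#' @param jitter_frac per-beat period jitter as a fraction of the mean period
#'   (`0..0.1`).
#' @param trigger_phase_deg cardiac phase (deg) at which the trigger is
#'   placed, after at least two full beats; `NULL` places it mid-beat.
#' @param seed integer seed for the jitter.
#' @param sample_rate_hz sampling rate of the emulated oximeter output (Hz).
#' @param quantize_pct quantize samples to the device's 1 percent amplitude
#'   resolution.
#' @return a [pulse_trace()]; the true systolic peak times are attached as
#'   attribute `"truth_peaks_s"` for validation.
#' @export
generate_pulse_trace <- function(rate_bpm = 84, duration_s = 6,
                                 jitter_frac = 0.04,
                                 trigger_phase_deg = NULL, seed = 1L,
                                 sample_rate_hz = 250,
                                 quantize_pct = FALSE) {
  if (rate_bpm < 20 || rate_bpm > 254)
    stopf("rate_bpm = %g outside the supported device range 20-254 bpm", rate_bpm)
  if (jitter_frac < 0 || jitter_frac > 0.1)
    stopf("jitter_frac must lie in [0, 0.1]")
  period <- 60 / rate_bpm
  if (duration_s < 3 * period)
    stopf("duration_s must cover at least 3 beats (%.2f s)", 3 * period)

  n_beats <- ceiling(duration_s / period) + 3L
  set.seed(seed)
  periods <- period * (1 + runif(n_beats, -jitter_frac / 2, jitter_frac / 2))
  # First systolic peak a quarter-beat in; virtual peak before t = 0 so the
  # waveform is defined from the first sample on.
  peaks <- 0.25 * period + c(0, cumsum(periods))
  all_peaks <- c(peaks[1] - periods[1], peaks)

  t <- seq(0, duration_s, by = 1 / sample_rate_hz)
  idx <- findInterval(t, all_peaks)
  u <- (t - all_peaks[idx]) / (all_peaks[idx + 1] - all_peaks[idx])
  g <- pulse_waveform(u)
  g_rng <- range(pulse_waveform(seq(0, 1, length.out = 2048)))
  samples <- 20 + 70 * (g - g_rng[1]) / (g_rng[2] - g_rng[1])
  if (quantize_pct) samples <- round(samples)

  in_peaks <- peaks[peaks > 0 & peaks < duration_s]
  if (length(in_peaks) < 4L)
    stopf("duration_s too short to place the trigger after two full beats")
  if (is.null(trigger_phase_deg)) {
    trigger <- in_peaks[3] + 0.4 * (in_peaks[4] - in_peaks[3])
  } else {
    frac <- wrap_deg(trigger_phase_deg) / 360
    trigger <- in_peaks[3] + frac * (in_peaks[4] - in_peaks[3])
  }
  if (trigger >= duration_s)
    stopf("duration_s too short to place the trigger after two full beats")
  out <- pulse_trace(samples, sample_rate_hz, trigger)
  attr(out, "truth_peaks_s") <- in_peaks
  out
}
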