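# Synthetic measurement cohorts.
#
# "Fast" mode emits feature vectors directly (the statistical stages run in
# milliseconds); "render" mode additionally renders the image sequence and
# pulse trace for every measurement, exercising the imaging stages.

#' Cohort generation parameters
#'
#' Population-level study conditions for [generate_cohort()].  Defaults are
#' the package's documented group values: subject phase offsets drawn from a
#' wrapped normal with mean 60 deg and spread 40 deg, IOP modulation
#' amplitude 0.75 mmHg with 0.25 mmHg reading noise, subject baselines
#' around 12 +/- 2.5 mmHg, and per-feature between/within-subject spreads in
#' the range observed clinically for healthy corneas.
#'
#' @param iop_baseline_mean,iop_baseline_sd subject baseline IOP (mmHg).
#' @param phase_offset_mean_deg,phase_offset_sd_deg population distribution
#'   of the pulse-to-IOP phase lag (deg).
#' @param iop_mod_amp_mmHg,iop_noise_sd_mmHg modulation amplitude and
#'   reading noise (mmHg).
#' @param phase_jitter_sd_deg achieved-phase jitter around the evenly spread
#'   targets (deg); the protocol *aims* for even coverage of the circle but
#'   never hits the targets exactly.
#' @param w1_mean,w1_between_sd,w1_within_sd 1st applanation time (ms).
#' @param w2_mean,w2_between_sd,w2_within_sd 2nd applanation time (ms).
#' @param w3_mean,w3_between_sd,w3_within_sd maximum deformation (mm).
#' @param w4_mean,w4_between_sd,w4_within_sd vibration frequency (Hz).
#' @param rate_bpm pulse rate for rendered pulse traces (beats/min).
#' @param rate_jitter_frac per-beat period jitter for rendered traces.
#' @return named list of parameters.
#' @export
cohort_config <- function(iop_baseline_mean = 12, iop_baseline_sd = 2.5,
                          phase_offset_mean_deg = 60,
                          phase_offset_sd_deg = 40,
                          iop_mod_amp_mmHg = 0.75,
                          iop_noise_sd_mmHg = 0.25,
                          phase_jitter_sd_deg = 10,
                          w1_mean = 7.1, w1_between_sd = 0.3, w1_within_sd = 0.12,
                          w2_mean = 22.0, w2_between_sd = 0.4, w2_within_sd = 0.18,
                          w3_mean = 1.09, w3_between_sd = 0.055, w3_within_sd = 0.03,
                          w4_mean = 415, w4_between_sd = 17, w4_within_sd = 3,
                          rate_bpm = 84, rate_jitter_frac = 0.04) {
  as.list(environment())
}

#' Generate a synthetic measurement cohort
#'
#' Draws subject-level baselines and phase lags, spreads each subject's
#' measurement phases quasi-evenly over the cardiac circle (with jitter),
#' generates IOP readings under the cosine modulation model, and emits
#' measurement records.  In `"fast"` mode the image-derived features
#' `w(1)..w(4)` are synthesized directly from their documented
#' distributions; in `"render"` mode each measurement also gets a rendered
#' frame sequence and a pulse trace with the trigger at the achieved phase,
#' and `w(6)` is left to be measured by the imaging/pulse pipeline.
#'
#' @param n_subjects number of subjects (default 10).
#' @param n_meas_per_subject measurements per subject (default 6, >= 3).
#' @param config a [cohort_config()].
#' @param seed integer seed; the cohort is bit-reproducible given the seed.
#' @param mode `"fast"` or `"render"`.
#' @param render_args named list of overrides passed to
#'   [render_deformation_sequence()] (render mode only).
#' @param process optional function `(frames, trace, truth) -> value`
#'   applied to each rendered measurement as soon as it is generated; when
#'   given, `measurements` stores the function's results instead of the raw
#'   frame stacks, keeping memory flat (a full stack is ~13 MB of doubles
#'   per measurement times 140 frames).
#' @return list with `records` (data.frame: subject, measurement, eye,
#'   phase_true_deg, w1_ms..w6_deg), `truths` (per-subject list of
#'   subject-level ground truth), and in render mode `measurements` (per
#'   record: `frames`, `trace`, `truth`, or the `process` results).
#' @export
generate_cohort <- function(n_subjects = 10, n_meas_per_subject = 6,
                            config = cohort_config(), seed = 1L,
                            mode = c("fast", "render"),
                            render_args = list(), process = NULL) {
  mode <- match.arg(mode)
  if (n_meas_per_subject < 3) stopf("need at least 3 measurements per subject")
  cfg <- config
  set.seed(seed)
  K <- n_meas_per_subject

  subj <- data.frame(
    subject = seq_len(n_subjects),
    eye = rep(c("right", "left"), length.out = n_subjects),
    baseline = rnorm(n_subjects, cfg$iop_baseline_mean, cfg$iop_baseline_sd),
    offset = wrap_deg(rnorm(n_subjects, cfg$phase_offset_mean_deg,
                            cfg$phase_offset_sd_deg)),
    w1 = rnorm(n_subjects, cfg$w1_mean, cfg$w1_between_sd),
    w2 = rnorm(n_subjects, cfg$w2_mean, cfg$w2_between_sd),
    w3 = rnorm(n_subjects, cfg$w3_mean, cfg$w3_between_sd),
    w4 = rnorm(n_subjects, cfg$w4_mean, cfg$w4_between_sd))
  # keep applanations ordered and the vibration in the measurable band
  subj$w1 <- pmax(subj$w1, 1)
  subj$w2 <- pmax(subj$w2, subj$w1 + 5)
  subj$w4 <- pmin(pmax(subj$w4, 150), 1500)

  records <- NULL
  truths <- vector("list", n_subjects)
  measurements <- if (mode == "render") vector("list", n_subjects * K) else NULL

  for (v in seq_len(n_subjects)) {
    s <- subj[v, ]
    truth_v <- synthetic_truth(
      applanation1_ms = s$w1, applanation2_ms = s$w2,
      max_deformation_mm = max(s$w3, 0.5), vibration_hz = s$w4,
      iop_baseline_mmHg = s$baseline,
      iop_mod_amp_mmHg = cfg$iop_mod_amp_mmHg,
      phase_offset_deg = s$offset,
      noise_sd_mmHg = cfg$iop_noise_sd_mmHg,
      seed = child_seed(seed, v))
    truths[[v]] <- truth_v

    # quasi-even phase coverage: evenly spaced targets with a random start,
    # jittered by the achieved-phase spread
    start <- runif(1, 0, 360 / K)
    targets <- wrap_deg(start + (0:(K - 1)) * 360 / K)
    achieved <- wrap_deg(targets + rnorm(K, 0, cfg$phase_jitter_sd_deg))
    iop <- generate_iop_readings(truth_v, achieved, seed = child_seed(seed, 7000 + v))

    rec <- data.frame(
      subject = v, measurement = seq_len(K), eye = s$eye,
      phase_true_deg = achieved,
      w1_ms = s$w1 + rnorm(K, 0, cfg$w1_within_sd),
      w2_ms = s$w2 + rnorm(K, 0, cfg$w2_within_sd),
      w3_mm = pmax(0.2, s$w3 + rnorm(K, 0, cfg$w3_within_sd)),
      w4_hz = pmax(150, s$w4 + rnorm(K, 0, cfg$w4_within_sd)),
      w5_mmHg = iop,
      w6_deg = bin_phase(achieved))

    if (mode == "render") {
      for (k in seq_len(K)) {
        m_seed <- child_seed(seed, v * 100 + k)
        truth_m <- synthetic_truth(
          applanation1_ms = rec$w1_ms[k], applanation2_ms = rec$w2_ms[k],
          max_deformation_mm = rec$w3_mm[k], vibration_hz = rec$w4_hz[k],
          iop_baseline_mmHg = s$baseline,
          iop_mod_amp_mmHg = cfg$iop_mod_amp_mmHg,
          phase_offset_deg = s$offset,
          noise_sd_mmHg = cfg$iop_noise_sd_mmHg,
          seed = m_seed)
        rendered <- do.call(render_deformation_sequence,
                            c(list(truth = truth_m), render_args))
        trace <- generate_pulse_trace(
          rate_bpm = cfg$rate_bpm, duration_s = 6,
          jitter_frac = cfg$rate_jitter_frac,
          trigger_phase_deg = achieved[k], seed = m_seed)
        m <- list(frames = rendered$frames, trace = trace, truth = rendered$truth)
        measurements[[(v - 1) * K + k]] <-
          if (is.null(process)) m else process(m$frames, m$trace, m$truth)
      }
    }
    records <- rbind(records, rec)
  }
  out <- list(records = records, truths = truths, seed = seed, config = cfg)
  if (mode == "render") out$measurements <- measurements
  out
}
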