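# Cardiac phase from a pulse-oximeter trace, binned to the 12 x 30 deg grid.

#' Detect systolic beats in a pulse trace
#'
#' Estimates the dominant beat period from the autocorrelation of the
#' demeaned trace, finds systolic peaks as local maxima separated by at
#' least half that period, and refines each peak time by parabolic
#' interpolation over its three-sample neighbourhood.
#'
#' @param trace a [pulse_trace()].
#' @param min_separation_frac minimum peak separation as a fraction of the
#'   dominant period.
#' @return object of class `beat_times`: list with `peak_times_s`,
#'   `mean_period_s`, `period_cv`.
#' @export
detect_beats <- function(trace, min_separation_frac = 0.5) {
  stopifnot(inherits(trace, "pulse_trace"))
  x <- trace$samples
  fs <- trace$sample_rate_hz
  xc <- x - mean(x)
  if (sd(x) < 1e-9) stopf("insufficient beats: trace is constant")

  # Dominant period: first prominent autocorrelation peak beyond 0.2 s
  # (above 300 bpm nothing physiological remains).
  n <- length(xc)
  ac <- stats::acf(xc, lag.max = min(n - 2, ceiling(3 * fs)), plot = FALSE)$acf[, 1, 1]
  lag_min <- max(2L, ceiling(0.2 * fs))
  cand <- which(diff(sign(diff(ac))) == -2) + 1   # local maxima of acf
  cand <- cand[cand > lag_min]
  if (length(cand) == 0) stopf("insufficient beats: no periodicity found")
  period_s <- (cand[which.max(ac[cand])] - 1) / fs

  min_sep <- max(2L, floor(min_separation_frac * period_s * fs))
  pk <- pracma::findpeaks(x, minpeakdistance = min_sep,
                          minpeakheight = mean(x) + 0.25 * sd(x))
  if (is.null(pk) || nrow(pk) < 2) stopf("insufficient beats: fewer than 2 peaks")
  idx <- sort(pk[, 2])
  times <- vapply(idx, function(i) {
    if (i <= 1 || i >= n) return((i - 1) / fs)
    ref <- parabolic_refine(x[i - 1], x[i], x[i + 1])
    (i - 1 + ref$offset) / fs
  }, numeric(1))
  periods <- diff(times)
  structure(
    list(peak_times_s = times,
         mean_period_s = mean(periods),
         period_cv = if (length(periods) > 1) sd(periods) / mean(periods) else 0),
    class = "beat_times")
}

#' @export
print.beat_times <- function(x, ...) {
  cat(sprintf("<beat_times> %d peaks, mean period %.1f ms (%.0f bpm), cv %.3f\n",
              length(x$peak_times_s), 1000 * x$mean_period_s,
              60 / x$mean_period_s, x$period_cv))
  invisible(x)
}

#' Cardiac phase at a given time
#'
#' Phase is defined by linear interpolation between the two systolic peaks
#' bracketing `t_s`: `360 * (t - previous peak) / (next peak - previous
#' peak)`, with 0 deg at the systolic peak.  Interpolating between adjacent
#' peaks (rather than against the mean period) keeps rate jitter from
#' accumulating.  Times within one mean period after the last peak are
#' extrapolated with the mean period.
#'
#' @param trace a [pulse_trace()] (used only for bounds reporting).
#' @param t_s time of interest (s), typically the tonometer trigger.
#' @param beats a [detect_beats()] result.
#' @return phase in degrees, in `[0, 360)`.
#' @export
phase_at <- function(trace, t_s, beats) {
  pk <- beats$peak_times_s
  if (t_s < pk[1]) stopf("phase undefined: t precedes the first detected beat")
  k <- findInterval(t_s, pk)
  if (k < length(pk)) {
    prev <- pk[k]; nxt <- pk[k + 1]
  } else {
    if (t_s > pk[length(pk)] + beats$mean_period_s)
      stopf("phase undefined: t is more than one period past the last beat")
    prev <- pk[length(pk)]; nxt <- prev + beats$mean_period_s
  }
  wrap_deg(360 * (t_s - prev) / (nxt - prev))
}

#' Bin a phase to the 12 x 30-degree grid
#'
#' Nearest multiple of 30 deg modulo 360 (345-360 deg maps to 0 deg).  Ties
#' at exact bin midpoints (15, 45, ...) round down to the lower bin.
#'
#' @param phase_deg phase in `[0, 360)` (vectorized).
#' @return binned phase, an element of `{0, 30, ..., 330}`.
#' @export
bin_phase <- function(phase_deg) {
  if (any(phase_deg < 0 | phase_deg >= 360))
    stopf("phase must lie in [0, 360)")
  b <- phase_deg / 30
  lower <- floor(b)
  frac <- b - lower
  bin <- ifelse(frac <= 0.5, lower, lower + 1)
  wrap_deg(30 * bin)
}

#' Read a pulse trace from CSV
#'
#' Expects columns `time_s` and `amplitude_pct`.  The trigger time is taken
#' from a JSON sidecar (`<path>.json` with field `trigger_time_s`) or from a
#' `# trigger_time_s: <value>` comment in the CSV header.
#'
#' @param path CSV path.
#' @return a [pulse_trace()].
#' @export
read_pulse_csv <- function(path) {
  if (!file.exists(path)) stopf("pulse trace not found: %s", path)
  header <- readLines(path, n = 5)
  df <- read.csv(path, comment.char = "#")
  if (!all(c("time_s", "amplitude_pct") %in% names(df)))
    stopf("pulse CSV %s must have columns time_s, amplitude_pct", path)
  dt <- diff(df$time_s)
  if (max(abs(dt - dt[1])) > 1e-6) stopf("pulse samples must be uniform in time")
  trigger <- NA_real_
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    trigger <- jsonlite::read_json(sidecar)$trigger_time_s %||% NA_real_
  } else {
    m <- regmatches(header, regexec("#\\s*trigger_time_s:\\s*([0-9.eE+-]+)", header))
    hit <- vapply(m, length, integer(1)) == 2
    if (any(hit)) trigger <- as.numeric(m[[which(hit)[1]]][2])
  }
  if (is.na(trigger)) stopf("no trigger time found for %s", path)
  pulse_trace(df$amplitude_pct, 1 / dt[1], trigger - df$time_s[1])
}

#' Write a pulse trace to CSV (with trigger header comment)
#'
#' @param trace a [pulse_trace()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_pulse_csv <- function(trace, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# trigger_time_s: %.9g", trace$trigger_time_s), con)
  t <- (seq_along(trace$samples) - 1) / trace$sample_rate_hz
  utils::write.table(
    data.frame(time_s = t, amplitude_pct = trace$samples),
    con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}
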