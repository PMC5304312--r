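# Phase-shift Pearson correlation scan, outlier rejection, significance,
# and cohort aggregates.
#
# Per subject v and feature j, the correlation r_v(j) between the K repeated
# feature values and the cardiac phase at the trigger is evaluated over a
# grid of artificial phase shifts phi.  In the default ("circular") mode the
# phase enters through a cosine reference, r(phi) = pearson_r(w, cos(phase -
# phi)): r(phi) is then maximal when phi equals the phase at which the
# feature peaks, r(phi + 180) = -r(phi) holds identically, and the argmax is
# a direct estimate of the pulse-to-IOP phase lag.  The "linear" mode
# correlates the feature against the shifted wrapped phase value itself,
# (phase + phi) mod 360, as a documented alternative.

#' Pearson correlation coefficient
#'
#' The centred cross-product over the product of centred norms, computed
#' directly from the defining sums.
#'
#' @param x,y numeric vectors of equal length `K >= 3`.
#' @return correlation in `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  K <- length(x)
  if (length(y) != K) stopf("x and y must have equal length")
  if (K < 3) stopf("need at least 3 paired observations")
  if (anyNA(x) || anyNA(y)) stopf("missing values in correlation input")
  dx <- x - mean(x)
  dy <- y - mean(y)
  den <- sqrt(sum(dx^2)) * sqrt(sum(dy^2))
  if (den == 0) stopf("undefined correlation: constant input vector")
  r <- sum(dx * dy) / den
  max(-1, min(1, r))
}

#' Shift wrapped phases
#'
#' @param phases_deg phases in `[0, 360)`.
#' @param phi_deg shift in degrees.
#' @return `(phases + phi) mod 360`, element-wise.
#' @export
shift_phase <- function(phases_deg, phi_deg) {
  if (any(phases_deg < 0 | phases_deg >= 360))
    stopf("phases must lie in [0, 360)")
  wrap_deg(phases_deg + phi_deg)
}

#' Phase-shift correlation scan for one subject
#'
#' @param values feature values `w(j)` for the subject's K measurements.
#' @param phases_deg matching binned cardiac phases `w(6)`.
#' @param phi_grid_deg shift grid (default 0..350 deg in 10 deg steps, finer
#'   than the 30 deg measurement bins so the argmax is resolved).
#' @param mode `"circular"` (default; cosine reference, see the file
#'   preamble) or `"linear"` (wrapped phase as a linear value).
#' @return object of class `correlation_scan`: list with `phi_grid_deg`,
#'   `r`, `phi_max_deg`, `r_max`, `phi_min_deg`, `r_min`, `K`, `mode`.
#'   Ties in the argmax/argmin break toward the smallest shift.
#' @export
scan_phase_shifts <- function(values, phases_deg,
                              phi_grid_deg = seq(0, 350, by = 10),
                              mode = c("circular", "linear")) {
  mode <- match.arg(mode)
  K <- length(values)
  if (length(phases_deg) != K) stopf("values and phases must match")
  if (K < 3) stopf("need at least 3 measurements for a correlation scan")
  if (length(unique(phases_deg)) < 3)
    stopf("need at least 3 distinct phases for a correlation scan")
  r <- vapply(phi_grid_deg, function(phi) {
    ref <- if (mode == "circular") {
      cospi(shift_phase(phases_deg, -phi) / 180)
    } else {
      shift_phase(phases_deg, phi)
    }
    tryCatch(pearson_r(values, ref), error = function(e) NA_real_)
  }, numeric(1))
  if (all(is.na(r))) stopf("undefined correlation at every phase shift")
  i_max <- which(r == max(r, na.rm = TRUE))[1]
  i_min <- which(r == min(r, na.rm = TRUE))[1]
  structure(
    list(phi_grid_deg = phi_grid_deg, r = r,
         phi_max_deg = phi_grid_deg[i_max], r_max = r[i_max],
         phi_min_deg = phi_grid_deg[i_min], r_min = r[i_min],
         K = K, mode = mode),
    class = "correlation_scan")
}

#' @export
print.correlation_scan <- function(x, ...) {
  cat(sprintf("<correlation_scan> %s mode, K = %d: r_max = %.3f @ %g deg, r_min = %.3f @ %g deg\n",
              x$mode, x$K, x$r_max, x$phi_max_deg, x$r_min, x$phi_min_deg))
  invisible(x)
}

#' @export
plot.correlation_scan <- function(x, ...) {
  graphics::plot(x$phi_grid_deg, x$r, type = "l", ylim = c(-1, 1),
                 xlab = expression(paste("phase shift ", phi, " (deg)")),
                 ylab = "r", ...)
  abline(h = 0, lty = 3)
  points(c(x$phi_max_deg, x$phi_min_deg), c(x$r_max, x$r_min), pch = 19)
  invisible(x)
}

#' Two-sided significance of a correlation
#'
#' Student's t test of `r` on `K - 2` degrees of freedom:
#' `t = r sqrt(K-2) / sqrt(1 - r^2)`.  `|r| = 1` returns `p = 0` (limit
#' case).
#'
#' @param r correlation coefficient.
#' @param K number of paired observations (>= 3).
#' @return two-sided p-value.
#' @export
correlation_significance <- function(r, K) {
  if (K < 3) stopf("need K >= 3")
  if (abs(r) > 1) stopf("|r| must not exceed 1")
  if (abs(r) == 1) return(0)
  tval <- r * sqrt(K - 2) / sqrt(1 - r^2)
  2 * pt(-abs(tval), df = K - 2)
}

#' Reject subjects with weak optimal correlations
#'
#' Subjects whose maximum absolute correlation stays below a threshold are
#' flagged as rejected.  Two documented presets: `"thick"` (threshold 0.3)
#' removes only grossly aberrant subjects ("thick errors"); `"strict"`
#' (threshold 0.55) additionally removes marginal outliers.
#'
#' @param extrema data.frame with columns `subject`, `r_max` (and optionally
#'   `r_min`, `phi_max_deg`, `phi_min_deg`), one row per subject - e.g. from
#'   [scan_cohort()] or a reference table.
#' @param preset `"thick"` or `"strict"`; ignored when `min_abs_r` is given.
#' @param min_abs_r explicit threshold overriding the preset.
#' @return the input with logical column `retained` and character column
#'   `reject_reason` appended.
#' @export
reject_outliers <- function(extrema, preset = c("thick", "strict"),
                            min_abs_r = NULL) {
  preset <- match.arg(preset)
  thr <- min_abs_r %||% c(thick = 0.3, strict = 0.55)[[preset]]
  max_abs <- pmax(abs(extrema$r_max),
                  if ("r_min" %in% names(extrema)) abs(extrema$r_min) else 0)
  retained <- max_abs >= thr
  if (!any(retained)) stopf("empty retained set: every subject rejected at |r| >= %g", thr)
  extrema$retained <- retained
  extrema$reject_reason <- ifelse(retained, "",
                                  sprintf("max |r| = %.2f < %.2f", max_abs, thr))
  extrema
}

#' Scan a whole cohort
#'
#' Runs [scan_phase_shifts()] for one feature across all subjects of a
#' measurement record table.
#'
#' @param records data.frame with columns `subject`, the feature column, and
#'   `w6_deg` (one row per measurement).
#' @param feature feature column to correlate (default `"w5_mmHg"`).
#' @param phi_grid_deg,mode passed to [scan_phase_shifts()].
#' @return list with `scans` (named list of `correlation_scan`) and
#'   `extrema` (data.frame: subject, K, r_max, phi_max_deg, r_min,
#'   phi_min_deg, p_value).
#' @export
scan_cohort <- function(records, feature = "w5_mmHg",
                        phi_grid_deg = seq(0, 350, by = 10),
                        mode = c("circular", "linear")) {
  mode <- match.arg(mode)
  if (!feature %in% names(records)) stopf("no column `%s` in records", feature)
  subjects <- sort(unique(records$subject))
  scans <- lapply(subjects, function(v) {
    rec <- records[records$subject == v, ]
    scan_phase_shifts(rec[[feature]], rec$w6_deg, phi_grid_deg, mode)
  })
  names(scans) <- as.character(subjects)
  extrema <- data.frame(
    subject = subjects,
    K = vapply(scans, `[[`, numeric(1), "K"),
    r_max = vapply(scans, `[[`, numeric(1), "r_max"),
    phi_max_deg = vapply(scans, `[[`, numeric(1), "phi_max_deg"),
    r_min = vapply(scans, `[[`, numeric(1), "r_min"),
    phi_min_deg = vapply(scans, `[[`, numeric(1), "phi_min_deg"))
  extrema$p_value <- mapply(correlation_significance, extrema$r_max, extrema$K)
  list(scans = scans, extrema = extrema)
}

#' Per-subject feature summary table
#'
#' Mean and standard deviation of each feature over a subject's repeated
#' measurements.
#'
#' @param records measurement record table (columns `subject`, optionally
#'   `eye`, and `w1_ms..w5_mmHg`).
#' @param std_mode `"sample"` (K-1 denominator, default) or `"population"`.
#' @return data.frame, one row per subject: `subject`, `eye`, then
#'   `<feature>_mean` / `<feature>_sd` per feature.
#' @export
summarize_features <- function(records, std_mode = c("sample", "population")) {
  std_mode <- match.arg(std_mode)
  sdev <- if (std_mode == "sample") sd else pop_sd
  feats <- intersect(c("w1_ms", "w2_ms", "w3_mm", "w4_hz", "w5_mmHg"),
                     names(records))
  subjects <- sort(unique(records$subject))
  out <- data.frame(subject = subjects)
  if ("eye" %in% names(records))
    out$eye <- vapply(subjects, function(v)
      as.character(records$eye[records$subject == v][1]), character(1))
  for (f in feats) {
    out[[paste0(f, "_mean")]] <- vapply(subjects, function(v)
      mean(records[[f]][records$subject == v]), numeric(1))
    out[[paste0(f, "_sd")]] <- vapply(subjects, function(v)
      sdev(records[[f]][records$subject == v]), numeric(1))
  }
  out
}

#' Cohort summary: feature tables, correlation extrema and pooled statistics
#'
#' Aggregates a cohort the way the study tables are laid out: per-subject
#' feature means and standard deviations, per-subject correlation extrema
#' with their phase shifts, the pooled mean and spread of the retained
#' maximum correlations, per-subject significance, the recovered
#' pulse-to-IOP phase lag (circular mean of the retained `phi_max`), and
#' the non-synchronization spread (the largest per-subject IOP standard
#' deviation - how far readings can wander when the trigger is not
#' synchronized to the cardiac phase).
#'
#' Standard-deviation conventions differ between uses: feature tables
#' default to the sample (K-1) estimator, the pooled correlation summary to
#' the population (N) estimator; both modes are always reported in the
#' `pooled` element.
#'
#' @param records measurement record table.
#' @param scan result of [scan_cohort()] (or `NULL` to summarize features
#'   only).
#' @param preset outlier-rejection preset, see [reject_outliers()].
#' @param feature_std_mode std convention for the feature table.
#' @return object of class `cohort_summary`.
#' @export
cohort_summary <- function(records, scan = NULL, preset = "thick",
                           feature_std_mode = "sample") {
  features <- summarize_features(records, feature_std_mode)
  iop_spread <- if ("w5_mmHg_sd" %in% names(features))
    max(features$w5_mmHg_sd) else NA_real_
  out <- list(features = features,
              iop_nonsync_spread_mmHg = iop_spread,
              preset = preset)
  if (!is.null(scan)) {
    extrema <- reject_outliers(scan$extrema, preset)
    kept <- extrema[extrema$retained, ]
    out$extrema <- extrema
    out$pooled <- list(
      n_retained = nrow(kept),
      r_max_mean = mean(kept$r_max),
      r_max_sd_population = pop_sd(kept$r_max),
      r_max_sd_sample = if (nrow(kept) > 1) sd(kept$r_max) else NA_real_,
      phase_lag_deg = circular_mean_deg(kept$phi_max_deg),
      significant = kept$subject[kept$p_value < 0.05])
  }
  structure(out, class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("<cohort_summary>\n")
  cat(sprintf("  %d subjects; non-synchronization IOP spread %.2f mmHg\n",
              nrow(x$features), x$iop_nonsync_spread_mmHg))
  if (!is.null(x$pooled)) {
    p <- x$pooled
    cat(sprintf("  retained %d subjects (preset '%s'): r_max %.2f +/- %.2f (pop. sd; sample sd %.2f)\n",
                p$n_retained, x$preset, p$r_max_mean, p$r_max_sd_population,
                p$r_max_sd_sample))
    cat(sprintf("  recovered pulse-to-IOP phase lag: %.0f deg; %d/%d retained subjects significant at p < 0.05\n",
                p$phase_lag_deg, length(p$significant), p$n_retained))
  }
  invisible(x)
}
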