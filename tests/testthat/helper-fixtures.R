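# Shared fixtures.  Rendered sequences are expensive, so small-geometry
# renders are memoized per parameter set within a test run.

.render_cache <- new.env(parent = emptyenv())

# A reduced-geometry render (120 x 288 px) that keeps the full physics but
# runs in a few seconds.  The resting central flatness at this size is only
# ~12 um (vs ~43 um at full size), so the pixel-noise default is scaled
# down with the geometry; full-geometry recovery at full noise is covered
# by the acceptance suite.  Analyzer settings that must match: central_cols
# = 80, flatness_threshold_mm = 0.005 (default).
small_render <- function(truth = synthetic_truth(max_deformation_mm = 1.04,
                                                 seed = 42),
                         noise_sd = 0.01, ...) {
  key <- paste(deparse(list(unclass(truth), noise_sd, ...)), collapse = "")
  if (!is.null(.render_cache[[key]])) return(.render_cache[[key]])
  out <- render_deformation_sequence(
    truth, rows = 120, cols = 288, apex_row_px = 25,
    central_cols = 80, noise_sd = noise_sd, ...)
  .render_cache[[key]] <- out
  out
}

small_extract <- function(rendered) {
  extract_sequence_features(rendered$frames, central_cols = 80)
}

# Build a contour_set directly from a frames x cols matrix of edge rows.
make_contour_set <- function(y, pixel_scale_um = 20, frame_interval_us = 231) {
  structure(
    list(y = y,
         valid = matrix(TRUE, nrow(y), ncol(y)),
         filled = matrix(FALSE, nrow(y), ncol(y)),
         frame_ok = rep(TRUE, nrow(y)),
         frame_interval_us = frame_interval_us,
         pixel_scale_um = pixel_scale_um),
    class = "contour_set")
}

# Build a deformation_profile directly from an apex time series (mm).
make_profile <- function(apex_mm, flatness = NULL, frame_interval_us = 231) {
  n <- length(apex_mm)
  structure(
    list(time_ms = (seq_len(n) - 1) * frame_interval_us / 1000,
         apex_mm = apex_mm,
         central_flatness = flatness %||% rep(NA_real_, n),
         apex_col = NA_integer_,
         frame_ok = rep(TRUE, n)),
    class = "deformation_profile")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Direct transliteration of the defining correlation sums (independent
# oracle for pearson_r): explicit loops, no vectorized shortcuts.
pearson_brute <- function(x, y) {
  K <- length(x)
  mx <- sum(x) / K
  my <- sum(y) / K
  num <- 0; dx2 <- 0; dy2 <- 0
  for (k in seq_len(K)) {
    num <- num + (x[k] - mx) * (y[k] - my)
    dx2 <- dx2 + (x[k] - mx)^2
    dy2 <- dy2 + (y[k] - my)^2
  }
  num / sqrt(dx2 * dy2)
}
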