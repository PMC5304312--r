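# Rendering of synthetic corneal cross-section sequences.
#
# Geometry (all lengths mm unless noted, rows increase downward):
#   resting contour  r(x) = apex_row + p(x),       p(x) = x^2 / (2 R)
#   deformation      d(x, t) = A(t) B(x) + vib(t) V(x)   (positive = into the eye)
#   whole-eye motion E(t), a uniform downward shift ramping up after the peak
#
# The indentation profile B is proportional to the resting sag p inside the
# central analysis window, so the central contour at amplitude A equals
# const + (1 - A/a*) p(x): central flatness is *linear* in A and vanishes
# exactly at the flattening amplitude a*.  The amplitude envelope A(t) is a
# raised-cosine bump solved so that the analyzer's flatness statistic crosses
# its threshold exactly at the injected applanation times.

# Resting sag (mm) at signed distance x (mm) from the apex.
resting_sag <- function(x_mm, radius_mm) x_mm^2 / (2 * radius_mm)

# Indentation spatial profile: 1 - p/a* inside the flattening zone, exact out
# to `exact_mm`, then tapered smoothly to zero where p = a*.
indentation_profile <- function(x_mm, radius_mm, flatten_amp_mm, exact_mm) {
  p <- resting_sag(x_mm, radius_mm)
  base <- pmax(0, 1 - p / flatten_amp_mm)
  x_star <- sqrt(2 * radius_mm * flatten_amp_mm)   # where base reaches 0
  if (exact_mm >= x_star)
    stopf("central exact zone must lie inside the flattening zone")
  ax <- abs(x_mm)
  taper <- ifelse(ax <= exact_mm, 1,
           ifelse(ax >= x_star, 0,
                  cospi((ax - exact_mm) / (x_star - exact_mm) / 2)^2))
  base * taper
}

# Flatness statistic used both here and by the analyzer: RMS deviation (mm)
# of a quadratic fit to the central contour from its best straight line.
central_flatness_mm <- function(contour_mm, central_cols) {
  n <- length(contour_mm)
  i0 <- floor((n - central_cols) / 2) + 1
  y <- contour_mm[i0:(i0 + central_cols - 1)]
  x <- seq_along(y)
  q <- lm.fit(cbind(1, x, x^2), y)$fitted.values
  l <- lm.fit(cbind(1, x), q)$fitted.values
  sqrt(mean((q - l)^2))
}

#' Render a synthetic corneal deformation image sequence
#'
#' Renders grayscale frames of a bright anterior corneal band over a dark
#' background.  The resting shape is a parabolic arc (default radius of
#' curvature 7.8 mm); a centred bell-shaped indentation follows a smooth
#' rise-peak-recovery envelope whose central-flatness threshold crossings
#' land exactly at the injected applanation times; whole-eye motion ramps up
#' after the deformation peak; a windowed sinusoid at the injected vibration
#' frequency rides on the apex; pixel noise and band blur are configurable.
#'
#' @param truth a [synthetic_truth()].
#' @param rows,cols,n_frames image geometry (defaults 200 x 576 x 140).
#' @param frame_interval_us,pixel_scale_um time base and scale.
#' @param radius_mm resting corneal radius of curvature.
#' @param apex_row_px resting row of the corneal apex (from the top).
#' @param flatten_amp_mm apex amplitude at which the central region is
#'   geometrically flat (must be below the truth's peak deformation).
#' @param central_cols,flatness_threshold_mm the applanation criterion the
#'   envelope is solved against; keep identical to the analyzer settings.
#' @param band_depth_px thickness of the bright corneal band.
#' @param band_intensity,bg_intensity band/background intensity levels.
#' @param edge_blur_px 1/e width of the band edges (logistic profile).
#' @param noise_sd additive Gaussian pixel noise (intensity units).
#' @return list with elements `frames` (a [frame_sequence()]) and `truth`
#'   (the input truth, with the rendering geometry attached as attributes
#'   `"apex_col"` and `"contour_rows"`, the true per-frame contour).
#' @export
render_deformation_sequence <- function(truth,
                                        rows = 200, cols = 576, n_frames = 140,
                                        frame_interval_us = 231,
                                        pixel_scale_um = 20,
                                        radius_mm = 7.8,
                                        apex_row_px = 60,
                                        flatten_amp_mm = 0.4,
                                        central_cols = 150,
                                        flatness_threshold_mm = 0.005,
                                        band_depth_px = 25,
                                        band_intensity = 0.85,
                                        bg_intensity = 0.08,
                                        edge_blur_px = 1.2,
                                        noise_sd = 0.02) {
  stopifnot(inherits(truth, "synthetic_truth"))
  scale_mm <- pixel_scale_um / 1000
  t_ms <- (seq_len(n_frames) - 1) * frame_interval_us / 1000
  x_mm <- (seq_len(cols) - (cols + 1) / 2) * scale_mm

  exact_mm <- (central_cols / 2 + 10) * scale_mm  # exact zone covers analyzer window
  B <- indentation_profile(x_mm, radius_mm, flatten_amp_mm, exact_mm)
  p_mm <- resting_sag(x_mm, radius_mm)

  t1 <- truth$applanation1_ms; t2 <- truth$applanation2_ms
  A_max <- truth$max_deformation_mm

  # Amplitude at which the analyzer's flatness statistic equals its
  # threshold (linear in A by construction, but solved numerically so any
  # profile/criterion change stays self-consistent).
  rest_mm <- p_mm
  flat_of_A <- function(a) central_flatness_mm(rest_mm + a * B, central_cols)
  f0 <- flat_of_A(0)
  if (f0 <= flatness_threshold_mm)
    stopf("resting cornea already flatter than the applanation threshold")
  t_pk <- (t1 + t2) / 2
  if (A_max == 0) {
    A_t <- rep(0, n_frames)            # static cornea (identity case)
  } else {
    if (A_max <= flatten_amp_mm)
      stopf("max_deformation_mm must exceed flatten_amp_mm for applanation to occur")
    a_cross <- uniroot(function(a) flat_of_A(a) - flatness_threshold_mm,
                       c(0, flatten_amp_mm), tol = 1e-10)$root
    # Raised-cosine envelope A(t) = A_max cos^2(pi (t - t_pk) / (2 s)) with
    # A(t1) = A(t2) = a_cross.
    half <- pi * (t2 - t1) / (4 * acos(sqrt(a_cross / A_max)))
    if (t_pk - half < 0 || t_pk + half > t_ms[n_frames])
      stopf("deformation envelope extends outside the sequence; widen the sequence or narrow the applanations")
    A_t <- ifelse(abs(t_ms - t_pk) < half,
                  A_max * cospi((t_ms - t_pk) / (2 * half))^2, 0)
  }

  # Apex vibration, windowed to [t1, t2] with zero endpoints so the
  # applanation crossings are untouched.
  vib_amp_mm <- truth$vibration_amp_um / 1000
  win <- ifelse(t_ms > t1 & t_ms < t2, sinpi((t_ms - t1) / (t2 - t1))^2, 0)
  vib_t <- vib_amp_mm * win * sinpi(2 * truth$vibration_hz * (t_ms - t1) / 1000)
  V <- exp(-x_mm^2 / (2 * 1.0^2))   # 1 mm gaussian footprint at the apex

  # Whole-eye motion: smoothstep ramp from the deformation peak to the end.
  tau <- pmin(1, pmax(0, (t_ms - t_pk) / (t_ms[n_frames] - t_pk)))
  E_t <- truth$eye_motion_mm * (3 * tau^2 - 2 * tau^3)

  # True contour rows (real-valued, 1-based).
  contour <- matrix(0, n_frames, cols)
  for (i in seq_len(n_frames)) {
    d_mm <- A_t[i] * B + vib_t[i] * V + E_t[i]
    contour[i, ] <- apex_row_px + (p_mm + d_mm) / scale_mm
  }
  if (min(contour) < 2 || max(contour) > rows - 2)
    stopf("geometry pushes the corneal contour outside the frame")

  set.seed(truth$seed)
  frames <- array(0, dim = c(rows, cols, n_frames))
  m_idx <- matrix(seq_len(rows), rows, cols)
  for (i in seq_len(n_frames)) {
    r_mat <- matrix(contour[i, ], rows, cols, byrow = TRUE)
    img <- bg_intensity + (band_intensity - bg_intensity) *
      (plogis((m_idx - r_mat) / edge_blur_px) -
         plogis((m_idx - r_mat - band_depth_px) / edge_blur_px))
    if (noise_sd > 0) img <- img + rnorm(rows * cols, 0, noise_sd)
    frames[, , i] <- pmin(pmax(img, 0), 1)
  }

  out_truth <- truth
  attr(out_truth, "apex_col") <- (cols + 1) / 2
  attr(out_truth, "contour_rows") <- contour
  list(frames = frame_sequence(frames, frame_interval_us, pixel_scale_um),
       truth = out_truth)
}
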