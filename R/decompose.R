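# Separation of total contour displacement into resting shape, whole-eye
# response and corneal reaction.

#' Decompose contour motion into resting shape, eye motion and corneal reaction
#'
#' The first frame (pre-deformation) provides the resting contour.  Per
#' frame, the whole-eye (eyeball) response is estimated as the mean
#' displacement over the peripheral columns - the outermost fraction of the
#' window on each side, where the air puff does not indent the cornea but
#' the globe still retracts rigidly.  The corneal reaction is the remaining
#' per-column displacement, converted to millimetres, positive toward the
#' eye (indentation).
#'
#' @param contours a `contour_set` from [extract_contours()].
#' @param peripheral_frac fraction of columns on each side used for the
#'   whole-eye estimate (default 0.1).
#' @return object of class `response_decomposition`: list with `rest_shape`
#'   (resting contour, pixels), `eye_motion` (per-frame scalar, mm),
#'   `corneal_reaction` (frames x cols matrix, mm), `frame_ok`,
#'   `frame_interval_us`, `pixel_scale_um`.
#' @export
decompose_response <- function(contours, peripheral_frac = 0.1) {
  stopifnot(inherits(contours, "contour_set"))
  if (!contours$frame_ok[1])
    stopf("frame 1 is unusable: no resting reference for decomposition")
  y <- contours$y
  I <- nrow(y); N <- ncol(y)
  scale_mm <- contours$pixel_scale_um / 1000
  rest <- y[1, ]
  n_per <- max(1L, round(peripheral_frac * N))
  per_idx <- c(seq_len(n_per), N - seq_len(n_per) + 1L)
  disp_mm <- sweep(y, 2, rest) * scale_mm          # + = downward = into the eye
  eye_motion <- unname(rowMeans(disp_mm[, per_idx, drop = FALSE]))
  eye_motion[!contours$frame_ok] <- NA_real_
  reaction <- sweep(disp_mm, 1, eye_motion)
  structure(
    list(rest_shape = rest,
         eye_motion = eye_motion,
         corneal_reaction = reaction,
         frame_ok = contours$frame_ok,
         frame_interval_us = contours$frame_interval_us,
         pixel_scale_um = contours$pixel_scale_um),
    class = "response_decomposition")
}

#' @export
print.response_decomposition <- function(x, ...) {
  cat(sprintf(
    "<response_decomposition> %d frames x %d columns; peak reaction %.3f mm, peak eye motion %.3f mm\n",
    nrow(x$corneal_reaction), ncol(x$corneal_reaction),
    max(x$corneal_reaction, na.rm = TRUE), max(abs(x$eye_motion), na.rm = TRUE)))
  invisible(x)
}
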