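# Anterior corneal contour extraction.
#
# Per frame: 3x3 median filtering, gradient-based edge detection with
# hysteresis linking (Canny-style), per-column anterior-edge selection with
# sub-pixel refinement, and 5th-degree polynomial completion of gaps.

#' 3x3 median filter with edge replication
#'
#' Each pixel is replaced by the median of its 3x3 neighbourhood; the border
#' is handled by edge replication.  Implemented as a branch-free sorting
#' network so it is exact for any intensity range.
#'
#' @param frame numeric matrix (rows x cols), at least 3x3.
#' @return filtered matrix of the same size.
#' @export
median_filter_frame <- function(frame) {
  if (!is.matrix(frame) || nrow(frame) < 3 || ncol(frame) < 3)
    stopf("frame must be a matrix of at least 3x3 pixels")
  M <- nrow(frame); N <- ncol(frame)
  up <- c(1, seq_len(M - 1)); down <- c(seq_len(M - 1) + 1, M)
  lf <- c(1, seq_len(N - 1)); rt <- c(seq_len(N - 1) + 1, N)
  p <- list(frame[up, lf], frame[up, ], frame[up, rt],
            frame[, lf],  frame,       frame[, rt],
            frame[down, lf], frame[down, ], frame[down, rt])
  # 19-exchange median-of-9 network; sw(i, j) leaves p[[i]] <= p[[j]].
  sw <- function(i, j) {
    lo <- pmin(p[[i]], p[[j]]); hi <- pmax(p[[i]], p[[j]])
    p[[i]] <<- lo; p[[j]] <<- hi
  }
  sw(2, 3); sw(5, 6); sw(8, 9)
  sw(1, 2); sw(4, 5); sw(7, 8)
  sw(2, 3); sw(5, 6); sw(8, 9)
  sw(1, 4); sw(6, 9); sw(5, 8)
  sw(4, 7); sw(2, 5); sw(3, 6)
  sw(5, 8); sw(5, 3); sw(7, 5)
  sw(5, 3)
  p[[5]]
}

#' Detect the anterior corneal edge in one frame
#'
#' Canny-style detection: Sobel gradients, hysteresis thresholding at
#' fractions of the frame's gradient-magnitude maximum with connected-
#' component edge linking, then per column the uppermost retained edge with
#' a dark-to-bright (downward-increasing) transition is selected and refined
#' to sub-pixel precision by parabolic interpolation of the gradient peak.
#'
#' @param frame median-filtered frame (rows x cols matrix).
#' @param low_frac,high_frac hysteresis thresholds as fractions of the
#'   per-frame gradient-magnitude maximum.
#' @return list with `rows` (per-column sub-pixel edge row, `NA` where no
#'   edge) and `valid` (logical per-column detection flag).
#' @export
detect_corneal_edge <- function(frame, low_frac = 0.1, high_frac = 0.3) {
  M <- nrow(frame); N <- ncol(frame)
  up <- c(1, seq_len(M - 1)); down <- c(seq_len(M - 1) + 1, M)
  lf <- c(1, seq_len(N - 1)); rt <- c(seq_len(N - 1) + 1, N)
  gx <- (frame[up, rt] + 2 * frame[, rt] + frame[down, rt]) -
        (frame[up, lf] + 2 * frame[, lf] + frame[down, lf])
  gy <- (frame[down, lf] + 2 * frame[down, ] + frame[down, rt]) -
        (frame[up, lf] + 2 * frame[up, ] + frame[up, rt])
  mag <- sqrt(gx^2 + gy^2)
  mmax <- max(mag)
  if (mmax <= 0) return(list(rows = rep(NA_real_, N), valid = rep(FALSE, N)))

  # Vertical non-maximum suppression (the corneal band is near-horizontal).
  nms <- mag >= mag[up, ] & mag >= mag[down, ] & mag > 0
  weak <- nms & (mag >= low_frac * mmax)
  strong <- nms & (mag >= high_frac * mmax)
  if (!any(strong)) return(list(rows = rep(NA_real_, N), valid = rep(FALSE, N)))

  lab <- EBImage::bwlabel(EBImage::Image(t(weak)))
  lab <- t(EBImage::imageData(lab))
  keep_ids <- unique(lab[strong])
  edge <- weak & (lab %in% keep_ids)
  dim(edge) <- dim(weak)

  # Anterior edge: per column, the uppermost edge pixel whose intensity
  # increases downward (dark background above, bright band below).
  edge <- edge & (gy > 0)
  rows_out <- rep(NA_real_, N)
  hit <- which(edge, arr.ind = TRUE)
  if (nrow(hit) > 0) {
    first <- tapply(hit[, 1], hit[, 2], min)
    cols_hit <- as.integer(names(first))
    r0 <- as.integer(first)
    ok <- r0 > 1 & r0 < M
    sub <- rep(0, length(r0))
    if (any(ok)) {
      i <- which(ok)
      y1 <- mag[cbind(r0[i] - 1, cols_hit[i])]
      y2 <- mag[cbind(r0[i],     cols_hit[i])]
      y3 <- mag[cbind(r0[i] + 1, cols_hit[i])]
      denom <- y1 - 2 * y2 + y3
      off <- ifelse(abs(denom) > 1e-12, 0.5 * (y1 - y3) / denom, 0)
      sub[i] <- pmax(-1, pmin(1, off))
    }
    rows_out[cols_hit] <- r0 + sub
  }
  list(rows = rows_out, valid = !is.na(rows_out))
}

#' Complete a contour by 5th-degree polynomial approximation
#'
#' Fits a 5th-degree polynomial in the column index to the validly detected
#' edge points (least squares, on a centred and scaled abscissa for
#' conditioning) and replaces invalid spans by the polynomial's values.
#' Detected points are retained unchanged, so the operation is idempotent.
#'
#' @param rows per-column edge rows with `NA` in undetected columns.
#' @param valid logical per-column detection flags.
#' @param min_valid minimum number of valid columns required.
#' @param min_span_frac minimum fraction of the window the valid columns must
#'   span.
#' @details A single reweighting pass guards the least-squares fit against
#'   gross outliers among the detected points (e.g. spurious edges at the
#'   rim of an occlusion): points whose residual from the first fit exceeds
#'   `6 * MAD` are dropped and the polynomial refitted.  Retained detected
#'   points are returned unchanged, so the operation is idempotent.
#' @return list with `rows` (completed contour), `valid` (as input) and
#'   `filled` (columns replaced by the polynomial).
#' @export
complete_contour <- function(rows, valid, min_valid = 12,
                             min_span_frac = 0.5) {
  N <- length(rows)
  vi <- which(valid)
  if (length(vi) < min_valid)
    stopf("contour rejected: only %d valid columns (need >= %d)",
          length(vi), min_valid)
  if ((max(vi) - min(vi)) < min_span_frac * (N - 1))
    stopf("contour rejected: valid columns span less than %.0f%% of the window",
          100 * min_span_frac)
  filled <- !valid
  out <- rows
  if (any(filled)) {
    x <- (seq_len(N) - (N + 1) / 2) / (N / 2)   # centred, scaled to ~[-1, 1]
    X <- outer(x, 0:5, `^`)
    fit <- lm.fit(X[vi, , drop = FALSE], rows[vi])
    res <- abs(fit$residuals)
    cut <- 6 * max(stats::mad(fit$residuals), 1e-6)
    keep <- vi[res <= cut]
    if (length(keep) >= min_valid && length(keep) < length(vi)) {
      fit <- lm.fit(X[keep, , drop = FALSE], rows[keep])
      # detections rejected as gross outliers are replaced like gaps
      filled[setdiff(vi, keep)] <- TRUE
    }
    out[filled] <- drop(X[filled, , drop = FALSE] %*% fit$coefficients)
  }
  list(rows = out, valid = valid, filled = filled)
}

#' Extract completed contours from a whole frame sequence
#'
#' Runs median filtering, anterior-edge detection and polynomial completion
#' on every frame.
#'
#' @param fs a [frame_sequence()].
#' @param low_frac,high_frac hysteresis thresholds, see
#'   [detect_corneal_edge()].
#' @param min_valid,min_span_frac completion preconditions, see
#'   [complete_contour()].
#' @return object of class `contour_set`: list with `y` (frames x cols
#'   matrix of sub-pixel edge rows), `valid` and `filled` (logical matrices),
#'   `frame_ok` (per-frame usability flag), `frame_interval_us`,
#'   `pixel_scale_um`.
#' @export
extract_contours <- function(fs, low_frac = 0.1, high_frac = 0.3,
                             min_valid = 12, min_span_frac = 0.5) {
  stopifnot(inherits(fs, "frame_sequence"))
  d <- dim(fs$frames)
  I <- d[3]; N <- d[2]
  y <- matrix(NA_real_, I, N)
  valid <- filled <- matrix(FALSE, I, N)
  frame_ok <- rep(TRUE, I)
  for (i in seq_len(I)) {
    med <- median_filter_frame(fs$frames[, , i])
    det <- detect_corneal_edge(med, low_frac, high_frac)
    comp <- tryCatch(
      complete_contour(det$rows, det$valid, min_valid, min_span_frac),
      error = function(e) NULL)
    if (is.null(comp)) {
      frame_ok[i] <- FALSE
    } else {
      y[i, ] <- comp$rows
      valid[i, ] <- comp$valid
      filled[i, ] <- comp$filled
    }
  }
  structure(
    list(y = y, valid = valid, filled = filled, frame_ok = frame_ok,
         frame_interval_us = fs$frame_interval_us,
         pixel_scale_um = fs$pixel_scale_um),
    class = "contour_set")
}

#' @export
print.contour_set <- function(x, ...) {
  cat(sprintf("<contour_set> %d frames x %d columns, %d usable frames, %.2f%% filled\n",
              nrow(x$y), ncol(x$y), sum(x$frame_ok),
              100 * mean(x$filled[x$frame_ok, , drop = FALSE])))
  invisible(x)
}

#' Write a contour set as CSV
#'
#' One row per (frame, column): `frame, column, row, valid, filled`.
#' @param contours a `contour_set`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_contours_csv <- function(contours, path) {
  I <- nrow(contours$y); N <- ncol(contours$y)
  df <- data.frame(
    frame = rep(seq_len(I), each = N),
    column = rep(seq_len(N), I),
    row = as.vector(t(contours$y)),
    valid = as.vector(t(contours$valid)),
    filled = as.vector(t(contours$filled)))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
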