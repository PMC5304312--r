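# FrameSequence: a calibrated grayscale frame stack with its time base.
# Frames are stored rows x cols x frames; row 1 is the top of the image and
# row indices increase downward (toward the eye), matching display order.

#' Construct a frame sequence
#'
#' A calibrated stack of grayscale frames as acquired by a high-speed
#' Scheimpflug camera during an air-puff tonometry measurement.  The default
#' geometry mirrors the acquisition used throughout the package: 140 frames
#' of 200 x 576 pixels, one frame every 231 microseconds, 20 micrometres per
#' pixel.
#'
#' @param frames numeric array `rows x cols x n_frames` (intensities, any
#'   units; rendered sequences use `[0, 1]`).
#' @param frame_interval_us time between successive frames, microseconds.
#' @param pixel_scale_um physical size of one pixel, micrometres.
#' @return object of class `frame_sequence`.
#' @export
frame_sequence <- function(frames, frame_interval_us = 231,
                           pixel_scale_um = 20) {
  if (length(dim(frames)) != 3L)
    stopf("`frames` must be a rows x cols x frames array")
  if (dim(frames)[3] < 2L)
    stopf("a frame sequence needs at least 2 frames")
  if (frame_interval_us <= 0 || pixel_scale_um <= 0)
    stopf("frame interval and pixel scale must be positive")
  structure(
    list(frames = frames,
         frame_interval_us = frame_interval_us,
         pixel_scale_um = pixel_scale_um),
    class = "frame_sequence")
}

#' @export
print.frame_sequence <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf(
    "<frame_sequence> %d frames of %d x %d px, %g us/frame, %g um/px (%.2f ms total)\n",
    d[3], d[1], d[2], x$frame_interval_us, x$pixel_scale_um,
    (d[3] - 1) * x$frame_interval_us / 1000))
  invisible(x)
}

#' @export
dim.frame_sequence <- function(x) dim(x$frames)

# Frame timestamps in milliseconds from the first frame.
frame_times_ms <- function(fs) {
  (seq_len(dim(fs$frames)[3]) - 1) * fs$frame_interval_us / 1000
}

#' Write a frame sequence as a per-frame image directory
#'
#' Writes one image per frame (`frame_0001.png`, ...) plus a `meta.json`
#' sidecar holding the time base and pixel scale.  PNG and TIFF are lossless;
#' JPEG matches the historical device export format but is lossy.
#'
#' @param fs a [frame_sequence()].
#' @param dir output directory (created if missing).
#' @param format one of `"png"`, `"jpeg"`, `"tiff"`.
#' @return `dir`, invisibly.
#' @export
write_frame_dir <- function(fs, dir, format = c("png", "jpeg", "tiff")) {
  format <- match.arg(format)
  ext <- c(png = "png", jpeg = "jpg", tiff = "tif")[[format]]
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- dim(fs$frames)[3]
  for (i in seq_len(n)) {
    # EBImage images are indexed x (column), y (row): transpose for writing.
    img <- EBImage::Image(t(pmin(pmax(fs$frames[, , i], 0), 1)))
    EBImage::writeImage(img, file.path(dir, sprintf("frame_%04d.%s", i, ext)),
                        type = format)
  }
  jsonlite::write_json(
    list(frame_interval_us = fs$frame_interval_us,
         pixel_scale_um = fs$pixel_scale_um,
         n_frames = n),
    file.path(dir, "meta.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Read a frame sequence from a per-frame image directory
#'
#' Reads all `*.jpg`/`*.jpeg`/`*.png`/`*.tif` files in `dir` in lexical
#' order.  Calibration is taken from a `meta.json` sidecar when present,
#' otherwise from the arguments.
#'
#' @param dir directory of per-frame images.
#' @param frame_interval_us,pixel_scale_um calibration fallbacks used when
#'   no `meta.json` sidecar exists.
#' @return a [frame_sequence()].
#' @export
read_frame_dir <- function(dir, frame_interval_us = 231, pixel_scale_um = 20) {
  if (!dir.exists(dir)) stopf("frame directory not found: %s", dir)
  files <- sort(list.files(dir, pattern = "\\.(jpe?g|png|tiff?)$",
                           ignore.case = TRUE, full.names = TRUE))
  if (length(files) < 2L) stopf("fewer than 2 frame images in %s", dir)
  meta_path <- file.path(dir, "meta.json")
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path)
    frame_interval_us <- meta$frame_interval_us %||% frame_interval_us
    pixel_scale_um <- meta$pixel_scale_um %||% pixel_scale_um
  }
  imgs <- lapply(files, function(f) {
    d <- EBImage::imageData(EBImage::readImage(f))
    if (length(dim(d)) == 3L) d <- d[, , 1]  # collapse identical channels
    t(d)                                     # back to rows x cols
  })
  dims <- vapply(imgs, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stopf("frames in %s do not share dimensions", dir)
  arr <- array(unlist(imgs, use.names = FALSE),
               dim = c(dims[1, 1], dims[2, 1], length(imgs)))
  frame_sequence(arr, frame_interval_us, pixel_scale_um)
}
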