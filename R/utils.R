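# Small shared helpers: angle arithmetic, circular statistics, seeds.

#' Wrap angles to [0, 360)
#' @param deg numeric vector of angles in degrees.
#' @return angles reduced modulo 360 into `[0, 360)`.
#' @export
wrap_deg <- function(deg) deg %% 360

#' Signed smallest difference between two angles
#'
#' @param a,b angles in degrees.
#' @return `a - b` wrapped into `(-180, 180]`.
#' @export
angle_diff_deg <- function(a, b) {
  d <- (a - b) %% 360
  ifelse(d > 180, d - 360, d)
}

#' Circular mean of angles
#'
#' Mean direction of a set of angles, computed from the resultant vector.
#'
#' @param deg angles in degrees.
#' @param na.rm drop missing values first.
#' @return mean direction in `[0, 360)`; `NA` if the resultant vector has
#'   (numerically) zero length.
#' @export
circular_mean_deg <- function(deg, na.rm = FALSE) {
  if (na.rm) deg <- deg[!is.na(deg)]
  s <- mean(sinpi(deg / 180))
  c <- mean(cospi(deg / 180))
  if (sqrt(s^2 + c^2) < 1e-12) return(NA_real_)
  m <- (atan2(s, c) * 180 / pi) %% 360
  if (m >= 360 - 1e-9) 0 else m
}

# Population (1/N) standard deviation; stats::sd is the sample (1/(N-1)) form.
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

# Parabolic (three-point) interpolation of an extremum. Given values
# y1, y2, y3 at equispaced abscissae -1, 0, 1 with y2 the discrete extremum,
# returns list(offset, value): the sub-sample offset in (-1, 1) and the
# interpolated extremum value.
parabolic_refine <- function(y1, y2, y3) {
  denom <- y1 - 2 * y2 + y3
  if (abs(denom) < .Machine$double.eps * max(1, abs(y2))) {
    return(list(offset = 0, value = y2))
  }
  off <- 0.5 * (y1 - y3) / denom
  off <- max(-1, min(1, off))
  val <- y2 - 0.25 * (y1 - y3) * off
  list(offset = off, value = val)
}

# Derive a child seed from a base seed, kept inside 32-bit integer range.
child_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1000 + k) %% .Machine$integer.max)
}

# Non-cryptographic FNV-1a hash of a config (for output provenance stamps).
# 32-bit arithmetic is emulated in doubles via 16-bit limbs so the
# intermediate products stay exactly representable.
config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "")
  bytes <- utf8ToInt(s)
  h <- 2166136261
  m <- 16777619
  for (b in bytes) {
    lo8 <- h %% 256
    h <- h - lo8 + bitwXor(as.integer(lo8), as.integer(b))
    a <- h %/% 65536; c <- h %% 65536
    h <- (((a * m) %% 65536) * 65536 + c * m) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)
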