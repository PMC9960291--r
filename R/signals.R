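#' Uniformly sampled triaxial signal
#'
#' Container for a raw force-plate or accelerometer recording: three
#' equal-length axis vectors on an implicit uniform time grid. Sample `k`
#' (1-based) occurs at `t0 + (k - 1) / fs` seconds.
#'
#' @param x,y,z Numeric vectors of identical length (at least 2 samples).
#' @param fs Sampling frequency in Hz (positive scalar).
#' @param units Signal units: `"g"` (gravitational acceleration units,
#'   1 g = 9.807 m/s^2) or `"N"` (newtons).
#' @param t0 Clock time of the first sample, in seconds since the epoch
#'   (numeric) or a `POSIXct`. Defaults to 0.
#'
#' @return An object of class `triaxial_signal`: a list with elements
#'   `t0`, `fs`, `x`, `y`, `z`, `units`, `n`.
#' @export
#' @examples
#' sig <- triaxial_signal(x = c(3, 0), y = c(4, 0), z = c(0, -1), fs = 100)
#' resultant(sig)$v
triaxial_signal <- function(x, y, z, fs, units = c("g", "N"), t0 = 0) {
  units <- match.arg(units)
  x <- as.double(x); y <- as.double(y); z <- as.double(z)
  sig <- structure(
    list(t0 = as_epoch_seconds(t0), fs = as.double(fs),
         x = x, y = y, z = z, units = units, n = length(x)),
    class = "triaxial_signal"
  )
  validate_triaxial_signal(sig)
}

validate_triaxial_signal <- function(sig) {
  n <- length(sig$x)
  if (length(sig$y) != n || length(sig$z) != n) {
    stop("x, y and z must have identical length", call. = FALSE)
  }
  if (n < 2) stop("signal must have at least 2 samples", call. = FALSE)
  if (!is.finite(sig$fs) || sig$fs <= 0) {
    stop("fs must be a positive sampling frequency in Hz", call. = FALSE)
  }
  if (!sig$units %in% c("g", "N")) {
    stop("units must be 'g' or 'N'", call. = FALSE)
  }
  sig$n <- n
  sig
}

#' Uniformly sampled scalar signal
#'
#' One-channel signal, typically a resultant vector or a single axis pulled
#' out of a [triaxial_signal()], or a rate signal produced by
#' [centered_derivative()].
#'
#' @param v Numeric vector (at least 1 sample; a minimal centered derivative
#'   has a single interior value).
#' @param fs Sampling frequency in Hz.
#' @param units One of `"g"`, `"N"`, `"g/s"`, `"N/s"`.
#' @param t0 Clock time of the first sample (seconds since epoch or POSIXct).
#'
#' @return An object of class `scalar_signal` with elements `t0`, `fs`, `v`,
#'   `units`, `n`.
#' @export
scalar_signal <- function(v, fs, units = c("g", "N", "g/s", "N/s"), t0 = 0) {
  units <- match.arg(units)
  sig <- structure(
    list(t0 = as_epoch_seconds(t0), fs = as.double(fs),
         v = as.double(v), units = units, n = length(v)),
    class = "scalar_signal"
  )
  validate_scalar_signal(sig)
}

validate_scalar_signal <- function(sig) {
  # length 1 is allowed: the centered derivative of a minimal 3-sample
  # signal is a single interior value
  if (length(sig$v) < 1) stop("signal must have at least 1 sample", call. = FALSE)
  if (!is.finite(sig$fs) || sig$fs <= 0) {
    stop("fs must be a positive sampling frequency in Hz", call. = FALSE)
  }
  if (!sig$units %in% c("g", "N", "g/s", "N/s")) {
    stop("units must be one of 'g', 'N', 'g/s', 'N/s'", call. = FALSE)
  }
  sig$n <- length(sig$v)
  sig
}

as_epoch_seconds <- function(t0) {
  if (inherits(t0, "POSIXct")) return(as.double(t0))
  if (is.character(t0)) {
    parsed <- as.POSIXct(t0, tz = "UTC",
                         tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS"))
    return(as.double(parsed))
  }
  as.double(t0)
}

#' @export
print.triaxial_signal <- function(x, ...) {
  cat(sprintf("<triaxial_signal> %d samples @ %g Hz [%s], t0 = %s, duration %.3f s\n",
              x$n, x$fs, x$units, format_t0(x$t0), (x$n - 1) / x$fs))
  invisible(x)
}

#' @export
print.scalar_signal <- function(x, ...) {
  cat(sprintf("<scalar_signal> %d samples @ %g Hz [%s], t0 = %s, range [%.4g, %.4g]\n",
              x$n, x$fs, x$units, format_t0(x$t0), min(x$v), max(x$v)))
  invisible(x)
}

format_t0 <- function(t0) {
  if (t0 == 0) return("epoch 0")
  format(as.POSIXct(t0, origin = "1970-01-01", tz = "UTC"), "%Y-%m-%dT%H:%M:%OS2Z")
}

#' Sample times of a signal
#'
#' @param sig A `triaxial_signal` or `scalar_signal`.
#' @param relative If `TRUE` (default) times start at 0; otherwise `t0` is added.
#' @return Numeric vector of sample times in seconds.
#' @export
signal_times <- function(sig, relative = TRUE) {
  t <- (seq_len(sig$n) - 1) / sig$fs
  if (relative) t else t + sig$t0
}

#' Extract one axis of a triaxial signal as a scalar signal
#'
#' For vertical-vector analyses the pipeline runs on the sensor axis aligned
#' with the body's longitudinal axis, rectified (absolute value) so that
#' impact peaks are positive regardless of the sensor's sign convention.
#'
#' @param sig A [triaxial_signal()].
#' @param axis Which axis to extract: `"x"`, `"y"` or `"z"`.
#' @param rectify Take the absolute value (default `TRUE`).
#' @return A [scalar_signal()] with the same units, `fs` and `t0`.
#' @export
signal_axis <- function(sig, axis = c("x", "y", "z"), rectify = TRUE) {
  stopifnot(inherits(sig, "triaxial_signal"))
  axis <- match.arg(axis)
  v <- sig[[axis]]
  if (rectify) v <- abs(v)
  scalar_signal(v, fs = sig$fs, units = sig$units, t0 = sig$t0)
}
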