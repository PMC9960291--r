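#' Downsample a signal onto a coarser uniform grid
#'
#' Linear interpolation onto a grid that starts at `t0` with step
#' `1/target_fs` and covers the original span. Downsampling only: the
#' anti-aliasing role is played by the subsequent 20 Hz low-pass filter, and
#' linear interpolation keeps impact peak amplitudes close to the raw signal.
#'
#' @param sig A [triaxial_signal()] or [scalar_signal()].
#' @param target_fs Target sampling frequency in Hz; must not exceed `sig$fs`.
#' @return A signal of the same class with `fs = target_fs`.
#' @export
resample_to <- function(sig, target_fs) {
  if (!is.finite(target_fs) || target_fs <= 0) {
    stop("target_fs must be a positive frequency in Hz", call. = FALSE)
  }
  if (target_fs > sig$fs) {
    stop(sprintf("unsupported upsampling: target_fs = %g Hz exceeds signal fs = %g Hz",
                 target_fs, sig$fs), call. = FALSE)
  }
  if (target_fs == sig$fs) return(sig)
  t_old <- signal_times(sig)
  span <- t_old[length(t_old)]
  n_new <- floor(span * target_fs) + 1
  t_new <- (seq_len(n_new) - 1) / target_fs
  interp <- function(v) stats::approx(t_old, v, xout = t_new, method = "linear")$y
  if (inherits(sig, "triaxial_signal")) {
    triaxial_signal(interp(sig$x), interp(sig$y), interp(sig$z),
                    fs = target_fs, units = sig$units, t0 = sig$t0)
  } else {
    scalar_signal(interp(sig$v), fs = target_fs, units = sig$units, t0 = sig$t0)
  }
}

# Direct-form-II-transposed IIR filter with explicit initial state, the
# classic single-pass recursion y[i] = b.x - a.y.
lfilter <- function(b, a, x, zi = NULL) {
  nc <- length(b)
  if (is.null(zi)) zi <- numeric(nc - 1)
  n <- length(x)
  y <- numeric(n)
  z <- zi
  for (i in seq_len(n)) {
    xi <- x[i]
    yi <- b[1] * xi + z[1]
    if (nc > 2) {
      z[1:(nc - 2)] <- b[2:(nc - 1)] * xi + z[2:(nc - 1)] - a[2:(nc - 1)] * yi
    }
    z[nc - 1] <- b[nc] * xi - a[nc] * yi
    y[i] <- yi
  }
  y
}

# Steady-state filter state for a unit-step input: solving
# (I - A^T) zi = B for the DF2T state space guarantees that a constant
# input produces a constant output from the first sample.
lfilter_zi <- function(b, a) {
  nf <- length(a)
  comp <- matrix(0, nf - 1, nf - 1)
  comp[1, ] <- -a[-1] / a[1]
  if (nf > 2) comp[cbind(2:(nf - 1), 1:(nf - 2))] <- 1
  B <- b[-1] - a[-1] * b[1]
  solve(diag(nf - 1) - t(comp), B)
}

filtfilt_refl <- function(b, a, x, pad) {
  n <- length(x)
  # odd (point-symmetric) reflection about the first and last samples
  ext <- c(2 * x[1] - x[(pad + 1):2],
           x,
           2 * x[n] - x[(n - 1):(n - pad)])
  zi <- lfilter_zi(b, a)
  y <- lfilter(b, a, ext, zi * ext[1])
  y <- rev(lfilter(b, a, rev(y), zi * y[length(y)]))
  y[(pad + 1):(pad + n)]
}

#' Zero-phase Butterworth low-pass filter
#'
#' Applies an order-`order` Butterworth low-pass filter forward and then
#' backward (zero phase) per axis, so that impact-peak timing is preserved
#' for the sample-level synchronization step. The effective magnitude
#' response is the square of a single pass; the cutoff is not order-corrected
#' for the double pass. Edge transients are suppressed by odd-reflection
#' padding of `3 * (order + 1)` samples at each end together with
#' steady-state filter initialization, which makes the DC gain exactly 1 on
#' constant signals.
#'
#' @param sig A [triaxial_signal()] or [scalar_signal()].
#' @param cutoff Cutoff frequency in Hz; must satisfy `0 < cutoff < fs/2`.
#' @param order Filter order (default 4).
#' @return A signal of the same class and length.
#' @export
lowpass_butterworth <- function(sig, cutoff = 20, order = 4) {
  if (!is.finite(cutoff) || cutoff <= 0 || cutoff >= sig$fs / 2) {
    stop(sprintf("parameter error: cutoff must lie in (0, fs/2) = (0, %g) Hz", sig$fs / 2),
         call. = FALSE)
  }
  if (order < 1) stop("parameter error: order must be >= 1", call. = FALSE)
  pad <- 3L * (as.integer(order) + 1L)
  if (sig$n <= pad) {
    stop(sprintf("length error: signal of %d samples is too short for order-%d zero-phase filtering (needs > %d)",
                 sig$n, order, pad), call. = FALSE)
  }
  bf <- signal::butter(order, cutoff / (sig$fs / 2), type = "low")
  b <- bf$b; a <- bf$a
  if (inherits(sig, "triaxial_signal")) {
    triaxial_signal(filtfilt_refl(b, a, sig$x, pad),
                    filtfilt_refl(b, a, sig$y, pad),
                    filtfilt_refl(b, a, sig$z, pad),
                    fs = sig$fs, units = sig$units, t0 = sig$t0)
  } else {
    scalar_signal(filtfilt_refl(b, a, sig$v, pad),
                  fs = sig$fs, units = sig$units, t0 = sig$t0)
  }
}

#' Resultant (Euclidean norm) of a triaxial signal
#'
#' `r_i = sqrt(x_i^2 + y_i^2 + z_i^2)` at every sample; units are preserved.
#'
#' @param sig A [triaxial_signal()].
#' @return A [scalar_signal()].
#' @export
resultant <- function(sig) {
  stopifnot(inherits(sig, "triaxial_signal"))
  scalar_signal(sqrt(sig$x^2 + sig$y^2 + sig$z^2),
                fs = sig$fs, units = sig$units, t0 = sig$t0)
}

#' Synchronize two signals by clock and maximum cross-correlation
#'
#' First aligns the two streams by their recorded clocks (the `t0` difference
#' rounded to the nearest sample), then finds the residual lag within
#' `+/- max_lag_s` that maximizes the normalized cross-correlation of the
#' mean-removed signals. A positive lag means `b`'s content occurs later than
#' `a`'s. Ties are broken toward the smallest absolute lag, then toward the
#' negative lag. An explicit `manual_offset_s` (the per-trial manual
#' adjustment, rounded to whole samples) is added to the total and recorded
#' separately.
#'
#' @param a,b [scalar_signal()] objects with identical sampling frequency.
#' @param max_lag_s Half-width of the residual lag search window in seconds
#'   (default 5); must be smaller than half the shorter signal's duration.
#' @param manual_offset_s Manual synchronization adjustment in seconds
#'   (default 0).
#' @return A `sync_result` list: `lag_samples` (total, including clock,
#'   cross-correlation and manual components), `lag_seconds`, `peak_xcorr`,
#'   `clock_lag_samples`, `xcorr_lag_samples`, `manual_offset_samples`, `fs`.
#' @export
synchronize <- function(a, b, max_lag_s = 5, manual_offset_s = 0) {
  stopifnot(inherits(a, "scalar_signal"), inherits(b, "scalar_signal"))
  if (abs(a$fs - b$fs) > 1e-9 * a$fs) {
    stop("signals must share a sampling frequency; resample first", call. = FALSE)
  }
  fs <- a$fs
  min_dur <- (min(a$n, b$n) - 1) / fs
  if (max_lag_s >= min_dur / 2) {
    stop("max_lag_s must be smaller than half the shorter signal's duration",
         call. = FALSE)
  }
  if (stats::sd(a$v) == 0 || stats::sd(b$v) == 0) {
    stop("degenerate signal: zero variance, cannot cross-correlate", call. = FALSE)
  }
  k0 <- as.integer(round((b$t0 - a$t0) * fs))
  L <- as.integer(floor(max_lag_s * fs))
  a0 <- a$v - mean(a$v)
  b0 <- b$v - mean(b$v)
  # total-lag candidates: the clock offset plus a residual within +/- max_lag
  lags <- k0 + ((-L):L)
  r <- vapply(lags, function(l) {
    # pairs a[i] ~ b[i - l] under the hypothesis that b's content occurs
    # l samples later than a's in absolute time
    j_shift <- l - k0
    i_lo <- max(1L, 1L - j_shift)
    i_hi <- min(a$n, b$n - j_shift)
    if (i_hi - i_lo < 1L) return(NA_real_)
    ai <- a0[i_lo:i_hi]
    bj <- b0[(i_lo + j_shift):(i_hi + j_shift)]
    den <- sqrt(sum(ai^2) * sum(bj^2))
    if (den == 0) return(NA_real_)
    sum(ai * bj) / den
  }, numeric(1))
  if (all(is.na(r))) stop("no overlapping samples within the lag window", call. = FALSE)
  # maximize the correlation magnitude but report the signed value: an
  # inverted channel aligns at |r| ~ 1 with r < 0 and the caller decides
  best <- which(abs(r) == max(abs(r), na.rm = TRUE))
  # tie-break: smallest |residual lag|, then the negative residual
  best <- best[order(abs(lags[best] - k0), lags[best] - k0)][1]
  total <- lags[best]
  manual <- as.integer(round(manual_offset_s * fs))
  structure(
    list(lag_samples = total + manual,
         lag_seconds = (total + manual) / fs,
         peak_xcorr = r[best],
         clock_lag_samples = k0,
         xcorr_lag_samples = total - k0,
         manual_offset_samples = manual,
         fs = fs),
    class = "sync_result"
  )
}

#' @export
print.sync_result <- function(x, ...) {
  cat(sprintf("<sync_result> lag = %d samples (%.4f s) [clock %d + xcorr %d + manual %d], peak xcorr = %.4f\n",
              x$lag_samples, x$lag_seconds, x$clock_lag_samples,
              x$xcorr_lag_samples, x$manual_offset_samples, x$peak_xcorr))
  invisible(x)
}

#' Apply a synchronization lag to a signal
#'
#' Shifts the signal's clock origin so that content delayed by `lag_samples`
#' lines up with its reference; samples are untouched, only `t0` moves.
#' Pairing with another signal afterwards (see [pair_overlap()]) retains the
#' overlapping region only.
#'
#' @param sig A [scalar_signal()] (or [triaxial_signal()]).
#' @param lag_samples Signed integer lag, as reported by [synchronize()];
#'   `abs(lag_samples)` must be smaller than the signal length.
#' @return The shifted signal.
#' @export
apply_lag <- function(sig, lag_samples) {
  lag_samples <- as.integer(round(lag_samples))
  if (abs(lag_samples) >= sig$n) {
    stop("empty overlap: |lag| is not smaller than the signal length", call. = FALSE)
  }
  sig$t0 <- sig$t0 - lag_samples / sig$fs
  sig
}

#' Trim two signals to their common time window
#'
#' Uses the two clock origins (after [apply_lag()]) to find the overlapping
#' samples on the shared grid and trims both signals to it.
#'
#' @param a,b [scalar_signal()] objects with identical `fs`.
#' @return A list with trimmed signals `a` and `b` of equal length.
#' @export
pair_overlap <- function(a, b) {
  stopifnot(inherits(a, "scalar_signal"), inherits(b, "scalar_signal"))
  if (abs(a$fs - b$fs) > 1e-9 * a$fs) {
    stop("signals must share a sampling frequency", call. = FALSE)
  }
  k <- as.integer(round((b$t0 - a$t0) * a$fs))  # b[j] aligns with a[j + k]
  i_lo <- max(1L, 1L + k)
  i_hi <- min(a$n, b$n + k)
  if (i_hi - i_lo + 1L < 2L) stop("empty overlap between signals", call. = FALSE)
  list(
    a = scalar_signal(a$v[i_lo:i_hi], fs = a$fs, units = a$units,
                      t0 = a$t0 + (i_lo - 1) / a$fs),
    b = scalar_signal(b$v[(i_lo - k):(i_hi - k)], fs = b$fs, units = b$units,
                      t0 = b$t0 + (i_lo - k - 1) / b$fs)
  )
}
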