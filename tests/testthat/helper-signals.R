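# shared fixture builders; all randomness is locally seeded

# smooth band-limited random signal (moving-average filtered white noise)
smooth_random_signal <- function(n, fs = 100, seed = 1, units = "g", t0 = 0) {
  set.seed(seed)
  v <- stats::filter(rnorm(n + 40), rep(1 / 20, 20), sides = 1)
  scalar_signal(as.numeric(v[41:(n + 40)]) + 1, fs = fs, units = units, t0 = t0)
}

# baseline + Gaussian bumps with known apex samples
bump_signal <- function(fs = 100, duration = 10, bump_times = c(1, 6),
                        bump_peaks = c(8, 8), width = 0.05, baseline = 1,
                        units = "g") {
  t <- seq(0, duration, by = 1 / fs)
  v <- rep(baseline, length(t))
  for (k in seq_along(bump_times)) {
    v <- v + bump_peaks[k] * exp(-(t - bump_times[k])^2 / (2 * width^2))
  }
  apex <- vapply(bump_times, function(b) which.min(abs(t - b)), integer(1))
  list(sig = scalar_signal(v, fs = fs, units = units), apex = apex)
}

# delayed copy of a scalar signal: content shifted later by k samples,
# front-padded with the first value, same t0 and length
delayed_copy <- function(sig, k) {
  stopifnot(k >= 0, k < sig$n)
  v <- if (k == 0) sig$v else c(rep(sig$v[1], k), sig$v[1:(sig$n - k)])
  scalar_signal(v, fs = sig$fs, units = sig$units, t0 = sig$t0)
}

# one-subject zero-offset spec for fast trials
quiet_spec <- function(seed = 1, noise = FALSE) {
  protocol_spec(subjects = 1,
                noise_sd_force = if (noise) 4 else 0,
                noise_sd_accel = if (noise) 0.02 else 0,
                clock_offset_range = c(0, 0), seed = seed)
}

trial_meta <- function(truth, jump_type, height_cm, placement) {
  list(subject_id = "S001", body_mass_kg = truth$body_mass_kg,
       jump_type = jump_type, height_cm = height_cm, placement = placement)
}
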