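test_that("peak detection finds injected bumps and ignores flat signals", {
  flat <- scalar_signal(rep(1, 1000), fs = 100, units = "g")
  expect_identical(nrow(detect_peaks(flat, 4)), 0L)

  bs <- bump_signal(fs = 100, duration = 10, bump_times = c(1, 6), bump_peaks = c(8, 8))
  pk <- detect_peaks(bs$sig, min_separation_s = 4)
  expect_identical(pk$index, bs$apex)
})

test_that("close sub-separation pairs merge to the larger peak (greedy oracle)", {
  bs <- bump_signal(fs = 100, duration = 5, bump_times = c(1.0, 1.1),
                    bump_peaks = c(8, 6), width = 0.02)
  pk <- detect_peaks(bs$sig, min_separation_s = 0.2)
  expect_identical(nrow(pk), 1L)
  expect_identical(pk$index, bs$apex[1])
  # exhaustive pairwise check: every retained pair respects the separation
  bs2 <- bump_signal(fs = 100, duration = 20,
                     bump_times = c(1, 1.1, 5, 5.15, 10, 14, 14.05),
                     bump_peaks = c(8, 6, 5, 9, 7, 6, 6.5), width = 0.02)
  pk2 <- detect_peaks(bs2$sig, min_separation_s = 0.2)
  if (nrow(pk2) > 1) {
    gaps <- diff(pk2$index) / 100
    expect_true(all(gaps >= 0.2))
  }
  # each surviving peak is the maximum of its suppressed neighborhood
  for (i in seq_len(nrow(pk2))) {
    near <- abs(bs2$apex - pk2$index[i]) < 0.2 * 100
    expect_gte(pk2$magnitude[i], max(bs2$sig$v[bs2$apex[near]]) - 1e-9)
  }
})

test_that("peak detection is threshold-relative and scale-equivariant", {
  bs <- bump_signal(fs = 100, duration = 10, bump_times = c(2, 7), bump_peaks = c(5, 6))
  pk <- detect_peaks(bs$sig, 4)
  shifted <- scalar_signal(bs$sig$v + 10, fs = 100, units = "g")
  pk_shift <- detect_peaks(shifted, 4)
  expect_identical(pk_shift$index, pk$index)
  expect_equal(pk_shift$magnitude, pk$magnitude + 10)

  scaled <- scalar_signal(bs$sig$v * 3, fs = 100, units = "g")
  pk_scaled <- detect_peaks(scaled, 4)
  expect_identical(pk_scaled$index, pk$index)
  expect_equal(pk_scaled$magnitude, pk$magnitude * 3)
})

test_that("force-peak matching respects the window and clips bounds", {
  fs <- 100
  t <- seq(0, 10, by = 1 / fs)
  mk_force <- function(tmax) {
    scalar_signal(100 + 1000 * exp(-(t - tmax)^2 / (2 * 0.03^2)), fs = fs, units = "N")
  }
  acc_peak <- list(index = which.min(abs(t - 5)))

  same <- match_force_peak(mk_force(5), acc_peak, 0.2)
  expect_identical(same$index, acc_peak$index)

  late <- match_force_peak(mk_force(5.15), acc_peak, 0.2)
  expect_identical(late$index, which.min(abs(t - 5.15)))

  # max outside the window: take the windowed argmax, not the global max
  far <- mk_force(5.3)
  res <- match_force_peak(far, acc_peak, 0.2)
  expect_identical(res$index, acc_peak$index + as.integer(0.2 * fs))
  expect_lt(res$magnitude, max(far$v))

  expect_error(match_force_peak(mk_force(5), list(index = 5000), 0.2), "out-of-range")
})

test_that("centered derivative follows the interior formula exactly", {
  s <- scalar_signal(c(0, 1, 4), fs = 1, units = "N")
  d <- centered_derivative(s)
  expect_identical(d$n, 1L)
  expect_equal(d$v, 2)
  expect_identical(d$units, "N/s")

  t <- (0:499) / 100
  ramp <- scalar_signal(2 * t, fs = 100, units = "N")
  expect_true(all(abs(centered_derivative(ramp)$v - 2) < 1e-12))

  # exact for quadratics on uniform grids
  quad <- scalar_signal(t^2, fs = 100, units = "N")
  dq <- centered_derivative(quad)
  expect_equal(dq$v, 2 * t[2:499], tolerance = 1e-10)

  expect_error(centered_derivative(scalar_signal(c(1, 2), fs = 1, units = "N")),
               "length error")
})

test_that("centered derivative inverts an interleaved cumulative sum (discrete FTC)", {
  set.seed(51)
  fs <- 100
  w <- rnorm(200)
  F <- numeric(202)
  for (i in 3:202) F[i] <- F[i - 2] + 2 * w[i - 2] / fs
  d <- centered_derivative(scalar_signal(F, fs = fs, units = "N"))
  expect_equal(d$v, w, tolerance = 1e-9)
})

test_that("contact onset follows the quiet-band rules with fallback", {
  fs <- 100
  t <- seq(0, 3, by = 1 / fs)
  # force: 0 N until 1.00 s, then rise to a peak at 1.08 s
  fv <- ifelse(t < 1, 0, pmin((t - 1) / 0.08, 1)) * 2000
  force <- scalar_signal(fv, fs = fs, units = "N")
  ipk <- which.min(abs(t - 1.08))
  onset <- find_contact_onset(force, ipk, "force")
  expect_equal(t[onset], 1.00, tolerance = 0.011)
  expect_lt(onset, ipk)

  # acceleration: quiet 1 g until a bump
  av <- 1 + ifelse(t < 1.5, 0, 6 * exp(-(t - 1.6)^2 / (2 * 0.03^2)))
  acc <- scalar_signal(av, fs = fs, units = "g")
  apk <- which.min(abs(t - 1.6))
  on_a <- find_contact_onset(acc, apk, "acceleration")
  expect_true(abs(acc$v[on_a] - 1) <= 0.2)
  expect_true(abs(acc$v[on_a + 1] - 1) > 0.2 || on_a + 1 == apk)

  # monotone rise through the whole window: fall back to the window start
  mono <- scalar_signal(seq(100, 4000, length.out = 301), fs = fs, units = "N")
  expect_identical(find_contact_onset(mono, 250L, "force"),
                   250L - as.integer(round(fs)))

  expect_error(find_contact_onset(force, 2L, "force"), "onset error")
})

test_that("peak rate is exact on ramps and matches a dense-grid half-sine oracle", {
  fs <- 100
  t <- seq(0, 2, by = 1 / fs)
  ramp <- scalar_signal(pmax(0, pmin(t - 1, 0.5)) * 5000, fs = fs, units = "N")
  onset <- which.min(abs(t - 1))
  ipk <- which.min(abs(t - 1.5))
  expect_equal(peak_rate(ramp, onset, ipk), 5000)

  # half-sine rise: amplitude A over duration T, analytic max slope pi*A/(2T)
  A <- 3000; T_rise <- 0.3
  fs_fine <- 2000
  tf <- seq(0, 1, by = 1 / fs_fine)
  hv <- ifelse(tf < 0.2, 0, ifelse(tf < 0.2 + T_rise,
                                   A * sin(pi * (tf - 0.2) / (2 * T_rise)), A))
  hs <- scalar_signal(hv, fs = fs_fine, units = "N")
  on_h <- which.min(abs(tf - 0.2))
  pk_h <- which.min(abs(tf - (0.2 + T_rise)))
  got <- peak_rate(hs, on_h, pk_h)
  # brute-force fine-grid derivative oracle
  oracle <- max((hv[3:length(hv)] - hv[1:(length(hv) - 2)]) * fs_fine / 2)
  expect_equal(got, oracle)
  expect_equal(got, pi * A / (2 * T_rise), tolerance = 0.01)

  expect_error(peak_rate(ramp, 10L, 11L), "length error")
  expect_error(peak_rate(ramp, 11L, 10L), "onset")
})

test_that("trial summaries are event means with metadata copied through", {
  meta <- list(subject_id = "S001", body_mass_kg = 80, jump_type = "drop",
               height_cm = 40, placement = "hip", vector = "resultant")
  ev1 <- data.frame(pACC_g = 3, pAR_gs = 60, pGRF_N = 1000, pLR_Ns = 50000)
  s1 <- summarize_trial(ev1, meta)
  expect_equal(s1$pGRF_N, 1000)
  expect_identical(s1$subject_id, "S001")

  ev2 <- data.frame(pACC_g = c(3, 5), pAR_gs = c(60, 80),
                    pGRF_N = c(1000, 2000), pLR_Ns = c(5e4, 7e4))
  expect_equal(summarize_trial(ev2, meta)$pGRF_N, 1500)

  expect_error(summarize_trial(ev2[0, ], meta), "empty-trial")
})
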