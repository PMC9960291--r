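test_that("quiet standing force equals body weight and everything is seeded", {
  spec <- quiet_spec(seed = 5)
  tr <- simulate_trial(spec, 1, "drop", 20, n_jumps = 2)
  bw <- tr$truth$body_mass_kg * 9.807
  # first second of the trial is quiet standing
  expect_equal(median(tr$force$z[1:1000]), bw, tolerance = 1e-9)

  tr2 <- simulate_trial(spec, 1, "drop", 20, n_jumps = 2)
  expect_identical(tr$force$z, tr2$force$z)
  expect_identical(tr$accel$ankle$z, tr2$accel$ankle$z)

  noisy1 <- simulate_trial(protocol_spec(subjects = 1, seed = 5), 1, "drop", 20, n_jumps = 2)
  noisy2 <- simulate_trial(protocol_spec(subjects = 1, seed = 6), 1, "drop", 20, n_jumps = 2)
  expect_false(identical(noisy1$force$z, noisy2$force$z))

  expect_error(simulate_trial(spec, 1, "backflip", 20), "spec error")
})

test_that("body mass scales the noiseless force waveform exactly", {
  spec <- quiet_spec(seed = 9)
  tr <- simulate_trial(spec, 1, "drop", 20, n_jumps = 2)
  mass <- tr$truth$body_mass_kg
  # rebuild with a doubled-mass spec by comparing against the raw waveform:
  # the vertical force divides by mass into a mass-free shape
  shape <- tr$force$z / mass
  spec2 <- quiet_spec(seed = 9)
  spec2$body_mass_mean <- 2 * mass  # degenerate mass distribution at 2m
  spec2$body_mass_sd <- 0
  spec2$body_mass_range <- c(0, 1e6)
  tr2 <- simulate_trial(spec2, 1, "drop", 20, n_jumps = 2)
  expect_equal(tr2$truth$body_mass_kg, 2 * mass)
  expect_equal(tr2$force$z / (2 * mass), shape, tolerance = 1e-12)
  expect_equal(tr2$truth$force$pGRF_N, 2 * tr$truth$force$pGRF_N, tolerance = 1e-12)
  # acceleration is mass-independent
  expect_equal(tr2$accel$hip$z, tr$accel$hip$z, tolerance = 1e-12)
})

test_that("true peak force increases strictly with drop height", {
  spec <- quiet_spec(seed = 10)
  peaks <- vapply(seq(5, 40, by = 5), function(h) {
    simulate_trial(spec, 1, "drop", h, n_jumps = 1)$truth$force$pGRF_N[1]
  }, numeric(1))
  expect_true(all(diff(peaks) > 0))
})

test_that("ankle accelerations exceed hip and lower-back accelerations", {
  spec <- quiet_spec(seed = 11)
  tr <- simulate_trial(spec, 1, "drop", 30, n_jumps = 2)
  by_pl <- tapply(tr$truth$accel$pACC_g, tr$truth$accel$placement, mean)
  expect_gt(by_pl[["ankle"]], by_pl[["hip"]])
  expect_gt(by_pl[["ankle"]], by_pl[["lower_back"]])
})

test_that("summary tables honor the generating model moments", {
  spec <- protocol_spec(subjects = 78, seed = 1)
  sim <- simulate_summary_table(spec, b = c(-500, 190, 18, 1.3),
                                sd_subject = 40, sd_group = 60, sd_residual = 30)
  expect_identical(nrow(sim$summary), 78L * 13L)
  # residual reconstructed from the recorded latent draws
  resid <- sim$summary$pGRF_N - sim$truth$linear_predictor -
    sim$truth$u[sim$truth$subject_of_row] - sim$truth$v[sim$truth$condition_of_row]
  expect_equal(sd(resid), 30, tolerance = 0.1 * 30 / 30)
  expect_equal(resid, sim$truth$e, tolerance = 1e-9)

  # zero SDs: outcome equals the linear predictor exactly
  sim0 <- simulate_summary_table(spec, sd_subject = 0, sd_group = 0, sd_residual = 0)
  expect_equal(sim0$summary$pGRF_N, sim0$truth$linear_predictor, tolerance = 1e-12)

  # determinism and seed sensitivity
  sim_b <- simulate_summary_table(protocol_spec(subjects = 78, seed = 1))
  expect_identical(sim$summary, sim_b$summary)
  sim_c <- simulate_summary_table(protocol_spec(subjects = 78, seed = 2))
  expect_false(identical(sim$summary$pGRF_N, sim_c$summary$pGRF_N))

  expect_error(simulate_summary_table(spec, sd_subject = -1), "spec error")
})

test_that("adding subjects does not perturb existing subjects' draws", {
  small <- simulate_summary_table(protocol_spec(subjects = 5, seed = 3))
  big <- simulate_summary_table(protocol_spec(subjects = 8, seed = 3))
  expect_identical(small$summary$pGRF_N,
                   big$summary$pGRF_N[big$summary$subject_id %in%
                                        sprintf("S%03d", 1:5)])
})

test_that("fixture bundles are complete, re-readable and byte-stable", {
  spec <- protocol_spec(subjects = 1,
                        jump_set = data.frame(jump_type = "drop", height_cm = 20,
                                              n_jumps = 2L),
                        noise_sd_force = 0, noise_sd_accel = 0,
                        clock_offset_range = c(0, 0), seed = 13)
  d1 <- withr::local_tempdir()
  manifest <- write_fixture_bundle(spec, d1)
  csvs <- grep("\\.csv$", manifest$files, value = TRUE)
  expect_length(grep("_force", csvs), 1)
  expect_length(grep("_accel", csvs), 3)
  expect_true(file.exists(file.path(d1, "ground_truth.json")))

  # bundle re-reads to the in-memory objects
  tr <- simulate_trial(spec, 1, "drop", 20)
  force_back <- read_force_csv(file.path(d1, grep("_force", csvs, value = TRUE)))
  expect_identical(force_back$z, tr$force$z)
  acc_back <- read_accel_csv(file.path(d1, "S001_drop_20cm_accel_hip.csv"), "generic")
  expect_identical(acc_back$z, tr$accel$hip$z)
  spec_back <- read_protocol_spec(file.path(d1, "protocol_spec.yml"))
  expect_equal(spec_back$seed, spec$seed)
  expect_equal(spec_back$jump_set$height_cm, spec$jump_set$height_cm)

  # regeneration with the same seed is byte-identical
  d2 <- withr::local_tempdir()
  write_fixture_bundle(spec, d2)
  for (f in csvs) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  expect_identical(readLines(file.path(d1, "ground_truth.json")),
                   readLines(file.path(d2, "ground_truth.json")))
})

test_that("injected clock offsets are recovered to the sample by synchronization", {
  for (seed in 1:6) {
    spec <- protocol_spec(subjects = 1, clock_offset_range = c(-2, 2), seed = seed)
    tr <- simulate_trial(spec, 1, "continuous", 15)
    force_s <- resultant(lowpass_butterworth(resample_to(tr$force, 100), 20, 4))
    accel_s <- resultant(lowpass_butterworth(tr$accel$hip, 20, 4))
    sync <- synchronize(force_s, accel_s, max_lag_s = 2.5)
    expect_identical(sync$lag_samples,
                     as.integer(round(tr$truth$clock_offset_s * 100)))
  }
})
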