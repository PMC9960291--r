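test_that("the mixed model recovers noiseless truth and carries varcomp info", {
  sim <- simulate_summary_table(protocol_spec(subjects = 10, seed = 2),
                                b = c(-500, 190, 18, 1.3),
                                sd_subject = 0, sd_group = 0, sd_residual = 0)
  fit <- fit_mixed_model(sim$summary)
  expect_s3_class(fit, "loading_fit")
  expect_equal(unname(fit$fixef), c(-500, 190, 18, 1.3), tolerance = 1e-6)
  expect_true(all(fit$varcomp < 1e-4))
  expect_identical(fit$method, "ML")
  expect_true(is.finite(fit$minus2ll))
  expect_equal(conditional_r2(fit), 1, tolerance = 1e-6)
})

test_that("the mixed model recovers parameters from noisy study-scale data", {
  b <- c(-500, 190, 18, 1.3)
  sim <- simulate_summary_table(protocol_spec(subjects = 78, seed = 1),
                                b = b, sd_subject = 40, sd_group = 60,
                                sd_residual = 30)
  fit <- fit_mixed_model(sim$summary)
  se <- sqrt(diag(as.matrix(stats::vcov(fit$fit))))
  expect_true(all(abs(fit$fixef - b) < 3 * se))
  # variance components near their generating values
  expect_equal(unname(fit$varcomp["sd_residual"]), 30, tolerance = 0.15)
})

test_that("the mixed model enforces its preconditions", {
  sim <- simulate_summary_table(protocol_spec(subjects = 5, seed = 3))
  one <- sim$summary[sim$summary$subject_id == "S001", ]
  expect_error(fit_mixed_model(one), "2 subjects")
  onegrp <- sim$summary[sim$summary$jump_type == "continuous" &
                          sim$summary$height_cm == 5, ]
  expect_error(fit_mixed_model(onegrp), "groups")
  nas <- sim$summary; nas$pGRF_N[3] <- NA
  expect_error(fit_mixed_model(nas), "missing")
})

test_that("conditional R-squared matches a plug-in variance oracle", {
  # pure-noise outcome: R2c near 0
  set.seed(7)
  spec <- protocol_spec(subjects = 77, seed = 7)  # 77 x 13 = 1001 rows
  sim <- simulate_summary_table(spec, b = c(0, 0, 0, 0),
                                sd_subject = 0, sd_group = 0, sd_residual = 50)
  fit <- fit_mixed_model(sim$summary)
  expect_lt(conditional_r2(fit), 0.1)

  # variances chosen so the closed-form ratio is about 0.9
  sim2 <- simulate_summary_table(protocol_spec(subjects = 78, seed = 9),
                                 b = c(-500, 190, 18, 1.3),
                                 sd_subject = 40, sd_group = 60, sd_residual = 30)
  fit2 <- fit_mixed_model(sim2$summary)
  var_f <- stats::var(sim2$truth$linear_predictor)
  expected <- (var_f + 40^2 + 60^2) / (var_f + 40^2 + 60^2 + 30^2)
  expect_equal(conditional_r2(fit2), expected, tolerance = 0.05)
})

test_that("LOOCV holds each subject out exactly once with disjoint training sets", {
  sim <- simulate_summary_table(protocol_spec(subjects = 5, seed = 4))
  cv <- loocv(sim$summary)
  expect_length(cv$audit, 5)
  expect_setequal(vapply(cv$audit, `[[`, "", "test_subject"),
                  unique(sim$summary$subject_id))
  for (fold in cv$audit) {
    expect_false(fold$test_subject %in% fold$train_subjects)
    expect_length(fold$train_subjects, 4)
  }
  # every row predicted exactly once
  expect_setequal(cv$predictions$row, seq_len(nrow(sim$summary)))

  expect_error(loocv(sim$summary[sim$summary$subject_id %in% c("S001", "S002"), ]),
               "3 subjects")
})

test_that("LOOCV is exact on noiseless data", {
  sim <- simulate_summary_table(protocol_spec(subjects = 6, seed = 5),
                                sd_subject = 0, sd_group = 0, sd_residual = 0)
  cv <- loocv(sim$summary)
  expect_length(cv$failed, 0)
  acc <- accuracy_indices(cv$predictions$actual, cv$predictions$predicted)
  expect_equal(acc$mape_pct, 0, tolerance = 1e-6)
})

test_that("out-of-fold predictions approach the full fixed-effect fit as subjects grow", {
  oof_gap <- function(n_sub, seed) {
    sim <- simulate_summary_table(protocol_spec(subjects = n_sub, seed = seed),
                                  sd_subject = 5, sd_group = 5, sd_residual = 10)
    fit <- fit_mixed_model(sim$summary)
    full <- with(sim$summary, fit$fixef["b0"] + fit$fixef["b1"] * pACC_g +
                   fit$fixef["b2"] * body_mass_kg +
                   fit$fixef["b3"] * pACC_g * body_mass_kg)
    cv <- loocv(sim$summary)
    mean(abs(cv$predictions$predicted - full[cv$predictions$row]))
  }
  expect_lt(oof_gap(24, 6), oof_gap(6, 6))
})

test_that("accuracy indices match hand arithmetic and guard MAPE", {
  same <- accuracy_indices(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$mae, 0)
  expect_equal(same$mape_pct, 0)
  expect_equal(same$rmse, 0)

  prop <- accuracy_indices(c(10, 20, 40), 1.1 * c(10, 20, 40))
  expect_equal(prop$mape_pct, 10)

  two <- accuracy_indices(c(100, 200), c(110, 180))
  expect_equal(two$mae, 15)
  expect_equal(two$rmse, sqrt(250))
  expect_equal(two$mape_pct, 10)

  expect_error(accuracy_indices(c(1, 0, 2), c(1, 1, 2)), "row.* 2")
  expect_error(accuracy_indices(1:3, 1:2), "equal-length")
})

test_that("mae never exceeds rmse, with equality only for equal errors", {
  set.seed(71)
  for (i in 1:10) {
    a <- rnorm(50, 1000, 100)
    p <- a + rnorm(50, 0, 30)
    acc <- accuracy_indices(a, p)
    expect_lte(acc$mae, acc$rmse + 1e-12)
  }
  eq <- accuracy_indices(c(10, 20), c(12, 18))  # equal absolute errors
  expect_equal(eq$mae, eq$rmse)
})

test_that("Bland-Altman handles exact, constant-shift and degenerate cases", {
  a <- c(10, 20, 30, 40)
  r_same <- bland_altman(a, a)
  expect_equal(r_same$bias, 0)
  expect_equal(r_same$loa_low, r_same$loa_high)
  expect_true(r_same$degenerate)
  expect_true(is.na(r_same$t_stat))

  r_shift <- bland_altman(a, a - 5)
  expect_equal(r_shift$bias, 5)
  expect_true(r_shift$degenerate)
})

test_that("Bland-Altman bias is antisymmetric and LoA cover about 95 percent", {
  set.seed(81)
  means <- runif(200, 500, 4000)
  d <- rnorm(200, 0, 10)
  a <- means + d / 2
  p <- means - d / 2
  r <- bland_altman(a, p)
  expect_equal(r$bias, mean(d))
  expect_equal(bland_altman(p, a)$bias, -r$bias)
  expect_gte(r$pct_within_loa, 93)
  expect_lte(r$pct_within_loa, 97)
  expect_lt(r$prop_r2, 0.05)
  expect_gt(r$p_value, 0.05)  # unbiased by construction
})

test_that("Bland-Altman plots render to file, including the degenerate case", {
  set.seed(82)
  a <- rnorm(20, 1000, 100)
  r <- bland_altman(a, a + rnorm(20, 0, 10))
  p <- withr::local_tempfile(fileext = ".png")
  plot_bland_altman(r, p)
  expect_true(file.exists(p))
  expect_gt(file.size(p), 0)

  r_deg <- bland_altman(a, a)
  p2 <- withr::local_tempfile(fileext = ".png")
  plot_bland_altman(r_deg, p2)
  expect_true(file.exists(p2))
})
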