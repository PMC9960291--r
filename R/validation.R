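#' Specify the mixed model behind a prediction equation
#'
#' The model form is fixed: the outcome is regressed on the acceleration
#' predictor, body mass and their interaction as fixed effects, with random
#' intercepts for the subject and for the jump-type-by-height combination.
#' Estimation is by maximum likelihood by default, so that -2 log-likelihood
#' values are comparable across fixed-effect structures; REML is available
#' by flag.
#'
#' @param outcome Summary column holding the outcome (`"pGRF_N"` or `"pLR_Ns"`).
#' @param predictor Summary column holding the predictor (`"pACC_g"` or
#'   `"pAR_gs"`).
#' @param method `"ML"` (default) or `"REML"`.
#' @return A `mixed_model_spec` list.
#' @export
mixed_model_spec <- function(outcome = "pGRF_N", predictor = "pACC_g",
                             method = c("ML", "REML")) {
  method <- match.arg(method)
  structure(list(outcome = outcome, predictor = predictor, method = method,
                 fixed = c("intercept", "predictor", "mass", "predictor:mass"),
                 random = c("subject", "jump_type:height")),
            class = "mixed_model_spec")
}

# jump-type-by-height grouping factor, encoded by label concatenation
jump_group <- function(data) {
  factor(paste(data$jump_type, data$height_cm, sep = ":"))
}

#' Fit the loading prediction mixed model
#'
#' Fits `outcome ~ predictor * body_mass + (1 | subject) + (1 | jump_group)`
#' with [lme4::lmer()]. Convergence and singularity messages are captured and
#' carried on the result rather than raised.
#'
#' @param data A summary data.frame with columns `subject_id`,
#'   `body_mass_kg`, `jump_type`, `height_cm` and the spec's outcome and
#'   predictor columns; at least 2 subjects and 2 jump-type-by-height groups,
#'   no missing values.
#' @param spec A [mixed_model_spec()].
#' @return A `loading_fit` list: `fixef` (b0, b1, b2, b3), `varcomp`
#'   (SDs for subject, jump group and residual), `minus2ll`, `method`,
#'   `warnings`, `singular`, and the underlying `merMod` object as `fit`.
#' @export
fit_mixed_model <- function(data, spec = mixed_model_spec()) {
  stopifnot(inherits(spec, "mixed_model_spec"))
  data <- as.data.frame(data)
  need <- c("subject_id", "body_mass_kg", "jump_type", "height_cm",
            spec$outcome, spec$predictor)
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols) > 0) {
    stop(sprintf("data are missing columns: %s", paste(missing_cols, collapse = ", ")),
         call. = FALSE)
  }
  if (anyNA(data[need])) stop("missing values in model columns", call. = FALSE)
  if (length(unique(data$subject_id)) < 2) {
    stop("at least 2 subjects are required", call. = FALSE)
  }
  d <- data.frame(y = data[[spec$outcome]],
                  p = data[[spec$predictor]],
                  mass = data$body_mass_kg,
                  subject = factor(data$subject_id),
                  grp = jump_group(data))
  if (nlevels(d$grp) < 2) {
    stop("at least 2 jump-type-by-height groups are required", call. = FALSE)
  }
  warnings <- character(0)
  fit <- withCallingHandlers(
    lme4::lmer(y ~ p * mass + (1 | subject) + (1 | grp), data = d,
               REML = spec$method == "REML"),
    warning = function(w) {
      warnings <<- c(warnings, conditionMessage(w))
      invokeRestart("muffleWarning")
    },
    message = function(m) {
      warnings <<- c(warnings, conditionMessage(m))
      invokeRestart("muffleMessage")
    }
  )
  vc <- as.data.frame(lme4::VarCorr(fit))
  sd_of <- function(g) vc$sdcor[match(g, vc$grp)]
  beta <- lme4::fixef(fit)
  structure(list(
    fixef = c(b0 = unname(beta["(Intercept)"]), b1 = unname(beta["p"]),
              b2 = unname(beta["mass"]), b3 = unname(beta["p:mass"])),
    varcomp = c(sd_subject = sd_of("subject"), sd_jump_group = sd_of("grp"),
                sd_residual = sd_of("Residual")),
    minus2ll = as.numeric(-2 * stats::logLik(fit)),
    method = spec$method,
    warnings = warnings,
    singular = lme4::isSingular(fit),
    spec = spec,
    fit = fit,
    data = d
  ), class = "loading_fit")
}

#' @export
print.loading_fit <- function(x, ...) {
  cat(sprintf("<loading_fit> [%s] y = %.3f %+.3f p %+.3f mass %+.3f p:mass\n",
              x$method, x$fixef["b0"], x$fixef["b1"], x$fixef["b2"], x$fixef["b3"]))
  cat(sprintf("  random SDs: subject %.3f, jump group %.3f, residual %.3f; -2LL = %.1f\n",
              x$varcomp["sd_subject"], x$varcomp["sd_jump_group"],
              x$varcomp["sd_residual"], x$minus2ll))
  if (x$singular) cat("  note: singular fit\n")
  if (length(x$warnings)) {
    cat(sprintf("  fit messages: %s\n", paste(x$warnings, collapse = " | ")))
  }
  invisible(x)
}

#' Conditional R-squared of a fitted mixed model
#'
#' Variance explained by fixed and random effects together, in the
#' Nakagawa-Schielzeth formulation:
#' `(var_fixed + var_random) / (var_fixed + var_random + var_residual)`,
#' where `var_fixed` is the variance of the fixed-effect linear predictor
#' over the data.
#'
#' @param fit A `loading_fit` from [fit_mixed_model()].
#' @return A value in `[0, 1]`.
#' @export
conditional_r2 <- function(fit) {
  stopifnot(inherits(fit, "loading_fit"))
  X <- stats::model.matrix(fit$fit)
  var_f <- stats::var(as.numeric(X %*% lme4::fixef(fit$fit)))
  var_u <- sum(fit$varcomp[c("sd_subject", "sd_jump_group")]^2)
  var_e <- fit$varcomp[["sd_residual"]]^2
  total <- var_f + var_u + var_e
  if (total <= 0) stop("undefined R-squared: zero total variance", call. = FALSE)
  (var_f + var_u) / total
}

#' Subject-wise leave-one-out cross-validation
#'
#' Each subject's rows are held out once while the model is refit, with the
#' same specification, on the remaining subjects; the held-out rows are then
#' predicted from the fixed effects only (a subject unseen at training time
#' has no estimable random intercept). Folds whose refit fails are marked
#' failed and skipped; more than 10 percent failed folds is an error.
#'
#' @param data As for [fit_mixed_model()]; at least 3 subjects.
#' @param spec A [mixed_model_spec()].
#' @return A list with `predictions` (data.frame: `row`, `subject_id`,
#'   `fold`, `actual`, `predicted`), `audit` (per-fold test subject and
#'   training subjects, for a disjointness audit) and `failed` (character
#'   vector of failed test subjects).
#' @export
loocv <- function(data, spec = mixed_model_spec()) {
  data <- as.data.frame(data)
  subjects <- unique(as.character(data$subject_id))
  if (length(subjects) < 3) stop("LOOCV requires at least 3 subjects", call. = FALSE)
  preds <- vector("list", length(subjects))
  audit <- vector("list", length(subjects))
  failed <- character(0)
  for (k in seq_along(subjects)) {
    s <- subjects[k]
    test_rows <- which(data$subject_id == s)
    train <- data[-test_rows, , drop = FALSE]
    fit_k <- tryCatch(fit_mixed_model(train, spec), error = function(e) NULL)
    audit[[k]] <- list(fold = k, test_subject = s,
                       train_subjects = unique(as.character(train$subject_id)))
    if (is.null(fit_k)) {
      failed <- c(failed, s)
      next
    }
    nd <- data.frame(p = data[[spec$predictor]][test_rows],
                     mass = data$body_mass_kg[test_rows])
    yhat <- with(nd, fit_k$fixef["b0"] + fit_k$fixef["b1"] * p +
                   fit_k$fixef["b2"] * mass + fit_k$fixef["b3"] * p * mass)
    preds[[k]] <- data.frame(row = test_rows, subject_id = s, fold = k,
                             actual = data[[spec$outcome]][test_rows],
                             predicted = unname(yhat))
  }
  if (length(failed) > 0.1 * length(subjects)) {
    stop(sprintf("LOOCV failed: %d of %d folds did not refit", length(failed),
                 length(subjects)), call. = FALSE)
  }
  list(predictions = do.call(rbind, preds), audit = audit, failed = failed)
}

#' Accuracy indices: MAE, MAPE and RMSE
#'
#' `mae = mean(|a - p|)`, `mape_pct = 100 * mean(|a - p| / |a|)`,
#' `rmse = sqrt(mean((a - p)^2))`, together with the per-row SDs of the
#' absolute and percentage errors (accuracy is conventionally reported as
#' mean plus/minus SD).
#'
#' @param actual,predicted Equal-length numeric vectors (length >= 1).
#' @param mape Compute MAPE (default `TRUE`); requires all `actual != 0`.
#' @return A list: `mae`, `mape_pct`, `rmse`, `sd_ae`, `sd_ape_pct`.
#' @export
accuracy_indices <- function(actual, predicted, mape = TRUE) {
  if (length(actual) != length(predicted) || length(actual) < 1) {
    stop("actual and predicted must be equal-length, non-empty vectors", call. = FALSE)
  }
  ae <- abs(actual - predicted)
  out <- list(mae = mean(ae),
              mape_pct = NA_real_,
              rmse = sqrt(mean((actual - predicted)^2)),
              sd_ae = stats::sd(ae),
              sd_ape_pct = NA_real_)
  if (mape) {
    zero <- which(actual == 0)
    if (length(zero) > 0) {
      stop(sprintf("division error: MAPE undefined, actual value is 0 at row(s) %s",
                   paste(utils::head(zero, 5), collapse = ", ")), call. = FALSE)
    }
    ape <- 100 * ae / abs(actual)
    out$mape_pct <- mean(ape)
    out$sd_ape_pct <- stats::sd(ape)
  }
  out
}

#' Bland-Altman agreement analysis
#'
#' Differences are `actual - predicted` throughout. Reports the bias (mean
#' difference), the limits of agreement (bias plus/minus 1.96 SD of the
#' differences), a one-sample t-test of the differences against zero, the
#' proportional-bias regression of the difference on the pairwise mean
#' (OLS slope, R-squared and two-sided p-value), the accuracy indices and
#' the percentage of points inside the limits of agreement. With
#' zero-variance differences the t-test and proportional-bias regression are
#' undefined and reported as `NA` with `degenerate = TRUE`.
#'
#' @param actual,predicted Equal-length numeric vectors, length >= 3.
#' @return An `agreement_report` list; see Details.
#' @export
bland_altman <- function(actual, predicted) {
  if (length(actual) != length(predicted) || length(actual) < 3) {
    stop("Bland-Altman analysis needs at least 3 paired values", call. = FALSE)
  }
  d <- actual - predicted
  m <- (actual + predicted) / 2
  bias <- mean(d)
  sd_d <- stats::sd(d)
  degenerate <- sd_d == 0
  loa_low <- bias - 1.96 * sd_d
  loa_high <- bias + 1.96 * sd_d
  if (degenerate) {
    t_stat <- NA_real_; p_value <- NA_real_
    prop_slope <- NA_real_; prop_r2 <- NA_real_; prop_p <- NA_real_
  } else {
    tt <- stats::t.test(d, mu = 0)
    t_stat <- unname(tt$statistic); p_value <- tt$p.value
    if (stats::var(m) > 0) {
      ols <- stats::lm(d ~ m)
      sm <- summary(ols)
      prop_slope <- unname(stats::coef(ols)[2])
      prop_r2 <- sm$r.squared
      prop_p <- sm$coefficients[2, 4]
    } else {
      prop_slope <- NA_real_; prop_r2 <- NA_real_; prop_p <- NA_real_
    }
  }
  acc <- if (all(actual != 0)) accuracy_indices(actual, predicted) else
    accuracy_indices(actual, predicted, mape = FALSE)
  structure(list(
    n = length(d), bias = bias, sd_diff = sd_d,
    loa_low = loa_low, loa_high = loa_high,
    t_stat = t_stat, p_value = p_value,
    prop_slope = prop_slope, prop_r2 = prop_r2, prop_p = prop_p,
    mae = acc$mae, mape_pct = acc$mape_pct, rmse = acc$rmse,
    pct_within_loa = 100 * mean(d >= loa_low & d <= loa_high),
    degenerate = degenerate,
    means = m, diffs = d
  ), class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("<agreement_report> n = %d\n", x$n))
  cat(sprintf("  bias = %.4g [LoA %.4g, %.4g], %.1f%% of points within LoA\n",
              x$bias, x$loa_low, x$loa_high, x$pct_within_loa))
  if (x$degenerate) {
    cat("  zero-variance differences: t-test and proportional bias undefined\n")
  } else {
    cat(sprintf("  one-sample t vs 0: t = %.3f, p = %.4g\n", x$t_stat, x$p_value))
    cat(sprintf("  proportional bias: slope = %.4g, R2 = %.4g, p = %.4g\n",
                x$prop_slope, x$prop_r2, x$prop_p))
  }
  cat(sprintf("  MAE = %.4g, MAPE = %.4g%%, RMSE = %.4g\n", x$mae, x$mape_pct, x$rmse))
  invisible(x)
}

#' Draw a Bland-Altman plot
#'
#' Scatter of pairwise means against differences, with a solid bias line and
#' dashed limits of agreement. Degenerate reports (zero-variance
#' differences) still render, with an annotation.
#'
#' @param report An `agreement_report` from [bland_altman()].
#' @param path Output file; format chosen by extension (e.g. `.png`, `.pdf`).
#' @param title Optional plot title.
#' @return `path`, invisibly.
#' @export
plot_bland_altman <- function(report, path, title = "Bland-Altman agreement") {
  stopifnot(inherits(report, "agreement_report"))
  df <- data.frame(mean = report$means, diff = report$diffs)
  gg <- ggplot2::ggplot(df, ggplot2::aes(x = .data$mean, y = .data$diff)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = report$bias, linewidth = 1) +
    ggplot2::geom_hline(yintercept = c(report$loa_low, report$loa_high),
                        linetype = "dashed") +
    ggplot2::labs(title = title, x = "Mean of actual and predicted",
                  y = "Difference (actual - predicted)") +
    ggplot2::theme_minimal()
  if (report$degenerate) {
    gg <- gg + ggplot2::annotate("text", x = mean(df$mean), y = report$bias,
                                 vjust = -1, label = "degenerate: zero-variance differences")
  }
  ok <- tryCatch({
    ggplot2::ggsave(path, gg, width = 6, height = 4, dpi = 150)
    TRUE
  }, error = function(e) {
    stop(sprintf("I/O error writing figure to '%s': %s", path, conditionMessage(e)),
         call. = FALSE)
  })
  invisible(path)
}
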