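#' Protocol specification for the synthetic jump simulator
#'
#' Describes a simulated data-collection protocol: drop jumps from 5-40 cm
#' in 5 cm increments, box jumps onto 5, 15 and 30 cm boxes (two sets of
#' four jumps each, merged here into eight consecutive jumps per trial), and
#' 20 s of continuous jumps at 5 and 15 cm. Force is sampled at 1000 Hz and
#' the three body-worn accelerometers (ankle, lower back, hip) at 100 Hz.
#' The seed fully determines every draw: per-subject and per-trial random
#' streams are derived from the root seed, so adding subjects or trials does
#' not perturb existing ones.
#'
#' @param subjects Number of subjects (default 78).
#' @param body_mass_mean,body_mass_sd,body_mass_range Body-mass distribution
#'   in kg (Gaussian, truncated to the range; defaults 82.4, 20.6, 45-160).
#' @param jump_set Data.frame `jump_type`, `height_cm`, `n_jumps` describing
#'   the trial conditions; defaults to the 13 protocol conditions.
#' @param fs_force,fs_accel Sampling frequencies in Hz (1000, 100).
#' @param noise_sd_force Per-axis white-noise SD on the force plate, N
#'   (default 4).
#' @param noise_sd_accel Per-axis white-noise SD on the accelerometers, g
#'   (default 0.02).
#' @param clock_offset_range Uniform range of the accelerometer clock offset
#'   relative to the force plate, seconds (default c(-1, 1)); each draw is
#'   rounded to a whole accelerometer sample.
#' @param seed Root seed (integer).
#' @return A `protocol_spec` list.
#' @export
protocol_spec <- function(subjects = 78,
                          body_mass_mean = 82.4, body_mass_sd = 20.6,
                          body_mass_range = c(45, 160),
                          jump_set = default_jump_set(),
                          fs_force = 1000, fs_accel = 100,
                          noise_sd_force = 4, noise_sd_accel = 0.02,
                          clock_offset_range = c(-1, 1),
                          seed = 1L) {
  stopifnot(subjects >= 1, fs_force > 0, fs_accel > 0,
            noise_sd_force >= 0, noise_sd_accel >= 0)
  if (!all(jump_set$jump_type %in% JUMP_TYPES)) {
    stop("spec error: jump_type must be one of drop, box, continuous", call. = FALSE)
  }
  structure(list(subjects = as.integer(subjects),
                 body_mass_mean = body_mass_mean, body_mass_sd = body_mass_sd,
                 body_mass_range = body_mass_range,
                 jump_set = jump_set,
                 fs_force = fs_force, fs_accel = fs_accel,
                 noise_sd_force = noise_sd_force, noise_sd_accel = noise_sd_accel,
                 clock_offset_range = clock_offset_range,
                 seed = as.integer(seed)),
            class = "protocol_spec")
}

#' The 13 default protocol conditions
#'
#' @return A data.frame `jump_type`, `height_cm`, `n_jumps`.
#' @export
default_jump_set <- function() {
  rbind(
    data.frame(jump_type = "drop", height_cm = seq(5, 40, by = 5), n_jumps = 8L),
    data.frame(jump_type = "box", height_cm = c(5, 15, 30), n_jumps = 8L),
    data.frame(jump_type = "continuous", height_cm = c(5, 15), n_jumps = 16L)
  )
}

#' @export
print.protocol_spec <- function(x, ...) {
  cat(sprintf("<protocol_spec> %d subjects, %d conditions, force %g Hz / accel %g Hz, seed %d\n",
              x$subjects, nrow(x$jump_set), x$fs_force, x$fs_accel, x$seed))
  invisible(x)
}

# Run expr under a derived seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Derived sub-stream seeds: distinct (subject, condition, stream) triples map
# to distinct seeds for any root, so streams are independent of how many
# other subjects or trials are generated.
child_seed <- function(root, subject = 0L, condition = 0L, stream = 0L) {
  as.integer(((as.double(root) %% 2^20) * 1021 +
                subject * 4099 + condition * 211 + stream) %% (2^31 - 1))
}

GRAVITY <- 9.807  # m/s^2 per g

subject_mass <- function(spec, subject) {
  with_seed(child_seed(spec$seed, subject, 0L, 1L), {
    repeat {
      m <- stats::rnorm(1, spec$body_mass_mean, spec$body_mass_sd)
      if (m >= spec$body_mass_range[1] && m <= spec$body_mass_range[2]) return(m)
    }
  })
}

# normalized gamma-shaped pulse: 0 at tau <= 0, peak value 1 at tau = tau_peak
gamma_pulse <- function(tau, tau_peak, shape = 3) {
  out <- numeric(length(tau))
  pos <- tau > 0
  r <- tau[pos] / tau_peak
  out[pos] <- r^(shape - 1) * exp((shape - 1) * (1 - r))
  out
}

smoothstep <- function(t, lo, hi) {
  u <- pmin(pmax((t - lo) / (hi - lo), 0), 1)
  u * u * (3 - 2 * u)
}

# Support fraction of body weight on the plate: 1 when standing, 0 in
# flight, with smooth take-off and delayed post-landing recovery.
support_mask <- function(t, landings, flight_s, recover_from = 0.25, recover_to = 0.55) {
  s <- rep(1, length(t))
  for (tl in landings) {
    tko <- tl - flight_s
    drop_edge <- 1 - smoothstep(t, tko - 0.08, tko)
    rise <- smoothstep(t, tl + recover_from, tl + recover_to)
    s <- s * pmax(drop_edge, rise)
  }
  s
}

# Placement-specific transmission of the landing impact to the sensor,
# in g per m/s of impact velocity; the ankle sees the largest accelerations.
# The sensors share the force transient's pulse timing and mix so that the
# paired signals are time-locked and the clock offset is identifiable to
# the sample.
ACC_GAIN <- c(ankle = 3.5, lower_back = 2.4, hip = 2.6)

landing_times <- function(jump_type, n_jumps) {
  if (jump_type == "continuous") 2 + 1.2 * (seq_len(n_jumps) - 1)
  else 3 + 6 * (seq_len(n_jumps) - 1)
}

# noiseless vertical force waveform, N
force_waveform <- function(t, mass, v_imp, landings, flight_s) {
  bw <- mass * GRAVITY
  a1 <- bw * (0.9 + 1.05 * v_imp)   # passive impact spike
  a2 <- bw * 0.55                   # active push-off hump
  f <- bw * support_mask(t, landings, flight_s)
  for (tl in landings) {
    tau <- t - tl
    f <- f + a1 * gamma_pulse(tau, 0.05) + a2 * gamma_pulse(tau, 0.22)
  }
  pmax(f, 0)
}

# noiseless vertical acceleration waveform for one placement, g
accel_waveform <- function(t, placement, v_imp, landings, flight_s) {
  g1 <- ACC_GAIN[[placement]] * v_imp
  # push-off hump scaled to the same spike/hump ratio as the force transient
  g2 <- g1 * 0.55 / (0.9 + 1.05 * v_imp)
  a <- support_mask(t, landings, flight_s)  # 1 g standing, ~0 g in flight
  for (tl in landings) {
    tau <- t - tl
    a <- a + g1 * gamma_pulse(tau, 0.05) + g2 * gamma_pulse(tau, 0.22)
  }
  a
}

#' Simulate one paired force-plate/accelerometer trial
#'
#' Generates the raw signals for one subject performing one jump condition:
#' quiet standing at body weight, flight phases near 0 N, and an asymmetric
#' double-peak landing transient (passive impact spike plus active push-off
#' hump) whose amplitude scales with body mass and with the impact velocity
#' `sqrt(2 g h)`. Each accelerometer placement receives the transient with
#' its own gain (largest at the ankle) on a 1 g standing baseline, is
#' delayed by a per-trial clock offset (rounded to a whole accelerometer
#' sample) and carries white sensor noise. Ground truth (per-jump landing
#' time, peak force, peak loading rate, and per-placement peak acceleration
#' and acceleration rate, all measured on the noiseless sampled waveforms)
#' is recorded before noise is added.
#'
#' @param spec A [protocol_spec()].
#' @param subject Subject index (1-based).
#' @param jump_type `"drop"`, `"box"` or `"continuous"`.
#' @param height_cm Jump height in cm.
#' @param n_jumps Number of jumps in the trial; defaults to the spec's value
#'   for this condition.
#' @return A list: `force` (triaxial_signal, N, `fs_force`), `accel` (named
#'   list of triaxial_signal in g, one per placement, `fs_accel`), and
#'   `truth` (body mass, clock offset, per-jump force truth and
#'   per-placement acceleration truth).
#' @export
simulate_trial <- function(spec, subject, jump_type, height_cm, n_jumps = NULL) {
  stopifnot(inherits(spec, "protocol_spec"))
  if (!jump_type %in% JUMP_TYPES) {
    stop(sprintf("spec error: invalid jump type '%s'", jump_type), call. = FALSE)
  }
  cond <- which(spec$jump_set$jump_type == jump_type &
                  spec$jump_set$height_cm == height_cm)
  if (is.null(n_jumps)) {
    n_jumps <- if (length(cond) == 1) spec$jump_set$n_jumps[cond] else
      if (jump_type == "continuous") 16L else 8L
  }
  cond_id <- if (length(cond) == 1) cond else
    100L + as.integer(height_cm) + 50L * match(jump_type, JUMP_TYPES)
  mass <- subject_mass(spec, subject)
  v_imp <- sqrt(2 * GRAVITY * height_cm / 100)
  flight_s <- max(0.12, v_imp / GRAVITY)
  landings <- landing_times(jump_type, n_jumps)
  duration <- max(landings) + 4
  offset <- with_seed(child_seed(spec$seed, subject, cond_id, 2L), {
    stats::runif(1, spec$clock_offset_range[1], spec$clock_offset_range[2])
  })
  offset <- round(offset * spec$fs_accel) / spec$fs_accel

  t_f <- seq(0, duration, by = 1 / spec$fs_force)
  fz0 <- force_waveform(t_f, mass, v_imp, landings, flight_s)
  fx0 <- 0.03 * (fz0 - mass * GRAVITY * support_mask(t_f, landings, flight_s))
  fy0 <- -0.02 * fx0 / 0.03
  t_a <- seq(0, duration, by = 1 / spec$fs_accel)
  accel0 <- lapply(PLACEMENTS, function(pl) {
    az <- accel_waveform(t_a - offset, pl, v_imp, landings, flight_s)
    list(z = az,
         x = 0.05 * (az - support_mask(t_a - offset, landings, flight_s)),
         y = -0.04 * (az - support_mask(t_a - offset, landings, flight_s)))
  })
  names(accel0) <- PLACEMENTS

  truth <- trial_truth(spec, mass, offset, landings, t_f, fz0, fx0, fy0, v_imp, flight_s)

  noisy <- function(v, sd, stream, axis) {
    if (sd == 0) return(v)
    v + with_seed(child_seed(spec$seed, subject, cond_id, stream + axis),
                  stats::rnorm(length(v), 0, sd))
  }
  force <- triaxial_signal(noisy(fx0, spec$noise_sd_force, 10L, 0L),
                           noisy(fy0, spec$noise_sd_force, 10L, 1L),
                           noisy(fz0, spec$noise_sd_force, 10L, 2L),
                           fs = spec$fs_force, units = "N", t0 = 0)
  accel <- lapply(seq_along(PLACEMENTS), function(i) {
    a <- accel0[[i]]
    triaxial_signal(noisy(a$x, spec$noise_sd_accel, 20L + 10L * i, 0L),
                    noisy(a$y, spec$noise_sd_accel, 20L + 10L * i, 1L),
                    noisy(a$z, spec$noise_sd_accel, 20L + 10L * i, 2L),
                    fs = spec$fs_accel, units = "g", t0 = 0)
  })
  names(accel) <- PLACEMENTS
  list(force = force, accel = accel, truth = truth)
}

# measure per-jump truth on the noiseless sampled waveforms
trial_truth <- function(spec, mass, offset, landings, t_f, fz0, fx0, fy0,
                        v_imp, flight_s) {
  res_f <- sqrt(fx0^2 + fy0^2 + fz0^2)
  fs_f <- spec$fs_force
  force_rows <- lapply(seq_along(landings), function(j) {
    tl <- landings[j]
    i0 <- which.min(abs(t_f - tl))
    i1 <- min(length(res_f), i0 + as.integer(0.35 * fs_f))
    ipk <- i0 - 1L + which.max(res_f[i0:i1])
    seg <- scalar_signal(res_f, fs = fs_f, units = "N")
    rate <- peak_rate(seg, onset = max(1L, i0 - 1L), peak_index = ipk)
    data.frame(jump = j, t_land = tl, t_peak = (ipk - 1) / fs_f,
               pGRF_N = res_f[ipk], pLR_Ns = rate)
  })
  fs_a <- spec$fs_accel
  t_a <- seq(0, max(t_f), by = 1 / fs_a)
  accel_rows <- lapply(PLACEMENTS, function(pl) {
    az <- accel_waveform(t_a, pl, v_imp, landings, flight_s)  # undelayed truth
    ax <- 0.05 * (az - support_mask(t_a, landings, flight_s))
    ay <- -0.04 * (az - support_mask(t_a, landings, flight_s))
    res_a <- sqrt(ax^2 + ay^2 + az^2)
    do.call(rbind, lapply(seq_along(landings), function(j) {
      tl <- landings[j]
      i0 <- which.min(abs(t_a - tl))
      i1 <- min(length(res_a), i0 + as.integer(0.35 * fs_a))
      ipk <- i0 - 1L + which.max(res_a[i0:i1])
      seg <- scalar_signal(res_a, fs = fs_a, units = "g")
      rate <- peak_rate(seg, onset = max(1L, i0 - 1L), peak_index = ipk)
      data.frame(placement = pl, jump = j, t_peak = (ipk - 1) / fs_a,
                 pACC_g = res_a[ipk], pAR_gs = rate)
    }))
  })
  list(body_mass_kg = mass, clock_offset_s = offset,
       force = do.call(rbind, force_rows),
       accel = do.call(rbind, accel_rows))
}

#' Simulate a study-scale summary table with known mixed-model truth
#'
#' Generates one summary row per subject and jump condition with
#' `outcome = b0 + b1 p + b2 m + b3 p m + u_subject + v_condition + e`,
#' where `u`, `v` and `e` are Gaussian with the stated SDs. The predictor
#' `p` is drawn from placement- and jump-dependent ranges (ankle values
#' exceed hip and lower-back values). All latent draws are recorded in the
#' returned ground truth.
#'
#' @param spec A [protocol_spec()] (supplies subjects, jump set, masses, seed).
#' @param b Length-4 numeric: true intercept, predictor, mass and
#'   interaction coefficients.
#' @param sd_subject,sd_group,sd_residual Random-intercept and residual SDs
#'   (non-negative).
#' @param outcome,predictor Summary columns to fill (`"pGRF_N"`/`"pACC_g"`
#'   by default; use `"pLR_Ns"`/`"pAR_gs"` for loading-rate models).
#' @param placement,vector Labels stamped on the rows (one placement per
#'   table; default `"hip"`, `"resultant"`).
#' @return A list: `summary` (data.frame in the canonical column order) and
#'   `truth` (`b`, latent `u`, `v`, `e`, linear predictor per row).
#' @export
simulate_summary_table <- function(spec, b = c(-500, 190, 18, 1.3),
                                   sd_subject = 40, sd_group = 60, sd_residual = 30,
                                   outcome = "pGRF_N", predictor = "pACC_g",
                                   placement = "hip", vector = "resultant") {
  stopifnot(inherits(spec, "protocol_spec"), length(b) == 4)
  if (sd_subject < 0 || sd_group < 0 || sd_residual < 0) {
    stop("spec error: SDs must be non-negative", call. = FALSE)
  }
  if (spec$subjects < 2) stop("at least 2 subjects are required", call. = FALSE)
  conds <- spec$jump_set
  n_c <- nrow(conds)
  masses <- vapply(seq_len(spec$subjects), function(s) subject_mass(spec, s), numeric(1))
  u <- with_seed(child_seed(spec$seed, 0L, 0L, 3L),
                 stats::rnorm(spec$subjects, 0, sd_subject))
  v <- with_seed(child_seed(spec$seed, 0L, 0L, 4L),
                 stats::rnorm(n_c, 0, sd_group))
  gain <- ACC_GAIN[[placement]]
  rows <- vector("list", spec$subjects * n_c)
  e_all <- numeric(spec$subjects * n_c)
  lp_all <- numeric(spec$subjects * n_c)
  k <- 0L
  for (s in seq_len(spec$subjects)) {
    for (ci in seq_len(n_c)) {
      k <- k + 1L
      v_imp <- sqrt(2 * GRAVITY * conds$height_cm[ci] / 100)
      draws <- with_seed(child_seed(spec$seed, s, ci, 5L), stats::runif(2, 0.8, 1.2))
      pacc <- (1 + gain * v_imp) * draws[1]
      par_ <- 40 * pacc * draws[2]
      p <- if (predictor == "pACC_g") pacc else par_
      lp <- b[1] + b[2] * p + b[3] * masses[s] + b[4] * p * masses[s]
      e <- with_seed(child_seed(spec$seed, s, ci, 6L), stats::rnorm(1, 0, sd_residual))
      y <- lp + u[s] + v[ci] + e
      row <- data.frame(subject_id = sprintf("S%03d", s),
                        body_mass_kg = masses[s],
                        jump_type = conds$jump_type[ci],
                        height_cm = conds$height_cm[ci],
                        placement = placement, vector = vector,
                        pACC_g = pacc, pAR_gs = par_,
                        pGRF_N = NA_real_, pLR_Ns = NA_real_,
                        stringsAsFactors = FALSE)
      row[[outcome]] <- y
      # fill the companion loading column with a deterministic placeholder so
      # the table satisfies the summary contract (non-negative, complete)
      other <- setdiff(c("pGRF_N", "pLR_Ns"), outcome)
      row[[other]] <- if (other == "pLR_Ns") abs(y) * 55 else abs(y) / 55
      rows[[k]] <- row
      e_all[k] <- e
      lp_all[k] <- lp
    }
  }
  summary <- do.call(rbind, rows)
  list(summary = summary,
       truth = list(b = b, u = u, v = v, e = e_all, linear_predictor = lp_all,
                    sd_subject = sd_subject, sd_group = sd_group,
                    sd_residual = sd_residual,
                    subject_of_row = rep(seq_len(spec$subjects), each = n_c),
                    condition_of_row = rep(seq_len(n_c), times = spec$subjects)))
}

FIXTURE_BUNDLE_VERSION <- "1.0"

#' Write a self-describing fixture bundle
#'
#' Simulates every subject-by-condition trial of the spec and writes: one
#' force CSV per trial, one accelerometer CSV per placement per trial, a
#' ground-truth JSON, the spec itself (YAML) and a versioned manifest.
#'
#' @param spec A [protocol_spec()].
#' @param outdir Output directory (created if needed).
#' @param dialects Accelerometer dialect(s) to write: any of
#'   `"generic"`, `"actigraph_raw"` (default generic only).
#' @return The manifest, invisibly.
#' @export
write_fixture_bundle <- function(spec, outdir, dialects = "generic") {
  stopifnot(inherits(spec, "protocol_spec"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  truths <- list()
  for (s in seq_len(spec$subjects)) {
    for (ci in seq_len(nrow(spec$jump_set))) {
      jt <- spec$jump_set$jump_type[ci]
      h <- spec$jump_set$height_cm[ci]
      trial <- simulate_trial(spec, s, jt, h)
      stem <- sprintf("S%03d_%s_%02dcm", s, jt, h)
      fpath <- file.path(outdir, paste0(stem, "_force.csv"))
      write_force_csv(trial$force, fpath)
      files <- c(files, basename(fpath))
      for (pl in PLACEMENTS) {
        for (dl in dialects) {
          suffix <- if (dl == "generic") "" else "_actigraph"
          apath <- file.path(outdir, paste0(stem, "_accel_", pl, suffix, ".csv"))
          write_accel_csv(trial$accel[[pl]], apath, dialect = dl)
          files <- c(files, basename(apath))
        }
      }
      truths[[stem]] <- trial$truth
    }
  }
  truth_path <- file.path(outdir, "ground_truth.json")
  jsonlite::write_json(truths, truth_path, auto_unbox = TRUE, digits = NA)
  spec_path <- file.path(outdir, "protocol_spec.yml")
  yaml::write_yaml(list(subjects = spec$subjects,
                        body_mass_mean = spec$body_mass_mean,
                        body_mass_sd = spec$body_mass_sd,
                        body_mass_range = spec$body_mass_range,
                        jump_set = spec$jump_set,
                        fs_force = spec$fs_force, fs_accel = spec$fs_accel,
                        noise_sd_force = spec$noise_sd_force,
                        noise_sd_accel = spec$noise_sd_accel,
                        clock_offset_range = spec$clock_offset_range,
                        seed = spec$seed),
                   spec_path)
  manifest <- list(bundle_version = FIXTURE_BUNDLE_VERSION,
                   seed = spec$seed,
                   files = c(files, basename(truth_path), basename(spec_path)))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Read a protocol spec back from a fixture bundle
#'
#' @param path Path to `protocol_spec.yml`.
#' @return A [protocol_spec()].
#' @export
read_protocol_spec <- function(path) {
  cfg <- yaml::read_yaml(path)
  protocol_spec(subjects = cfg$subjects,
                body_mass_mean = cfg$body_mass_mean,
                body_mass_sd = cfg$body_mass_sd,
                body_mass_range = unlist(cfg$body_mass_range),
                jump_set = as.data.frame(cfg$jump_set),
                fs_force = cfg$fs_force, fs_accel = cfg$fs_accel,
                noise_sd_force = cfg$noise_sd_force,
                noise_sd_accel = cfg$noise_sd_accel,
                clock_offset_range = unlist(cfg$clock_offset_range),
                seed = cfg$seed)
}
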