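#' Default pipeline configuration
#'
#' All tunable processing parameters with their default values: resampling
#' target 100 Hz (the accelerometer rate), 4th-order 20 Hz zero-phase
#' Butterworth low-pass applied to the axis components before the resultant,
#' a +/-5 s cross-correlation search window with no manual offset, the
#' mean-plus-3-SD peak threshold with 0.2 s (continuous) / 4 s (drop, box)
#' minimum separation and force-matching windows, the contact-onset
#' thresholds, and `"z"` as the sensor axis aligned with the body's
#' longitudinal axis for vertical-vector analyses.
#'
#' @return A nested list of configuration values.
#' @export
default_config <- function() {
  list(
    resample = list(target_fs = 100),
    filter = list(cutoff_hz = 20, order = 4, stage = "components"),
    sync = list(max_lag_s = 5, manual_offset_s = 0),
    peaks = list(sd_multiplier = 3,
                 min_separation_s = list(drop = 4, box = 4, continuous = 0.2)),
    match = list(window_s = list(drop = 4, box = 4, continuous = 0.2)),
    onset = list(force_floor_n = 20, force_frac = 0.02, acc_band_g = 0.2),
    vertical_axis = "z"
  )
}

#' Build a run configuration
#'
#' Merges user overrides into [default_config()]; unknown keys at any level
#' are rejected.
#'
#' @param ... Named overrides, e.g. `sync = list(max_lag_s = 2)`.
#' @return The merged configuration list.
#' @export
run_config <- function(...) {
  overrides <- list(...)
  merge_config(default_config(), overrides, path = "")
}

merge_config <- function(base, overrides, path) {
  if (length(overrides) == 0) return(base)
  nm <- names(overrides)
  if (is.null(nm) || any(!nzchar(nm))) {
    stop(sprintf("config error: unnamed entry under '%s'", path), call. = FALSE)
  }
  unknown <- setdiff(nm, names(base))
  if (length(unknown) > 0) {
    stop(sprintf("config error: unknown key%s '%s' under '%s'",
                 if (length(unknown) > 1) "s" else "",
                 paste(unknown, collapse = "', '"),
                 if (nzchar(path)) path else "top level"), call. = FALSE)
  }
  for (k in nm) {
    if (is.list(base[[k]]) && is.list(overrides[[k]])) {
      base[[k]] <- merge_config(base[[k]], overrides[[k]], paste0(path, k, "."))
    } else {
      base[[k]] <- overrides[[k]]
    }
  }
  base
}

#' Process one raw trial end to end
#'
#' Runs the full processing chain on one paired force/acceleration recording:
#' resample the force signal to the accelerometer rate, low-pass filter,
#' reduce to the resultant (or rectified vertical axis), synchronize by
#' clock plus maximum cross-correlation, detect acceleration peaks, match
#' the force peak within the jump-type window, locate contact onsets,
#' compute peak rates, and average the per-event values into one summary
#' row.
#'
#' @param force A [triaxial_signal()] in newtons (raw force-plate rate).
#' @param accel A [triaxial_signal()] in g.
#' @param meta List with `subject_id`, `body_mass_kg`, `jump_type`,
#'   `height_cm`, `placement`.
#' @param vector `"resultant"` or `"vertical"`.
#' @param config A configuration from [run_config()].
#' @return A list: `summary` (one-row data.frame), `events` (per-event
#'   table), `sync` (the [synchronize()] result) and `qc` (peak count, lag,
#'   peak cross-correlation, dropped events).
#' @export
process_trial <- function(force, accel, meta, vector = "resultant",
                          config = default_config()) {
  stopifnot(inherits(force, "triaxial_signal"), inherits(accel, "triaxial_signal"))
  if (!vector %in% VECTORS) stop("vector must be 'resultant' or 'vertical'", call. = FALSE)
  jt <- meta$jump_type
  if (!jt %in% JUMP_TYPES) stop(sprintf("unknown jump type '%s'", jt), call. = FALSE)

  force_rs <- resample_to(force, config$resample$target_fs)
  accel_rs <- resample_to(accel, config$resample$target_fs)
  to_scalar <- function(sig) {
    if (vector == "resultant") resultant(sig)
    else signal_axis(sig, config$vertical_axis, rectify = TRUE)
  }
  if (config$filter$stage == "components") {
    force_s <- to_scalar(lowpass_butterworth(force_rs, config$filter$cutoff_hz,
                                             config$filter$order))
    accel_s <- to_scalar(lowpass_butterworth(accel_rs, config$filter$cutoff_hz,
                                             config$filter$order))
  } else {
    force_s <- lowpass_butterworth(to_scalar(force_rs), config$filter$cutoff_hz,
                                   config$filter$order)
    accel_s <- lowpass_butterworth(to_scalar(accel_rs), config$filter$cutoff_hz,
                                   config$filter$order)
  }

  # lag is the accelerometer stream's delay relative to the force plate
  sync <- synchronize(force_s, accel_s, max_lag_s = config$sync$max_lag_s,
                      manual_offset_s = config$sync$manual_offset_s)
  ov_pair <- pair_overlap(force_s, apply_lag(accel_s, sync$lag_samples))
  ov <- list(a = ov_pair$b, b = ov_pair$a)  # a = acceleration, b = force

  min_sep <- config$peaks$min_separation_s[[jt]]
  window_s <- config$match$window_s[[jt]]
  peaks <- detect_peaks(ov$a, min_separation_s = min_sep,
                        sd_multiplier = config$peaks$sd_multiplier)
  events <- list()
  dropped <- 0L
  for (i in seq_len(nrow(peaks))) {
    ev <- tryCatch({
      acc_peak <- peaks[i, ]
      f_peak <- match_force_peak(ov$b, acc_peak, window_s)
      on_a <- find_contact_onset(ov$a, acc_peak$index, "acceleration",
                                 acc_band_g = config$onset$acc_band_g)
      on_f <- find_contact_onset(ov$b, f_peak$index, "force",
                                 force_floor_n = config$onset$force_floor_n,
                                 force_frac = config$onset$force_frac)
      data.frame(acc_index = acc_peak$index, acc_time_s = acc_peak$time_s,
                 pACC_g = acc_peak$magnitude,
                 pAR_gs = peak_rate(ov$a, on_a, acc_peak$index),
                 force_index = f_peak$index, force_time_s = f_peak$time_s,
                 pGRF_N = f_peak$magnitude,
                 pLR_Ns = peak_rate(ov$b, on_f, f_peak$index))
    }, error = function(e) NULL)
    if (is.null(ev)) dropped <- dropped + 1L else events[[length(events) + 1L]] <- ev
  }
  events <- if (length(events)) do.call(rbind, events) else
    data.frame(acc_index = integer(0), acc_time_s = numeric(0), pACC_g = numeric(0),
               pAR_gs = numeric(0), force_index = integer(0), force_time_s = numeric(0),
               pGRF_N = numeric(0), pLR_Ns = numeric(0))
  meta$vector <- vector
  summary <- if (nrow(events) > 0) summarize_trial(events, meta) else NULL
  list(summary = summary, events = events, sync = sync,
       qc = list(n_peaks = nrow(peaks), n_events = nrow(events), dropped = dropped,
                 lag_samples = sync$lag_samples, peak_xcorr = sync$peak_xcorr))
}

#' Process a fixture bundle directory into a summary table
#'
#' Reads every trial of a bundle written by [write_fixture_bundle()], runs
#' [process_trial()] for each placement, and writes (optionally) the summary
#' CSV, a per-trial QC log and a machine-readable provenance record (config
#' hash, package version, input hashes).
#'
#' @param bundle_dir Bundle directory.
#' @param vector `"resultant"` or `"vertical"`.
#' @param config A configuration from [run_config()].
#' @param out_csv Optional path for the summary CSV.
#' @return A list: `summary` (data.frame), `qc` (data.frame), `provenance`.
#' @export
process_bundle <- function(bundle_dir, vector = "resultant",
                           config = default_config(), out_csv = NULL) {
  manifest_path <- file.path(bundle_dir, "manifest.json")
  if (!file.exists(manifest_path)) {
    stop(sprintf("no-input error: '%s' is not a fixture bundle (missing manifest.json)",
                 bundle_dir), call. = FALSE)
  }
  manifest <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  truth <- jsonlite::read_json(file.path(bundle_dir, "ground_truth.json"),
                               simplifyVector = TRUE)
  force_files <- grep("_force\\.csv$", manifest$files, value = TRUE)
  if (length(force_files) == 0) stop("no-input error: bundle contains no force files",
                                     call. = FALSE)
  rows <- list()
  qc <- list()
  for (ff in force_files) {
    stem <- sub("_force\\.csv$", "", ff)
    m <- regmatches(stem, regexec("^(S\\d+)_([a-z]+)_(\\d+)cm$", stem))[[1]]
    meta0 <- list(subject_id = m[2], jump_type = m[3],
                  height_cm = as.numeric(m[4]),
                  body_mass_kg = truth[[stem]]$body_mass_kg)
    force <- read_force_csv(file.path(bundle_dir, ff))
    for (pl in PLACEMENTS) {
      apath <- file.path(bundle_dir, sprintf("%s_accel_%s.csv", stem, pl))
      if (!file.exists(apath)) next
      accel <- read_accel_csv(apath, dialect = "generic")
      meta <- c(meta0, list(placement = pl))
      res <- process_trial(force, accel, meta, vector = vector, config = config)
      if (!is.null(res$summary)) rows[[length(rows) + 1L]] <- res$summary
      qc[[length(qc) + 1L]] <- data.frame(trial = stem, placement = pl,
                                          n_peaks = res$qc$n_peaks,
                                          n_events = res$qc$n_events,
                                          dropped = res$qc$dropped,
                                          lag_samples = res$qc$lag_samples,
                                          peak_xcorr = res$qc$peak_xcorr)
    }
  }
  if (length(rows) == 0) stop("no-input error: no trials produced events", call. = FALSE)
  summary <- do.call(rbind, rows)
  qc <- do.call(rbind, qc)
  prov <- provenance_record(config,
                            file.path(bundle_dir, c(force_files)))
  if (!is.null(out_csv)) {
    write_summary_table(summary, out_csv)
    jsonlite::write_json(prov, paste0(out_csv, ".provenance.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(summary = summary, qc = qc, provenance = prov)
}

#' Machine-readable provenance record for a pipeline run
#'
#' @param config The effective configuration.
#' @param input_paths Character vector of input files to hash.
#' @return A list: `package_version`, `config`, `config_hash` (MD5 of the
#'   serialized configuration), `input_hashes`, `timestamp`.
#' @export
provenance_record <- function(config, input_paths = character(0)) {
  cfg_file <- tempfile()
  on.exit(unlink(cfg_file))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA), cfg_file)
  existing <- input_paths[file.exists(input_paths)]
  list(package_version = as.character(utils::packageVersion("jumpload")),
       config = config,
       config_hash = unname(tools::md5sum(cfg_file)),
       input_hashes = as.list(tools::md5sum(existing)),
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
}
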