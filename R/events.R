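#' Detect impact peaks in a processed signal
#'
#' Candidate peaks are local maxima strictly above a trial-relative
#' threshold: the whole-trial mean plus `sd_multiplier` standard deviations
#' (SD with the n-1 denominator). Candidates closer together than
#' `min_separation_s` are resolved greedily by descending magnitude (ties go
#' to the earlier index), so only the largest peak of a close cluster
#' survives. The minimum separation is 0.2 s for continuous jumps and 4 s
#' for drop and box jumps.
#'
#' @param sig A [scalar_signal()] (filtered resultant or rectified vertical
#'   axis).
#' @param min_separation_s Minimum separation between retained peaks, seconds.
#' @param sd_multiplier Threshold multiplier (default 3).
#' @return A data.frame with one row per peak, columns `index`, `time_s`
#'   (relative to the signal start) and `magnitude`, sorted by index. A
#'   zero-variance signal yields zero rows.
#' @export
detect_peaks <- function(sig, min_separation_s, sd_multiplier = 3) {
  stopifnot(inherits(sig, "scalar_signal"))
  if (sig$n < 3) stop("signal must have at least 3 samples", call. = FALSE)
  if (!is.finite(min_separation_s) || min_separation_s <= 0) {
    stop("min_separation_s must be positive", call. = FALSE)
  }
  v <- sig$v
  s <- stats::sd(v)
  empty <- data.frame(index = integer(0), time_s = numeric(0), magnitude = numeric(0))
  if (s == 0) return(empty)
  threshold <- mean(v) + sd_multiplier * s
  n <- sig$n
  # local maxima; plateaus contribute their first sample
  i <- 2:(n - 1)
  cand <- i[v[i] > v[i - 1] & v[i] >= v[i + 1] & v[i] > threshold]
  if (length(cand) == 0) return(empty)
  min_sep <- min_separation_s * sig$fs
  ord <- cand[order(-v[cand], cand)]
  kept <- integer(0)
  for (idx in ord) {
    if (all(abs(idx - kept) >= min_sep)) kept <- c(kept, idx)
  }
  kept <- sort(kept)
  data.frame(index = kept, time_s = (kept - 1) / sig$fs, magnitude = v[kept])
}

#' Match the force peak belonging to an acceleration peak
#'
#' Returns the largest force sample within `+/- window_s` of the acceleration
#' peak (0.2 s for continuous jumps, 4 s otherwise), with the window clipped
#' to the signal bounds. Both signals must already be synchronized and
#' trimmed to a common grid (see [pair_overlap()]), so that sample indices
#' correspond.
#'
#' @param force A [scalar_signal()] in newtons on the common grid.
#' @param acc_peak One row of the [detect_peaks()] output (or any list with
#'   an `index` element).
#' @param window_s Search half-window in seconds.
#' @return A one-row data.frame `index`, `time_s`, `magnitude`; ties resolve
#'   to the earliest sample.
#' @export
match_force_peak <- function(force, acc_peak, window_s) {
  stopifnot(inherits(force, "scalar_signal"))
  idx <- as.integer(acc_peak$index)
  w <- as.integer(round(window_s * force$fs))
  i_lo <- idx - w
  i_hi <- idx + w
  if (i_hi < 1L || i_lo > force$n) {
    stop("out-of-range error: matching window lies entirely outside the force signal",
         call. = FALSE)
  }
  i_lo <- max(1L, i_lo)
  i_hi <- min(force$n, i_hi)
  seg <- force$v[i_lo:i_hi]
  best <- i_lo + which.max(seg) - 1L   # which.max returns the earliest tie
  data.frame(index = best, time_s = (best - 1) / force$fs, magnitude = force$v[best])
}

#' Centered first derivative of a signal
#'
#' Interior samples get `f'_i = (f_{i+1} - f_{i-1}) / (t_{i+1} - t_{i-1})`;
#' the two boundary samples are dropped, so the output has `n - 2` samples
#' and its time origin moves forward by one sample. Exact for linear and
#' quadratic sequences on a uniform grid.
#'
#' @param sig A [scalar_signal()] with at least 3 samples.
#' @return A [scalar_signal()] in `units`/s.
#' @export
centered_derivative <- function(sig) {
  stopifnot(inherits(sig, "scalar_signal"))
  n <- sig$n
  if (n < 3) stop("length error: centered derivative needs at least 3 samples", call. = FALSE)
  v <- sig$v
  d <- (v[3:n] - v[1:(n - 2)]) * sig$fs / 2
  scalar_signal(d, fs = sig$fs, units = paste0(sig$units, "/s"),
                t0 = sig$t0 + 1 / sig$fs)
}

#' Locate the contact onset preceding an impact peak
#'
#' The loading-rate window runs from the beginning of foot contact to the
#' curve peak. Contact onset is operationalized as: for force signals, the
#' last pre-peak sample at which the force is below
#' `max(force_floor_n, force_frac * peak magnitude)`; for acceleration
#' signals, the last pre-peak sample within `+/- acc_band_g` of the trial
#' median (the quiet-standing band). The search is limited to `search_s`
#' seconds before the peak; if no sample qualifies the window start is
#' returned.
#'
#' @param sig A [scalar_signal()].
#' @param peak_index Sample index of the peak.
#' @param kind `"force"` or `"acceleration"`.
#' @param force_floor_n,force_frac,acc_band_g Onset thresholds (defaults
#'   20 N, 2 percent of the peak, 0.2 g).
#' @param search_s Pre-peak search window in seconds (default 1).
#' @return The onset sample index (integer, `< peak_index`).
#' @export
find_contact_onset <- function(sig, peak_index, kind = c("force", "acceleration"),
                               force_floor_n = 20, force_frac = 0.02,
                               acc_band_g = 0.2, search_s = 1) {
  stopifnot(inherits(sig, "scalar_signal"))
  kind <- match.arg(kind)
  peak_index <- as.integer(peak_index)
  if (peak_index < 1L || peak_index > sig$n) stop("peak_index out of range", call. = FALSE)
  if ((peak_index - 1) / sig$fs < 0.05) {
    stop("onset error: peak occurs too close to the signal start (< 0.05 s of pre-peak data)",
         call. = FALSE)
  }
  w_start <- max(1L, peak_index - as.integer(round(search_s * sig$fs)))
  pre <- w_start:(peak_index - 1L)
  quiet <- if (kind == "force") {
    sig$v[pre] < max(force_floor_n, force_frac * sig$v[peak_index])
  } else {
    abs(sig$v[pre] - stats::median(sig$v)) <= acc_band_g
  }
  if (!any(quiet)) return(w_start)
  pre[max(which(quiet))]
}

#' Peak rate of change over the contact-to-peak window
#'
#' Maximum of the centered derivative restricted to `[onset, peak_index]`.
#' With a force input this is the peak loading rate (pLR, N/s); with an
#' acceleration input it is the peak acceleration rate (pAR, g/s).
#'
#' @param sig A [scalar_signal()].
#' @param onset,peak_index Window bounds (sample indices, `onset < peak_index`).
#' @return The maximum rate (units/s).
#' @export
peak_rate <- function(sig, onset, peak_index) {
  onset <- as.integer(onset); peak_index <- as.integer(peak_index)
  if (onset >= peak_index) stop("onset must precede the peak", call. = FALSE)
  if (peak_index - onset + 1L < 3L) {
    stop("length error: contact-to-peak segment must span at least 3 samples", call. = FALSE)
  }
  d <- centered_derivative(sig)
  # derivative sample j corresponds to original index j + 1
  j <- (max(onset, 2L):min(peak_index, sig$n - 1L)) - 1L
  max(d$v[j])
}

#' Aggregate matched events into a per-trial summary row
#'
#' Arithmetic means of pACC, pAR, pGRF and pLR over the trial's matched
#' events, with the trial metadata copied through.
#'
#' @param events A data.frame with one row per matched event and columns
#'   `pACC_g`, `pAR_gs`, `pGRF_N`, `pLR_Ns`.
#' @param meta A list or one-row data.frame with `subject_id`,
#'   `body_mass_kg`, `jump_type`, `height_cm`, `placement`, `vector`.
#' @return A one-row data.frame in the canonical summary-column order.
#' @export
summarize_trial <- function(events, meta) {
  events <- as.data.frame(events)
  if (nrow(events) == 0) stop("empty-trial error: no matched events to summarize", call. = FALSE)
  need <- c("pACC_g", "pAR_gs", "pGRF_N", "pLR_Ns")
  missing_cols <- setdiff(need, names(events))
  if (length(missing_cols) > 0) {
    stop(sprintf("events are missing columns: %s", paste(missing_cols, collapse = ", ")),
         call. = FALSE)
  }
  meta <- as.list(meta)
  data.frame(subject_id = as.character(meta$subject_id),
             body_mass_kg = as.double(meta$body_mass_kg),
             jump_type = as.character(meta$jump_type),
             height_cm = as.double(meta$height_cm),
             placement = as.character(meta$placement),
             vector = as.character(meta$vector),
             pACC_g = mean(events$pACC_g),
             pAR_gs = mean(events$pAR_gs),
             pGRF_N = mean(events$pGRF_N),
             pLR_Ns = mean(events$pLR_Ns),
             stringsAsFactors = FALSE)
}
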