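# Interictal epileptiform discharge (IED) detection on the normalized
# squared signal (NSS): 60-80 Hz band, 1250 Hz resampling, 5 SD onset /
# 20 SD peak thresholds, 30-250 ms duration window, and a profile-entropy
# shape filter.

# Smoothed squared band-limited power series at the resample rate
# (pre-normalization).
nss_power_series <- function(x, fs_hz, ied_cfg) {
  if (length(x) / fs_hz < 0.5) {
    stop("input too short for the IED preprocessing chain (< 0.5 s)")
  }
  y <- fft_resample(x, fs_hz, ied_cfg$resample_hz)
  y <- fft_bandpass(y, ied_cfg$resample_hz, ied_cfg$band_low_hz,
                    ied_cfg$band_high_hz, ied_cfg$transition_hz)
  gauss_smooth(y^2, ied_cfg$resample_hz, ied_cfg$smooth_sigma_ms / 1000)
}

# Robust baseline: median/MAD first, then plain mean/SD over the samples
# below the onset threshold (one iteration), so events cannot inflate their
# own threshold. `mask` optionally restricts which samples count as baseline.
robust_excluding_baseline <- function(sq, onset_sd, mask = NULL) {
  v <- if (is.null(mask)) sq else sq[mask]
  if (length(v) < 10) stop("too few baseline samples")
  m0 <- stats::median(v)
  s0 <- stats::mad(v)
  if (s0 <= 0) stop("degenerate baseline: NSS scale is zero")
  keep <- v <= m0 + onset_sd * s0
  m <- mean(v[keep]); s <- stats::sd(v[keep])
  if (!is.finite(s) || s <= 0) stop("degenerate baseline: NSS scale is zero")
  list(mean = m, sd = s)
}

#' Preprocess a signal into the normalized squared signal (NSS)
#'
#' Anti-aliased resampling to `resample_hz` (default 1250 Hz), zero-phase
#' 60-80 Hz band-pass, squaring, Gaussian smoothing (sigma 5 ms), and
#' normalization to baseline-SD units: `(power - mean) / sd` with robust
#' baseline statistics computed after excluding suprathreshold samples.
#'
#' @param x numeric vector, one channel of raw signal.
#' @param fs_hz input sampling rate (must be >= `resample_hz`).
#' @param config `ied` section of [default_config()].
#' @param baseline_mask optional logical vector at the resample rate
#'   restricting which samples enter the baseline statistics.
#' @return an object of class `nss` with fields `values` (baseline-SD
#'   units), `fs_hz`, `baseline_mean`, `baseline_sd`.
#' @export
preprocess_nss <- function(x, fs_hz, config = default_config()$ied,
                           baseline_mask = NULL) {
  if (fs_hz < config$resample_hz) {
    stop("input rate ", fs_hz, " Hz is below the resample rate ",
         config$resample_hz, " Hz")
  }
  sq <- nss_power_series(x, fs_hz, config)
  base <- robust_excluding_baseline(sq, config$onset_sd, baseline_mask)
  structure(list(values = (sq - base$mean) / base$sd,
                 fs_hz = config$resample_hz,
                 baseline_mean = base$mean, baseline_sd = base$sd),
            class = "nss")
}

#' Detect IED candidates on an NSS
#'
#' Maximal intervals with NSS above `onset_sd` (5) form candidates.
#' Candidates whose peak is below `peak_sd` (20) are rejected with reason
#' `"low_peak"`; candidates whose onset-crossing duration falls outside
#' 30-250 ms are rejected with reason `"duration"`.
#'
#' @param nss an [preprocess_nss()] result.
#' @param config `ied` config section.
#' @return data.frame of candidates with `start_s`, `end_s`, `peak_time_s`,
#'   `peak_nss_sd`, `duration_ms`, `accepted`, `reason`.
#' @export
detect_ied_candidates <- function(nss, config = default_config()$ied) {
  z <- nss$values
  fs <- nss$fs_hz
  above <- z > config$onset_sd
  runs <- rle_intervals(above)
  if (nrow(runs) == 0) {
    return(empty_ied_candidates())
  }
  out <- lapply(seq_len(nrow(runs)), function(i) {
    i0 <- runs$start[i]; i1 <- runs$end[i]
    seg <- z[i0:i1]
    pk <- which.max(seg)
    dur_ms <- (i1 - i0 + 1L) / fs * 1000
    reason <- ""
    if (max(seg) < config$peak_sd) reason <- "low_peak"
    else if (dur_ms < config$min_duration_ms ||
             dur_ms > config$max_duration_ms) reason <- "duration"
    data.frame(
      start_s = (i0 - 1L) / fs, end_s = i1 / fs,
      peak_time_s = (i0 - 1L + pk - 1L) / fs,
      peak_nss_sd = max(seg), duration_ms = dur_ms,
      accepted = reason == "", reason = reason, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

empty_ied_candidates <- function() {
  data.frame(start_s = numeric(), end_s = numeric(),
             peak_time_s = numeric(), peak_nss_sd = numeric(),
             duration_ms = numeric(), accepted = logical(),
             reason = character(), stringsAsFactors = FALSE)
}

# Maximal TRUE runs of a logical vector as a start/end index table.
rle_intervals <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep])
}

#' Entropy shape filter for IED candidates
#'
#' Scores each accepted candidate's NSS time profile (floored at zero) over
#' a window twice the event duration (the event extended by half its
#' duration on each side), summed into `entropy_bins` equal time bins and
#' normalized to probabilities. A genuine discharge is concentrated relative
#' to its surround, giving low Shannon entropy; a shape transition — a step
#' or plateau whose elevation persists across the window — approaches the
#' maximum `ln(N_bins)` and is rejected with reason `"shape_entropy"` when
#' the entropy exceeds the configured threshold (default `0.9 ln(10)`).
#' Events shorter than 2 NSS samples are rejected `"degenerate"`.
#'
#' @param events candidate data.frame from [detect_ied_candidates()].
#' @param nss the `nss` object the candidates were detected on.
#' @param config `ied` config section.
#' @return the data.frame with a `shape_entropy` column and updated
#'   `accepted`/`reason`.
#' @export
entropy_shape_filter <- function(events, nss,
                                 config = default_config()$ied) {
  if (nrow(events) == 0) {
    events$shape_entropy <- numeric(0)
    return(events)
  }
  events$shape_entropy <- NA_real_
  fs <- nss$fs_hz
  n <- length(nss$values)
  for (i in seq_len(nrow(events))) {
    if (!events$accepted[i]) next
    i0 <- as.integer(round(events$start_s[i] * fs)) + 1L
    i1 <- as.integer(round(events$end_s[i] * fs))
    if (i1 - i0 + 1L < 2L) {
      events$accepted[i] <- FALSE
      events$reason[i] <- "degenerate"
      next
    }
    ext <- as.integer(round((i1 - i0 + 1L) / 2))
    j0 <- max(1L, i0 - ext); j1 <- min(n, i1 + ext)
    seg <- pmax(nss$values[j0:j1], 0)
    bins <- cut(seq_along(seg), breaks = config$entropy_bins, labels = FALSE)
    mass <- tapply(seg, bins, sum)
    mass[is.na(mass)] <- 0
    p <- mass / sum(mass)
    S <- -sum(ifelse(p > 0, p * log(p), 0))
    events$shape_entropy[i] <- S
    if (S > config$entropy_threshold) {
      events$accepted[i] <- FALSE
      events$reason[i] <- "shape_entropy"
    }
  }
  events
}

#' Detect interictal discharges in a recording
#'
#' Full chain per channel: NSS preprocessing (baseline restricted to the
#' selected sleep states), onset/peak thresholding, duration validation and
#' the entropy shape filter. No manual curation step is applied; the
#' automated criteria stand alone (recorded in the table's `curation`
#' attribute).
#'
#' @param recording an [lfp_recording()].
#' @param config full configuration from [default_config()]/[load_config()].
#' @param states_filter sleep states to analyze (default `"NREM"`).
#' @param keep_rejected keep rejected candidates (with reasons) in the
#'   output.
#' @return event table (see [validate_events()]) with kind `"ied"` and
#'   columns `peak_nss_sd`, `duration_ms`, `shape_entropy`,
#'   `rejection_stage`.
#' @export
detect_ieds <- function(recording, config = default_config(),
                        states_filter = "NREM", keep_rejected = FALSE) {
  cfg <- config$ied
  mask <- state_mask(recording, states_filter, fs_hz = cfg$resample_hz)
  if (!any(mask)) {
    warning("no samples in the selected states; returning an empty table")
    return(empty_event_table())
  }
  out <- list()
  for (ch in seq_along(recording$channels)) {
    nss <- preprocess_nss(recording$samples[, ch], recording$fs_hz, cfg,
                          baseline_mask = mask)
    cand <- detect_ied_candidates(nss, cfg)
    cand <- entropy_shape_filter(cand, nss, cfg)
    if (nrow(cand) == 0) next
    in_state <- times_in_states(cand$peak_time_s, recording$states,
                                states_filter)
    cand <- cand[in_state, , drop = FALSE]
    if (!keep_rejected) cand <- cand[cand$accepted, , drop = FALSE]
    if (nrow(cand) == 0) next
    out[[length(out) + 1L]] <- data.frame(
      channel = recording$channels[ch],
      region = recording$regions[ch],
      kind = "ied",
      start_s = cand$start_s, end_s = cand$end_s,
      peak_time_s = cand$peak_time_s,
      peak_nss_sd = cand$peak_nss_sd,
      duration_ms = cand$duration_ms,
      shape_entropy = cand$shape_entropy,
      rejection_stage = cand$reason,
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0) return(empty_event_table())
  tab <- validate_events(do.call(rbind, out))
  attr(tab, "curation") <- "automated (no manual curation step)"
  tab
}

empty_event_table <- function() {
  data.frame(channel = character(), region = character(),
             kind = character(), start_s = numeric(), end_s = numeric(),
             peak_time_s = numeric(), stringsAsFactors = FALSE)
}
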