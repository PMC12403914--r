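# Four-stage high-frequency oscillation (HFO) detector:
#   1. 80-520 Hz band-pass, Hilbert envelope, robust baseline threshold;
#   2. wavelet time-frequency map to reject sharp (broadband) transients;
#   3. morphology: power floor and "bulb"-shaped single blob on the map;
#   4. cleanup against a stricter percentile of the background envelope;
# followed by ripple / fast-ripple classification at 200 Hz.

#' Band-pass filter and amplitude envelope
#'
#' Zero-phase band-pass (half-power edges at the configured band, default
#' 80-520 Hz) followed by the analytic-signal magnitude, lightly smoothed
#' (Gaussian, 2 ms).
#'
#' @param x numeric vector, one channel.
#' @param fs_hz sampling rate; must exceed twice the upper band edge.
#' @param config `hfo` section of [default_config()].
#' @return list with `filtered` and `envelope`, both the length of `x`.
#' @export
bandpass_and_envelope <- function(x, fs_hz, config = default_config()$hfo) {
  if (fs_hz <= 2 * config$band_high_hz) {
    stop("fs_hz must exceed twice the band upper edge (",
         2 * config$band_high_hz, " Hz)")
  }
  filtered <- fft_bandpass(x, fs_hz, config$band_low_hz,
                           config$band_high_hz, config$transition_hz)
  env <- Mod(analytic_signal(filtered))
  if (config$envelope_smooth_ms > 0) {
    env <- gauss_smooth(env, fs_hz, config$envelope_smooth_ms / 1000)
  }
  list(filtered = filtered, envelope = env)
}

#' Robust baseline statistics of an envelope
#'
#' Median and scaled MAD (1.4826 x) over the given samples, per channel and
#' sleep state.
#'
#' @param envelope numeric vector.
#' @param mask optional logical vector restricting the baseline samples.
#' @return list with `center` and `scale`.
#' @export
envelope_baseline <- function(envelope, mask = NULL) {
  v <- if (is.null(mask)) envelope else envelope[mask]
  if (length(v) < 10) stop("too few baseline samples")
  center <- stats::median(v)
  scale <- stats::mad(v)
  if (scale <= 0) stop("degenerate baseline: envelope scale is zero")
  list(center = center, scale = scale)
}

#' Detect candidate epochs on the envelope
#'
#' Candidates are maximal intervals where the envelope exceeds
#' `center + k_env * scale`; their extent is widened to where the envelope
#' falls back below `center + boundary_sd * scale`. Candidates closer than
#' `merge_gap_ms` are merged, and each must last at least
#' `max(min_duration_ms, min_cycles / f_dom)` where `f_dom` is estimated
#' from zero crossings of the filtered signal inside the candidate.
#'
#' @param envelope envelope series.
#' @param fs_hz sampling rate.
#' @param baseline result of [envelope_baseline()].
#' @param config `hfo` config section.
#' @param filtered optional band-passed signal for the cycle criterion; if
#'   `NULL`, only the duration criterion applies.
#' @return data.frame of candidate intervals (`start_idx`, `end_idx`,
#'   `peak_idx`, `peak_env`, 1-based sample indices).
#' @export
detect_candidate_epochs <- function(envelope, fs_hz, baseline,
                                    config = default_config()$hfo,
                                    filtered = NULL) {
  thr_hi <- baseline$center + config$k_env * baseline$scale
  thr_lo <- baseline$center + config$boundary_sd * baseline$scale
  core <- rle_intervals(envelope > thr_hi)
  if (nrow(core) == 0) return(empty_candidates())
  below <- envelope <= thr_lo
  n <- length(envelope)
  # widen each core run to the enclosing low-threshold excursion
  start <- integer(nrow(core)); end <- integer(nrow(core))
  for (i in seq_len(nrow(core))) {
    s <- core$start[i]
    while (s > 1L && !below[s - 1L]) s <- s - 1L
    e <- core$end[i]
    while (e < n && !below[e + 1L]) e <- e + 1L
    start[i] <- s; end[i] <- e
  }
  iv <- unique(data.frame(start = start, end = end))
  # merge intervals separated by less than merge_gap_ms
  gap <- as.integer(round(config$merge_gap_ms / 1000 * fs_hz))
  merged <- list()
  cur <- iv[1, ]
  for (i in seq_len(nrow(iv))[-1]) {
    if (iv$start[i] - cur$end <= gap) {
      cur$end <- max(cur$end, iv$end[i])
    } else {
      merged[[length(merged) + 1L]] <- cur
      cur <- iv[i, ]
    }
  }
  merged[[length(merged) + 1L]] <- cur
  iv <- do.call(rbind, merged)
  # duration / cycle criteria
  keep <- logical(nrow(iv))
  for (i in seq_len(nrow(iv))) {
    dur_s <- (iv$end[i] - iv$start[i] + 1L) / fs_hz
    min_dur <- config$min_duration_ms / 1000
    if (!is.null(filtered)) {
      seg <- filtered[iv$start[i]:iv$end[i]]
      zc <- sum(diff(sign(seg)) != 0)
      f_dom <- max(config$band_low_hz, (zc / 2) / dur_s)
      min_dur <- max(min_dur, config$min_cycles / f_dom)
    }
    keep[i] <- dur_s >= min_dur
  }
  iv <- iv[keep, , drop = FALSE]
  if (nrow(iv) == 0) return(empty_candidates())
  peak_idx <- vapply(seq_len(nrow(iv)), function(i) {
    iv$start[i] - 1L + which.max(envelope[iv$start[i]:iv$end[i]])
  }, 0L)
  data.frame(start_idx = iv$start, end_idx = iv$end, peak_idx = peak_idx,
             peak_env = envelope[peak_idx])
}

empty_candidates <- function() {
  data.frame(start_idx = integer(), end_idx = integer(),
             peak_idx = integer(), peak_env = numeric())
}

# Per-frequency baseline of the time-frequency map: median Morlet power at
# each grid frequency over short probe snippets spread across the baseline
# samples. Deterministic (evenly spaced probes).
tf_baseline <- function(x, fs_hz, config, mask = NULL, n_probes = 24,
                        probe_s = 0.5) {
  freqs <- tf_freq_grid(config$tf_low_hz, config$tf_high_hz,
                        config$tf_n_freqs)
  n <- length(x)
  len <- as.integer(round(probe_s * fs_hz))
  idx_ok <- if (is.null(mask)) rep(TRUE, n) else mask
  starts <- unique(as.integer(round(seq(1, n - len, length.out = n_probes))))
  starts <- starts[starts >= 1 & starts + len - 1L <= n]
  pows <- matrix(NA_real_, nrow = length(freqs), ncol = 0)
  for (s in starts) {
    if (!all(idx_ok[c(s, s + len - 1L)])) next
    tf <- morlet_power(x[s:(s + len - 1L)], fs_hz, freqs,
                       config$tf_n_cycles)
    trim <- as.integer(round(0.1 * len))
    pows <- cbind(pows, apply(tf[, trim:(len - trim), drop = FALSE], 1,
                              stats::median))
  }
  if (ncol(pows) == 0) stop("no usable baseline probes for the TF map")
  list(freqs = freqs, power = apply(pows, 1, stats::median))
}

# Normalized TF map of a candidate snippet: power / per-frequency baseline
# median. Returns the map plus the column range covering the candidate.
candidate_tf_map <- function(x, fs_hz, start_idx, end_idx, config, base,
                             context_s = 0.25) {
  n <- length(x)
  pad <- as.integer(round(context_s * fs_hz))
  s <- max(1L, start_idx - pad)
  e <- min(n, end_idx + pad)
  tf <- morlet_power(x[s:e], fs_hz, base$freqs, config$tf_n_cycles)
  tf <- tf / base$power
  list(map = tf, freqs = base$freqs,
       cand_cols = (start_idx - s + 1L):(end_idx - s + 1L))
}

#' Reject sharp transients by time-frequency analysis
#'
#' Sharp transients (epileptiform spikes, artifacts) spread power vertically
#' across the map, including below the HFO band. For each candidate the
#' baseline-normalized Morlet power averaged over the sub-band frequencies
#' (grid frequencies below `band_low_hz`) at the candidate's in-band peak
#' time is compared with the in-band peak power; candidates whose ratio
#' exceeds `rho_max` are rejected with stage `"sharp_transient"`.
#'
#' @param x raw (unfiltered) channel signal.
#' @param fs_hz sampling rate.
#' @param candidates data.frame from [detect_candidate_epochs()].
#' @param config `hfo` config section.
#' @param base per-frequency TF baseline from the same channel/state.
#' @return `candidates` with columns `rejection_stage` (empty or
#'   `"sharp_transient"`), `peak_freq_hz`, `sharp_ratio`.
#' @export
reject_sharp_transients <- function(x, fs_hz, candidates,
                                    config = default_config()$hfo,
                                    base = NULL) {
  if (nrow(candidates) == 0) {
    candidates$rejection_stage <- character(0)
    candidates$peak_freq_hz <- numeric(0)
    candidates$sharp_ratio <- numeric(0)
    return(candidates)
  }
  if (any(candidates$end_idx > length(x)) || any(candidates$start_idx < 1)) {
    stop("candidate indices fall outside the signal")
  }
  if (is.null(base)) base <- tf_baseline(x, fs_hz, config)
  in_band <- base$freqs >= config$band_low_hz &
    base$freqs <= config$band_high_hz
  sub_band <- base$freqs < config$band_low_hz
  candidates$rejection_stage <- ""
  candidates$peak_freq_hz <- NA_real_
  candidates$sharp_ratio <- NA_real_
  for (i in seq_len(nrow(candidates))) {
    ctf <- candidate_tf_map(x, fs_hz, candidates$start_idx[i],
                            candidates$end_idx[i], config, base)
    sub <- ctf$map[in_band, ctf$cand_cols, drop = FALSE]
    pk <- arrayInd(which.max(sub), dim(sub))
    peak_power <- sub[pk]
    peak_col <- ctf$cand_cols[pk[2]]
    candidates$peak_freq_hz[i] <- base$freqs[which(in_band)[pk[1]]]
    low_power <- mean(ctf$map[sub_band, peak_col])
    ratio <- low_power / peak_power
    candidates$sharp_ratio[i] <- ratio
    if (ratio > config$rho_max) candidates$rejection_stage[i] <-
        "sharp_transient"
  }
  candidates
}

#' Morphology ("bulb" shape) filter on the time-frequency map
#'
#' A genuine oscillation appears as a compact, isolated blob on the
#' normalized map. Keep a candidate iff (a) the in-band peak power reaches
#' `power_floor` times the per-frequency baseline, and (b) the supra-half-
#' maximum region around the peak is a connected blob whose relative
#' frequency extent is at most `max_rel_bandwidth` and which is separated
#' from the low-frequency edge of the map by a trough of at least
#' `min_isolation_db`. Rejection reasons: `"low_power"`, `"non_bulb"`.
#'
#' @param tf normalized candidate map from `candidate_tf_map()` (list with
#'   `map`, `freqs`, `cand_cols`).
#' @param config `hfo` config section.
#' @return list with `keep` (logical), `reason` (`""`, `"low_power"`,
#'   `"non_bulb"`), `peak_freq_hz`.
#' @export
morphology_filter <- function(tf, config = default_config()$hfo) {
  in_band <- tf$freqs >= config$band_low_hz & tf$freqs <= config$band_high_hz
  sub <- tf$map[in_band, tf$cand_cols, drop = FALSE]
  if (all(sub <= 0)) {
    return(list(keep = FALSE, reason = "low_power", peak_freq_hz = NA_real_))
  }
  pk <- arrayInd(which.max(sub), dim(sub))
  peak_power <- sub[pk]
  peak_row <- which(in_band)[pk[1]]
  peak_col <- tf$cand_cols[pk[2]]
  peak_freq <- tf$freqs[peak_row]
  if (peak_power < config$power_floor) {
    return(list(keep = FALSE, reason = "low_power",
                peak_freq_hz = peak_freq))
  }
  # flood fill the supra-half-maximum region containing the peak
  above <- tf$map >= peak_power / 2
  blob <- flood_fill(above, peak_row, peak_col)
  rows <- which(apply(blob, 1, any))
  f_lo <- tf$freqs[min(rows)]; f_hi <- tf$freqs[max(rows)]
  if ((f_hi - f_lo) / peak_freq > config$max_rel_bandwidth) {
    return(list(keep = FALSE, reason = "non_bulb", peak_freq_hz = peak_freq))
  }
  # isolation: the frequency profile at the peak time must dip below
  # peak / 10^(iso_db/10) somewhere between the map bottom and the blob;
  # a blob touching the lowest grid row is by definition not isolated
  profile <- tf$map[, peak_col]
  iso <- peak_power / 10^(config$min_isolation_db / 10)
  if (min(rows) == 1L) {
    return(list(keep = FALSE, reason = "non_bulb", peak_freq_hz = peak_freq))
  }
  below_rows <- seq_len(min(rows) - 1L)
  if (min(profile[below_rows]) > iso) {
    return(list(keep = FALSE, reason = "non_bulb", peak_freq_hz = peak_freq))
  }
  list(keep = TRUE, reason = "", peak_freq_hz = peak_freq)
}

# 4-connected flood fill from (row, col) over a logical matrix.
flood_fill <- function(mask, row, col) {
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  if (!mask[row, col]) return(out)
  stack <- list(c(row, col))
  out[row, col] <- TRUE
  while (length(stack) > 0) {
    p <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      q <- p + d
      if (q[1] >= 1 && q[1] <= nrow(mask) && q[2] >= 1 &&
          q[2] <= ncol(mask) && mask[q[1], q[2]] && !out[q[1], q[2]]) {
        out[q[1], q[2]] <- TRUE
        stack[[length(stack) + 1L]] <- q
      }
    }
  }
  out
}

#' Background cleanup of accepted events
#'
#' Removes events whose peak envelope does not reach a stricter percentile
#' (default 99.9th) of the state-specific background envelope distribution;
#' such events are annotated with stage `"background"`.
#'
#' @param events data.frame with a `peak_env` column.
#' @param envelope envelope series the events came from.
#' @param config `hfo` config section.
#' @param mask optional logical baseline mask.
#' @return `events` with updated `rejection_stage`.
#' @export
clean_background <- function(events, envelope,
                             config = default_config()$hfo, mask = NULL) {
  if (nrow(events) == 0) return(events)
  v <- if (is.null(mask)) envelope else envelope[mask]
  q <- stats::quantile(v, config$background_percentile, names = FALSE)
  drop <- events$peak_env < q
  events$rejection_stage[drop & events$rejection_stage == ""] <- "background"
  events
}

#' Classify an HFO by peak frequency
#'
#' `"ripple"` below `boundary_hz` (200 Hz), `"fast_ripple"` at or above it
#' (the boundary itself is assigned upward).
#'
#' @param peak_freq_hz event peak frequency.
#' @param config `hfo` config section.
#' @return `"ripple"` or `"fast_ripple"`.
#' @export
classify_hfo <- function(peak_freq_hz, config = default_config()$hfo) {
  if (any(peak_freq_hz < config$band_low_hz |
          peak_freq_hz > config$band_high_hz)) {
    stop("peak frequency outside the detection band [",
         config$band_low_hz, ", ", config$band_high_hz, "] Hz")
  }
  ifelse(peak_freq_hz < config$boundary_hz, "ripple", "fast_ripple")
}

#' Detect high-frequency oscillations in a recording
#'
#' Runs the full four-stage pipeline per channel within the selected sleep
#' states and classifies accepted events as ripple / fast ripple.
#'
#' @param recording an [lfp_recording()].
#' @param config full configuration list ([default_config()] layout).
#' @param states_filter sleep states to analyze (subset of NREM/REM).
#' @param keep_rejected also return rejected candidates with their
#'   `rejection_stage`.
#' @return event table with kind `"hfo"`, `peak_freq_hz`, `peak_env_sd`,
#'   `class` and `rejection_stage` columns.
#' @export
detect_hfos <- function(recording, config = default_config(),
                        states_filter = "NREM", keep_rejected = FALSE) {
  cfg <- config$hfo
  mask <- state_mask(recording, states_filter)
  if (!any(mask)) {
    warning("no samples in the selected states; returning an empty table")
    return(empty_event_table())
  }
  fs <- recording$fs_hz
  out <- list()
  for (ch in seq_along(recording$channels)) {
    x <- recording$samples[, ch]
    fe <- bandpass_and_envelope(x, fs, cfg)
    baseline <- envelope_baseline(fe$envelope, mask)
    cand <- detect_candidate_epochs(fe$envelope, fs, baseline, cfg,
                                    filtered = fe$filtered)
    if (nrow(cand) == 0) next
    in_state <- times_in_states((cand$peak_idx - 1L) / fs,
                                recording$states, states_filter)
    cand <- cand[in_state, , drop = FALSE]
    if (nrow(cand) == 0) next
    base <- tf_baseline(x, fs, cfg, mask)
    cand <- reject_sharp_transients(x, fs, cand, cfg, base)
    cand$class <- NA_character_
    for (i in seq_len(nrow(cand))) {
      if (cand$rejection_stage[i] != "") next
      ctf <- candidate_tf_map(x, fs, cand$start_idx[i], cand$end_idx[i],
                              cfg, base)
      m <- morphology_filter(ctf, cfg)
      if (!m$keep) {
        cand$rejection_stage[i] <- m$reason
      } else {
        cand$peak_freq_hz[i] <- m$peak_freq_hz
      }
    }
    cand <- clean_background(cand, fe$envelope, cfg, mask)
    ok <- cand$rejection_stage == ""
    cand$class[ok] <- classify_hfo(
      pmin(pmax(cand$peak_freq_hz[ok], cfg$band_low_hz), cfg$band_high_hz),
      cfg)
    if (!keep_rejected) cand <- cand[ok, , drop = FALSE]
    if (nrow(cand) == 0) next
    out[[length(out) + 1L]] <- data.frame(
      channel = recording$channels[ch],
      region = recording$regions[ch],
      kind = "hfo",
      start_s = (cand$start_idx - 1L) / fs,
      end_s = cand$end_idx / fs,
      peak_time_s = (cand$peak_idx - 1L) / fs,
      peak_freq_hz = cand$peak_freq_hz,
      peak_env_sd = (cand$peak_env - baseline$center) / baseline$scale,
      class = cand$class,
      rejection_stage = cand$rejection_stage,
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0) return(empty_event_table())
  validate_events(do.call(rbind, out))
}
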