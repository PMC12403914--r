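# Synthetic LFP sessions with known ground truth: 1/f background, Gabor
# oscillation bursts (ripple / fast-ripple band), epileptiform spike
# transients, NREM/REM scheduling, tunable IED->HFO coupling, and behavioral
# scores linearly tied to coupling strength.

#' Simulation configuration
#'
#' Defines one synthetic recording session. Defaults describe the study
#' conditions the rest of the pipeline is tested under: a 30-minute
#' wide-band recording sampled at 3000 Hz, pink (1/f) background, IEDs and
#' uncoupled HFOs at 2 events/min inside NREM, HFO bursts at 6x the
#' band-filtered background SD, IED transients targeting a 30-SD peak on
#' the detector's normalized squared signal, and a repeating
#' 25 min NREM / 5 min REM state schedule.
#'
#' @param duration_s session length in seconds.
#' @param fs_hz sampling rate, samples/second.
#' @param n_channels number of channels.
#' @param regions region tag per channel (recycled).
#' @param background_exponent spectral slope alpha of the 1/f^alpha background.
#' @param background_sd background standard deviation, signal units (uV).
#' @param ied_rate_per_min IED Poisson rate inside the event states.
#' @param hfo_rate_per_min baseline (uncoupled) HFO Poisson rate.
#' @param ripple_fraction probability an HFO atom is a ripple (else fast ripple).
#' @param coupling_prob probability in [0,1] that an IED triggers an HFO.
#' @param coupling_lag_ms mean lag of a triggered HFO after its IED.
#' @param coupling_jitter_ms SD of that lag.
#' @param hfo_snr HFO atom peak amplitude as a multiple of the 80-520 Hz
#'   band-filtered background SD.
#' @param hfo_n_cycles cycles per HFO atom (Hann envelope).
#' @param ied_peak_nss_sd target IED peak on the normalized squared signal,
#'   in baseline-SD units.
#' @param ied_width_range_ms range the IED fast-activity width is drawn from.
#' @param state_schedule data.frame (`label`,`start_s`,`end_s`) or `NULL` for
#'   the default repeating 25 min NREM / 5 min REM plan.
#' @param event_states states events are placed in (default `"NREM"`).
#' @param behavior_slope,behavior_intercept,behavior_noise_sd linear link
#'   from coupling strength to task completion time (seconds).
#' @param seed integer RNG seed.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(duration_s = 1800, fs_hz = 3000,
                              n_channels = 1, regions = "hippocampus",
                              background_exponent = 1, background_sd = 50,
                              ied_rate_per_min = 2, hfo_rate_per_min = 2,
                              ripple_fraction = 0.7, coupling_prob = 0.5,
                              coupling_lag_ms = 50, coupling_jitter_ms = 20,
                              hfo_snr = 6, hfo_n_cycles = 6,
                              ied_peak_nss_sd = 30,
                              ied_width_range_ms = c(40, 180),
                              state_schedule = NULL,
                              event_states = "NREM",
                              behavior_slope = 600,
                              behavior_intercept = 300,
                              behavior_noise_sd = 60,
                              seed = 1) {
  if (duration_s <= 0) stop("duration_s must be positive")
  if (fs_hz <= 2 * 500) stop("fs_hz must exceed twice the highest injected ",
                             "frequency (500 Hz)")
  if (ied_rate_per_min < 0 || hfo_rate_per_min < 0) {
    stop("rates must be non-negative")
  }
  if (coupling_prob < 0 || coupling_prob > 1) {
    stop("coupling_prob must lie in [0, 1]")
  }
  if (ripple_fraction < 0 || ripple_fraction > 1) {
    stop("ripple_fraction must lie in [0, 1]")
  }
  if (behavior_noise_sd < 0) stop("behavior_noise_sd must be non-negative")
  if (is.null(state_schedule)) {
    state_schedule <- default_state_schedule(duration_s)
  }
  state_schedule <- normalize_states(state_schedule)
  regions <- rep_len(regions, n_channels)
  structure(list(
    duration_s = duration_s, fs_hz = fs_hz, n_channels = n_channels,
    regions = regions, background_exponent = background_exponent,
    background_sd = background_sd, ied_rate_per_min = ied_rate_per_min,
    hfo_rate_per_min = hfo_rate_per_min, ripple_fraction = ripple_fraction,
    coupling_prob = coupling_prob, coupling_lag_ms = coupling_lag_ms,
    coupling_jitter_ms = coupling_jitter_ms, hfo_snr = hfo_snr,
    hfo_n_cycles = hfo_n_cycles, ied_peak_nss_sd = ied_peak_nss_sd,
    ied_width_range_ms = ied_width_range_ms,
    state_schedule = state_schedule, event_states = event_states,
    behavior_slope = behavior_slope, behavior_intercept = behavior_intercept,
    behavior_noise_sd = behavior_noise_sd, seed = as.integer(seed)),
    class = "simulation_config")
}

#' Default sleep-state schedule
#'
#' Repeating blocks of 25 min NREM followed by 5 min REM, truncated at the
#' session end.
#'
#' @param duration_s session length in seconds.
#' @param nrem_min,rem_min block lengths in minutes.
#' @return state-interval data.frame.
#' @export
default_state_schedule <- function(duration_s, nrem_min = 25, rem_min = 5) {
  block <- (nrem_min + rem_min) * 60
  out <- list()
  t0 <- 0
  while (t0 < duration_s) {
    n_end <- min(t0 + nrem_min * 60, duration_s)
    if (n_end > t0) out[[length(out) + 1L]] <-
        data.frame(label = "NREM", start_s = t0, end_s = n_end)
    r_end <- min(t0 + block, duration_s)
    if (r_end > n_end) out[[length(out) + 1L]] <-
        data.frame(label = "REM", start_s = n_end, end_s = r_end)
    t0 <- t0 + block
  }
  do.call(rbind, out)
}

#' Generate 1/f background LFP
#'
#' Spectrally shaped Gaussian noise: white Gaussian noise is filtered in the
#' frequency domain with amplitude proportional to f^(-alpha/2) (DC removed),
#' then rescaled to `background_sd`. Channels are independent; the draw is
#' fully determined by `config$seed`.
#'
#' @param config a [simulation_config()].
#' @return an [lfp_recording()] carrying the configured state schedule.
#' @export
generate_background <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  n <- as.integer(round(config$duration_s * config$fs_hz))
  set.seed(config$seed)
  samples <- matrix(0, nrow = n, ncol = config$n_channels)
  for (ch in seq_len(config$n_channels)) {
    samples[, ch] <- one_over_f_noise(n, config$fs_hz,
                                      config$background_exponent,
                                      config$background_sd)
  }
  lfp_recording(samples, fs_hz = config$fs_hz,
                channels = paste0("ch", seq_len(config$n_channels)),
                regions = config$regions,
                states = config$state_schedule)
}

one_over_f_noise <- function(n, fs_hz, alpha, sd_target) {
  w <- stats::rnorm(n)
  f <- abs(fft_freqs(n, fs_hz))
  shape <- numeric(n)
  nz <- f > 0
  shape[nz] <- f[nz]^(-alpha / 2)
  x <- Re(stats::fft(stats::fft(w) * shape, inverse = TRUE)) / n
  x * sd_target / stats::sd(x)
}

# Hann-windowed sinusoidal (Gabor) atom, peak amplitude `amplitude`.
gabor_atom <- function(fs_hz, freq_hz, n_cycles, amplitude) {
  dur <- n_cycles / freq_hz
  n <- max(3L, as.integer(round(dur * fs_hz)))
  t <- (seq_len(n) - (n + 1) / 2) / fs_hz
  win <- 0.5 * (1 + cos(2 * pi * t / dur))
  win[abs(t) > dur / 2] <- 0
  amplitude * win * sin(2 * pi * freq_hz * t)
}

# Tukey (tapered cosine) window, taper fraction `alpha` at each end combined.
tukey_window <- function(n, alpha = 0.3) {
  if (n <= 2) return(rep(1, n))
  u <- (seq_len(n) - 1) / (n - 1)
  w <- rep(1, n)
  edge <- alpha / 2
  lo <- u < edge
  hi <- u > 1 - edge
  w[lo] <- 0.5 * (1 + cos(pi * (u[lo] / edge - 1)))
  w[hi] <- 0.5 * (1 + cos(pi * ((u[hi] - 1 + edge) / edge)))
  w
}

# Epileptiform transient: sharp biphasic difference-of-Gaussians spike
# (fixed 3 ms sigma, broadband), a Tukey-windowed fast-activity component
# (~70 Hz) of duration width_ms that carries the 60-80 Hz detection-band
# energy, and an optional trailing half-sine slow wave. `amplitude` scales
# the fast-activity peak; the spike and slow wave keep fixed relative sizes.
ied_atom <- function(fs_hz, width_ms, amplitude, slow_wave = TRUE,
                     carrier_hz = 70) {
  width_s <- width_ms / 1000
  n_fast <- max(5L, as.integer(round(width_s * fs_hz)))
  t_fast <- (seq_len(n_fast) - (n_fast + 1) / 2) / fs_hz
  fast <- tukey_window(n_fast, 0.2) * sin(2 * pi * carrier_hz * t_fast)
  s1 <- 0.003; s2 <- 0.006
  spike <- exp(-t_fast^2 / (2 * s1^2)) - 0.6 * exp(-t_fast^2 / (2 * s2^2))
  spike <- spike / max(abs(spike))
  atom <- fast + 1.5 * spike
  if (slow_wave) {
    sw_dur <- 0.2
    n_sw <- as.integer(round(sw_dur * fs_hz))
    sw <- 0.5 * sin(pi * seq_len(n_sw) / n_sw)
    atom <- c(atom, sw)
    center <- (n_fast + 1) / 2
  } else {
    center <- (n_fast + 1) / 2
  }
  list(wave = amplitude * atom, center_idx = center)
}

# Add `atom` (vector) to one channel so that atom index `center_idx` lands on
# time_s; errors if it would extend past either end.
add_atom <- function(recording, channel, time_s, atom, center_idx) {
  fs <- recording$fs_hz
  i0 <- as.integer(round(time_s * fs)) + 1L - as.integer(round(center_idx)) + 1L
  i1 <- i0 + length(atom) - 1L
  if (i0 < 1L || i1 > n_samples(recording)) {
    stop("injected atom extends past the recording bounds (",
         sprintf("samples %d..%d of %d", i0, i1, n_samples(recording)), ")")
  }
  recording$samples[i0:i1, channel] <-
    recording$samples[i0:i1, channel] + atom
  recording
}

#' Inject a high-frequency oscillation burst
#'
#' Adds a Hann-windowed sinusoidal atom centred at `time_s` and returns the
#' modified recording together with a ground-truth record; the truth class is
#' `"ripple"` below 200 Hz and `"fast_ripple"` at or above it.
#'
#' @param recording an [lfp_recording()].
#' @param channel channel index.
#' @param time_s burst centre, seconds.
#' @param freq_hz carrier frequency, 80-500 Hz.
#' @param n_cycles number of cycles.
#' @param amplitude peak amplitude, signal units.
#' @return list with `recording` and one-row `truth` data.frame.
#' @export
inject_hfo_burst <- function(recording, channel, time_s, freq_hz,
                             n_cycles = 6, amplitude = 1) {
  if (freq_hz < 80 || freq_hz > 500) {
    stop("freq_hz must lie in [80, 500]")
  }
  atom <- gabor_atom(recording$fs_hz, freq_hz, n_cycles, amplitude)
  recording <- add_atom(recording, channel, time_s, atom,
                        (length(atom) + 1) / 2)
  truth <- data.frame(
    channel = channel, time_s = time_s, kind = "hfo",
    freq_hz = freq_hz, n_cycles = n_cycles, amplitude = amplitude,
    width_ms = NA_real_, parent_ied_time_s = NA_real_,
    class = if (freq_hz < 200) "ripple" else "fast_ripple",
    stringsAsFactors = FALSE)
  list(recording = recording, truth = truth)
}

#' Inject an interictal-discharge transient
#'
#' Adds a sharp epileptiform transient (biphasic spike + fast-activity
#' component of the given width + optional slow wave). Widths outside the
#' detectable 30-250 ms range are permitted and tagged
#' `"subthreshold_duration"` in the truth record for negative controls.
#'
#' @param recording an [lfp_recording()].
#' @param channel channel index.
#' @param time_s transient centre, seconds.
#' @param amplitude fast-activity peak amplitude, signal units.
#' @param width_ms fast-activity width in milliseconds.
#' @param slow_wave append a half-sine slow wave (default TRUE).
#' @return list with `recording` and one-row `truth` data.frame.
#' @export
inject_ied_transient <- function(recording, channel, time_s, amplitude,
                                 width_ms, slow_wave = TRUE) {
  a <- ied_atom(recording$fs_hz, width_ms, amplitude, slow_wave)
  recording <- add_atom(recording, channel, time_s, a$wave, a$center_idx)
  truth <- data.frame(
    channel = channel, time_s = time_s, kind = "ied",
    freq_hz = NA_real_, n_cycles = NA_real_, amplitude = amplitude,
    width_ms = width_ms, parent_ied_time_s = NA_real_,
    class = if (width_ms >= 30 && width_ms <= 250) "detectable"
            else "subthreshold_duration",
    stringsAsFactors = FALSE)
  list(recording = recording, truth = truth)
}

# Draw uniform times within the union of the configured event-state
# intervals.
draw_times_in_states <- function(n, states, labels) {
  st <- states[states$label %in% labels, , drop = FALSE]
  lens <- st$end_s - st$start_s
  total <- sum(lens)
  if (total <= 0) stop("event-state schedule has zero total time")
  u <- stats::runif(n, 0, total)
  cum <- cumsum(c(0, lens))
  idx <- findInterval(u, cum, rightmost.closed = TRUE)
  idx[idx > nrow(st)] <- nrow(st)
  sort(st$start_s[idx] + (u - cum[idx]))
}

#' Draw the event-level ground truth of a coupled session
#'
#' Samples the point processes only (no waveform): per channel, IED times as
#' a homogeneous Poisson process at `ied_rate_per_min` inside the event
#' states; each IED independently triggers one HFO with probability
#' `coupling_prob` at lag Normal(`coupling_lag_ms`, `coupling_jitter_ms`);
#' uncoupled HFOs as an independent Poisson process. Triggered HFOs whose lag
#' would fall outside the recording are redrawn once, then dropped.
#'
#' @param config a [simulation_config()].
#' @return list with data.frames `ied` and `hfo` (times, frequencies,
#'   classes, parentage) — the `SimulationTruth` event part.
#' @export
draw_session_events <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  st <- config$state_schedule
  if ((config$ied_rate_per_min > 0 || config$hfo_rate_per_min > 0) &&
      state_time_s(st, config$event_states) <= 0) {
    stop("event-state schedule is empty but event rates are positive")
  }
  set.seed(config$seed + 1L)
  minutes <- state_time_s(st, config$event_states) / 60
  ied_list <- list(); hfo_list <- list()
  for (ch in seq_len(config$n_channels)) {
    n_ied <- stats::rpois(1, config$ied_rate_per_min * minutes)
    ied_t <- draw_times_in_states(n_ied, st, config$event_states)
    wid <- stats::runif(n_ied, config$ied_width_range_ms[1],
                        config$ied_width_range_ms[2])
    ied_list[[ch]] <- data.frame(channel = rep(ch, length(ied_t)),
                                 time_s = ied_t,
                                 width_ms = wid, stringsAsFactors = FALSE)
    # triggered HFOs
    trig <- stats::runif(n_ied) < config$coupling_prob
    trig_t <- numeric(0); trig_parent <- numeric(0); trig_lag <- numeric(0)
    for (i in which(trig)) {
      for (attempt in 1:2) {
        lag <- stats::rnorm(1, config$coupling_lag_ms,
                            config$coupling_jitter_ms) / 1000
        tt <- ied_t[i] + lag
        if (tt > 0.1 && tt < config$duration_s - 0.1) {
          trig_t <- c(trig_t, tt)
          trig_parent <- c(trig_parent, ied_t[i])
          trig_lag <- c(trig_lag, lag * 1000)
          break
        }
      }
    }
    n_unc <- stats::rpois(1, config$hfo_rate_per_min * minutes)
    unc_t <- draw_times_in_states(n_unc, st, config$event_states)
    all_t <- c(trig_t, unc_t)
    n_hfo <- length(all_t)
    is_ripple <- stats::runif(n_hfo) < config$ripple_fraction
    freq <- ifelse(is_ripple, stats::runif(n_hfo, 85, 195),
                   stats::runif(n_hfo, 205, 495))
    hfo_list[[ch]] <- data.frame(
      channel = rep(ch, n_hfo), time_s = all_t, freq_hz = freq,
      n_cycles = rep(config$hfo_n_cycles, n_hfo),
      triggered_by_ied = c(rep(TRUE, length(trig_t)),
                           rep(FALSE, length(unc_t))),
      parent_ied_time_s = c(trig_parent, rep(NA_real_, length(unc_t))),
      lag_ms = c(trig_lag, rep(NA_real_, length(unc_t))),
      class = ifelse(freq < 200, "ripple", "fast_ripple"),
      stringsAsFactors = FALSE)
  }
  list(ied = do.call(rbind, ied_list), hfo = do.call(rbind, hfo_list))
}

#' Generate a full coupled session: waveform plus ground truth
#'
#' Draws the event truth with [draw_session_events()], generates the 1/f
#' background, calibrates atom amplitudes per channel (HFO peak =
#' `hfo_snr` x the 80-520 Hz band-filtered background SD; IED amplitude set
#' so its normalized-squared-signal peak hits `ied_peak_nss_sd` baseline
#' SDs), and injects every atom.
#'
#' @param config a [simulation_config()].
#' @return list with `recording` (an [lfp_recording()]) and `truth`
#'   (list: `ied`, `hfo`, `behavior_link`, `config`).
#' @export
generate_coupled_session <- function(config) {
  truth <- draw_session_events(config)
  rec <- generate_background(config)
  cfg <- default_config()
  for (ch in seq_len(config$n_channels)) {
    bg <- rec$samples[, ch]
    band <- fft_bandpass(bg, config$fs_hz, cfg$hfo$band_low_hz,
                         cfg$hfo$band_high_hz, cfg$hfo$transition_hz)
    band_sd <- stats::sd(band)
    hfo_amp <- config$hfo_snr * band_sd
    hfo_ch <- truth$hfo[truth$hfo$channel == ch, , drop = FALSE]
    for (i in seq_len(nrow(hfo_ch))) {
      atom <- gabor_atom(config$fs_hz, hfo_ch$freq_hz[i],
                         hfo_ch$n_cycles[i], hfo_amp)
      rec <- add_atom(rec, ch, hfo_ch$time_s[i], atom,
                      (length(atom) + 1) / 2)
    }
    truth$hfo$amplitude[truth$hfo$channel == ch] <- hfo_amp
    ied_ch <- truth$ied[truth$ied$channel == ch, , drop = FALSE]
    if (nrow(ied_ch) > 0) {
      base <- nss_baseline_of(bg, config$fs_hz, cfg$ied)
      amps <- vapply(seq_len(nrow(ied_ch)), function(i) {
        calibrate_ied_amplitude(ied_ch$width_ms[i], config$fs_hz, cfg$ied,
                                base, config$ied_peak_nss_sd)
      }, 0)
      for (i in seq_len(nrow(ied_ch))) {
        a <- ied_atom(config$fs_hz, ied_ch$width_ms[i], amps[i])
        rec <- add_atom(rec, ch, ied_ch$time_s[i], a$wave, a$center_idx)
      }
      truth$ied$amplitude[truth$ied$channel == ch] <- amps
    }
  }
  truth$behavior_link <- list(slope = config$behavior_slope,
                              intercept = config$behavior_intercept,
                              noise_sd = config$behavior_noise_sd)
  truth$config <- config
  list(recording = rec, truth = truth)
}

# Baseline (mean, sd) of the smoothed squared band signal of a background
# series, as the IED preprocessing computes it.
nss_baseline_of <- function(x, fs_hz, ied_cfg) {
  sq <- nss_power_series(x, fs_hz, ied_cfg)
  robust_excluding_baseline(sq, ied_cfg$onset_sd)
}

# Amplitude giving a target NSS peak (in baseline-SD units) for one atom.
calibrate_ied_amplitude <- function(width_ms, fs_hz, ied_cfg, baseline,
                                    target_sd) {
  a <- ied_atom(fs_hz, width_ms, amplitude = 1, slow_wave = TRUE)
  pad <- numeric(as.integer(round(0.5 * fs_hz)))
  probe <- c(pad, a$wave, pad)
  resp <- nss_power_series(probe, fs_hz, ied_cfg)
  unit_peak <- max(resp)
  sqrt(target_sd * baseline$sd / unit_peak)
}

#' Generate behavioral completion times from coupling strengths
#'
#' `y_i = intercept + slope * h_i + e_i`, `e ~ Normal(0, noise_sd^2)`.
#'
#' @param coupling_values per-animal coupling strengths h.
#' @param slope,intercept linear link (seconds per unit h; seconds).
#' @param noise_sd residual SD in seconds (>= 0).
#' @param seed integer RNG seed.
#' @return numeric vector of completion times, seconds.
#' @export
generate_behavior_scores <- function(coupling_values, slope, intercept,
                                     noise_sd, seed = 1) {
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (length(coupling_values) < 3) {
    stop("at least 3 animals are required for downstream regression")
  }
  set.seed(as.integer(seed))
  intercept + slope * coupling_values +
    stats::rnorm(length(coupling_values), 0, noise_sd)
}

#' Write simulation truth to TSV
#'
#' One row per injected atom: channel, time_s, kind (hfo/ied), freq_hz,
#' n_cycles, amplitude, width_ms, parent_ied_time_s, class.
#'
#' @param truth truth list from [generate_coupled_session()] or
#'   [draw_session_events()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  hfo <- truth$hfo
  ied <- truth$ied
  rows <- rbind(
    data.frame(channel = hfo$channel, time_s = hfo$time_s, kind = "hfo",
               freq_hz = hfo$freq_hz, n_cycles = hfo$n_cycles,
               amplitude = if ("amplitude" %in% names(hfo)) hfo$amplitude
                           else NA_real_,
               width_ms = NA_real_,
               parent_ied_time_s = hfo$parent_ied_time_s,
               class = hfo$class, stringsAsFactors = FALSE),
    data.frame(channel = ied$channel, time_s = ied$time_s, kind = "ied",
               freq_hz = NA_real_, n_cycles = NA_real_,
               amplitude = if ("amplitude" %in% names(ied)) ied$amplitude
                           else NA_real_,
               width_ms = ied$width_ms, parent_ied_time_s = NA_real_,
               class = "detectable", stringsAsFactors = FALSE))
  rows <- rows[order(rows$channel, rows$time_s), ]
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
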