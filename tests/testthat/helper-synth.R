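# Shared helpers: small synthetic inputs and independent brute-force oracles.

in_states <- function(t, states, labels) {
  lfpcoupling:::times_in_states(t, states, labels)
}

tone <- function(freq_hz, duration_s, fs_hz = 3000, amplitude = 1) {
  amplitude * sin(2 * pi * freq_hz * (seq_len(duration_s * fs_hz) / fs_hz))
}

# One-channel recording of pure 1/f background with a single NREM interval.
quiet_recording <- function(duration_s = 60, fs_hz = 3000, seed = 1,
                            states = NULL) {
  cfg <- simulation_config(
    duration_s = duration_s, fs_hz = fs_hz, seed = seed,
    ied_rate_per_min = 0, hfo_rate_per_min = 0, coupling_prob = 0,
    state_schedule = if (is.null(states)) {
      data.frame(label = "NREM", start_s = 0, end_s = duration_s)
    } else states)
  generate_background(cfg)
}

# Fraction of truth times matched by a detection within tol (recall), and of
# detections matched by a truth time (precision).
match_scores <- function(detected_t, truth_t, tol = 0.05) {
  if (length(detected_t) == 0) return(c(recall = 0, precision = NA_real_))
  recall <- mean(vapply(truth_t, function(tt) any(abs(detected_t - tt) < tol),
                        TRUE))
  precision <- mean(vapply(detected_t,
                           function(tt) any(abs(truth_t - tt) < tol), TRUE))
  c(recall = recall, precision = precision)
}

# O(n^2) PETH oracle: double loop over anchors and events.
peth_bruteforce <- function(anchors, events, window_ms = 500,
                            bin_width_ms = 10) {
  n_bins <- as.integer(2 * window_ms / bin_width_ms)
  counts <- integer(n_bins)
  for (a in anchors) {
    for (e in events) {
      lag_ms <- (e - a) * 1000
      if (lag_ms >= -window_ms && lag_ms < window_ms) {
        k <- floor((lag_ms + window_ms) / bin_width_ms) + 1L
        counts[k] <- counts[k] + 1L
      }
    }
  }
  counts
}

# Sample-by-sample candidate-interval oracle for the HFO envelope stage:
# core samples above thr_hi, each core run widened to the surrounding
# excursion above thr_lo, overlapping results merged if closer than gap_n.
candidate_scan_oracle <- function(env, thr_hi, thr_lo, gap_n) {
  n <- length(env)
  core <- which(env > thr_hi)
  if (length(core) == 0) {
    return(data.frame(start = integer(), end = integer()))
  }
  iv <- list()
  for (i in core) {
    s <- i; while (s > 1 && env[s - 1] > thr_lo) s <- s - 1
    e <- i; while (e < n && env[e + 1] > thr_lo) e <- e + 1
    iv[[length(iv) + 1L]] <- c(s, e)
  }
  iv <- unique(iv)
  iv <- iv[order(vapply(iv, `[`, 0, 1))]
  merged <- list(iv[[1]])
  for (p in iv[-1]) {
    last <- merged[[length(merged)]]
    if (p[1] - last[2] <= gap_n) {
      merged[[length(merged)]] <- c(last[1], max(last[2], p[2]))
    } else {
      merged[[length(merged) + 1L]] <- p
    }
  }
  data.frame(start = vapply(merged, `[`, 0, 1),
             end = vapply(merged, `[`, 0, 2))
}

# Direct NSS threshold-scan oracle: maximal runs above onset_sd.
nss_scan_oracle <- function(z, onset_sd) {
  above <- z > onset_sd
  if (!any(above)) return(data.frame(start = integer(), end = integer()))
  d <- diff(c(FALSE, above, FALSE))
  data.frame(start = which(d == 1), end = which(d == -1) - 1L)
}
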