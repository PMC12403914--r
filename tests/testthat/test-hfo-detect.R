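# HFO detector stages: filtering/envelope, candidate epochs, sharp-transient
# rejection, morphology, background cleanup, classification, end-to-end.

hcfg <- default_config()$hfo

test_that("band-pass and envelope behave on tones and noise", {
  fs <- 3000
  x <- tone(150, 2, fs)
  fe <- bandpass_and_envelope(x, fs, hcfg)
  core <- fe$envelope[1000:5000]
  expect_lt(max(abs(core - 1)), 0.05)       # analytic envelope of a tone
  y <- bandpass_and_envelope(tone(30, 2, fs), fs, hcfg)$filtered
  expect_lt(sqrt(mean(y^2)), 0.01)          # stop band
  set.seed(8)
  w <- rnorm(fs * 4)
  filt <- bandpass_and_envelope(w, fs, hcfg)$filtered
  sp <- stats::spec.pgram(stats::ts(filt, frequency = fs), plot = FALSE)
  in_band <- sp$freq >= 70 & sp$freq <= 530
  expect_gt(sum(sp$spec[in_band]) / sum(sp$spec), 0.98)
  expect_error(bandpass_and_envelope(x, 900, hcfg), "twice the band")
})

test_that("candidate epochs match a brute-force threshold scan", {
  fs <- 3000
  for (seed in 1:4) {
    rec <- quiet_recording(8, seed = seed)
    amp <- 6 * sd(fft_bandpass(rec$samples[, 1], fs, 80, 520))
    r <- rec
    for (tt in c(2, 4, 6)) {
      r <- inject_hfo_burst(r, 1, tt, freq_hz = 140,
                            amplitude = amp)$recording
    }
    fe <- bandpass_and_envelope(r$samples[, 1], fs, hcfg)
    bl <- envelope_baseline(fe$envelope)
    cand <- detect_candidate_epochs(fe$envelope, fs, bl, hcfg,
                                    filtered = NULL)
    thr_hi <- bl$center + hcfg$k_env * bl$scale
    thr_lo <- bl$center + hcfg$boundary_sd * bl$scale
    gap_n <- round(hcfg$merge_gap_ms / 1000 * fs)
    oracle <- candidate_scan_oracle(fe$envelope, thr_hi, thr_lo, gap_n)
    min_n <- round(hcfg$min_duration_ms / 1000 * fs)
    oracle <- oracle[oracle$end - oracle$start + 1 >= min_n, ]
    expect_equal(cand$start_idx, oracle$start)
    expect_equal(cand$end_idx, oracle$end)
  }
})

test_that("flat envelopes yield no candidates and close bursts merge", {
  fs <- 3000
  bl <- list(center = 1, scale = 0.1)
  expect_equal(nrow(detect_candidate_epochs(rep(0.5, fs), fs, bl, hcfg)), 0L)
  # two bursts 5 ms apart with a 10 ms merge gap become one candidate
  env <- rep(0.5, fs)
  env[1000:1060] <- 3
  env[1076:1136] <- 3                      # 15-sample gap = 5 ms
  cand <- detect_candidate_epochs(env, fs, bl, hcfg)
  expect_equal(nrow(cand), 1L)
  expect_lte(cand$start_idx, 1000L)
  expect_gte(cand$end_idx, 1136L)
})

test_that("sharp transients are rejected while genuine bursts survive", {
  fs <- 3000
  rec <- quiet_recording(20, seed = 6)
  band_sd <- sd(fft_bandpass(rec$samples[, 1], fs, 80, 520))
  r <- inject_hfo_burst(rec, 1, 5, freq_hz = 150,
                        amplitude = 6 * band_sd)$recording
  r <- inject_ied_transient(r, 1, 12, amplitude = 25 * band_sd,
                            width_ms = 60)$recording
  x <- r$samples[, 1]
  fe <- bandpass_and_envelope(x, fs, hcfg)
  bl <- envelope_baseline(fe$envelope)
  cand <- detect_candidate_epochs(fe$envelope, fs, bl, hcfg, fe$filtered)
  t_peaks <- (cand$peak_idx - 1) / fs
  expect_true(any(abs(t_peaks - 5) < 0.05))    # burst found at stage 1
  expect_true(any(abs(t_peaks - 12) < 0.08))   # spike crosses threshold too
  base <- lfpcoupling:::tf_baseline(x, fs, hcfg)
  out <- reject_sharp_transients(x, fs, cand, hcfg, base)
  burst_rows <- abs((out$peak_idx - 1) / fs - 5) < 0.05
  spike_rows <- abs((out$peak_idx - 1) / fs - 12) < 0.08
  expect_true(all(out$rejection_stage[burst_rows] == ""))
  expect_true(all(out$rejection_stage[spike_rows] == "sharp_transient"))
  # the decision matches an independently computed brute-force TF ratio
  freqs <- lfpcoupling:::tf_freq_grid(hcfg$tf_low_hz, hcfg$tf_high_hz,
                                      hcfg$tf_n_freqs)
  for (i in which(burst_rows | spike_rows)) {
    s <- max(1, out$start_idx[i] - 750); e <- min(length(x),
                                                  out$end_idx[i] + 750)
    tfm <- lfpcoupling:::morlet_power(x[s:e], fs, freqs, hcfg$tf_n_cycles) /
      base$power
    cols <- (out$start_idx[i] - s + 1):(out$end_idx[i] - s + 1)
    ib <- freqs >= hcfg$band_low_hz & freqs <= hcfg$band_high_hz
    sub <- tfm[ib, cols, drop = FALSE]
    pk <- arrayInd(which.max(sub), dim(sub))
    ratio <- mean(tfm[freqs < hcfg$band_low_hz, cols[pk[2]]]) / sub[pk]
    expect_equal(out$sharp_ratio[i], ratio, tolerance = 1e-9)
    expect_equal(out$rejection_stage[i] == "sharp_transient",
                 ratio > hcfg$rho_max)
  }
  expect_equal(nrow(reject_sharp_transients(x, fs,
                                            lfpcoupling:::empty_candidates(),
                                            hcfg, base)), 0L)
})

test_that("morphology filter separates bulbs, stacks, and weak power", {
  freqs <- lfpcoupling:::tf_freq_grid(60, 600, 40)
  n_t <- 200
  mk <- function(fill) list(map = fill, freqs = freqs, cand_cols = 50:150)
  # single compact blob at ~150 Hz -> keep
  blob <- outer(exp(-(log(freqs) - log(150))^2 / (2 * 0.08^2)),
                exp(-(seq_len(n_t) - 100)^2 / (2 * 15^2))) * 100
  expect_true(morphology_filter(mk(blob), hcfg)$keep)
  # vertical stripe spanning the whole frequency axis -> non_bulb
  stripe <- matrix(0, 40, n_t); stripe[, 95:105] <- 100
  res <- morphology_filter(mk(stripe), hcfg)
  expect_false(res$keep); expect_equal(res$reason, "non_bulb")
  # same blob at half the power floor -> low_power
  weak <- blob / max(blob) * hcfg$power_floor / 2
  res <- morphology_filter(mk(weak), hcfg)
  expect_false(res$keep); expect_equal(res$reason, "low_power")
  # degenerate all-zero map -> low_power
  res <- morphology_filter(mk(matrix(0, 40, n_t)), hcfg)
  expect_false(res$keep); expect_equal(res$reason, "low_power")
  # blob reaching down to the map bottom without a trough -> non_bulb
  smear <- blob
  smear[freqs <= 150, ] <- pmax(smear[freqs <= 150, ],
                                matrix(rep(blob[sum(freqs <= 150), ],
                                           each = sum(freqs <= 150)),
                                       sum(freqs <= 150)))
  res <- morphology_filter(mk(smear), hcfg)
  expect_false(res$keep); expect_equal(res$reason, "non_bulb")
})

test_that("background cleanup keeps strong events and is monotone", {
  set.seed(3)
  env <- abs(rnorm(100000))
  q999 <- quantile(env, 0.999, names = FALSE)
  ev <- data.frame(peak_env = c(quantile(env, 0.9995, names = FALSE),
                                median(env)),
                   rejection_stage = c("", ""))
  out <- clean_background(ev, env, hcfg)
  expect_equal(out$rejection_stage, c("", "background"))
  # acceptance is monotone in amplitude
  amps <- seq(0.5 * q999, 2 * q999, length.out = 20)
  kept <- vapply(amps, function(a) {
    clean_background(data.frame(peak_env = a, rejection_stage = ""),
                     env, hcfg)$rejection_stage == ""
  }, TRUE)
  expect_true(all(diff(kept) >= 0))
})

test_that("classification follows the 200 Hz boundary with upward ties", {
  expect_equal(classify_hfo(150, hcfg), "ripple")
  expect_equal(classify_hfo(300, hcfg), "fast_ripple")
  expect_equal(classify_hfo(200, hcfg), "fast_ripple")
  expect_error(classify_hfo(50, hcfg), "outside the detection band")
})

test_that("end-to-end detection recovers injected bursts and honors states", {
  cfg <- simulation_config(duration_s = 300, seed = 17,
                           ied_rate_per_min = 0, hfo_rate_per_min = 4,
                           coupling_prob = 0,
                           state_schedule = data.frame(
                             label = c("NREM", "REM"),
                             start_s = c(0, 240), end_s = c(240, 300)))
  sess <- generate_coupled_session(cfg)
  ev <- detect_hfos(sess$recording)
  sc <- match_scores(ev$peak_time_s, sess$truth$hfo$time_s)
  expect_gte(sc["recall"], 0.9)
  expect_gte(sc["precision"], 0.9)
  # no event peaks inside REM when filtering to NREM
  expect_false(any(in_states(ev$peak_time_s, sess$recording$states, "REM")))
  # detector output is invariant to global signal scaling
  scaled <- sess$recording
  scaled$samples <- scaled$samples * 7
  ev2 <- detect_hfos(scaled)
  expect_equal(ev2$peak_time_s, ev$peak_time_s)
  expect_equal(ev2$class, ev$class)
  # every rejected candidate carries exactly one rejection stage
  evr <- detect_hfos(sess$recording, keep_rejected = TRUE)
  expect_true(all(evr$rejection_stage %in%
                    c("", "sharp_transient", "low_power", "non_bulb",
                      "background")))
  expect_true(all(!is.na(evr$class[evr$rejection_stage == ""])))
})

test_that("a session with zero-amplitude injections yields no events", {
  cfg <- simulation_config(duration_s = 120, seed = 23, hfo_snr = 0,
                           ied_rate_per_min = 0, hfo_rate_per_min = 3,
                           coupling_prob = 0)
  sess <- generate_coupled_session(cfg)
  expect_identical(sess$recording$samples,
                   generate_background(cfg)$samples)
  ev <- detect_hfos(sess$recording)
  hits <- sum(vapply(ev$peak_time_s, function(t)
    any(abs(sess$truth$hfo$time_s - t) < 0.05), TRUE))
  expect_equal(hits, 0L)
})
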