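# IED detector: NSS preprocessing, thresholding, entropy shape filter,
# end-to-end behavior and invariants.

icfg <- default_config()$ied

test_that("NSS has the resampled length and flattens a pure tone", {
  fs <- 3000
  x <- tone(70, 10, fs)
  nss <- preprocess_nss(x + rnorm(length(x), sd = 1e-3), fs, icfg)
  expect_equal(length(nss$values), 12500L)
  sq <- lfpcoupling:::nss_power_series(x, fs, icfg)
  core <- sq[2000:10500]
  expect_lt(sd(core) / mean(core), 0.10)
  expect_error(preprocess_nss(numeric(3000) , fs, icfg), "baseline|short")
  expect_error(preprocess_nss(rnorm(3000), 1000, icfg), "below the resample")
})

test_that("candidates match a direct threshold scan and report reasons", {
  rec <- quiet_recording(10, seed = 31)
  base <- lfpcoupling:::nss_baseline_of(rec$samples[, 1], rec$fs_hz, icfg)
  amp25 <- lfpcoupling:::calibrate_ied_amplitude(100, rec$fs_hz, icfg,
                                                 base, 25)
  r <- inject_ied_transient(rec, 1, 3, amplitude = amp25,
                            width_ms = 100)$recording
  amp10 <- lfpcoupling:::calibrate_ied_amplitude(100, rec$fs_hz, icfg,
                                                 base, 10)
  r <- inject_ied_transient(r, 1, 6, amplitude = amp10,
                            width_ms = 100)$recording
  amp300 <- lfpcoupling:::calibrate_ied_amplitude(300, rec$fs_hz, icfg,
                                                  base, 25)
  r <- inject_ied_transient(r, 1, 8.5, amplitude = amp300,
                            width_ms = 300)$recording
  nss <- preprocess_nss(r$samples[, 1], r$fs_hz, icfg)
  cand <- detect_ied_candidates(nss, icfg)
  # oracle equivalence of the candidate intervals
  oracle <- nss_scan_oracle(nss$values, icfg$onset_sd)
  expect_equal(round(cand$start_s * nss$fs_hz) + 1, oracle$start)
  expect_equal(round(cand$end_s * nss$fs_hz), oracle$end)
  near <- function(t) which(abs(cand$peak_time_s - t) < 0.2)
  expect_true(any(cand$accepted[near(3)]))
  expect_true(all(cand$reason[near(6)] == "low_peak"))
  expect_true(all(cand$reason[near(8.5)] == "duration"))
  expect_gt(min(cand$duration_ms[near(8.5)]), icfg$max_duration_ms)
  expect_true(all(cand$reason %in%
                    c("", "low_peak", "duration")))
})

test_that("entropy shape filter keeps peaked profiles, rejects plateaus", {
  # synthetic NSS: triangular single peak vs sustained plateau
  fs <- icfg$resample_hz
  z <- rep(-0.1, 5000)
  tri <- c(seq(0, 30, length.out = 63), seq(30, 0, length.out = 63))
  z[1000:1125] <- tri
  z[3000:4500] <- 25      # sustained elevation: a level-shift "transition"
  nss <- structure(list(values = z, fs_hz = fs, baseline_mean = 0,
                        baseline_sd = 1), class = "nss")
  # second event: a 30-250 ms chunk carved out of the sustained elevation
  # (how a level shift fragments at the onset threshold)
  ev <- data.frame(start_s = c(999, 3599) / fs,
                   end_s = c(1125, 3800) / fs,
                   peak_time_s = c(1062, 3700) / fs,
                   peak_nss_sd = c(30, 25), duration_ms = c(100, 160),
                   accepted = c(TRUE, TRUE), reason = c("", ""))
  out <- entropy_shape_filter(ev, nss, icfg)
  expect_true(out$accepted[1])
  expect_false(out$accepted[2])
  expect_equal(out$reason[2], "shape_entropy")
  # entropy agrees with a direct evaluation of the formula
  i0 <- 1000L; i1 <- 1125L; ext <- as.integer(round((i1 - i0 + 1) / 2))
  seg <- pmax(z[(i0 - ext):(i1 + ext)], 0)
  bins <- cut(seq_along(seg), 10, labels = FALSE)
  p <- tapply(seg, bins, sum) / sum(seg)
  expect_equal(out$shape_entropy[1],
               -sum(p[p > 0] * log(p[p > 0])), tolerance = 1e-12)
  # a flat profile filling its whole scoring window scores exactly ln(10)
  z2 <- rep(0, 3000); z2[1000:2000] <- 10
  nss2 <- structure(list(values = z2, fs_hz = fs, baseline_mean = 0,
                         baseline_sd = 1), class = "nss")
  ev2 <- data.frame(start_s = 1250 / fs, end_s = 1750 / fs,
                    peak_time_s = 1500 / fs, peak_nss_sd = 10,
                    duration_ms = 400, accepted = TRUE, reason = "")
  out2 <- entropy_shape_filter(ev2, nss2, icfg)
  expect_equal(out2$shape_entropy, log(10), tolerance = 1e-9)
  expect_false(out2$accepted)
  # empty input passes through
  expect_equal(nrow(entropy_shape_filter(
    lfpcoupling:::empty_ied_candidates(), nss, icfg)), 0L)
})

test_that("end-to-end detection recovers injected transients, masks states", {
  cfg <- simulation_config(duration_s = 300, seed = 37, hfo_rate_per_min = 0,
                           coupling_prob = 0, ied_rate_per_min = 6,
                           state_schedule = data.frame(
                             label = c("NREM", "REM"),
                             start_s = c(0, 240), end_s = c(240, 300)))
  sess <- generate_coupled_session(cfg)
  ev <- detect_ieds(sess$recording)
  sc <- match_scores(ev$peak_time_s, sess$truth$ied$time_s)
  expect_gte(sc["recall"], 0.85)
  expect_gte(sc["precision"], 0.9)
  expect_false(any(in_states(ev$peak_time_s, sess$recording$states, "REM")))
  expect_true(all(ev$peak_nss_sd >= icfg$peak_sd))
  expect_true(all(ev$duration_ms >= icfg$min_duration_ms &
                    ev$duration_ms <= icfg$max_duration_ms))
  # scale invariance: NSS is baseline-normalized
  scaled <- sess$recording
  scaled$samples <- scaled$samples * 0.2
  ev2 <- detect_ieds(scaled)
  expect_equal(ev2$peak_time_s, ev$peak_time_s)
  # rejected candidates carry exactly one recognised reason
  evr <- detect_ieds(sess$recording, keep_rejected = TRUE)
  expect_true(all(evr$rejection_stage %in%
                    c("", "low_peak", "duration", "shape_entropy",
                      "degenerate")))
})

test_that("lowering thresholds never decreases the accepted-event count", {
  cfg <- simulation_config(duration_s = 120, seed = 41, hfo_rate_per_min = 0,
                           coupling_prob = 0, ied_rate_per_min = 6,
                           ied_peak_nss_sd = 22,
                           state_schedule = data.frame(
                             label = "NREM", start_s = 0, end_s = 120))
  sess <- generate_coupled_session(cfg)
  nss <- preprocess_nss(sess$recording$samples[, 1],
                        sess$recording$fs_hz, icfg)
  counts <- vapply(c(25, 20, 15, 10), function(pk) {
    c2 <- icfg; c2$peak_sd <- pk
    sum(detect_ied_candidates(nss, c2)$accepted)
  }, 0L)
  expect_true(all(diff(counts) >= 0))
  counts_on <- vapply(c(7, 5, 4), function(on) {
    c2 <- icfg; c2$onset_sd <- on
    sum(detect_ied_candidates(nss, c2)$accepted)
  }, 0L)
  expect_true(all(diff(counts_on) >= 0))
})

test_that("false-positive rate on pure background is low", {
  fp_per_min <- vapply(1:10, function(seed) {
    rec <- quiet_recording(1800, seed = 100 + seed)
    nrow(detect_ieds(rec)) / 30
  }, 0)
  expect_lt(mean(fp_per_min), 0.2)
})
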