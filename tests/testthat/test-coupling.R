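# PETH construction, entropy, coupling strength, bootstrap significance.

test_that("PETH places lags in half-open bins", {
  p <- build_peth(1.0, 1.1, window_ms = 500, bin_width_ms = 100)
  expect_equal(p$n_bins, 10L)
  expect_equal(sum(p$counts), 1L)
  # lag +100 ms falls in bin [+100, +200)
  expect_equal(which(p$counts == 1), 7L)
  # lag exactly +500 ms is excluded, -500 ms is included
  expect_equal(build_peth(1, 1.5)$n_events_in_window, 0L)
  expect_equal(build_peth(1, 0.5)$n_events_in_window, 1L)
  expect_error(build_peth(numeric(0), 1), "at least one anchor")
  expect_error(build_peth(1, 1, window_ms = 500, bin_width_ms = 300),
               "divisible")
  # empty window -> flagged, not an error
  p0 <- build_peth(10, 20)
  expect_true(p0$empty)
  expect_true(all(is.na(p0$p)))
})

test_that("PETH counting equals the O(n^2) brute-force oracle", {
  set.seed(5)
  for (rep in 1:25) {
    anchors <- runif(200, 0, 600)
    events <- runif(1000, 0, 600)
    p <- build_peth(anchors, events)
    expect_identical(p$counts, peth_bruteforce(anchors, events))
  }
})

test_that("entropy matches closed forms and validates input", {
  expect_equal(shannon_entropy(rep(1 / 100, 100)), log(100),
               tolerance = 1e-12)
  expect_equal(shannon_entropy(c(1, rep(0, 9))), 0)
  expect_equal(shannon_entropy(c(0.5, 0.25, 0.25)),
               1.0397207708399179, tolerance = 1e-12)
  expect_error(shannon_entropy(c(0.5, 0.6)), "sum to 1")
  expect_error(shannon_entropy(c(-0.1, 1.1)), "non-negative")
})

test_that("coupling strength has the exact uniform/delta limits", {
  mk <- function(counts) {
    n <- length(counts)
    structure(list(counts = counts, p = counts / sum(counts),
                   n_bins = n, window_ms = n * 5, bin_width_ms = 10,
                   n_anchors = 10, n_events_in_window = sum(counts),
                   empty = sum(counts) == 0), class = "peth")
  }
  expect_equal(as.numeric(coupling_strength(mk(rep(5L, 100)))), 0)
  d <- integer(100); d[37] <- 12L
  expect_equal(as.numeric(coupling_strength(mk(d))), 1)
  p3 <- mk(c(2L, 1L, 1L))            # p = (0.5, 0.25, 0.25)
  expect_equal(as.numeric(coupling_strength(p3)),
               (log(3) - 1.0397207708399179) / log(3), tolerance = 1e-12)
  # empty PETH -> h = 0 with undefined flag
  h0 <- coupling_strength(mk(integer(100)))
  expect_equal(as.numeric(h0), 0)
  expect_true(attr(h0, "undefined"))
  # h strictly decreases as a delta is smoothed toward uniform
  hs <- vapply(seq(0, 1, by = 0.1), function(lam) {
    counts <- (1 - lam) * c(1, rep(0, 99)) + lam * rep(1 / 100, 100)
    peth <- mk(integer(100)); peth$p <- counts / sum(counts)
    peth$empty <- FALSE
    as.numeric(coupling_strength(peth))
  }, 0)
  expect_true(all(diff(hs) < 0))
})

test_that("h is invariant to bin relabeling and joint time translation", {
  set.seed(9)
  anchors <- sort(runif(100, 100, 500))
  events <- sort(c(anchors + rnorm(100, 0.05, 0.02), runif(60, 0, 600)))
  h1 <- as.numeric(coupling_strength(build_peth(anchors, events)))
  h2 <- as.numeric(coupling_strength(build_peth(anchors + 37.5,
                                                events + 37.5)))
  expect_equal(h1, h2, tolerance = 1e-12)
  p <- build_peth(anchors, events)
  p_perm <- p
  perm <- sample(p$n_bins)
  p_perm$counts <- p$counts[perm]; p_perm$p <- p$p[perm]
  expect_equal(as.numeric(coupling_strength(p_perm)),
               as.numeric(coupling_strength(p)), tolerance = 1e-12)
})

test_that("bootstrap is seeded, p-values bounded, and detects coupling", {
  set.seed(2)
  anchors <- sort(runif(60, 1, 1790))
  events <- sort((anchors + rnorm(60, 0.05, 0.01)) %% 1800)
  r1 <- bootstrap_significance(anchors, events, 1800, n_boot = 100,
                               seed = 7)
  r2 <- bootstrap_significance(anchors, events, 1800, n_boot = 100,
                               seed = 7)
  expect_identical(r1$boot_null, r2$boot_null)
  expect_true(r1$p_boot > 0 && r1$p_boot <= 1)
  expect_lte(r1$p_boot, 0.02)            # tight coupling is significant
  expect_equal(r1$S_max, log(100))
  expect_error(bootstrap_significance(anchors, events, 1800, n_boot = 0),
               "n_boot")
  # fewer than 2 events -> undefined coupling, no p-value
  r3 <- bootstrap_significance(anchors, events[1], 1800)
  expect_true(r3$undefined)
  expect_true(is.na(r3$p_boot))
})

test_that("uncoupled streams are rarely significant; coupled ones always", {
  # power: coupling_prob = 1, jitter 10 ms, rates 2/min, 30 min sessions
  p_coupled <- vapply(1:20, function(seed) {
    cfg <- simulation_config(duration_s = 1800, coupling_prob = 1,
                             coupling_jitter_ms = 10,
                             ied_rate_per_min = 2, hfo_rate_per_min = 2,
                             seed = 300 + seed)
    tr <- draw_session_events(cfg)
    a <- collapse_to_state_time(tr$ied$time_s, cfg$state_schedule, "NREM")
    e <- collapse_to_state_time(tr$hfo$time_s, cfg$state_schedule, "NREM")
    bootstrap_significance(a$times, e$times, a$span_s,
                           n_boot = 200, seed = seed)$p_boot
  }, 0)
  expect_gte(mean(p_coupled <= 0.01), 0.95)
  # independence: coupling_prob = 0 -> h below the null 97.5th percentile
  ok <- vapply(1:20, function(seed) {
    cfg <- simulation_config(duration_s = 1800, coupling_prob = 0,
                             ied_rate_per_min = 2, hfo_rate_per_min = 2,
                             seed = 600 + seed)
    tr <- draw_session_events(cfg)
    a <- collapse_to_state_time(tr$ied$time_s, cfg$state_schedule, "NREM")
    e <- collapse_to_state_time(tr$hfo$time_s, cfg$state_schedule, "NREM")
    r <- bootstrap_significance(a$times, e$times, a$span_s,
                                n_boot = 200, seed = seed)
    # not in the upper-2.5% rejection region of its own null (ties, which
    # the discrete G statistic produces often, count as non-rejection)
    r$g <= quantile(r$boot_null_g, 0.975)
  }, TRUE)
  expect_gte(mean(ok), 0.9)
})
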