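#!/usr/bin/env Rscript
# Step 2: run both detectors on every simulated session (NREM only) and
# score them against the injected ground truth.

suppressPackageStartupMessages(library(lfpcoupling))

cohort <- read.delim("results/cohort.tsv")
all_events <- list()
for (i in seq_len(nrow(cohort))) {
  dir <- file.path("results/sessions", cohort$animal[i])
  rec <- read_recording(dir, "fixture")
  truth <- read.delim(file.path(dir, "truth.tsv"))
  hfo <- detect_hfos(rec, states_filter = "NREM")
  ied <- detect_ieds(rec, states_filter = "NREM")
  ev <- rbind(hfo[, intersect(names(hfo), names(ied))],
              ied[, intersect(names(hfo), names(ied))])
  score <- function(det, tru) {
    if (length(det) == 0) return(c(NA, NA))
    c(mean(vapply(tru, function(t) any(abs(det - t) < 0.05), TRUE)),
      mean(vapply(det, function(t) any(abs(tru - t) < 0.05), TRUE)))
  }
  sh <- score(hfo$peak_time_s, truth$time_s[truth$kind == "hfo"])
  si <- score(ied$peak_time_s, truth$time_s[truth$kind == "ied"])
  cat(sprintf(
    "%s: %3d HFOs (recall %.2f, precision %.2f), %3d IEDs (recall %.2f, precision %.2f)\n",
    cohort$animal[i], nrow(hfo), sh[1], sh[2], nrow(ied), si[1], si[2]))
  ev$animal <- cohort$animal[i]
  ev$group <- cohort$group[i]
  all_events[[i]] <- cbind(ev,
                           peak_freq_hz = c(hfo$peak_freq_hz,
                                            rep(NA, nrow(ied))),
                           class = c(hfo$class, rep(NA, nrow(ied))))
}
events <- do.call(rbind, all_events)
write_events(events, "results/events.tsv")
cat(sprintf("wrote %d events to results/events.tsv\n", nrow(events)))
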