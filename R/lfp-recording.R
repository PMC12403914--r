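# Container for a continuous multi-channel LFP recording.

REGION_LEVELS <- c("striatum", "mPFC", "hippocampus", "thalamus", "other")
STATE_LEVELS <- c("NREM", "REM", "WAKE")

#' Construct an LFP recording object
#'
#' Holds a continuous multi-channel local field potential: a samples matrix
#' (rows = samples, columns = channels), the sampling rate, per-channel labels
#' with brain-region tags, and sleep-state interval annotations. Times are in
#' seconds, sample indexing is 0-based and half-open: sample k occupies
#' `[k/fs, (k+1)/fs)`.
#'
#' @param samples numeric matrix (samples x channels) or vector (one channel).
#' @param fs_hz sampling rate in samples/second.
#' @param channels character vector of channel labels.
#' @param regions character vector of region tags, one per channel; one of
#'   `"striatum"`, `"mPFC"`, `"hippocampus"`, `"thalamus"`, `"other"`.
#' @param start_time_s recording start time in seconds (default 0).
#' @param states data.frame of sleep-state intervals with columns `label`
#'   (NREM/REM/WAKE), `start_s`, `end_s`; intervals are half-open
#'   `[start_s, end_s)` and must not overlap.
#' @return an object of class `lfp_recording`.
#' @export
lfp_recording <- function(samples, fs_hz, channels = NULL, regions = NULL,
                          start_time_s = 0, states = NULL) {
  if (is.vector(samples)) samples <- matrix(samples, ncol = 1)
  stopifnot(is.matrix(samples), is.numeric(samples))
  if (nrow(samples) == 0L) stop("recording must contain at least one sample")
  if (!is.numeric(fs_hz) || length(fs_hz) != 1L || fs_hz <= 0) {
    stop("fs_hz must be a single positive number")
  }
  nc <- ncol(samples)
  if (is.null(channels)) channels <- paste0("ch", seq_len(nc))
  if (is.null(regions)) regions <- rep("other", nc)
  if (length(channels) != nc || length(regions) != nc) {
    stop("channels and regions must have one entry per channel")
  }
  bad <- setdiff(unique(regions), REGION_LEVELS)
  if (length(bad) > 0) {
    stop("unknown region tag(s) ", paste(bad, collapse = ", "),
         "; allowed: ", paste(REGION_LEVELS, collapse = ", "))
  }
  states <- normalize_states(states)
  structure(
    list(samples = samples, fs_hz = fs_hz, channels = as.character(channels),
         regions = as.character(regions), start_time_s = start_time_s,
         states = states),
    class = "lfp_recording")
}

#' @export
print.lfp_recording <- function(x, ...) {
  cat(sprintf("<lfp_recording> %d channel(s), %.1f s at %g Hz\n",
              ncol(x$samples), nrow(x$samples) / x$fs_hz, x$fs_hz))
  cat("  channels:", paste0(x$channels, " [", x$regions, "]",
                            collapse = ", "), "\n")
  if (nrow(x$states) > 0) {
    tot <- tapply(x$states$end_s - x$states$start_s, x$states$label, sum)
    cat("  states:", paste(names(tot), sprintf("%.1f min", tot / 60),
                           collapse = ", "), "\n")
  }
  invisible(x)
}

#' Number of samples per channel
#' @param recording an `lfp_recording`.
#' @return integer sample count.
#' @export
n_samples <- function(recording) nrow(recording$samples)

#' Recording duration in seconds
#' @param recording an `lfp_recording`.
#' @return duration in seconds.
#' @export
duration_s <- function(recording) nrow(recording$samples) / recording$fs_hz

# Validate, sort and type a state-interval table. NULL -> empty table.
normalize_states <- function(states) {
  if (is.null(states) || (is.data.frame(states) && nrow(states) == 0L)) {
    return(data.frame(label = character(), start_s = numeric(),
                      end_s = numeric(), stringsAsFactors = FALSE))
  }
  stopifnot(is.data.frame(states),
            all(c("label", "start_s", "end_s") %in% names(states)))
  states <- states[, c("label", "start_s", "end_s")]
  states$label <- as.character(states$label)
  bad <- setdiff(unique(states$label), STATE_LEVELS)
  if (length(bad) > 0) {
    stop("unknown state label(s): ", paste(bad, collapse = ", "))
  }
  if (any(states$start_s >= states$end_s)) {
    stop("state intervals must satisfy start_s < end_s")
  }
  states <- states[order(states$start_s), , drop = FALSE]
  if (nrow(states) > 1 &&
      any(states$start_s[-1] < states$end_s[-nrow(states)])) {
    stop("state intervals overlap")
  }
  rownames(states) <- NULL
  states
}

#' Logical sample mask for a set of sleep states
#'
#' Membership follows the half-open rule: sample k (time `k/fs`) belongs to an
#' interval `[start_s, end_s)` iff `start_s <= k/fs < end_s`.
#'
#' @param recording an `lfp_recording`.
#' @param labels character vector of state labels to include.
#' @param fs_hz optional rate overriding the recording's (e.g. for a
#'   resampled derived series); mask length is then `round(duration * fs_hz)`.
#' @return logical vector over samples.
#' @export
state_mask <- function(recording, labels, fs_hz = NULL) {
  if (is.null(fs_hz)) fs_hz <- recording$fs_hz
  n <- as.integer(round(duration_s(recording) * fs_hz))
  mask <- logical(n)
  st <- recording$states
  st <- st[st$label %in% labels, , drop = FALSE]
  t <- (seq_len(n) - 1L) / fs_hz
  for (i in seq_len(nrow(st))) {
    mask <- mask | (t >= st$start_s[i] & t < st$end_s[i])
  }
  mask
}

#' Total time spent in given states, in seconds
#'
#' @param states state-interval data.frame (`label`, `start_s`, `end_s`).
#' @param labels labels to include.
#' @return total seconds.
#' @export
state_time_s <- function(states, labels) {
  st <- states[states$label %in% labels, , drop = FALSE]
  sum(st$end_s - st$start_s)
}

# TRUE for times t (seconds) lying in any interval of the given states.
times_in_states <- function(t, states, labels) {
  st <- states[states$label %in% labels, , drop = FALSE]
  res <- logical(length(t))
  for (i in seq_len(nrow(st))) {
    res <- res | (t >= st$start_s[i] & t < st$end_s[i])
  }
  res
}
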