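# On-disk contracts: fixture format (float32 + JSON sidecar), minimal EDF,
# TSV event tables, and the validated configuration loader.

EVENT_REQUIRED_COLS <- c("channel", "region", "kind", "start_s", "end_s",
                         "peak_time_s")

#' Write a recording to disk
#'
#' The fixture format is the canonical lossless medium: one 32-bit
#' little-endian float binary file per channel plus a JSON sidecar
#' (`header.json`) carrying fs_hz, channel labels, regions, start time and
#' the state intervals. EDF export writes a standard 16-bit European Data
#' Format file (region tags encoded in the label as `name::region`); EDF is
#' quantized, so round trips are approximate by design. EDF stores whole
#' 1-second records, so the signal is zero-padded to a full second and state
#' annotations are not carried.
#'
#' @param recording an [lfp_recording()].
#' @param path fixture: a directory (created); edf: a file path.
#' @param format `"fixture"` or `"edf"`.
#' @return `path`, invisibly.
#' @export
write_recording <- function(recording, path, format = c("fixture", "edf")) {
  format <- match.arg(format)
  stopifnot(inherits(recording, "lfp_recording"))
  if (nrow(recording$samples) == 0L) stop("cannot write an empty recording")
  if (format == "fixture") write_fixture(recording, path)
  else write_edf(recording, path)
  invisible(path)
}

#' Read a recording from disk
#'
#' @param path fixture directory or EDF file written by [write_recording()].
#' @param format `"fixture"` or `"edf"`.
#' @return an [lfp_recording()].
#' @export
read_recording <- function(path, format = c("fixture", "edf")) {
  format <- match.arg(format)
  if (format == "fixture") read_fixture(path) else read_edf(path)
}

write_fixture <- function(recording, path) {
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  files <- sprintf("chan%03d.f32", seq_along(recording$channels))
  header <- list(
    format = "lfp-fixture-v1",
    fs_hz = recording$fs_hz,
    n_samples = nrow(recording$samples),
    channels = recording$channels,
    regions = recording$regions,
    start_time_s = recording$start_time_s,
    files = files,
    states = recording$states)
  jsonlite::write_json(header, file.path(path, "header.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  for (i in seq_along(files)) {
    con <- file(file.path(path, files[i]), "wb")
    writeBin(as.vector(recording$samples[, i]), con, size = 4L,
             endian = "little")
    close(con)
  }
  invisible(path)
}

read_fixture <- function(path) {
  hf <- file.path(path, "header.json")
  if (!file.exists(hf)) stop("no fixture header found at ", hf)
  h <- jsonlite::read_json(hf, simplifyVector = TRUE)
  bad <- setdiff(unique(h$regions), REGION_LEVELS)
  if (length(bad) > 0) {
    stop("unknown region tag(s) in fixture header: ",
         paste(bad, collapse = ", "),
         "; allowed: ", paste(REGION_LEVELS, collapse = ", "))
  }
  n <- as.integer(h$n_samples)
  samples <- matrix(0, nrow = n, ncol = length(h$files))
  for (i in seq_along(h$files)) {
    con <- file(file.path(path, h$files[i]), "rb")
    samples[, i] <- readBin(con, numeric(), n = n, size = 4L,
                            endian = "little")
    close(con)
  }
  states <- if (is.null(h$states) || length(h$states) == 0) NULL
            else as.data.frame(h$states, stringsAsFactors = FALSE)
  lfp_recording(samples, fs_hz = h$fs_hz, channels = h$channels,
                regions = h$regions, start_time_s = h$start_time_s,
                states = states)
}

# --- minimal EDF (European Data Format) -----------------------------------
# Standard 256-byte fixed header + 256 bytes per signal; 16-bit little-endian
# samples in 1-second data records. Good enough for interchange; the fixture
# format is the lossless medium.

edf_pad <- function(s, width) {
  s <- substr(as.character(s), 1L, width)
  formatC(s, width = width, flag = "-")
}

# EDF label fields are 16 bytes; regions are carried as short codes.
EDF_REGION_CODES <- c(striatum = "str", mPFC = "pfc", hippocampus = "hpc",
                      thalamus = "thl", other = "oth")

write_edf <- function(recording, path) {
  fs <- recording$fs_hz
  if (abs(fs - round(fs)) > 1e-9) stop("EDF export requires an integer fs_hz")
  fs <- as.integer(round(fs))
  x <- recording$samples
  n <- nrow(x)
  n_rec <- as.integer(ceiling(n / fs))
  if (n_rec * fs > n) {
    x <- rbind(x, matrix(0, nrow = n_rec * fs - n, ncol = ncol(x)))
  }
  ns <- ncol(x)
  pmin_ <- apply(x, 2, min); pmax_ <- apply(x, 2, max)
  flat <- pmax_ - pmin_ < 1e-12
  pmax_[flat] <- pmin_[flat] + 1
  dmin <- -32768; dmax <- 32767
  labels <- paste0(recording$channels, "::",
                   EDF_REGION_CODES[recording$regions])
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s, w) writeChar(edf_pad(s, w), con, nchars = w, eos = NULL)
  wr("0", 8); wr("X X X X", 80); wr("Startdate X X X X", 80)
  wr("01.01.00", 8); wr("00.00.00", 8)
  wr(as.character(256L * (ns + 1L)), 8); wr("", 44)
  wr(as.character(n_rec), 8); wr("1", 8); wr(as.character(ns), 4)
  for (s in labels) wr(s, 16)
  for (i in seq_len(ns)) wr("", 80)                    # transducer type
  for (i in seq_len(ns)) wr("uV", 8)                   # physical dimension
  for (v in pmin_) wr(sprintf("%.8g", v), 8)
  for (v in pmax_) wr(sprintf("%.8g", v), 8)
  for (i in seq_len(ns)) wr(as.character(dmin), 8)
  for (i in seq_len(ns)) wr(as.character(dmax), 8)
  for (i in seq_len(ns)) wr("", 80)                    # prefiltering
  for (i in seq_len(ns)) wr(as.character(fs), 8)       # samples per record
  for (i in seq_len(ns)) wr("", 32)                    # reserved
  scale <- (pmax_ - pmin_) / (dmax - dmin)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * fs + 1):(r * fs)
    for (s in seq_len(ns)) {
      dig <- round((x[idx, s] - pmin_[s]) / scale[s]) + dmin
      dig <- as.integer(pmin(pmax(dig, dmin), dmax))
      writeBin(dig, con, size = 2L, endian = "little")
    }
  }
  invisible(path)
}

read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)                                # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  for (i in seq_len(ns)) rd(80)
  for (i in seq_len(ns)) rd(8)
  pmin_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  pmax_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  dmin <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  dmax <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  for (i in seq_len(ns)) rd(80)
  nsamp <- vapply(seq_len(ns), function(i) as.integer(rd(8)), 0L)
  for (i in seq_len(ns)) rd(32)
  if (length(unique(nsamp / rec_dur)) != 1L) {
    stop("unsupported input: channels have mixed sampling rates (",
         paste(unique(nsamp / rec_dur), collapse = ", "), " Hz)")
  }
  fs <- nsamp[1] / rec_dur
  dat <- matrix(0, nrow = n_rec * nsamp[1], ncol = ns)
  for (r in seq_len(n_rec)) {
    for (s in seq_len(ns)) {
      dig <- readBin(con, integer(), n = nsamp[s], size = 2L,
                     endian = "little", signed = TRUE)
      scale <- (pmax_[s] - pmin_[s]) / (dmax[s] - dmin[s])
      dat[((r - 1) * nsamp[s] + 1):(r * nsamp[s]), s] <-
        (dig - dmin[s]) * scale + pmin_[s]
    }
  }
  parts <- strsplit(labels, "::", fixed = TRUE)
  channels <- vapply(parts, `[`, "", 1L)
  codes <- vapply(parts, function(p) if (length(p) > 1) p[2] else "oth", "")
  rev_codes <- stats::setNames(names(EDF_REGION_CODES), EDF_REGION_CODES)
  regions <- unname(rev_codes[codes])
  regions[is.na(regions)] <- "other"
  lfp_recording(dat, fs_hz = fs, channels = channels, regions = regions)
}

# --- event tables ----------------------------------------------------------

#' Validate an event table
#'
#' Checks the required columns (`channel`, `region`, `kind`, `start_s`,
#' `end_s`, `peak_time_s`), the ordering `start_s <= peak_time_s <= end_s`
#' and sorts rows by (channel, start_s). Extra columns are preserved.
#'
#' @param events data.frame of detected events.
#' @return the validated, sorted data.frame.
#' @export
validate_events <- function(events) {
  stopifnot(is.data.frame(events))
  missing_cols <- setdiff(EVENT_REQUIRED_COLS, names(events))
  if (length(missing_cols) > 0) {
    stop("event table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (nrow(events) > 0) {
    if (any(events$end_s < events$start_s)) {
      stop("event table has rows with end_s < start_s")
    }
    ok <- is.na(events$peak_time_s) |
      (events$peak_time_s >= events$start_s &
         events$peak_time_s <= events$end_s)
    if (!all(ok)) stop("peak_time_s must lie within [start_s, end_s]")
    events <- events[order(events$channel, events$start_s), , drop = FALSE]
    rownames(events) <- NULL
  }
  events
}

#' Write an event table as TSV
#' @param events data.frame passing [validate_events()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  events <- validate_events(events)
  utils::write.table(events, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read an event table from TSV
#' @param path TSV file with a header row.
#' @return validated data.frame (possibly 0 rows).
#' @export
read_events <- function(path) {
  events <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  for (col in c("channel", "region", "kind")) {
    if (col %in% names(events)) events[[col]] <- as.character(events[[col]])
  }
  validate_events(events)
}

#' Read or write a sleep-state interval table (TSV)
#' @param path TSV with columns `label`, `start_s`, `end_s`.
#' @return normalized state data.frame.
#' @export
read_states <- function(path) {
  normalize_states(utils::read.delim(path, sep = "\t",
                                     stringsAsFactors = FALSE))
}

#' @rdname read_states
#' @param states state data.frame.
#' @export
write_states <- function(states, path) {
  utils::write.table(normalize_states(states), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

# --- configuration ---------------------------------------------------------

#' Default analysis configuration
#'
#' Nested list of every detector and coupling parameter with its default:
#' `hfo` (band 80-520 Hz, envelope threshold 3 robust SD, boundary 1 SD,
#' minimum 3 cycles and 6 ms, 10 ms merge gap, Morlet 7 cycles over a
#' log-spaced 60-600 Hz grid, sharp-transient power ratio 1.0, power floor
#' 10x baseline, relative bandwidth 1.0, 6 dB isolation, 99.9th percentile
#' background cleaning, 200 Hz class boundary), `ied` (band 60-80 Hz,
#' resample 1250 Hz, onset 5 SD, peak 20 SD, duration 30-250 ms, profile
#' entropy threshold 0.9 ln(10) with 10 bins) and `coupling` (window 500 ms,
#' bin 10 ms, 200 bootstrap surrogates).
#'
#' @return nested named list.
#' @export
default_config <- function() {
  list(
    hfo = list(
      band_low_hz = 80, band_high_hz = 520, transition_hz = 20,
      k_env = 3, boundary_sd = 1, min_cycles = 3, min_duration_ms = 6,
      merge_gap_ms = 10, envelope_smooth_ms = 2,
      tf_n_cycles = 7, tf_low_hz = 60, tf_high_hz = 600, tf_n_freqs = 40,
      rho_max = 1.0, power_floor = 30, max_rel_bandwidth = 1.0,
      min_isolation_db = 6, background_percentile = 0.999,
      boundary_hz = 200),
    ied = list(
      band_low_hz = 60, band_high_hz = 80, transition_hz = 8,
      resample_hz = 1250, onset_sd = 5, peak_sd = 20,
      min_duration_ms = 30, max_duration_ms = 250,
      smooth_sigma_ms = 5, entropy_bins = 10,
      entropy_threshold = 0.9 * log(10)),
    coupling = list(
      window_ms = 500, bin_width_ms = 10, n_boot = 200,
      surrogate = "circular_shift"))
}

#' Load and validate an analysis configuration
#'
#' Reads a YAML or JSON document and merges it over [default_config()].
#' Unknown keys at any level are rejected; threshold relations are validated
#' (positive SD multiples, `onset_sd < peak_sd`,
#' `min_duration_ms < max_duration_ms`, band edges ordered, resample rate
#' above twice the band). An empty or missing document yields the full
#' default set.
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON file, or `NULL` for defaults.
#' @param overrides optional nested list applied after the file.
#' @return validated nested configuration list.
#' @export
load_config <- function(path = NULL, overrides = NULL) {
  cfg <- default_config()
  user <- list()
  if (!is.null(path)) {
    user <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
      jsonlite::read_json(path, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(path)
    }
    if (is.null(user)) user <- list()
  }
  cfg <- merge_config(cfg, user, path = "")
  if (!is.null(overrides)) cfg <- merge_config(cfg, overrides, path = "")
  validate_config(cfg)
  cfg
}

merge_config <- function(base, user, path = "") {
  if (length(user) == 0) return(base)
  unknown <- setdiff(names(user), names(base))
  if (length(unknown) > 0) {
    stop("unknown configuration key(s): ",
         paste0(sub("^\\.", "", paste0(path, ".", unknown)), collapse = ", "))
  }
  for (k in names(user)) {
    if (is.list(base[[k]]) && !is.null(names(base[[k]]))) {
      base[[k]] <- merge_config(base[[k]], as.list(user[[k]]),
                                paste0(path, ".", k))
    } else {
      base[[k]] <- user[[k]]
    }
  }
  base
}

validate_config <- function(cfg) {
  h <- cfg$hfo; d <- cfg$ied; cp <- cfg$coupling
  chk <- function(cond, msg) if (!isTRUE(cond)) stop("invalid config: ", msg)
  chk(h$band_low_hz < h$boundary_hz && h$boundary_hz <= h$band_high_hz,
      "hfo band_low < boundary_hz <= band_high required")
  chk(h$k_env > 0, "hfo.k_env must be positive")
  chk(h$min_cycles >= 1, "hfo.min_cycles must be >= 1")
  chk(d$onset_sd > 0 && d$onset_sd < d$peak_sd,
      "ied thresholds require 0 < onset_sd < peak_sd")
  chk(d$min_duration_ms < d$max_duration_ms,
      "ied.min_duration_ms must be below ied.max_duration_ms")
  chk(d$resample_hz > 2 * d$band_high_hz,
      "ied.resample_hz must exceed twice the band upper edge")
  chk(d$band_low_hz < d$band_high_hz, "ied band edges out of order")
  chk(cp$window_ms > 0 && cp$bin_width_ms > 0 &&
        abs(cp$window_ms / cp$bin_width_ms -
              round(cp$window_ms / cp$bin_width_ms)) < 1e-9,
      "coupling window_ms must be divisible by bin_width_ms")
  chk(cp$n_boot >= 1, "coupling.n_boot must be >= 1")
  invisible(cfg)
}
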