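#' Construct a polysomnography recording
#'
#' Container for synchronized EEG + EMG sample streams with sampling rate,
#' start clock time, and the vivarium light schedule used to split analyses
#' into light and dark phases.
#'
#' @param eeg,emg numeric sample streams in microvolts, equal length.
#' @param fs_hz sampling rate, > 0.
#' @param start_clock recording start as "HH:MM:SS" (or seconds after
#'   midnight).
#' @param light_on,light_off light-phase boundaries, default 07:00 / 19:00
#'   (standard 12:12 cycle).
#' @return object of class `psg_recording`.
#' @export
recording <- function(eeg, emg, fs_hz, start_clock = "07:00:00",
                      light_on = "07:00", light_off = "19:00") {
  eeg <- as.numeric(eeg); emg <- as.numeric(emg)
  if (length(eeg) != length(emg)) stop("eeg and emg must have equal length")
  if (fs_hz <= 0) stop("fs_hz must be > 0")
  on_s <- parse_clock(light_on); off_s <- parse_clock(light_off)
  if (on_s == off_s) stop("light_on and light_off must differ")
  structure(list(eeg = eeg, emg = emg, fs_hz = fs_hz,
                 start_clock_s = parse_clock(start_clock),
                 light_on_s = on_s, light_off_s = off_s),
            class = "psg_recording")
}

#' @export
print.psg_recording <- function(x, ...) {
  cat(sprintf(
    "<psg_recording> %d samples @ %g Hz (%.1f s), start %s, lights %s-%s\n",
    length(x$eeg), x$fs_hz, length(x$eeg) / x$fs_hz,
    format_clock(x$start_clock_s), format_clock(x$light_on_s),
    format_clock(x$light_off_s)))
  invisible(x)
}

#' Write a recording to CSV (+ YAML sidecar) or EDF
#'
#' CSV carries columns `time_s,eeg_uV,emg_uV`; sampling rate, start clock
#' and light schedule go to a YAML sidecar (`<path>.yaml`). EDF writes a
#' minimal 2-signal EDF file (16-bit; exact only up to quantization).
#'
#' @param rec a [recording()].
#' @param path output file path.
#' @param format "csv" or "edf".
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, format = c("csv", "edf")) {
  stopifnot(inherits(rec, "psg_recording"))
  format <- match.arg(format)
  if (format == "csv") {
    n <- length(rec$eeg)
    df <- data.frame(time_s = (seq_len(n) - 1) / rec$fs_hz,
                     eeg_uV = rec$eeg, emg_uV = rec$emg)
    utils::write.csv(df, path, row.names = FALSE)
    yaml::write_yaml(list(fs_hz = rec$fs_hz,
                          start_clock = format_clock(rec$start_clock_s),
                          light_on = format_clock(rec$light_on_s),
                          light_off = format_clock(rec$light_off_s)),
                     paste0(path, ".yaml"))
  } else {
    write_edf(rec, path)
  }
  invisible(path)
}

#' Read a recording from CSV or EDF
#'
#' CSV must have a header `time_s,eeg_uV,emg_uV` or `eeg_uV,emg_uV`; in the
#' latter case (or always, if present) the sampling rate and clock metadata
#' are taken from the `<path>.yaml` sidecar, falling back to the `fs_hz`
#' argument. EDF channels are matched by the configured label names.
#'
#' @param path input file.
#' @param format "csv" or "edf" (default guessed from the extension).
#' @param fs_hz fallback sampling rate for CSV without sidecar; for files
#'   with a `time_s` column the rate is inferred and checked.
#' @param channels channel labels expected in an EDF file,
#'   `c(eeg = "EEG", emg = "EMG")`.
#' @param start_clock,light_on,light_off fallbacks when no metadata source
#'   provides them.
#' @return a [recording()].
#' @export
read_recording <- function(path, format = NULL, fs_hz = NULL,
                           channels = c(eeg = "EEG", emg = "EMG"),
                           start_clock = "07:00:00",
                           light_on = "07:00", light_off = "19:00") {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(format))
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "csv"
  format <- match.arg(format, c("csv", "edf"))
  if (format == "edf") return(read_edf(path, channels, light_on, light_off))

  df <- utils::read.csv(path, check.names = FALSE)
  need <- c("eeg_uV", "emg_uV")
  if (!all(need %in% names(df)))
    stop("CSV must contain columns ", paste(need, collapse = ", "),
         "; found: ", paste(names(df), collapse = ", "))
  meta <- list()
  sidecar <- paste0(path, ".yaml")
  if (file.exists(sidecar)) meta <- yaml::read_yaml(sidecar)
  fs <- meta$fs_hz %||% fs_hz
  if ("time_s" %in% names(df) && nrow(df) > 1) {
    fs_inf <- 1 / stats::median(diff(df$time_s))
    if (is.null(fs)) fs <- fs_inf
    else if (abs(fs_inf - fs) / fs > 1e-3)
      stop(sprintf("fs mismatch: time column implies %.4g Hz, metadata %.4g Hz",
                   fs_inf, fs))
  }
  if (is.null(fs)) stop("sampling rate unknown: provide fs_hz or a YAML sidecar")
  recording(df$eeg_uV, df$emg_uV, fs,
            start_clock = meta$start_clock %||% start_clock,
            light_on = meta$light_on %||% light_on,
            light_off = meta$light_off %||% light_off)
}

#' Zero-phase Butterworth bandpass filter
#'
#' 4th-order Butterworth applied forward and backward
#' ([signal::filtfilt()]), so the passband is phase-preserving — important
#' because features are computed on epoch-aligned windows. Standard
#' preprocessing bands are EEG 0.5-100 Hz and EMG 10-100 Hz.
#'
#' @param x numeric signal.
#' @param low_hz,high_hz passband edges, `0 < low < high < fs/2`.
#' @param fs_hz sampling rate.
#' @param order filter order (default 4).
#' @return filtered signal, same length.
#' @export
bandpass <- function(x, low_hz, high_hz, fs_hz, order = 4L) {
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < fs_hz / 2))
    stop("require 0 < low_hz < high_hz < fs_hz/2 (Nyquist)")
  bf <- signal::butter(order, c(low_hz, high_hz) / (fs_hz / 2), type = "pass")
  as.numeric(signal::filtfilt(bf, x))
}

#' Partition a recording into fixed-length scoring epochs
#'
#' Epochs tile the recording from its first sample; a trailing partial
#' epoch is dropped. Each epoch is tagged light or dark from the clock time
#' of its start sample against the recording's light schedule.
#'
#' @param rec a [recording()].
#' @param epoch_len_s epoch length in seconds (default 10).
#' @return data.frame with one row per epoch: `index` (1-based),
#'   `start_sample`, `t_start_s`, `phase` ("light"/"dark"), and attributes
#'   `epoch_len_s`, `samples_per_epoch`.
#' @export
epochize <- function(rec, epoch_len_s = 10) {
  stopifnot(inherits(rec, "psg_recording"))
  spe <- epoch_len_s * rec$fs_hz
  if (abs(spe - round(spe)) > 1e-9)
    stop("epoch_len_s * fs_hz must be an integer")
  spe <- as.integer(round(spe))
  n_ep <- length(rec$eeg) %/% spe
  if (n_ep < 1) stop("recording shorter than one epoch")
  t0 <- (seq_len(n_ep) - 1) * epoch_len_s
  clock <- (rec$start_clock_s + t0) %% 86400
  on <- rec$light_on_s; off <- rec$light_off_s
  phase <- if (on < off) {
    ifelse(clock >= on & clock < off, "light", "dark")
  } else {
    ifelse(clock >= on | clock < off, "light", "dark")
  }
  out <- data.frame(index = seq_len(n_ep),
                    start_sample = (seq_len(n_ep) - 1L) * spe + 1L,
                    t_start_s = t0, phase = phase,
                    stringsAsFactors = FALSE)
  attr(out, "epoch_len_s") <- epoch_len_s
  attr(out, "samples_per_epoch") <- spe
  out
}

# Extract the sample matrix (samples x epochs) for one channel.
epoch_matrix <- function(rec, epochs, channel = c("eeg", "emg")) {
  channel <- match.arg(channel)
  spe <- attr(epochs, "samples_per_epoch")
  n_ep <- nrow(epochs)
  matrix(rec[[channel]][seq_len(spe * n_ep)], nrow = spe)
}

## ---- minimal EDF (16-bit European Data Format) support ----------------

pad <- function(x, n) formatC(as.character(x), width = -n)

write_edf <- function(rec, path) {
  fs <- rec$fs_hz
  if (abs(fs - round(fs)) > 1e-9)
    stop("EDF export requires an integer sampling rate")
  fs <- as.integer(round(fs))
  n_rec <- length(rec$eeg) %/% fs  # 1-s data records
  if (n_rec < 1) stop("recording shorter than one EDF data record (1 s)")
  ns <- 2L
  sig <- list(EEG = rec$eeg[seq_len(n_rec * fs)],
              EMG = rec$emg[seq_len(n_rec * fs)])
  phys_min <- vapply(sig, function(s) floor(min(s, -1)), 0)
  phys_max <- vapply(sig, function(s) ceiling(max(s, 1)), 0)
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad("0", 8), pad("mouse", 80), pad("somnoplaque", 80),
    pad("01.01.26", 8), pad(gsub(":", ".", format_clock(rec$start_clock_s)), 8),
    pad(256 * (1 + ns), 8), pad("", 44), pad(n_rec, 8), pad("1", 8), pad(ns, 4))
  writeChar(hdr, con, eos = NULL)
  fld <- function(vals, w) writeChar(paste0(vapply(vals, pad, "", n = w),
                                            collapse = ""), con, eos = NULL)
  fld(names(sig), 16)                      # labels
  fld(rep("", ns), 80)                     # transducer
  fld(rep("uV", ns), 8)                    # dimension
  fld(phys_min, 8); fld(phys_max, 8)
  fld(rep(-32768L, ns), 8); fld(rep(32767L, ns), 8)
  fld(rep("", ns), 80)                     # prefiltering
  fld(rep(fs, ns), 8)                      # samples per record
  fld(rep("", ns), 32)                     # reserved
  gain <- (phys_max - phys_min) / 65535
  for (r in seq_len(n_rec)) {
    at <- ((r - 1L) * fs + 1L):(r * fs)
    for (k in seq_len(ns)) {
      dig <- round((sig[[k]][at] - phys_min[k]) / gain[k]) - 32768
      writeBin(as.integer(pmin(pmax(dig, -32768), 32767)), con, size = 2,
               endian = "little")
    }
  }
  invisible(path)
}

read_edf <- function(path, channels = c(eeg = "EEG", emg = "EMG"),
                     light_on = "07:00", light_off = "19:00") {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) trimws(readChar(con, n, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8)
  start <- rd(8)
  rd(8); rd(44)
  n_rec <- as.integer(rd(8)); dur <- as.numeric(rd(8)); ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  for (i in seq_len(ns)) rd(80)
  for (i in seq_len(ns)) rd(8)
  phys_min <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  phys_max <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dig_min <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dig_max <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(80)
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(32)
  want <- match(channels, labels)
  if (anyNA(want))
    stop("EDF missing channel(s): ",
         paste(channels[is.na(want)], collapse = ", "),
         " (file has: ", paste(labels, collapse = ", "), ")")
  if (length(unique(spr[want])) != 1L)
    stop("sampling rate differs between requested channels")
  raw <- vector("list", ns)
  for (i in seq_len(ns)) raw[[i]] <- vector("list", n_rec)
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      raw[[i]][[r]] <- readBin(con, integer(), n = spr[i], size = 2,
                               signed = TRUE, endian = "little")
    }
  }
  phys <- function(i) {
    dig <- unlist(raw[[i]])
    phys_min[i] + (dig - dig_min[i]) *
      (phys_max[i] - phys_min[i]) / (dig_max[i] - dig_min[i])
  }
  start_s <- tryCatch(parse_clock(gsub("\\.", ":", start)),
                      error = function(e) 0)
  recording(phys(want[1]), phys(want[2]), fs_hz = spr[want[1]] / dur,
            start_clock = start_s, light_on = light_on, light_off = light_off)
}
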