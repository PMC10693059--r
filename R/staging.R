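#' Per-epoch spectral and EMG features for sleep scoring
#'
#' For every epoch, computes the Hann periodogram of the EEG segment
#' (no overlap) and integrates it over the standard bands; the EMG feature
#' is the root-mean-square of the EMG segment. An epoch is flagged as
#' artifact when any sample exceeds `artifact_amp` in absolute value or
#' contains non-finite samples (flagged, never an exception).
#'
#' @param rec a [recording()].
#' @param epochs epoch table from [epochize()].
#' @param bands named band list, default [sleep_bands()].
#' @param range analysis range for `total_power`, default `c(0.5, 24)` Hz.
#' @param artifact_amp absolute-amplitude artifact cutoff in microvolts
#'   (applied to the EEG; this amplitude criterion is the package's
#'   operational definition of "epochs without artifact").
#' @return data.frame, one row per epoch: `index`, `t_start_s`, `phase`,
#'   one column per band (power in uV^2), `total_power`, `emg_rms`,
#'   `artifact`.
#' @export
compute_features <- function(rec, epochs, bands = sleep_bands(),
                             range = c(0.5, 24), artifact_amp = 400) {
  stopifnot(inherits(rec, "psg_recording"))
  eegm <- epoch_matrix(rec, epochs, "eeg")
  emgm <- epoch_matrix(rec, epochs, "emg")
  bad <- !is.finite(eegm)
  if (any(bad)) eegm[bad] <- 0  # compute on zero-filled copy; flag below
  pg <- hann_periodogram(eegm, rec$fs_hz)
  out <- data.frame(index = epochs$index, t_start_s = epochs$t_start_s,
                    phase = epochs$phase, stringsAsFactors = FALSE)
  for (b in names(bands))
    out[[b]] <- band_power_from_psd(pg, bands[[b]][1], bands[[b]][2])
  out$total_power <- band_power_from_psd(pg, range[1], range[2])
  out$emg_rms <- sqrt(colMeans(emgm^2, na.rm = TRUE))
  out$emg_rms[!is.finite(out$emg_rms)] <- 0
  out$artifact <- apply(abs(eegm) > artifact_amp, 2, any) | colSums(bad) > 0
  attr(out, "range") <- range
  attr(out, "artifact_amp") <- artifact_amp
  out
}

#' Staging thresholds
#'
#' @param emg_high EMG RMS (uV) at or above which an epoch is Wake.
#' @param theta_delta_rem theta/delta power-ratio threshold for REM
#'   (default 3, the published scoring criterion).
#' @param delta_frac_nrem minimum delta/total fraction for NREM; only used
#'   when `unscored = TRUE` in [classify_epochs()].
#' @param artifact_amp absolute-amplitude artifact cutoff (uV).
#' @return object of class `staging_thresholds`.
#' @export
staging_thresholds <- function(emg_high, theta_delta_rem = 3,
                               delta_frac_nrem = 0.3, artifact_amp = 400) {
  vals <- c(emg_high = emg_high, theta_delta_rem = theta_delta_rem,
            delta_frac_nrem = delta_frac_nrem, artifact_amp = artifact_amp)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all thresholds must be finite and > 0")
  structure(as.list(vals), class = "staging_thresholds")
}

#' Derive staging thresholds from the data
#'
#' The EMG Wake threshold is the Otsu split of log(EMG RMS) over
#' artifact-free epochs (wake vs. sleep muscle tone is strongly bimodal);
#' the NREM delta-fraction threshold is the midpoint between the two class
#' means of the Otsu split of the delta/total fraction. Both are
#' deterministic functions of the data. If thresholds are already supplied
#' they are returned unchanged, and if the EMG distribution shows no usable
#' bimodal structure a warning is issued and `fallback` is used.
#'
#' @param features feature table from [compute_features()].
#' @param supplied optional `staging_thresholds` passed through verbatim.
#' @param theta_delta_rem REM ratio threshold (default 3).
#' @param min_epochs minimum artifact-free epochs required (default 100).
#' @param fallback EMG threshold used when the distribution is unimodal
#'   (default: 2x the median EMG RMS).
#' @param min_separation minimal log-EMG class-mean separation (natural log
#'   units) below which the distribution is declared unimodal.
#' @return a [staging_thresholds()].
#' @export
derive_thresholds <- function(features, supplied = NULL, theta_delta_rem = 3,
                              min_epochs = 100L, fallback = NULL,
                              min_separation = 0.5) {
  if (!is.null(supplied)) {
    stopifnot(inherits(supplied, "staging_thresholds"))
    return(supplied)
  }
  ok <- !features$artifact & is.finite(features$emg_rms) & features$emg_rms > 0
  if (sum(ok) < min_epochs)
    stop("need >= ", min_epochs, " artifact-free epochs to derive thresholds")
  o_emg <- otsu_threshold(log(features$emg_rms[ok]))
  if (isTRUE(o_emg$degenerate) || o_emg$separation < min_separation) {
    warning("EMG RMS distribution looks unimodal; using fallback threshold")
    emg_high <- fallback %||% (2 * stats::median(features$emg_rms[ok]))
  } else {
    emg_high <- exp(o_emg$threshold)
  }
  dfrac <- features$delta[ok] / features$total_power[ok]
  dfrac <- dfrac[is.finite(dfrac)]
  o_d <- otsu_threshold(dfrac)
  delta_frac_nrem <- (o_d$mean_lo + o_d$mean_hi) / 2
  if (!is.finite(delta_frac_nrem) || delta_frac_nrem <= 0)
    delta_frac_nrem <- 0.3
  staging_thresholds(emg_high = emg_high, theta_delta_rem = theta_delta_rem,
                     delta_frac_nrem = delta_frac_nrem,
                     artifact_amp = attr(features, "artifact_amp") %||% 400)
}

#' Hypnogram container
#'
#' @param states character vector over Wake/NREM/REM/Artifact (optionally
#'   Unscored).
#' @param epoch_len_s epoch length in seconds.
#' @return object of class `hypnogram`.
#' @export
hypnogram <- function(states, epoch_len_s = 10) {
  states <- as.character(states)
  if (length(states) == 0) stop("hypnogram must be non-empty")
  allowed <- c(SLEEP_STATES, "Artifact", "Unscored")
  if (!all(states %in% allowed))
    stop("states must be in: ", paste(allowed, collapse = ", "))
  structure(list(states = states, epoch_len_s = epoch_len_s),
            class = "hypnogram")
}

#' @export
print.hypnogram <- function(x, ...) {
  tab <- table(factor(x$states, levels = unique(c(SLEEP_STATES, "Artifact",
                                                  unique(x$states)))))
  cat(sprintf("<hypnogram> %d epochs x %g s\n", length(x$states),
              x$epoch_len_s))
  print(tab[tab > 0])
  invisible(x)
}

#' Rule-based epoch classification
#'
#' Fixed decision cascade per epoch, mirroring the published scoring
#' criteria:
#' 1. artifact flag set -> `Artifact`;
#' 2. EMG RMS >= `emg_high` -> `Wake` (heightened muscle activity
#'    dominates, whatever the spectrum);
#' 3. theta/delta power ratio > `theta_delta_rem` -> `REM` (theta
#'    predominance with low muscle tone);
#' 4. otherwise -> `NREM` (the residual low-EMG sleep class), unless
#'    `unscored = TRUE`, in which case low-EMG epochs whose delta fraction
#'    falls below `delta_frac_nrem` become `Unscored`.
#'
#' The classifier is stateless across epochs: no smoothing or contextual
#' transition rules are applied by default.
#'
#' @param features feature table from [compute_features()].
#' @param thresholds a [staging_thresholds()].
#' @param unscored if TRUE, route spectrally ambiguous low-EMG epochs to
#'   `Unscored` instead of NREM.
#' @param epoch_len_s epoch length recorded on the hypnogram.
#' @return a [hypnogram()].
#' @export
classify_epochs <- function(features, thresholds, unscored = FALSE,
                            epoch_len_s = 10) {
  stopifnot(inherits(thresholds, "staging_thresholds"))
  td <- features$theta / features$delta
  td[!is.finite(td)] <- Inf  # zero delta with any theta is maximal ratio
  td[features$theta == 0 & features$delta == 0] <- 0
  st <- rep("NREM", nrow(features))
  if (unscored) {
    dfrac <- features$delta / features$total_power
    st[is.finite(dfrac) & dfrac < thresholds$delta_frac_nrem] <- "Unscored"
  }
  st[td > thresholds$theta_delta_rem] <- "REM"
  st[features$emg_rms >= thresholds$emg_high] <- "Wake"
  st[features$artifact] <- "Artifact"
  hypnogram(st, epoch_len_s = epoch_len_s)
}
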