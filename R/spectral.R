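#' Standard EEG frequency bands
#'
#' Half-open intervals `[lo, hi)` in Hz so adjacent bands are disjoint.
#' Two theta presets are shipped because both are in common use for rodent
#' scoring: `theta` (6-9 Hz, the scoring-criterion band that drives the REM
#' theta/delta ratio) and `theta_wide` (4-8 Hz, often used for band-power
#' reporting). `swa` (slow-wave activity, 0.5-1 Hz) is nested inside delta.
#'
#' @return named list of `c(lo, hi)` pairs.
#' @export
sleep_bands <- function() {
  list(delta = c(0.5, 4), theta = c(6, 9), theta_wide = c(4, 8),
       alpha = c(8, 12), sigma = c(12, 16), beta = c(16, 24),
       swa = c(0.5, 1))
}

# One-sided Hann periodogram (power spectral density, unit^2/Hz) of each
# column of a samples-x-epochs matrix. No overlap, no averaging across
# epochs here. Normalised by the window energy U = sum(w^2) so that
# sum(psd) * df == sum((w*x)^2) / U (Parseval, including the Hann energy
# gain) and white noise has an unbiased flat density.
hann_periodogram <- function(xm, fs) {
  if (is.null(dim(xm))) xm <- matrix(xm, ncol = 1)
  N <- nrow(xm)
  w <- 0.5 * (1 - cos(2 * pi * (seq_len(N) - 1) / N))  # periodic Hann
  U <- sum(w^2)
  X <- stats::mvfft(xm * w)
  half <- N %/% 2
  k <- seq_len(half + 1L)               # DC .. Nyquist (N even)
  P <- Mod(X[k, , drop = FALSE])^2 / (fs * U)
  dbl <- 2:(if (N %% 2 == 0) half else half + 1L)
  P[dbl, ] <- 2 * P[dbl, ]
  list(freq = (k - 1) * fs / N, psd = P, df = fs / N)
}

# Integrate a psd matrix (bins x epochs) over a half-open band [lo, hi).
band_power_from_psd <- function(pg, lo, hi) {
  sel <- pg$freq >= lo & pg$freq < hi
  colSums(pg$psd[sel, , drop = FALSE]) * pg$df
}

#' State-specific relative power spectral density
#'
#' Averages the Hann periodograms (no overlap) of all artifact-free epochs
#' scored as `state` within the requested window, then normalises by total
#' power over the analysis range, yielding a relative PSD whose bins sum
#' to 1. This is the standard way group spectra are compared when absolute
#' EEG gain differs between animals.
#'
#' @param rec a [recording()].
#' @param hypnogram a [hypnogram()] aligned to `epochs`.
#' @param state one of Wake/NREM/REM.
#' @param epochs the epoch table from [epochize()] (provides phase labels).
#' @param window "24h", "light" or "dark".
#' @param range analysis range in Hz for the normalisation, default
#'   `c(0.5, 24)` (the widest band commonly reported); configurable up to
#'   just below Nyquist.
#' @return object of class `state_spectrum`: `freq`, `relative_psd`
#'   (fraction per bin over `range`), `n_epochs_averaged`, `state`,
#'   `window`, `empty` flag.
#' @export
state_psd <- function(rec, hypnogram, state, epochs, window = "24h",
                      range = c(0.5, 24)) {
  stopifnot(inherits(rec, "psg_recording"), inherits(hypnogram, "hypnogram"))
  window <- match.arg(window, c("24h", "light", "dark"))
  states <- hypnogram$states
  if (length(states) != nrow(epochs))
    stop("hypnogram and epoch table lengths differ")
  keep <- states == state & states != "Artifact"
  if (window != "24h") keep <- keep & epochs$phase == window
  out <- list(state = state, window = window, range = range)
  if (!any(keep)) {
    out$freq <- numeric(0); out$relative_psd <- numeric(0)
    out$n_epochs_averaged <- 0L; out$empty <- TRUE
    return(structure(out, class = "state_spectrum"))
  }
  xm <- epoch_matrix(rec, epochs, "eeg")[, keep, drop = FALSE]
  pg <- hann_periodogram(xm, rec$fs_hz)
  mean_psd <- rowMeans(pg$psd)
  sel <- pg$freq >= range[1] & pg$freq < range[2]
  tot <- sum(mean_psd[sel])
  out$freq <- pg$freq[sel]
  out$relative_psd <- if (tot > 0) mean_psd[sel] / tot else mean_psd[sel] * NA
  out$n_epochs_averaged <- sum(keep)
  out$empty <- FALSE
  structure(out, class = "state_spectrum")
}

#' @export
print.state_spectrum <- function(x, ...) {
  cat(sprintf("<state_spectrum> %s / %s: %d epochs averaged over %g-%g Hz\n",
              x$state, x$window, x$n_epochs_averaged, x$range[1], x$range[2]))
  invisible(x)
}

#' Relative band power
#'
#' Fraction of total power in a band: the integral of the (relative) PSD
#' over `[lo, hi)` divided by the integral over the analysis range.
#' Works on a [state_psd()] spectrum or on the feature table from
#' [compute_features()] (where it is band power / total power per epoch).
#'
#' @param x a `state_spectrum` or a feature data.frame.
#' @param band `c(lo, hi)` in Hz, or the name of a band in [sleep_bands()].
#' @return fraction in `[0, 1]` (vector, for a feature table); `NA` with a
#'   warning when total power is zero.
#' @export
relative_band_power <- function(x, band) UseMethod("relative_band_power")

resolve_band <- function(band) {
  if (is.character(band)) {
    b <- sleep_bands()[[band]]
    if (is.null(b)) stop("unknown band name: ", band)
    b
  } else as.numeric(band)
}

#' @export
relative_band_power.state_spectrum <- function(x, band) {
  band <- resolve_band(band)
  if (x$empty) return(NA_real_)
  tot <- sum(x$relative_psd)
  if (!is.finite(tot) || tot <= 0) {
    warning("zero total power: relative band power undefined")
    return(NA_real_)
  }
  sum(x$relative_psd[x$freq >= band[1] & x$freq < band[2]]) / tot
}

#' @export
relative_band_power.data.frame <- function(x, band) {
  band <- resolve_band(band)
  bands <- sleep_bands()
  hit <- vapply(bands, function(b) isTRUE(all.equal(b, band)), TRUE)
  if (!any(hit))
    stop("feature tables carry only the named bands in sleep_bands()")
  p <- x[[names(bands)[hit][1]]]
  tot <- x$total_power
  bad <- !is.na(tot) & tot <= 0
  if (any(bad)) warning(sum(bad), " epochs with zero total power -> NA")
  out <- p / tot
  out[bad] <- NA_real_
  out
}

#' Ratio between two band powers
#'
#' Simple power ratio (e.g. the theta/delta ratio used for the REM
#' criterion), computed per epoch from a feature table.
#'
#' @param features data.frame from [compute_features()].
#' @param num_band,den_band band names (columns of the feature table).
#' @return numeric vector; `NA` with a warning where the denominator is 0.
#' @export
band_ratio <- function(features, num_band = "theta", den_band = "delta") {
  num <- features[[num_band]]; den <- features[[den_band]]
  if (is.null(num) || is.null(den))
    stop("feature table lacks band column(s): ", num_band, ", ", den_band)
  bad <- !is.na(den) & den <= 0
  if (any(bad)) warning(sum(bad), " epochs with zero denominator power -> NA")
  out <- num / den
  out[bad] <- NA_real_
  out
}

#' Slow-wave activity (0.5-1 Hz) relative power
#'
#' SWA is the restorative low-frequency component of NREM sleep; this is
#' simply [relative_band_power()] over the 0.5-1 Hz sub-band of delta.
#'
#' @param spectrum a `state_spectrum`.
#' @return fraction in `[0, 1]`.
#' @export
swa_power <- function(spectrum) relative_band_power(spectrum, "swa")
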