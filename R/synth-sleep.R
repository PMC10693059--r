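#' Sleep states used throughout the package
#' @export
SLEEP_STATES <- c("Wake", "NREM", "REM")

#' Parameters for the synthetic sleep/EEG generator
#'
#' Defines a 3-state (Wake/NREM/REM) Markov chain over fixed-length epochs
#' together with per-state EEG spectral signatures and EMG tone. The default
#' spectral weights encode the canonical rodent polysomnography signatures:
#' NREM is delta-dominant with strong slow-wave (0.5-1 Hz) content, REM is
#' theta-dominant with a theta/delta power ratio far above the REM scoring
#' criterion, and Wake mixes high-frequency EEG with a 5-fold higher EMG
#' amplitude than either sleep state.
#'
#' @param transition_matrix 3x3 row-stochastic matrix over (Wake, NREM, REM).
#' @param epoch_len_s epoch length in seconds (default 10).
#' @param fs_hz sampling rate in Hz (default 500; the acquisition hardware
#'   band in such studies extends to 200 Hz so Nyquist must be >= 400 Hz).
#' @param spectral_weights 3x5 matrix (rows Wake/NREM/REM, columns
#'   swa/delta/theta/beta/background) of RMS amplitudes (arbitrary microvolt
#'   units) for the band-limited EEG components.
#' @param emg_amp named numeric, EMG white-noise RMS per state.
#' @param forbid_wake_to_rem if TRUE, require P(Wake -> REM) == 0.
#' @param seed integer seed; all randomness of the generators flows from it.
#' @return object of class `sleep_sim_params`.
#' @export
sleep_sim_params <- function(transition_matrix = NULL,
                             epoch_len_s = 10,
                             fs_hz = 500,
                             spectral_weights = NULL,
                             emg_amp = c(Wake = 5, NREM = 1, REM = 1),
                             forbid_wake_to_rem = FALSE,
                             seed = 1L) {
  if (is.null(transition_matrix)) {
    transition_matrix <- rbind(
      Wake = c(0.92, 0.08, 0.00),
      NREM = c(0.05, 0.93, 0.02),
      REM  = c(0.10, 0.05, 0.85))
    colnames(transition_matrix) <- SLEEP_STATES
  }
  transition_matrix <- as.matrix(transition_matrix)
  if (!all(dim(transition_matrix) == c(3L, 3L)))
    stop("transition_matrix must be 3x3 over (Wake, NREM, REM)")
  if (any(transition_matrix < 0) ||
      any(abs(rowSums(transition_matrix) - 1) > 1e-12))
    stop("transition_matrix rows must be non-negative and sum to 1 (+/- 1e-12)")
  if (forbid_wake_to_rem && transition_matrix[1, 3] != 0)
    stop("forbid_wake_to_rem is set but P(Wake -> REM) != 0")
  if (is.null(spectral_weights)) {
    spectral_weights <- rbind(
      Wake = c(swa = 0.2, delta = 0.5, theta = 1.0, beta = 1.5, background = 1.0),
      NREM = c(swa = 1.5, delta = 3.0, theta = 0.5, beta = 0.3, background = 0.5),
      REM  = c(swa = 0.1, delta = 0.4, theta = 3.0, beta = 0.5, background = 0.5))
  }
  spectral_weights <- as.matrix(spectral_weights)
  if (any(spectral_weights < 0) || any(emg_amp < 0))
    stop("all amplitudes must be >= 0")
  if (epoch_len_s <= 0 || fs_hz <= 0) stop("epoch_len_s and fs_hz must be > 0")
  structure(list(transition_matrix = transition_matrix,
                 epoch_len_s = epoch_len_s, fs_hz = fs_hz,
                 spectral_weights = spectral_weights,
                 emg_amp = emg_amp,
                 forbid_wake_to_rem = forbid_wake_to_rem,
                 seed = as.integer(seed)),
            class = "sleep_sim_params")
}

# Frequency supports (Hz) of the synthetic EEG components.
synth_component_bands <- function() {
  list(swa = c(0.5, 1), delta = c(0.5, 4), theta = c(6, 9), beta = c(16, 24))
}

#' Simulate a ground-truth hypnogram from the Markov sleep model
#'
#' @param params [sleep_sim_params()].
#' @param n_epochs number of epochs (>= 1).
#' @param init initial state (default "Wake").
#' @return character vector of states, class `state_sequence`, with the
#'   epoch length attached as attribute `epoch_len_s`.
#' @export
simulate_hypnogram <- function(params, n_epochs, init = "Wake") {
  stopifnot(inherits(params, "sleep_sim_params"))
  if (n_epochs < 1) stop("n_epochs must be >= 1")
  P <- params$transition_matrix
  init <- match.arg(init, SLEEP_STATES)
  with_seed(params$seed, {
    s <- integer(n_epochs)
    s[1] <- match(init, SLEEP_STATES)
    if (n_epochs > 1) {
      u <- stats::runif(n_epochs - 1)
      cp <- t(apply(P, 1, cumsum))
      for (i in 2:n_epochs) {
        s[i] <- findInterval(u[i - 1], cp[s[i - 1], ], left.open = TRUE) + 1L
      }
    }
    structure(SLEEP_STATES[s], epoch_len_s = params$epoch_len_s,
              class = "state_sequence")
  })
}

#' Estimate the Markov transition matrix from a state sequence
#'
#' Empirical transition probabilities by row-normalised transition counts.
#' Used to check that architecture metrics and the generator are mutually
#' consistent (parameter recovery), and to characterise fragmentation.
#'
#' @param states character vector of states (any labels; Artifact epochs, if
#'   present, are dropped before counting).
#' @return row-stochastic matrix over the states observed.
#' @export
estimate_transition_matrix <- function(states) {
  states <- as.character(states)
  states <- states[states != "Artifact"]
  if (length(states) < 2) stop("need >= 2 epochs to estimate transitions")
  lev <- intersect(c(SLEEP_STATES, sort(unique(states))), unique(states))
  from <- factor(states[-length(states)], levels = lev)
  to <- factor(states[-1], levels = lev)
  n <- table(from, to)
  p <- sweep(unclass(n), 1, pmax(rowSums(n), 1), "/")
  p
}

#' Synthesize an EEG/EMG recording from a hypnogram
#'
#' EEG is the sum of band-limited Gaussian noise components (slow-wave,
#' delta, theta, beta) plus a 1/f background, each generated once for the
#' whole recording and amplitude-modulated per epoch by the state's spectral
#' weights, so the trace is continuous across state transitions. EMG is
#' white noise scaled by the state's EMG amplitude. A pure-tone mode
#' replaces each noise component by a sinusoid at the band center for
#' analytic tests.
#'
#' @param states a `state_sequence` from [simulate_hypnogram()] (or any
#'   character vector of Wake/NREM/REM labels).
#' @param params [sleep_sim_params()].
#' @param mode "noise" (default) or "tones".
#' @param artifact_epochs optional integer epoch indices that receive large
#'   amplitude spikes (opt-in artifact injection).
#' @param artifact_amp spike amplitude for injected artifacts.
#' @param start_clock,light_on,light_off clock strings stored on the
#'   returned recording.
#' @return a [recording()] object.
#' @export
simulate_polysomnography <- function(states, params, mode = c("noise", "tones"),
                                     artifact_epochs = integer(0),
                                     artifact_amp = 50,
                                     start_clock = "07:00:00",
                                     light_on = "07:00", light_off = "19:00") {
  stopifnot(inherits(params, "sleep_sim_params"))
  mode <- match.arg(mode)
  states <- as.character(states)
  if (length(states) == 0) stop("states must be non-empty")
  if (!all(states %in% SLEEP_STATES)) stop("unknown states in sequence")
  bands <- synth_component_bands()
  if (params$fs_hz / 2 <= max(vapply(bands, max, 0)))
    stop("fs_hz too low for the requested spectral components (Nyquist)")
  spe <- params$epoch_len_s * params$fs_hz
  if (abs(spe - round(spe)) > 1e-9)
    stop("epoch_len_s * fs_hz must be an integer number of samples")
  spe <- as.integer(round(spe))
  n <- spe * length(states)
  si <- match(states, SLEEP_STATES)

  with_seed(params$seed + 1L, {
    eeg <- numeric(n)
    t <- (seq_len(n) - 1) / params$fs_hz
    for (b in names(bands)) {
      w <- params$spectral_weights[, b][si]
      if (all(w == 0)) next
      comp <- if (mode == "noise") {
        bandlimited_noise(n, params$fs_hz, bands[[b]][1], bands[[b]][2])
      } else {
        fc <- mean(bands[[b]])
        sqrt(2) * sin(2 * pi * fc * t)  # unit RMS tone
      }
      eeg <- eeg + comp * rep(w, each = spe)
    }
    wbg <- params$spectral_weights[, "background"][si]
    if (any(wbg > 0)) {
      bg <- if (mode == "noise") {
        one_over_f_noise(n, params$fs_hz)
      } else numeric(n)
      eeg <- eeg + bg * rep(wbg, each = spe)
    }
    emg <- stats::rnorm(n) * rep(params$emg_amp[states], each = spe)
    if (length(artifact_epochs)) {
      for (e in artifact_epochs) {
        at <- (e - 1L) * spe + seq_len(min(10L, spe))
        eeg[at] <- eeg[at] + artifact_amp * c(1, -1)
      }
    }
    recording(eeg = eeg, emg = emg, fs_hz = params$fs_hz,
              start_clock = start_clock, light_on = light_on,
              light_off = light_off)
  })
}
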