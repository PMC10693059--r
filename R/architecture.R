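#' Minutes in each vigilance state per analysis window
#'
#' Integer epoch accounting: minutes = epoch count x epoch length / 60, per
#' state, for the whole recording ("24h") and for the light and dark
#' phases. Sums over states equal the recording duration exactly, and
#' light + dark equal the whole-recording totals.
#'
#' @param hypnogram a [hypnogram()].
#' @param phases character vector of "light"/"dark" per epoch (the `phase`
#'   column of [epochize()]'s table).
#' @return data.frame `window, state, minutes` (tidy long format), covering
#'   every state present plus Wake/NREM/REM always.
#' @export
state_times <- function(hypnogram, phases) {
  stopifnot(inherits(hypnogram, "hypnogram"))
  states <- hypnogram$states
  if (length(states) != length(phases))
    stop("hypnogram and phase labels must be aligned")
  lev <- unique(c(SLEEP_STATES, "Artifact", states))
  f <- factor(states, levels = lev)
  per_min <- hypnogram$epoch_len_s / 60
  rows <- lapply(c("24h", "light", "dark"), function(w) {
    sel <- if (w == "24h") rep(TRUE, length(f)) else phases == w
    cnt <- table(f[sel])
    data.frame(window = w, state = names(cnt),
               minutes = as.numeric(cnt) * per_min,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Detect bouts (maximal same-state runs of at least `min_epochs`)
#'
#' A bout is a maximal run of at least `min_epochs` consecutive epochs of
#' one state (default 2, i.e. >= 20 s at 10-s epochs). Artifact epochs
#' never form bouts and break runs, since they are excluded epochs.
#'
#' @param hypnogram a [hypnogram()].
#' @param min_epochs minimum run length (default 2).
#' @return data.frame `state, start_epoch (1-based), n_epochs, duration_s`.
#' @export
detect_bouts <- function(hypnogram, min_epochs = 2L) {
  stopifnot(inherits(hypnogram, "hypnogram"))
  r <- rle(hypnogram$states)
  start <- cumsum(c(1L, r$lengths[-length(r$lengths)]))
  keep <- r$lengths >= min_epochs & !(r$values %in% c("Artifact", "Unscored"))
  out <- data.frame(state = r$values[keep], start_epoch = start[keep],
                    n_epochs = r$lengths[keep],
                    duration_s = r$lengths[keep] * hypnogram$epoch_len_s,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Bout count and mean length per state per window
#'
#' Mean bout length (s) and bout count per state for the whole recording
#' and per phase. A bout is assigned to the window containing its start
#' epoch. Empty cells report `NA` mean (missing, not zero) and count 0.
#'
#' @param bouts bout table from [detect_bouts()].
#' @param phases per-epoch "light"/"dark" labels.
#' @param states which states to report (default Wake/NREM/REM).
#' @return data.frame `window, state, n_bouts, mean_length_s`.
#' @export
bout_stats <- function(bouts, phases, states = SLEEP_STATES) {
  grid <- expand.grid(window = c("24h", "light", "dark"), state = states,
                      stringsAsFactors = FALSE)
  bw <- phases[bouts$start_epoch]
  rows <- mapply(function(w, s) {
    sel <- bouts$state == s & (w == "24h" | bw == w)
    c(n = sum(sel),
      mean = if (any(sel)) mean(bouts$duration_s[sel]) else NA_real_)
  }, grid$window, grid$state)
  data.frame(window = grid$window, state = grid$state,
             n_bouts = as.integer(rows["n", ]),
             mean_length_s = as.numeric(rows["mean", ]),
             stringsAsFactors = FALSE)
}

#' Hourly time-in-state fractions
#'
#' Fraction of each successive clock hour spent in `state` (epochs of the
#' state / epochs in the hour, all epochs counted in the denominator).
#'
#' @param hypnogram a [hypnogram()].
#' @param state state of interest.
#' @return data.frame `hour` (1-based, partial final hour included),
#'   `fraction` in `[0, 1]`.
#' @export
hourly_timecourse <- function(hypnogram, state = "NREM") {
  stopifnot(inherits(hypnogram, "hypnogram"))
  eph <- 3600 / hypnogram$epoch_len_s
  if (abs(eph - round(eph)) > 1e-9)
    stop("epoch length must divide one hour")
  idx <- ceiling(seq_along(hypnogram$states) / eph)
  frac <- tapply(hypnogram$states == state, idx, mean)
  data.frame(hour = as.integer(names(frac)), fraction = as.numeric(frac))
}

#' Full sleep-architecture summary
#'
#' Convenience wrapper combining [state_times()], [detect_bouts()] and
#' [bout_stats()] into one tidy table `window, state, metric, value`.
#'
#' @param hypnogram a [hypnogram()].
#' @param phases per-epoch phase labels.
#' @param min_epochs bout definition (default 2 epochs).
#' @return tidy long data.frame.
#' @export
architecture_summary <- function(hypnogram, phases, min_epochs = 2L) {
  tm <- state_times(hypnogram, phases)
  bs <- bout_stats(detect_bouts(hypnogram, min_epochs), phases)
  long <- rbind(
    data.frame(window = tm$window, state = tm$state, metric = "minutes",
               value = tm$minutes, stringsAsFactors = FALSE),
    data.frame(window = bs$window, state = bs$state, metric = "n_bouts",
               value = as.numeric(bs$n_bouts), stringsAsFactors = FALSE),
    data.frame(window = bs$window, state = bs$state, metric = "mean_bout_s",
               value = bs$mean_length_s, stringsAsFactors = FALSE))
  rownames(long) <- NULL
  long
}
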