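#' Simulate a motion-index trace with scheduled freezing
#'
#' Frames inside `freeze_windows` receive motion-index values strictly
#' below `threshold`, all other frames strictly above, so the true
#' below-threshold fraction is exactly the scheduled fraction.
#'
#' @param duration_s trace length in seconds.
#' @param fps frame rate (default 30).
#' @param freeze_windows list of `c(start_s, end_s)` half-open intervals.
#' @param threshold motion-index freezing threshold.
#' @param seed integer seed.
#' @return list: `trace` (data.frame `t_s, motion_index`), `fps`,
#'   `threshold`, `truth` (list with `freeze_fraction`).
#' @export
simulate_motion_trace <- function(duration_s = 100, fps = 30,
                                  freeze_windows = list(c(10, 40)),
                                  threshold = 10, seed = 1L) {
  with_seed(seed, {
    n <- round(duration_s * fps)
    t_s <- (seq_len(n) - 1) / fps
    frozen <- rep(FALSE, n)
    for (w in freeze_windows) frozen <- frozen | (t_s >= w[1] & t_s < w[2])
    mi <- numeric(n)
    mi[frozen] <- stats::runif(sum(frozen), 0, 0.5 * threshold)
    mi[!frozen] <- stats::runif(sum(!frozen), 1.5 * threshold, 5 * threshold)
    list(trace = data.frame(t_s = t_s, motion_index = mi), fps = fps,
         threshold = threshold,
         truth = list(freeze_fraction = mean(frozen)))
  })
}

#' Simulate a Y-maze arm-entry sequence
#'
#' Entries have no immediate repeats (as after re-entry collapsing). At
#' each step the arm completing a distinct-arm triad is chosen with
#' probability `p_alternate`, otherwise the arm repeating the
#' second-to-last entry. The planted alternation percentage is recomputed
#' from the emitted string by direct triad counting.
#'
#' @param n_entries number of entries (>= 3).
#' @param p_alternate probability of completing a distinct triad.
#' @param seed integer seed.
#' @return list: `entries` (character vector over A/B/C), `truth` (list
#'   with `alternation_pct`).
#' @export
simulate_entry_sequence <- function(n_entries = 30, p_alternate = 0.7,
                                    seed = 1L) {
  if (n_entries < 3) stop("n_entries must be >= 3")
  arms <- c("A", "B", "C")
  with_seed(seed, {
    e <- character(n_entries)
    e[1] <- sample(arms, 1)
    e[2] <- sample(setdiff(arms, e[1]), 1)
    for (i in 3:n_entries) {
      novel <- setdiff(arms, e[c(i - 2, i - 1)])
      e[i] <- if (stats::runif(1) < p_alternate) novel else e[i - 2]
    }
    tri <- vapply(3:n_entries, function(i) length(unique(e[(i - 2):i])) == 3L,
                  TRUE)
    list(entries = e, truth = list(alternation_pct = 100 * mean(tri)))
  })
}

#' Simulate an open-field track
#'
#' Random walk with fixed step length, reflected at the arena walls; a
#' stationary track has zero steps. True path length is accumulated from
#' the emitted positions.
#'
#' @param n_frames number of frames.
#' @param step_cm per-frame step length (0 = stationary).
#' @param arena_cm arena side (square), default 27.
#' @param fps frame rate.
#' @param start optional `c(x, y)` start (default arena center).
#' @param seed integer seed.
#' @return list: `track` (data.frame `t_s, x_cm, y_cm`), `arena_cm`,
#'   `truth` (list with `distance_cm`).
#' @export
simulate_track <- function(n_frames = 3000, step_cm = 1, arena_cm = 27,
                           fps = 30, start = NULL, seed = 1L) {
  with_seed(seed, {
    x <- numeric(n_frames); y <- numeric(n_frames)
    p <- start %||% c(arena_cm / 2, arena_cm / 2)
    x[1] <- p[1]; y[1] <- p[2]
    if (n_frames > 1) for (i in 2:n_frames) {
      ang <- stats::runif(1, 0, 2 * pi)
      nx <- x[i - 1] + step_cm * cos(ang)
      ny <- y[i - 1] + step_cm * sin(ang)
      nx <- min(max(nx, 0), arena_cm); ny <- min(max(ny, 0), arena_cm)
      x[i] <- nx; y[i] <- ny
    }
    list(track = data.frame(t_s = (seq_len(n_frames) - 1) / fps,
                            x_cm = x, y_cm = y),
         arena_cm = arena_cm,
         truth = list(distance_cm = sum(sqrt(diff(x)^2 + diff(y)^2))))
  })
}

#' Percentage of time spent freezing
#'
#' Frames with motion index strictly below `threshold` are grouped into
#' runs; runs lasting at least `min_freeze_s` count as freezing (default
#' 1 s — set 0 for a pure threshold reading). Freezing percentage is 100 x
#' freezing frames / total frames.
#'
#' @param motion_index numeric per-frame motion index, or the data.frame
#'   `t_s, motion_index` emitted by [simulate_motion_trace()].
#' @param fps frame rate, > 0.
#' @param threshold motion-index value below which no movement is
#'   detectable (a required calibration input).
#' @param min_freeze_s minimum run duration counted as freezing.
#' @return percentage in `[0, 100]`.
#' @export
freezing_percentage <- function(motion_index, fps, threshold,
                                min_freeze_s = 1) {
  if (is.data.frame(motion_index)) motion_index <- motion_index$motion_index
  if (fps <= 0) stop("fps must be > 0")
  n <- length(motion_index)
  if (n == 0) stop("empty trace")
  below <- motion_index < threshold
  r <- rle(below)
  ok <- r$values & (r$lengths / fps >= min_freeze_s)
  100 * sum(r$lengths[ok]) / n
}

#' Y-maze spontaneous alternation percentage
#'
#' Sliding windows of three consecutive entries; an alternation is a
#' window visiting three distinct arms. Percentage = 100 x alternating
#' windows / (N - 2). Immediate re-entries are collapsed on ingest (with a
#' message when any are dropped), matching the all-four-limbs entry
#' definition under which consecutive identical entries do not occur.
#'
#' @param entries character vector of arm labels.
#' @return percentage in `[0, 100]`; `NA` (flagged by a warning) for fewer
#'   than 3 entries after collapsing.
#' @export
alternation_percentage <- function(entries) {
  entries <- as.character(entries)
  if (length(entries) > 1) {
    dup <- c(FALSE, entries[-1] == entries[-length(entries)])
    if (any(dup)) {
      message("collapsed ", sum(dup), " immediate re-entries")
      entries <- entries[!dup]
    }
  }
  n <- length(entries)
  if (n < 3) {
    warning("fewer than 3 entries: alternation undefined")
    return(NA_real_)
  }
  a <- entries[1:(n - 2)]; b <- entries[2:(n - 1)]; c <- entries[3:n]
  tri <- a != b & b != c & a != c
  100 * sum(tri) / (n - 2)
}

#' Open-field locomotion metrics
#'
#' Total path length, and time in the center vs. border zone of a square
#' arena. The center zone is a concentric square whose side is
#' `center_fraction` of the arena side (default 0.5, i.e. 25% of the
#' area); center + border time always equals total time.
#'
#' @param track data.frame `x_cm, y_cm` (per frame; a `t_s` column is
#'   ignored), or the list from [simulate_track()].
#' @param arena_cm arena side in cm.
#' @param center_fraction side fraction of the center square.
#' @param fps frame rate for time conversion (default 30).
#' @return data.frame with one row: `distance_cm`, `center_s`, `border_s`,
#'   `center_pct`.
#' @export
open_field_metrics <- function(track, arena_cm = 27, center_fraction = 0.5,
                               fps = 30) {
  if (is.list(track) && !is.data.frame(track) && !is.null(track$track)) {
    arena_cm <- track$arena_cm %||% arena_cm
    track <- track$track
  }
  x <- track$x_cm; y <- track$y_cm
  if (is.null(x) || is.null(y)) stop("track needs x_cm and y_cm columns")
  dist <- sum(sqrt(diff(x)^2 + diff(y)^2))
  half_gap <- arena_cm * (1 - center_fraction) / 2
  inside <- x >= half_gap & x <= arena_cm - half_gap &
    y >= half_gap & y <= arena_cm - half_gap
  n <- length(x)
  data.frame(distance_cm = dist,
             center_s = sum(inside) / fps,
             border_s = sum(!inside) / fps,
             center_pct = 100 * mean(inside))
}
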