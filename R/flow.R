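#' Simulate a flow-cytometry sample as a mixture of populations
#'
#' Events are drawn from log-normal intensity mixtures per channel, one
#' component per population, emulating the brain single-cell suspensions
#' used for microglial phenotyping: resident microglia are CD11b-high /
#' CD45-low, infiltrating macrophages CD11b-high / CD45-high, and
#' lymphocytes CD11b-low. Within the microglia population a planted
#' fraction is Methoxy-positive (amyloid-phagocytosing) with a 10-fold
#' intensity separation. A paired control sample (`role = "control"`)
#' plants zero Methoxy-positive events, for control-anchored threshold
#' derivation.
#'
#' @param n_events number of events (0 gives an empty sample).
#' @param pop_fractions named fractions summing to 1 over
#'   `microglia`, `macrophage`, `lymphocyte`.
#' @param methoxy_pos_frac fraction of microglia planted Methoxy-positive
#'   (ignored for the control role).
#' @param channel_means optional matrix (populations x channels) of log10
#'   means to override the defaults.
#' @param channel_sds log10 sd (scalar or per channel).
#' @param role "experimental" or "control".
#' @param seed integer seed.
#' @return list of class `flow_sample`: `events` (data.frame of
#'   intensities for CD11b, CD45, Methoxy, CD36, CD68, CSF1R), `truth`
#'   (data.frame `population, methoxy_pos`), `role`, `n_events`.
#' @export
simulate_flow_sample <- function(n_events = 10000,
                                 pop_fractions = c(microglia = 0.6,
                                                   macrophage = 0.25,
                                                   lymphocyte = 0.15),
                                 methoxy_pos_frac = 0.2,
                                 channel_means = NULL,
                                 channel_sds = 0.15,
                                 role = c("experimental", "control"),
                                 seed = 1L) {
  role <- match.arg(role)
  if (abs(sum(pop_fractions) - 1) > 1e-9)
    stop("pop_fractions must sum to 1")
  channels <- c("CD11b", "CD45", "Methoxy", "CD36", "CD68", "CSF1R")
  if (is.null(channel_means)) {
    channel_means <- rbind(  # log10 intensity locations
      microglia  = c(CD11b = 4.0, CD45 = 2.5, Methoxy = 2.0, CD36 = 3.0,
                     CD68 = 3.0, CSF1R = 3.5),
      macrophage = c(CD11b = 4.0, CD45 = 3.8, Methoxy = 2.0, CD36 = 3.2,
                     CD68 = 3.4, CSF1R = 3.0),
      lymphocyte = c(CD11b = 2.0, CD45 = 3.2, Methoxy = 2.0, CD36 = 2.0,
                     CD68 = 2.0, CSF1R = 2.0))
  }
  sds <- rep(channel_sds, length.out = length(channels))
  names(sds) <- channels
  with_seed(seed, {
    if (n_events == 0) {
      ev <- as.data.frame(stats::setNames(
        replicate(length(channels), numeric(0), simplify = FALSE), channels))
      return(structure(list(events = ev,
                            truth = data.frame(population = character(0),
                                               methoxy_pos = logical(0)),
                            role = role, n_events = 0L),
                       class = "flow_sample"))
    }
    pop <- sample(names(pop_fractions), n_events, replace = TRUE,
                  prob = pop_fractions)
    ev <- matrix(0, n_events, length(channels),
                 dimnames = list(NULL, channels))
    for (p in rownames(channel_means)) {
      sel <- pop == p
      if (!any(sel)) next
      for (ch in channels)
        ev[sel, ch] <- 10^stats::rnorm(sum(sel), channel_means[p, ch], sds[ch])
    }
    mpos <- rep(FALSE, n_events)
    if (role == "experimental" && methoxy_pos_frac > 0) {
      mg <- which(pop == "microglia")
      mpos[mg] <- stats::runif(length(mg)) < methoxy_pos_frac
      base <- channel_means["microglia", "Methoxy"]
      ev[mpos, "Methoxy"] <-
        10^stats::rnorm(sum(mpos), base + 1, sds["Methoxy"])  # 10-fold up
    }
    structure(list(events = as.data.frame(ev),
                   truth = data.frame(population = pop, methoxy_pos = mpos),
                   role = role, n_events = n_events),
              class = "flow_sample")
  })
}

#' Monotone display/gating transform for flow intensities
#'
#' Per-channel `asinh(x / cofactor)` (default) or `log10`. Both are
#' strictly monotone, so event ordering is preserved for any cofactor and
#' gates can be stated on the transformed scale; `asinh` handles zero and
#' slightly negative values, while `log10` errors on non-positive input.
#'
#' @param events data.frame of intensities.
#' @param method "asinh" or "log10".
#' @param cofactor asinh cofactor, > 0 (default 150).
#' @param channels channels to transform (default all numeric columns).
#' @return data.frame of transformed intensities.
#' @export
flow_transform <- function(events, method = c("asinh", "log10"),
                           cofactor = 150, channels = NULL) {
  method <- match.arg(method)
  if (method == "asinh" && cofactor <= 0) stop("cofactor must be > 0")
  channels <- channels %||% names(events)[vapply(events, is.numeric, TRUE)]
  out <- events
  for (ch in channels) {
    x <- events[[ch]]
    if (method == "log10") {
      if (any(x <= 0, na.rm = TRUE))
        stop("log10 transform of non-positive intensities; use asinh")
      out[[ch]] <- log10(x)
    } else {
      out[[ch]] <- asinh(x / cofactor)
    }
  }
  attr(out, "transform") <- list(method = method, cofactor = cofactor,
                                 channels = channels)
  out
}

#' Invert [flow_transform()]
#' @param events transformed data.frame (carrying the `transform`
#'   attribute, or supply `method`/`cofactor`).
#' @inheritParams flow_transform
#' @return data.frame on the original intensity scale.
#' @export
flow_inverse <- function(events, method = NULL, cofactor = NULL,
                         channels = NULL) {
  tr <- attr(events, "transform")
  method <- method %||% tr$method
  cofactor <- cofactor %||% tr$cofactor
  channels <- channels %||% tr$channels %||%
    names(events)[vapply(events, is.numeric, TRUE)]
  out <- events
  for (ch in channels) {
    out[[ch]] <- if (method == "log10") 10^events[[ch]]
    else sinh(events[[ch]]) * cofactor
  }
  attr(out, "transform") <- NULL
  out
}

#' Rectangular microglia gate (CD11b-high, CD45-low)
#'
#' Keeps events with `CD11b >= cd11b_min` and
#' `cd45_bounds[1] <= CD45 <= cd45_bounds[2]`, with thresholds stated on
#' whatever scale `events` is on (use [flow_transform()] first for
#' transformed-scale gates). An empty gate is valid and flagged.
#'
#' @param events data.frame with CD11b and CD45 columns.
#' @param cd11b_min lower CD11b bound.
#' @param cd45_bounds `c(lo, hi)` CD45 bounds.
#' @return list of class `gate_result`: `index` (row indices gated in),
#'   `fraction` of parent, `definition`, `empty`.
#' @export
gate_microglia <- function(events, cd11b_min, cd45_bounds) {
  if (!all(c("CD11b", "CD45") %in% names(events)))
    stop("events must carry CD11b and CD45 channels")
  sel <- which(events$CD11b >= cd11b_min &
                 events$CD45 >= cd45_bounds[1] &
                 events$CD45 <= cd45_bounds[2])
  structure(list(index = sel,
                 fraction = if (nrow(events)) length(sel) / nrow(events)
                 else NA_real_,
                 definition = list(cd11b_min = cd11b_min,
                                   cd45_bounds = cd45_bounds),
                 empty = length(sel) == 0L),
            class = "gate_result")
}

#' Derive a positivity threshold from a control sample
#'
#' The control-anchored procedure: non-phagocytosing control animals (e.g.
#' wild-type mice injected with the dye) define the null intensity
#' distribution; the threshold is a high quantile (default 99.5%) of the
#' control channel within the parent gate, so fresh control draws exceed
#' it at a rate of about `1 - quantile`.
#'
#' @param control_events data.frame of control-sample events (already
#'   gated to the parent population, or supply `gate`).
#' @param channel channel name (e.g. "Methoxy").
#' @param quantile quantile level in `(0, 1]` (default 0.995); 1 gives the
#'   control maximum.
#' @param gate optional `gate_result` restricting the control events.
#' @param min_events minimum control events required (default 100).
#' @return numeric threshold (deterministic given the data).
#' @export
control_threshold <- function(control_events, channel, quantile = 0.995,
                              gate = NULL, min_events = 100L) {
  x <- control_events[[channel]]
  if (is.null(x)) stop("channel not found: ", channel)
  if (!is.null(gate)) x <- x[gate$index]
  x <- x[!is.na(x)]
  if (length(x) < min_events)
    stop("need >= ", min_events, " control events in the parent gate, got ",
         length(x))
  as.numeric(stats::quantile(x, quantile, type = 7, names = FALSE))
}

#' Percentage of events above a threshold
#'
#' Strict inequality (`> threshold`). Empty input yields `NA`, not 0.
#'
#' @param events data.frame (typically pre-gated).
#' @param channel channel name.
#' @param threshold positivity cutoff on the same scale as `events`.
#' @return percentage in `[0, 100]`, or `NA` for empty input.
#' @export
positive_fraction <- function(events, channel, threshold) {
  x <- events[[channel]]
  if (is.null(x)) stop("channel not found: ", channel)
  x <- x[!is.na(x)]
  if (length(x) == 0) return(NA_real_)
  100 * mean(x > threshold)
}

#' Median fluorescence intensity (MFI)
#'
#' Median of the channel on the untransformed intensity scale; empty input
#' yields `NA`.
#'
#' @inheritParams positive_fraction
#' @return median intensity or `NA`.
#' @export
median_intensity <- function(events, channel) {
  x <- events[[channel]]
  if (is.null(x)) stop("channel not found: ", channel)
  x <- x[!is.na(x)]
  if (length(x) == 0) return(NA_real_)
  stats::median(x)
}

# subset a flow event table by a gate
#' Apply a gate to an event table
#' @param events data.frame of events.
#' @param gate a `gate_result`.
#' @return the gated subset of `events`.
#' @export
apply_gate <- function(events, gate) events[gate$index, , drop = FALSE]
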