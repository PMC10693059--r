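#' FRET ratio -> calcium calibration parameters
#'
#' Parameters of the Hill relation for a ratiometric sensor such as
#' YC3.6: dissociation constant `Kd` (nM), Hill coefficient `hill_n`, and
#' the empirical ratio extremes `Rmin` (calcium-free) and `Rmax`
#' (saturated).
#'
#' @param Kd dissociation constant, nM, > 0.
#' @param hill_n Hill coefficient, > 0.
#' @param Rmin,Rmax empirical ratio extremes, `Rmin < Rmax`.
#' @return object of class `calibration_params`.
#' @export
calibration_params <- function(Kd, hill_n, Rmin, Rmax) {
  if (!(Kd > 0 && hill_n > 0)) stop("Kd and hill_n must be > 0")
  if (!(Rmin < Rmax)) stop("require Rmin < Rmax")
  structure(list(Kd = Kd, hill_n = hill_n, Rmin = Rmin, Rmax = Rmax),
            class = "calibration_params")
}

#' Synthetic YC3.6-like calibration profile
#'
#' The in-situ Kd, Hill coefficient, Rmin and Rmax of a given sensor and
#' preparation must come from a calibration experiment; none is a universal
#' constant. This named profile ships purely so examples and synthetic
#' tests run end-to-end; its values are chosen to be physiologically
#' plausible for a cameleon-type sensor (and, as a configuration check, a
#' ratio of 1.79 maps to roughly 235 nM under it).
#'
#' @return a [calibration_params()].
#' @export
yc36_synthetic_calibration <- function() {
  calibration_params(Kd = 232, hill_n = 1.7, Rmin = 1.0, Rmax = 2.6)
}

#' Background-corrected ROI ratio
#'
#' R = (mean YFP - YFP background) / (mean CFP - CFP background) over the
#' ROI pixels. When the corrected CFP signal is not positive the ROI is
#' excluded (NA with a reason code) rather than producing a division
#' blow-up. Multiplying both channels by a common gain leaves R unchanged.
#'
#' @param yfp_image,cfp_image co-registered numeric matrices, same shape.
#' @param roi logical mask (same shape) or integer pixel indices.
#' @param background_roi optional mask/indices of a dark region; its mean
#'   per channel is subtracted. Default: no background (0).
#' @return single numeric ratio; `NA` with attribute
#'   `exclusion_reason = "nonpositive_cfp"` when excluded.
#' @export
measure_roi_ratio <- function(yfp_image, cfp_image, roi,
                              background_roi = NULL) {
  if (!all(dim(yfp_image) == dim(cfp_image)))
    stop("YFP and CFP images must have the same shape")
  if (is.logical(roi)) roi <- which(roi)
  if (length(roi) == 0) stop("roi is empty")
  bg_y <- 0; bg_c <- 0
  if (!is.null(background_roi)) {
    if (is.logical(background_roi)) background_roi <- which(background_roi)
    bg_y <- mean(yfp_image[background_roi])
    bg_c <- mean(cfp_image[background_roi])
  }
  num <- mean(yfp_image[roi]) - bg_y
  den <- mean(cfp_image[roi]) - bg_c
  if (!is.finite(den) || den <= 0) {
    out <- NA_real_
    attr(out, "exclusion_reason") <- "nonpositive_cfp"
    return(out)
  }
  num / den
}

#' Measure ratios for every ROI in a label image
#'
#' @param yfp_image,cfp_image co-registered matrices.
#' @param label_image integer label matrix (0 = background); ROI `i` is the
#'   pixel set labelled `i`.
#' @param background_roi as in [measure_roi_ratio()].
#' @return data.frame `neurite_id, n_px, R, excluded, reason`.
#' @export
measure_label_ratios <- function(yfp_image, cfp_image, label_image,
                                 background_roi = NULL) {
  ids <- sort(setdiff(unique(as.integer(label_image)), 0L))
  rows <- lapply(ids, function(i) {
    r <- measure_roi_ratio(yfp_image, cfp_image, label_image == i,
                           background_roi)
    data.frame(neurite_id = i, n_px = sum(label_image == i), R = as.numeric(r),
               excluded = is.na(r),
               reason = attr(r, "exclusion_reason") %||% "",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Convert a FRET ratio to calcium concentration (Hill relation)
#'
#' `Ca = Kd * ((R - Rmin) / (Rmax - R))^(1/n)`, strictly increasing on
#' (Rmin, Rmax). Ratios at or below Rmin saturate to 0 nM; ratios at or
#' above Rmax are censored (returned as `NA`, flagged via the `censored`
#' attribute) rather than reported as infinite.
#'
#' @param R numeric ratio vector.
#' @param calib a [calibration_params()].
#' @return numeric vector of nM with logical attributes `saturated_low`
#'   and `censored`.
#' @export
ratio_to_calcium <- function(R, calib) {
  stopifnot(inherits(calib, "calibration_params"))
  lo <- R <= calib$Rmin
  hi <- R >= calib$Rmax
  mid <- !lo & !hi & !is.na(R)
  out <- rep(NA_real_, length(R))
  out[lo] <- 0
  out[mid] <- calib$Kd *
    ((R[mid] - calib$Rmin) / (calib$Rmax - R[mid]))^(1 / calib$hill_n)
  attr(out, "saturated_low") <- lo & !is.na(R)
  attr(out, "censored") <- hi & !is.na(R)
  out
}

#' Inverse Hill relation: calcium concentration to ratio
#'
#' `R = (Rmin + Rmax * (Ca/Kd)^n) / (1 + (Ca/Kd)^n)`; algebraic inverse of
#' [ratio_to_calcium()] on (Rmin, Rmax).
#'
#' @param ca_nM calcium concentrations in nM, >= 0.
#' @param calib a [calibration_params()].
#' @return numeric ratio vector.
#' @export
calcium_to_ratio <- function(ca_nM, calib) {
  stopifnot(inherits(calib, "calibration_params"))
  s <- (ca_nM / calib$Kd)^calib$hill_n
  (calib$Rmin + calib$Rmax * s) / (1 + s)
}

#' Calcium-overload threshold from control ratios
#'
#' tau = control mean + 2 x sample SD (n-1 denominator). The control group
#' is the nontransgenic population; neurites with R strictly above tau are
#' called overloaded, so for Gaussian controls about 2.3% of control
#' neurites fall beyond the threshold by construction.
#'
#' @param control_ratios numeric, >= 2 values.
#' @param n_sd number of SDs above the mean (default 2).
#' @return object of class `overload_threshold`: `control_mean`,
#'   `control_sd`, `n_sd`, `tau`.
#' @export
overload_threshold <- function(control_ratios, n_sd = 2) {
  control_ratios <- control_ratios[!is.na(control_ratios)]
  if (length(control_ratios) < 2)
    stop("need >= 2 control ratios")
  m <- mean(control_ratios); s <- stats::sd(control_ratios)
  structure(list(control_mean = m, control_sd = s, n_sd = n_sd,
                 tau = m + n_sd * s),
            class = "overload_threshold")
}

#' @export
print.overload_threshold <- function(x, ...) {
  cat(sprintf("<overload_threshold> tau = %.4f (control %.4f +/- %.4f, +%g SD)\n",
              x$tau, x$control_mean, x$control_sd, x$n_sd))
  invisible(x)
}

#' Percentage of neurites above the overload threshold
#'
#' Strict inequality: a neurite exactly at tau is not overloaded.
#'
#' @param ratios numeric ratios (NA dropped).
#' @param tau an [overload_threshold()] or a bare numeric cutoff.
#' @return percentage in `[0, 100]`.
#' @export
overload_fraction <- function(ratios, tau) {
  if (inherits(tau, "overload_threshold")) tau <- tau$tau
  ratios <- ratios[!is.na(ratios)]
  if (length(ratios) == 0) return(NA_real_)
  100 * mean(ratios > tau)
}

#' Ratio histogram counts
#'
#' @param ratios numeric vector (may be empty).
#' @param bin_edges strictly increasing edges; bins are `[e_i, e_{i+1})`,
#'   with the last bin closed on the right, so counts sum to the number of
#'   in-range ratios.
#' @return integer counts, length `length(bin_edges) - 1`.
#' @export
ratio_histogram <- function(ratios, bin_edges) {
  if (is.unsorted(bin_edges, strictly = TRUE))
    stop("bin_edges must be strictly increasing")
  nb <- length(bin_edges) - 1L
  ratios <- ratios[!is.na(ratios)]
  if (length(ratios) == 0) return(integer(nb))
  k <- findInterval(ratios, bin_edges, rightmost.closed = TRUE)
  tabulate(k[k >= 1 & k <= nb], nb)
}

#' Pseudocolor a ratio map over a reference intensity image
#'
#' HSV composition in the style of ratiometric calcium maps: the ratio,
#' clamped to `[rmin, rmax]`, is mapped linearly onto the hue range
#' `hue_range` (default blue -> red, a jet-like sweep) at full saturation;
#' the normalised reference image supplies the value channel, so pixels
#' with zero reference intensity are black whatever their ratio, and
#' pixels with `NA` ratio render as grayscale reference.
#'
#' @param ratio_map numeric matrix of ratios (NA = no ratio).
#' @param reference_intensity co-registered matrix supplying brightness.
#' @param rmin,rmax ratio extremes anchoring the hue scale.
#' @param hue_range hue endpoints in `[0, 1]` (default `c(2/3, 0)`).
#' @return array `nrow x ncol x 3` of RGB in `[0, 1]`.
#' @export
pseudocolor <- function(ratio_map, reference_intensity, rmin, rmax,
                        hue_range = c(2 / 3, 0)) {
  if (!all(dim(ratio_map) == dim(reference_intensity)))
    stop("ratio map and reference image must be co-registered (same shape)")
  if (!(rmin < rmax)) stop("require rmin < rmax")
  v <- reference_intensity
  vmax <- max(v, na.rm = TRUE)
  v <- if (vmax > 0) pmin(pmax(v / vmax, 0), 1) else v * 0
  r01 <- pmin(pmax((ratio_map - rmin) / (rmax - rmin), 0), 1)
  h <- hue_range[1] + r01 * (hue_range[2] - hue_range[1])
  s <- ifelse(is.na(ratio_map), 0, 1)
  h[is.na(h)] <- 0
  cols <- grDevices::hsv(h, s, v)
  rgb <- grDevices::col2rgb(cols) / 255
  array(c(rgb["red", ], rgb["green", ], rgb["blue", ]),
        dim = c(dim(ratio_map), 3L))
}
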