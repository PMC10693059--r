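#' Maximum intensity projection of a z-stack
#'
#' @param zstack 3-D array (z, y, x) or list of equally sized matrices.
#' @return matrix of per-pixel maxima over z.
#' @export
max_projection <- function(zstack) {
  if (is.list(zstack)) {
    if (length(zstack) == 0) stop("stack is empty")
    return(Reduce(pmax, zstack))
  }
  d <- dim(zstack)
  if (is.null(d) || length(d) != 3L) stop("zstack must be 3-D (z, y, x) or a list")
  apply(zstack, c(2, 3), max)
}

#' Segment plaques by thresholding + connected components
#'
#' Threshold the image (Otsu by default, or a fixed value), label connected
#' components (8-connectivity in 2-D, 26-connectivity in 3-D), remove
#' components smaller than `min_size_px`, and clip to an optional ROI mask.
#' The min-size filter suppresses shot noise; empty results are valid.
#'
#' @param image numeric matrix (2-D) or array (3-D).
#' @param method "otsu" or "fixed".
#' @param threshold intensity cutoff for `method = "fixed"`; pixels
#'   strictly above it are foreground.
#' @param min_size_px minimum component size in pixels/voxels (default 10).
#' @param roi_mask optional logical analysis region; labels outside are
#'   discarded (and the region defines the burden denominator).
#' @param pixel_size_um physical size of a pixel edge (scalar, or length-3
#'   for anisotropic 3-D voxels).
#' @return object of class `plaque_label_map`: `labels`, `sizes_px` (named
#'   per label), `pixel_size_um`, `roi_mask`, `threshold`, `ndim`.
#' @export
segment_plaques <- function(image, method = c("otsu", "fixed"),
                            threshold = NULL, min_size_px = 10L,
                            roi_mask = NULL, pixel_size_um = 1) {
  method <- match.arg(method)
  d <- dim(image)
  if (is.null(d) || !(length(d) %in% c(2L, 3L)))
    stop("image must be 2-D or 3-D")
  if (method == "fixed") {
    if (is.null(threshold)) stop("fixed method requires a threshold")
  } else {
    threshold <- otsu_threshold(as.numeric(image))$threshold
  }
  mask <- image > threshold
  if (!is.null(roi_mask)) {
    if (!all(dim(roi_mask) == d)) stop("roi_mask shape must match the image")
    mask <- mask & roi_mask
  }
  labels <- label_components(mask)
  nlab <- max(labels)
  sizes <- tabulate(labels[labels > 0], nbins = nlab)
  small <- which(sizes < min_size_px)
  if (length(small)) labels[labels %in% small] <- 0L
  # relabel consecutively
  keep <- sort(setdiff(unique(as.integer(labels)), 0L))
  relab <- integer(max(c(keep, 0L)))
  relab[keep] <- seq_along(keep)
  labels[labels > 0L] <- relab[labels[labels > 0L]]
  sizes <- tabulate(labels[labels > 0], nbins = length(keep))
  if (length(sizes)) names(sizes) <- seq_along(sizes)
  structure(list(labels = labels, sizes_px = sizes,
                 pixel_size_um = pixel_size_um, roi_mask = roi_mask,
                 threshold = threshold, ndim = length(d)),
            class = "plaque_label_map")
}

#' @export
print.plaque_label_map <- function(x, ...) {
  cat(sprintf("<plaque_label_map> %d-D, %d plaques, threshold %.4g\n",
              x$ndim, length(x$sizes_px), x$threshold))
  invisible(x)
}

#' Plaque count, mean size, and burden
#'
#' Burden = 100 x plaque-positive area (or volume) / ROI area (or volume).
#' The denominator is the ROI mask when one was supplied at segmentation,
#' otherwise the whole image. Sizes are reported in physical units
#' (um^2 for 2-D, um^3 for 3-D).
#'
#' @param map a [segment_plaques()] result.
#' @return data.frame with one row: `count`, `mean_size_um2` (or `_um3`),
#'   `total_size_um2`(`_um3`), `burden_pct`.
#' @export
plaque_summary <- function(map) {
  stopifnot(inherits(map, "plaque_label_map"))
  unit <- prod(rep(map$pixel_size_um, length.out = map$ndim))
  roi_px <- if (is.null(map$roi_mask)) length(map$labels) else
    sum(map$roi_mask)
  if (roi_px == 0) stop("ROI has zero area")
  count <- length(map$sizes_px)
  total <- sum(map$sizes_px) * unit
  out <- data.frame(
    count = count,
    mean_size = if (count > 0) total / count else NA_real_,
    total_size = total,
    burden_pct = 100 * sum(map$sizes_px) / roi_px)
  suff <- if (map$ndim == 2L) "um2" else "um3"
  names(out)[2:3] <- paste0(c("mean_size_", "total_size_"), suff)
  out
}

#' Read / write TIFF images and stacks
#'
#' Thin wrappers over the tiff package; stacks are returned as 3-D
#' (z, y, x) arrays. Intensities are kept as stored (no rescaling beyond
#' tiff's native `[0,1]` float convention).
#'
#' @param path file path.
#' @return `read_tiff_stack`: 3-D array; `write_tiff_stack` writes a 3-D
#'   array or matrix and returns the path invisibly.
#' @export
read_tiff_stack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- array(0, dim = c(length(pages), dim(pages[[1]])[1:2]))
  for (i in seq_along(pages)) {
    p <- pages[[i]]
    if (length(dim(p)) == 3L) p <- p[, , 1]
    arr[i, , ] <- p
  }
  arr
}

#' @rdname read_tiff_stack
#' @param x matrix or 3-D (z, y, x) array with values in `[0, 1]`.
#' @export
write_tiff_stack <- function(x, path) {
  if (is.matrix(x)) x <- array(x, dim = c(1L, dim(x)))
  pages <- lapply(seq_len(dim(x)[1]), function(z) x[z, , ])
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}
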