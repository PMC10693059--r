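`%||%` <- function(a, b) if (is.null(a)) b else a

#' Otsu threshold for a numeric vector
#'
#' Splits a 1-D sample into two classes by maximising the between-class
#' variance over a histogram of `nbins` equal-width bins. Used to separate
#' bimodal feature distributions (e.g. log EMG RMS of wake vs. sleep epochs)
#' without hand-tuned cutoffs.
#'
#' @param x numeric vector (NA dropped).
#' @param nbins number of histogram bins.
#' @return list with `threshold` (bin-edge value), `mean_lo`, `mean_hi`
#'   (class means) and `separation` (ratio of class means on the input
#'   scale, a crude bimodality diagnostic).
#' @export
otsu_threshold <- function(x, nbins = 256L) {
  x <- x[is.finite(x)]
  if (length(x) == 0L) stop("otsu_threshold: no finite values")
  if (diff(range(x)) == 0) {
    return(list(threshold = x[1], mean_lo = x[1], mean_hi = x[1],
                separation = 1, degenerate = TRUE))
  }
  edges <- seq(min(x), max(x), length.out = nbins + 1L)
  h <- tabulate(findInterval(x, edges, rightmost.closed = TRUE), nbins)
  p <- h / sum(h)
  centers <- (edges[-1] + edges[-(nbins + 1L)]) / 2
  omega <- cumsum(p)
  mu <- cumsum(p * centers)
  mu_t <- mu[nbins]
  # between-class variance for split after bin k
  denom <- omega * (1 - omega)
  sigma_b <- (mu_t * omega - mu)^2 / ifelse(denom > 0, denom, NA)
  k <- which.max(sigma_b)
  thr <- edges[k + 1L]
  lo <- x[x <= thr]; hi <- x[x > thr]
  list(threshold = thr,
       mean_lo = mean(lo), mean_hi = if (length(hi)) mean(hi) else mean(lo),
       separation = if (length(hi)) mean(hi) - mean(lo) else 0,
       degenerate = FALSE)
}

# Band-limited Gaussian noise, unit RMS, via frequency-domain brick-wall
# selection. Returns zeros if the band contains no FFT bin.
bandlimited_noise <- function(n, fs, lo, hi) {
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  f <- (seq_len(n) - 1) * fs / n
  f_fold <- pmin(f, fs - f)  # two-sided spectrum folded to [0, fs/2]
  keep <- f_fold >= lo & f_fold <= hi
  if (!any(keep)) return(numeric(n))
  X[!keep] <- 0
  y <- Re(stats::fft(X, inverse = TRUE)) / n
  r <- sqrt(mean(y^2))
  if (r == 0) return(y)
  y / r
}

# 1/f ("pink"-like) background noise, unit RMS, shaped as amplitude
# proportional to 1/sqrt(f) between f_lo and f_hi.
one_over_f_noise <- function(n, fs, f_lo = 0.5, f_hi = 50) {
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  f <- (seq_len(n) - 1) * fs / n
  f_fold <- pmin(f, fs - f)
  amp <- ifelse(f_fold >= f_lo & f_fold <= f_hi, 1 / sqrt(pmax(f_fold, f_lo)), 0)
  y <- Re(stats::fft(X * amp, inverse = TRUE)) / n
  r <- sqrt(mean(y^2))
  if (r == 0) return(y)
  y / r
}

# Parse "HH:MM" or "HH:MM:SS" to seconds after midnight.
parse_clock <- function(x) {
  if (is.numeric(x)) return(as.numeric(x) %% 86400)
  parts <- as.numeric(strsplit(x, ":", fixed = TRUE)[[1]])
  if (length(parts) == 2L) parts <- c(parts, 0)
  if (length(parts) != 3L || anyNA(parts))
    stop("clock times must be 'HH:MM' or 'HH:MM:SS', got: ", x)
  (parts[1] * 3600 + parts[2] * 60 + parts[3]) %% 86400
}

format_clock <- function(sec) {
  sec <- round(sec) %% 86400
  sprintf("%02d:%02d:%02d", sec %/% 3600, (sec %% 3600) %/% 60, sec %% 60)
}

#' Connected-component labelling of a binary mask
#'
#' Labels foreground regions of a 2-D matrix (8-connectivity) or 3-D array
#' (26-connectivity). Edges between neighbouring foreground cells are built
#' by vectorised array shifts and components are resolved with
#' [igraph::components()].
#'
#' @param mask logical (or 0/1) matrix or 3-D array.
#' @return integer array of the same dimension; 0 = background, regions
#'   labelled 1..k in order of their first (column-major) pixel.
#' @export
label_components <- function(mask) {
  d <- dim(mask)
  if (is.null(d) || !(length(d) %in% c(2L, 3L)))
    stop("mask must be a 2-D matrix or 3-D array")
  mask <- array(as.logical(mask), dim = d)
  mask[is.na(mask)] <- FALSE
  fg <- which(mask)
  labels <- array(0L, dim = d)
  if (length(fg) == 0L) return(labels)

  offsets <- half_neighbourhood(length(d))
  idx <- array(seq_along(mask), dim = d)
  edges <- vector("list", nrow(offsets))
  for (i in seq_len(nrow(offsets))) {
    off <- offsets[i, ]
    a <- slab(idx, off, lead = TRUE)
    b <- slab(idx, off, lead = FALSE)
    both <- mask[a] & mask[b]
    edges[[i]] <- cbind(a[both], b[both])
  }
  edges <- do.call(rbind, edges)
  # map linear indices -> vertex ids over foreground only
  vid <- integer(length(mask))
  vid[fg] <- seq_along(fg)
  g <- igraph::graph_from_edgelist(
    cbind(vid[edges[, 1]], vid[edges[, 2]]), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(fg) - igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  # relabel components 1..k in order of first appearance (column-major)
  first_seen <- !duplicated(comp)
  relab <- integer(max(comp))
  relab[comp[first_seen]] <- seq_len(sum(first_seen))
  labels[fg] <- relab[comp]
  labels
}

# Half-neighbourhood offsets (one of each +/- pair) for 2-D (8-conn) or
# 3-D (26-conn) connectivity.
half_neighbourhood <- function(ndim) {
  if (ndim == 2L) {
    g <- expand.grid(dx = -1:1, dy = -1:1)
  } else {
    g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  }
  g <- as.matrix(g)
  keep <- apply(g, 1, function(o) {
    nz <- which(o != 0)
    length(nz) > 0 && o[nz[1]] > 0  # lexicographically positive half
  })
  g[keep, , drop = FALSE]
}

# Index slab for an offset: linear indices of cells having a neighbour at
# +offset (lead = TRUE) or the corresponding neighbour cells (lead = FALSE).
slab <- function(idx, off, lead = TRUE) {
  d <- dim(idx)
  args <- lapply(seq_along(d), function(k) {
    o <- off[k]
    if (o > 0) {
      if (lead) seq_len(d[k] - o) else (1 + o):d[k]
    } else if (o < 0) {
      if (lead) (1 - o):d[k] else seq_len(d[k] + o)
    } else seq_len(d[k])
  })
  do.call(`[`, c(list(idx), args))
}

# Deterministic per-call RNG scope: runs expr with the given seed without
# disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}
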