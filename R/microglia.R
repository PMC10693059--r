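#' Soma set container / identity ingestion path
#'
#' Accepts an externally supplied soma point list verbatim (the equivalent
#' of importing spot coordinates from a 3-D rendering tool).
#'
#' @param points data.frame with columns `cell_id, z_um, y_um, x_um`
#'   (and optionally `soma_volume_um3`).
#' @return object of class `soma_set` (a validated data.frame).
#' @export
soma_set <- function(points) {
  need <- c("cell_id", "z_um", "y_um", "x_um")
  if (!all(need %in% names(points)))
    stop("soma points need columns: ", paste(need, collapse = ", "))
  structure(as.data.frame(points), class = c("soma_set", "data.frame"))
}

# separable Gaussian blur along each axis of a 3-D array; sigma in voxels
gauss_blur_3d <- function(vol, sigma_vox) {
  d <- dim(vol)
  for (k in 1:3) {
    s <- sigma_vox[k]
    if (s <= 0) next
    half <- max(1L, ceiling(3 * s))
    kern <- stats::dnorm(-half:half, sd = s)
    kern <- kern / sum(kern)
    vol <- apply_along(vol, k, function(v)
      stats::filter(c(rev(v[seq_len(half)]), v, rev(v[length(v) - seq_len(half) + 1])),
                    kern, sides = 2)[(half + 1):(half + length(v))])
  }
  vol
}

# apply a vector function along axis k of a 3-D array
apply_along <- function(vol, k, f) {
  d <- dim(vol)
  perm <- c(k, setdiff(1:3, k))
  v <- aperm(vol, perm)
  m <- matrix(v, nrow = d[k])
  m <- apply(m, 2, f)
  aperm(array(m, dim = d[perm]), order(perm))
}

#' Detect microglial somata in a 3-D volume
#'
#' Scale-space blob detection: the volume is smoothed with an anisotropic
#' Gaussian at the expected soma scale (`sigma_um`, converted to voxels per
#' axis — voxel sizes are mandatory, anisotropy is never ignored) and local
#' maxima of the smoothed response above `threshold_rel` x the global
#' maximum are reported as somata. Alternatively pass a point table, which
#' is returned unchanged via [soma_set()].
#'
#' @param volume 3-D numeric array (z, y, x), or a data.frame of points.
#' @param voxel_size_um voxel size `c(z, y, x)` in micrometres (mandatory
#'   for volumes).
#' @param sigma_um soma scale in micrometres (default 4).
#' @param threshold_rel detection threshold relative to the maximum
#'   smoothed response (default 0.3).
#' @return a [soma_set()] with centroid coordinates in micrometres
#'   (voxel i maps to `(i - 1) * voxel_size`).
#' @export
detect_somata <- function(volume, voxel_size_um = NULL, sigma_um = 4,
                          threshold_rel = 0.3) {
  if (is.data.frame(volume)) return(soma_set(volume))
  d <- dim(volume)
  if (is.null(d) || length(d) != 3L) stop("volume must be 3-D (z, y, x)")
  if (is.null(voxel_size_um) || length(voxel_size_um) != 3L ||
      any(voxel_size_um <= 0))
    stop("voxel_size_um (z, y, x) is mandatory and must be > 0")
  if (max(volume) <= 0)
    return(soma_set(data.frame(cell_id = integer(0), z_um = numeric(0),
                               y_um = numeric(0), x_um = numeric(0))))
  sm <- gauss_blur_3d(volume, sigma_um / voxel_size_um)
  thr <- threshold_rel * max(sm)
  # local maxima over the 26-neighbourhood
  is_max <- sm >= thr
  for (off in split(neighbour_offsets_26(), seq_len(26))) {
    o <- unlist(off)
    shifted <- shift_array(sm, o, fill = -Inf)
    is_max <- is_max & (sm >= shifted)
    if (!any(is_max)) break
  }
  # border voxels have no full neighbourhood; exclude them from peaks
  if (all(d >= 3L)) {
    is_max[c(1L, d[1]), , ] <- FALSE
    is_max[, c(1L, d[2]), ] <- FALSE
    is_max[, , c(1L, d[3])] <- FALSE
  }
  pk <- which(is_max, arr.ind = TRUE)
  if (nrow(pk) > 1) {  # merge peaks closer than sigma (plateau ties)
    ord <- order(-sm[is_max])
    pk <- pk[ord, , drop = FALSE]
    keep <- rep(TRUE, nrow(pk))
    pum <- sweep(pk - 1, 2, voxel_size_um, "*")
    for (i in seq_len(nrow(pk))) {
      if (!keep[i]) next
      if (i < nrow(pk)) {
        later <- (i + 1):nrow(pk)
        dd <- sqrt(rowSums((pum[later, , drop = FALSE] -
                              matrix(pum[i, ], length(later), 3,
                                     byrow = TRUE))^2))
        keep[later][dd < sigma_um] <- FALSE
      }
    }
    pk <- pk[keep, , drop = FALSE]
  }
  soma_set(data.frame(cell_id = seq_len(nrow(pk)),
                      z_um = (pk[, 1] - 1) * voxel_size_um[1],
                      y_um = (pk[, 2] - 1) * voxel_size_um[2],
                      x_um = (pk[, 3] - 1) * voxel_size_um[3]))
}

neighbour_offsets_26 <- function() {
  g <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  as.data.frame(g[rowSums(abs(g)) > 0, ])
}

shift_array <- function(a, off, fill = 0) {
  d <- dim(a)
  out <- array(fill, dim = d)
  src <- dst <- vector("list", 3)
  for (k in 1:3) {
    o <- off[k]
    if (o >= 0) { dst[[k]] <- seq_len(d[k] - o); src[[k]] <- (1 + o):d[k] }
    else { dst[[k]] <- (1 - o):d[k]; src[[k]] <- seq_len(d[k] + o) }
    if (d[k] - abs(o) <= 0) return(out)
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

#' Distance from each soma to the nearest plaque voxel, in 3-D
#'
#' Exact Euclidean distance from each soma centroid to the nearest
#' plaque-positive voxel center, with anisotropic voxel scaling applied
#' (voxel i sits at `(i - 1) * voxel_size`). With no plaque voxels, all
#' distances are `Inf` and the result carries `no_plaques = TRUE`.
#'
#' @param somata a [soma_set()] (or plain data.frame of points).
#' @param plaque_mask logical/integer 3-D array; non-zero voxels are
#'   plaque. Integer labels are retained to attribute each cell to its
#'   nearest plaque.
#' @param voxel_size_um voxel size `c(z, y, x)` in micrometres.
#' @param radius_um association radius (default 25).
#' @return data.frame of class `cell_plaque_clustering`: `cell_id,
#'   distance_um, nearest_plaque, associated` (distance <= radius).
#' @export
distance_to_plaques <- function(somata, plaque_mask, voxel_size_um,
                                radius_um = 25) {
  somata <- soma_set(somata)
  d <- dim(plaque_mask)
  if (is.null(d) || length(d) != 3L) stop("plaque_mask must be 3-D")
  if (length(voxel_size_um) != 3L || any(voxel_size_um <= 0))
    stop("voxel_size_um (z, y, x) must be > 0")
  lab <- if (is.logical(plaque_mask)) (plaque_mask) * 1L else
    as.integer(plaque_mask)
  lab <- array(lab, dim = d)
  pv <- which(lab > 0, arr.ind = TRUE)
  n <- nrow(somata)
  if (nrow(pv) == 0) {
    out <- data.frame(cell_id = somata$cell_id,
                      distance_um = rep(Inf, n),
                      nearest_plaque = rep(NA_integer_, n),
                      associated = rep(FALSE, n))
    attr(out, "no_plaques") <- TRUE
    class(out) <- c("cell_plaque_clustering", "data.frame")
    return(out)
  }
  pz <- (pv[, 1] - 1) * voxel_size_um[1]
  py <- (pv[, 2] - 1) * voxel_size_um[2]
  px <- (pv[, 3] - 1) * voxel_size_um[3]
  plab <- lab[pv]
  dist <- numeric(n); nearest <- integer(n)
  for (i in seq_len(n)) {
    d2 <- (pz - somata$z_um[i])^2 + (py - somata$y_um[i])^2 +
      (px - somata$x_um[i])^2
    j <- which.min(d2)
    dist[i] <- sqrt(d2[j]); nearest[i] <- plab[j]
  }
  out <- data.frame(cell_id = somata$cell_id, distance_um = dist,
                    nearest_plaque = nearest,
                    associated = dist <= radius_um)
  attr(out, "no_plaques") <- FALSE
  attr(out, "radius_um") <- radius_um
  class(out) <- c("cell_plaque_clustering", "data.frame")
  out
}

#' Plaque-associated microglia counts
#'
#' Cells whose nearest-plaque-surface distance is at most `radius_um`
#' (inclusive, default 25) are plaque-associated; cells beyond the
#' radius are excluded. Reports the total and the per-plaque counts.
#'
#' @param clustering result of [distance_to_plaques()].
#' @param radius_um association radius in micrometres (default 25).
#' @return list: `total` (count), `fraction` of cells associated,
#'   `per_plaque` (named integer vector over plaque labels).
#' @export
associated_count <- function(clustering, radius_um = 25) {
  assoc <- clustering$distance_um <= radius_um
  per <- table(factor(clustering$nearest_plaque[assoc]))
  list(total = sum(assoc),
       fraction = if (nrow(clustering)) mean(assoc) else NA_real_,
       per_plaque = stats::setNames(as.integer(per), names(per)))
}

#' Microglial process length by geodesic centerline tracing
#'
#' Approximates filament length from a binary per-cell mask: foreground
#' voxels form a 26-connected graph with physical edge lengths; within each
#' cell the soma is taken at the thickest voxel (peak of an erosion-depth
#' map) and centerline branches are extracted greedily — repeatedly route
#' the geodesically farthest voxel to the current centerline through its
#' shortest path — while the residual distance exceeds a thickness-aware
#' floor (`max(min_branch_um, 2.5 x soma erosion depth)`). A compact blob
#' therefore reports ~0 length, while thin processes are traced tip-to-tip.
#' Connected fragments smaller than `fragment_floor_vox` voxels are
#' ignored.
#'
#' @param cell_mask logical 3-D array, a single cell's segmentation (may
#'   contain several fragments).
#' @param voxel_size_um voxel size `c(z, y, x)` in micrometres.
#' @param min_branch_um minimum branch length counted (default 5).
#' @param fragment_floor_vox ignore fragments below this size (default 10).
#' @return list: `length_um` (total centerline length),
#'   `soma_volume_um3` (volume of voxels at >= 50% of peak erosion depth,
#'   a crude soma estimate), `n_branches`, `n_fragments_ignored`.
#' @export
process_length <- function(cell_mask, voxel_size_um, min_branch_um = 5,
                           fragment_floor_vox = 10L) {
  d <- dim(cell_mask)
  if (is.null(d) || length(d) != 3L) stop("cell_mask must be 3-D")
  if (length(voxel_size_um) != 3L || any(voxel_size_um <= 0))
    stop("voxel_size_um (z, y, x) must be > 0")
  mask <- array(as.logical(cell_mask), dim = d)
  labels <- label_components(mask)
  sizes <- tabulate(labels[labels > 0], nbins = max(labels))
  total_len <- 0; n_branch <- 0L; ignored <- 0L; soma_vol <- 0
  depth <- erosion_depth(mask)  # in 26-conn erosion steps
  for (comp in seq_along(sizes)) {
    if (sizes[comp] < fragment_floor_vox) { ignored <- ignored + 1L; next }
    vox <- which(labels == comp)
    res <- trace_centerline(vox, d, voxel_size_um, depth, min_branch_um)
    total_len <- total_len + res$length_um
    n_branch <- n_branch + res$n_branches
    soma_vol <- soma_vol + res$soma_volume_um3
  }
  list(length_um = total_len, soma_volume_um3 = soma_vol,
       n_branches = n_branch, n_fragments_ignored = ignored)
}

# erosion-depth map: number of 26-connected erosion passes a voxel
# survives (1 = surface). Proxy for local thickness in voxel units.
erosion_depth <- function(mask) {
  depth <- array(0L, dim = dim(mask))
  cur <- mask
  k <- 0L
  offs <- neighbour_offsets_26()
  while (any(cur)) {
    k <- k + 1L
    depth[cur] <- k
    nxt <- cur
    for (i in seq_len(nrow(offs)))
      nxt <- nxt & shift_array(cur, as.numeric(offs[i, ]), fill = FALSE)
    if (identical(nxt, cur)) break
    cur <- nxt
  }
  depth
}

trace_centerline <- function(vox, d, vs, depth, min_branch_um) {
  # graph over the component's voxels, 26-conn, physical edge weights
  ai <- arrayInd(vox, d)
  id <- integer(prod(d)); id[vox] <- seq_along(vox)
  offs <- as.matrix(neighbour_offsets_26())
  offs <- offs[apply(offs, 1, function(o) {
    nz <- which(o != 0); o[nz[1]] > 0 }), , drop = FALSE]  # half set
  ef <- integer(0); et <- integer(0); ew <- numeric(0)
  for (i in seq_len(nrow(offs))) {
    o <- offs[i, ]
    nb <- sweep(ai, 2, o, "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3]
    lin <- (nb[ok, 3] - 1) * d[1] * d[2] + (nb[ok, 2] - 1) * d[1] + nb[ok, 1]
    hit <- id[lin] > 0
    ef <- c(ef, which(ok)[hit])
    et <- c(et, id[lin[hit]])
    ew <- c(ew, rep(sqrt(sum((o * vs)^2)), sum(hit)))
  }
  g <- igraph::make_empty_graph(n = length(vox), directed = FALSE)
  g <- igraph::add_edges(g, rbind(ef, et))
  igraph::E(g)$weight <- ew
  dep <- depth[vox]
  soma <- which.max(dep)
  # erosion depth is a Chebyshev inradius, which understates the Euclidean
  # radius by up to sqrt(3); 2.5x gives headroom so compact blobs yield no
  # branches while thin processes (depth 1-2) are unaffected
  soma_depth_um <- max(dep) * min(vs)
  floor_um <- max(min_branch_um, 2.5 * soma_depth_um)
  soma_vol <- sum(dep >= 0.5 * max(dep)) * prod(vs)
  skel <- soma
  total <- 0; nb <- 0L
  repeat {
    dv <- igraph::distances(g, v = skel)
    dmin <- apply(dv, 2, min)
    far <- which.max(dmin)
    if (!is.finite(dmin[far]) || dmin[far] <= floor_um) break
    src <- skel[which.min(dv[, far])]
    path <- igraph::shortest_paths(g, from = src, to = far,
                                   output = "vpath")$vpath[[1]]
    total <- total + dmin[far]
    nb <- nb + 1L
    skel <- union(skel, as.integer(path))
    if (nb > 64L) break  # safety valve
  }
  list(length_um = total, n_branches = nb, soma_volume_um3 = soma_vol)
}
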