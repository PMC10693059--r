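#' Parameters for the synthetic FRET neurite generator
#'
#' Emulates the bimodal neurite YFP/CFP ratio distribution seen in
#' amyloidosis models: a healthy subpopulation around `ratio_normal` and an
#' overloaded subpopulation around `ratio_overload`. Defaults place the
#' overloaded mean 6 control SDs above the healthy mean so recovery against
#' a mean + 2 SD threshold is well posed.
#'
#' @param n_neurites number of neurites to render.
#' @param frac_overload fraction in `[0, 1]` drawn from the overloaded
#'   component.
#' @param ratio_normal,ratio_overload `c(mean, sd)` of the two ratio
#'   components; `ratio_overload[1]` must exceed `ratio_normal[1]`.
#' @param noise photon-noise scale: Gaussian sd per pixel is
#'   `noise * sqrt(intensity)` (0 = noiseless).
#' @param image_size image side in pixels.
#' @param cfp_level base CFP intensity of a neurite pixel.
#' @param seed integer seed.
#' @return object of class `fret_sim_params`.
#' @export
fret_sim_params <- function(n_neurites = 200, frac_overload = 0.15,
                            ratio_normal = c(1.50, 0.10),
                            ratio_overload = c(2.10, 0.10),
                            noise = 0.5, image_size = 256,
                            cfp_level = 200, seed = 1L) {
  if (frac_overload < 0 || frac_overload > 1)
    stop("frac_overload must be in [0, 1]")
  if (ratio_overload[1] <= ratio_normal[1])
    stop("ratio_overload mean must exceed ratio_normal mean")
  if (noise < 0 || image_size < 8 || n_neurites < 0) stop("invalid parameters")
  structure(list(n_neurites = n_neurites, frac_overload = frac_overload,
                 ratio_normal = ratio_normal, ratio_overload = ratio_overload,
                 noise = noise, image_size = image_size,
                 cfp_level = cfp_level, seed = as.integer(seed)),
            class = "fret_sim_params")
}

#' Render a synthetic YFP/CFP image pair with per-neurite ground truth
#'
#' Neurites are curvilinear random-walk strokes; each owns a disjoint pixel
#' set (pixels already claimed by an earlier neurite are skipped, so ROIs
#' never overlap). Within a neurite, CFP is constant and YFP = true ratio x
#' CFP before noise, so the noiseless ROI-mean ratio equals the planted
#' ratio exactly.
#'
#' @param params a [fret_sim_params()].
#' @return list: `yfp`, `cfp` (matrices), `labels` (integer ROI label
#'   matrix), `truth` (data.frame `neurite_id, true_ratio, overload,
#'   n_px`).
#' @export
simulate_fret_pair <- function(params) {
  stopifnot(inherits(params, "fret_sim_params"))
  sz <- params$image_size
  with_seed(params$seed, {
    yfp <- matrix(0, sz, sz); cfp <- matrix(0, sz, sz)
    labels <- matrix(0L, sz, sz)
    n <- params$n_neurites
    overload <- if (n > 0) stats::runif(n) < params$frac_overload else logical(0)
    mu <- ifelse(overload, params$ratio_overload[1], params$ratio_normal[1])
    sdv <- ifelse(overload, params$ratio_overload[2], params$ratio_normal[2])
    ratio <- stats::rnorm(n, mu, sdv)
    ratio <- pmax(ratio, 0.05)
    npx <- integer(n)
    for (i in seq_len(n)) {
      len <- sample(15:40, 1)
      y <- stats::runif(1, 3, sz - 2); x <- stats::runif(1, 3, sz - 2)
      ang <- stats::runif(1, 0, 2 * pi)
      for (s in seq_len(len)) {
        ang <- ang + stats::rnorm(1, 0, 0.25)
        y <- min(max(y + sin(ang), 1), sz); x <- min(max(x + cos(ang), 1), sz)
        ri <- round(y); ci <- round(x)
        if (labels[ri, ci] == 0L) {
          labels[ri, ci] <- i
          cfp[ri, ci] <- params$cfp_level
          yfp[ri, ci] <- ratio[i] * params$cfp_level
          npx[i] <- npx[i] + 1L
        }
      }
    }
    if (params$noise > 0) {
      yfp <- yfp + stats::rnorm(sz * sz, 0, params$noise * sqrt(pmax(yfp, 0) + 1))
      cfp <- cfp + stats::rnorm(sz * sz, 0, params$noise * sqrt(pmax(cfp, 0) + 1))
    }
    keep <- npx > 0
    list(yfp = yfp, cfp = cfp, labels = labels,
         truth = data.frame(neurite_id = seq_len(n), true_ratio = ratio,
                            overload = overload, n_px = npx)[keep, ,
                                                            drop = FALSE])
  })
}

#' Synthetic 2-D plaque image with known burden
#'
#' Bright disks on a dark background; by default disk centers are placed
#' with rejection sampling so disks do not overlap, in which case the true
#' burden also matches the analytic `sum(pi r^2)` up to pixelation.
#' The truth mask counts the pixel-union of the disks, so burden truth is
#' exact for the rendered image even when overlap is allowed.
#'
#' @param image_size image side in pixels.
#' @param n_plaques number of disks.
#' @param radius_range `c(min, max)` disk radius in pixels.
#' @param allow_overlap allow overlapping disks (default FALSE).
#' @param fg,bg foreground / background intensity.
#' @param noise Gaussian pixel noise sd.
#' @param pixel_size_um physical pixel size.
#' @param seed integer seed.
#' @return list: `image`, `truth` (list with `mask`, `count`,
#'   `burden_pct`, `centers`, `radii`, `analytic_area_px`).
#' @export
simulate_plaque_image <- function(image_size = 128, n_plaques = 5,
                                  radius_range = c(8, 14),
                                  allow_overlap = FALSE,
                                  fg = 200, bg = 10, noise = 5,
                                  pixel_size_um = 1, seed = 1L) {
  if (n_plaques < 0) stop("n_plaques must be >= 0")
  with_seed(seed, {
    sz <- image_size
    mask <- matrix(FALSE, sz, sz)
    centers <- matrix(numeric(0), ncol = 2)
    radii <- numeric(0)
    tries <- 0
    while (length(radii) < n_plaques && tries < 2000 * max(n_plaques, 1)) {
      tries <- tries + 1
      r <- stats::runif(1, radius_range[1], radius_range[2])
      cy <- stats::runif(1, r + 1, sz - r)
      cx <- stats::runif(1, r + 1, sz - r)
      if (!allow_overlap && nrow(centers) > 0 &&
          any(sqrt((centers[, 1] - cy)^2 + (centers[, 2] - cx)^2) <
              radii + r + 2)) next
      centers <- rbind(centers, c(cy, cx)); radii <- c(radii, r)
    }
    if (length(radii) < n_plaques)
      stop("could not place ", n_plaques, " non-overlapping plaques")
    yy <- row(mask); xx <- col(mask)
    for (i in seq_along(radii)) {
      mask <- mask | ((yy - centers[i, 1])^2 + (xx - centers[i, 2])^2 <=
                        radii[i]^2)
    }
    img <- matrix(bg, sz, sz)
    img[mask] <- fg
    if (noise > 0) img <- img + matrix(stats::rnorm(sz * sz, 0, noise), sz, sz)
    list(image = img,
         truth = list(mask = mask, count = length(radii),
                      burden_pct = 100 * sum(mask) / (sz * sz),
                      centers = centers, radii = radii,
                      analytic_area_px = sum(pi * radii^2),
                      pixel_size_um = pixel_size_um))
  })
}

#' Parameters for the synthetic 3-D microglia/plaque volume
#'
#' @param dims volume shape `c(z, y, x)` in voxels.
#' @param voxel_size_um voxel size `c(z, y, x)` in micrometres, all > 0.
#' @param n_plaques number of plaque balls.
#' @param radius_range_um plaque radius range in micrometres.
#' @param n_microglia number of somata.
#' @param attraction "uniform", or "exponential" for plaque-attracted
#'   placement with acceptance probability
#'   `floor + (1 - floor) * exp(-d / lambda_um)`.
#' @param lambda_um attraction length scale.
#' @param floor acceptance floor for the exponential kernel.
#' @param seed integer seed.
#' @return object of class `volume_sim_params`.
#' @export
volume_sim_params <- function(dims = c(40, 64, 64),
                              voxel_size_um = c(2, 1, 1),
                              n_plaques = 3, radius_range_um = c(5, 10),
                              n_microglia = 40,
                              attraction = c("uniform", "exponential"),
                              lambda_um = 20, floor = 0.05, seed = 1L) {
  attraction <- match.arg(attraction)
  if (any(voxel_size_um <= 0)) stop("voxel sizes must be > 0")
  if (n_plaques < 0 || n_microglia < 0) stop("counts must be >= 0")
  structure(list(dims = dims, voxel_size_um = voxel_size_um,
                 n_plaques = n_plaques, radius_range_um = radius_range_um,
                 n_microglia = n_microglia, attraction = attraction,
                 lambda_um = lambda_um, floor = floor,
                 seed = as.integer(seed)),
            class = "volume_sim_params")
}

# physical center of 1-based voxel index i along axis k: (i-1)*voxel_size
voxel_axis_coords <- function(dims, voxel_size_um) {
  lapply(1:3, function(k) (seq_len(dims[k]) - 1) * voxel_size_um[k])
}

#' Simulate a 3-D plaque mask and microglia soma point cloud
#'
#' Plaques are balls rasterised into the anisotropic voxel grid (a voxel is
#' plaque-positive when its center lies within a ball); somata are points
#' in continuous micrometre coordinates, placed uniformly or with an
#' exponential attraction toward the nearest plaque surface. True
#' nearest-plaque-voxel distances are computed at generation time by a
#' naive per-soma scan over all plaque voxels.
#'
#' @param params a [volume_sim_params()].
#' @return list: `plaque_mask` (logical z-y-x array), `soma_points`
#'   (data.frame `cell_id, z_um, y_um, x_um`), `truth` (data.frame with
#'   `true_distance_um` per soma; `Inf` when there are no plaques).
#' @export
simulate_microglia_volume <- function(params) {
  stopifnot(inherits(params, "volume_sim_params"))
  d <- params$dims; vs <- params$voxel_size_um
  ext <- (d - 1) * vs  # physical extent of voxel centers
  with_seed(params$seed, {
    mask <- array(FALSE, dim = d)
    ax <- voxel_axis_coords(d, vs)
    if (params$n_plaques > 0) {
      for (i in seq_len(params$n_plaques)) {
        r <- stats::runif(1, params$radius_range_um[1],
                          params$radius_range_um[2])
        ctr <- vapply(1:3, function(k) stats::runif(1, r, ext[k] - r), 0)
        dz2 <- (ax[[1]] - ctr[1])^2
        dy2 <- (ax[[2]] - ctr[2])^2
        dx2 <- (ax[[3]] - ctr[3])^2
        mask <- mask | (outer(outer(dz2, dy2, "+"), dx2, "+") <= r^2)
      }
    }
    pv <- which(mask, arr.ind = TRUE)
    pcoord <- if (nrow(pv) > 0)
      cbind(ax[[1]][pv[, 1]], ax[[2]][pv[, 2]], ax[[3]][pv[, 3]])
    else matrix(numeric(0), ncol = 3)
    naive_dist <- function(p) {
      if (nrow(pcoord) == 0) return(Inf)
      best <- Inf
      for (j in seq_len(nrow(pcoord))) {   # deliberate naive scan
        dj <- sqrt(sum((pcoord[j, ] - p)^2))
        if (dj < best) best <- dj
      }
      best
    }
    # placement-time distance (vectorised; the truth table below still uses
    # the naive scan so it stays an independent brute-force measurement)
    fast_dist <- function(p) {
      if (nrow(pcoord) == 0) return(Inf)
      sqrt(min((pcoord[, 1] - p[1])^2 + (pcoord[, 2] - p[2])^2 +
                 (pcoord[, 3] - p[3])^2))
    }
    pts <- matrix(numeric(0), ncol = 3)
    while (nrow(pts) < params$n_microglia) {
      p <- vapply(1:3, function(k) stats::runif(1, 0, ext[k]), 0)
      if (params$attraction == "exponential" && nrow(pcoord) > 0) {
        acc <- params$floor + (1 - params$floor) *
          exp(-fast_dist(p) / params$lambda_um)
        if (stats::runif(1) > acc) next
      }
      pts <- rbind(pts, p)
    }
    td <- if (nrow(pts)) apply(pts, 1, naive_dist) else numeric(0)
    soma <- data.frame(cell_id = seq_len(nrow(pts)),
                       z_um = pts[, 1], y_um = pts[, 2], x_um = pts[, 3])
    list(plaque_mask = mask, soma_points = soma,
         truth = data.frame(cell_id = soma$cell_id, true_distance_um = td))
  })
}
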