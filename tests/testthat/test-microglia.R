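test_that("distance to the nearest plaque voxel is exact", {
  # 3-4-5 triangle: plaque voxel centered at (0, 3, 4) um
  mask <- array(FALSE, c(3, 8, 8)); mask[1, 4, 5] <- TRUE
  cl <- distance_to_plaques(data.frame(cell_id = 1, z_um = 0, y_um = 0,
                                       x_um = 0), mask, c(1, 1, 1))
  expect_equal(cl$distance_um, 5)

  # soma inside a plaque -> 0
  mask2 <- array(FALSE, c(4, 4, 4)); mask2[2, 2, 2] <- TRUE
  cl2 <- distance_to_plaques(data.frame(cell_id = 1, z_um = 1, y_um = 1,
                                        x_um = 1), mask2, c(1, 1, 1))
  expect_equal(cl2$distance_um, 0)

  # no plaques -> Inf distances with an explicit flag
  cl3 <- distance_to_plaques(data.frame(cell_id = 1:2, z_um = c(0, 1),
                                        y_um = c(0, 1), x_um = c(0, 1)),
                             array(FALSE, c(3, 3, 3)), c(1, 1, 1))
  expect_true(all(is.infinite(cl3$distance_um)))
  expect_true(attr(cl3, "no_plaques"))
})

test_that("distances match the all-pairs oracle on random anisotropic volumes", {
  set.seed(11)
  for (i in 1:30) {
    d <- c(sample(4:8, 1), sample(6:12, 1), sample(6:12, 1))
    vs <- c(runif(1, 1, 3), runif(1, 0.5, 1.5), runif(1, 0.5, 1.5))
    mask <- array(runif(prod(d)) < 0.05, dim = d)
    if (!any(mask)) mask[1, 1, 1] <- TRUE
    pts <- data.frame(cell_id = 1:5,
                      z_um = runif(5, 0, (d[1] - 1) * vs[1]),
                      y_um = runif(5, 0, (d[2] - 1) * vs[2]),
                      x_um = runif(5, 0, (d[3] - 1) * vs[3]))
    cl <- distance_to_plaques(pts, mask, vs)
    for (j in 1:5) {
      expect_lt(abs(cl$distance_um[j] -
                      oracle_min_distance(unlist(pts[j, 2:4]), mask, vs)),
                1e-6)
    }
  }
})

test_that("association respects the inclusive 25 um radius and is monotone", {
  mask <- array(FALSE, c(3, 3, 60)); mask[1, 1, 1] <- TRUE
  pts <- data.frame(cell_id = 1:3, z_um = 0, y_um = 0,
                    x_um = c(24.9, 25.0, 25.1))
  cl <- distance_to_plaques(pts, mask, c(1, 1, 1))
  expect_equal(cl$associated, c(TRUE, TRUE, FALSE))  # <= 25, 25.1 excluded
  ac <- associated_count(cl, 25)
  expect_equal(ac$total, 2L)
  # radius 0: only cells touching plaque
  expect_equal(associated_count(cl, 0)$total, 0L)
  cl0 <- distance_to_plaques(data.frame(cell_id = 1, z_um = 0, y_um = 0,
                                        x_um = 0), mask, c(1, 1, 1))
  expect_equal(associated_count(cl0, 0)$total, 1L)
  # monotone non-decreasing in radius
  counts <- vapply(c(0, 10, 25, 40), function(r)
    associated_count(cl, r)$total, 0L)
  expect_true(all(diff(counts) >= 0))
})

test_that("distances are invariant to padding and linear in voxel size", {
  mask <- array(FALSE, c(4, 6, 6)); mask[2, 3, 4] <- TRUE
  pts <- data.frame(cell_id = 1, z_um = 0.5, y_um = 1.2, x_um = 0.3)
  d1 <- distance_to_plaques(pts, mask, c(2, 1, 1))$distance_um
  padded <- array(FALSE, c(8, 10, 10)); padded[1:4, 1:6, 1:6] <- mask
  expect_equal(distance_to_plaques(pts, padded, c(2, 1, 1))$distance_um, d1)
  # doubling voxel size doubles distances (with soma coords also doubled)
  pts2 <- pts; pts2[, 2:4] <- pts[, 2:4] * 2
  expect_equal(distance_to_plaques(pts2, mask, c(4, 2, 2))$distance_um, 2 * d1)
})

test_that("soma detection finds planted gaussian blobs at their centroids", {
  vol <- array(0, c(20, 40, 40))
  ctrs <- rbind(c(10, 8, 8), c(10, 8, 30), c(10, 30, 8), c(10, 30, 30),
                c(10, 19, 19))  # >= 8 um apart
  zz <- slice.index(vol, 1); yy <- slice.index(vol, 2); xx <- slice.index(vol, 3)
  for (i in 1:5)
    vol <- vol + exp(-(((zz - ctrs[i, 1]) * 2)^2 + (yy - ctrs[i, 2])^2 +
                         (xx - ctrs[i, 3])^2) / (2 * 3^2))
  ss <- detect_somata(vol, c(2, 1, 1), sigma_um = 3)
  expect_equal(nrow(ss), 5L)
  got <- ss[order(ss$y_um, ss$x_um), ]
  want <- (ctrs - 1) * matrix(c(2, 1, 1), 5, 3, byrow = TRUE)
  want <- want[order(want[, 2], want[, 3]), ]
  expect_true(all(abs(got$z_um - want[, 1]) <= 2))  # +/- 1 voxel (z is 2 um)
  expect_true(all(abs(got$y_um - want[, 2]) <= 1))
  expect_true(all(abs(got$x_um - want[, 3]) <= 1))

  # empty volume -> no detections; voxel size is mandatory
  expect_equal(nrow(detect_somata(array(0, c(5, 5, 5)), c(1, 1, 1))), 0L)
  expect_error(detect_somata(array(0, c(5, 5, 5))), "mandatory")

  # supplied point lists pass through unchanged
  pts <- data.frame(cell_id = 1:2, z_um = c(1, 2), y_um = c(3, 4),
                    x_um = c(5, 6))
  expect_equal(as.data.frame(detect_somata(pts)), pts)
})

test_that("process length traces rods and ignores compact blobs", {
  # straight rod, 3 voxels wide, 40 um end to end
  rod <- array(FALSE, c(5, 7, 45)); rod[2:4, 3:5, 3:43] <- TRUE
  pl <- process_length(rod, c(1, 1, 1))
  expect_lt(abs(pl$length_um - 40), 2)

  # sphere (no processes): below the thickness floor
  sp <- array(FALSE, c(15, 15, 15))
  zz <- slice.index(sp, 1); yy <- slice.index(sp, 2); xx <- slice.index(sp, 3)
  sp[(zz - 8)^2 + (yy - 8)^2 + (xx - 8)^2 <= 36] <- TRUE
  expect_lt(process_length(sp, c(1, 1, 1))$length_um, 5)

  # two rods of 30 and 20 um from one soma: additive
  v <- array(FALSE, c(7, 40, 40))
  v[3:5, 3:5, 3:5] <- TRUE
  v[4, 4, 5:35] <- TRUE
  v[4, 5:25, 4] <- TRUE
  pl2 <- process_length(v, c(1, 1, 1))
  expect_lt(abs(pl2$length_um - 50), 5)
  expect_equal(pl2$n_branches, 2L)

  # tiny fragments are ignored and counted
  frag <- rod
  frag[1, 7, 45] <- TRUE  # 1-voxel speck
  plf <- process_length(frag, c(1, 1, 1))
  expect_equal(plf$n_fragments_ignored, 1L)
  expect_lt(abs(plf$length_um - 40), 2)

  # unit linearity: doubling voxel size doubles the length
  pl_half <- process_length(rod, c(2, 2, 2))
  expect_equal(pl_half$length_um, 2 * pl$length_um, tolerance = 1e-9)
})
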