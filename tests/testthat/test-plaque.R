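test_that("max projection is the per-pixel maximum over z", {
  a <- matrix(1:9, 3, 3)
  expect_equal(max_projection(list(a)), a)
  b <- matrix(0, 3, 3); b[1, 1] <- 99
  expect_equal(max_projection(list(a, b))[1, 1], 99)
  expect_equal(max_projection(array(0, c(4, 3, 3))), matrix(0, 3, 3))
  stack <- array(0, c(2, 5, 5))
  stack[1, 1:2, 1:2] <- 5; stack[2, 4:5, 4:5] <- 7
  mp <- max_projection(stack)
  expect_equal(sum(mp == 5), 4); expect_equal(sum(mp == 7), 4)
})

test_that("segmentation counts disjoint supra-threshold disks", {
  sim <- simulate_plaque_image(image_size = 100, n_plaques = 3,
                               radius_range = c(6, 9), noise = 0, seed = 1)
  seg <- segment_plaques(sim$image, method = "fixed", threshold = 100,
                         min_size_px = 5)
  expect_equal(plaque_summary(seg)$count, 3)
  # threshold above max intensity: empty but valid
  seg0 <- segment_plaques(sim$image, method = "fixed",
                          threshold = max(sim$image) + 1)
  s0 <- plaque_summary(seg0)
  expect_equal(s0$count, 0)
  expect_equal(s0$burden_pct, 0)
  expect_true(is.na(s0$mean_size_um2))
})

test_that("labelling matches the flood-fill oracle on random disk images", {
  for (s in 1:25) {
    sim <- simulate_plaque_image(image_size = 80, n_plaques = sample(0:4, 1),
                                 radius_range = c(4, 8), allow_overlap = TRUE,
                                 noise = 0, seed = s)
    seg <- segment_plaques(sim$image, method = "fixed", threshold = 100,
                           min_size_px = 1)
    oracle <- oracle_flood_fill(sim$image > 100)
    # identical partition: same count and identical region membership
    expect_equal(length(seg$sizes_px), max(oracle))
    expect_true(all((seg$labels > 0) == (oracle > 0)))
    if (max(oracle) > 0) {
      cross <- table(seg$labels[oracle > 0], oracle[oracle > 0])
      expect_equal(sum(cross > 0), max(oracle))  # 1-1 label correspondence
    }
  }
})

test_that("burden arithmetic and physical units are exact", {
  img <- matrix(0, 100, 100)
  img[1:25, 1:25] <- 10
  seg <- segment_plaques(img, method = "fixed", threshold = 5,
                         min_size_px = 1, pixel_size_um = 2)
  s <- plaque_summary(seg)
  expect_equal(s$count, 1)
  expect_equal(s$burden_pct, 6.25)
  expect_equal(s$mean_size_um2, 625 * 4)  # 625 px at 2 um pixels

  # noiseless synthetic disks: burden within 2% of the analytic disk areas
  sim <- simulate_plaque_image(image_size = 150, n_plaques = 4,
                               radius_range = c(8, 12), noise = 0, seed = 3)
  seg2 <- segment_plaques(sim$image, method = "fixed", threshold = 100,
                          min_size_px = 1)
  got <- plaque_summary(seg2)$burden_pct
  want <- 100 * sim$truth$analytic_area_px / (150 * 150)
  expect_lt(abs(got - want) / want, 0.02)

  # roi mask defines the denominator; zero-area roi errors
  roi <- matrix(FALSE, 100, 100); roi[1:50, 1:50] <- TRUE
  segr <- segment_plaques(img, method = "fixed", threshold = 5,
                          min_size_px = 1, roi_mask = roi)
  expect_equal(plaque_summary(segr)$burden_pct, 25)
  segr$roi_mask <- matrix(FALSE, 100, 100)
  expect_error(plaque_summary(segr), "zero area")
})

test_that("min-size filtering is monotone and counts are additive", {
  sim <- simulate_plaque_image(image_size = 120, n_plaques = 5,
                               radius_range = c(3, 10), noise = 0, seed = 4)
  counts <- vapply(c(1, 10, 50, 150, 400), function(ms) {
    plaque_summary(segment_plaques(sim$image, method = "fixed",
                                   threshold = 100, min_size_px = ms))$count
  }, 0)
  expect_true(all(diff(counts) <= 0))

  # disjoint plaques in two half-images sum
  a <- simulate_plaque_image(image_size = 100, n_plaques = 2, noise = 0,
                             seed = 5)
  b <- simulate_plaque_image(image_size = 100, n_plaques = 3, noise = 0,
                             seed = 6)
  joined <- rbind(a$image, b$image)
  cj <- plaque_summary(segment_plaques(joined, method = "fixed",
                                       threshold = 100))$count
  expect_equal(cj, 5)
})

test_that("otsu segmentation is invariant to intensity rescaling", {
  sim <- simulate_plaque_image(image_size = 100, n_plaques = 3, noise = 2,
                               seed = 7)
  s1 <- segment_plaques(sim$image)
  s2 <- segment_plaques(sim$image * 7.3)
  expect_equal(plaque_summary(s1)$burden_pct, plaque_summary(s2)$burden_pct)
})

test_that("3-D segmentation labels with 26-connectivity", {
  vol <- array(0, c(6, 6, 6))
  vol[1:2, 1:2, 1:2] <- 10
  vol[3, 3, 3] <- 10        # touches the first block only diagonally
  seg <- segment_plaques(vol, method = "fixed", threshold = 5, min_size_px = 1)
  expect_equal(plaque_summary(seg)$count, 1)  # diagonal contact connects
  vol[5:6, 5:6, 5:6] <- 10  # separated block
  seg2 <- segment_plaques(vol, method = "fixed", threshold = 5, min_size_px = 1)
  expect_equal(plaque_summary(seg2)$count, 2)
})

test_that("tiff stacks round trip through the projection pipeline", {
  arr <- array(runif(3 * 8 * 8), c(3, 8, 8))
  p <- file.path(tempdir(), "stack.tif")
  write_tiff_stack(arr, p)
  back <- read_tiff_stack(p)
  expect_equal(back, arr, tolerance = 1e-4)  # 16-bit tiff quantization
  expect_equal(max_projection(back), apply(arr, c(2, 3), max),
               tolerance = 1e-4)
  unlink(p)
})
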