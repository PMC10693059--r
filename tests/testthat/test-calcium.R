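calib <- calibration_params(Kd = 250, hill_n = 1.7, Rmin = 1.0, Rmax = 2.6)

test_that("ROI ratios are background-corrected and scale-invariant", {
  yfp <- matrix(300, 10, 10); cfp <- matrix(200, 10, 10)
  roi <- matrix(FALSE, 10, 10); roi[3:5, 3:5] <- TRUE
  expect_equal(measure_roi_ratio(yfp, cfp, roi), 1.5)

  # background subtraction
  bg <- matrix(FALSE, 10, 10); bg[9:10, 9:10] <- TRUE
  yfp2 <- yfp + 50; cfp2 <- cfp + 50
  yfp2[bg] <- 50; cfp2[bg] <- 50
  expect_equal(measure_roi_ratio(yfp2, cfp2, roi, bg), 1.5)

  # common gain cancels
  expect_equal(measure_roi_ratio(3.7 * yfp, 3.7 * cfp, roi), 1.5)

  # CFP at background level -> exclusion, not a division blow-up
  cfp0 <- matrix(0, 10, 10)
  r <- measure_roi_ratio(yfp, cfp0, roi)
  expect_true(is.na(r))
  expect_equal(attr(r, "exclusion_reason"), "nonpositive_cfp")
  expect_error(measure_roi_ratio(yfp, cfp, matrix(FALSE, 10, 10)), "empty")
})

test_that("Hill conversion is exact at landmarks and inverts to 1e-9", {
  expect_equal(as.numeric(ratio_to_calcium(calib$Rmin, calib)), 0)
  mid <- (calib$Rmin + calib$Rmax) / 2
  expect_equal(as.numeric(ratio_to_calcium(mid, calib)), calib$Kd)

  set.seed(4)
  R <- runif(1000, calib$Rmin + 1e-6, calib$Rmax - 1e-6)
  ca <- as.numeric(ratio_to_calcium(R, calib))
  expect_true(all(abs(calcium_to_ratio(ca, calib) - R) < 1e-9))
  # strictly increasing
  Rs <- sort(R)
  expect_true(all(diff(as.numeric(ratio_to_calcium(Rs, calib))) > 0))

  # saturation and censoring flags instead of 0-division / infinities
  out <- ratio_to_calcium(c(0.5, 2.9), calib)
  expect_equal(as.numeric(out), c(0, NA))
  expect_equal(attr(out, "saturated_low"), c(TRUE, FALSE))
  expect_equal(attr(out, "censored"), c(FALSE, TRUE))
})

test_that("overload threshold is control mean + 2 sample SD, strict >", {
  thr <- overload_threshold(c(1.0, 1.2))
  expect_equal(thr$control_mean, 1.1)
  expect_equal(thr$control_sd, sd(c(1.0, 1.2)))
  expect_equal(thr$tau, 1.1 + 2 * 0.1414214, tolerance = 1e-6)

  # all-equal controls: tau = c, anything above is overloaded
  thr0 <- overload_threshold(rep(1.5, 10))
  expect_equal(thr0$tau, 1.5)
  expect_equal(overload_fraction(c(1.5, 1.6), thr0), 50)  # strict at tau

  expect_error(overload_threshold(1.7), ">= 2")
})

test_that("overload recovery and control false-positive rate are calibrated", {
  # planted 15% at 6-SD separation, recovered within 3 points over seeds
  errs <- vapply(1:8, function(s) {
    sim <- simulate_fret_pair(fret_sim_params(n_neurites = 150,
                                              frac_overload = 0.15, seed = s))
    ctl <- simulate_fret_pair(fret_sim_params(n_neurites = 150,
                                              frac_overload = 0,
                                              seed = s + 100))
    m <- measure_label_ratios(sim$yfp, sim$cfp, sim$labels)
    cm <- measure_label_ratios(ctl$yfp, ctl$cfp, ctl$labels)
    overload_fraction(m$R, overload_threshold(cm$R)) -
      100 * mean(sim$truth$overload)
  }, 0)
  expect_lt(abs(mean(errs)), 3)

  # Gaussian controls put ~2.3% beyond their own mean + 2 SD threshold
  set.seed(5)
  fp <- replicate(300, {
    ctl <- rnorm(400, 1.5, 0.1)
    overload_fraction(rnorm(400, 1.5, 0.1), overload_threshold(ctl))
  })
  expect_equal(mean(fp), 100 * pnorm(-2), tolerance = 0.25)
})

test_that("overload fraction rises with the overloaded component mean", {
  fracs <- vapply(c(1.9, 2.1, 2.4), function(mu) {
    sim <- simulate_fret_pair(fret_sim_params(
      n_neurites = 200, frac_overload = 0.3,
      ratio_overload = c(mu, 0.10), noise = 0, seed = 17))
    m <- measure_label_ratios(sim$yfp, sim$cfp, sim$labels)
    overload_fraction(m$R, 1.75)
  }, 0)
  expect_true(all(diff(fracs) >= 0))
})

test_that("ratio histograms count in-range values into half-open bins", {
  edges <- seq(1, 2, by = 0.25)
  expect_equal(ratio_histogram(numeric(0), edges), integer(4))
  counts <- ratio_histogram(c(1.0, 1.1, 1.25, 1.9, 2.0, 2.5), edges)
  expect_equal(sum(counts), 5L)  # 2.5 out of range; 2.0 closes the last bin
  expect_equal(counts, c(2L, 1L, 0L, 2L))
  expect_error(ratio_histogram(1, c(1, 1, 2)), "increasing")
})

test_that("pseudocolor maps ratio to hue and reference to brightness", {
  rmap <- matrix(c(1.0, 2.6, 1.8, NA), 2, 2)
  ref <- matrix(c(100, 100, 0, 100), 2, 2)
  img <- pseudocolor(rmap, ref, rmin = 1.0, rmax = 2.6)
  # Rmin -> blue extreme, Rmax -> red extreme
  expect_equal(img[1, 1, ], c(0, 0, 1))
  expect_equal(img[2, 1, ], c(1, 0, 0))
  # zero reference -> black regardless of ratio
  expect_equal(img[1, 2, ], c(0, 0, 0))
  # NA ratio -> gray (equal channels)
  expect_equal(img[2, 2, 1], img[2, 2, 2])
  expect_equal(img[2, 2, 2], img[2, 2, 3])
  # all-zero reference: black image, no division error
  img0 <- pseudocolor(rmap, ref * 0, 1, 2.6)
  expect_true(all(img0 == 0))
})
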