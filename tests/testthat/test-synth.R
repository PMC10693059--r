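test_that("Markov hypnogram generator honours the transition matrix", {
  # absorbing chain: identity matrix keeps the initial state forever
  p_id <- sleep_sim_params(transition_matrix = diag(3), seed = 5)
  h <- simulate_hypnogram(p_id, 50, init = "NREM")
  expect_true(all(h == "NREM"))

  # empirical stay-probability matches the generator within sampling error
  P <- rbind(c(0.85, 0.15, 0), c(0.08, 0.90, 0.02), c(0.10, 0.05, 0.85))
  p <- sleep_sim_params(transition_matrix = P, seed = 11)
  h <- simulate_hypnogram(p, 10000)
  est <- estimate_transition_matrix(h)
  expect_lt(abs(est["NREM", "NREM"] - 0.90), 0.02)
  expect_lt(abs(est["Wake", "Wake"] - 0.85), 0.02)

  # 24 h of 10-s epochs
  expect_length(simulate_hypnogram(sleep_sim_params(seed = 1), 8640), 8640)

  # seeded determinism
  expect_identical(simulate_hypnogram(p, 200), simulate_hypnogram(p, 200))

  # non-stochastic matrices are rejected
  expect_error(sleep_sim_params(transition_matrix = matrix(1, 3, 3)),
               "sum to 1")
  expect_error(sleep_sim_params(transition_matrix = -diag(3)))
})

test_that("synthetic polysomnography carries the planted state signatures", {
  ep <- make_test_psg(rep("NREM", 30), seed = 2)
  f <- compute_features(ep$rec, ep$epochs)
  expect_true(mean(f$delta / f$total_power) > mean(f$beta / f$total_power))

  # Wake EMG 10x NREM: every wake epoch RMS beats every NREM epoch RMS
  sp <- sleep_sim_params(fs_hz = 100, emg_amp = c(Wake = 10, NREM = 1, REM = 1),
                         seed = 3)
  states <- rep(c("Wake", "NREM"), each = 20)
  rec <- simulate_polysomnography(
    structure(states, class = "state_sequence"), sp)
  f2 <- compute_features(rec, epochize(rec, 10))
  expect_gt(min(f2$emg_rms[states == "Wake"]),
            max(f2$emg_rms[states == "NREM"]))

  # REM epochs exceed the theta/delta REM criterion by construction
  ep3 <- make_test_psg(rep("REM", 20), seed = 4)
  f3 <- compute_features(ep3$rec, ep3$epochs)
  expect_true(all(band_ratio(f3, "theta", "delta") > 3))

  # zero amplitudes produce a silent recording
  w0 <- matrix(0, 3, 5,
               dimnames = list(c("Wake", "NREM", "REM"),
                               c("swa", "delta", "theta", "beta", "background")))
  sp0 <- sleep_sim_params(fs_hz = 100, spectral_weights = w0,
                          emg_amp = c(Wake = 0, NREM = 0, REM = 0), seed = 5)
  rec0 <- simulate_polysomnography(
    structure(rep("Wake", 3), class = "state_sequence"), sp0)
  expect_true(all(rec0$eeg == 0) && all(rec0$emg == 0))
})

test_that("FRET pair generator plants exact ratios and labelled overload", {
  # no overload requested -> no overload labels
  s0 <- simulate_fret_pair(fret_sim_params(n_neurites = 50, frac_overload = 0,
                                           seed = 1))
  expect_false(any(s0$truth$overload))

  # noiseless rendering reproduces the planted ratio exactly
  s1 <- simulate_fret_pair(fret_sim_params(n_neurites = 20, noise = 0,
                                           seed = 2))
  m <- measure_label_ratios(s1$yfp, s1$cfp, s1$labels)
  merged <- merge(m, s1$truth, by = "neurite_id")
  expect_equal(merged$R, merged$true_ratio, tolerance = 1e-12)

  # planted overload fraction is binomially consistent across seeds
  fracs <- vapply(1:20, function(s) {
    sim <- simulate_fret_pair(fret_sim_params(n_neurites = 200,
                                              frac_overload = 0.15, seed = s))
    mean(sim$truth$overload)
  }, 0)
  se <- sqrt(0.15 * 0.85 / (200 * 20))
  expect_lt(abs(mean(fracs) - 0.15), 4 * se)
})

test_that("plaque image generator geometry is analytic", {
  s0 <- simulate_plaque_image(n_plaques = 0, seed = 1)
  expect_equal(s0$truth$burden_pct, 0)
  expect_equal(s0$truth$count, 0)

  # one disk of radius 10 px in 100x100: burden ~ pi*100/1e4
  s1 <- simulate_plaque_image(image_size = 100, n_plaques = 1,
                              radius_range = c(10, 10), noise = 0, seed = 2)
  expect_equal(s1$truth$burden_pct, 100 * pi * 100 / 1e4, tolerance = 0.02)
})

test_that("microglia volume truth distances are brute-force verified", {
  vp <- volume_sim_params(dims = c(16, 24, 24), n_plaques = 2,
                          radius_range_um = c(3, 5), n_microglia = 10,
                          seed = 6)
  sim <- simulate_microglia_volume(vp)
  for (i in seq_len(nrow(sim$soma_points))) {
    p <- unlist(sim$soma_points[i, c("z_um", "y_um", "x_um")])
    expect_equal(sim$truth$true_distance_um[i],
                 oracle_min_distance(p, sim$plaque_mask, vp$voxel_size_um),
                 tolerance = 1e-9)
  }
})

test_that("uniformly placed somata match the analytic shell fraction", {
  # single centered ball; fraction of uniform points within 25 um of its
  # surface ~ (volume of r+25 ball  intersect box - ball volume + ball) / box
  vp <- volume_sim_params(dims = c(41, 81, 81), voxel_size_um = c(1, 1, 1),
                          n_plaques = 1, radius_range_um = c(8, 8),
                          n_microglia = 600, attraction = "uniform", seed = 9)
  sim <- simulate_microglia_volume(vp)
  cl <- distance_to_plaques(sim$soma_points, sim$plaque_mask,
                            vp$voxel_size_um)
  got <- mean(cl$distance_um <= 25)
  # Monte-Carlo analytic estimate on an independent uniform grid of points
  set.seed(99)
  ctr_mask <- which(sim$plaque_mask, arr.ind = TRUE)
  ctr <- colMeans(ctr_mask - 1)  # ball center in um (isotropic unit voxels)
  ext <- (vp$dims - 1)
  pts <- cbind(runif(20000, 0, ext[1]), runif(20000, 0, ext[2]),
               runif(20000, 0, ext[3]))
  want <- mean(sqrt((pts[, 1] - ctr[1])^2 + (pts[, 2] - ctr[2])^2 +
                      (pts[, 3] - ctr[3])^2) <= 8 + 25)
  expect_lt(abs(got - want), 4 * sqrt(want * (1 - want) / 600) + 0.02)
})

test_that("flow sample generator plants labelled mixtures", {
  s1 <- simulate_flow_sample(500, pop_fractions = c(microglia = 1,
                                                    macrophage = 0,
                                                    lymphocyte = 0),
                             seed = 1)
  expect_true(all(s1$truth$population == "microglia"))

  s2 <- simulate_flow_sample(20000, methoxy_pos_frac = 0.2, seed = 2)
  mg <- s2$truth$population == "microglia"
  frac <- mean(s2$truth$methoxy_pos[mg])
  expect_lt(abs(frac - 0.2), 3 * sqrt(0.2 * 0.8 / sum(mg)))
  # 10-fold separation: planted positives are brighter than negatives
  expect_gt(median(s2$events$Methoxy[s2$truth$methoxy_pos]),
            5 * median(s2$events$Methoxy[mg & !s2$truth$methoxy_pos]))

  s0 <- simulate_flow_sample(0, seed = 3)
  expect_equal(nrow(s0$events), 0L)
  # control samples plant no positives
  sc <- simulate_flow_sample(1000, role = "control", seed = 4)
  expect_false(any(sc$truth$methoxy_pos))
})

test_that("behavior generators carry exact ground truth", {
  mt <- simulate_motion_trace(duration_s = 100, freeze_windows = list(c(0, 30)),
                              seed = 1)
  expect_equal(mt$truth$freeze_fraction, 0.3)
  expect_equal(mean(mt$trace$motion_index < mt$threshold), 0.3)

  es <- simulate_entry_sequence(40, p_alternate = 0.5, seed = 2)
  expect_equal(es$truth$alternation_pct, oracle_alternation(es$entries))
  expect_false(any(es$entries[-1] == es$entries[-length(es$entries)]))

  tk <- simulate_track(100, step_cm = 0, seed = 3)
  expect_equal(tk$truth$distance_cm, 0)
})

test_that("generators are bit-reproducible for identical params and seed", {
  expect_identical(simulate_fret_pair(fret_sim_params(seed = 7)),
                   simulate_fret_pair(fret_sim_params(seed = 7)))
  expect_identical(simulate_flow_sample(500, seed = 7),
                   simulate_flow_sample(500, seed = 7))
  expect_identical(simulate_plaque_image(seed = 7),
                   simulate_plaque_image(seed = 7))
})
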