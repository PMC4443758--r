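test_that("all generators are deterministic under a fixed seed", {
  p <- release_model_params(n_pool = 100, p_r = 0.4, q_mean = 1)
  s1 <- simulate_evoked_train(p, "train_60Hz_30", n_sweeps = 2, seed = 42)
  s2 <- simulate_evoked_train(p, "train_60Hz_30", n_sweeps = 2, seed = 42)
  expect_identical(s1, s2)

  mp <- mini_train_params()
  expect_identical(simulate_mini_record(mp, 5, seed = 9),
                   simulate_mini_record(mp, 5, seed = 9))

  cp <- ca_linescan_params(n_scans = 3)
  expect_identical(simulate_ca_linescan(cp, seed = 3),
                   simulate_ca_linescan(cp, seed = 3))

  ap <- arch_trace_params(extra_ap_prob = 0.3)
  expect_identical(simulate_arch_record(ap, n_events = 5, seed = 4),
                   simulate_arch_record(ap, n_events = 5, seed = 4))
})

test_that("released quanta never exceed the pool without replenishment", {
  p <- release_model_params(n_pool = 80, p_r = 0.6, q_mean = 1,
                            replenish_rate = 0)
  for (seed in 1:20) {
    sim <- simulate_evoked_train(p, "train_60Hz_30", n_sweeps = 1,
                                 seed = seed)
    expect_lte(sum(sim$ground_truth$released), 80)
    expect_true(all(diff(sim$ground_truth$pool_after[1, ]) <= 1e-9))
  }
})

test_that("first-stimulus release counts follow the binomial oracle", {
  p <- release_model_params(n_pool = 100, p_r = 0.5, q_mean = 1, q_cv = 0,
                            replenish_rate = 0)
  sim <- simulate_evoked_train(p, "single_AP", n_sweeps = 200, seed = 31)
  counts <- sim$ground_truth$released[, 1]
  se <- sqrt(100 * 0.5 * 0.5)  # binomial SD
  expect_lt(abs(mean(counts) - 50), 3 * se / sqrt(200))
  # with q_cv = 0 amplitudes are exactly count * q_mean
  expect_equal(sim$ground_truth$amplitudes[, 1], counts * 1)
})

test_that("p_r = 1 exhausts the pool on the first stimulus", {
  p <- release_model_params(n_pool = 50, p_r = 1, q_mean = 1, q_cv = 0,
                            replenish_rate = 0)
  sim <- simulate_evoked_train(p, "train_60Hz_30", n_sweeps = 1, seed = 5)
  expect_equal(sim$ground_truth$released[1, 1], 50)
  expect_true(all(sim$ground_truth$released[1, -1] == 0))
  expect_true(all(sim$ground_truth$amplitudes[1, -1] == 0))
})

test_that("calcium scaling of release probability is a power law with clipping rules", {
  p <- release_model_params(n_pool = 100, p_r = 0.5, q_mean = 1,
                            ca_exponent = 3, ca_ref_mM = 3)
  sim <- simulate_evoked_train(p, "single_AP", ca_mM = 1.5, n_sweeps = 1,
                               seed = 1)
  expect_equal(sim$ground_truth$p_eff, 0.5 * (1.5 / 3)^3)
  expect_error(simulate_evoked_train(p, "single_AP", ca_mM = 6, seed = 1),
               "exceeds 1")
  clipped <- simulate_evoked_train(p, "single_AP", ca_mM = 6, seed = 1,
                                   clip = TRUE)
  expect_equal(clipped$ground_truth$p_eff, 1)
})

test_that("scaling q_mean scales every EPSC amplitude by the same factor", {
  p1 <- release_model_params(n_pool = 100, p_r = 0.4, q_mean = 1, q_cv = 0.3)
  p2 <- release_model_params(n_pool = 100, p_r = 0.4, q_mean = 2.5,
                             q_cv = 0.3)
  s1 <- simulate_evoked_train(p1, "train_60Hz_30", n_sweeps = 2, seed = 17)
  s2 <- simulate_evoked_train(p2, "train_60Hz_30", n_sweeps = 2, seed = 17)
  expect_identical(s1$ground_truth$released, s2$ground_truth$released)
  expect_equal(s2$ground_truth$amplitudes, 2.5 * s1$ground_truth$amplitudes)
})

test_that("paired-pulse amplitude ratio matches the (1 - p) depletion oracle", {
  p <- release_model_params(n_pool = 200, p_r = 0.5, q_mean = 1, q_cv = 0,
                            replenish_rate = 0)
  sim <- simulate_evoked_train(p, "paired_pulse", n_sweeps = 300, seed = 23)
  r <- sim$ground_truth$released
  # E[EPSC2]/E[EPSC1] = (1 - p): compare the ratio of means (the per-sweep
  # ratio carries a small 1/(N p) Jensen bias) with its delta-method SE
  ratio <- mean(r[, 2]) / mean(r[, 1])
  expect_lt(abs(ratio - 0.5), 3 * ratio_of_means_se(r[, 2], r[, 1]))
})

test_that("miniature records follow the Poisson-lognormal construction", {
  mp <- mini_train_params(rate_hz = 2, noise_sd = 0.05)
  sim <- simulate_mini_record(mp, 100, seed = 12)
  expect_lt(abs(nrow(sim$events) - 200), 3 * sqrt(200))

  # a single noiseless event peaks at its drawn amplitude
  mp0 <- mini_train_params(rate_hz = 0.02, amp_cv = 0, noise_sd = 0)
  for (seed in 1:20) {
    s <- simulate_mini_record(mp0, 50, seed = seed)
    if (nrow(s$events) == 1) {
      expect_equal(max(s$trace$samples), s$events$amplitude[1],
                   tolerance = 1e-3)
    }
  }
})

test_that("vglut overexpression scales amplitudes only, with coupled seeds", {
  wt <- simulate_mini_record(mini_train_params(vglut_scale = 1), 30,
                             seed = 77)
  oe <- simulate_mini_record(mini_train_params(vglut_scale = 1.55), 30,
                             seed = 77)
  expect_equal(oe$events$t_onset, wt$events$t_onset)
  expect_equal(oe$events$amplitude, 1.55 * wt$events$amplitude)
})

test_that("line-scan generator round-trips its true dF/F peak", {
  cp <- ca_linescan_params(noise_sd = 0, drift_frac = 0, dff_peak = 0.35,
                           n_scans = 2)
  sim <- simulate_ca_linescan(cp, seed = 8)
  d <- dff(sim$scans[[1]]$roi, sim$scans[[1]]$background,
           sim$ground_truth$stim_time_s)
  expect_equal(max(d$samples), 0.35, tolerance = 1e-12)

  # a zero-amplitude transient leaves a flat resting baseline
  cp0 <- ca_linescan_params(noise_sd = 0, drift_frac = 0, dff_peak = 0,
                            n_scans = 1)
  s0 <- simulate_ca_linescan(cp0, seed = 8)
  expect_equal(diff(range(s0$scans[[1]]$roi$samples)), 0)
})

test_that("bleaching drift beyond 15% triggers the imaging exclusion", {
  cp <- ca_linescan_params(noise_sd = 0, drift_frac = -0.2, n_scans = 1)
  sim <- simulate_ca_linescan(cp, seed = 2)
  qc <- imaging_qc(sim$scans[[1]]$roi, sim$ground_truth$stim_time_s)
  expect_true(qc$excluded)
  expect_identical(qc$reason, "drift_gt_15pct")
})

test_that("arch generator ground truth matches its analytic widths", {
  sim <- simulate_arch_record(arch_noiseless(), n_events = 1, seed = 1)
  w <- waveform_widths(sim$ground_truth$ap_waveform)
  expect_equal(w$whm_ms, 1.2, tolerance = 0.25)
  expect_equal(w$full_width_ms, 2.4, tolerance = 0.25)

  # null AP: photobleach subtraction leaves only noise in the measurement
  # window; bound the max of ~270 Gaussian residuals at 4 sigma
  apn <- arch_trace_params(ap_peak = 0, noise_sd = 0.5, extra_ap_prob = 0)
  s0 <- simulate_arch_record(apn, n_events = 1, seed = 6)
  res <- subtract_photobleach(s0$sweeps$sweeps[[1]], 0.060)
  tt <- trace_times(res)
  win <- tt > 0.012 & tt < 0.08
  expect_lte(max(abs(res$samples[win])), 4 * 0.5)
})

test_that("homeostasis population holds the set-point exactly at zero noise", {
  pop <- simulate_homeostasis_population(30, c(0.4, 0.9, 1.5, 2.0),
                                         noise_cv = 0, seed = 1)
  expect_equal(pop$quantal_content * pop$mepsp_mean, rep(30, 4))
  expect_error(simulate_homeostasis_population(30, numeric(0)), "non-empty")
})

test_that("cooperativity dataset validates its design", {
  p <- release_model_params()
  expect_error(simulate_cooperativity_dataset(p, c(1, 2), 10, seed = 1),
               "3 calcium levels")
  expect_error(simulate_cooperativity_dataset(p, c(0.3, 0.75, 1.5), 0,
                                              seed = 1),
               "sweeps_per_level")
})
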