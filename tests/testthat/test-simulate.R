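test_that("aperiodic synthesis reproduces the target power law", {
  # zero exponent: white noise, fitted log-log slope ~ 0
  rec0 <- recording(matrix(simulate_aperiodic_signal(
    aperiodic_spec(0, 0), 60, 250, seed = 3), 1), 250)
  f0 <- loglog_fit(rec0)
  expect_lt(abs(f0["slope"]), 0.1)

  # steep exponent recovered by an independent OLS oracle on the Welch PSD
  rec2 <- recording(matrix(simulate_aperiodic_signal(
    aperiodic_spec(0, 2), 120, 250, seed = 3), 1), 250)
  f2 <- loglog_fit(rec2)
  expect_lt(abs(f2["slope"] - (-2)), 0.1)
  expect_lt(abs(f2["intercept"]), 0.15)

  # offset is a pure log10 gain: b -> b + 1 multiplies the signal by
  # sqrt(10) sample-for-sample under the same seed
  s0 <- simulate_aperiodic_signal(aperiodic_spec(0, 1), 10, 250, seed = 7)
  s1 <- simulate_aperiodic_signal(aperiodic_spec(1, 1), 10, 250, seed = 7)
  expect_equal(s1, s0 * sqrt(10), tolerance = 1e-12)

  expect_error(simulate_aperiodic_signal(aperiodic_spec(0, 1), 0.001, 250),
               "at least 2 samples")
})

test_that("PSD recovery holds across the exponent/offset grid", {
  for (x in c(0.5, 1, 1.5, 2)) {
    rec <- recording(matrix(simulate_aperiodic_signal(
      aperiodic_spec(0.5, x), 120, 250, seed = 11 + round(10 * x)), 1), 250)
    ft <- loglog_fit(rec)
    expect_lt(abs(ft["slope"] + x), 0.1)
    expect_lt(abs(ft["intercept"] - 0.5), 0.15)
  }
})

test_that("centre-frequency trajectories respect their process and bounds", {
  spec0 <- alpha_dynamics_spec(mean_cf = 10.5, cf_jitter_sd = 0)
  expect_equal(make_cf_trajectory(spec0, 5, seed = 1), rep(10.5, 5))

  # clipped-normal SD oracle: Monte-Carlo estimate from plain rnorm
  spec <- alpha_dynamics_spec(mean_cf = 10, cf_jitter_sd = 0.5)
  traj <- make_cf_trajectory(spec, 10000, seed = 2)
  oracle_sd <- withr::with_seed(99, sd(pmin(pmax(rnorm(2e5, 10, 0.5), 8), 13)))
  expect_lt(abs(sd(traj) - oracle_sd), 0.05)
  expect_lt(abs(mean(traj) - 10), 0.05)

  # bounds hold for both processes at aggressive jitter
  for (kind in c("iid_gaussian", "bounded_random_walk")) {
    for (seed in 1:5) {
      tr <- make_cf_trajectory(
        alpha_dynamics_spec(10, 2, trajectory_kind = kind), 500, seed = seed)
      expect_true(all(tr >= 8 & tr <= 13))
    }
  }
  expect_error(alpha_dynamics_spec(trajectory_kind = "brownian"))
})

test_that("zero-amplitude alpha leaves the pure aperiodic signal", {
  ap <- aperiodic_spec(0, 1)
  al0 <- alpha_dynamics_spec(10, 0.5, amplitude = 0)
  ch <- simulate_channel(ap, al0, 20, 250, seed = 5)
  base <- simulate_aperiodic_signal(ap, 20, 250,
                                    seed = derive_seed(5, "aperiodic"))
  expect_identical(ch$signal, base)
})

test_that("simulated channels round-trip through the spectral stage", {
  # stable centre frequency: fitted alpha cf sits at the planted 10 Hz
  rec <- sim_channel_rec(jitter = 0, duration = 120, seed = 21)
  pts <- parameterize_recording(rec)
  d <- pts$channels[[1]]
  expect_gt(pts$alpha_coverage, 0.9)
  expect_lt(abs(median(d$alpha_cf, na.rm = TRUE) - 10), 0.3)

  # window-averaged fitted peak height recovers the planted amplitude
  rec2 <- sim_channel_rec(amplitude = 0.6, width = 2, jitter = 0,
                          duration = 120, seed = 22)
  pts2 <- parameterize_recording(rec2)
  amp <- mean(pts2$channels[[1]]$alpha_amplitude, na.rm = TRUE)
  expect_lt(abs(amp - 0.6), 0.2)
})

test_that("subject simulation is deterministic with independent channels", {
  d <- cohort_preset("null", n_high = 2, n_low = 2, n_channels = 8,
                     duration = 120, seed = 9)
  r1 <- simulate_subject(d, "H01", "high", "pre")
  r2 <- simulate_subject(d, "H01", "high", "pre")
  expect_identical(r1$data, r2$data)
  expect_equal(dim(r1$data), c(8L, 30000L))

  cors <- cor(t(r1$data))
  off_diag <- cors[upper.tri(cors)]
  expect_true(all(abs(off_diag) < 0.1))

  expect_error(simulate_subject(d, "X", "high", "mid"), "no parameters")
})

test_that("cohort simulation produces two recordings per subject", {
  d <- cohort_preset("null", n_high = 3, n_low = 3, n_channels = 2,
                     duration = 10, seed = 4)
  cohort <- simulate_cohort(d)
  expect_length(cohort, 12)
  conds <- vapply(cohort, function(r) r$condition, character(1))
  ids <- vapply(cohort, function(r) r$subject_id, character(1))
  expect_equal(sum(conds == "pre"), 6)
  expect_equal(length(unique(ids)), 6)

  # the effect preset differs from the null preset only in the high
  # group's post-induction jitter
  de <- cohort_preset("effect")
  expect_equal(de$group_condition_params$high$post$alpha$cf_jitter_sd, 1.0)
  expect_equal(de$group_condition_params$low$post$alpha$cf_jitter_sd, 0.4)
  expect_equal(de$group_condition_params$high$pre,
               de$group_condition_params$low$pre)
})

test_that("false alpha peaks are rare when no oscillation is present", {
  rec <- sim_channel_rec(amplitude = 0, duration = 120, seed = 31)
  pts <- parameterize_recording(rec)
  expect_lt(pts$alpha_coverage, 0.1)
  expect_true(pts$flagged[1])
})
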