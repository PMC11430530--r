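test_that("short-time spectra have the documented geometry", {
  st1 <- spectral_settings(n_avg = 1)
  rec <- recording(matrix(rnorm(75000), 1), 250)
  sp <- compute_stft_psd(rec, st1)
  # floor((300 - 1) / 0.5) + 1 windows of 1 s at 50% overlap
  expect_equal(ncol(sp$psd[[1]]), 599)
  expect_equal(range(sp$freqs), c(1, 40))
  expect_equal(sp$freqs[2] - sp$freqs[1], 0.5)

  # a pure sinusoid concentrates every window's maximum at its frequency
  tt <- seq_len(5000) / 250
  tone <- recording(matrix(sin(2 * pi * 10 * tt), 1), 250)
  spt <- compute_stft_psd(tone, st1)
  peaks <- sp$freqs[apply(spt$psd[[1]], 2, which.max)]
  expect_true(all(peaks == 10))

  # white noise has a flat mean spectrum (regression oracle)
  wn <- recording(matrix(rnorm(30000), 1), 250)
  ft <- loglog_fit(wn)
  expect_lt(abs(ft["slope"]), 0.1)

  # local averaging shortens the series by n_avg - 1
  st3 <- spectral_settings(n_avg = 3)
  sp3 <- compute_stft_psd(rec, st3)
  expect_equal(ncol(sp3$psd[[1]]), 599 - 2)
  # and each averaged column is the mean of n_avg consecutive raw columns
  expect_equal(sp3$psd[[1]][, 1],
               rowMeans(sp$psd[[1]][, 1:3]), tolerance = 1e-12)

  expect_error(compute_stft_psd(recording(matrix(rnorm(100), 1), 250)),
               "shorter than one analysis window")
  expect_error(compute_stft_psd(recording(matrix(rnorm(1000), 1), 60)),
               "cannot resolve")
})

test_that("aperiodic fits recover exact and peak-contaminated lines", {
  f <- seq(1, 40, 0.5)
  sp <- window_spectrum(f, 1.5 - 1.0 * log10(f))
  fit <- fit_aperiodic(sp)
  expect_equal(fit$offset, 1.5, tolerance = 1e-6)
  expect_equal(fit$exponent, 1.0, tolerance = 1e-6)
  expect_length(unlist(fit), 2) # knee-free: exactly two parameters

  # robust fit resists a planted peak; oracle = OLS on bins > 3w from c
  y <- 0 - 1.0 * log10(f) + 0.8 * exp(-(f - 10)^2 / (2 * 4))
  rob <- fit_aperiodic(window_spectrum(f, y), robust = TRUE)
  mask <- abs(f - 10) > 6
  oracle <- coef(lm(y[mask] ~ log10(f[mask])))
  expect_lt(abs(rob$offset - 0), 0.05)
  expect_lt(abs(rob$exponent - 1), 0.05)
  expect_lt(abs(rob$offset - oracle[1]), 0.05)
  expect_lt(abs(rob$exponent - (-oracle[2])), 0.05)

  expect_error(fit_aperiodic(window_spectrum(c(1, 2, 3), c(1, 1, 1))),
               "at least 4")
})

test_that("peak fitting finds planted Gaussians and respects limits", {
  st <- spectral_settings()
  f <- seq(1, 40, 0.5)

  # noise clearly below the 1 dB minimum height yields no peaks
  noise <- withr::with_seed(1, rnorm(length(f), 0, 0.02))
  expect_equal(nrow(fit_peaks(window_spectrum(f, noise), st)), 0)

  # a single planted Gaussian is recovered; oracle = dense-grid nonlinear
  # least squares (minpack.lm) on the same flattened spectrum
  flat <- 0.6 * exp(-(f - 10)^2 / (2 * 4))
  pk <- fit_peaks(window_spectrum(f, flat), st)
  expect_equal(nrow(pk), 1)
  expect_lt(abs(pk$center_frequency - 10), 0.1)
  expect_lt(abs(pk$amplitude - 0.6), 0.05)
  expect_lt(abs(pk$width - 2), 0.2)
  df <- data.frame(f = f, y = flat)
  oracle <- coef(minpack.lm::nlsLM(
    y ~ a * exp(-(f - c)^2 / (2 * w^2)), data = df,
    start = list(c = 9, a = 0.4, w = 1.5)))
  expect_lt(abs(pk$center_frequency - oracle["c"]), 0.1)
  expect_lt(abs(pk$amplitude - oracle["a"]), 0.05)
  expect_lt(abs(pk$width - oracle["w"]), 0.2)

  # four clear peaks, but at most max_n_peaks are returned
  four <- 0.9 * exp(-(f - 5)^2 / 2) + 0.8 * exp(-(f - 12)^2 / 2) +
    0.8 * exp(-(f - 21)^2 / 2) + 0.7 * exp(-(f - 31)^2 / 2)
  expect_lte(nrow(fit_peaks(window_spectrum(f, four), st)), 3)
})

test_that("per-window parametrization assembles a consistent model", {
  st <- spectral_settings()
  f <- seq(1, 40, 0.5)

  # peak-free power law: no peaks, near-perfect fit
  y0 <- 1 - 1.5 * log10(f)
  wf0 <- parameterize_window(window_spectrum(f, y0), st)
  expect_equal(nrow(wf0$peaks), 0)
  expect_equal(unname(wf0$aperiodic["offset"]), 1, tolerance = 1e-6)
  expect_equal(unname(wf0$aperiodic["exponent"]), 1.5, tolerance = 1e-6)
  expect_gt(wf0$r_squared, 0.999)

  # planted aperiodic + peak round trip
  y <- 1 - 1 * log10(f) + 0.6 * exp(-(f - 10)^2 / (2 * 4))
  wf <- parameterize_window(window_spectrum(f, y), st)
  expect_equal(nrow(wf$peaks), 1)
  expect_lt(abs(wf$aperiodic["offset"] - 1), 0.05)
  expect_lt(abs(wf$aperiodic["exponent"] - 1), 0.05)
  expect_lt(abs(wf$peaks$center_frequency - 10), 0.1)

  # reported mse is exactly the mean squared residual of the model
  expect_equal(wf$mse, mean((y - predict(wf))^2), tolerance = 1e-10)
  expect_equal(residuals(wf), y - fitted(wf), tolerance = 1e-12)

  # coef flattens aperiodic + peak parameters
  expect_named(coef(wf), c("offset", "exponent", "cf1", "amp1", "width1"))
})

test_that("single-window and batched fits agree", {
  st <- spectral_settings()
  rec <- sim_channel_rec(jitter = 0.5, duration = 30, seed = 13)
  sp <- compute_stft_psd(rec, st)
  m <- sp$psd[[1]]
  pts <- parameterize_recording(sp, st)
  for (w in c(1, 7, 20)) {
    wf <- parameterize_window(window_spectrum(sp$freqs, log10(m[, w])), st)
    expect_equal(unname(wf$aperiodic["offset"]),
                 pts$channels[[1]]$offset[w], tolerance = 1e-10)
    a <- select_alpha_peak(wf$peaks, st$alpha_band)
    if (is.null(a)) {
      expect_true(is.na(pts$channels[[1]]$alpha_cf[w]))
    } else {
      expect_equal(a$center_frequency, pts$channels[[1]]$alpha_cf[w],
                   tolerance = 1e-10)
    }
    expect_equal(wf$mse, pts$channels[[1]]$mse[w], tolerance = 1e-12)
  }
})

test_that("alpha-peak selection follows the band and amplitude rules", {
  pks <- data.frame(center_frequency = c(6, 10),
                    amplitude = c(0.9, 0.5), width = c(1, 1))
  expect_equal(select_alpha_peak(pks)$center_frequency, 10)
  expect_null(select_alpha_peak(pks[1, ]))
  expect_null(select_alpha_peak(pks[0, ]))

  # largest in-band amplitude wins, checked against exhaustive comparison
  withr::with_seed(5, {
    for (i in 1:20) {
      k <- sample(1:4, 1)
      pks <- data.frame(center_frequency = runif(k, 4, 16),
                        amplitude = runif(k, 0.1, 1),
                        width = runif(k, 0.8, 3))
      got <- select_alpha_peak(pks)
      inb <- pks[pks$center_frequency >= 8 & pks$center_frequency <= 13, ]
      if (nrow(inb) == 0) {
        expect_null(got)
      } else {
        expect_equal(got$amplitude, max(inb$amplitude))
      }
    }
  })
})

test_that("whole-recording parametrization has coherent shapes and flags", {
  st <- spectral_settings()
  rec <- sim_channel_rec(jitter = 0, duration = 60, seed = 41)
  sp <- compute_stft_psd(rec, st)
  pts <- parameterize_recording(rec, st)
  d <- pts$channels[[1]]
  expect_equal(nrow(d), ncol(sp$psd[[1]]))
  expect_true(all(c("offset", "exponent", "alpha_cf", "alpha_amplitude",
                    "alpha_width", "mse", "r_squared") %in% names(d)))
  expect_lt(sd(d$alpha_cf, na.rm = TRUE), 0.3) # stable cf at zero jitter
  expect_false(pts$flagged[1])
  smry <- summary(pts)
  expect_true("sd_alpha_cf" %in% names(smry))
})
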