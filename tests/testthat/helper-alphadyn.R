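# shared fixtures and oracles, built in code

# one simulated channel wrapped as a recording
sim_channel_rec <- function(offset = 0, exponent = 1, mean_cf = 10,
                            jitter = 0, amplitude = 1.5, width = 0.8,
                            duration = 60, fs = 250, seed = 1, ...) {
  ch <- simulate_channel(aperiodic_spec(offset, exponent),
                         alpha_dynamics_spec(mean_cf, jitter, amplitude,
                                             width),
                         duration, fs, seed = seed, ...)
  rec <- recording(matrix(ch$signal, 1), fs)
  attr(rec, "cf_trajectory") <- ch$cf_trajectory
  rec
}

# log-log OLS slope/intercept of a mean Welch spectrum (independent of the
# package's aperiodic fitter)
loglog_fit <- function(rec, settings = spectral_settings(n_avg = 1)) {
  sp <- compute_stft_psd(rec, settings)
  y <- log10(rowMeans(sp$psd[[1]]))
  cf <- coef(lm(y ~ log10(sp$freqs)))
  c(intercept = unname(cf[1]), slope = unname(cf[2]))
}

# brute-force LZ76 parsing straight from the definition: extend the
# current phrase while it occurs as a substring of the extended history
# s[1 .. l+k-2]; the trailing phrase counts as a component
lz76_brute <- function(bits) {
  s <- paste(bits, collapse = "")
  n <- nchar(s)
  c_count <- 0L
  l <- 1L
  while (l <= n) {
    k <- 1L
    while (l + k - 1L <= n) {
      phrase <- substr(s, l, l + k - 1L)
      history <- substr(s, 1L, l + k - 2L)
      if (!grepl(phrase, history, fixed = TRUE)) break
      k <- k + 1L
    }
    c_count <- c_count + 1L
    l <- l + k
  }
  c_count
}

# hand-built parameter_ts object (for feature-stage tests that need exact
# control over the per-window series)
make_pts <- function(series_list, coverage = NULL, flagged = NULL,
                     subject_id = "S01", condition = "pre",
                     group = "high") {
  chans <- lapply(series_list, function(s) {
    n <- length(s$alpha_cf)
    data.frame(time = seq_len(n), offset = s$offset %||% rep(0, n),
               exponent = s$exponent %||% rep(1, n),
               alpha_cf = s$alpha_cf,
               alpha_amplitude = s$alpha_amplitude %||% rep(0.5, n),
               alpha_width = s$alpha_width %||% rep(1, n),
               mse = s$mse %||% rep(0.01, n),
               r_squared = rep(0.95, n))
  })
  names(chans) <- names(series_list)
  if (is.null(coverage))
    coverage <- vapply(chans, function(d) mean(!is.na(d$alpha_cf)),
                       numeric(1))
  if (is.null(flagged)) flagged <- coverage < 0.25
  structure(list(channels = chans, alpha_coverage = coverage,
                 flagged = flagged, n_negative_exponent = 0L,
                 subject_id = subject_id, condition = condition,
                 group = group, fs = 250,
                 settings = spectral_settings()),
            class = "parameter_ts")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Gaussian-feature cohort tables for decoding tests: n subjects per class,
# d channels; `effect` added to class "high" on `informative` channels
make_gauss_table <- function(n_per_class, d, effect = 0, informative = 1,
                             seed = 1, noise_cor = 0,
                             feature_name = "sd_alpha_cf",
                             condition_tag = "pre") {
  withr::with_seed(seed, {
    n <- 2 * n_per_class
    base <- matrix(rnorm(n * d), n, d)
    if (noise_cor > 0) {
      shared <- rnorm(n)
      base <- sqrt(1 - noise_cor) * base + sqrt(noise_cor) * shared
    }
    labels <- rep(c("high", "low"), each = n_per_class)
    base[labels == "high", informative] <-
      base[labels == "high", informative] + effect
    feature_table(base, feature_name, condition_tag, labels,
                  sprintf("S%02d", seq_len(n)))
  })
}
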