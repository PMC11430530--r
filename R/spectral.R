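#' Settings for time-resolved spectral parametrization
#'
#' Collects every tunable of the short-time spectral decomposition and the
#' per-window model fit. Defaults follow the published time-resolved
#' parametrization protocol: 1-s Hann windows with 50% overlap, spectra
#' restricted to 1--40 Hz, up to three Gaussian peaks, a minimum peak
#' height of 1 dB (0.1 log10-power units), a peak threshold of 2 SD, a
#' proximity threshold of 0.75, peak width limits of 1.5--6 Hz (applied to
#' twice the Gaussian SD), and no aperiodic knee. `n_avg` (the number of
#' consecutive spectra averaged per time bin, not printed in the protocol)
#' defaults to 7, chosen by a calibration experiment trading single-window
#' chi-square noise against temporal smearing of the centre-frequency
#' trajectory (see the methods vignette).
#'
#' @param win_len STFT window length, seconds.
#' @param overlap Fractional overlap between windows.
#' @param f_range Fitted frequency range, Hz.
#' @param n_avg Number of consecutive periodograms averaged per output
#'   spectrum (stride 1).
#' @param zero_pad Zero-padding factor for the FFT (2 gives a 0.5 Hz grid
#'   from 1-s windows; Gaussian fitting on the native 1 Hz grid is coarse).
#' @param max_n_peaks Maximum number of Gaussian peaks per window.
#' @param min_peak_height Minimum peak height over the aperiodic fit. With
#'   `peak_height_unit = "db"` the value is in dB and divided by 10
#'   internally (1 dB = 0.1 log10 power); `"log10"` uses it as-is.
#' @param peak_height_unit `"db"` or `"log10"` (see above).
#' @param peak_threshold Relative detection threshold, in SD of the
#'   flattened spectrum.
#' @param width_limits Limits on peak width, Hz, applied to `2 * w` where
#'   `w` is the Gaussian SD (the common full-width-like convention).
#' @param proximity_threshold Peaks closer than this multiple of the width
#'   to the range edge (or to a larger peak) are dropped.
#' @param robust_percentile Quantile of the positive residuals used by the
#'   peak-resistant aperiodic refit.
#' @param alpha_band Band (Hz) within which the alpha peak is selected.
#' @param persistence_neighbors,persistence_tol,persistence_min
#'   Time-resolved outlier-peak removal: an alpha detection is kept only
#'   when at least `persistence_min` of the `persistence_neighbors` time
#'   bins on each side (starting at lag `n_avg`, so the compared bins are
#'   built from independent data) carry a detection within
#'   `persistence_tol` Hz.
#'   Transient noise bumps rarely recur at the same frequency, while a
#'   genuine alpha rhythm does; `persistence_min = 0` disables the filter.
#' @param coverage_floor Channels whose fraction of alpha-bearing windows
#'   falls below this floor are flagged for exclusion reporting.
#' @return An object of class `spectral_settings`.
#' @export
spectral_settings <- function(win_len = 1, overlap = 0.5,
                              f_range = c(1, 40), n_avg = 7, zero_pad = 2,
                              max_n_peaks = 3, min_peak_height = 1,
                              peak_height_unit = c("db", "log10"),
                              peak_threshold = 2,
                              width_limits = c(1.5, 6),
                              proximity_threshold = 0.75,
                              robust_percentile = 0.025,
                              alpha_band = c(8, 13),
                              persistence_neighbors = 6,
                              persistence_tol = 2.5,
                              persistence_min = 4,
                              coverage_floor = 0.25) {
  peak_height_unit <- match.arg(peak_height_unit)
  stopifnot(win_len > 0, overlap >= 0, overlap < 1, length(f_range) == 2,
            f_range[1] > 0, f_range[2] > f_range[1], n_avg >= 1,
            zero_pad >= 1, max_n_peaks >= 0, peak_threshold >= 0,
            length(width_limits) == 2, width_limits[1] > 0,
            width_limits[2] > width_limits[1])
  structure(list(win_len = win_len, overlap = overlap, f_range = f_range,
                 n_avg = as.integer(n_avg), zero_pad = zero_pad,
                 max_n_peaks = as.integer(max_n_peaks),
                 min_peak_height = min_peak_height,
                 peak_height_unit = peak_height_unit,
                 peak_threshold = peak_threshold,
                 width_limits = width_limits,
                 proximity_threshold = proximity_threshold,
                 robust_percentile = robust_percentile,
                 alpha_band = alpha_band,
                 persistence_neighbors = as.integer(persistence_neighbors),
                 persistence_tol = persistence_tol,
                 persistence_min = as.integer(persistence_min),
                 coverage_floor = coverage_floor),
            class = "spectral_settings")
}

# effective minimum peak height in log10 units
min_height_log10 <- function(settings) {
  if (settings$peak_height_unit == "db") settings$min_peak_height / 10
  else settings$min_peak_height
}

# Hann-tapered modified periodograms of one channel: returns the full
# one-sided frequency grid and an F x W matrix of linear PSD values
# (density units: power per Hz; 2 / (fs * sum(w^2)) normalisation).
stft_psd_matrix <- function(x, fs, win_len = 1, overlap = 0.5,
                            zero_pad = 2) {
  nwin <- round(win_len * fs)
  hop <- round(nwin * (1 - overlap))
  n <- length(x)
  if (n < nwin) stop("signal shorter than one analysis window")
  n_windows <- floor((n - nwin) / hop) + 1
  starts <- (seq_len(n_windows) - 1L) * hop
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(nwin - 1)) / nwin) # periodic Hann
  idx <- outer(seq_len(nwin), starts, `+`)
  seg <- matrix(x[idx], nrow = nwin) * w
  nfft <- round(zero_pad * nwin)
  if (nfft > nwin) seg <- rbind(seg, matrix(0, nfft - nwin, n_windows))
  ft <- mvfft(seg)
  half <- floor(nfft / 2)
  psd <- (2 / (fs * sum(w^2))) * Mod(ft[2:(half + 1), , drop = FALSE])^2
  freqs <- seq_len(half) * fs / nfft
  times <- starts / fs + win_len / 2
  list(freqs = freqs, psd = psd, times = times)
}

#' Short-time power spectra of a recording
#'
#' Computes one Hann-tapered modified periodogram per sliding window for
#' every channel and (optionally) averages `n_avg` consecutive
#' periodograms per output time bin (stride 1), then restricts the
#' frequency grid to `f_range`.
#'
#' @param rec A [recording()].
#' @param settings A [spectral_settings()].
#' @return An object of class `stft_psd`: list with `freqs` (Hz), `psd`
#'   (list per channel of frequencies x windows matrices, linear PSD),
#'   `times` (window centre times, s), `channel_names`, `fs`, `settings`.
#' @examples
#' rec <- recording(matrix(rnorm(2 * 2500), 2), fs = 250)
#' sp <- compute_stft_psd(rec, spectral_settings(n_avg = 1))
#' dim(sp$psd[[1]])
#' @export
compute_stft_psd <- function(rec, settings = spectral_settings()) {
  stopifnot(inherits(rec, "recording"),
            inherits(settings, "spectral_settings"))
  if (ncol(rec$data) < round(settings$win_len * rec$fs))
    stop("recording is shorter than one analysis window")
  if (rec$fs < 2 * settings$f_range[2])
    stop(sprintf("fs = %g Hz cannot resolve %g Hz", rec$fs,
                 settings$f_range[2]))
  out <- vector("list", nrow(rec$data))
  freqs <- NULL
  times <- NULL
  for (ch in seq_len(nrow(rec$data))) {
    ps <- stft_psd_matrix(rec$data[ch, ], rec$fs, settings$win_len,
                          settings$overlap, settings$zero_pad)
    m <- ps$psd
    tt <- ps$times
    if (settings$n_avg > 1) {
      k <- settings$n_avg
      if (ncol(m) < k) stop("too few windows for the requested n_avg")
      cs <- cbind(0, t(apply(m, 1, cumsum)))
      m <- (cs[, (k + 1):ncol(cs), drop = FALSE] -
              cs[, 1:(ncol(cs) - k), drop = FALSE]) / k
      tt <- (head(tt, ncol(m)) + tt[k:length(tt)]) / 2
    }
    keep <- ps$freqs >= settings$f_range[1] & ps$freqs <= settings$f_range[2]
    out[[ch]] <- m[keep, , drop = FALSE]
    freqs <- ps$freqs[keep]
    times <- tt
  }
  names(out) <- rec$channel_names
  structure(list(freqs = freqs, psd = out, times = times,
                 channel_names = rec$channel_names, fs = rec$fs,
                 settings = settings,
                 subject_id = rec$subject_id, condition = rec$condition,
                 group = rec$group),
            class = "stft_psd")
}

#' @export
print.stft_psd <- function(x, ...) {
  cat(sprintf("<stft_psd> %d channels x %d windows, %d bins (%g-%g Hz)\n",
              length(x$psd), ncol(x$psd[[1]]), length(x$freqs),
              min(x$freqs), max(x$freqs)))
  invisible(x)
}

#' One window's power spectrum
#'
#' @param freqs Strictly increasing frequency grid, Hz.
#' @param log_power log10 power values, same length as `freqs`.
#' @param window_index,window_time Optional position of the window.
#' @return An object of class `window_spectrum`.
#' @export
window_spectrum <- function(freqs, log_power, window_index = NA_integer_,
                            window_time = NA_real_) {
  stopifnot(length(freqs) == length(log_power))
  if (any(!is.finite(freqs)) || any(!is.finite(log_power)))
    stop("window_spectrum values must be finite")
  if (any(diff(freqs) <= 0)) stop("`freqs` must be strictly increasing")
  structure(list(freqs = freqs, log_power = log_power,
                 window_index = window_index, window_time = window_time),
            class = "window_spectrum")
}

# core aperiodic fit on raw vectors; returns c(offset, exponent)
aperiodic_core <- function(freqs, log_power, robust = TRUE,
                           percentile = 0.025) {
  X <- cbind(1, -log10(freqs))
  cf <- stats::.lm.fit(X, log_power)$coefficients
  if (robust) {
    r <- log_power - X %*% cf
    rz <- pmax(r, 0)
    thr <- quantile(rz, percentile, names = FALSE)
    keep <- rz <= thr
    if (sum(keep) >= 4)
      cf <- stats::.lm.fit(X[keep, , drop = FALSE], log_power[keep])$coefficients
  }
  c(offset = cf[1], exponent = cf[2])
}

#' Fit the aperiodic (1/f-like) component of one spectrum
#'
#' Least-squares fit of `log_power ~ offset - exponent * log10(f)` (a
#' knee-free Lorentzian in log-log space). In robust mode an initial fit
#' is made on all bins, and the model is refit on the bins whose positive
#' residual falls below the configured quantile of positive residuals --
#' bins inside oscillatory peaks sit far above the initial fit and are
#' thereby excluded.
#'
#' @param spectrum A [window_spectrum()] (at least 4 bins).
#' @param robust Use the peak-resistant two-pass fit?
#' @param percentile Quantile used by the robust pass.
#' @return Object of class `aperiodic_fit`: list with `offset` and
#'   `exponent`. A negative exponent (possible on white-noise-like
#'   windows) is allowed and reported as attribute `negative_exponent`.
#' @examples
#' f <- seq(1, 40, 0.5)
#' sp <- window_spectrum(f, 1.5 - 1.0 * log10(f))
#' fit_aperiodic(sp)
#' @export
fit_aperiodic <- function(spectrum, robust = TRUE, percentile = 0.025) {
  stopifnot(inherits(spectrum, "window_spectrum"))
  if (length(spectrum$freqs) < 4)
    stop("need at least 4 frequency bins")
  if (length(unique(spectrum$freqs)) < 2)
    stop("degenerate frequency grid")
  cf <- aperiodic_core(spectrum$freqs, spectrum$log_power, robust,
                       percentile)
  structure(list(offset = unname(cf[1]), exponent = unname(cf[2])),
            class = "aperiodic_fit",
            negative_exponent = unname(cf[2]) < 0)
}

#' @export
print.aperiodic_fit <- function(x, ...) {
  cat(sprintf("<aperiodic_fit> offset = %.4f, exponent = %.4f\n",
              x$offset, x$exponent))
  invisible(x)
}

gauss_eval <- function(freqs, peaks) {
  m <- numeric(length(freqs))
  if (is.null(peaks) || nrow(peaks) == 0) return(m)
  for (k in seq_len(nrow(peaks)))
    m <- m + peaks$amplitude[k] *
      exp(-(freqs - peaks$center_frequency[k])^2 / (2 * peaks$width[k]^2))
  m
}

# core peak fit on raw vectors; returns data.frame of peaks
fit_peaks_core <- function(freqs, flat, settings) {
  pk <- fit_peaks_cpp(freqs, flat, settings$max_n_peaks,
                      min_height_log10(settings), settings$peak_threshold,
                      settings$width_limits[1] / 2, # limits are on 2*w
                      settings$width_limits[2] / 2,
                      settings$proximity_threshold)
  data.frame(center_frequency = pk[, 1], amplitude = pk[, 2],
             width = pk[, 3])
}

#' Fit Gaussian peaks to a flattened spectrum
#'
#' Iterative peak detection followed by a joint bounded least-squares
#' refit. The maximum of the flattened (aperiodic-subtracted) spectrum is
#' taken as a candidate; detection stops when the next maximum falls below
#' `max(min_peak_height, peak_threshold * SD(flattened))` or when
#' `max_n_peaks` candidates have been collected. Each candidate's width is
#' guessed from its half-height extent (clipped to the width limits) and
#' its Gaussian subtracted before searching again. All candidates are then
#' refit jointly by bounded Levenberg-Marquardt, and peaks that collapsed,
#' sit within `proximity_threshold * width` of the range edge, or overlap
#' a larger peak are dropped.
#'
#' @param flattened A [window_spectrum()] whose `log_power` is the
#'   original log10 power minus the aperiodic fit.
#' @param settings A [spectral_settings()].
#' @return data.frame with columns `center_frequency`, `amplitude`,
#'   `width` (Gaussian SD), at most `max_n_peaks` rows (possibly none).
#' @export
fit_peaks <- function(flattened, settings = spectral_settings()) {
  stopifnot(inherits(flattened, "window_spectrum"))
  fit_peaks_core(flattened$freqs, flattened$log_power, settings)
}

# full per-window model fit on raw vectors; returns list(aperiodic, peaks,
# mse, r_squared, flagged)
fit_window_core <- function(freqs, log_power, settings) {
  o <- fit_window_cpp(freqs, log_power, settings$max_n_peaks,
                      min_height_log10(settings), settings$peak_threshold,
                      settings$width_limits[1] / 2,
                      settings$width_limits[2] / 2,
                      settings$proximity_threshold,
                      settings$robust_percentile)
  peaks <- data.frame(center_frequency = o$peaks[, 1],
                      amplitude = o$peaks[, 2], width = o$peaks[, 3])
  flagged <- !all(is.finite(c(o$aperiodic, o$mse))) ||
    (nrow(peaks) > 0 && any(!is.finite(as.matrix(peaks))))
  list(aperiodic = c(offset = o$aperiodic[1], exponent = o$aperiodic[2]),
       peaks = peaks, mse = o$mse, r_squared = o$r_squared,
       flagged = flagged)
}

#' Parameterize one window's power spectrum
#'
#' The full per-window decomposition: robust aperiodic fit, flattening,
#' iterative Gaussian peak fitting with joint refit, subtraction of the
#' fitted peaks from the original spectrum, and a final (non-robust)
#' aperiodic refit on the peak-removed spectrum. The assembled model is
#' `aperiodic + sum of Gaussians`; goodness of fit is reported both as the
#' mean squared residual in log10 units (`mse`) and as the fraction of
#' variance explained (`r_squared`).
#'
#' @param spectrum A [window_spectrum()].
#' @param settings A [spectral_settings()].
#' @return An object of class `window_fit` with elements `aperiodic`
#'   (named vector: offset, exponent), `peaks` (data.frame), `mse`,
#'   `r_squared`, `flagged`, plus the input spectrum. Methods: `print`,
#'   `coef`, `predict`, `fitted`, `residuals`, `plot`.
#' @examples
#' f <- seq(1, 40, 0.5)
#' y <- 1 - log10(f) + 0.6 * exp(-(f - 10)^2 / 8)
#' wf <- parameterize_window(window_spectrum(f, y))
#' coef(wf)
#' @export
parameterize_window <- function(spectrum, settings = spectral_settings()) {
  stopifnot(inherits(spectrum, "window_spectrum"))
  core <- fit_window_core(spectrum$freqs, spectrum$log_power, settings)
  structure(c(core, list(freqs = spectrum$freqs,
                         log_power = spectrum$log_power,
                         settings = settings)),
            class = "window_fit")
}

#' @export
print.window_fit <- function(x, ...) {
  cat(sprintf("<window_fit> offset = %.3f, exponent = %.3f, %d peak(s), mse = %.4g, R^2 = %.3f\n",
              x$aperiodic["offset"], x$aperiodic["exponent"],
              nrow(x$peaks), x$mse, x$r_squared))
  if (nrow(x$peaks) > 0) print(round(x$peaks, 3))
  invisible(x)
}

#' @export
coef.window_fit <- function(object, ...) {
  out <- object$aperiodic
  if (nrow(object$peaks) > 0) {
    for (k in seq_len(nrow(object$peaks))) {
      v <- unlist(object$peaks[k, ])
      names(v) <- paste0(c("cf", "amp", "width"), k)
      out <- c(out, v)
    }
  }
  out
}

#' @export
predict.window_fit <- function(object, freqs = object$freqs, ...) {
  (object$aperiodic["offset"] - object$aperiodic["exponent"] * log10(freqs)) +
    gauss_eval(freqs, object$peaks)
}

#' @export
fitted.window_fit <- function(object, ...) predict(object)

#' @export
residuals.window_fit <- function(object, ...) {
  object$log_power - predict(object)
}

#' @export
plot.window_fit <- function(x, ...) {
  plot(x$freqs, x$log_power, type = "l", xlab = "frequency (Hz)",
       ylab = "log10 power", ...)
  lines(x$freqs, predict(x), col = "red", lwd = 2)
  lines(x$freqs,
        x$aperiodic["offset"] - x$aperiodic["exponent"] * log10(x$freqs),
        col = "blue", lty = 2)
  legend("topright", c("spectrum", "model", "aperiodic"),
         col = c("black", "red", "blue"), lty = c(1, 1, 2), bty = "n")
  invisible(x)
}

#' Select the alpha-band peak
#'
#' Among the fitted peaks whose centre frequency lies inside `band`,
#' returns the one with the largest amplitude; `NULL` when no peak
#' qualifies.
#'
#' @param peaks data.frame as returned by [fit_peaks()].
#' @param band Alpha band limits, Hz.
#' @return One-row data.frame or `NULL`.
#' @export
select_alpha_peak <- function(peaks, band = c(8, 13)) {
  if (is.null(peaks) || nrow(peaks) == 0) return(NULL)
  inb <- peaks$center_frequency >= band[1] & peaks$center_frequency <= band[2]
  if (!any(inb)) return(NULL)
  cand <- peaks[inb, , drop = FALSE]
  cand[which.max(cand$amplitude), , drop = FALSE]
}

#' Time-resolved parametrization of a whole recording
#'
#' Applies the per-window decomposition to every channel and window of a
#' recording and extracts the alpha-band peak per window, yielding
#' per-channel time courses of the five spectral parameters (alpha centre
#' frequency, amplitude, width; aperiodic offset, exponent) plus
#' goodness-of-fit. Channels whose fraction of alpha-bearing windows falls
#' below `settings$coverage_floor` are flagged for exclusion reporting.
#'
#' @param rec A [recording()] (or a precomputed [compute_stft_psd()]
#'   object).
#' @param settings A [spectral_settings()].
#' @param verbose Emit a message when channels are flagged?
#' @return An object of class `parameter_ts`: list with `channels` (one
#'   data.frame per channel: time, offset, exponent, alpha_cf,
#'   alpha_amplitude, alpha_width, mse, r_squared), `alpha_coverage`,
#'   `flagged`, `n_negative_exponent`, metadata and settings.
#' @export
parameterize_recording <- function(rec, settings = spectral_settings(),
                                   verbose = FALSE) {
  sp <- if (inherits(rec, "stft_psd")) rec else compute_stft_psd(rec, settings)
  freqs <- sp$freqs
  n_ch <- length(sp$psd)
  chans <- vector("list", n_ch)
  coverage <- numeric(n_ch)
  n_neg <- 0L
  for (ch in seq_len(n_ch)) {
    out <- fit_windows_batch_cpp(freqs, log10(sp$psd[[ch]]),
                                 settings$max_n_peaks,
                                 min_height_log10(settings),
                                 settings$peak_threshold,
                                 settings$width_limits[1] / 2,
                                 settings$width_limits[2] / 2,
                                 settings$proximity_threshold,
                                 settings$robust_percentile,
                                 settings$alpha_band[1],
                                 settings$alpha_band[2])
    n_neg <- n_neg + sum(out[, 2] < 0, na.rm = TRUE)
    if (settings$persistence_min > 0)
      out[, 3:5] <- filter_persistent_alpha(out[, 3:5, drop = FALSE],
                                            settings)
    chans[[ch]] <- data.frame(time = sp$times,
                              offset = out[, 1], exponent = out[, 2],
                              alpha_cf = out[, 3],
                              alpha_amplitude = out[, 4],
                              alpha_width = out[, 5],
                              mse = out[, 6], r_squared = out[, 7])
    coverage[ch] <- mean(!is.na(out[, 3]))
  }
  names(chans) <- sp$channel_names
  names(coverage) <- sp$channel_names
  flagged <- coverage < settings$coverage_floor
  if (verbose && any(flagged))
    message(sprintf("alpha coverage below %.2f in channel(s): %s",
                    settings$coverage_floor,
                    paste(sp$channel_names[flagged], collapse = ", ")))
  structure(list(channels = chans, alpha_coverage = coverage,
                 flagged = flagged, n_negative_exponent = n_neg,
                 subject_id = sp$subject_id, condition = sp$condition,
                 group = sp$group, fs = sp$fs, settings = settings),
            class = "parameter_ts")
}

# Drop alpha detections that do not recur at a nearby frequency in the
# surrounding windows (time-resolved outlier-peak removal): transient
# noise bumps fail the persistence requirement, real rhythms pass it.
filter_persistent_alpha <- function(alpha_cols, settings) {
  cf <- alpha_cols[, 1]
  W <- length(cf)
  # with n_avg-fold local averaging, bins closer than n_avg windows share
  # most of their data, so a transient bump trivially "recurs" there;
  # compare against bins built from independent data instead
  lags <- settings$n_avg + 0:(settings$persistence_neighbors - 1L)
  keep <- !is.na(cf)
  for (w in which(!is.na(cf))) {
    nb_idx <- c(w - lags, w + lags)
    nb_idx <- nb_idx[nb_idx >= 1L & nb_idx <= W]
    n_match <- sum(abs(cf[nb_idx] - cf[w]) <= settings$persistence_tol,
                   na.rm = TRUE)
    if (n_match < settings$persistence_min) keep[w] <- FALSE
  }
  alpha_cols[!keep, ] <- NA_real_
  alpha_cols
}

#' @export
print.parameter_ts <- function(x, ...) {
  cat(sprintf("<parameter_ts> %s [%s/%s]: %d channels x %d windows; alpha coverage %.2f-%.2f%s\n",
              x$subject_id, x$group, x$condition, length(x$channels),
              nrow(x$channels[[1]]), min(x$alpha_coverage),
              max(x$alpha_coverage),
              if (any(x$flagged)) sprintf(" (%d flagged)", sum(x$flagged))
              else ""))
  invisible(x)
}

#' @export
summary.parameter_ts <- function(object, ...) {
  pars <- c("offset", "exponent", "alpha_cf", "alpha_amplitude",
            "alpha_width", "mse")
  out <- t(vapply(object$channels, function(d) {
    vapply(pars, function(p) sd(d[[p]], na.rm = TRUE), numeric(1))
  }, numeric(length(pars))))
  colnames(out) <- paste0("sd_", pars)
  cbind(as.data.frame(out), alpha_coverage = object$alpha_coverage,
        flagged = object$flagged)
}

#' @export
plot.parameter_ts <- function(x, channel = 1, ...) {
  d <- x$channels[[channel]]
  op <- par(mfrow = c(3, 1), mar = c(3, 4, 1, 1))
  on.exit(par(op))
  plot(d$time, d$alpha_cf, type = "p", pch = 16, cex = 0.5,
       xlab = "", ylab = "alpha CF (Hz)", ...)
  plot(d$time, d$exponent, type = "l", xlab = "", ylab = "exponent")
  plot(d$time, d$offset, type = "l", xlab = "time (s)", ylab = "offset")
  invisible(x)
}
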