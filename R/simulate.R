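#' Synthesize a 1/f-like aperiodic signal
#'
#' Frequency-domain shaping of Gaussian white noise: the target one-sided
#' power spectral density `S(f) = 10^offset * f^-exponent` is imposed as
#' deterministic Fourier amplitudes with uniform random phases, and the
#' signal is recovered by an inverse transform. This yields the exact
#' target PSD in expectation (a Welch estimate regressed in log10-log10
#' coordinates over 1--40 Hz recovers slope `-exponent` and intercept
#' `offset`). Below `f_plateau` the density rolls off like a fourth-order
#' high-pass filter, mimicking acquisition hardware and keeping spectral
#' leakage from unresolved near-DC power out of the fitted range.
#'
#' @param spec An [aperiodic_spec()].
#' @param duration Length in seconds.
#' @param fs Sampling rate in Hz.
#' @param seed Optional integer seed (phases are the only randomness).
#' @param f_plateau High-pass corner frequency (Hz), kept below the
#'   fitted range so the power law holds on all of it.
#' @return Numeric vector of `round(duration * fs)` samples.
#' @examples
#' x <- simulate_aperiodic_signal(aperiodic_spec(0, 1), 10, 250, seed = 1)
#' @export
simulate_aperiodic_signal <- function(spec, duration, fs, seed = NULL,
                                      f_plateau = 0.75) {
  stopifnot(inherits(spec, "aperiodic_spec"))
  n <- round(duration * fs)
  if (n < 2) stop("`duration * fs` must be at least 2 samples")
  half <- floor(n / 2)
  f <- seq_len(half) * fs / n
  key <- sprintf("apsyn_%d_%g_%g_%g_%g", n, fs, spec$offset,
                 spec$exponent, f_plateau)
  s_target <- .alphadyn_cache[[key]]
  if (is.null(s_target)) {
    s_target <- compensate_window_kernel(
      aperiodic_target_psd(f, spec, f_plateau), n, fs)
    .alphadyn_cache[[key]] <- s_target
  }
  amp <- sqrt(s_target * fs * n / 2)
  if (n %% 2 == 0) amp[half] <- 0 # drop the Nyquist line
  phases <- with_seed_or_current(seed, runif(half, 0, 2 * pi))
  spec_pos <- amp * exp(1i * phases)
  full <- complex(n)
  full[2:(half + 1)] <- spec_pos
  full[n:(n - half + 2)] <- Conj(spec_pos[seq_len(half - 1)])
  Re(fft(full, inverse = TRUE)) / n
}

# A 1-s Hann-windowed periodogram estimates the convolution of the true
# PSD with the squared window transform (about +-1 Hz wide). On a steep
# power law this elevates the 1.5-3 Hz bins by up to ~0.1 log10 units,
# which tilts downstream straight-line fits. Pre-compensate the synthesis
# amplitudes below 10 Hz by fixed-point iteration so the *analyzed*
# spectrum, not just the raw one, follows the target model.
compensate_window_kernel <- function(s, n, fs, win_len = 1,
                                     f_min_comp = 0.6, f_max_comp = 10,
                                     n_iter = 10, damping = 0.6) {
  df <- fs / n
  nwin <- round(win_len * fs)
  if (nwin >= n) return(s)
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(nwin - 1)) / nwin)
  k <- Mod(fft(c(w, rep(0, n - nwin))))^2
  hb <- min(ceiling(4 / df), floor(n / 2) - 1L) # kernel support +-4 Hz
  ker <- c(rev(k[2:(hb + 1)]), k[1], k[2:(hb + 1)])
  ker <- ker / sum(ker)
  i_lo <- max(1L, ceiling(f_min_comp / df))
  n_comp <- min(ceiling(f_max_comp / df), length(s))
  if (i_lo >= n_comp) return(s)
  upd <- i_lo:n_comp
  # log-ratio corrections are smoothed to ~half the kernel width: the
  # inverse problem has no information at sub-kernel scales, and an
  # unconstrained fixed point oscillates there
  n_sm <- 2L * max(1L, round(0.25 / df)) + 1L
  sm_ker <- rep(1 / n_sm, n_sm)
  hs <- (n_sm - 1L) %/% 2L
  s_syn <- s
  m <- min(length(s), n_comp + 2L * hb)
  for (i in seq_len(n_iter)) {
    # even extension across DC so the kernel can reach below bin 1
    ext <- c(rev(s_syn[seq_len(hb)]), s_syn[1], s_syn[seq_len(m)])
    sm <- stats::filter(ext, ker, sides = 2)
    realized <- as.numeric(sm[(hb + 2):(hb + 1 + n_comp)])
    lr <- log(s[upd] / pmax(realized[upd], .Machine$double.xmin))
    lr_ext <- c(rep(lr[1], hs), lr, rep(lr[length(lr)], hs))
    lr_s <- as.numeric(stats::filter(lr_ext, sm_ker, sides = 2))[(hs + 1):(hs + length(lr))]
    s_syn[upd] <- s_syn[upd] * exp(damping * lr_s)
  }
  s_syn
}

# Target aperiodic PSD: power law above the high-pass corner, fourth-order
# high-pass rolloff below it (as acquisition hardware would impose). The
# corner sits below the fitted range so the power law holds on all of it;
# the rolloff keeps near-DC power from leaking into the 1-2 Hz bins of
# 1-s-window spectral estimates.
aperiodic_target_psd <- function(f, spec, f_plateau = 0.75) {
  s <- 10^spec$offset * pmax(f, f_plateau)^(-spec$exponent)
  low <- f < f_plateau
  if (any(low)) s[low] <- s[low] * (f[low] / f_plateau)^4
  s
}

#' Centre-frequency trajectory of the alpha peak
#'
#' Generates the sequence of alpha centre frequencies used by the channel
#' simulator, one value per time segment. Both processes are confined to
#' the 8--13 Hz band: the i.i.d. process by clipping, the random walk by
#' reflection at the band edges.
#'
#' @param spec An [alpha_dynamics_spec()].
#' @param n_windows Number of values to generate (>= 1).
#' @param seed Optional integer seed.
#' @return Numeric vector of length `n_windows`, all values in `[8, 13]`.
#' @examples
#' make_cf_trajectory(alpha_dynamics_spec(cf_jitter_sd = 0.5), 10, seed = 1)
#' @export
make_cf_trajectory <- function(spec, n_windows, seed = NULL) {
  stopifnot(inherits(spec, "alpha_dynamics_spec"))
  n_windows <- as.integer(n_windows)
  if (n_windows < 1) stop("`n_windows` must be >= 1")
  with_seed_or_current(seed, {
    if (spec$cf_jitter_sd == 0) {
      rep(spec$mean_cf, n_windows)
    } else if (spec$trajectory_kind == "iid_gaussian") {
      pmin(pmax(rnorm(n_windows, spec$mean_cf, spec$cf_jitter_sd), 8), 13)
    } else { # bounded_random_walk
      steps <- rnorm(n_windows, 0, spec$cf_jitter_sd)
      v <- numeric(n_windows)
      cur <- spec$mean_cf
      for (i in seq_len(n_windows)) {
        cur <- cur + steps[i]
        # reflect into [8, 13] (repeat in case of a huge step)
        while (cur < 8 || cur > 13) {
          if (cur < 8) cur <- 16 - cur
          if (cur > 13) cur <- 26 - cur
        }
        v[i] <- cur
      }
      v
    }
  })
}

# Effective spectral smearing kernel seen by an OLA noise piece: the
# analysis Hann window multiplied into the piece's sqrt-Hann envelope, at
# every hop alignment. Cached per (fs, piece length).
ola_analysis_kernel <- function(fs, L, win_len = 1) {
  key <- sprintf("olak_%g_%d_%g", fs, L, win_len)
  hit <- .alphadyn_cache[[key]]
  if (!is.null(hit)) return(hit)
  nwin <- round(win_len * fs)
  hop <- nwin %/% 2L
  wp <- sin(pi * (0:(L - 1)) / L)
  wa <- 0.5 - 0.5 * cos(2 * pi * (0:(nwin - 1)) / nwin)
  acc <- numeric(L)
  for (tau in seq(0L, L - nwin, by = hop)) {
    prod <- wp[(tau + 1):(tau + nwin)] * wa
    acc <- acc + Mod(fft(c(prod, rep(0, L - nwin))))^2
  }
  hb <- min(ceiling(4 * L / fs), floor(L / 2) - 1L) # support +-4 Hz
  ker <- c(rev(acc[2:(hb + 1)]), acc[1], acc[2:(hb + 1)])
  ker <- ker / sum(ker)
  .alphadyn_cache[[key]] <- ker
  ker
}

# One piece of the oscillatory component: shaped Gaussian noise whose
# linear PSD is P_ap(f) * (10^G(f) - 1), where G is the Gaussian peak in
# log10 space at centre frequency cf. Added to the aperiodic signal this
# gives a total expected PSD of P_ap * 10^G -- i.e. the analysis model
# (aperiodic plus log-space Gaussian) holds exactly, for any peak width.
# The target density is pre-compensated for the piece-plus-analysis window
# smearing, which would otherwise skew the analyzed peak toward low
# frequencies (the aperiodic floor is higher there).
# compensated target density of one piece for a given centre frequency
peak_piece_target <- function(m, fs, ap, alpha, cf, f_plateau = 0.75) {
  half <- floor(m / 2)
  f <- seq_len(half) * fs / m
  g <- alpha$amplitude * exp(-(f - cf)^2 / (2 * alpha$width^2))
  p_ap <- aperiodic_target_psd(f, ap, f_plateau)
  p_peak <- p_ap * (10^g - 1)
  p_peak[abs(f - cf) > 6 * alpha$width] <- 0 # negligible tails

  ker <- ola_analysis_kernel(fs, m)
  hb <- (length(ker) - 1L) %/% 2L
  s_syn <- p_peak
  for (i in 1:3) {
    ext <- c(rev(s_syn[seq_len(hb)]), s_syn[1], s_syn,
             rep(0, hb)) # even extension at DC, zero beyond Nyquist
    sm <- stats::filter(ext, ker, sides = 2)
    realized <- as.numeric(sm[(hb + 2):(hb + 1 + half)])
    s_syn <- pmax(s_syn * p_peak / pmax(realized, .Machine$double.xmin), 0)
    s_syn[p_peak == 0] <- 0
  }
  amp <- sqrt(s_syn * fs * m / 2)
  if (m %% 2 == 0) amp[half] <- 0
  amp
}

# Oscillatory component over the whole recording: overlap-add of 2-s
# sqrt-Hann-windowed shaped-noise pieces at 75% overlap (power
# complementary after rescaling, so the expected PSD is preserved), each
# piece taking the centre frequency of the trajectory block containing
# its centre. Dense short pieces decorrelate the spectral fine structure
# along time without audible joints.
peak_noise_signal <- function(n, fs, ap, alpha, traj, blk, seed,
                              piece_len = 2) {
  L <- round(piece_len * fs)
  hop <- L %/% 4L
  win <- sin(pi * (0:(L - 1)) / L) / sqrt(2) # sqrt-Hann; sum of squares
  # over the 4-fold overlap is 2, so scale to keep unit power
  starts <- seq(-L + hop, n - 1L, by = hop)
  centres <- starts + L %/% 2L # 0-based sample index of piece centres
  blocks <- pmin(pmax(centres %/% blk, 0L) + 1L, length(traj))
  ub <- unique(blocks)
  half <- floor(L / 2)
  targets <- vapply(ub, function(b)
    peak_piece_target(L, fs, ap, alpha, traj[b]), numeric(half))
  P <- length(starts)
  phases <- with_seed_or_current(seed,
                                 matrix(runif(half * P, 0, 2 * pi), half, P))
  spos <- targets[, match(blocks, ub), drop = FALSE] * exp(1i * phases)
  full <- matrix(0 + 0i, L, P)
  full[2:(half + 1), ] <- spos
  full[L:(L - half + 2), ] <- Conj(spos[seq_len(half - 1), , drop = FALSE])
  pieces <- (Re(mvfft(full, inverse = TRUE)) / L) * win
  x <- numeric(n + 2L * L)
  offset <- L # pre-roll so the first samples get full coverage
  for (i in seq_len(P)) {
    idx <- (offset + starts[i] + 1L):(offset + starts[i] + L)
    x[idx] <- x[idx] + pieces[, i]
  }
  x[(offset + 1L):(offset + n)]
}

#' Simulate one EEG channel (aperiodic + drifting alpha peak)
#'
#' The channel is the sum of a shaped-noise aperiodic signal and an
#' oscillatory alpha component. The alpha centre frequency is piecewise
#' constant over `cf_block_len`-second blocks drawn from
#' [make_cf_trajectory()]; the oscillatory component is synthesized as
#' band-shaped Gaussian noise whose linear power density is
#' `P_aperiodic(f) * (10^G(f) - 1)` with `G` the Gaussian peak (height
#' `amplitude`, SD `width`) in log10 space, so the expected total spectrum
#' equals the analysis model `aperiodic + Gaussian` exactly. The component
#' is built by power-complementary overlap-add of short windowed noise
#' pieces, so its spectral fine structure decorrelates over a couple of
#' seconds and block transitions are click-free.
#'
#' @param ap An [aperiodic_spec()].
#' @param alpha An [alpha_dynamics_spec()]; `amplitude = 0` returns the
#'   pure aperiodic signal (bit-identical under the same seed).
#' @param duration,fs Length (s) and sampling rate (Hz).
#' @param seed Optional integer seed; sub-seeds for the aperiodic phases,
#'   the trajectory and each block are derived from it.
#' @param cf_block_len Block length (s) over which the centre frequency is
#'   held constant.
#' @return List with `signal` (numeric vector) and `cf_trajectory` (the
#'   generating centre-frequency values, one per block).
#' @export
simulate_channel <- function(ap, alpha, duration, fs, seed = NULL,
                             cf_block_len = 4) {
  stopifnot(inherits(ap, "aperiodic_spec"),
            inherits(alpha, "alpha_dynamics_spec"))
  n <- round(duration * fs)
  base <- simulate_aperiodic_signal(
    ap, duration, fs,
    seed = if (is.null(seed)) NULL else derive_seed(seed, "aperiodic"))
  n_blocks <- ceiling(duration / cf_block_len)
  traj <- make_cf_trajectory(
    alpha, n_blocks,
    seed = if (is.null(seed)) NULL else derive_seed(seed, "trajectory"))
  if (alpha$amplitude == 0)
    return(list(signal = base, cf_trajectory = traj))

  osc <- peak_noise_signal(n, fs, ap, alpha, traj,
                           blk = round(cf_block_len * fs),
                           seed = if (is.null(seed)) NULL
                                  else derive_seed(seed, "peak"))
  list(signal = base + osc, cf_trajectory = traj)
}

#' Simulate a full recording for one subject and condition
#'
#' Channels are simulated independently (no volume conduction), each from
#' its own deterministic child seed, so the same `(seed, subject_id,
#' condition)` always reproduces the identical recording.
#'
#' @param design A [cohort_design()].
#' @param subject_id Subject identifier.
#' @param group `"high"` or `"low"`; must exist in the design map.
#' @param condition `"pre"` or `"post"`; must exist in the design map.
#' @param seed Master seed; defaults to the design seed.
#' @return A [recording()]; the per-channel generating centre-frequency
#'   trajectories are attached as attribute `"cf_trajectories"`.
#' @export
simulate_subject <- function(design, subject_id, group, condition,
                             seed = design$seed) {
  stopifnot(inherits(design, "cohort_design"))
  cell <- design$group_condition_params[[group]][[condition]]
  if (is.null(cell))
    stop(sprintf("design has no parameters for group '%s', condition '%s'",
                 group, condition))
  n <- round(design$duration * design$fs)
  dat <- matrix(0, design$n_channels, n)
  trajs <- vector("list", design$n_channels)
  for (ch in seq_len(design$n_channels)) {
    sim <- simulate_channel(cell$aperiodic, cell$alpha, design$duration,
                            design$fs,
                            seed = derive_seed(seed, subject_id, condition, ch))
    dat[ch, ] <- sim$signal
    trajs[[ch]] <- sim$cf_trajectory
  }
  rec <- recording(dat, design$fs, subject_id = subject_id,
                   condition = condition, group = group)
  attr(rec, "cf_trajectories") <- trajs
  rec
}

#' Simulate a two-group, two-condition cohort
#'
#' @param design A [cohort_design()], e.g. from [cohort_preset()].
#' @return A list of `2 * (n_high + n_low)` [recording()] objects (classed
#'   `cohort`), ordered subject-major (pre then post per subject).
#' @examples
#' cohort <- simulate_cohort(cohort_preset("null", n_high = 2, n_low = 2,
#'                                         duration = 10))
#' length(cohort) # 8
#' @export
simulate_cohort <- function(design) {
  stopifnot(inherits(design, "cohort_design"))
  ids <- c(sprintf("H%02d", seq_len(design$n_high)),
           sprintf("L%02d", seq_len(design$n_low)))
  groups <- rep(c("high", "low"), c(design$n_high, design$n_low))
  out <- vector("list", 2L * length(ids))
  k <- 0L
  for (i in seq_along(ids)) {
    for (cond in c("pre", "post")) {
      k <- k + 1L
      out[[k]] <- simulate_subject(design, ids[i], groups[i], cond)
    }
  }
  structure(out, class = "cohort", design = design)
}

#' @export
print.cohort <- function(x, ...) {
  d <- attr(x, "design")
  cat(sprintf("<cohort> %d recordings (%d high + %d low subjects x pre/post), %d ch, %.0f s @ %g Hz\n",
              length(x), d$n_high, d$n_low, d$n_channels, d$duration, d$fs))
  invisible(x)
}
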