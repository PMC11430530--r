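#' Aperiodic (1/f-like) component specification
#'
#' Describes the arrhythmic part of a simulated EEG power spectrum,
#' `P(f) = 10^offset * f^-exponent`, i.e. a straight line with intercept
#' `offset` and slope `-exponent` in log10-log10 coordinates.
#'
#' @param offset Broadband offset `b`, in log10-power units.
#' @param exponent Spectral exponent `x` (slope magnitude); must be >= 0.
#' @return An object of class `aperiodic_spec`.
#' @examples
#' aperiodic_spec(offset = 0, exponent = 1)
#' @export
aperiodic_spec <- function(offset = 0, exponent = 1) {
  if (!is.numeric(offset) || length(offset) != 1L || !is.finite(offset))
    stop("`offset` must be a single finite number")
  if (!is.numeric(exponent) || length(exponent) != 1L || !is.finite(exponent))
    stop("`exponent` must be a single finite number")
  if (exponent < 0) stop("`exponent` must be >= 0")
  structure(list(offset = offset, exponent = exponent),
            class = "aperiodic_spec")
}

#' Alpha-peak dynamics specification
#'
#' Describes the rhythmic alpha component of a simulated channel: a spectral
#' peak of height `amplitude` (log10 units above the aperiodic component)
#' and width `width` (Gaussian SD, Hz), whose centre frequency wanders
#' around `mean_cf` with per-segment jitter `cf_jitter_sd`.
#'
#' Two centre-frequency processes are available: `"iid_gaussian"` draws
#' independent values `N(mean_cf, cf_jitter_sd)` clipped to 8--13 Hz;
#' `"bounded_random_walk"` integrates Gaussian steps of SD `cf_jitter_sd`
#' and reflects the walk at the band edges, giving the autocorrelated drift
#' seen in real alpha rhythms.
#'
#' @param mean_cf Mean centre frequency in Hz, inside the 8--13 Hz band.
#' @param cf_jitter_sd SD of the centre-frequency process, Hz (>= 0).
#' @param amplitude Peak height above the aperiodic fit at the peak
#'   frequency, log10-power units (>= 0; 0 disables the oscillation).
#' @param width Gaussian SD of the spectral peak, Hz.
#' @param trajectory_kind `"iid_gaussian"` or `"bounded_random_walk"`.
#' @return An object of class `alpha_dynamics_spec`.
#' @examples
#' alpha_dynamics_spec(mean_cf = 10, cf_jitter_sd = 0.5)
#' @export
alpha_dynamics_spec <- function(mean_cf = 10, cf_jitter_sd = 0.4,
                                amplitude = 1.5, width = 0.8,
                                trajectory_kind = c("iid_gaussian",
                                                    "bounded_random_walk")) {
  trajectory_kind <- match.arg(trajectory_kind)
  num1 <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
      stop(sprintf("`%s` must be a single finite number", nm))
    x
  }
  mean_cf <- num1(mean_cf, "mean_cf")
  cf_jitter_sd <- num1(cf_jitter_sd, "cf_jitter_sd")
  amplitude <- num1(amplitude, "amplitude")
  width <- num1(width, "width")
  if (mean_cf < 8 || mean_cf > 13)
    stop("`mean_cf` must lie within the 8-13 Hz alpha band")
  if (cf_jitter_sd < 0) stop("`cf_jitter_sd` must be >= 0")
  if (amplitude < 0) stop("`amplitude` must be >= 0")
  if (width < 0.75 || width > 6)
    stop("`width` (Gaussian SD) must lie in [0.75, 6] Hz")
  structure(list(mean_cf = mean_cf, cf_jitter_sd = cf_jitter_sd,
                 amplitude = amplitude, width = width,
                 trajectory_kind = trajectory_kind),
            class = "alpha_dynamics_spec")
}

#' Two-group, two-condition cohort design
#'
#' Bundles everything [simulate_cohort()] needs: group sizes, recording
#' geometry, and one `(aperiodic, alpha)` specification pair per
#' group-by-condition cell.
#'
#' @param n_high,n_low Subjects per susceptibility group (>= 2 each).
#' @param n_channels Number of EEG channels.
#' @param duration Recording duration per condition, seconds (>= 10).
#' @param fs Sampling rate, Hz (> 80 so that 40 Hz is resolvable).
#' @param group_condition_params Named list
#'   `list(high = list(pre =, post =), low = list(pre =, post =))`, each
#'   cell a `list(aperiodic = aperiodic_spec, alpha = alpha_dynamics_spec)`.
#' @param seed Integer master seed for the whole cohort.
#' @return An object of class `cohort_design`.
#' @seealso [cohort_preset()] for ready-made null / planted-effect designs.
#' @export
cohort_design <- function(n_high, n_low, n_channels, duration, fs,
                          group_condition_params, seed = 1L) {
  stopifnot(n_high >= 2, n_low >= 2, n_channels >= 1)
  if (duration < 10) stop("`duration` must be >= 10 s")
  if (fs <= 80) stop("`fs` must exceed 80 Hz so that 40 Hz is resolvable")
  for (g in c("high", "low")) {
    if (is.null(group_condition_params[[g]]))
      stop(sprintf("missing group '%s' in `group_condition_params`", g))
    for (cond in c("pre", "post")) {
      cell <- group_condition_params[[g]][[cond]]
      if (is.null(cell))
        stop(sprintf("missing condition '%s' for group '%s'", cond, g))
      if (!inherits(cell$aperiodic, "aperiodic_spec") ||
          !inherits(cell$alpha, "alpha_dynamics_spec"))
        stop("each design cell needs $aperiodic and $alpha specifications")
    }
  }
  structure(list(n_high = as.integer(n_high), n_low = as.integer(n_low),
                 n_channels = as.integer(n_channels),
                 duration = duration, fs = fs,
                 group_condition_params = group_condition_params,
                 seed = as.integer(seed)),
            class = "cohort_design")
}

#' Ready-made cohort designs
#'
#' `"null"` gives every group-by-condition cell identical parameters, so
#' group labels are exchangeable and any decoder should sit at chance.
#' `"effect"` keeps the two groups identical pre-induction but raises the
#' post-induction centre-frequency jitter of the high-susceptibility group
#' (1.0 Hz vs 0.4 Hz), the planted analogue of the headline finding that
#' high-susceptibility individuals show larger alpha-peak-frequency
#' variability under hypnosis.
#'
#' @param preset `"null"` or `"effect"`.
#' @param n_high,n_low,n_channels,duration,fs,seed See [cohort_design()].
#' @param cf_jitter_pre Pre-induction jitter SD for both groups, Hz.
#' @param cf_jitter_post_high,cf_jitter_post_low Post-induction jitter SDs.
#' @param base_alpha,base_aperiodic Template specifications shared by all
#'   cells (only `cf_jitter_sd` differs between cells).
#' @return A `cohort_design`.
#' @examples
#' d <- cohort_preset("effect", n_high = 3, n_low = 3, duration = 30)
#' @export
cohort_preset <- function(preset = c("null", "effect"),
                          n_high = 20, n_low = 20, n_channels = 8,
                          duration = 120, fs = 250, seed = 1L,
                          cf_jitter_pre = 0.4,
                          cf_jitter_post_high = if (preset == "effect") 1.0 else cf_jitter_pre,
                          cf_jitter_post_low = cf_jitter_pre,
                          base_alpha = alpha_dynamics_spec(),
                          base_aperiodic = aperiodic_spec()) {
  preset <- match.arg(preset)
  cell <- function(jit) {
    a <- base_alpha
    a$cf_jitter_sd <- jit
    list(aperiodic = base_aperiodic,
         alpha = do.call(alpha_dynamics_spec, unclass(a)))
  }
  params <- list(
    high = list(pre = cell(cf_jitter_pre), post = cell(cf_jitter_post_high)),
    low  = list(pre = cell(cf_jitter_pre), post = cell(cf_jitter_post_low)))
  cohort_design(n_high, n_low, n_channels, duration, fs, params, seed)
}
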