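#' Multichannel EEG recording container
#'
#' A light container for one subject-by-condition recording: a channels x
#' samples matrix plus sampling rate and metadata. All samples must be
#' finite (inputs are assumed artifact-cleaned).
#'
#' @param data Numeric matrix, channels x samples.
#' @param fs Sampling rate in Hz.
#' @param channel_names Character vector, one name per row of `data`.
#' @param subject_id Subject identifier.
#' @param condition `"pre"` or `"post"` (induction).
#' @param group `"high"` or `"low"` (hypnotic susceptibility), or `NA`.
#' @return An object of class `recording`.
#' @export
recording <- function(data, fs, channel_names = NULL,
                      subject_id = NA_character_,
                      condition = NA_character_, group = NA_character_) {
  if (!is.matrix(data) || !is.numeric(data))
    stop("`data` must be a numeric channels x samples matrix")
  if (any(!is.finite(data)))
    stop("recording contains non-finite samples")
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("`fs` must be a positive sampling rate in Hz")
  if (is.null(channel_names))
    channel_names <- sprintf("C%02d", seq_len(nrow(data)))
  if (length(channel_names) != nrow(data))
    stop("length(channel_names) must equal nrow(data)")
  if (!is.na(condition) && !condition %in% c("pre", "post"))
    stop("`condition` must be 'pre' or 'post'")
  if (!is.na(group) && !group %in% c("high", "low"))
    stop("`group` must be 'high' or 'low'")
  rownames(data) <- channel_names
  structure(list(data = data, fs = fs, channel_names = channel_names,
                 subject_id = subject_id, condition = condition,
                 group = group),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %s [%s/%s]: %d channels x %d samples @ %g Hz (%.1f s)\n",
              x$subject_id, x$group, x$condition, nrow(x$data),
              ncol(x$data), x$fs, ncol(x$data) / x$fs))
  invisible(x)
}

#' @export
plot.recording <- function(x, channels = seq_len(min(4L, nrow(x$data))),
                           t_max = 10, ...) {
  n <- min(ncol(x$data), round(t_max * x$fs))
  tt <- seq_len(n) / x$fs
  sub <- x$data[channels, seq_len(n), drop = FALSE]
  off <- 3 * stats::mad(sub)
  matplot(tt, t(sub + off * (seq_along(channels) - 1)), type = "l", lty = 1,
          xlab = "time (s)", ylab = "", yaxt = "n",
          main = sprintf("%s (%s)", x$subject_id, x$condition), ...)
  invisible(x)
}
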