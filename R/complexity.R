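#' Binarize a signal epoch
#'
#' Converts one epoch to a 0/1 sequence around a per-epoch threshold:
#' values strictly below the threshold become 0, values at or above it
#' become 1 (ties are deterministic). The default median split is
#' scale-free and invariant to monotone transforms of the signal.
#'
#' @param signal Numeric vector (>= 2 samples).
#' @param threshold_rule `"median"` or `"mean"`.
#' @return Integer vector of 0/1 values (class `binary_sequence`).
#' @examples
#' binarize_epoch(c(-1, 2, -3, 4)) # 0 1 0 1
#' @export
binarize_epoch <- function(signal, threshold_rule = c("median", "mean")) {
  threshold_rule <- match.arg(threshold_rule)
  if (length(signal) < 2) stop("epoch must have at least 2 samples")
  if (any(!is.finite(signal))) stop("epoch contains non-finite samples")
  thr <- if (threshold_rule == "median") median(signal) else mean(signal)
  structure(as.integer(signal >= thr), class = "binary_sequence",
            threshold = thr, rule = threshold_rule)
}

#' Lempel-Ziv (LZ76) complexity of a binary sequence
#'
#' Counts the components of the exhaustive production history: scanning
#' left to right, the current phrase is extended while it can be copied
#' from the prior history; every failed extension closes a component. An
#' incompressible random sequence of length n approaches `n / log2(n)`
#' components, so `c * log2(n) / n` normalizes toward 1 for fair-coin
#' noise.
#'
#' @param seq Integer/numeric vector of 0s and 1s (or a
#'   [binarize_epoch()] result).
#' @return Integer component count (>= 1).
#' @examples
#' lz76_complexity(rep(0, 50)) # 2: "0" then "0...0"
#' @export
lz76_complexity <- function(seq) {
  lz76_cpp(as.integer(seq))
}

#' Lempel-Ziv complexity features of a recording
#'
#' Splits each channel into non-overlapping epochs (trailing partial
#' epoch dropped), binarizes each epoch around its own threshold, and
#' computes the LZ76 component count plus its Shannon normalization
#' `c * log2(n) / n` per epoch.
#'
#' @param rec A [recording()].
#' @param epoch_len Epoch length in seconds.
#' @param threshold_rule Passed to [binarize_epoch()].
#' @return An object of class `lz_result`: `raw` and `normalized`
#'   (channels x epochs matrices), `mean_raw`, `mean_normalized` (per
#'   channel).
#' @export
compute_lz_features <- function(rec, epoch_len = 60,
                                threshold_rule = c("median", "mean")) {
  stopifnot(inherits(rec, "recording"))
  threshold_rule <- match.arg(threshold_rule)
  n_epoch <- round(epoch_len * rec$fs)
  n_full <- floor(ncol(rec$data) / n_epoch)
  if (n_full < 1)
    stop(sprintf("recording (%.1f s) shorter than one %.0f s epoch",
                 ncol(rec$data) / rec$fs, epoch_len))
  n_ch <- nrow(rec$data)
  raw <- matrix(NA_real_, n_ch, n_full)
  for (ch in seq_len(n_ch)) {
    for (e in seq_len(n_full)) {
      seg <- rec$data[ch, ((e - 1) * n_epoch + 1):(e * n_epoch)]
      raw[ch, e] <- lz76_complexity(binarize_epoch(seg, threshold_rule))
    }
  }
  normalized <- raw * log2(n_epoch) / n_epoch
  rownames(raw) <- rownames(normalized) <- rec$channel_names
  structure(list(raw = raw, normalized = normalized,
                 mean_raw = rowMeans(raw),
                 mean_normalized = rowMeans(normalized),
                 epoch_len = epoch_len, n_samples_epoch = n_epoch,
                 threshold_rule = threshold_rule,
                 subject_id = rec$subject_id, condition = rec$condition,
                 group = rec$group),
            class = "lz_result")
}

#' @export
print.lz_result <- function(x, ...) {
  cat(sprintf("<lz_result> %s [%s]: %d channels x %d epochs of %.0f s; normalized complexity %.3f-%.3f\n",
              x$subject_id, x$condition, nrow(x$raw), ncol(x$raw),
              x$epoch_len, min(x$mean_normalized), max(x$mean_normalized)))
  invisible(x)
}
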