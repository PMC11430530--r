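#' Derive a child seed deterministically
#'
#' Folds a master seed together with an arbitrary sequence of labels
#' (subject ids, channel indices, stage names, ...) into a new integer seed
#' below 2^31, so that every stochastic sub-task of a simulation has its own
#' reproducible stream regardless of evaluation order.
#'
#' @param seed Integer master seed.
#' @param ... Further atomic labels mixed into the hash.
#' @return A single integer in `[0, 2147483562]`.
#' @examples
#' derive_seed(1, "S01", "pre", 3)
#' @export
derive_seed <- function(seed, ...) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  m <- 2147483563
  h <- as.double(seed) %% m
  parts <- unlist(lapply(list(...), as.character), use.names = FALSE)
  for (p in parts) {
    for (b in utf8ToInt(p)) h <- (h * 31 + b) %% m
    h <- (h * 31 + 7) %% m # separator so c("ab","c") != c("a","bc")
  }
  as.integer(h)
}

# Evaluate `expr` under `seed` without disturbing the caller's RNG state;
# a NULL seed evaluates in the ambient stream.
with_seed_or_current <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(seed, expr)
}
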