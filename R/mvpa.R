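#' Decoding configuration
#'
#' Settings for class-balanced leave-one-subject-out decoding: each fold
#' holds one subject out and draws `n_per_class_train` subjects per class
#' at random from the remainder for training; the whole sweep is repeated
#' `n_repetitions` times. Significance comes from `n_permutations`
#' label-shuffled reruns (which may use fewer repetitions,
#' `perm_repetitions`, for tractability).
#'
#' @param n_per_class_train Training subjects drawn per class (15 matches
#'   a 38-subject cohort with 19 or 20 per group).
#' @param n_repetitions Repetitions of the LOOCV sweep for the observed
#'   statistic.
#' @param n_permutations Label permutations for the null distribution.
#' @param alpha One-tailed significance level.
#' @param n_tests_bonferroni Family size for Bonferroni correction
#'   (5 spectral features per contrast).
#' @param svm_c SVM regularization constant C.
#' @param standardize z-score channels on each training draw?
#' @param perm_repetitions Repetitions used inside each permutation.
#' @param seed Integer seed governing subject draws and permutations.
#' @return An object of class `decoding_config`.
#' @export
decoding_config <- function(n_per_class_train = 15, n_repetitions = 10,
                            n_permutations = 1000, alpha = 0.05,
                            n_tests_bonferroni = 5, svm_c = 1,
                            standardize = TRUE, perm_repetitions = 1,
                            seed = 1L) {
  stopifnot(n_per_class_train >= 1, n_repetitions >= 1,
            n_permutations >= 1, alpha > 0, alpha < 1,
            n_tests_bonferroni >= 1, svm_c > 0, perm_repetitions >= 1)
  structure(list(n_per_class_train = as.integer(n_per_class_train),
                 n_repetitions = as.integer(n_repetitions),
                 n_permutations = as.integer(n_permutations),
                 alpha = alpha,
                 n_tests_bonferroni = as.integer(n_tests_bonferroni),
                 svm_c = svm_c, standardize = isTRUE(standardize),
                 perm_repetitions = as.integer(perm_repetitions),
                 seed = as.integer(seed)),
            class = "decoding_config")
}

# Mann-Whitney AUC of decision values against binary labels (midranks).
auc_from_decisions <- function(decisions, is_positive) {
  n1 <- sum(is_positive)
  n0 <- sum(!is_positive)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(decisions) # midranks handle ties
  (sum(r[is_positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# One balanced-LOOCV sweep (all repetitions) for a given label vector;
# returns per-repetition AUCs and the summed Haufe pattern.
run_balanced_loocv <- function(X, labels, cfg, n_repetitions, haufe) {
  n <- nrow(X)
  y <- ifelse(labels == "high", 1, -1)
  idx_high <- which(y == 1)
  idx_low <- which(y == -1)
  m <- cfg$n_per_class_train
  if (m > length(idx_high) - 1 || m > length(idx_low) - 1)
    stop(sprintf("n_per_class_train = %d infeasible with %d high / %d low subjects",
                 m, length(idx_high), length(idx_low)))
  aucs <- numeric(n_repetitions)
  haufe_sum <- numeric(ncol(X))
  n_folds_total <- 0L
  for (rep_i in seq_len(n_repetitions)) {
    train_idx <- matrix(0L, 2L * m, n)
    for (f in seq_len(n)) {
      h_pool <- setdiff(idx_high, f)
      l_pool <- setdiff(idx_low, f)
      train_idx[, f] <- c(h_pool[sample.int(length(h_pool), m)],
                          l_pool[sample.int(length(l_pool), m)])
    }
    res <- linsvm_loocv_cpp(X, y, train_idx, seq_len(n), cfg$svm_c,
                            cfg$standardize, haufe)
    aucs[rep_i] <- auc_from_decisions(res$decisions, y == 1)
    haufe_sum <- haufe_sum + res$haufe_sum
    n_folds_total <- n_folds_total + n
  }
  list(aucs = aucs, haufe = haufe_sum / n_folds_total)
}

#' Balanced leave-one-subject-out SVM decoding
#'
#' For each repetition, every subject is held out once; a class-balanced
#' training set of `n_per_class_train` subjects per group is drawn at
#' random from the remainder, channels are z-scored on the training draw,
#' a linear SVM is fit, and the held-out decision value recorded. The AUC
#' is computed by rank comparison of the pooled held-out decision values
#' against the true labels within each repetition, then averaged across
#' repetitions. The Haufe activation pattern (training-feature covariance
#' times the weight vector) is averaged over all folds, converting the
#' classifier weights into an interpretable channel topography.
#'
#' @param table A [feature_table()].
#' @param cfg A [decoding_config()]; `cfg$seed` governs the subject draws.
#' @return List with `auc_observed`, `per_repetition_aucs`,
#'   `haufe_pattern`.
#' @export
balanced_loocv_auc <- function(table, cfg = decoding_config()) {
  stopifnot(inherits(table, "feature_table"),
            inherits(cfg, "decoding_config"))
  res <- withr::with_seed(
    derive_seed(cfg$seed, table$feature_name, table$condition_tag, "obs"),
    run_balanced_loocv(table$values, table$labels, cfg,
                       cfg$n_repetitions, haufe = TRUE))
  pat <- res$haufe
  names(pat) <- colnames(table$values)
  list(auc_observed = mean(res$aucs), per_repetition_aucs = res$aucs,
       haufe_pattern = pat)
}

#' Permutation test of decoding performance
#'
#' Reruns the full balanced-LOOCV procedure `n_permutations` times with
#' subject labels shuffled once per permutation (before the whole sweep,
#' so the test statistic stays exchangeable under the null), building a
#' surrogate AUC distribution. The p-value uses the add-one estimator
#' `(1 + #\{null >= observed\}) / (1 + n_permutations)`; performance is
#' flagged significant when the observed AUC exceeds the 95th percentile
#' of the surrogate distribution (one-tailed `alpha = 0.05`).
#'
#' @param table A [feature_table()].
#' @param cfg A [decoding_config()].
#' @return An object of class `decoding_result` with `auc_observed`,
#'   `per_repetition_aucs`, `null_aucs`, `p_value`, `significant_raw`,
#'   `significant_bonferroni`, `haufe_pattern`.
#' @export
permutation_test <- function(table, cfg = decoding_config()) {
  stopifnot(inherits(table, "feature_table"),
            inherits(cfg, "decoding_config"))
  obs <- balanced_loocv_auc(table, cfg)
  null_aucs <- withr::with_seed(
    derive_seed(cfg$seed, table$feature_name, table$condition_tag, "perm"),
    vapply(seq_len(cfg$n_permutations), function(p) {
      perm_labels <- sample(table$labels)
      mean(run_balanced_loocv(table$values, perm_labels, cfg,
                              cfg$perm_repetitions, haufe = FALSE)$aucs)
    }, numeric(1)))
  p_value <- (1 + sum(null_aucs >= obs$auc_observed)) /
    (1 + cfg$n_permutations)
  crit <- quantile(null_aucs, 1 - cfg$alpha, names = FALSE)
  structure(list(auc_observed = obs$auc_observed,
                 per_repetition_aucs = obs$per_repetition_aucs,
                 null_aucs = null_aucs, p_value = p_value,
                 significant_raw = obs$auc_observed > crit,
                 significant_bonferroni =
                   p_value <= cfg$alpha / cfg$n_tests_bonferroni,
                 haufe_pattern = obs$haufe_pattern,
                 feature_name = table$feature_name,
                 condition_tag = table$condition_tag, cfg = cfg),
            class = "decoding_result")
}

#' @export
print.decoding_result <- function(x, ...) {
  cat(sprintf("<decoding_result> %s [%s]: AUC = %.3f, p = %.4g%s%s\n",
              x$feature_name, x$condition_tag, x$auc_observed, x$p_value,
              if (x$significant_raw) " *" else "",
              if (x$significant_bonferroni) " (Bonferroni)" else ""))
  invisible(x)
}

#' @export
plot.decoding_result <- function(x, ...) {
  hist(x$null_aucs, breaks = 30, main = sprintf("%s [%s]", x$feature_name,
                                                x$condition_tag),
       xlab = "null AUC", col = "grey85", border = "white",
       xlim = range(c(x$null_aucs, x$auc_observed)), ...)
  abline(v = x$auc_observed, col = "red", lwd = 2)
  invisible(x)
}

#' Bonferroni adjustment of permutation p-values
#'
#' A result is family-wise significant when `p <= alpha / n_tests`.
#'
#' @param p_values Numeric vector of p-values.
#' @param n_tests Family size (>= `length(p_values)`).
#' @param alpha Family-wise level.
#' @return Logical vector of significance flags.
#' @export
bonferroni_adjust <- function(p_values, n_tests, alpha = 0.05) {
  if (n_tests < length(p_values))
    stop("`n_tests` must be at least the number of p-values")
  p.adjust(p_values, method = "bonferroni", n = n_tests) <= alpha
}

#' Decode every feature-by-contrast table
#'
#' Runs [permutation_test()] on each table and assembles a summary. The
#' Bonferroni family is the five spectral variability features within each
#' contrast; goodness-of-fit control features (`mean_mse`, `sd_mse`) and
#' complexity (`mean_lz`) form their own (smaller) families.
#'
#' @param tables Output of [assemble_feature_tables()].
#' @param cfg A [decoding_config()]; `n_tests_bonferroni` is set per
#'   family internally.
#' @param contrasts Which contrasts to decode.
#' @param features Optional subset of feature names; defaults to all.
#' @return List of `decoding_result`s (classed `decoding_set`) with a
#'   `summary` data.frame attribute: feature, contrast, auc, p, flags.
#' @export
decode_all_features <- function(tables, cfg = decoding_config(),
                                contrasts = c("pre", "delta"),
                                features = NULL) {
  main <- attr(tables, "main_features")
  if (is.null(main)) main <- character(0)
  fams <- list()
  results <- list()
  for (key in names(tables)) {
    tb <- tables[[key]]
    if (!tb$condition_tag %in% contrasts) next
    if (!is.null(features) && !tb$feature_name %in% features) next
    family <- if (tb$feature_name %in% main) "spectral"
      else if (tb$feature_name %in% c("mean_mse", "sd_mse")) "gof"
      else "complexity"
    fams[[key]] <- family
  }
  fam_sizes <- lapply(split(names(fams), unlist(fams)), length)
  # family size counts features within one contrast
  n_contrasts <- length(contrasts)
  for (key in names(fams)) {
    tb <- tables[[key]]
    cfg_k <- cfg
    cfg_k$n_tests_bonferroni <-
      max(1L, as.integer(fam_sizes[[fams[[key]]]] / n_contrasts))
    results[[key]] <- permutation_test(tb, cfg_k)
  }
  smry <- do.call(rbind, lapply(names(results), function(key) {
    r <- results[[key]]
    data.frame(feature = r$feature_name, contrast = r$condition_tag,
               family = fams[[key]], auc = r$auc_observed, p = r$p_value,
               significant_raw = r$significant_raw,
               significant_bonferroni = r$significant_bonferroni)
  }))
  smry <- smry[order(-smry$auc), ]
  rownames(smry) <- NULL
  structure(results, class = "decoding_set", summary = smry)
}

#' @export
print.decoding_set <- function(x, ...) {
  cat("<decoding_set>\n")
  print(attr(x, "summary"), digits = 3)
  invisible(x)
}
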