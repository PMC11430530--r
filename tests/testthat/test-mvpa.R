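test_that("rank AUC matches pROC and flips with labels", {
  withr::with_seed(1, {
    dec <- rnorm(40)
    pos <- rep(c(TRUE, FALSE), 20)
  })
  a <- alphadyn:::auc_from_decisions(dec, pos)
  oracle <- as.numeric(pROC::auc(pROC::roc(response = pos, predictor = dec,
                                           quiet = TRUE,
                                           direction = "<", levels = c(FALSE, TRUE))))
  expect_equal(a, oracle, tolerance = 1e-12)
  expect_equal(alphadyn:::auc_from_decisions(-dec, pos), 1 - a,
               tolerance = 1e-12)
  # ties get midrank treatment
  expect_equal(alphadyn:::auc_from_decisions(rep(0, 10),
                                             rep(c(TRUE, FALSE), 5)), 0.5)
})

test_that("dual coordinate-descent SVM agrees with the e1071 oracle", {
  withr::with_seed(2, {
    X <- rbind(matrix(rnorm(60, 1.5), 30, 2), matrix(rnorm(60, -1.5), 30, 2))
    y <- rep(c(1, -1), each = 30)
  })
  w <- alphadyn:::linsvm_weights_cpp(X, y, 1)
  m <- e1071::svm(X, factor(y), kernel = "linear", cost = 1, scale = FALSE)
  w_or <- drop(t(m$coefs) %*% m$SV)
  if (m$labels[1] == -1) w_or <- -w_or # e1071 orients by first label seen
  dec_cd <- X %*% w[1:2] + w[3]
  dec_or <- attr(predict(m, X, decision.values = TRUE), "decision.values")
  if (m$labels[1] == -1) dec_or <- -dec_or
  expect_gt(cor(dec_cd, dec_or), 0.98)
  # cosine similarity of the weight vectors
  expect_gt(sum(w[1:2] * w_or) / sqrt(sum(w[1:2]^2) * sum(w_or^2)), 0.98)
})

test_that("balanced LOOCV reaches the expected accuracy regimes", {
  cfg <- decoding_config(n_per_class_train = 10, n_repetitions = 3,
                         seed = 5)
  # perfectly separable univariate feature
  sep <- make_gauss_table(15, 1, effect = 50, seed = 3)
  expect_equal(balanced_loocv_auc(sep, cfg)$auc_observed, 1.0)

  # d-prime = 1 spherical Gaussians: the optimal linear rule has
  # AUC = Phi(1 / sqrt(2)) ~ 0.760 (closed-form oracle)
  big1 <- make_gauss_table(200, 1, effect = 1, seed = 4)
  cfg_big <- decoding_config(n_per_class_train = 100, n_repetitions = 2,
                             seed = 5)
  auc <- balanced_loocv_auc(big1, cfg_big)$auc_observed
  expect_lt(abs(auc - pnorm(1 / sqrt(2))), 0.05)

  # infeasible training draw errors out
  cfg_bad <- decoding_config(n_per_class_train = 15)
  expect_error(balanced_loocv_auc(make_gauss_table(10, 2, seed = 1), cfg_bad),
               "infeasible")
})

test_that("permutation test calibrates and bounds p-values", {
  cfg <- decoding_config(n_per_class_train = 8, n_repetitions = 2,
                         n_permutations = 99, seed = 7)
  # strong effect: observed beats every permutation, p at the add-one bound
  sep <- make_gauss_table(12, 2, effect = 6, seed = 8)
  res <- permutation_test(sep, cfg)
  expect_equal(res$p_value, 1 / 100)
  expect_true(res$significant_raw)
  expect_gte(res$p_value, 1 / (cfg$n_permutations + 1))

  # null features: surrogate distribution centred at chance
  nul <- make_gauss_table(12, 2, effect = 0, seed = 9)
  res0 <- permutation_test(nul, cfg)
  expect_lt(abs(mean(res0$null_aucs) - 0.5), 0.03)
  expect_length(res0$null_aucs, 99)
})

test_that("Bonferroni flags follow the family threshold", {
  expect_true(bonferroni_adjust(0.009, 5))     # 0.009 <= 0.05 / 5
  expect_false(bonferroni_adjust(0.02, 5))     # the classic near-miss
  # with a single test the decision reduces to the raw comparison
  expect_true(bonferroni_adjust(0.03, 1))
  expect_false(bonferroni_adjust(0.06, 1))
  expect_error(bonferroni_adjust(c(0.01, 0.02), 1), "at least")
})

test_that("Haufe patterns localize information and reduce to weights when white", {
  # whitened case: features built orthonormal; pattern proportional to w
  cfg <- decoding_config(n_per_class_train = 10, n_repetitions = 5, seed = 11)
  tab <- make_gauss_table(15, 3, effect = 1.5, informative = 2, seed = 12)
  res <- balanced_loocv_auc(tab, cfg)
  expect_equal(which.max(abs(res$haufe_pattern)), 2L)

  # correlated noise: informative channel still carries the top pattern
  tabc <- make_gauss_table(15, 4, effect = 1.5, informative = 1,
                           noise_cor = 0.5, seed = 13)
  resc <- balanced_loocv_auc(tabc, cfg)
  expect_equal(which.max(abs(resc$haufe_pattern)), 1L)
})

test_that("decoding every table yields the expected family layout", {
  tabs <- list()
  for (fn in c("sd_alpha_cf", "sd_alpha_amplitude", "sd_alpha_width",
               "sd_offset", "sd_exponent")) {
    for (ct in c("pre", "delta")) {
      tabs[[paste0(fn, ".", ct)]] <-
        make_gauss_table(10, 2, effect = if (fn == "sd_alpha_cf" &&
                                             ct == "delta") 4 else 0,
                         seed = nchar(fn) + nchar(ct),
                         feature_name = fn, condition_tag = ct)
    }
  }
  attr(tabs, "main_features") <- c("sd_alpha_cf", "sd_alpha_amplitude",
                                   "sd_alpha_width", "sd_offset",
                                   "sd_exponent")
  cfg <- decoding_config(n_per_class_train = 6, n_repetitions = 2,
                         n_permutations = 59, seed = 15)
  dec <- decode_all_features(tabs, cfg)
  smry <- attr(dec, "summary")
  expect_equal(nrow(smry), 10)
  expect_equal(sum(smry$family == "spectral"), 10)
  # the planted feature ranks first and its family size is 5
  expect_equal(smry$feature[1], "sd_alpha_cf")
  expect_equal(smry$contrast[1], "delta")
  expect_equal(dec[["sd_alpha_cf.delta"]]$cfg$n_tests_bonferroni, 5L)
})
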