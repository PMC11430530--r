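test_that("binarization splits around the epoch threshold", {
  b <- binarize_epoch(c(-1, 2, -3, 4))
  expect_equal(as.integer(b), c(0L, 1L, 0L, 1L))

  # median rule balances the sequence to within one sample
  withr::with_seed(1, {
    for (i in 1:10) {
      x <- rnorm(101 + i)
      m <- mean(binarize_epoch(x))
      expect_gte(m, 0.5 - 1e-12)
      expect_lte(m, 0.5 + 1 / length(x))
    }
  })

  # median binarization is invariant to monotone transforms
  withr::with_seed(2, x <- rnorm(501))
  expect_identical(as.integer(binarize_epoch(exp(x))),
                   as.integer(binarize_epoch(x)))
  expect_identical(as.integer(binarize_epoch(2 * x - 7)),
                   as.integer(binarize_epoch(x)))

  # mean vs median rules differ on few samples for symmetric noise
  withr::with_seed(3, x <- rnorm(15000))
  frac_diff <- mean(binarize_epoch(x, "mean") != binarize_epoch(x, "median"))
  expect_lt(frac_diff, 0.05)

  # constant signal: everything at the threshold maps to 1 (ties rule)
  expect_true(all(binarize_epoch(rep(3, 10)) == 1L))
  expect_error(binarize_epoch(3), "at least 2")
})

test_that("LZ76 matches the definitional brute-force parser", {
  expect_equal(lz76_complexity(rep(0, 2)), 2)
  expect_equal(lz76_complexity(rep(0, 500)), 2)
  expect_equal(lz76_complexity(c(1)), 1)
  expect_error(lz76_complexity(c(0, 1, 2)), "non-binary")

  # exhaustive check over all short strings
  for (n in 1:8) {
    for (v in 0:(2^n - 1)) {
      bits <- as.integer(intToBits(v))[1:n]
      expect_equal(lz76_complexity(bits), lz76_brute(bits),
                   info = paste("n =", n, "v =", v))
    }
  }

  # random medium-length strings
  withr::with_seed(4, {
    for (i in 1:50) {
      bits <- sample(0:1, 120, replace = TRUE)
      expect_equal(lz76_complexity(bits), lz76_brute(bits))
    }
  })
})

test_that("LZ76 is monotone along prefixes", {
  withr::with_seed(5, bits <- sample(0:1, 300, replace = TRUE))
  prev <- 0
  for (n in c(5, 20, 80, 150, 300)) {
    cur <- lz76_complexity(bits[1:n])
    expect_gte(cur, prev)
    prev <- cur
  }
})

test_that("normalized complexity separates noise from structure", {
  fs <- 250
  withr::with_seed(6, {
    noise <- rnorm(fs * 300)
    square <- rep(rep(c(0, 1), each = fs / 2), 150) + rnorm(fs * 300, 0, 1e-3)
  })
  rec <- recording(rbind(noise, square), fs,
                   channel_names = c("noise", "square"))
  lz <- compute_lz_features(rec, epoch_len = 60)
  expect_equal(ncol(lz$raw), 5) # 300 s / 60 s
  expect_gt(lz$mean_normalized["noise"], 5 * lz$mean_normalized["square"])

  # fair-coin sequences approach normalized complexity 1
  withr::with_seed(7, coin <- sample(0:1, 15000, replace = TRUE))
  c_norm <- lz76_complexity(coin) * log2(15000) / 15000
  expect_gt(c_norm, 0.85)
  expect_lt(c_norm, 1.15)

  expect_error(compute_lz_features(recording(matrix(rnorm(250), 1), 250),
                                   epoch_len = 60), "shorter than")
})
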