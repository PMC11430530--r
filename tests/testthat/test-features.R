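test_that("variability is the sample SD over available windows", {
  pts <- make_pts(list(
    C1 = list(alpha_cf = rep(10, 50)),             # constant -> 0
    C2 = list(alpha_cf = c(9, 11, rep(NA, 48))),   # {9,11} -> sqrt(2)
    C3 = list(alpha_cf = c(9.5, rep(NA, 49)))))    # < 2 windows -> NA
  v <- compute_variability(pts, "alpha_cf")
  expect_equal(unname(v["C1"]), 0)
  expect_equal(unname(v["C2"]), sqrt(2), tolerance = 1e-12)
  expect_true(is.na(v["C3"]))

  # recovery against the generating trajectory itself as oracle
  traj <- make_cf_trajectory(alpha_dynamics_spec(10, 0.8), 500, seed = 3)
  pts2 <- make_pts(list(C1 = list(alpha_cf = traj)))
  expect_lt(abs(compute_variability(pts2, "alpha_cf")[1] - sd(traj)), 1e-12)
})

test_that("variability is shift-invariant and absolutely homogeneous", {
  withr::with_seed(8, {
    x <- rnorm(200, 1, 0.4)
    for (k in c(-2, 0.5, 3)) {
      p1 <- make_pts(list(C = list(alpha_cf = x + k)))
      p2 <- make_pts(list(C = list(alpha_cf = x * k)))
      expect_equal(compute_variability(p1, "alpha_cf")[[1]], sd(x),
                   tolerance = 1e-12)
      expect_equal(compute_variability(p2, "alpha_cf")[[1]], abs(k) * sd(x),
                   tolerance = 1e-12)
    }
  })
})

test_that("delta tables subtract post minus pre with matched structure", {
  m <- matrix(0.3, 4, 3)
  lab <- c("high", "high", "low", "low")
  pre <- feature_table(m, "sd_alpha_cf", "pre", lab)
  post <- feature_table(m + 0.5, "sd_alpha_cf", "post", lab)
  d <- compute_delta(post, pre)
  expect_true(all(d$values == 0.5))
  expect_equal(d$condition_tag, "delta")

  # identity and antisymmetry
  expect_true(all(compute_delta(pre, pre)$values == 0))
  expect_equal(compute_delta(pre, post)$values, -d$values)

  bad <- feature_table(m[, 1:2], "sd_alpha_cf", "post", lab)
  expect_error(compute_delta(bad, pre), "channel sets differ")
  bad2 <- feature_table(m, "sd_alpha_cf", "post", lab,
                        subject_ids = c("a", "b", "c", "d"))
  expect_error(compute_delta(bad2, pre), "subject sets differ")
})

test_that("feature assembly produces the full family and applies exclusions", {
  mk_subj <- function(cfsd, flag_ch = FALSE) {
    mk <- function() {
      series <- list(
        C1 = list(alpha_cf = rnorm(60, 10, cfsd)),
        C2 = list(alpha_cf = if (flag_ch) rep(NA_real_, 60)
                             else rnorm(60, 10, cfsd)))
      if (flag_ch) series$C2$alpha_cf[1:5] <- 10 # coverage 5/60 < 0.25
      make_pts(series)
    }
    list(pre = mk(), post = mk(), group = sample(c("high", "low"), 1))
  }
  withr::with_seed(11, {
    pts <- lapply(1:8, function(i) mk_subj(0.5))
    names(pts) <- sprintf("S%02d", 1:8)
    for (i in 1:4) pts[[i]]$group <- "high"
    for (i in 5:8) pts[[i]]$group <- "low"
    tabs <- assemble_feature_tables(pts)
  })
  expect_setequal(attr(tabs, "main_features"),
                  c("sd_alpha_cf", "sd_alpha_amplitude", "sd_alpha_width",
                    "sd_offset", "sd_exponent"))
  # every feature appears for both contrasts; tables are subjects x channels
  expect_true(all(c("sd_alpha_cf.pre", "sd_alpha_cf.delta",
                    "sd_exponent.pre", "mean_mse.delta") %in% names(tabs)))
  expect_equal(dim(tabs[["sd_alpha_cf.pre"]]$values), c(8L, 2L))

  # a subject flagged in any channel disappears from every table
  withr::with_seed(12, {
    pts2 <- lapply(1:8, function(i) mk_subj(0.5, flag_ch = i == 3))
    names(pts2) <- sprintf("S%02d", 1:8)
    for (i in 1:4) pts2[[i]]$group <- "high"
    for (i in 5:8) pts2[[i]]$group <- "low"
    tabs2 <- assemble_feature_tables(pts2)
  })
  expect_equal(attr(tabs2, "excluded"), "S03")
  for (tb in tabs2) expect_false("S03" %in% tb$subject_ids)

  pts3 <- list(S01 = list(pre = pts[[1]]$pre, group = "high"))
  expect_error(assemble_feature_tables(pts3), "missing a condition")
})

test_that("null-cohort delta tables are centred at zero", {
  withr::with_seed(21, {
    pts <- lapply(1:10, function(i) {
      mk <- function() make_pts(list(C1 = list(alpha_cf = rnorm(80, 10, 0.5)),
                                     C2 = list(alpha_cf = rnorm(80, 10, 0.5))))
      list(pre = mk(), post = mk(),
           group = if (i <= 5) "high" else "low")
    })
    names(pts) <- sprintf("S%02d", 1:10)
    tabs <- assemble_feature_tables(pts)
  })
  d <- tabs[["sd_alpha_cf.delta"]]$values
  expect_lt(abs(mean(d)), 2 * sd(d) / sqrt(length(d)) + 0.02)
})
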