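test_that("ICC(2,1) reproduces hand-worked matrices", {
  # perfect agreement
  m_perfect <- cbind(c(1, 2, 3), c(1, 2, 3))
  r1 <- icc_2way_random_absolute(m_perfect)
  expect_equal(r1$icc, 1)

  # constant offset between raters: hand ANOVA gives 2/3
  m_offset <- cbind(c(1, 2, 3), c(2, 3, 4))
  r2 <- icc_2way_random_absolute(m_offset)
  expect_equal(r2$icc, 2 / 3)
  expect_equal(r2$ms$msr, 2)
  expect_equal(r2$ms$msc, 1.5)
  expect_equal(r2$ms$mse, 0)
  expect_true(r2$ci_low <= r2$icc && r2$icc <= r2$ci_high)

  expect_error(icc_2way_random_absolute(cbind(1, 1)), "at least 2")
  expect_error(icc_2way_random_absolute(matrix(3, 4, 3)), "zero")
})

test_that("ICC matches the ANOVA oracle and listwise-deletes missing rows", {
  withr::with_seed(42, {
    for (i in 1:10) {
      m <- matrix(rnorm(50), nrow = 10) + rnorm(10)
      expect_equal(icc_2way_random_absolute(m)$icc, oracle_icc_anova(m),
                   tolerance = 1e-12)
    }
    m <- matrix(rnorm(40), nrow = 8)
    m_na <- rbind(m, c(NA, rnorm(4)))
    expect_equal(icc_2way_random_absolute(m_na)$icc,
                 icc_2way_random_absolute(m)$icc)
  })
})

test_that("ICC is near zero for independent raters", {
  withr::with_seed(7, {
    m <- matrix(rnorm(5e4), ncol = 5)
    expect_lt(abs(icc_2way_random_absolute(m)$icc), 0.05)
  })
})

test_that("ICC interpretation bins are lower-inclusive", {
  expect_equal(interpret_icc(c(0.97, 0.49, 0.75, 0.5, 0.9, 0.89)),
               c("excellent", "poor", "good", "moderate", "excellent",
                 "good"))
})

test_that("Pearson correlation behaves and rejects degenerate input", {
  x <- c(1, 2, 3)
  expect_equal(pearson_r(x, x), 1)
  expect_equal(pearson_r(x, -x), -1)
  expect_equal(round(pearson_r(x, c(1, 2, 4)), 3), 0.982)
  expect_error(pearson_r(x, c(2, 2, 2)), "zero variance")
})

test_that("Lin's CCC penalises location and scale shift", {
  x <- c(1, 2, 3)
  expect_equal(lins_ccc(x, x)$ccc, 1)
  expect_equal(lins_ccc(x, c(2, 3, 4))$ccc, 4 / 7)

  withr::with_seed(13, {
    z <- rnorm(200)
    shifted <- 2 + 1.5 * z
    res <- lins_ccc(shifted, z)
    expect_equal(res$pearson_r, 1)
    expect_lt(res$ccc, 1)
    # equal means and variances: CCC equals Pearson r
    a <- rnorm(300)
    b <- rnorm(300)
    b <- (b - mean(b)) / sd(b) * sd(a) + mean(a)
    res2 <- lins_ccc(a, b)
    expect_equal(res2$ccc, res2$pearson_r, tolerance = 1e-12)
  })
  expect_error(lins_ccc(c(1, 1, 1), c(2, 2, 2)), "zero variance")
})

test_that("CCC interpretation follows the Altman ladder", {
  expect_equal(interpret_ccc(c(0.88, 0.59, 0.10, 0.8, 0.2)),
               c("excellent", "moderate", "poor", "excellent", "fair"))
})

test_that("absolute error and mean bias follow their definitions", {
  expect_equal(mean_absolute_error(c(1, 2), c(1, 2)), 0)
  expect_equal(mean_absolute_error(c(1, 3), c(2, 2)), 1)

  b <- mean_bias_loa(c(1, 3), c(2, 2))
  expect_equal(b$bias_mg, 0)
  expect_equal(round(b$loa_high_mg, 2), 2.77)   # 1.96 * sqrt(2)
  expect_equal(b$loa_low_mg, -b$loa_high_mg)

  b2 <- mean_bias_loa(c(7, 8, 9), c(2, 3, 4))   # constant +5 offset
  expect_equal(b2$bias_mg, 5)
  expect_equal(c(b2$loa_low_mg, b2$loa_high_mg), c(5, 5))
  # the SE-based CI is much narrower than the limits of agreement
  b3 <- mean_bias_loa(rnorm(100), rnorm(100))
  expect_lt(b3$ci_high_mg - b3$ci_low_mg, b3$loa_high_mg - b3$loa_low_mg)
})

test_that("Bland-Altman points are pairwise means and differences", {
  pts <- bland_altman_points(c(4, 2), c(2, 2))
  expect_equal(pts$mean_of_pair_mg, c(3, 2))
  expect_equal(pts$difference_mg, c(2, 0))
  tb <- perfect_epoch_table()
  pts2 <- bland_altman_points(tb$enmo_mean_mg, tb$reference_mg)
  expect_equal(nrow(pts2), nrow(tb))
  expect_true(all(pts2$difference_mg == 0))
})

test_that("validity summary pools seconds per brand", {
  tb <- perfect_epoch_table("actigraph", n_devices = 2, seconds = 0:9)
  sm <- summarize_validity(tb, "mean")
  expect_equal(nrow(sm), 1L)
  expect_equal(sm$n_obs, 2L * 7L * 10L)
  expect_equal(sm$pearson_r, 1)
  expect_equal(sm$ccc, 1)
  expect_equal(sm$mae_mg, 0)
  expect_equal(sm$bias_mg, 0)

  sm_rms <- summarize_validity(tb, "rms")
  expect_equal(sm_rms$n_obs, sm$n_obs)
  expect_error(summarize_validity(tb, "median"))
})

test_that("per-speed errors aggregate back to the pooled MAE", {
  withr::with_seed(99, {
    tb <- perfect_epoch_table("garmin", n_devices = 3, seconds = 0:19)
    tb$enmo_mean_mg <- tb$enmo_mean_mg + rnorm(nrow(tb), 0, 5)
    ps <- per_speed_error_summary(tb, "mean")
    expect_equal(nrow(ps), 7L)
    pooled <- summarize_validity(tb, "mean")
    expect_equal(sum(ps$mae_mg * ps$n_obs) / sum(ps$n_obs), pooled$mae_mg)
  })
})

test_that("reliability stacking recovers batch structure", {
  tb <- perfect_epoch_table("apple", n_devices = 5, seconds = 0:4)
  # perfectly agreeing devices in two identical batches
  expect_equal(summarize_reliability(list(tb, tb), "mean")$icc, 1)

  # a single batch equals the plain ICC on its matrix
  withr::with_seed(17, {
    tb2 <- tb
    tb2$enmo_mean_mg <- tb2$enmo_mean_mg + rnorm(nrow(tb2), 0, 3)
    direct <- icc_2way_random_absolute(reliability_matrix(tb2, "mean"))
    stacked <- summarize_reliability(tb2, "mean")
    expect_equal(stacked$icc, direct$icc)
    expect_equal(stacked$ci_low, direct$ci_low)
  })

  # inconsistent device counts across batches are an error
  tb3 <- perfect_epoch_table("apple", n_devices = 4, seconds = 0:4)
  expect_error(summarize_reliability(list(tb, tb3), "mean"), "inconsistent")
})

test_that("reliability ICC recovers known variance components", {
  withr::with_seed(23, {
    n <- 4000; k <- 5
    sr <- 1; sc <- 0; se <- 0.7
    m <- matrix(rnorm(n) * sqrt(sr), n, k) +
      matrix(rnorm(k) * sqrt(sc), n, k, byrow = TRUE) +
      matrix(rnorm(n * k) * sqrt(se), n, k)
    icc <- icc_2way_random_absolute(m)$icc
    expect_lt(abs(icc - sr / (sr + sc + se)), 0.02)
  })
})
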