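test_that("equivalence bounds resolve as fixed or as a reference fraction", {
  expect_equal(derive_bound(NULL, equivalence_bounds(6.3)), 6.3)

  tb <- make_epoch_table(
    device_id = "d1", brand = "custom", frequency_hz = 1.0,
    second_index = 0:9, enmo_mean_mg = rep(90, 10),
    reference_mg = rep(100, 10)
  )
  frac <- equivalence_bounds(derivation = "fraction_of_mean_reference",
                             fraction = 0.10)
  expect_equal(derive_bound(tb, frac), 10)
  expect_error(derive_bound(tb[0, ], frac), "empty")
  expect_error(equivalence_bounds(bound_mg = -1), "positive")

  # 10% of the mean reference over the validity frequencies is ~5.4 mg,
  # not the fixed 6.3 mg — both routes are available
  tb_val <- perfect_epoch_table("actigraph", n_devices = 1, seconds = 0:9)
  expect_equal(derive_bound(tb_val, frac),
               0.10 * mean(reference_acceleration_mg(validity_frequencies())),
               tolerance = 1e-12)
  expect_equal(round(derive_bound(tb_val, frac), 1), 5.4)
})

test_that("one-sample TOST matches hand-computed 90% intervals", {
  # zero differences are trivially equivalent
  r0 <- tost_one_sample(rep(0, 10), bound_mg = 1)
  expect_true(r0$equivalent)
  expect_equal(c(r0$lower90_mg, r0$upper90_mg), c(0, 0))

  # n = 9, mean 2, SD 3: SE = 1, t_{0.95,8} = 1.860, CI (0.14, 3.86)
  base <- c(-1.2, 0.4, 1.1, -0.8, 0.3, 1.9, -1.4, 0.2, -0.5)
  d <- 2 + 3 * (base - mean(base)) / sd(base)
  r1 <- tost_one_sample(d, bound_mg = 5)
  expect_equal(round(r1$lower90_mg, 2), 0.14)
  expect_equal(round(r1$upper90_mg, 2), 3.86)
  expect_true(r1$equivalent)
  expect_equal(r1$interpretation,
               "significantly within the equivalence bounds")

  # same spread, mean 4.5: CI (2.64, 6.36) crosses the bound
  d2 <- 4.5 + 3 * (base - mean(base)) / sd(base)
  r2 <- tost_one_sample(d2, bound_mg = 5)
  expect_equal(round(r2$lower90_mg, 2), 2.64)
  expect_equal(round(r2$upper90_mg, 2), 6.36)
  expect_false(r2$equivalent)
  expect_equal(r2$interpretation,
               "not significantly within the equivalence bounds")
})

test_that("degenerate inputs collapse the interval to the mean", {
  r <- tost_one_sample(rep(3, 5), bound_mg = 5)
  expect_true(r$equivalent)
  r2 <- tost_one_sample(rep(7, 5), bound_mg = 5)
  expect_false(r2$equivalent)
  r3 <- tost_one_sample(2, bound_mg = 5)
  expect_equal(c(r3$lower90_mg, r3$upper90_mg), c(2, 2))
})

test_that("CI rule and p-value rule agree on randomized inputs", {
  withr::with_seed(31, {
    for (i in 1:200) {
      n <- sample(3:40, 1)
      d <- rnorm(n, mean = runif(1, -8, 8), sd = runif(1, 0.1, 6))
      b <- runif(1, 0.5, 8)
      r <- tost_one_sample(d, bound_mg = b)
      expect_identical(r$equivalent, r$p_lower < 0.05 && r$p_upper < 0.05)
    }
  })
})

test_that("the equivalence report covers brand x aggregation", {
  tb <- dplyr::bind_rows(
    perfect_epoch_table("actigraph", 2, 0:9),
    perfect_epoch_table("apple", 2, 0:9),
    perfect_epoch_table("garmin", 2, 0:9),
    perfect_epoch_table("fitbit", 2, 0:9)
  )
  tb <- shakeval:::new_epoch_table(tb)
  rep_perfect <- table3_report(tb)
  expect_equal(nrow(rep_perfect), 8L)
  expect_true(all(rep_perfect$equivalent))

  # a +50 mg offset is far outside a 6.3 mg zone
  tb_off <- tb
  tb_off$enmo_mean_mg <- tb_off$enmo_mean_mg + 50
  tb_off$enmo_rms_mg <- tb_off$enmo_rms_mg + 50
  rep_off <- table3_report(shakeval:::new_epoch_table(tb_off))
  expect_true(all(!rep_off$equivalent))
  expect_true(all(abs(rep_off$mean_diff_mg - 50) < 1e-9))
})
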