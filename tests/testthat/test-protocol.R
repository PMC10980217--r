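test_that("frequency-to-acceleration conversion reproduces known values", {
  cfg_used <- shaker_config()
  cfg_printed <- shaker_config(conversion_variant = "as_printed")

  expect_equal(round(reference_acceleration_mg(0.6, cfg_used), 1), 4.4)
  expect_equal(round(reference_acceleration_mg(3.2, cfg_used), 1), 124.7)
  expect_equal(round(reference_acceleration_mg(0.6, cfg_printed), 1), 13.8)
  expect_equal(reference_acceleration_mg(0, cfg_used), 0)
  expect_equal(reference_acceleration_mg(0, cfg_printed), 0)
  expect_error(reference_acceleration_mg(-1), "non-negative")
})

test_that("conversion is quadratic, monotone, and variants differ by pi", {
  cfg_used <- shaker_config()
  cfg_printed <- shaker_config(conversion_variant = "as_printed")
  f <- c(0.3, 0.6, 1.0, 1.6, 2.5, 3.2)
  a <- reference_acceleration_mg(f, cfg_used)
  expect_true(all(diff(a) > 0))
  expect_equal(reference_acceleration_mg(2 * f, cfg_used), 4 * a)
  expect_equal(reference_acceleration_mg(f, cfg_printed) / a, rep(pi, 6))
})

test_that("validity protocol has the published layout", {
  p <- build_validity_protocol()
  expect_s3_class(p, "trial_protocol")
  expect_equal(nrow(p), 9L)
  expect_equal(protocol_duration(p), 870)
  expect_equal(sum(p$label == "oscillation"), 7L)
  # first oscillation block: 3.2 Hz starting at 15 s
  expect_equal(p$frequency_hz[2], 3.2)
  expect_equal(p$start_s[2], 15)
  expect_equal(p$frequency_hz[p$label == "oscillation"],
               c(3.2, 2.8, 2.4, 1.9, 1.5, 1.0, 0.6))
  # segments tile [0, total) without gaps or overlaps
  expect_equal(p$start_s, cumsum(c(0, head(p$duration_s, -1))))
})

test_that("reliability sequence durations match the batch timing", {
  expect_equal(protocol_duration(build_reliability_sequence(0.6, 5)), 630)
  expect_equal(protocol_duration(build_reliability_sequence(3.2, 1)), 150)
  p <- build_reliability_sequence(3.2, 5)
  osc <- p[p$label == "oscillation", ]
  expect_equal(nrow(osc), 5L)
  expect_true(all(osc$frequency_hz == 3.2))
  expect_equal(osc$trial_id, 1:5)
  expect_error(build_reliability_sequence(0.6, 0), "n_trials")

  # per-trial rests are longer: 5 * (15 + 120 + 15)
  p2 <- build_reliability_sequence(0.6, 5, per_trial_rests = TRUE)
  expect_equal(protocol_duration(p2), 750)
})

test_that("reliability design bookkeeping gives 80 trials", {
  design <- reliability_study_design()
  expect_equal(nrow(design), 4L * 2L * 2L)
  expect_equal(sum(design$n_trials), 80L)
})

test_that("reference trace maps segments to per-second reference values", {
  cfg <- shaker_config()
  p <- build_validity_protocol()
  tr <- reference_trace(p, cfg)
  expect_equal(nrow(tr), 870L)
  expect_equal(tr$second, 0:869)
  a32 <- reference_acceleration_mg(3.2, cfg)
  expect_true(all(tr$reference_mg[tr$second >= 15 & tr$second < 135] == a32))
  expect_true(all(tr$reference_mg[tr$second < 15] == 0))
  expect_true(all(tr$reference_mg[tr$second >= 855] == 0))

  p1 <- build_reliability_sequence(0.6, 1)
  tr1 <- reference_trace(p1, cfg)
  a06 <- reference_acceleration_mg(0.6, cfg)
  expect_equal(sum(tr1$reference_mg == 0), 30L)
  expect_equal(sum(abs(tr1$reference_mg - a06) < 1e-12), 120L)
})

test_that("protocol serialization round-trips through YAML and JSON", {
  p <- build_reliability_sequence(3.2, 3)
  for (ext in c("yaml", "json")) {
    path <- withr::local_tempfile(fileext = paste0(".", ext))
    write_protocol(p, path)
    q <- read_protocol(path)
    expect_equal(as.data.frame(q), as.data.frame(p))
    expect_equal(attr(q, "kind"), "reliability")
  }
})

test_that("degenerate shaker configurations are rejected", {
  expect_error(shaker_config(orbit_diameter_cm = 0))
  expect_error(shaker_config(gravity_cm_s2 = -1))
})
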