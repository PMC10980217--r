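test_that("brand presets carry the documented hardware parameters", {
  expect_equal(brand_preset("actigraph")$sampling_hz, 100)
  expect_equal(brand_preset("actigraph")$dynamic_range_g, 8)
  expect_equal(brand_preset("apple")$sampling_hz, 100)
  expect_equal(brand_preset("garmin")$sampling_hz, 25)
  expect_equal(brand_preset("fitbit")$sampling_hz, 50)
  expect_equal(brand_preset("fitbit")$dynamic_range_g, 4)
  expect_error(brand_preset("polar"), "unknown brand")
  # overrides pass through
  expect_equal(brand_preset("garmin", noise_sd_g = 0)$noise_sd_g, 0)
})

test_that("ideal plate acceleration is gravity at rest and a rotating
           constant-magnitude vector during oscillation", {
  cfg <- shaker_config()
  p <- build_validity_protocol()
  at_rest <- ideal_plate_acceleration(c(0, 5, 869.5), p, cfg)
  expect_equal(unname(at_rest),
               matrix(c(0, 0, 0, 0, 0, 0, 1, 1, 1), ncol = 3))

  t_osc <- seq(20, 130, by = 0.37)  # inside the 3.2 Hz block
  acc <- ideal_plate_acceleration(t_osc, p, cfg)
  horiz <- sqrt(acc[, 1]^2 + acc[, 2]^2)
  expect_equal(horiz,
               rep(reference_acceleration_mg(3.2, cfg) / 1000,
                   length(t_osc)))
  # the phase advances by exactly one turn over 1/f seconds
  a0 <- ideal_plate_acceleration(20, p, cfg)
  a1 <- ideal_plate_acceleration(20 + 1 / 3.2, p, cfg)
  expect_equal(a0, a1, tolerance = 1e-9)
  expect_error(ideal_plate_acceleration(870, p, cfg), "within")
})

test_that("ideal ENMO oracle matches closed forms", {
  cfg <- shaker_config()
  # flat mounting: constant ENMO (sqrt(1 + a^2) - 1) * 1000
  a32 <- reference_acceleration_mg(3.2, cfg) / 1000
  o <- ideal_enmo_stats(3.2, mounting_flat(), cfg)
  expect_equal(unname(o["mean_mg"]), (sqrt(1 + a32^2) - 1) * 1000,
               tolerance = 1e-10)
  expect_equal(unname(o["rms_mg"]), unname(o["mean_mg"]), tolerance = 1e-10)

  # at rest there is nothing to measure
  expect_equal(unname(ideal_enmo_stats(0)), c(0, 0))

  # upright mounting, small amplitude: mean ENMO ~ a^2 / 4 (in mg)
  cfg_small <- shaker_config()
  f_small <- sqrt(0.01 * 980 / (4 * pi * 0.95))  # frequency with a = 0.01 g
  o2 <- ideal_enmo_stats(f_small, mounting_upright(), cfg_small)
  expect_equal(unname(o2["mean_mg"]), 0.01^2 / 4 * 1000, tolerance = 0.01)
})

test_that("streams are deterministic in the seed and respect clipping", {
  cfg <- shaker_config()
  p <- build_reliability_sequence(3.2, 1)
  spec <- brand_preset("fitbit", device_id = "f1", dropout_rate = 0.05)
  s1 <- simulate_device_stream(p, spec, cfg, seed = 11)
  s2 <- simulate_device_stream(p, spec, cfg, seed = 11)
  s3 <- simulate_device_stream(p, spec, cfg, seed = 12)
  expect_identical(s1$data, s2$data)
  expect_false(identical(s1$data, s3$data))
  expect_true(all(abs(as.matrix(s1$data[, c("x_g", "y_g", "z_g")])) <= 4))

  # a 5 g bias on one axis against a +/-4 g range clips to 4 g
  spec_clip <- device_spec("c1", sampling_hz = 10, dynamic_range_g = 4,
                           noise_sd_g = 0, bias_g = c(5, 0, 0))
  sc <- simulate_device_stream(p, spec_clip, cfg, seed = 1)
  expect_true(all(sc$data$x_g == 4))
})

test_that("a noiseless device at rest records exactly (0, 0, 1)", {
  cfg <- shaker_config()
  p <- shakeval:::new_trial_protocol(
    tibble::tibble(label = "rest", frequency_hz = 0, duration_s = 10,
                   trial_id = NA_integer_),
    kind = "reliability"
  )
  spec <- device_spec("r1", sampling_hz = 20, noise_sd_g = 0,
                      mounting = mounting_flat())
  s <- simulate_device_stream(p, spec, cfg, seed = 3)
  expect_true(all(s$data$x_g == 0))
  expect_true(all(s$data$y_g == 0))
  expect_true(all(s$data$z_g == 1))
})

test_that("the all-negative-ENMO fault keeps the vector norm below 1 g", {
  cfg <- shaker_config()
  p <- build_validity_protocol()
  spec <- brand_preset("actigraph", device_id = "a210",
                       fault_mode = "all_negative_enmo")
  s <- simulate_device_stream(p, spec, cfg, seed = 9)
  enmo <- compute_enmo(s)
  expect_true(all(enmo < 0))
})

test_that("dropout removes whole seconds and nothing else", {
  cfg <- shaker_config()
  p <- build_reliability_sequence(0.6, 1)
  spec <- device_spec("d1", sampling_hz = 10, noise_sd_g = 0,
                      dropout_rate = 0.3)
  s <- simulate_device_stream(p, spec, cfg, seed = 21)
  secs <- table(floor(s$data$t_s + 1e-9))
  expect_true(all(secs == 10))          # surviving seconds are complete
  expect_lt(length(secs), 150)          # and some seconds are gone
})

test_that("brand batches vary between devices but are seed-reproducible", {
  d1 <- simulate_brand_devices("garmin", 3, seed = 5)
  d2 <- simulate_brand_devices("garmin", 3, seed = 5)
  expect_identical(d1, d2)
  expect_false(identical(d1[[1]]$bias_g, d1[[2]]$bias_g))
  expect_equal(vapply(d1, function(s) s$device_id, character(1)),
               c("garmin_01", "garmin_02", "garmin_03"))
})

test_that("mounting orientations must be orthonormal", {
  expect_error(mounting_orientation(matrix(1, 3, 3)), "orthonormal")
  expect_silent(mounting_orientation(mounting_upright()$rotation))
})
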