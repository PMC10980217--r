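#' Mounting orientation of a device on the shaker plate
#'
#' A 3x3 orthonormal rotation describing how the orbit-plane motion of the
#' shaker maps onto the device's sensing axes. The model keeps gravity fixed
#' along the device z axis and rotates the orbital motion relative to it, so
#' the orientation controls how much of the rotating centripetal acceleration
#' adds to, rather than stays perpendicular to, the gravity component — which
#' is what determines the ENMO magnitude the device reports.
#'
#' Two named orientations cover the cases of interest:
#' * `mounting_flat()` — identity; the orbital motion stays perpendicular to
#'   gravity, so the signal norm is constant at sqrt(1 + a^2) and ENMO is
#'   small (quadratic in the amplitude a).
#' * `mounting_upright()` — the orbit plane contains the gravity axis (a
#'   device clamped on edge); the norm oscillates as
#'   sqrt(1 + 2 a sin(theta) + a^2) over the cycle and second-level RMS ENMO
#'   scales roughly as a/sqrt(2), matching the magnitudes devices report on a
#'   shaker. This is the default mounting.
#'
#' @param rotation 3x3 orthonormal matrix (device axes in terms of
#'   orbit-plane x, y and the axis perpendicular to the plate).
#' @return An object of class `mounting_orientation`.
#' @export
mounting_orientation <- function(rotation = diag(3)) {
  rotation <- as.matrix(rotation)
  if (!all(dim(rotation) == c(3L, 3L)) ||
      max(abs(crossprod(rotation) - diag(3))) > 1e-8) {
    stop("`rotation` must be a 3x3 orthonormal matrix", call. = FALSE)
  }
  structure(list(rotation = rotation), class = "mounting_orientation")
}

#' @rdname mounting_orientation
#' @export
mounting_flat <- function() mounting_orientation(diag(3))

#' @rdname mounting_orientation
#' @export
mounting_upright <- function() {
  # rotate the orbit plane 90 degrees about its x axis: plate y -> device z
  mounting_orientation(matrix(c(1, 0, 0,
                                0, 0, -1,
                                0, 1, 0), nrow = 3, byrow = TRUE))
}

#' Device hardware model
#'
#' Describes a (simulated) accelerometer: sampling rate, dynamic range,
#' per-axis bias/gain/noise, mounting, dropout and fault modes. Defaults are
#' documented stand-ins for typical MEMS hardware, not calibrated to any real
#' device.
#'
#' @param device_id Identifier string.
#' @param brand One of `"actigraph"`, `"apple"`, `"garmin"`, `"fitbit"`,
#'   `"custom"`.
#' @param sampling_hz Sampling rate, samples per second.
#' @param dynamic_range_g Half-range in g; components are clipped to
#'   plus/minus this bound.
#' @param noise_sd_g Per-axis Gaussian noise SD in g (default 0.01, a typical
#'   MEMS noise scale).
#' @param bias_g Additive per-axis offset, length-3, in g.
#' @param gain Multiplicative per-axis scale, length-3.
#' @param mounting A [mounting_orientation()]; defaults to
#'   [mounting_upright()].
#' @param dropout_rate Probability that any whole 1 s block of samples is
#'   missing (0 <= rate < 1).
#' @param fault_mode `"none"` or `"all_negative_enmo"` (a faulty unit whose
#'   recorded vector norm never reaches 1 g, so every ENMO value is
#'   negative).
#' @return An object of class `device_spec`.
#' @export
device_spec <- function(device_id, brand = "custom", sampling_hz = 100,
                        dynamic_range_g = 8, noise_sd_g = 0.01,
                        bias_g = c(0, 0, 0), gain = c(1, 1, 1),
                        mounting = mounting_upright(), dropout_rate = 0,
                        fault_mode = c("none", "all_negative_enmo")) {
  fault_mode <- match.arg(fault_mode)
  brand <- match.arg(brand, c("actigraph", "apple", "garmin", "fitbit",
                              "custom"))
  stopifnot(
    sampling_hz > 0, dynamic_range_g > 0, noise_sd_g >= 0,
    length(bias_g) == 3L, length(gain) == 3L,
    dropout_rate >= 0, dropout_rate < 1,
    inherits(mounting, "mounting_orientation")
  )
  structure(
    list(device_id = as.character(device_id), brand = brand,
         sampling_hz = sampling_hz, dynamic_range_g = dynamic_range_g,
         noise_sd_g = noise_sd_g, bias_g = as.numeric(bias_g),
         gain = as.numeric(gain), mounting = mounting,
         dropout_rate = dropout_rate, fault_mode = fault_mode),
    class = "device_spec"
  )
}

#' Brand hardware presets
#'
#' Sampling rates follow the devices studied: ActiGraph 100 Hz, Apple 100 Hz,
#' Garmin 25 Hz, Fitbit 50 Hz. Dynamic ranges: ActiGraph +/-8 g, Fitbit
#' +/-4 g; Apple and Garmin are documented defaults of +/-8 g (not specified
#' by the hardware documentation available to us). All other parameters are
#' the [device_spec()] defaults and may be overridden through `...`.
#'
#' @param brand One of `"actigraph"`, `"apple"`, `"garmin"`, `"fitbit"`.
#' @param device_id Identifier; defaults to the brand name.
#' @param ... Overrides passed to [device_spec()].
#' @return A `device_spec`.
#' @examples
#' brand_preset("fitbit")$sampling_hz  # 50
#' @export
brand_preset <- function(brand, device_id = brand, ...) {
  presets <- list(
    actigraph = list(sampling_hz = 100, dynamic_range_g = 8),
    apple     = list(sampling_hz = 100, dynamic_range_g = 8),
    garmin    = list(sampling_hz = 25,  dynamic_range_g = 8),
    fitbit    = list(sampling_hz = 50,  dynamic_range_g = 4)
  )
  if (!brand %in% names(presets)) {
    stop("unknown brand: ", brand, call. = FALSE)
  }
  args <- c(list(device_id = device_id, brand = brand), presets[[brand]])
  override <- list(...)
  args[names(override)] <- override
  do.call(device_spec, args)
}

#' Ideal plate acceleration in the shaker frame
#'
#' The proper acceleration an ideal sensor riding the plate would measure,
#' in the shaker frame (x, y span the orbit plane, z up): during oscillation
#' at frequency f the rotating centripetal component of amplitude a (in g)
#' plus the constant 1 g gravity reaction on z; at rest, (0, 0, 1).
#'
#' @param t_s Times in seconds from protocol start; vectorised.
#' @param protocol A `trial_protocol`.
#' @param config A [shaker_config()] (fixes the amplitude via the conversion
#'   variant).
#' @param phase Phase offset at each segment start, radians; scalar or one
#'   value per protocol segment.
#' @return A length(t_s) x 3 matrix of accelerations in g.
#' @export
ideal_plate_acceleration <- function(t_s, protocol, config = shaker_config(),
                                     phase = 0) {
  stopifnot(inherits(protocol, "trial_protocol"))
  total <- protocol_duration(protocol)
  if (any(t_s < 0 | t_s >= total)) {
    stop("`t_s` must lie within [0, protocol duration)", call. = FALSE)
  }
  phase <- rep_len(phase, nrow(protocol))
  idx <- findInterval(t_s, protocol$start_s)
  f <- protocol$frequency_hz[idx]
  a <- reference_acceleration_mg(f, config) / 1000
  osc <- protocol$label[idx] == "oscillation"
  theta <- 2 * pi * f * (t_s - protocol$start_s[idx]) + phase[idx]
  out <- cbind(
    x = ifelse(osc, a * cos(theta), 0),
    y = ifelse(osc, a * sin(theta), 0),
    z = 1
  )
  rownames(out) <- NULL
  out
}

#' Closed-form / quadrature oracle for cycle-average ENMO
#'
#' Mean and RMS of per-sample ENMO over one full oscillation cycle for an
#' ideal noiseless device, used as an independent check on the sampled
#' pipeline. For a flat mounting ENMO is constant at
#' (sqrt(1 + a^2) - 1) * 1000; for any other mounting the cycle average is
#' computed by quadrature over the phase angle.
#'
#' @param f_hz Oscillation frequency, Hz.
#' @param mounting A [mounting_orientation()].
#' @param config A [shaker_config()].
#' @param n_quad Number of quadrature nodes over the cycle.
#' @return Named numeric vector `c(mean_mg, rms_mg)`.
#' @export
ideal_enmo_stats <- function(f_hz, mounting = mounting_upright(),
                             config = shaker_config(), n_quad = 4096) {
  stopifnot(f_hz >= 0)
  if (f_hz == 0) {
    return(c(mean_mg = 0, rms_mg = 0))
  }
  a <- reference_acceleration_mg(f_hz, config) / 1000
  theta <- (seq_len(n_quad) - 0.5) / n_quad * 2 * pi   # midpoint rule
  motion <- rbind(a * cos(theta), a * sin(theta), 0)
  dev <- mounting$rotation %*% motion
  dev[3, ] <- dev[3, ] + 1
  enmo <- (sqrt(colSums(dev^2)) - 1) * 1000
  c(mean_mg = mean(enmo), rms_mg = sqrt(mean(enmo^2)))
}

#' Simulate a raw triaxial device stream on the shaker
#'
#' Samples the ideal plate acceleration at the device's rate, maps the
#' orbital motion through the mounting orientation (gravity stays on the
#' device z axis), applies per-axis gain, bias and Gaussian noise, clips each
#' component to the dynamic range, and deletes whole 1 s blocks according to
#' the dropout rate. The phase at each segment start is drawn from the seeded
#' RNG, so per-second aggregates are phase-robust only for seconds containing
#' at least one full cycle. The same protocol, spec, config and seed always
#' reproduce an identical stream.
#'
#' The `"all_negative_enmo"` fault mode halves the recorded vector (a broken
#' sensitivity stage), so the vector norm never reaches 1 g and every
#' downstream ENMO value is negative — the implausible-device signature the
#' exclusion rule screens for.
#'
#' @param protocol A `trial_protocol`.
#' @param spec A [device_spec()].
#' @param config A [shaker_config()].
#' @param seed Integer seed; required for reproducibility.
#' @return A `raw_stream`: list with `device_id`, `brand`, `sampling_hz`,
#'   `spec`, `seed`, and `data`, a tibble of `t_s`, `x_g`, `y_g`, `z_g`.
#' @export
simulate_device_stream <- function(protocol, spec, config = shaker_config(),
                                   seed) {
  stopifnot(inherits(protocol, "trial_protocol"),
            inherits(spec, "device_spec"))
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  withr::with_seed(as.integer(seed), {
    total <- protocol_duration(protocol)
    fs <- spec$sampling_hz
    n <- round(total * fs)
    t_s <- (seq_len(n) - 1) / fs
    phase <- runif(nrow(protocol), 0, 2 * pi)
    plate <- ideal_plate_acceleration(t_s, protocol, config, phase = phase)
    motion <- plate
    motion[, 3] <- motion[, 3] - 1           # remove gravity from shaker z
    dev <- motion %*% t(spec$mounting$rotation)
    dev[, 3] <- dev[, 3] + 1                 # gravity on device z
    dev <- sweep(dev, 2, spec$gain, `*`)
    dev <- sweep(dev, 2, spec$bias_g, `+`)
    if (spec$noise_sd_g > 0) {
      dev <- dev + matrix(rnorm(3 * n, 0, spec$noise_sd_g), ncol = 3)
    }
    if (spec$fault_mode == "all_negative_enmo") {
      dev <- dev * 0.5
    }
    r <- spec$dynamic_range_g
    dev <- pmin(pmax(dev, -r), r)
    keep <- rep(TRUE, n)
    if (spec$dropout_rate > 0) {
      secs <- floor(t_s + 1e-9)
      dropped <- which(runif(total) < spec$dropout_rate) - 1L
      keep <- !(secs %in% dropped)
    }
    structure(
      list(
        device_id = spec$device_id, brand = spec$brand, sampling_hz = fs,
        spec = spec, seed = as.integer(seed),
        protocol_duration_s = total,
        data = tibble::tibble(t_s = t_s[keep], x_g = dev[keep, 1],
                              y_g = dev[keep, 2], z_g = dev[keep, 3])
      ),
      class = "raw_stream"
    )
  })
}

#' @export
print.raw_stream <- function(x, ...) {
  cat("<raw_stream>", x$device_id, sprintf("(%s, %g Hz, %d samples)\n",
      x$brand, x$sampling_hz, nrow(x$data)))
  invisible(x)
}

#' Simulate a batch of devices of one brand
#'
#' Draws per-device bias and gain perturbations around the brand preset so
#' that co-mounted units disagree realistically. Inter-device spread defaults
#' (bias SD 3 mg per axis, gain SD 0.2%) reflect factory-calibrated MEMS
#' parts: calibration error must stay small against gravity, since a 1% gain
#' error alone would shift the 1 g baseline by 10 mg — more than the entire
#' mean-aggregate ENMO signal of slow orbital motion — and would routinely
#' produce healthy devices whose ENMO never crosses zero. They are documented
#' modelling choices, not measured values.
#'
#' @param brand Brand name accepted by [brand_preset()].
#' @param n_devices Number of devices.
#' @param seed Integer seed governing the device-level draws.
#' @param bias_sd_g SD of per-axis additive bias across devices, g.
#' @param gain_sd SD of per-axis gain across devices.
#' @param ... Further overrides passed to [brand_preset()] for every device.
#' @return A list of `device_spec`s with `device_id`s `"<brand>_01"`, ...
#' @export
simulate_brand_devices <- function(brand, n_devices, seed,
                                   bias_sd_g = 0.003, gain_sd = 0.002, ...) {
  withr::with_seed(as.integer(seed), {
    lapply(seq_len(n_devices), function(i) {
      brand_preset(
        brand,
        device_id = sprintf("%s_%02d", brand, i),
        bias_g = rnorm(3, 0, bias_sd_g),
        gain = rnorm(3, 1, gain_sd),
        ...
      )
    })
  })
}
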