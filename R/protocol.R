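#' Orbital shaker configuration
#'
#' Describes the orbital shaker used as the acceleration reference. An orbital
#' shaker translates its plate in a horizontal circle of fixed diameter at a
#' set rotational frequency, so a device clamped to the plate experiences a
#' centripetal acceleration of constant magnitude that rotates in the orbit
#' plane.
#'
#' Two frequency-to-acceleration conversion variants are supported. The
#' textbook centripetal expression is a = 4 * pi^2 * r * f^2 (`"as_printed"`).
#' The reference magnitudes this class of study reports (4.4 mg at 0.6 Hz,
#' 124.7 mg at 3.2 Hz for a 1.9 cm orbit) correspond to a = 4 * pi * r * f^2,
#' i.e. the textbook value divided by pi; that variant (`"as_used"`) is the
#' default so that derived reference accelerations match the published
#' anchors. Both are retained and the ratio between them is exactly pi.
#'
#' @param orbit_diameter_cm Orbit diameter in cm (twice the orbit radius).
#' @param gravity_cm_s2 Standard gravity in cm/s^2 used to express the
#'   centripetal acceleration in units of g. 980 reproduces the published
#'   reference values to one decimal.
#' @param conversion_variant `"as_used"` (default) or `"as_printed"`; see
#'   Details.
#' @return An object of class `shaker_config`.
#' @examples
#' cfg <- shaker_config()
#' reference_acceleration_mg(3.2, cfg)
#' @export
shaker_config <- function(orbit_diameter_cm = 1.9,
                          gravity_cm_s2 = 980,
                          conversion_variant = c("as_used", "as_printed")) {
  conversion_variant <- match.arg(conversion_variant)
  if (!is.numeric(orbit_diameter_cm) || length(orbit_diameter_cm) != 1L ||
      orbit_diameter_cm <= 0) {
    stop("`orbit_diameter_cm` must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(gravity_cm_s2) || length(gravity_cm_s2) != 1L ||
      gravity_cm_s2 <= 0) {
    stop("`gravity_cm_s2` must be a single positive number", call. = FALSE)
  }
  structure(
    list(
      orbit_diameter_cm = orbit_diameter_cm,
      radius_cm = orbit_diameter_cm / 2,
      gravity_cm_s2 = gravity_cm_s2,
      conversion_variant = conversion_variant
    ),
    class = "shaker_config"
  )
}

#' @export
print.shaker_config <- function(x, ...) {
  cat("<shaker_config>\n")
  cat("  orbit diameter:", x$orbit_diameter_cm, "cm (radius",
      x$radius_cm, "cm)\n")
  cat("  gravity:", x$gravity_cm_s2, "cm/s^2\n")
  cat("  conversion variant:", x$conversion_variant, "\n")
  invisible(x)
}

#' Reference acceleration of the shaker plate at a given frequency
#'
#' Converts a shaker rotational frequency (Hz) to the magnitude of the
#' centripetal acceleration of the plate, expressed in milligravity (mg).
#' The result is quadratic in frequency and zero at rest.
#'
#' @param f_hz Rotational frequency in Hz (rotations per second); vectorised.
#' @param config A [shaker_config()].
#' @return Reference acceleration in mg, same length as `f_hz`.
#' @examples
#' reference_acceleration_mg(c(0.6, 3.2))
#' @export
reference_acceleration_mg <- function(f_hz, config = shaker_config()) {
  stopifnot(inherits(config, "shaker_config"))
  if (!is.numeric(f_hz) || any(!is.finite(f_hz)) || any(f_hz < 0)) {
    stop("`f_hz` must be finite and non-negative", call. = FALSE)
  }
  a_cm_s2 <- switch(config$conversion_variant,
    as_printed = 4 * pi^2 * config$radius_cm * f_hz^2,
    as_used    = 4 * pi   * config$radius_cm * f_hz^2
  )
  1000 * a_cm_s2 / config$gravity_cm_s2
}

#' Oscillation levels of the validity protocol
#'
#' The seven shaker frequencies used for validity testing, with their
#' reference accelerations under a given shaker configuration. Frequencies
#' span 0.6-3.2 Hz, chosen to bracket human locomotion cadences.
#'
#' @param frequencies_hz Frequencies in Hz; defaults to the protocol's seven
#'   speeds in test order (fastest first).
#' @param config A [shaker_config()].
#' @return A tibble with columns `frequency_hz`, `reference_mg`.
#' @export
oscillation_levels <- function(frequencies_hz = validity_frequencies(),
                               config = shaker_config()) {
  tibble::tibble(
    frequency_hz = frequencies_hz,
    reference_mg = reference_acceleration_mg(frequencies_hz, config)
  )
}

#' @rdname oscillation_levels
#' @export
validity_frequencies <- function() c(3.2, 2.8, 2.4, 1.9, 1.5, 1.0, 0.6)

new_trial_protocol <- function(segments, kind) {
  segments <- tibble::as_tibble(segments)
  stopifnot(all(c("label", "frequency_hz", "duration_s", "trial_id") %in%
                  names(segments)))
  if (any(segments$duration_s <= 0)) {
    stop("segment durations must be positive", call. = FALSE)
  }
  if (any(segments$label == "rest" & segments$frequency_hz != 0)) {
    stop("rest segments must have frequency 0", call. = FALSE)
  }
  segments$start_s <- cumsum(c(0, head(segments$duration_s, -1)))
  segments <- segments[, c("label", "frequency_hz", "start_s", "duration_s",
                           "trial_id")]
  structure(segments, kind = kind,
            class = c("trial_protocol", class(tibble::tibble())))
}

#' Total duration of a trial protocol in seconds
#' @param protocol A `trial_protocol`.
#' @return Duration in seconds.
#' @export
protocol_duration <- function(protocol) {
  stopifnot(inherits(protocol, "trial_protocol"))
  sum(protocol$duration_s)
}

#' Build the validity trial protocol
#'
#' A validity trial begins with a 15 s rest, runs through seven 2-minute
#' oscillation blocks at 3.2, 2.8, 2.4, 1.9, 1.5, 1.0 and 0.6 Hz (fastest
#' first), and ends with another 15 s rest: 870 s (14 min 30 s) in total.
#'
#' @param rest_s Rest duration at each end, seconds.
#' @param block_s Duration of each oscillation block, seconds.
#' @param frequencies_hz Oscillation frequencies in run order.
#' @param trial_id Identifier recorded on every segment.
#' @return A `trial_protocol` (tibble of segments with columns `label`,
#'   `frequency_hz`, `start_s`, `duration_s`, `trial_id`).
#' @examples
#' p <- build_validity_protocol()
#' protocol_duration(p)  # 870
#' @export
build_validity_protocol <- function(rest_s = 15, block_s = 120,
                                    frequencies_hz = validity_frequencies(),
                                    trial_id = 1L) {
  segs <- tibble::tibble(
    label = c("rest", rep("oscillation", length(frequencies_hz)), "rest"),
    frequency_hz = c(0, frequencies_hz, 0),
    duration_s = c(rest_s, rep(block_s, length(frequencies_hz)), rest_s),
    trial_id = as.integer(trial_id)
  )
  new_trial_protocol(segs, kind = "validity")
}

#' Build a reliability trial sequence
#'
#' One reliability batch runs `n_trials` back-to-back 2-minute oscillation
#' trials at a single speed, flanked by a 15 s rest at each end (the bookend
#' layout: five trials at one speed occupy 10 min 30 s). Set
#' `per_trial_rests = TRUE` to instead insert a rest before and after every
#' trial.
#'
#' @param speed_hz Oscillation frequency in Hz; the study used 0.6 and 3.2 Hz.
#' @param n_trials Number of consecutive trials (>= 1).
#' @param rest_s Rest duration, seconds.
#' @param trial_s Trial duration, seconds.
#' @param per_trial_rests Insert rests around every trial instead of only at
#'   the ends.
#' @return A `trial_protocol` with `trial_id` recorded on each oscillation
#'   segment.
#' @examples
#' protocol_duration(build_reliability_sequence(0.6, 5))  # 630
#' @export
build_reliability_sequence <- function(speed_hz, n_trials, rest_s = 15,
                                       trial_s = 120,
                                       per_trial_rests = FALSE) {
  if (!is.numeric(n_trials) || length(n_trials) != 1L || n_trials < 1) {
    stop("`n_trials` must be >= 1", call. = FALSE)
  }
  if (!is.numeric(speed_hz) || length(speed_hz) != 1L || speed_hz <= 0) {
    stop("`speed_hz` must be a single positive frequency", call. = FALSE)
  }
  n_trials <- as.integer(n_trials)
  if (per_trial_rests) {
    segs <- do.call(rbind, lapply(seq_len(n_trials), function(i) {
      tibble::tibble(
        label = c("rest", "oscillation", "rest"),
        frequency_hz = c(0, speed_hz, 0),
        duration_s = c(rest_s, trial_s, rest_s),
        trial_id = i
      )
    }))
  } else {
    segs <- tibble::tibble(
      label = c("rest", rep("oscillation", n_trials), "rest"),
      frequency_hz = c(0, rep(speed_hz, n_trials), 0),
      duration_s = c(rest_s, rep(trial_s, n_trials), rest_s),
      trial_id = c(NA_integer_, seq_len(n_trials), NA_integer_)
    )
  }
  new_trial_protocol(segs, kind = "reliability")
}

#' Reliability study design bookkeeping
#'
#' The full reliability design: for each brand, two batches of five
#' co-mounted devices are each run through `n_trials` trials at every speed.
#' With four brands, two batches, two speeds and five trials this gives the
#' study's 80 reliability trials.
#'
#' @param brands Character vector of device brands.
#' @param batches Number of 5-device batches per brand.
#' @param speeds_hz Speeds tested, Hz.
#' @param n_trials Trials per batch per speed.
#' @return A tibble with one row per brand x batch x speed and a `n_trials`
#'   column; `sum(n_trials)` is the total trial count.
#' @export
reliability_study_design <- function(brands = c("actigraph", "apple",
                                                "garmin", "fitbit"),
                                     batches = 2L,
                                     speeds_hz = c(0.6, 3.2),
                                     n_trials = 5L) {
  design <- expand.grid(
    brand = brands, batch = seq_len(batches), speed_hz = speeds_hz,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  design$n_trials <- as.integer(n_trials)
  tibble::as_tibble(design)
}

#' Per-second reference acceleration trace for a protocol
#'
#' One value per whole second of the protocol: 0 mg during rest, the
#' reference acceleration of the running frequency during oscillation.
#' Seconds are 0-based and half-open, measured from protocol start.
#'
#' @param protocol A `trial_protocol`.
#' @param config A [shaker_config()].
#' @return A tibble with columns `second`, `reference_mg`.
#' @export
reference_trace <- function(protocol, config = shaker_config()) {
  stopifnot(inherits(protocol, "trial_protocol"))
  total <- protocol_duration(protocol)
  seconds <- seq_len(total) - 1L
  idx <- findInterval(seconds, protocol$start_s)
  ref <- ifelse(protocol$label[idx] == "oscillation",
                reference_acceleration_mg(protocol$frequency_hz[idx], config),
                0)
  tibble::tibble(second = as.integer(seconds), reference_mg = ref)
}

#' Serialize / deserialize a trial protocol
#'
#' Protocols are written as YAML (or JSON) listing each segment's label,
#' frequency and duration, plus the protocol kind; start times are recomputed
#' on read.
#'
#' @param protocol A `trial_protocol`.
#' @param path Output (input) file path; format chosen by extension
#'   (`.yaml`/`.yml` or `.json`).
#' @return `write_protocol()` returns `path` invisibly; `read_protocol()`
#'   returns a `trial_protocol`.
#' @export
write_protocol <- function(protocol, path) {
  stopifnot(inherits(protocol, "trial_protocol"))
  obj <- list(
    kind = attr(protocol, "kind"),
    segments = lapply(seq_len(nrow(protocol)), function(i) {
      seg <- list(label = protocol$label[i],
                  frequency_hz = protocol$frequency_hz[i],
                  duration_s = protocol$duration_s[i])
      if (!is.na(protocol$trial_id[i])) seg$trial_id <- protocol$trial_id[i]
      seg
    })
  )
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(obj, path)
  }
  invisible(path)
}

#' @rdname write_protocol
#' @export
read_protocol <- function(path) {
  obj <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  segs <- do.call(rbind, lapply(obj$segments, function(s) {
    tibble::tibble(
      label = s$label,
      frequency_hz = as.numeric(s$frequency_hz),
      duration_s = as.numeric(s$duration_s),
      trial_id = if (is.null(s$trial_id) || length(s$trial_id) != 1L) {
        NA_integer_
      } else {
        as.integer(s$trial_id)
      }
    )
  }))
  new_trial_protocol(segs, kind = obj$kind)
}

#' Export the per-second reference trace as CSV
#'
#' @inheritParams reference_trace
#' @param path Output CSV path (columns `second`, `reference_mg`).
#' @return `path`, invisibly.
#' @export
write_reference_trace <- function(protocol, path, config = shaker_config()) {
  readr::write_csv(reference_trace(protocol, config), path)
  invisible(path)
}
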