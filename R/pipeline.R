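#' Per-sample ENMO of a raw stream
#'
#' ENMO (Euclidean Norm Minus One) is the vector magnitude of the triaxial
#' acceleration in g minus 1 g, scaled to milligravity (mg): for each sample,
#' `(sqrt(x^2 + y^2 + z^2) - 1) * 1000`. Negative values are retained by
#' default — a device whose norm sits below 1 g produces all-negative ENMO,
#' which is exactly the implausibility signature the exclusion rule needs to
#' see — with truncation at zero available as an option for workflows that
#' follow the GGIR convention.
#'
#' @param stream A `raw_stream` (see [simulate_device_stream()] or
#'   [read_raw_csv()]).
#' @param truncate_zero Truncate negative ENMO to 0 (default `FALSE`).
#' @return Numeric vector of per-sample ENMO in mg, one per stream sample.
#' @examples
#' # a 3-4-5 triple has unit norm, so ENMO = 0
#' @export
compute_enmo <- function(stream, truncate_zero = FALSE) {
  stopifnot(inherits(stream, "raw_stream"))
  d <- stream$data
  if (nrow(d) == 0L) stop("stream is empty", call. = FALSE)
  enmo <- (sqrt(d$x_g^2 + d$y_g^2 + d$z_g^2) - 1) * 1000
  if (truncate_zero) enmo <- pmax(enmo, 0)
  enmo
}

#' Aggregate per-sample ENMO to second-level mean and RMS
#'
#' Groups samples into whole seconds `[s, s + 1)` measured from stream start
#' and computes the arithmetic mean and the root mean square of ENMO within
#' each second. Seconds with fewer samples than the sampling rate (partial
#' boundary seconds, dropped blocks) are omitted rather than padded.
#'
#' @param enmo_mg Per-sample ENMO in mg.
#' @param t_s Sample timestamps in seconds, same length.
#' @param sampling_hz Nominal sampling rate used to decide completeness.
#' @return A tibble with columns `second`, `enmo_mean_mg`, `enmo_rms_mg`.
#' @export
aggregate_to_seconds <- function(enmo_mg, t_s, sampling_hz) {
  stopifnot(length(enmo_mg) == length(t_s), sampling_hz > 0)
  sec <- as.integer(floor(t_s + 1e-9))
  out <- tibble::tibble(second = sec, enmo = enmo_mg) |>
    dplyr::group_by(.data$second) |>
    dplyr::summarise(
      n = dplyr::n(),
      enmo_mean_mg = mean(.data$enmo),
      enmo_rms_mg = sqrt(mean(.data$enmo^2)),
      .groups = "drop"
    )
  out <- out[out$n >= round(sampling_hz), c("second", "enmo_mean_mg",
                                            "enmo_rms_mg")]
  out
}

#' Extract the middle minute of each oscillation block
#'
#' Keeps the seconds with index 30-89 of every 2-minute oscillation segment
#' (the unique centred minute, avoiding spin-up/spin-down transients at the
#' block edges) and labels them with the segment frequency, trial and
#' within-segment second index. Rest segments contribute nothing.
#'
#' @param seconds_tbl Per-second tibble from [aggregate_to_seconds()].
#' @param protocol The `trial_protocol` the stream followed.
#' @param window Half-open within-segment window of seconds to keep.
#' @return A tibble with columns `trial_id`, `frequency_hz`, `second_index`,
#'   `enmo_mean_mg`, `enmo_rms_mg`.
#' @export
extract_middle_minute <- function(seconds_tbl, protocol,
                                  window = c(30, 90)) {
  stopifnot(inherits(protocol, "trial_protocol"))
  osc <- protocol[protocol$label == "oscillation", ]
  if (any(osc$duration_s < 120)) {
    stop("protocol mismatch: oscillation segments must last >= 120 s",
         call. = FALSE)
  }
  pieces <- lapply(seq_len(nrow(osc)), function(i) {
    lo <- osc$start_s[i] + window[1]
    hi <- osc$start_s[i] + window[2]
    keep <- seconds_tbl[seconds_tbl$second >= lo & seconds_tbl$second < hi, ]
    if (nrow(keep) == 0L) return(NULL)
    tibble::tibble(
      trial_id = osc$trial_id[i],
      frequency_hz = osc$frequency_hz[i],
      second_index = as.integer(keep$second - osc$start_s[i]),
      enmo_mean_mg = keep$enmo_mean_mg,
      enmo_rms_mg = keep$enmo_rms_mg
    )
  })
  out <- dplyr::bind_rows(pieces)
  if (nrow(out) == 0L) {
    out <- tibble::tibble(trial_id = integer(), frequency_hz = double(),
                          second_index = integer(), enmo_mean_mg = double(),
                          enmo_rms_mg = double())
  }
  out
}

empty_epoch_table <- function() {
  tibble::tibble(
    device_id = character(), brand = character(), trial_id = integer(),
    frequency_hz = double(), second_index = integer(),
    enmo_mean_mg = double(), enmo_rms_mg = double(), reference_mg = double()
  )
}

new_epoch_table <- function(records, provenance = list()) {
  structure(tibble::as_tibble(records), provenance = provenance,
            class = c("epoch_table", class(tibble::tibble())))
}

#' Build the long analysis table of device-seconds
#'
#' Runs every stream through ENMO computation, second-level aggregation and
#' middle-minute extraction, then joins the shaker reference acceleration of
#' the running frequency. One row per device-second, the unit of analysis for
#' all downstream statistics. Streams are assumed time-aligned to the
#' protocol start; apply `offset_s` per device if a clock offset is known.
#'
#' @param streams A list of `raw_stream`s (a single stream is accepted).
#' @param protocol The `trial_protocol` all streams followed.
#' @param config A [shaker_config()].
#' @param truncate_zero Passed to [compute_enmo()].
#' @param offset_s Per-device clock offset in seconds subtracted from
#'   timestamps before alignment; scalar or one per stream.
#' @return An `epoch_table` tibble with columns `device_id`, `brand`,
#'   `trial_id`, `frequency_hz`, `second_index`, `enmo_mean_mg`,
#'   `enmo_rms_mg`, `reference_mg`.
#' @export
build_epoch_table <- function(streams, protocol, config = shaker_config(),
                              truncate_zero = FALSE, offset_s = 0) {
  if (inherits(streams, "raw_stream")) streams <- list(streams)
  if (length(streams) == 0L) {
    return(new_epoch_table(empty_epoch_table()))
  }
  stopifnot(all(vapply(streams, inherits, logical(1), "raw_stream")),
            inherits(protocol, "trial_protocol"))
  offset_s <- rep_len(offset_s, length(streams))
  total <- protocol_duration(protocol)
  levels <- oscillation_levels(
    unique(protocol$frequency_hz[protocol$label == "oscillation"]), config
  )
  pieces <- lapply(seq_along(streams), function(i) {
    s <- streams[[i]]
    t_s <- s$data$t_s - offset_s[i]
    # allow a couple of trailing dropped seconds, but reject streams that
    # genuinely do not span the protocol
    if (nrow(s$data) == 0L || max(t_s) + 1 / s$sampling_hz < total - 2) {
      stop("stream '", s$device_id, "' is shorter than the protocol",
           call. = FALSE)
    }
    enmo <- compute_enmo(s, truncate_zero = truncate_zero)
    secs <- aggregate_to_seconds(enmo, t_s, s$sampling_hz)
    mid <- extract_middle_minute(secs, protocol)
    if (nrow(mid) == 0L) return(NULL)
    tibble::tibble(device_id = s$device_id, brand = s$brand, mid)
  })
  records <- dplyr::bind_rows(pieces)
  if (nrow(records) == 0L) records <- empty_epoch_table()
  records <- dplyr::left_join(records, levels, by = "frequency_hz")
  new_epoch_table(
    records,
    provenance = list(
      conversion_variant = config$conversion_variant,
      truncate_zero = truncate_zero,
      middle_minute = c(30, 90),
      n_streams = length(streams)
    )
  )
}

#' Exclude devices whose ENMO is implausible throughout
#'
#' A device is excluded when every one of its second-level mean ENMO values
#' is below 0 mg — the signature of a faulty unit whose recorded magnitude
#' never reaches 1 g. Devices with at least one non-negative value are kept
#' (the rule is "all values below zero"). Exclusions are reported with a
#' reason so the decision is auditable.
#'
#' @param table An `epoch_table`.
#' @param expected_device_ids Optionally, the full roster of device ids that
#'   should appear; a device with no observations at all is kept (the rule
#'   holds vacuously) with a warning documenting the ambiguity.
#' @return A list with `table` (the kept rows, still an `epoch_table`) and
#'   `excluded` (tibble of `device_id`, `reason`).
#' @export
flag_implausible_devices <- function(table, expected_device_ids = NULL) {
  stopifnot(inherits(table, "epoch_table"))
  if (!is.null(expected_device_ids)) {
    missing_ids <- setdiff(expected_device_ids, unique(table$device_id))
    if (length(missing_ids) > 0L) {
      warning("device(s) with no observations kept (exclusion rule is ",
              "vacuous): ", paste(missing_ids, collapse = ", "),
              call. = FALSE)
    }
  }
  if (nrow(table) == 0L) {
    return(list(table = table,
                excluded = tibble::tibble(device_id = character(),
                                          reason = character())))
  }
  by_dev <- dplyr::summarise(
    dplyr::group_by(table, .data$device_id),
    n = dplyr::n(),
    all_negative = all(.data$enmo_mean_mg < 0),
    .groups = "drop"
  )
  bad <- by_dev$device_id[by_dev$all_negative & by_dev$n > 0L]
  excluded <- tibble::tibble(
    device_id = bad,
    reason = rep("all second-level mean ENMO values below 0 mg", length(bad))
  )
  kept <- table[!table$device_id %in% bad, ]
  list(table = new_epoch_table(kept, attr(table, "provenance")),
       excluded = excluded)
}
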