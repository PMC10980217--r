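default_study_config <- function() {
  list(
    seed = 1L,
    out_dir = "results",
    shaker = list(orbit_diameter_cm = 1.9, gravity_cm_s2 = 980,
                  conversion_variant = "as_used"),
    brands = c("actigraph", "apple", "garmin", "fitbit"),
    devices_per_brand = 10L,
    noise_sd_g = 0.01,
    bias_sd_g = 0.003,
    gain_sd = 0.002,
    bound = list(bound_mg = 6.3, derivation = "fixed", fraction = 0.10),
    reliability = list(speeds_hz = c(0.6, 3.2), n_trials = 5L, batches = 2L),
    write_epoch_table = TRUE
  )
}

load_study_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.json$", config, ignore.case = TRUE)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  stopifnot(is.list(config))
  defaults <- default_study_config()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0L) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  merged <- utils::modifyList(defaults, config)
  merged$seed <- as.integer(merged$seed)
  merged
}

#' Run the full shaker validation study end-to-end
#'
#' Simulates raw streams for every brand (validity trial and all reliability
#' batches), processes them to the epoch table, applies the
#' implausible-device exclusion, computes the reliability ICC table, the
#' validity summary table, the per-speed error summary, Bland-Altman points
#' and the equivalence (TOST) table, and writes everything as CSV to the
#' output directory along with a plain-text run log recording the seeds and
#' exclusion decisions. Deterministic for a fixed configuration.
#'
#' @param config A configuration list, or the path of a YAML/JSON file.
#'   Recognised keys (all optional): `seed`, `out_dir`, `shaker`
#'   (`orbit_diameter_cm`, `gravity_cm_s2`, `conversion_variant`), `brands`,
#'   `devices_per_brand`, `noise_sd_g`, `bias_sd_g`, `gain_sd`, `bound`
#'   (`bound_mg`, `derivation`, `fraction`), `reliability` (`speeds_hz`,
#'   `n_trials`, `batches`), `write_epoch_table`. Unknown keys are rejected
#'   before any computation.
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with `epoch_table`, `excluded`, `reliability`
#'   (Table 1 analogue), `validity` (Table 2 analogue), `per_speed`,
#'   `equivalence` (Table 3 analogue), `bland_altman`, and `config`.
#' @export
run_study <- function(config = list(), quiet = FALSE) {
  cfg <- load_study_config(config)
  say <- function(...) if (!quiet) message(...)
  shaker <- shaker_config(cfg$shaker$orbit_diameter_cm,
                          cfg$shaker$gravity_cm_s2,
                          cfg$shaker$conversion_variant)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)

  seeds <- withr::with_seed(cfg$seed, {
    sample.int(.Machine$integer.max - 1L, 2L)
  })

  # --- validity arm -------------------------------------------------------
  validity_protocol <- build_validity_protocol()
  say("simulating validity streams for ",
      length(cfg$brands), " brand(s) x ", cfg$devices_per_brand,
      " device(s)")
  streams <- list()
  for (bi in seq_along(cfg$brands)) {
    brand <- cfg$brands[bi]
    specs <- simulate_brand_devices(
      brand, cfg$devices_per_brand, seed = seeds[1] %% 2e9 + bi,
      bias_sd_g = cfg$bias_sd_g, gain_sd = cfg$gain_sd,
      noise_sd_g = cfg$noise_sd_g
    )
    streams <- c(streams, lapply(seq_along(specs), function(i) {
      simulate_device_stream(validity_protocol, specs[[i]], shaker,
                             seed = (seeds[1] + bi * 1000L + i) %% 2000000000L)
    }))
  }
  epochs <- build_epoch_table(streams, validity_protocol, shaker)
  screened <- flag_implausible_devices(epochs)
  if (nrow(screened$excluded) > 0L) {
    say("excluded device(s): ",
        paste(screened$excluded$device_id, collapse = ", "))
  }
  kept <- screened$table

  validity <- dplyr::bind_rows(
    summarize_validity(kept, "mean"), summarize_validity(kept, "rms")
  )
  per_speed <- dplyr::bind_rows(
    per_speed_error_summary(kept, "mean"), per_speed_error_summary(kept, "rms")
  )
  bounds <- equivalence_bounds(cfg$bound$bound_mg, cfg$bound$derivation,
                               cfg$bound$fraction)
  equivalence <- table3_report(kept, bounds)
  ba <- dplyr::bind_rows(lapply(c("mean", "rms"), function(agg) {
    dplyr::bind_rows(lapply(unique(kept$brand), function(b) {
      sub <- kept[kept$brand == b, ]
      pts <- bland_altman_points(pick_aggregate(sub, agg), sub$reference_mg)
      tibble::tibble(brand = b, aggregation = agg, pts)
    }))
  }))

  # --- reliability arm ----------------------------------------------------
  say("simulating reliability batches")
  rel_rows <- list()
  for (bi in seq_along(cfg$brands)) {
    brand <- cfg$brands[bi]
    batch_tables <- list()
    for (batch in seq_len(cfg$reliability$batches)) {
      specs <- simulate_brand_devices(
        brand, 5L, seed = (seeds[2] + bi * 100L + batch) %% 2000000000L,
        bias_sd_g = cfg$bias_sd_g, gain_sd = cfg$gain_sd,
        noise_sd_g = cfg$noise_sd_g
      )
      for (si in seq_along(cfg$reliability$speeds_hz)) {
        speed <- cfg$reliability$speeds_hz[si]
        protocol <- build_reliability_sequence(speed,
                                               cfg$reliability$n_trials)
        batch_streams <- lapply(seq_along(specs), function(i) {
          simulate_device_stream(
            protocol, specs[[i]], shaker,
            seed = (seeds[2] + bi * 10000L + batch * 100L + si * 10L + i) %%
              2000000000L
          )
        })
        batch_tables[[length(batch_tables) + 1L]] <-
          build_epoch_table(batch_streams, protocol, shaker)
      }
    }
    for (agg in c("mean", "rms")) {
      fit <- summarize_reliability(batch_tables, agg)
      rel_rows[[length(rel_rows) + 1L]] <- tibble::tibble(
        brand = brand, aggregation = agg, icc = fit$icc,
        ci_low = fit$ci_low, ci_high = fit$ci_high,
        n_subjects = fit$n_subjects, k_raters = fit$k_raters,
        interpretation = fit$interpretation
      )
    }
  }
  reliability <- dplyr::bind_rows(rel_rows)

  # --- reports ------------------------------------------------------------
  out <- function(name) file.path(cfg$out_dir, name)
  readr::write_csv(reliability, out("table1_reliability.csv"))
  readr::write_csv(validity, out("table2_validity.csv"))
  readr::write_csv(equivalence, out("table3_equivalence.csv"))
  readr::write_csv(per_speed, out("per_speed_error.csv"))
  readr::write_csv(ba, out("bland_altman.csv"))
  if (isTRUE(cfg$write_epoch_table)) {
    write_epoch_table(kept, out("epoch_table.csv"))
  }
  log_lines <- c(
    paste0("shakeval ", as.character(packageVersion("shakeval"))),
    paste0("timestamp: ", format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z")),
    paste0("config hash: ", rlang::hash(cfg)),
    paste0("seed: ", cfg$seed),
    paste0("conversion variant: ", shaker$conversion_variant),
    paste0("brands: ", paste(cfg$brands, collapse = ", ")),
    paste0("devices per brand: ", cfg$devices_per_brand),
    paste0("excluded devices: ",
           if (nrow(screened$excluded) == 0L) "none"
           else paste(screened$excluded$device_id, collapse = ", ")),
    paste0("epoch rows kept: ", nrow(kept))
  )
  writeLines(log_lines, out("run_log.txt"))
  say("reports written to ", cfg$out_dir)

  invisible(list(epoch_table = kept, excluded = screened$excluded,
                 reliability = reliability, validity = validity,
                 per_speed = per_speed, equivalence = equivalence,
                 bland_altman = ba, config = cfg))
}
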