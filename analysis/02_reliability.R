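#!/usr/bin/env Rscript

# Step 2: inter-device reliability.
#
# Per brand, two batches of five co-mounted devices each run five 2-minute
# trials at 0.6 Hz and at 3.2 Hz (the 80-trial design). Batches are stacked
# as additional subjects with device columns indexed by clamp position, and
# ICC(2,1) — two-way random effects, absolute agreement, single measure —
# is computed per brand for both second-level aggregates.

library(shakeval)

seed <- if (length(commandArgs(TRUE)) >= 1) {
  as.integer(commandArgs(TRUE)[1])
} else {
  20230711L
}
dir.create("results", showWarnings = FALSE)

cfg <- shaker_config()
design <- reliability_study_design()
message("reliability design: ", nrow(design), " batch-speed runs, ",
        sum(design$n_trials), " trials in total")

rows <- list()
for (brand in unique(design$brand)) {
  batch_tables <- list()
  sub <- design[design$brand == brand, ]
  for (j in seq_len(nrow(sub))) {
    specs <- simulate_brand_devices(
      brand, 5, seed = seed + match(brand, unique(design$brand)) * 1000L +
        sub$batch[j] * 10L
    )
    protocol <- build_reliability_sequence(sub$speed_hz[j], sub$n_trials[j])
    streams <- lapply(seq_along(specs), function(i) {
      simulate_device_stream(protocol, specs[[i]], cfg,
                             seed = seed + j * 100L + i +
                               match(brand, unique(design$brand)) * 10000L)
    })
    batch_tables[[j]] <- build_epoch_table(streams, protocol, cfg)
  }
  for (agg in c("mean", "rms")) {
    fit <- summarize_reliability(batch_tables, agg)
    message(sprintf("%-9s %4s: ICC = %.3f (%.3f, %.3f) — %s",
                    brand, agg, fit$icc, fit$ci_low, fit$ci_high,
                    fit$interpretation))
    rows[[length(rows) + 1L]] <- tibble::tibble(
      brand = brand, aggregation = agg, icc = fit$icc,
      ci_low = fit$ci_low, ci_high = fit$ci_high,
      n_subjects = fit$n_subjects, k_raters = fit$k_raters,
      interpretation = fit$interpretation
    )
  }
}

readr::write_csv(dplyr::bind_rows(rows), "results/table1_reliability.csv")
message("wrote results/table1_reliability.csv")
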