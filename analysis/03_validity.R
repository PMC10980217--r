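#!/usr/bin/env Rscript

# Step 3: validity against the shaker reference.
#
# Pools the middle-minute device-seconds per brand and computes Pearson r,
# Lin's CCC (with Fisher-z CI), mean absolute error, and mean bias with 95%
# limits of agreement, for both aggregation methods; also the per-speed
# error profile and the Bland-Altman point exports.

library(shakeval)

dir.create("results", showWarnings = FALSE)
epochs <- read_epoch_table("results/epoch_table.csv")
message("loaded ", nrow(epochs), " device-seconds from results/epoch_table.csv")

validity <- dplyr::bind_rows(summarize_validity(epochs, "mean"),
                             summarize_validity(epochs, "rms"))
print(as.data.frame(validity[, c("brand", "aggregation", "n_obs", "mean_mg",
                                 "pearson_r", "ccc", "ccc_interpretation",
                                 "mae_mg", "bias_mg")]), digits = 3)

per_speed <- dplyr::bind_rows(per_speed_error_summary(epochs, "mean"),
                              per_speed_error_summary(epochs, "rms"))

ba <- dplyr::bind_rows(lapply(c("mean", "rms"), function(agg) {
  dplyr::bind_rows(lapply(unique(epochs$brand), function(b) {
    sub <- epochs[epochs$brand == b, ]
    x <- if (agg == "mean") sub$enmo_mean_mg else sub$enmo_rms_mg
    tibble::tibble(brand = b, aggregation = agg,
                   bland_altman_points(x, sub$reference_mg))
  }))
}))

readr::write_csv(validity, "results/table2_validity.csv")
readr::write_csv(per_speed, "results/per_speed_error.csv")
readr::write_csv(ba, "results/bland_altman.csv")
message("wrote results/table2_validity.csv, per_speed_error.csv, ",
        "bland_altman.csv")
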