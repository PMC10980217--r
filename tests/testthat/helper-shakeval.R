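# Independent oracles and small fixture builders shared across tests.

# ICC(2,1) computed from an aov/lm two-way ANOVA fit, independent of the
# package's direct mean-square algebra.
oracle_icc_anova <- function(mat) {
  df <- data.frame(
    y = as.vector(mat),
    subj = factor(rep(seq_len(nrow(mat)), times = ncol(mat))),
    rater = factor(rep(seq_len(ncol(mat)), each = nrow(mat)))
  )
  ms <- stats::anova(stats::lm(y ~ subj + rater, data = df))$`Mean Sq`
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  n <- nrow(mat); k <- ncol(mat)
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

# Lin's CCC by direct moment computation (population moments).
oracle_ccc_moments <- function(x, y) {
  n <- length(x)
  sx2 <- sum((x - mean(x))^2) / n
  sy2 <- sum((y - mean(y))^2) / n
  sxy <- sum((x - mean(x)) * (y - mean(y))) / n
  2 * sxy / (sx2 + sy2 + (mean(x) - mean(y))^2)
}

# A hand-built epoch table: one row per (device, frequency, second).
make_epoch_table <- function(device_id, brand, frequency_hz, second_index,
                             enmo_mean_mg, enmo_rms_mg = abs(enmo_mean_mg),
                             reference_mg =
                               reference_acceleration_mg(frequency_hz),
                             trial_id = 1L) {
  tb <- tibble::tibble(
    device_id = device_id, brand = brand, trial_id = trial_id,
    frequency_hz = frequency_hz, second_index = as.integer(second_index),
    enmo_mean_mg = enmo_mean_mg, enmo_rms_mg = enmo_rms_mg,
    reference_mg = reference_mg
  )
  shakeval:::new_epoch_table(tb)
}

# An epoch table whose device aggregates equal the reference exactly.
perfect_epoch_table <- function(brand = "actigraph", n_devices = 2,
                                seconds = 0:9) {
  grid <- expand.grid(
    device = seq_len(n_devices), frequency_hz = validity_frequencies(),
    second_index = seconds, KEEP.OUT.ATTRS = FALSE
  )
  ref <- reference_acceleration_mg(grid$frequency_hz)
  make_epoch_table(
    device_id = sprintf("%s_%02d", brand, grid$device), brand = brand,
    frequency_hz = grid$frequency_hz, second_index = grid$second_index,
    enmo_mean_mg = ref, enmo_rms_mg = ref, reference_mg = ref
  )
}

# A raw stream wrapping explicit samples (for unit tests of the pipeline).
make_stream <- function(x, y, z, sampling_hz = 4, device_id = "dev",
                        brand = "custom") {
  n <- length(x)
  structure(
    list(device_id = device_id, brand = brand, sampling_hz = sampling_hz,
         spec = NULL, seed = NA_integer_, protocol_duration_s = NA_real_,
         data = tibble::tibble(t_s = (seq_len(n) - 1) / sampling_hz,
                               x_g = x, y_g = y, z_g = z)),
    class = "raw_stream"
  )
}
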