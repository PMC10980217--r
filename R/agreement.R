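#' Two-way random-effects absolute-agreement ICC, single measure
#'
#' ICC(2,1): subjects (here, seconds) and raters (here, co-mounted devices)
#' are both random effects and agreement is absolute, so rater mean shifts
#' count against reliability. From the two-way ANOVA mean squares with n
#' subjects and k raters:
#'
#'   ICC = (MSR - MSE) / (MSR + (k - 1) MSE + k (MSC - MSE) / n)
#'
#' where MSR, MSC and MSE are the subject, rater and residual mean squares.
#' The 95% confidence interval uses the F-based method of McGraw & Wong
#' (1996) with Satterthwaite degrees of freedom.
#'
#' Rows with any missing value are removed (listwise deletion).
#'
#' @param mat Numeric matrix, subjects (seconds) in rows, raters (devices)
#'   in columns; at least 2 complete rows and 2 columns.
#' @param aggregation Label recorded in the result (`"mean"` or `"rms"`).
#' @param conf_level Confidence level for the interval.
#' @return An `icc_result`: list with `icc`, `ci_low`, `ci_high`,
#'   `n_subjects`, `k_raters`, `aggregation`, `interpretation`, and the
#'   ANOVA mean squares in `ms`.
#' @examples
#' m <- cbind(c(1, 2, 3), c(2, 3, 4))
#' icc_2way_random_absolute(m)$icc  # 2/3
#' @export
icc_2way_random_absolute <- function(mat, aggregation = "mean",
                                     conf_level = 0.95) {
  mat <- as.matrix(mat)
  mat <- mat[complete.cases(mat), , drop = FALSE]
  n <- nrow(mat)
  k <- ncol(mat)
  if (n < 2L || k < 2L) {
    stop("need at least 2 complete subjects and 2 raters", call. = FALSE)
  }
  grand <- mean(mat)
  row_m <- rowMeans(mat)
  col_m <- colMeans(mat)
  ssr <- k * sum((row_m - grand)^2)
  ssc <- n * sum((col_m - grand)^2)
  sst <- sum((mat - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + k * (msc - mse) / n
  if (denom <= .Machine$double.eps * max(1, abs(msr))) {
    stop("total variance is zero; ICC is undefined", call. = FALSE)
  }
  icc <- (msr - mse) / denom

  alpha <- 1 - conf_level
  if (1 - icc < 1e-12) {
    ci <- c(icc, icc)   # degenerate: perfect agreement, no residual variance
  } else {
    a <- (k * icc) / (n * (1 - icc))
    b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
    v <- (a * msc + b * mse)^2 /
      ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
    fl <- qf(1 - alpha / 2, n - 1, v)
    fu <- qf(1 - alpha / 2, v, n - 1)
    lower <- n * (msr - fl * mse) /
      (fl * (k * msc + (k * n - k - n) * mse) + n * msr)
    upper <- n * (fu * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * fu * msr)
    ci <- c(lower, upper)
  }
  structure(
    list(icc = icc, ci_low = ci[1], ci_high = ci[2], n_subjects = n,
         k_raters = k, aggregation = aggregation,
         interpretation = interpret_icc(icc),
         ms = list(msr = msr, msc = msc, mse = mse)),
    class = "icc_result"
  )
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC(2,1) = %.3f (95%% CI %.3f, %.3f) — %s reliability\n",
              x$icc, x$ci_low, x$ci_high, x$interpretation))
  cat(sprintf("  %d subjects (seconds) x %d raters (devices), %s aggregation\n",
              x$n_subjects, x$k_raters, x$aggregation))
  invisible(x)
}

#' Interpret an ICC value
#'
#' Koo & Li style bins: below 0.50 poor, 0.50-0.75 moderate, 0.75-0.90 good,
#' 0.90 and above excellent. Boundaries are lower-inclusive (0.75 is "good",
#' 0.90 is "excellent").
#'
#' @param icc Finite ICC value(s).
#' @return Character vector of categories.
#' @export
interpret_icc <- function(icc) {
  stopifnot(all(is.finite(icc)))
  cut(icc, breaks = c(-Inf, 0.5, 0.75, 0.9, Inf), right = FALSE,
      labels = c("poor", "moderate", "good", "excellent")) |>
    as.character()
}

#' Pearson product-moment correlation
#'
#' Thin wrapper over [stats::cor()] that rejects degenerate input instead of
#' returning `NA`.
#'
#' @param x,y Equal-length numeric series (length >= 2) with nonzero
#'   variance.
#' @return Correlation in `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2L)
  if (sd(x) == 0 || sd(y) == 0) {
    stop("zero variance: Pearson correlation undefined", call. = FALSE)
  }
  cor(x, y)
}

#' Lin's concordance correlation coefficient
#'
#' Measures agreement with the identity line: the Pearson correlation
#' penalised for location and scale shift,
#' `ccc = 2 s_xy / (s_x^2 + s_y^2 + (mean(x) - mean(y))^2)` with population
#' (1/n) moments, per Lin (1989). The confidence interval uses the Fisher
#' z-transform with Lin's asymptotic standard error.
#'
#' @param x Device series.
#' @param y Reference series, same length (>= 3).
#' @param conf_level Confidence level.
#' @return A list with `ccc`, `ci_low`, `ci_high`, `pearson_r`, `c_b` (the
#'   bias-correction factor `ccc / r`), and `n`.
#' @examples
#' lins_ccc(c(1, 2, 3), c(2, 3, 4))$ccc  # 4/7
#' @export
lins_ccc <- function(x, y, conf_level = 0.95) {
  n <- length(x)
  stopifnot(length(y) == n, n >= 3L)
  mx <- mean(x); my <- mean(y)
  sx2 <- mean((x - mx)^2)
  sy2 <- mean((y - my)^2)
  sxy <- mean((x - mx) * (y - my))
  if (sx2 == 0 && sy2 == 0) {
    stop("both series have zero variance: CCC undefined", call. = FALSE)
  }
  ccc <- 2 * sxy / (sx2 + sy2 + (mx - my)^2)
  r <- if (sx2 > 0 && sy2 > 0) sxy / sqrt(sx2 * sy2) else NA_real_

  if (!is.na(r) && abs(r) > 0 && 1 - ccc^2 > 1e-12) {
    u <- (mx - my) / (sx2 * sy2)^0.25
    # the asymptotic variance can round fractionally negative when r ~ 1
    se_ccc <- sqrt(max(0, (
      (1 - r^2) * ccc^2 / ((1 - ccc^2) * r^2) +
        4 * ccc^3 * (1 - ccc) * u^2 / (r * (1 - ccc^2)^2) -
        2 * ccc^4 * u^4 / (r^2 * (1 - ccc^2)^2)
    ) / (n - 2)))
    z <- atanh(ccc)
    se_z <- se_ccc / (1 - ccc^2)
    zcrit <- qnorm(1 - (1 - conf_level) / 2)
    ci <- tanh(z + c(-1, 1) * zcrit * se_z)
  } else {
    ci <- c(ccc, ccc)   # degenerate: perfect concordance or undefined slope
  }
  list(ccc = ccc, ci_low = ci[1], ci_high = ci[2], pearson_r = r,
       c_b = if (is.na(r) || r == 0) NA_real_ else ccc / r, n = n)
}

#' Interpret a concordance correlation coefficient
#'
#' Altman-style ladder used for narrative interpretation: below 0.20 poor,
#' 0.20-0.40 fair, 0.40-0.60 moderate, 0.60-0.80 good, 0.80 and above
#' excellent (lower-inclusive boundaries).
#'
#' @param ccc Finite CCC value(s).
#' @return Character vector of categories.
#' @export
interpret_ccc <- function(ccc) {
  stopifnot(all(is.finite(ccc)))
  cut(ccc, breaks = c(-Inf, 0.2, 0.4, 0.6, 0.8, Inf), right = FALSE,
      labels = c("poor", "fair", "moderate", "good", "excellent")) |>
    as.character()
}

#' Mean absolute error against a reference
#'
#' @param x Device series.
#' @param ref Reference series, same length (>= 1).
#' @return Mean of `abs(x - ref)`, in the units of the inputs (mg here).
#' @export
mean_absolute_error <- function(x, ref) {
  stopifnot(length(x) == length(ref), length(x) >= 1L)
  mean(abs(x - ref))
}

#' Mean bias with 95% limits of agreement
#'
#' Bias is `mean(x - ref)` (device minus reference, so negative means the
#' device underestimates). The limits of agreement are
#' `bias +/- 1.96 * SD(x - ref)` (sample SD) — the interval expected to
#' contain 95% of individual differences. A standard-error-based confidence
#' interval for the mean bias (`bias +/- t * SD / sqrt(n)`) is also
#' returned, clearly labelled: the two intervals answer different questions
#' and differ in width by a factor of about `sqrt(n)`.
#'
#' @param x Device series.
#' @param ref Reference series, same length (>= 2).
#' @return A list with `bias_mg`, `loa_low_mg`, `loa_high_mg`,
#'   `ci_low_mg`, `ci_high_mg` (SE-based CI for the mean), `sd_diff_mg`,
#'   `n`.
#' @export
mean_bias_loa <- function(x, ref) {
  stopifnot(length(x) == length(ref), length(x) >= 2L)
  d <- x - ref
  n <- length(d)
  bias <- mean(d)
  s <- sd(d)
  se <- s / sqrt(n)
  tcrit <- qt(0.975, n - 1)
  list(bias_mg = bias,
       loa_low_mg = bias - 1.96 * s, loa_high_mg = bias + 1.96 * s,
       ci_low_mg = bias - tcrit * se, ci_high_mg = bias + tcrit * se,
       sd_diff_mg = s, n = n)
}

#' Bland-Altman points for plotting
#'
#' @param x Device series.
#' @param ref Reference series, same length.
#' @return A tibble with `mean_of_pair_mg = (x + ref) / 2` and
#'   `difference_mg = x - ref`, one row per pair.
#' @export
bland_altman_points <- function(x, ref) {
  stopifnot(length(x) == length(ref))
  tibble::tibble(mean_of_pair_mg = (x + ref) / 2, difference_mg = x - ref)
}

pick_aggregate <- function(table, aggregation) {
  aggregation <- match.arg(aggregation, c("mean", "rms"))
  switch(aggregation, mean = table$enmo_mean_mg, rms = table$enmo_rms_mg)
}

#' Per-brand validity summary (pooled across devices and frequencies)
#'
#' For each brand: number of device-seconds, pooled mean and SD of the
#' chosen ENMO aggregate, Pearson correlation with the reference, Lin's CCC
#' with 95% CI and interpretation, mean absolute error, and mean bias with
#' 95% limits of agreement. All middle-minute seconds are pooled across
#' devices and oscillation frequencies within a brand.
#'
#' @param table An `epoch_table` (after any device exclusions).
#' @param aggregation `"mean"` or `"rms"`.
#' @return A tibble, one row per brand.
#' @export
summarize_validity <- function(table, aggregation = c("mean", "rms")) {
  aggregation <- match.arg(aggregation)
  stopifnot(inherits(table, "epoch_table"), nrow(table) > 0L)
  brands <- unique(table$brand)
  dplyr::bind_rows(lapply(brands, function(b) {
    sub <- table[table$brand == b, ]
    x <- pick_aggregate(sub, aggregation)
    ref <- sub$reference_mg
    cc <- lins_ccc(x, ref)
    bias <- mean_bias_loa(x, ref)
    tibble::tibble(
      brand = b, aggregation = aggregation, n_obs = nrow(sub),
      mean_mg = mean(x), sd_mg = sd(x),
      pearson_r = pearson_r(x, ref),
      ccc = cc$ccc, ccc_ci_low = cc$ci_low, ccc_ci_high = cc$ci_high,
      ccc_interpretation = interpret_ccc(cc$ccc),
      mae_mg = mean_absolute_error(x, ref),
      bias_mg = bias$bias_mg,
      loa_low_mg = bias$loa_low_mg, loa_high_mg = bias$loa_high_mg
    )
  }))
}

#' Per-brand, per-frequency error summary
#'
#' Mean absolute error and mean bias within each oscillation frequency, with
#' standard errors (SD of the per-second absolute errors or differences over
#' the square root of the count).
#'
#' @inheritParams summarize_validity
#' @return A tibble, one row per brand x frequency.
#' @export
per_speed_error_summary <- function(table, aggregation = c("mean", "rms")) {
  aggregation <- match.arg(aggregation)
  stopifnot(inherits(table, "epoch_table"), nrow(table) > 0L)
  table$value <- pick_aggregate(table, aggregation)
  table |>
    dplyr::group_by(.data$brand, .data$frequency_hz) |>
    dplyr::summarise(
      aggregation = aggregation,
      n_obs = dplyr::n(),
      reference_mg = .data$reference_mg[1],
      mae_mg = mean(abs(.data$value - .data$reference_mg)),
      mae_se_mg = sd(abs(.data$value - .data$reference_mg)) /
        sqrt(dplyr::n()),
      bias_mg = mean(.data$value - .data$reference_mg),
      bias_se_mg = sd(.data$value - .data$reference_mg) / sqrt(dplyr::n()),
      .groups = "drop"
    )
}

#' Seconds-by-devices matrix for reliability analysis
#'
#' Pivots an epoch table (one batch of co-mounted devices) into the
#' subjects-by-raters matrix ICC expects: rows are seconds (identified by
#' trial, frequency and within-trial second), columns are devices in clamp
#' order.
#'
#' @param table An `epoch_table` for one batch.
#' @param aggregation `"mean"` or `"rms"`.
#' @param device_order Column order; defaults to first appearance (clamp
#'   positions 1..k).
#' @return A numeric matrix with `NA` where a device-second is missing.
#' @export
reliability_matrix <- function(table, aggregation = c("mean", "rms"),
                               device_order = NULL) {
  aggregation <- match.arg(aggregation)
  stopifnot(inherits(table, "epoch_table"), nrow(table) > 0L)
  if (is.null(device_order)) device_order <- unique(table$device_id)
  table$value <- pick_aggregate(table, aggregation)
  wide <- tidyr::pivot_wider(
    table[, c("trial_id", "frequency_hz", "second_index", "device_id",
              "value")],
    names_from = "device_id", values_from = "value"
  )
  as.matrix(wide[, device_order, drop = FALSE])
}

#' Per-brand reliability ICC across batches
#'
#' The study tests 10 devices of a brand as two batches of five co-mounted
#' units, yet reports a single ICC per brand. Here batches are stacked as
#' additional subjects (seconds), with the five device columns indexed by
#' clamp position 1-5, so the "rater" is the clamp position rather than the
#' physical unit. With a single batch this reduces to
#' [icc_2way_random_absolute()] on that batch. Listwise deletion is applied
#' within each batch before stacking.
#'
#' @param batch_tables A list of `epoch_table`s, one per batch (or a single
#'   table). All batches must have the same number of devices.
#' @param aggregation `"mean"` or `"rms"`.
#' @param conf_level Confidence level for the ICC interval.
#' @return An `icc_result`.
#' @export
summarize_reliability <- function(batch_tables,
                                  aggregation = c("mean", "rms"),
                                  conf_level = 0.95) {
  aggregation <- match.arg(aggregation)
  if (inherits(batch_tables, "epoch_table")) batch_tables <- list(batch_tables)
  mats <- lapply(batch_tables, function(tb) {
    m <- reliability_matrix(tb, aggregation)
    m[complete.cases(m), , drop = FALSE]
  })
  ks <- vapply(mats, ncol, integer(1))
  if (length(unique(ks)) != 1L) {
    stop("batches have inconsistent device counts: ",
         paste(ks, collapse = ", "), call. = FALSE)
  }
  stacked <- do.call(rbind, mats)
  colnames(stacked) <- paste0("position_", seq_len(ncol(stacked)))
  icc_2way_random_absolute(stacked, aggregation = aggregation,
                           conf_level = conf_level)
}
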