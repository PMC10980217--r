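#' Equivalence bound specification
#'
#' The equivalence zone is plus/minus 10% of the shaker reference
#' acceleration. The fixed half-width used for table reproduction is 6.3 mg;
#' alternatively the bound can be derived at run time as a fraction of the
#' mean reference acceleration over the analysis table
#' (`derivation = "fraction_of_mean_reference"`). Note that 10% of the mean
#' of the seven protocol reference levels is about 5.4 mg, not 6.3 mg; both
#' routes are provided because the provenance of the fixed value is not
#' derivable, and the fixed value is the default.
#'
#' @param bound_mg Fixed half-width of the equivalence zone in mg.
#' @param derivation `"fixed"` or `"fraction_of_mean_reference"`.
#' @param fraction Fraction of the mean reference used when deriving.
#' @return An `equivalence_bounds` object.
#' @export
equivalence_bounds <- function(bound_mg = 6.3,
                               derivation = c("fixed",
                                              "fraction_of_mean_reference"),
                               fraction = 0.10) {
  derivation <- match.arg(derivation)
  if (derivation == "fixed" && (!is.numeric(bound_mg) || bound_mg <= 0)) {
    stop("`bound_mg` must be positive", call. = FALSE)
  }
  structure(list(bound_mg = bound_mg, derivation = derivation,
                 fraction = fraction),
            class = "equivalence_bounds")
}

#' Resolve the equivalence bound for an analysis table
#'
#' @param table An `epoch_table` (may be empty for fixed bounds).
#' @param bounds_spec An [equivalence_bounds()].
#' @return The half-width of the equivalence zone in mg.
#' @export
derive_bound <- function(table, bounds_spec = equivalence_bounds()) {
  stopifnot(inherits(bounds_spec, "equivalence_bounds"))
  switch(bounds_spec$derivation,
    fixed = bounds_spec$bound_mg,
    fraction_of_mean_reference = {
      if (is.null(table) || nrow(table) == 0L) {
        stop("cannot derive a fractional bound from an empty table",
             call. = FALSE)
      }
      bounds_spec$fraction * mean(table$reference_mg)
    }
  )
}

#' One-sample TOST equivalence test
#'
#' Two one-sided t-tests of the mean difference (device minus reference)
#' against the equivalence bounds: H0a: mu <= -bound and H0b: mu >= +bound.
#' Equivalence is concluded when both are rejected at level `alpha`, which is
#' the same as the (1 - 2 alpha) = 90% confidence interval of the mean
#' difference lying strictly inside (-bound, +bound).
#'
#' Degenerate inputs (a single observation, or zero spread) collapse the
#' interval to the mean and equivalence is decided by the interval rule; the
#' one-sided p-values are then 0/1 limits.
#'
#' @param differences Per-second differences in mg (device - reference).
#' @param bound_mg Equivalence half-width in mg (> 0).
#' @param alpha One-sided test level (default 0.05, giving a 90% CI).
#' @return A `tost_result`: list with `mean_diff_mg`, `lower90_mg`,
#'   `upper90_mg`, `bound_mg`, `equivalent`, `p_lower`, `p_upper`, `n`,
#'   `interpretation`.
#' @examples
#' tost_one_sample(rnorm(50, 0, 1), bound_mg = 6.3)$equivalent
#' @export
tost_one_sample <- function(differences, bound_mg, alpha = 0.05) {
  stopifnot(is.numeric(differences), length(differences) >= 1L,
            bound_mg > 0)
  n <- length(differences)
  m <- mean(differences)
  s <- if (n >= 2L) sd(differences) else 0
  if (n >= 2L && s > 0) {
    se <- s / sqrt(n)
    tcrit <- qt(1 - alpha, n - 1)
    ci <- m + c(-1, 1) * tcrit * se
    p_lower <- pt((m + bound_mg) / se, n - 1, lower.tail = FALSE)
    p_upper <- pt((m - bound_mg) / se, n - 1)
  } else {
    ci <- c(m, m)
    p_lower <- as.numeric(m <= -bound_mg)
    p_upper <- as.numeric(m >= bound_mg)
  }
  equivalent <- ci[1] > -bound_mg && ci[2] < bound_mg
  structure(
    list(mean_diff_mg = m, lower90_mg = ci[1], upper90_mg = ci[2],
         bound_mg = bound_mg, equivalent = equivalent,
         p_lower = p_lower, p_upper = p_upper, n = n,
         interpretation = if (equivalent) {
           "significantly within the equivalence bounds"
         } else {
           "not significantly within the equivalence bounds"
         }),
    class = "tost_result"
  )
}

#' @export
print.tost_result <- function(x, ...) {
  cat(sprintf(
    "TOST: mean diff %.2f mg, 90%% CI (%.2f, %.2f), bound +/-%.2f mg -> %s\n",
    x$mean_diff_mg, x$lower90_mg, x$upper90_mg, x$bound_mg,
    x$interpretation))
  invisible(x)
}

#' Per-brand equivalence report
#'
#' Runs the one-sample TOST on the pooled per-second differences (device
#' ENMO aggregate minus reference) for every brand and aggregation method.
#' Pooling ignores device-level clustering, so per-second observations are
#' treated as independent — the convention of the study design this
#' reproduces, noted here because it makes the confidence intervals
#' anti-conservative.
#'
#' @param table An `epoch_table` (after exclusions).
#' @param bounds_spec An [equivalence_bounds()].
#' @param aggregations Aggregations to report.
#' @param alpha One-sided level (default 0.05).
#' @return A tibble, one row per aggregation x brand, with the TOST columns.
#' @export
table3_report <- function(table, bounds_spec = equivalence_bounds(),
                          aggregations = c("mean", "rms"), alpha = 0.05) {
  stopifnot(inherits(table, "epoch_table"), nrow(table) >= 2L)
  bound <- derive_bound(table, bounds_spec)
  brands <- unique(table$brand)
  rows <- list()
  for (agg in aggregations) {
    for (b in brands) {
      sub <- table[table$brand == b, ]
      if (nrow(sub) < 2L) next
      d <- pick_aggregate(sub, agg) - sub$reference_mg
      res <- tost_one_sample(d, bound, alpha = alpha)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        aggregation = agg, brand = b, n_obs = res$n,
        mean_diff_mg = res$mean_diff_mg,
        lower90_mg = res$lower90_mg, upper90_mg = res$upper90_mg,
        bound_mg = bound, equivalent = res$equivalent,
        p_lower = res$p_lower, p_upper = res$p_upper,
        interpretation = res$interpretation
      )
    }
  }
  dplyr::bind_rows(rows)
}
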