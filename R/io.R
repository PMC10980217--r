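#' Column dialect for raw device CSV exports
#'
#' Device logging apps export raw triaxial data as CSV with varying column
#' names, header junk and units. A dialect maps the four logical columns
#' (timestamp, x, y, z) onto source column names and records how to parse
#' them; readers never guess.
#'
#' Two example dialects ship with the package: `dialect_generic()` for the
#' package's own export format (`timestamp_s,x_g,y_g,z_g`, units g), and
#' `dialect_milli_g()` for the same layout with readings in milli-g.
#'
#' @param name Dialect name.
#' @param column_map Named list mapping `timestamp`, `x`, `y`, `z` to source
#'   column names.
#' @param header_rows_to_skip Rows to skip before the header line.
#' @param timestamp_format `NULL` for numeric seconds, otherwise a
#'   [strptime()] format; parsed timestamps are re-expressed as seconds from
#'   the first sample.
#' @param units `"g"` or `"milli_g"` (rescaled to g on read).
#' @return A `column_dialect` object.
#' @export
column_dialect <- function(name, column_map, header_rows_to_skip = 0,
                           timestamp_format = NULL,
                           units = c("g", "milli_g")) {
  units <- match.arg(units)
  required <- c("timestamp", "x", "y", "z")
  if (!all(required %in% names(column_map))) {
    stop("column_map must name all of: ", paste(required, collapse = ", "),
         call. = FALSE)
  }
  structure(list(name = name, column_map = column_map,
                 header_rows_to_skip = header_rows_to_skip,
                 timestamp_format = timestamp_format, units = units),
            class = "column_dialect")
}

#' @rdname column_dialect
#' @export
dialect_generic <- function() {
  column_dialect(
    "generic",
    column_map = list(timestamp = "timestamp_s", x = "x_g", y = "y_g",
                      z = "z_g")
  )
}

#' @rdname column_dialect
#' @export
dialect_milli_g <- function() {
  column_dialect(
    "milli_g",
    column_map = list(timestamp = "timestamp_s", x = "x_mg", y = "y_mg",
                      z = "z_mg"),
    units = "milli_g"
  )
}

#' Read a raw triaxial CSV export into a stream
#'
#' Applies a [column_dialect()]: skips header junk, maps and checks columns,
#' parses timestamps, rescales milli-g readings to g, and enforces strictly
#' increasing timestamps (a duplicated or backwards timestamp is an error
#' naming the offending row).
#'
#' @param path CSV file path.
#' @param dialect A [column_dialect()].
#' @param device_id Identifier for the stream; defaults to the file name.
#' @param brand Brand label (default `"custom"`).
#' @param sampling_hz Sampling rate; inferred from the median timestamp
#'   spacing when `NULL`.
#' @return A `raw_stream`.
#' @export
read_raw_csv <- function(path, dialect = dialect_generic(),
                         device_id = NULL, brand = "custom",
                         sampling_hz = NULL) {
  stopifnot(inherits(dialect, "column_dialect"))
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.csv(path, skip = dialect$header_rows_to_skip,
                 check.names = FALSE)
  cm <- dialect$column_map
  missing_cols <- setdiff(unlist(cm), names(df))
  if (length(missing_cols) > 0L) {
    stop("missing mapped column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  ts_raw <- df[[cm$timestamp]]
  if (is.null(dialect$timestamp_format)) {
    t_s <- suppressWarnings(as.numeric(ts_raw))
  } else {
    parsed <- strptime(as.character(ts_raw), dialect$timestamp_format,
                       tz = "UTC")
    t_s <- as.numeric(parsed) - as.numeric(parsed[1])
  }
  if (any(is.na(t_s))) {
    stop("unparseable timestamp at row ", which(is.na(t_s))[1], call. = FALSE)
  }
  bad <- which(diff(t_s) <= 0)
  if (length(bad) > 0L) {
    stop("timestamps not strictly increasing at row ", bad[1] + 1L,
         call. = FALSE)
  }
  scale <- if (dialect$units == "milli_g") 1 / 1000 else 1
  xyz <- lapply(cm[c("x", "y", "z")], function(col) {
    as.numeric(df[[col]]) * scale
  })
  if (is.null(sampling_hz)) {
    sampling_hz <- if (length(t_s) >= 2L) 1 / median(diff(t_s)) else 1
  }
  structure(
    list(device_id = device_id %||% basename(path), brand = brand,
         sampling_hz = sampling_hz, spec = NULL, seed = NA_integer_,
         protocol_duration_s = NA_real_,
         data = tibble::tibble(t_s = t_s, x_g = xyz$x, y_g = xyz$y,
                               z_g = xyz$z)),
    class = "raw_stream"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a raw stream as CSV (with an optional sidecar description)
#'
#' Columns `timestamp_s,x_g,y_g,z_g` in g. When the stream was simulated, a
#' JSON sidecar records the generating device spec and seed next to the CSV.
#'
#' @param stream A `raw_stream`.
#' @param path Output CSV path.
#' @param sidecar Write `<path>.json` with device spec and seed.
#' @return `path`, invisibly.
#' @export
write_raw_csv <- function(stream, path, sidecar = TRUE) {
  stopifnot(inherits(stream, "raw_stream"))
  d <- stream$data
  readr::write_csv(
    tibble::tibble(timestamp_s = d$t_s, x_g = d$x_g, y_g = d$y_g,
                   z_g = d$z_g),
    path
  )
  if (sidecar && !is.null(stream$spec)) {
    spec <- stream$spec
    jsonlite::write_json(
      list(device_id = spec$device_id, brand = spec$brand,
           sampling_hz = spec$sampling_hz,
           dynamic_range_g = spec$dynamic_range_g,
           noise_sd_g = spec$noise_sd_g, bias_g = spec$bias_g,
           gain = spec$gain,
           mounting_rotation = spec$mounting$rotation,
           dropout_rate = spec$dropout_rate, fault_mode = spec$fault_mode,
           seed = stream$seed),
      paste0(path, ".json"), auto_unbox = TRUE, digits = NA
    )
  }
  invisible(path)
}

epoch_table_columns <- c("device_id", "brand", "trial_id", "frequency_hz",
                         "second_index", "enmo_mean_mg", "enmo_rms_mg",
                         "reference_mg")

#' Write / read an epoch table as CSV
#'
#' Lossless round-trip: values are written with full double precision
#' (shortest round-trip representation) and read back with explicit column
#' types; a file missing required columns is rejected with their names.
#'
#' @param table An `epoch_table`.
#' @param path CSV path.
#' @return `write_epoch_table()` returns `path` invisibly;
#'   `read_epoch_table()` returns an `epoch_table`.
#' @export
write_epoch_table <- function(table, path) {
  stopifnot(inherits(table, "epoch_table"))
  readr::write_csv(table[, epoch_table_columns], path)
  invisible(path)
}

#' @rdname write_epoch_table
#' @export
read_epoch_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header <- readr::read_csv(path, n_max = 0, show_col_types = FALSE)
  missing_cols <- setdiff(epoch_table_columns, names(header))
  if (length(missing_cols) > 0L) {
    stop("epoch table file missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- readr::read_csv(
    path,
    col_types = readr::cols(
      device_id = readr::col_character(), brand = readr::col_character(),
      trial_id = readr::col_integer(), frequency_hz = readr::col_double(),
      second_index = readr::col_integer(),
      enmo_mean_mg = readr::col_double(),
      enmo_rms_mg = readr::col_double(), reference_mg = readr::col_double()
    )
  )
  new_epoch_table(df[, epoch_table_columns])
}

#' Read a collapsed aggregated dataset from XLSX (optional)
#'
#' Convenience reader for externally supplied spreadsheet exports of
#' second-level aggregated data. The column layout of such files varies, so
#' a mapping from epoch-table columns to spreadsheet columns must be
#' supplied; unmapped optional columns are filled with `NA`. Requires the
#' readxl package.
#'
#' @param path XLSX path.
#' @param column_map Named character vector mapping epoch-table column names
#'   (`device_id`, `brand`, `trial_id`, `frequency_hz`, `second_index`,
#'   `enmo_mean_mg`, `enmo_rms_mg`, `reference_mg`) to spreadsheet columns.
#' @param sheet Sheet name or index.
#' @return An `epoch_table`.
#' @export
read_aggregated_xlsx <- function(path, column_map, sheet = 1) {
  if (!requireNamespace("readxl", quietly = TRUE)) {
    stop("the readxl package is required for XLSX input", call. = FALSE)
  }
  df <- readxl::read_excel(path, sheet = sheet)
  missing_cols <- setdiff(unname(column_map), names(df))
  if (length(missing_cols) > 0L) {
    stop("missing mapped column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  out <- tibble::tibble(.rows = nrow(df))
  for (col in epoch_table_columns) {
    out[[col]] <- if (col %in% names(column_map)) {
      df[[column_map[[col]]]]
    } else if (col %in% c("device_id", "brand")) {
      NA_character_
    } else {
      NA_real_
    }
  }
  new_epoch_table(out)
}
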