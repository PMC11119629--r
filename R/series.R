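#' Labelled, equally spaced time series of interaction counts or increments
#'
#' Container for the univariate, equally time-spaced series the recurrence
#' pipeline consumes: either raw interaction counts `N(t)` (e.g. numbers of
#' intermolecular hydrogen bonds saved every 100 ps of an MD run) or their
#' per-step increments `dN/dt` (see [increments()]).
#'
#' @param values Numeric vector, length >= 1, all finite. (Embedding and
#'   parameter selection need longer series; a length-1 series only arises
#'   as the increment of a 2-point count series.)
#' @param dt Positive scalar; time between consecutive samples (e.g. 0.1 ns).
#' @param label Free-text label carried through the pipeline
#'   (e.g. `"HBo@290K"`).
#' @param is_increment Logical; `TRUE` if `values` are already increments.
#' @return An object of class `rp_series`.
#' @seealso [increments()], [read_series()], [write_series()], [synth_series()]
#' @examples
#' s <- rp_series(c(3, 5, 4, 6), dt = 0.1, label = "HBo@290K")
#' increments(s)
#' @export
rp_series <- function(values, dt = 1, label = "series", is_increment = FALSE) {
  values <- as.numeric(values)
  if (length(values) < 1L)
    stop_rp("rp_insufficient_data_error", "a series needs at least 1 value")
  if (!all(is.finite(values)))
    stop_rp("rp_parse_error", "all series values must be finite (no NA/NaN/Inf)")
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    stop_rp("rp_config_error", "'dt' must be a positive finite scalar")
  structure(
    list(values = values, dt = as.numeric(dt),
         label = as.character(label)[1L],
         is_increment = isTRUE(is_increment)),
    class = "rp_series"
  )
}

#' @export
print.rp_series <- function(x, ...) {
  cat(sprintf("<rp_series> %s: %d %s, dt = %g\n", x$label, length(x$values),
              if (x$is_increment) "increments" else "counts", x$dt))
  n <- min(8L, length(x$values))
  cat("  values: ", paste(signif(x$values[seq_len(n)], 5), collapse = ", "),
      if (length(x$values) > n) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' @export
length.rp_series <- function(x) length(x$values)

#' Per-step increments of a count series
#'
#' Forward difference scaled by the sampling step: element `i` is
#' `(N(i+1) - N(i)) / dt`. Turning a monotone aggregation curve into its
#' increments yields the non-monotonic, quasi-stationary signal that
#' recurrence analysis assumes. Output length is `L - 1`.
#'
#' The downstream pipeline is invariant to the `1/dt` scaling whenever the
#' recurrence threshold is set by recurrence-rate targeting
#' ([lambda_for_rate()]).
#'
#' @param series An [rp_series()] of raw counts (`is_increment = FALSE`).
#' @return An `rp_series` of increments, label suffixed with `" dN/dt"`.
#' @examples
#' increments(rp_series(c(0, 5, 5, 2)))$values  # 5, 0, -3
#' @export
increments <- function(series) {
  stopifnot(inherits(series, "rp_series"))
  if (isTRUE(series$is_increment))
    stop_rp("rp_config_error", "series is already an increment series")
  v <- series$values
  if (length(v) < 2L)
    stop_rp("rp_insufficient_data_error", "need at least 2 values to difference")
  rp_series(diff(v) / series$dt, dt = series$dt,
            label = paste0(series$label, " dN/dt"), is_increment = TRUE)
}

# Sniff the delimiter from the header line: tab wins if present, else comma.
sniff_sep <- function(path) {
  header <- readLines(path, n = 1L, warn = FALSE)
  if (grepl("\t", header, fixed = TRUE)) "\t" else ","
}

#' Read one labelled series from a delimited text file
#'
#' Reads CSV or TSV (delimiter sniffed from the header row) with one optional
#' `time` column and one column per series. The time column, when present,
#' must be equally spaced (relative tolerance `1e-6`) and sets `dt`;
#' otherwise `dt = 1`.
#'
#' @param path Path to a delimited text file with a header row.
#' @param column Name of the column to read.
#' @param is_increment Logical flag stored on the returned series; inputs are
#'   never auto-classified as counts or increments.
#' @return An [rp_series()].
#' @export
read_series <- function(path, column, is_increment = FALSE) {
  if (!file.exists(path))
    stop_rp("rp_io_error", sprintf("file not found: %s", path))
  sep <- sniff_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, colClasses = NA,
                          stringsAsFactors = FALSE)
  if (!column %in% names(df))
    stop_rp("rp_missing_column_error",
            sprintf("column '%s' not found (have: %s)", column,
                    paste(names(df), collapse = ", ")))
  vals <- df[[column]]
  if (!is.numeric(vals)) {
    bad <- which(is.na(suppressWarnings(as.numeric(as.character(vals)))))[1L]
    stop_rp("rp_parse_error",
            sprintf("non-numeric value in column '%s' at data row %d",
                    column, if (is.na(bad)) -1L else bad))
  }
  if (anyNA(vals))
    stop_rp("rp_parse_error",
            sprintf("missing value in column '%s' at data row %d (gapless series required)",
                    column, which(is.na(vals))[1L]))
  dt <- 1
  if ("time" %in% names(df)) {
    tv <- df[["time"]]
    if (!is.numeric(tv))
      stop_rp("rp_parse_error", "time column is not numeric")
    steps <- diff(tv)
    if (length(steps) < 1L || any(steps <= 0))
      stop_rp("rp_spacing_error", "time column must be strictly increasing")
    if (diff(range(steps)) > 1e-6 * max(abs(steps)))
      stop_rp("rp_spacing_error",
              "time column is not equally spaced (relative tolerance 1e-6)")
    dt <- mean(steps)
  }
  rp_series(vals, dt = dt, label = column, is_increment = is_increment)
}

#' Write a series to delimited text
#'
#' Writes a CSV with a `time` column reconstructed from `dt` (starting at 0)
#' and one data column named after the series label. [read_series()] inverts
#' it exactly on values, `dt` and label.
#'
#' @param series An [rp_series()].
#' @param path Output path; the directory must exist.
#' @return `path`, invisibly.
#' @export
write_series <- function(series, path) {
  stopifnot(inherits(series, "rp_series"))
  if (!dir.exists(dirname(path)))
    stop_rp("rp_io_error", sprintf("directory does not exist: %s", dirname(path)))
  n <- length(series$values)
  df <- data.frame(time = (seq_len(n) - 1L) * series$dt, v = series$values)
  names(df)[2L] <- series$label
  ok <- tryCatch({
    utils::write.table(df, path, sep = ",", row.names = FALSE,
                       col.names = TRUE, quote = FALSE, fileEncoding = "UTF-8")
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop_rp("rp_io_error", sprintf("could not write %s", path))
  invisible(path)
}
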