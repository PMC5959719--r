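# Delimited-text I/O for trace tables, event tables and structured reports.
# Trace files are wide (time_s + one column per bouton); event tables have
# one row per stimulus; reports are JSON.

#' Read a trace table
#'
#' Reads a delimited text file with a `time_s` column and one column per
#' bouton, returning the long tibble used throughout the package. The
#' sampling rate is inferred from the time stamps.
#'
#' @param path File path (comma- or tab-delimited; auto-detected).
#' @return Long tibble `time_s`, `bouton_id`, `intensity` with the inferred
#'   sampling rate in attribute `"sampling_rate_hz"`.
#' @export
read_traces <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  first <- readLines(path, n = 1)
  delim <- if (grepl("\t", first)) "\t" else ","
  # base parser: strtod is correctly rounded, so full-precision tables
  # round-trip to the exact binary doubles
  tb <- tryCatch(
    as_tibble(utils::read.delim(path, sep = delim, check.names = FALSE)),
    error = function(e) abort(sprintf("could not parse %s: %s", path,
                                      conditionMessage(e)))
  )
  if (!"time_s" %in% names(tb)) {
    abort(sprintf("%s has no 'time_s' column (found: %s)", path,
                  paste(names(tb), collapse = ", ")))
  }
  bad <- names(tb)[!vapply(tb, is.numeric, logical(1))]
  if (length(bad) > 0) {
    abort(sprintf("non-numeric column(s) in %s: %s", path,
                  paste(bad, collapse = ", ")))
  }
  if (ncol(tb) < 2) abort(sprintf("%s contains no bouton columns", path))
  out <- tb |>
    tidyr::pivot_longer(-"time_s", names_to = "bouton_id",
                        values_to = "intensity") |>
    arrange(.data$bouton_id, .data$time_s)
  attr(out, "sampling_rate_hz") <- infer_sampling_rate(out$time_s)
  out
}

# doubles rendered with 17 significant digits so written tables round-trip
# to the exact binary values
format_doubles <- function(df) {
  dplyr::mutate(df, across(dplyr::where(is.double),
                           ~ ifelse(is.na(.x), NA, sprintf("%.17g", .x))))
}

#' Write a trace table
#'
#' Doubles are written with 17 significant digits, so a write/read
#' round-trip reproduces the samples bit for bit.
#'
#' @param traces Long trace tibble.
#' @param path Output path; `.csv` writes comma-separated, anything else
#'   tab-separated.
#' @return `path`, invisibly.
#' @export
write_traces <- function(traces, path) {
  check_trace_df(traces)
  wide <- traces |>
    select("time_s", "bouton_id", "intensity") |>
    tidyr::pivot_wider(names_from = "bouton_id", values_from = "intensity") |>
    format_doubles()
  if (grepl("\\.csv$", path)) readr::write_csv(wide, path) else {
    readr::write_tsv(wide, path)
  }
  invisible(path)
}

#' Write an event table
#'
#' One row per stimulus per bouton, failures included.
#'
#' @param events Event tibble from [detect_events()].
#' @param path Output path (`.csv` or tab-separated otherwise).
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  events <- format_doubles(events)
  if (grepl("\\.csv$", path)) readr::write_csv(events, path) else {
    readr::write_tsv(events, path)
  }
  invisible(path)
}

#' Write a structured JSON report
#'
#' @param report A named list (fit summaries, statistics, provenance).
#' @param path Output `.json` path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
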