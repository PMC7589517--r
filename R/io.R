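# Delimited-text interchange for traces, records and plate tables.

.trace_cols <- c("droplet_id", "time_min", "channel", "relocation",
                 "cell_present")

#' Read / write long-format droplet traces
#'
#' Traces are exchanged as plain CSV with columns `droplet_id`,
#' `time_min`, `channel`, `relocation`, `cell_present`.
#'
#' @param traces Trace data frame.
#' @param path File path.
#' @return `read_traces` returns the validated data frame;
#'   `write_traces` returns `path` invisibly.
#' @export
write_traces <- function(traces, path) {
  stopifnot(all(.trace_cols %in% names(traces)))
  utils::write.csv(traces[.trace_cols], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_traces
#' @export
read_traces <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(.trace_cols, names(df))
  if (length(miss)) {
    stop("trace file is missing columns: ", paste(miss, collapse = ", "))
  }
  if (any(df$relocation < 0)) stop("relocation values must be >= 0")
  df$cell_present <- as.logical(df$cell_present)
  df
}

#' Read / write per-droplet cell records
#'
#' @param records Record data frame from [analyze_droplets()].
#' @param path File path.
#' @return `read_records` returns the data frame; `write_records`
#'   returns `path` invisibly.
#' @export
write_records <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_records
#' @export
read_records <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Read an ELISA plate table
#'
#' @param path CSV with columns `coating_level`, `concentration_nM`,
#'   `time_min`, `signal` (a `well` column is allowed and ignored).
#' @return Plate data frame for [analyze_elisa_plates()].
#' @export
read_plates <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("coating_level", "concentration_nM", "time_min", "signal")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("plate file is missing columns: ", paste(miss, collapse = ", "))
  }
  df
}
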