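# Plain-text interchange: delimited event tables (optionally gzipped),
# layout / truth tables, and the TSV artifacts each pipeline stage writes.

#' Write a delimited event table
#'
#' Columns `FSC-A`, `SSC-A`, `FITC-A`, `PE-A`, `time_ms`, tab-separated,
#' gzipped when the path ends in `.gz`.
#'
#' @param events event table from [simulate_events()].
#' @param path output path.
#' @export
write_event_table <- function(events, path) {
  out <- data.frame(`FSC-A` = events$FSC, `SSC-A` = events$SSC,
                    `FITC-A` = events$FITC, `PE-A` = events$PE,
                    time_ms = events$time_ms, check.names = FALSE)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a delimited event table
#' @param path event table written by [write_event_table()].
#' @param sampling_rate ul/s, attached as attribute.
#' @param sample_id attached as attribute.
#' @return event table data frame (`FSC`, `SSC`, `FITC`, `PE`, `time_ms`).
#' @export
read_event_table <- function(path, sampling_rate = NULL, sample_id = NULL) {
  x <- utils::read.delim(path, check.names = FALSE)
  need <- c("FSC-A", "SSC-A", "FITC-A", "PE-A", "time_ms")
  miss <- setdiff(need, names(x))
  if (length(miss)) stopf("event table %s lacks column(s): %s", path,
                          paste(miss, collapse = ", "))
  out <- data.frame(FSC = x[["FSC-A"]], SSC = x[["SSC-A"]],
                    FITC = x[["FITC-A"]], PE = x[["PE-A"]],
                    time_ms = x[["time_ms"]])
  attr(out, "sampling_rate") <- sampling_rate
  attr(out, "sample_id") <- sample_id
  out
}

#' Write a pipeline artifact as TSV
#' @param x data frame.
#' @param path output path.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a layout table (TSV)
#'
#' Expected columns: `sample_id`, `genotype_id`, `condition`,
#' `sampling_rate_ul_per_s`, `replicate`, `censored` (and `file` for
#' file-based preprocessing).
#' @param path TSV path.
#' @export
read_layout <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "genotype_id", "condition", "replicate")
  miss <- setdiff(need, names(x))
  if (length(miss)) stopf("layout lacks column(s): %s", paste(miss, collapse = ", "))
  x
}
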