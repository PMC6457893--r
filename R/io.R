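# Plain-text serialization: spike trains as two-column CSV
# (channel_id, time_ms), voltage traces as two-column CSV (time_ms, mV),
# template libraries as JSON.

#' Write spike trains to CSV
#'
#' @param spike_trains list of numeric vectors (ms)
#' @param path file path
#' @export
write_spikes_csv <- function(spike_trains, path) {
  df <- data.frame(
    channel_id = rep(seq_along(spike_trains), lengths(spike_trains)),
    time_ms = unlist(spike_trains, use.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read spike trains from CSV
#' @param path file written by [write_spikes_csv()]
#' @return list of numeric vectors indexed by channel
#' @export
read_spikes_csv <- function(path) {
  df <- utils::read.csv(path)
  split(df$time_ms, factor(df$channel_id,
                           levels = seq_len(max(df$channel_id))))
}

#' Write a voltage trace to two-column CSV (time_ms, mV)
#' @param trace list with `sample_times` and `voltage`
#' @param path file path
#' @export
write_trace_csv <- function(trace, path) {
  utils::write.csv(data.frame(time_ms = trace$sample_times,
                              mV = trace$voltage),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read a voltage trace from two-column CSV
#' @param path file path
#' @return list with `sample_times`, `voltage`
#' @export
read_trace_csv <- function(path) {
  df <- utils::read.csv(path)
  list(sample_times = df[[1]], voltage = df[[2]])
}

#' Serialize a template library to JSON
#' @param library a [gen_template_library()] object
#' @param path file path
#' @export
write_template_library_json <- function(library, path) {
  plain <- lapply(unclass(library), function(cls)
    lapply(cls, function(tm) {
      tm <- unclass(tm)
      tm[!vapply(tm, is.null, logical(1))]
    }))
  jsonlite::write_json(plain, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a template library from JSON
#' @param path file written by [write_template_library_json()]
#' @export
read_template_library_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  lib <- lapply(raw, function(cls) lapply(cls, function(tm) {
    do.call(mossy_template, tm[!vapply(tm, is.null, logical(1))])
  }))
  structure(lib, class = "template_library")
}
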