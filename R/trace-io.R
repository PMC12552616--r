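# Plain-text formats: traces as single-column CSV with comment headers,
# dwell and event tables as TSV.

#' Write a trace to CSV
#'
#' Header lines (prefixed `#`) carry sampling rate, potential and seed, then
#' a single `current_pA` column. Lossless round trip with [read_trace()].
#'
#' @param trace A `nanopore_trace`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "nanopore_trace"))
  if (anyNA(trace$current) || !all(is.finite(trace$current))) {
    stop("trace contains non-finite samples", call. = FALSE)
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# porevoc trace v1",
               sprintf("# sampling_rate_hz: %.10g", trace$sampling_rate),
               sprintf("# potential_mV: %.10g", trace$potential),
               sprintf("# seed: %d", as.integer(trace$seed)),
               "current_pA"), con)
  writeLines(format(trace$current, digits = 17, trim = TRUE, scientific = FALSE), con)
  invisible(path)
}

#' Read a trace from CSV
#'
#' @param path File written by [write_trace()].
#' @return A `nanopore_trace`.
#' @export
read_trace <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  head <- readLines(path, n = 8L)
  if (!length(head)) stop("empty trace file: ", path, call. = FALSE)
  grab <- function(key) {
    ln <- grep(paste0("^# ", key, ":"), head, value = TRUE)
    if (!length(ln)) stop("trace header missing '", key, "'", call. = FALSE)
    as.numeric(sub(paste0("^# ", key, ":\\s*"), "", ln[1L]))
  }
  fs <- grab("sampling_rate_hz")
  pot <- grab("potential_mV")
  seed <- grab("seed")
  dt <- data.table::fread(path, skip = "current_pA", header = TRUE)
  x <- dt[["current_pA"]]
  if (is.null(x) || !length(x)) stop("trace file has no samples: ", path, call. = FALSE)
  if (anyNA(x)) stop("trace contains NA samples: ", path, call. = FALSE)
  structure(list(current = as.numeric(x), sampling_rate = fs, potential = pot,
                 seed = as.integer(seed)),
            class = "nanopore_trace")
}

#' Write / read a ground-truth dwell table (TSV)
#'
#' Columns: `state`, `analyte`, `diastereomer`, `start_s`, `duration_s`.
#'
#' @param dwells A `dwell_seq`.
#' @param path File path.
#' @return `path` invisibly / a `dwell_seq`.
#' @export
write_dwells <- function(dwells, path) {
  stopifnot(inherits(dwells, "dwell_seq"))
  out <- data.frame(state = dwells$state, analyte = dwells$analyte,
                    diastereomer = dwells$diastereomer,
                    start_s = dwells$start, duration_s = dwells$duration)
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

#' @rdname write_dwells
#' @export
read_dwells <- function(path) {
  dt <- as.data.frame(data.table::fread(path, sep = "\t"))
  out <- data.frame(state = dt$state, analyte = dt$analyte,
                    diastereomer = dt$diastereomer,
                    start = dt$start_s, duration = dt$duration_s,
                    stringsAsFactors = FALSE)
  structure(out, class = c("dwell_seq", "data.frame"),
            duration_s = max(dt$start_s + dt$duration_s))
}

#' Write / read an event table (TSV)
#'
#' Columns: `start_s`, `duration_s`, `ires_pct`, `rms_noise_pA`, `label`.
#'
#' @param events An `event_table` (or data.frame with the event columns).
#' @param path File path.
#' @return `path` invisibly / an `event_table`.
#' @export
write_events <- function(events, path) {
  lab <- if (!is.null(events$label)) events$label else NA_character_
  out <- data.frame(start_s = events$start, duration_s = events$duration,
                    ires_pct = events$ires_pct, rms_noise_pA = events$rms_noise,
                    label = lab)
  hdr <- c(sprintf("# duration_s: %.10g", attr(events, "duration_s") %||% NA),
           sprintf("# baseline_pA: %.10g", attr(events, "baseline") %||% NA),
           sprintf("# dead_time_s: %.10g", attr(events, "dead_time") %||% NA))
  writeLines(hdr, path)
  suppressWarnings(
    data.table::fwrite(out, path, sep = "\t", append = TRUE, col.names = TRUE)
  )
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  head <- readLines(path, n = 3L)
  grab <- function(key) {
    ln <- grep(paste0("^# ", key, ":"), head, value = TRUE)
    if (!length(ln)) return(NA_real_)
    suppressWarnings(as.numeric(sub(paste0("^# ", key, ":\\s*"), "", ln[1L])))
  }
  dt <- as.data.frame(data.table::fread(path, skip = 3L, sep = "\t", header = TRUE))
  out <- data.frame(start = dt$start_s, duration = dt$duration_s,
                    ires_pct = dt$ires_pct, rms_noise = dt$rms_noise_pA,
                    label = as.character(dt$label), stringsAsFactors = FALSE)
  structure(out, class = c("event_table", "data.frame"),
            duration_s = grab("duration_s"), baseline = grab("baseline_pA"),
            dead_time = grab("dead_time_s"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
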