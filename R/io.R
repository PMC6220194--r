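## Plain-text round-trips for traces, events, counts and unit metadata.
## All files are tab-delimited with a header row; trace files carry their
## metadata in '#'-prefixed lines before the header.

#' Write a phase trace to a delimited text file
#'
#' Two columns (`time_s`, `phase_deg`) with a header row, preceded by
#' commented metadata lines (`unit_id`, `frequency_hz`, `sampling_rate_hz`,
#' `start_time_s`). One file per contiguous recording segment; encode the
#' unit id and segment index in the file name.
#'
#' @param trace A [phase_trace()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  if (!inherits(trace, "phase_trace"))
    stopf("`trace` must be a phase_trace object")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# unit_id: %s", trace$unit_id),
    sprintf("# frequency_hz: %.10g", trace$frequency),
    sprintf("# sampling_rate_hz: %.10g", trace$sampling_rate),
    sprintf("# start_time_s: %.10g", trace$start_time),
    "time_s\tphase_deg"), con)
  write.table(
    data.frame(time_s = sprintf("%.6f", trace_times(trace)),
               phase_deg = sprintf("%.8g", trace$samples)),
    con, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a phase trace written by [write_trace()]
#' @param path File path.
#' @return A [phase_trace()].
#' @export
read_trace <- function(path) {
  if (!file.exists(path)) stopf("trace file not found: %s", path)
  hdr <- readLines(path, n = 20L)
  meta_lines <- grep("^#", hdr, value = TRUE)
  meta <- list()
  for (ln in meta_lines) {
    kv <- strsplit(sub("^#\\s*", "", ln), ":\\s*")[[1]]
    meta[[kv[1]]] <- kv[2]
  }
  dat <- read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  phase_trace(dat$phase_deg,
              sampling_rate = as.numeric(meta$sampling_rate_hz),
              unit_id = meta$unit_id %||% "u1",
              frequency = as.numeric(meta$frequency_hz %||% 1.5e6),
              start_time = as.numeric(meta$start_time_s %||% dat$time_s[1]))
}

#' Write detected peak events to a delimited file
#' @param events `peak_events` data frame from [detect_peaks()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  out <- data.frame(unit_id = events$unit_id,
                    time_s = events$time,
                    amplitude_deg = events$amplitude,
                    width_s = events$width)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a peak-events file written by [write_events()]
#' @param path File path.
#' @return `peak_events` data frame.
#' @export
read_events <- function(path) {
  dat <- read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE,
                    colClasses = c(unit_id = "character"))
  out <- data.frame(unit_id = dat$unit_id, time = dat$time_s,
                    amplitude = dat$amplitude_deg, width = dat$width_s,
                    stringsAsFactors = FALSE)
  class(out) <- c("peak_events", class(out))
  out
}

#' Write window counts to a delimited file
#' @param counts `window_counts` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_window_counts <- function(counts, path) {
  out <- data.frame(unit_id = counts$unit_id,
                    window_start_s = counts$window_start,
                    window_length_s = counts$window_length,
                    count = counts$count)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a window-counts file written by [write_window_counts()]
#' @param path File path.
#' @return `window_counts` data frame.
#' @export
read_window_counts <- function(path) {
  dat <- read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE,
                    colClasses = c(unit_id = "character"))
  out <- data.frame(unit_id = dat$unit_id,
                    window_start = dat$window_start_s,
                    window_length = dat$window_length_s,
                    count = dat$count, stringsAsFactors = FALSE)
  class(out) <- c("window_counts", class(out))
  out
}

#' Write analysis-unit metadata to a delimited file
#' @param meta Data frame of [analysis_unit_meta()] rows.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_unit_meta <- function(meta, path) {
  write.table(as.data.frame(meta), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read a unit-metadata file written by [write_unit_meta()]
#' @param path File path.
#' @return Data frame with one row per unit.
#' @export
read_unit_meta <- function(path) {
  dat <- read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE,
                    colClasses = c(unit_id = "character",
                                   chamber_id = "character"))
  class(dat) <- c("analysis_unit_meta", class(dat))
  dat
}

#' Write the ground-truth sidecar of a synthetic experiment
#'
#' JSON record of per-unit colony parameters, fill times and event times,
#' plus the media schedule — everything needed to score detection and
#' estimation against the simulation truth.
#'
#' @param experiment A `synthetic_experiment` from [simulate_experiment()].
#' @param path Output path (JSON).
#' @return `path`, invisibly.
#' @export
write_truth <- function(experiment, path) {
  truth <- lapply(experiment$truth, function(u) {
    list(params = unclass(u$params)[c("growth_rate_per_cell",
                                      "pad_capacity", "initial_cells",
                                      "budding_index", "fill_model")],
         fill_time = u$fill_time,
         event_times = u$events$events$time,
         event_budded = u$events$events$budded)
  })
  media <- list(
    switch_duration = experiment$media$switch_duration,
    segments = experiment$media$segments)
  jsonlite::write_json(list(units = truth, media = media),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
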