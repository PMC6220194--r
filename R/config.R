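## Experiment configuration: YAML round-trip with validation and defaults.

config_defaults <- function() {
  list(sampling_rate = 1000, frequency = 1.5e6, t_EIS = 0,
       window_length = 240, budding_index = 0.6, switch_buffer = 40,
       band_low = 0.1, band_high = 30, min_separation = 0.05,
       write_traces = FALSE)
}

unit_known_keys <- c("unit_id", "chamber_id", "pads_filled",
                     "cell_count_start", "cell_count_end",
                     "growth_rate_per_cell", "pad_capacity",
                     "initial_cells", "budding_index", "fill_model",
                     "threshold", "rates")
top_known_keys <- c("seed", "duration", "sampling_rate", "frequency",
                    "t_EIS", "window_length", "budding_index",
                    "switch_buffer", "band_low", "band_high",
                    "min_separation", "write_traces", "noise", "media",
                    "schedule", "units", "reference_condition")

#' Build a validated experiment configuration
#'
#' Programmatic equivalent of [load_config()]: takes the raw nested list
#' (as parsed from YAML/JSON), applies defaults and validates every field.
#' Rejects unknown keys so typos in config files fail loudly.
#'
#' @param x Nested list; see the package README for the layout. Required:
#'   `seed`, `duration`, and a non-empty `units` list, each unit with a
#'   `unit_id` and a `growth_rate_per_cell` (or per-condition `rates`).
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(x) {
  if (!is.list(x)) stopf("config must be a list")
  unknown <- setdiff(names(x), top_known_keys)
  if (length(unknown))
    stopf("unknown config keys: %s", paste(unknown, collapse = ", "))
  for (k in c("seed", "duration"))
    if (is.null(x[[k]])) stopf("config field `%s` is required", k)
  d <- config_defaults()
  for (k in names(d)) if (is.null(x[[k]])) x[[k]] <- d[[k]]

  check_number(x$seed, "seed")
  check_number(x$duration, "duration", lower = 0, allow_zero = FALSE)
  check_number(x$sampling_rate, "sampling_rate", lower = 100)
  check_number(x$t_EIS, "t_EIS", lower = 0)
  check_number(x$window_length, "window_length", lower = 0,
               allow_zero = FALSE)
  check_number(x$budding_index, "budding_index", lower = 0, upper = 1)
  check_number(x$switch_buffer, "switch_buffer", lower = 0)
  x$write_traces <- isTRUE(x$write_traces)

  x$noise <- do.call(noise_model, as.list(x$noise %||% list()))

  if (!is.null(x$media)) {
    m <- x$media
    if (inherits(m, "media_schedule")) {
      ## already built
    } else {
      x$media <- media_schedule(
        condition = vapply(m$segments, `[[`, character(1), "condition"),
        start_time = vapply(m$segments, function(s)
          as.numeric(s$start_time), numeric(1)),
        switch_duration = m$switch_duration %||% 40)
    }
  } else {
    x$media <- media_schedule("default", 0)
  }

  if (is.null(x$units) || length(x$units) == 0L)
    stopf("no analysis units: config must define at least one unit")
  x$units <- lapply(x$units, function(u) {
    unknown <- setdiff(names(u), unit_known_keys)
    if (length(unknown))
      stopf("unknown unit keys: %s", paste(unknown, collapse = ", "))
    if (is.null(u$unit_id)) stopf("every unit needs a `unit_id`")
    if (is.null(u$growth_rate_per_cell)) {
      if (is.null(u$rates))
        stopf("unit '%s': `growth_rate_per_cell` (or per-condition `rates`) is required",
              u$unit_id)
      u$growth_rate_per_cell <- max(unlist(u$rates))
    }
    u$pad_capacity <- u$pad_capacity %||% 400
    u$initial_cells <- u$initial_cells %||% u$pad_capacity
    u$budding_index <- u$budding_index %||% x$budding_index
    u$fill_model <- u$fill_model %||% "deterministic-exponential"
    u$chamber_id <- u$chamber_id %||% "c1"
    u$pads_filled <- u$pads_filled %||% 4
    u$cell_count_start <- u$cell_count_start %||% u$pad_capacity
    u$cell_count_end <- u$cell_count_end %||% u$pad_capacity
    u$threshold <- u$threshold %||% default_threshold(x$frequency)
    check_number(u$threshold, sprintf("units[%s]$threshold", u$unit_id),
                 lower = 0, allow_zero = FALSE)
    if (!is.null(u$rates)) {
      u$rates <- unlist(u$rates)
      missing_cond <- setdiff(x$media$segments$condition, names(u$rates))
      if (length(missing_cond))
        stopf("unit '%s': `rates` missing conditions %s", u$unit_id,
              paste(missing_cond, collapse = ", "))
    }
    u
  })
  ids <- vapply(x$units, `[[`, character(1), "unit_id")
  if (anyDuplicated(ids))
    stopf("duplicate unit_id: %s", ids[duplicated(ids)][1])

  if (!is.null(x$schedule) && !inherits(x$schedule, "multiplex_schedule")) {
    s <- x$schedule
    x$schedule <- multiplex_schedule(
      unit_id = if (is.null(s$unit_id)) ids else unlist(s$unit_id),
      window_length = s$window_length %||% x$window_length,
      switching_overhead = s$switching_overhead %||% 0)
  }
  structure(x, class = "experiment_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Load an experiment configuration from a YAML/JSON file
#'
#' Reads a structured config file, applies defaults (band 0.1-30 Hz,
#' frequency-dependent threshold, 240 s windows, budding index 0.6, 40 s
#' switch buffer) and validates all fields; unknown keys are rejected with
#' the offending field names.
#'
#' @param path Path to a YAML (or JSON, which YAML parses) config file.
#' @return An `experiment_config` object.
#' @seealso [write_config()], [experiment_config()]
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  experiment_config(yaml::read_yaml(path))
}

#' Write an experiment configuration to YAML
#'
#' Inverse of [load_config()]: `load_config(write_config(cfg, f))` equals
#' `cfg`.
#'
#' @param config An `experiment_config`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  if (!inherits(config, "experiment_config"))
    stopf("`config` must be an experiment_config object")
  x <- unclass(config)
  x$noise <- unclass(x$noise)
  segs <- x$media$segments
  x$media <- list(
    switch_duration = x$media$switch_duration,
    segments = lapply(seq_len(nrow(segs)), function(i)
      list(start_time = segs$start_time[i],
           condition = segs$condition[i])))
  if (!is.null(x$schedule)) {
    en <- x$schedule$entries
    x$schedule <- list(unit_id = en$unit_id,
                       window_length = en$window_length,
                       switching_overhead = x$schedule$switching_overhead)
  }
  x$units <- lapply(x$units, function(u) {
    if (!is.null(u$rates)) u$rates <- as.list(u$rates)
    u
  })
  yaml::write_yaml(x, path)
  invisible(path)
}
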