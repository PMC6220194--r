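#' Colony parameters for one analysis unit
#'
#' Describes the yeast colony clamped under the pads of one analysis unit.
#' Once the space under the pads is full, the colony size stays constant and
#' every division pushes one cell out over the sensing electrodes, so the
#' per-cell escape (peak) rate is the quantity the normalized peak rate
#' estimates.
#'
#' @param growth_rate_per_cell Per-cell escape/peak rate in events per hour
#'   per cell. This is the rate of *peaks*: a budded mother-plus-bud passes
#'   as one object and yields a single peak, so the absolute per-cell growth
#'   rate is `growth_rate_per_cell * (1 + budding_index)`.
#' @param pad_capacity Colony size (cells) once the pads are full.
#' @param initial_cells Cells present at `t = 0`; defaults to a pre-filled
#'   pad (`pad_capacity`), the state at which impedance recording starts.
#' @param budding_index Fraction of passing cells that are budded, in
#'   `[0, 1]`.
#' @param fill_model Either `"deterministic-exponential"` (default):
#'   `N(t) = min(N0 * exp(r t), K)`; or `"stochastic-birth"`: a pure-birth
#'   process with per-cell division rate `growth_rate_per_cell`.
#' @return An object of class `colony_params`.
#' @examples
#' colony_params(growth_rate_per_cell = 0.288, pad_capacity = 400)
#' @export
colony_params <- function(growth_rate_per_cell,
                          pad_capacity = 400,
                          initial_cells = pad_capacity,
                          budding_index = 0.6,
                          fill_model = c("deterministic-exponential",
                                         "stochastic-birth")) {
  check_number(growth_rate_per_cell, "growth_rate_per_cell", lower = 0)
  check_number(pad_capacity, "pad_capacity", lower = 1)
  check_number(initial_cells, "initial_cells", lower = 0,
               upper = pad_capacity)
  check_number(budding_index, "budding_index", lower = 0, upper = 1)
  fill_model <- match.arg(fill_model)
  structure(
    list(growth_rate_per_cell = growth_rate_per_cell,
         pad_capacity = pad_capacity,
         initial_cells = initial_cells,
         budding_index = budding_index,
         fill_model = fill_model),
    class = "colony_params")
}

#' Media schedule: piecewise-constant conditions with switching transients
#'
#' @param condition Character vector of condition labels, one per segment.
#' @param start_time Numeric vector of segment start times (seconds),
#'   strictly increasing, first element 0.
#' @param switch_duration Length of the media-exchange transient at each
#'   switch, in seconds (default 40 s, the time for a full medium exchange
#'   at 10 uL/min).
#' @return An object of class `media_schedule` with a `segments` data frame.
#' @examples
#' media_schedule(c("YPD", "YPD+Ca", "YPD"), c(0, 6, 16) * 3600)
#' @export
media_schedule <- function(condition, start_time, switch_duration = 40) {
  if (length(condition) != length(start_time) || length(condition) < 1L)
    stopf("`condition` and `start_time` must be equal-length, non-empty")
  if (!is.numeric(start_time) || any(!is.finite(start_time)))
    stopf("`start_time` must be finite numbers (seconds)")
  if (start_time[1] != 0)
    stopf("the first media segment must start at time 0")
  if (length(start_time) > 1 && any(diff(start_time) <= 0))
    stopf("media segment start times must be strictly increasing")
  check_number(switch_duration, "switch_duration", lower = 0)
  structure(
    list(segments = data.frame(start_time = as.numeric(start_time),
                               condition = as.character(condition),
                               stringsAsFactors = FALSE),
         switch_duration = switch_duration),
    class = "media_schedule")
}

#' Noise and waveform model for synthetic phase traces
#'
#' Parameterizes the raw phase channel: slow baseline drift, white Gaussian
#' noise, and the transient peak produced by each cell passage. The default
#' peak amplitude (4e-3 degrees) sits in the middle of the working threshold
#' range at 1.5 MHz; peak amplitudes are log-normal around the median and
#' widths (full width at half maximum) Gaussian around `peak_width_mean`.
#'
#' @param gaussian_sd White-noise standard deviation (degrees).
#' @param drift_amplitude Amplitude of the slow sinusoidal baseline drift
#'   (degrees). The drift is meant to be removed by the 0.1 Hz high-pass
#'   corner of the detection filter.
#' @param drift_period Drift period (seconds); keep well above `1/0.1 Hz`.
#' @param peak_amplitude_median Median peak amplitude (degrees).
#' @param peak_amplitude_log_sd Log-scale standard deviation of peak
#'   amplitudes (dimensionless).
#' @param peak_width_mean Mean peak width, FWHM, in seconds.
#' @param peak_width_sd Standard deviation of peak widths (seconds).
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(gaussian_sd = 5e-4,
                        drift_amplitude = 5e-3,
                        drift_period = 300,
                        peak_amplitude_median = 4e-3,
                        peak_amplitude_log_sd = 0.1,
                        peak_width_mean = 0.02,
                        peak_width_sd = 0.002) {
  for (nm in c("gaussian_sd", "drift_amplitude", "drift_period",
               "peak_amplitude_median", "peak_amplitude_log_sd",
               "peak_width_mean", "peak_width_sd"))
    check_number(get(nm), nm, lower = 0)
  structure(
    list(gaussian_sd = gaussian_sd,
         drift_amplitude = drift_amplitude,
         drift_period = drift_period,
         peak_amplitude_median = peak_amplitude_median,
         peak_amplitude_log_sd = peak_amplitude_log_sd,
         peak_width_mean = peak_width_mean,
         peak_width_sd = peak_width_sd),
    class = "noise_model")
}

#' Cell-passage event stream for one analysis unit
#'
#' @param unit_id Identifier of the analysis unit.
#' @param time Strictly increasing event times (seconds).
#' @param budded Logical vector: was the passing cell budded
#'   (mother + bud passing as one object, one peak)?
#' @return An object of class `event_stream` with an `events` data frame.
#' @export
event_stream <- function(unit_id, time = numeric(0),
                         budded = logical(length(time))) {
  if (length(budded) != length(time))
    stopf("`time` and `budded` must have equal length")
  if (length(time) > 1 && any(diff(time) <= 0))
    stopf("event times must be strictly increasing")
  if (any(!is.finite(time)) && length(time) > 0)
    stopf("event times must be finite")
  structure(
    list(unit_id = as.character(unit_id),
         events = data.frame(time = as.numeric(time),
                             budded = as.logical(budded))),
    class = "event_stream")
}

#' A uniformly sampled phase trace
#'
#' One contiguous recording segment of the impedance phase signal (degrees)
#' for one analysis unit at one stimulation frequency. Gaps in recording are
#' represented as separate `phase_trace` objects, never as missing samples.
#'
#' @param samples Numeric vector of phase values (degrees).
#' @param sampling_rate Sampling rate in Hz; must exceed twice the 30 Hz
#'   upper filter corner.
#' @param unit_id Analysis-unit identifier.
#' @param frequency Stimulation frequency in Hz (1.12e6 or 1.5e6 on the
#'   device; any positive value accepted).
#' @param start_time Time of the first sample, seconds from experiment
#'   start.
#' @return An object of class `phase_trace`.
#' @export
phase_trace <- function(samples, sampling_rate, unit_id = "u1",
                        frequency = 1.5e6, start_time = 0) {
  if (!is.numeric(samples)) stopf("`samples` must be numeric")
  check_number(sampling_rate, "sampling_rate", lower = 60 + 1e-9)
  check_number(frequency, "frequency", lower = 0, allow_zero = FALSE)
  check_number(start_time, "start_time")
  structure(
    list(unit_id = as.character(unit_id),
         frequency = frequency,
         sampling_rate = sampling_rate,
         start_time = start_time,
         samples = as.numeric(samples)),
    class = "phase_trace")
}

#' Sample times of a phase trace
#' @param trace A [phase_trace()].
#' @return Numeric vector of sample times in seconds.
#' @export
trace_times <- function(trace) {
  trace$start_time + (seq_along(trace$samples) - 1L) / trace$sampling_rate
}

#' Peak-detection configuration
#'
#' @param band_low,band_high Bandpass corners in Hz (defaults 0.1 and 30).
#' @param threshold Detection threshold on the filtered signal, degrees.
#'   Defaults depend on the stimulation frequency; see
#'   [default_threshold()].
#' @param min_separation Minimum separation between reported peaks
#'   (seconds); closer maxima are merged keeping the larger.
#' @return An object of class `detection_config`.
#' @export
detection_config <- function(band_low = 0.1, band_high = 30,
                             threshold = 4e-3, min_separation = 0.05) {
  check_number(band_low, "band_low", lower = 0, allow_zero = FALSE)
  check_number(band_high, "band_high", lower = 0, allow_zero = FALSE)
  if (band_high <= band_low)
    stopf("`band_high` (%g) must exceed `band_low` (%g)",
          band_high, band_low)
  check_number(threshold, "threshold", lower = 0, allow_zero = FALSE)
  check_number(min_separation, "min_separation", lower = 0)
  structure(
    list(band_low = band_low, band_high = band_high,
         threshold = threshold, min_separation = min_separation),
    class = "detection_config")
}

#' Default detection threshold for a stimulation frequency
#'
#' Midpoints of the working threshold ranges: 4e-3 degrees at 1.5 MHz
#' (range 2e-3 to 6e-3) and 0.65e-3 degrees at 1.12 MHz (range 0.5e-3 to
#' 0.8e-3). Thresholds depend on medium conditions in practice and should
#' be overridden per unit when known.
#'
#' @param frequency Stimulation frequency in Hz.
#' @return Threshold in degrees.
#' @export
default_threshold <- function(frequency) {
  check_number(frequency, "frequency", lower = 0, allow_zero = FALSE)
  if (frequency < 1.3e6) 0.65e-3 else 4e-3
}

#' Metadata for one analysis unit
#'
#' Cell counts under the pads at the beginning and end of the recording
#' session (from simultaneous bright-field imaging) are averaged for
#' normalization of peak counts.
#'
#' @param unit_id Analysis-unit identifier.
#' @param chamber_id Culture-chamber identifier (three chambers of five
#'   units each on the device).
#' @param pads_filled Number of filled clamping pads, 0-4.
#' @param cell_count_start,cell_count_end Cells under the pads at start and
#'   end of the recording session.
#' @return An object of class `analysis_unit_meta` (one-row data frame).
#' @export
analysis_unit_meta <- function(unit_id, cell_count_start, cell_count_end,
                               pads_filled = 4, chamber_id = "c1") {
  check_number(cell_count_start, "cell_count_start", lower = 0)
  check_number(cell_count_end, "cell_count_end", lower = 0)
  check_number(pads_filled, "pads_filled", lower = 0, upper = 4)
  out <- data.frame(unit_id = as.character(unit_id),
                    chamber_id = as.character(chamber_id),
                    pads_filled = as.integer(pads_filled),
                    cell_count_start = cell_count_start,
                    cell_count_end = cell_count_end,
                    stringsAsFactors = FALSE)
  class(out) <- c("analysis_unit_meta", class(out))
  out
}

#' @export
print.colony_params <- function(x, ...) {
  cat("Colony parameters\n")
  cat(sprintf("  per-cell peak rate: %g /h\n", x$growth_rate_per_cell))
  cat(sprintf("  pad capacity: %g cells (initial %g)\n",
              x$pad_capacity, x$initial_cells))
  cat(sprintf("  budding index: %g; fill model: %s\n",
              x$budding_index, x$fill_model))
  invisible(x)
}

#' @export
print.phase_trace <- function(x, ...) {
  cat(sprintf(
    "Phase trace [unit %s] %d samples @ %g Hz, t = %.3f..%.3f s, %.3g MHz\n",
    x$unit_id, length(x$samples), x$sampling_rate, x$start_time,
    x$start_time + (length(x$samples) - 1) / x$sampling_rate,
    x$frequency / 1e6))
  invisible(x)
}

#' @export
print.event_stream <- function(x, ...) {
  cat(sprintf("Event stream [unit %s]: %d events, %d budded\n",
              x$unit_id, nrow(x$events), sum(x$events$budded)))
  invisible(x)
}

#' @export
print.media_schedule <- function(x, ...) {
  cat("Media schedule (switch transient", x$switch_duration, "s):\n")
  print(x$segments)
  invisible(x)
}
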