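#' Normalize windowed peak counts to per-cell peak rates
#'
#' Converts each window's peak count into the normalized peak rate:
#' `count / (N_bar * window_length_hours)`, where `N_bar` is the arithmetic
#' mean of the cell counts under the pads at the beginning and end of the
#' recording session. The normalized peak rate (events per hour per cell)
#' is proportional to the per-cell growth rate and comparable across
#' analysis units with different numbers of filled pads.
#'
#' @param counts A `window_counts` data frame from
#'   [count_peaks_in_windows()].
#' @param meta An [analysis_unit_meta()] row for the same unit.
#' @return Data frame of class `peak_rate_series` with columns `unit_id`,
#'   `condition` (NA until [segment_by_condition()]), `window_start`,
#'   `window_length`, `count`, `peak_rate_norm`.
#' @examples
#' cts <- data.frame(unit_id = "u1", window_start = 0,
#'                   window_length = 240, count = 24)
#' meta <- analysis_unit_meta("u1", 500, 500)
#' normalize_peak_rate(cts, meta)$peak_rate_norm  # 24/(500/15) = 0.72 /h
#' @export
normalize_peak_rate <- function(counts, meta) {
  required <- c("window_start", "window_length", "count")
  if (!all(required %in% names(counts)))
    stopf("`counts` must have columns %s", paste(required, collapse = ", "))
  if (!all(c("cell_count_start", "cell_count_end") %in% names(meta)))
    stopf("`meta` must carry cell_count_start and cell_count_end")
  n_bar <- (meta$cell_count_start[1] + meta$cell_count_end[1]) / 2
  if (!is.finite(n_bar) || n_bar <= 0)
    stopf("unit '%s' is not normalizable: average cell count is %s",
          meta$unit_id[1], format(n_bar))
  if (any(counts$window_length <= 0))
    stopf("window lengths must be positive")
  out <- data.frame(
    unit_id = meta$unit_id[1],
    condition = NA_character_,
    window_start = counts$window_start,
    window_length = counts$window_length,
    count = counts$count,
    peak_rate_norm = counts$count / (n_bar * counts$window_length / 3600),
    stringsAsFactors = FALSE)
  class(out) <- c("peak_rate_series", class(out))
  out
}

#' Budding-index correction of a peak rate
#'
#' A budded cell (mother plus attached bud) passes the electrodes as one
#' object and yields a single peak, so each peak carries on average
#' `1 + BI` cells, where `BI` is the budding index (fraction of passing
#' cells that are budded). The absolute growth rate is therefore the peak
#' rate scaled by `(1 + BI)`.
#'
#' @param rate Peak rate(s), events/h (vectorized).
#' @param budding_index Budding index in `[0, 1]` (default 0.6, the value
#'   measured by imaging cells flowing over the electrodes; FACS on the
#'   same cells gave 0.68).
#' @return Corrected growth rate(s), per hour.
#' @examples
#' correct_for_budding(0.288, 0.6)  # 0.4608
#' @export
correct_for_budding <- function(rate, budding_index = 0.6) {
  if (!is.numeric(rate) || any(!is.finite(rate)))
    stopf("`rate` must be finite numeric")
  check_number(budding_index, "budding_index", lower = 0, upper = 1)
  rate * (1 + budding_index)
}

#' Assign rate windows to media conditions
#'
#' Each window is assigned to the media condition whose segment fully
#' contains it. Windows overlapping a switch time +/- `buffer` seconds are
#' discarded: the medium exchange takes ~40 s, during which the condition
#' is undefined.
#'
#' @param series A `peak_rate_series` from [normalize_peak_rate()].
#' @param media A [media_schedule()].
#' @param buffer Seconds around each switch time to exclude; defaults to
#'   the schedule's `switch_duration`.
#' @return The series with the `condition` column filled and buffered
#'   windows removed. A warning is emitted if nothing survives.
#' @export
segment_by_condition <- function(series, media,
                                 buffer = media$switch_duration) {
  if (!inherits(media, "media_schedule"))
    stopf("`media` must be a media_schedule object")
  check_number(buffer, "buffer", lower = 0)
  segs <- media$segments
  starts <- segs$start_time
  ends <- c(starts[-1], Inf)
  ws <- series$window_start
  we <- ws + series$window_length
  cond <- rep(NA_character_, length(ws))
  for (k in seq_len(nrow(segs))) {
    lo <- if (k == 1) starts[k] else starts[k] + buffer
    hi <- if (k == nrow(segs)) Inf else ends[k] - buffer
    inside <- ws >= lo & we <= hi
    cond[inside] <- segs$condition[k]
  }
  out <- series[!is.na(cond), , drop = FALSE]
  out$condition <- cond[!is.na(cond)]
  rownames(out) <- NULL
  if (nrow(out) == 0L)
    warnf("no windows survive condition segmentation (all inside switch buffers)")
  class(out) <- unique(c("peak_rate_series", class(out)))
  out
}

#' Per-condition growth-rate summary
#'
#' Summarizes a peak-rate series into mean, standard error and
#' budding-corrected growth rate per (unit, condition). The SEM uses the
#' sample (n-1) standard deviation over windows divided by sqrt(n); with a
#' single window the SEM is reported as 0 and flagged undefined.
#'
#' @param series A `peak_rate_series`, typically after
#'   [segment_by_condition()]; rows with `NA` condition are summarized
#'   under condition `"all"`.
#' @param budding_index Budding index used for the absolute growth rate.
#' @return Data frame of class `growth_rate_estimate`, one row per
#'   (unit_id, condition): `mean_peak_rate`, `sem_peak_rate`, `n_windows`,
#'   `sem_defined`, `budding_index`, `growth_rate`, `sem_growth_rate`.
#' @examples
#' s <- data.frame(unit_id = "u1", condition = "YPD", window_start = 0:2,
#'                 window_length = 240, count = 1,
#'                 peak_rate_norm = c(0.2, 0.3, 0.4))
#' condition_summary(s, budding_index = 0)
#' @export
condition_summary <- function(series, budding_index = 0.6) {
  if (nrow(series) == 0L) stopf("empty series: nothing to summarize")
  check_number(budding_index, "budding_index", lower = 0, upper = 1)
  cond <- series$condition
  if (is.null(cond)) cond <- rep(NA_character_, nrow(series))
  cond[is.na(cond)] <- "all"
  key <- interaction(series$unit_id, cond, drop = TRUE)
  rows <- lapply(split(seq_len(nrow(series)), key), function(i) {
    r <- series$peak_rate_norm[i]
    n <- length(r)
    m <- mean(r)
    sem <- if (n > 1) stats::sd(r) / sqrt(n) else 0
    data.frame(unit_id = series$unit_id[i][1],
               condition = cond[i][1],
               mean_peak_rate = m,
               sem_peak_rate = sem,
               n_windows = n,
               sem_defined = n > 1,
               budding_index = budding_index,
               growth_rate = m * (1 + budding_index),
               sem_growth_rate = sem * (1 + budding_index),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("growth_rate_estimate", class(out))
  out
}

#' Relative growth-rate change between two conditions
#'
#' Returns `100 * (rate_other - rate_reference) / rate_reference` percent.
#' The reference is the pre-switch (slower, calcium-containing) condition,
#' so a recovery to faster growth is a positive change.
#'
#' @param rate_reference Reference rate(s), per hour; must be positive.
#' @param rate_other Comparison rate(s), per hour.
#' @return Relative change(s) in percent.
#' @examples
#' relative_change(0.196, 0.32)  # ~63%
#' relative_change(0.25, 0.30)   # 20%
#' @export
relative_change <- function(rate_reference, rate_other) {
  if (!is.numeric(rate_reference) || any(!is.finite(rate_reference)))
    stopf("`rate_reference` must be finite numeric")
  if (any(rate_reference <= 0))
    stopf("`rate_reference` must be positive")
  if (!is.numeric(rate_other) || any(!is.finite(rate_other)))
    stopf("`rate_other` must be finite numeric")
  100 * (rate_other - rate_reference) / rate_reference
}
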