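#' Simulate a full multi-unit experiment
#'
#' Digital twin of one device run: for every configured analysis unit,
#' simulates the colony (fill + Poisson escape events, media-modulated
#' when per-condition rates are given) and synthesizes the raw phase
#' trace. Per-unit seeds are derived deterministically from the config
#' seed, so identical configs give bit-identical experiments.
#'
#' @param config An `experiment_config` from [load_config()] or
#'   [experiment_config()].
#' @return An object of class `synthetic_experiment`: list with `traces`
#'   (one continuous [phase_trace()] per unit), `truth` (per-unit params,
#'   fill time and [event_stream()]), `schedule` (or NULL), `media`,
#'   `duration`, `config`.
#' @export
simulate_experiment <- function(config) {
  if (!inherits(config, "experiment_config"))
    stopf("`config` must be an experiment_config object")
  n <- length(config$units)
  seeds <- derive_seeds(config$seed, 2L * n)
  multi_condition <- nrow(config$media$segments) > 1L
  traces <- vector("list", n)
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    u <- config$units[[i]]
    cp <- colony_params(u$growth_rate_per_cell, u$pad_capacity,
                        u$initial_cells, u$budding_index, u$fill_model)
    rate_fn <- if (multi_condition && !is.null(u$rates))
      media_rate_fn(config$media, u$rates)
    else NULL
    sim <- simulate_colony(cp, config$duration, seeds[2 * i - 1L],
                           rate_fn = rate_fn)
    ev <- event_stream(u$unit_id, sim$events$events$time,
                       sim$events$events$budded)
    traces[[i]] <- synthesize_trace(ev, config$noise,
                                    config$sampling_rate,
                                    config$duration, seeds[2 * i],
                                    frequency = config$frequency)
    truth[[i]] <- list(params = cp, fill_time = sim$fill_time,
                       cell_count_fn = sim$cell_count_fn, events = ev)
  }
  names(truth) <- vapply(config$units, `[[`, character(1), "unit_id")
  structure(list(traces = traces, truth = truth,
                 schedule = config$schedule, media = config$media,
                 duration = config$duration, config = config),
            class = "synthetic_experiment")
}

#' Run the full analysis pipeline on a configuration
#'
#' Executes simulate -> detect -> estimate -> report in order: simulates
#' the experiment, crops traces to the multiplex schedule (if any),
#' filters and detects peaks per contiguous segment, counts peaks in
#' fixed-length windows laid inside each segment's filter-settled span,
#' normalizes by average cell count and window duration, segments windows
#' by media condition, and summarizes mean +/- SEM and budding-corrected
#' growth rates per unit and condition, with relative changes against the
#' reference condition.
#'
#' @param config An `experiment_config`.
#' @param output_dir Directory for result files; created if missing. When
#'   `NULL` nothing is written and the results are only returned.
#' @return Invisible list of class `padflux_results`: `events`, `counts`,
#'   `rates`, `summary`, `relative_changes`, `truth`, `log`.
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  if (!inherits(config, "experiment_config"))
    stopf("`config` must be an experiment_config object")
  log_lines <- c(sprintf("padflux %s | R %s",
                         as.character(utils::packageVersion("padflux")),
                         paste(R.version$major, R.version$minor, sep = ".")),
                 sprintf("seed: %g | duration: %g s | sampling: %g Hz",
                         config$seed, config$duration,
                         config$sampling_rate))

  ## --- stage 1: simulate ----------------------------------------------
  ## coincident passages are expected at realistic rates: log, don't warn
  n_dense <- 0L
  exper <- withCallingHandlers(
    tryCatch(simulate_experiment(config),
             error = function(e) stopf("stage simulate: %s",
                                       conditionMessage(e))),
    padflux_dense_events = function(w) {
      n_dense <<- n_dense + 1L
      invokeRestart("muffleWarning")
    })
  if (n_dense > 0)
    log_lines <- c(log_lines, sprintf(
      "simulate: %d unit(s) had events closer than one peak width (superposed)",
      n_dense))
  n_events_true <- vapply(exper$truth, function(u)
    nrow(u$events$events), integer(1))
  log_lines <- c(log_lines, sprintf(
    "simulate: %d units, %s true events", length(exper$traces),
    paste(n_events_true, collapse = "/")))

  ## crop to recording windows when a schedule is present
  segments <- if (!is.null(config$schedule)) {
    wins <- schedule_windows(config$schedule, config$duration)
    apply_multiplex_schedule(exper$traces, wins)
  } else {
    exper$traces
  }

  ## --- stage 2: detect --------------------------------------------------
  margin_of <- function() 1 / config$band_low
  thresholds <- vapply(config$units, `[[`, numeric(1), "threshold")
  names(thresholds) <- vapply(config$units, `[[`, character(1), "unit_id")
  events_list <- list()
  counts_list <- list()
  for (seg in segments) {
    dc <- detection_config(config$band_low, config$band_high,
                           thresholds[[seg$unit_id]],
                           config$min_separation)
    pk <- tryCatch(detect_peaks(seg, dc),
                   error = function(e) stopf("stage detect (unit %s): %s",
                                             seg$unit_id,
                                             conditionMessage(e)))
    events_list[[length(events_list) + 1L]] <- pk
    ## stage 3 (count): windows inside the filter-settled span so the
    ## counting span matches the detection span exactly
    m <- margin_of()
    seg_end <- seg$start_time + length(seg$samples) / seg$sampling_rate
    span <- c(seg$start_time + m, seg_end - m)
    if (span[2] - span[1] >= config$window_length)
      counts_list[[length(counts_list) + 1L]] <-
        count_peaks_in_windows(pk, config$window_length, span)
  }
  events <- if (length(events_list)) do.call(rbind, events_list)
            else data.frame(unit_id = character(0), time = numeric(0),
                            amplitude = numeric(0), width = numeric(0))
  counts <- if (length(counts_list)) do.call(rbind, counts_list)
            else stopf("stage count: no recording segment is long enough for a single %g s window",
                       config$window_length)
  log_lines <- c(log_lines, sprintf(
    "detect: %d peaks in %d segments; count: %d windows of %g s",
    nrow(events), length(segments), nrow(counts), config$window_length))

  ## --- stage 4: estimate ------------------------------------------------
  summaries <- list()
  rates_list <- list()
  for (u in config$units) {
    meta <- analysis_unit_meta(u$unit_id, u$cell_count_start,
                               u$cell_count_end, u$pads_filled,
                               u$chamber_id)
    cts <- counts[counts$unit_id == u$unit_id, , drop = FALSE]
    if (nrow(cts) == 0L) next
    series <- normalize_peak_rate(cts, meta)
    series <- segment_by_condition(series, config$media,
                                   config$switch_buffer)
    if (nrow(series) == 0L) next
    rates_list[[u$unit_id]] <- series
    summaries[[u$unit_id]] <- condition_summary(series, u$budding_index)
  }
  if (!length(summaries))
    stopf("stage estimate: no unit produced any usable windows")
  rates <- do.call(rbind, rates_list)
  summary_df <- do.call(rbind, summaries)
  rownames(rates) <- rownames(summary_df) <- NULL
  log_lines <- c(log_lines, sprintf(
    "estimate: %d (unit x condition) summaries from %d windows (%d discarded near switches)",
    nrow(summary_df), nrow(rates), nrow(counts) - nrow(rates)))

  ## relative change per unit vs the reference (slower) condition
  rel <- relative_changes_table(summary_df,
                                config$reference_condition %||% NULL)

  results <- structure(
    list(events = events, counts = counts, rates = rates,
         summary = summary_df, relative_changes = rel,
         truth = exper$truth, config = config, log = log_lines),
    class = "padflux_results")

  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    write_events(events, file.path(output_dir, "events.tsv"))
    write_window_counts(counts, file.path(output_dir, "window_counts.tsv"))
    write.table(rates, file.path(output_dir, "peak_rates.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(summary_df, file.path(output_dir, "summary.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(summary = summary_df, relative_changes = rel,
           seed = config$seed),
      file.path(output_dir, "summary.json"),
      dataframe = "rows", auto_unbox = TRUE, digits = NA)
    write_truth(exper, file.path(output_dir, "truth.json"))
    if (isTRUE(config$write_traces))
      for (k in seq_along(segments))
        write_trace(segments[[k]],
                    file.path(output_dir,
                              sprintf("trace_%s_seg%03d.tsv",
                                      segments[[k]]$unit_id, k)))
    write_report(results, file.path(output_dir, "report.txt"))
    writeLines(log_lines, file.path(output_dir, "run.log"))
  }
  invisible(results)
}

## Per-unit relative changes of every condition against the reference.
## Reference defaults to the slowest condition (smallest mean peak rate)
## within each unit — the calcium condition in the media-switch design.
relative_changes_table <- function(summary_df, reference_condition = NULL) {
  rows <- lapply(split(summary_df, summary_df$unit_id), function(s) {
    if (nrow(s) < 2L) return(NULL)
    ref_cond <- if (!is.null(reference_condition) &&
                    reference_condition %in% s$condition)
      reference_condition
    else s$condition[which.min(s$mean_peak_rate)]
    ref <- s$mean_peak_rate[s$condition == ref_cond][1]
    if (ref <= 0) return(NULL)
    oth <- s[s$condition != ref_cond, , drop = FALSE]
    data.frame(unit_id = oth$unit_id,
               reference_condition = ref_cond,
               condition = oth$condition,
               relative_change_pct =
                 relative_change(ref, oth$mean_peak_rate),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows))
    return(data.frame(unit_id = character(0),
                      reference_condition = character(0),
                      condition = character(0),
                      relative_change_pct = numeric(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a human-readable report of pipeline results
#'
#' Tabulates per-condition growth-rate estimates and relative changes.
#' Units whose pads were not fully occupied (`pads_filled < 4`) are
#' flagged, as partially occupied pads inflate the variability of the
#' normalized peak rate; single-window SEMs are flagged undefined.
#'
#' @param results A `padflux_results` object from [run_pipeline()].
#' @param path Output file; when `NULL` the report is returned as a
#'   character vector only.
#' @return The report lines, invisibly.
#' @export
write_report <- function(results, path = NULL) {
  if (!inherits(results, "padflux_results"))
    stopf("`results` must be a padflux_results object")
  s <- results$summary
  fmt_sem <- function(sem, ok) ifelse(ok, sprintf("%.4f", sem),
                                      "undefined (n=1)")
  lines <- c("padflux growth-rate report",
             "==========================", "",
             "Per-condition estimates (rates in /h):", "")
  hdr <- sprintf("%-8s %-10s %8s %-16s %4s %8s %-16s",
                 "unit", "condition", "peakrate", "SEM", "n",
                 "growth", "SEM(growth)")
  lines <- c(lines, hdr)
  for (i in seq_len(nrow(s))) {
    lines <- c(lines, sprintf(
      "%-8s %-10s %8.3f %-16s %4d %8.3f %-16s",
      s$unit_id[i], s$condition[i], s$mean_peak_rate[i],
      fmt_sem(s$sem_peak_rate[i], s$sem_defined[i]), s$n_windows[i],
      s$growth_rate[i],
      fmt_sem(s$sem_growth_rate[i], s$sem_defined[i])))
  }
  rel <- results$relative_changes
  if (nrow(rel) > 0) {
    lines <- c(lines, "", "Relative growth-rate changes:", "")
    for (i in seq_len(nrow(rel)))
      lines <- c(lines, sprintf(
        "  %s: %s -> %s: %+.0f%% (reference: %s)",
        rel$unit_id[i], rel$reference_condition[i], rel$condition[i],
        rel$relative_change_pct[i], rel$reference_condition[i]))
  }
  partial <- vapply(results$config$units,
                    function(u) u$pads_filled < 4, logical(1))
  if (any(partial)) {
    ids <- vapply(results$config$units, `[[`, character(1),
                  "unit_id")[partial]
    lines <- c(lines, "",
               sprintf("Note: unit(s) %s had fewer than 4 filled pads; expect higher peak-rate variability.",
                       paste(ids, collapse = ", ")))
  }
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

#' @export
print.padflux_results <- function(x, ...) {
  cat(write_report(x), sep = "\n")
  invisible(x)
}
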