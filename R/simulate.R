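#' Simulate a clamped yeast colony and its escape-event stream
#'
#' Generates the colony trajectory of one analysis unit: cells grow under
#' the pads until the pad area is full, after which the colony size stays
#' constant and each division pushes one cell out over the electrodes. The
#' escape events after the fill time form a Poisson process with rate
#' `growth_rate_per_cell * pad_capacity` (events/h, converted internally to
#' per-second); before the fill time there are no events. Each event is
#' independently flagged budded with probability `budding_index`.
#'
#' @param params A [colony_params()] object.
#' @param duration Simulated duration in seconds.
#' @param seed Integer seed; identical seeds give bit-identical output.
#' @param rate_fn Optional function of time (seconds) returning the
#'   per-cell escape rate in events/h, e.g. from [media_rate_fn()]. When
#'   supplied, events are drawn from an inhomogeneous Poisson process with
#'   rate `rate_fn(t) * pad_capacity` via thinning. Defaults to the
#'   constant `params$growth_rate_per_cell`.
#' @return A list with `fill_time` (seconds; `Inf` if the pad never fills),
#'   `cell_count_fn` (a function time -> cells), and `events`
#'   (an [event_stream()]).
#' @examples
#' cp <- colony_params(0.288, pad_capacity = 400)
#' sim <- simulate_colony(cp, duration = 4 * 3600, seed = 1)
#' nrow(sim$events$events)   # ~ 0.288 * 400 * 4 = 461 expected
#' @export
simulate_colony <- function(params, duration, seed, rate_fn = NULL) {
  if (!inherits(params, "colony_params"))
    stopf("`params` must be a colony_params object")
  check_number(duration, "duration", lower = 0, allow_zero = FALSE)
  if (!is.null(rate_fn) && !is.function(rate_fn))
    stopf("`rate_fn` must be a function of time (s) or NULL")

  r_h <- params$growth_rate_per_cell    # events/h per cell
  K <- params$pad_capacity
  N0 <- params$initial_cells

  with_seed(seed, {
    ## --- fill phase ------------------------------------------------------
    if (N0 >= K) {
      fill_time <- 0
      cell_count_fn <- local({
        K <- K
        function(t) rep(K, length(t))
      })
    } else if (r_h == 0) {
      fill_time <- Inf
      cell_count_fn <- local({
        N0 <- N0
        function(t) rep(N0, length(t))
      })
    } else if (params$fill_model == "deterministic-exponential") {
      ## N(t) = min(N0 e^{rt}, K), r in /h, t in s
      fill_time <- log(K / N0) / r_h * 3600
      cell_count_fn <- local({
        N0 <- N0; K <- K; r_h <- r_h
        function(t) pmin(N0 * exp(r_h * t / 3600), K)
      })
    } else {
      ## pure-birth (Yule) process: division rate r per cell
      n_births <- ceiling(K) - ceiling(N0)
      ns <- ceiling(N0) + seq_len(n_births) - 1L
      waits <- rexp(n_births, rate = ns * r_h / 3600)
      birth_times <- cumsum(waits)
      fill_time <- birth_times[n_births]
      cell_count_fn <- local({
        bt <- c(0, birth_times); counts <- c(ceiling(N0), ns + 1L); K <- K
        function(t) pmin(counts[findInterval(t, bt)], K)
      })
    }

    ## --- shedding phase: (in)homogeneous Poisson escape events -----------
    t0 <- fill_time
    times <- numeric(0)
    if (is.finite(t0) && t0 < duration) {
      if (is.null(rate_fn)) {
        lambda <- r_h * K / 3600            # events/s
        if (lambda > 0) {
          ## draw inter-arrival times in blocks until duration is covered
          times <- t0 + cumsum(rexp(ceiling(lambda * (duration - t0) * 1.5
                                            + 50), lambda))
          while (length(times) && times[length(times)] < duration) {
            extra <- times[length(times)] +
              cumsum(rexp(ceiling(lambda * duration * 0.2 + 50), lambda))
            times <- c(times, extra)
          }
          times <- times[times < duration]
        }
      } else {
        ## thinning against the max rate over a fine grid
        grid <- seq(t0, duration, length.out = 4096)
        lam_h <- rate_fn(grid)
        if (any(!is.finite(lam_h)) || any(lam_h < 0))
          stopf("`rate_fn` must return finite, non-negative rates")
        lam_max <- max(lam_h) * K / 3600
        if (lam_max > 0) {
          cand <- t0 + cumsum(rexp(ceiling(lam_max * (duration - t0) * 1.5
                                           + 50), lam_max))
          while (length(cand) && cand[length(cand)] < duration) {
            extra <- cand[length(cand)] +
              cumsum(rexp(ceiling(lam_max * duration * 0.2 + 50), lam_max))
            cand <- c(cand, extra)
          }
          cand <- cand[cand < duration]
          keep <- runif(length(cand)) <
            (rate_fn(cand) * K / 3600) / lam_max
          times <- cand[keep]
        }
      }
    }
    budded <- if (length(times)) rbinom(length(times), 1L,
                                        params$budding_index) == 1L
              else logical(0)
    list(fill_time = fill_time,
         cell_count_fn = cell_count_fn,
         events = event_stream("u1", times, budded))
  })
}

#' Per-cell rate profile under a media schedule
#'
#' Builds a function of time giving the per-cell escape rate (events/h)
#' under a piecewise-constant media schedule. At each media switch the rate
#' ramps linearly over `switch_duration` seconds from the old to the new
#' condition's rate (the medium exchange takes ~40 s; the cellular response
#' kinetics are not modeled beyond this ramp).
#'
#' @param media A [media_schedule()].
#' @param rates Named numeric vector mapping condition label -> per-cell
#'   rate (events/h).
#' @return A vectorized function `f(t)` (t in seconds) returning events/h.
#' @examples
#' m <- media_schedule(c("YPD", "YPD+Ca"), c(0, 21600))
#' f <- media_rate_fn(m, c("YPD" = 0.32, "YPD+Ca" = 0.196))
#' f(c(0, 21600 + 40))
#' @export
media_rate_fn <- function(media, rates) {
  if (!inherits(media, "media_schedule"))
    stopf("`media` must be a media_schedule object")
  segs <- media$segments
  missing_cond <- setdiff(segs$condition, names(rates))
  if (length(missing_cond))
    stopf("`rates` is missing conditions: %s",
          paste(missing_cond, collapse = ", "))
  seg_rate <- unname(rates[segs$condition])
  if (any(!is.finite(seg_rate)) || any(seg_rate < 0))
    stopf("all rates must be finite and non-negative")
  starts <- segs$start_time
  ramp <- media$switch_duration
  function(t) {
    i <- findInterval(t, starts)
    i[i < 1L] <- 1L
    out <- seg_rate[i]
    if (ramp > 0 && length(starts) > 1) {
      for (k in 2:length(starts)) {
        in_ramp <- i == k & (t - starts[k]) < ramp
        if (any(in_ramp)) {
          frac <- (t[in_ramp] - starts[k]) / ramp
          out[in_ramp] <- seg_rate[k - 1] +
            frac * (seg_rate[k] - seg_rate[k - 1])
        }
      }
    }
    out
  }
}

#' Synthesize a raw phase trace from an event stream
#'
#' Builds the raw phase channel as the sum of a slow sinusoidal baseline
#' drift, white Gaussian noise, and one transient unimodal (Gaussian) peak
#' per cell-passage event. Peak amplitudes are log-normal around the
#' configured median, widths (FWHM) Gaussian around the configured mean.
#' Events outside `[start_time, start_time + duration]` are ignored. Events
#' closer together than one peak width superpose additively (coincident
#' passage) with a warning.
#'
#' @param events An [event_stream()].
#' @param noise A [noise_model()].
#' @param sampling_rate Sampling rate in Hz; at least 100 Hz so that
#'   peaks of a few tens of ms are resolvable.
#' @param duration Trace duration in seconds.
#' @param seed Integer seed.
#' @param frequency Stimulation frequency recorded in the trace metadata.
#' @param start_time Time of the first sample, seconds.
#' @return A [phase_trace()].
#' @export
synthesize_trace <- function(events, noise, sampling_rate = 1000, duration,
                             seed, frequency = 1.5e6, start_time = 0) {
  if (!inherits(events, "event_stream"))
    stopf("`events` must be an event_stream object")
  if (!inherits(noise, "noise_model"))
    stopf("`noise` must be a noise_model object")
  check_number(sampling_rate, "sampling_rate", lower = 100)
  check_number(duration, "duration", lower = 0, allow_zero = FALSE)

  n <- floor(duration * sampling_rate)
  t_rel <- (seq_len(n) - 1L) / sampling_rate    # relative to start_time

  ev <- events$events$time
  ev <- ev[ev >= start_time & ev <= start_time + duration]
  if (length(ev) > 1 && any(diff(ev) < noise$peak_width_mean))
    warning(warningCondition(
      sprintf("events closer than one peak width (%g s): peaks will superpose additively",
              noise$peak_width_mean),
      class = "padflux_dense_events"))

  with_seed(seed, {
    x <- numeric(n)
    if (noise$drift_amplitude > 0 && noise$drift_period > 0)
      x <- x + noise$drift_amplitude * sin(2 * pi * t_rel /
                                           noise$drift_period)
    if (noise$gaussian_sd > 0)
      x <- x + rnorm(n, 0, noise$gaussian_sd)
    if (length(ev)) {
      amps <- rlnorm(length(ev), log(noise$peak_amplitude_median),
                     noise$peak_amplitude_log_sd)
      widths <- rnorm(length(ev), noise$peak_width_mean,
                      noise$peak_width_sd)
      widths <- pmax(widths, 2 / sampling_rate)
      sigmas <- widths / (2 * sqrt(2 * log(2)))   # FWHM -> sd
      for (j in seq_along(ev)) {
        tc <- ev[j] - start_time
        i0 <- max(1L, floor((tc - 5 * sigmas[j]) * sampling_rate) + 1L)
        i1 <- min(n, ceiling((tc + 5 * sigmas[j]) * sampling_rate) + 1L)
        if (i0 > i1) next
        idx <- i0:i1
        x[idx] <- x[idx] +
          amps[j] * exp(-(t_rel[idx] - tc)^2 / (2 * sigmas[j]^2))
      }
    }
    phase_trace(x, sampling_rate, unit_id = events$unit_id,
                frequency = frequency, start_time = start_time)
  })
}

#' Round-robin multiplex schedule
#'
#' One impedance analyzer is routed sequentially across the analysis units;
#' each unit gets one recording window per cycle. Entries are ordered;
#' `cycle_time` is the sum of window lengths plus switching overhead.
#'
#' @param unit_id Character vector of unit identifiers (each at most once).
#' @param window_length Recording window per unit per cycle, seconds;
#'   recycled to the number of units.
#' @param switching_overhead Dead time per switch between units, seconds.
#' @return An object of class `multiplex_schedule`.
#' @examples
#' multiplex_schedule(paste0("u", 1:15), window_length = 240)
#' @export
multiplex_schedule <- function(unit_id, window_length = 240,
                               switching_overhead = 0) {
  unit_id <- as.character(unit_id)
  if (anyDuplicated(unit_id))
    stopf("every unit may appear at most once per cycle")
  if (!is.numeric(window_length) || any(window_length <= 0) ||
      any(!is.finite(window_length)))
    stopf("window lengths must be positive finite numbers")
  check_number(switching_overhead, "switching_overhead", lower = 0)
  window_length <- rep_len(window_length, length(unit_id))
  structure(
    list(entries = data.frame(unit_id = unit_id,
                              window_length = window_length,
                              stringsAsFactors = FALSE),
         switching_overhead = switching_overhead,
         cycle_time = sum(window_length) +
           switching_overhead * length(unit_id)),
    class = "multiplex_schedule")
}

#' @export
print.multiplex_schedule <- function(x, ...) {
  cat(sprintf("Multiplex schedule: %d units/cycle, cycle time %g s (%g s overhead/switch)\n",
              nrow(x$entries), x$cycle_time, x$switching_overhead))
  print(x$entries)
  invisible(x)
}

#' Expand a multiplex schedule into concrete recording windows
#'
#' Repeats the round-robin cycle from `start_time` until `duration` is
#' exhausted; windows that would extend beyond the end are dropped (partial
#' cycles are allowed, partial windows are not).
#'
#' @param schedule A [multiplex_schedule()].
#' @param duration Total experiment duration, seconds.
#' @param start_time Time of the first window, seconds.
#' @return Data frame with columns `unit_id`, `start`, `end`, `cycle`.
#' @export
schedule_windows <- function(schedule, duration, start_time = 0) {
  if (!inherits(schedule, "multiplex_schedule"))
    stopf("`schedule` must be a multiplex_schedule object")
  check_number(duration, "duration", lower = 0, allow_zero = FALSE)
  en <- schedule$entries
  if (nrow(en) == 0L)
    return(data.frame(unit_id = character(0), start = numeric(0),
                      end = numeric(0), cycle = integer(0)))
  oh <- schedule$switching_overhead
  slot <- en$window_length + oh
  n_cycles <- max(1L, ceiling(duration / schedule$cycle_time))
  offsets <- cumsum(c(0, slot[-nrow(en)]))
  starts <- as.vector(outer(offsets, (seq_len(n_cycles) - 1L) *
                            schedule$cycle_time, `+`)) + start_time
  out <- data.frame(
    unit_id = rep(en$unit_id, n_cycles),
    start = starts,
    end = starts + rep(en$window_length, n_cycles),
    cycle = rep(seq_len(n_cycles), each = nrow(en)))
  out <- out[out$end <= start_time + duration + 1e-9, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Crop traces to their scheduled recording windows
#'
#' Emulates the single shared impedance analyzer: each unit's continuous
#' trace is cropped to the union of its scheduled windows, yielding one
#' trace segment per window. Gaps contain no samples. Windows must not
#' overlap across units (one analyzer).
#'
#' @param traces A list of [phase_trace()] objects (one per unit), or a
#'   `synthetic_experiment` from [simulate_experiment()].
#' @param windows Data frame as from [schedule_windows()] with columns
#'   `unit_id`, `start`, `end`. Not used when `traces` is a
#'   `synthetic_experiment` carrying its own schedule.
#' @param ... Unused.
#' @return A list of [phase_trace()] segments, in window order.
#' @export
apply_multiplex_schedule <- function(traces, windows, ...) {
  UseMethod("apply_multiplex_schedule")
}

#' @export
apply_multiplex_schedule.synthetic_experiment <- function(traces, windows,
                                                          ...) {
  if (missing(windows))
    windows <- schedule_windows(traces$schedule, traces$duration)
  apply_multiplex_schedule.default(traces$traces, windows)
}

#' @export
apply_multiplex_schedule.default <- function(traces, windows, ...) {
  if (inherits(traces, "phase_trace")) traces <- list(traces)
  if (nrow(windows) == 0L) return(list())
  ## single analyzer: windows must not overlap in time
  w <- windows[order(windows$start), , drop = FALSE]
  if (nrow(w) > 1 && any(w$start[-1] < w$end[-nrow(w)] - 1e-9))
    stopf("recording windows overlap in time; one analyzer can only record one unit at a time")
  ids <- vapply(traces, function(tr) tr$unit_id, character(1))
  segs <- vector("list", nrow(w))
  for (k in seq_len(nrow(w))) {
    tr <- traces[[match(w$unit_id[k], ids)]]
    if (is.na(match(w$unit_id[k], ids)))
      stopf("no trace for scheduled unit '%s'", w$unit_id[k])
    fs <- tr$sampling_rate
    i0 <- floor((w$start[k] - tr$start_time) * fs + 1e-9) + 1L
    i1 <- floor((w$end[k] - tr$start_time) * fs - 1e-9) + 1L
    i0 <- max(1L, i0); i1 <- min(length(tr$samples), i1)
    if (i0 > i1) next
    segs[[k]] <- phase_trace(tr$samples[i0:i1], fs, unit_id = tr$unit_id,
                             frequency = tr$frequency,
                             start_time = tr$start_time + (i0 - 1L) / fs)
  }
  segs[!vapply(segs, is.null, logical(1))]
}
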