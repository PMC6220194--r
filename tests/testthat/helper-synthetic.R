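# Shared fixtures: noise-free noise models and brute-force oracles.

quiet_noise <- function(...) {
  noise_model(gaussian_sd = 0, drift_amplitude = 0,
              peak_amplitude_log_sd = 0, peak_width_sd = 0, ...)
}

# brute-force windowed histogram: the oracle for count_peaks_in_windows
oracle_window_counts <- function(times, window_length, segment) {
  n_win <- floor((segment[2] - segment[1]) / window_length)
  vapply(seq_len(n_win), function(k) {
    s <- segment[1] + (k - 1) * window_length
    sum(times >= s & times < s + window_length)
  }, integer(1))
}

# brute-force pairwise interval-overlap check for schedules
intervals_overlap <- function(starts, ends) {
  n <- length(starts)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && starts[i] < ends[j] - 1e-9 && starts[j] < ends[i] - 1e-9)
      return(TRUE)
  }
  FALSE
}

# event-level rate recovery (no trace synthesis): simulate a colony,
# count events in windows, normalize -- used for estimator properties
recover_rate <- function(rate, capacity, duration, seed,
                         window_length = 240) {
  cp <- colony_params(rate, pad_capacity = capacity)
  sim <- simulate_colony(cp, duration, seed)
  cts <- count_peaks_in_windows(sim$events, window_length, c(0, duration))
  meta <- analysis_unit_meta("u1", capacity, capacity)
  normalize_peak_rate(cts, meta)
}
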