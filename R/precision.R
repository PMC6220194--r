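#' Closed-form SEM of a Poisson rate estimate
#'
#' Cells passing the electrodes form a Poisson process, so the rate
#' estimated as the mean of `n_cycles` per-window rates (equivalently total
#' count over total recording time for equal windows) has standard error
#' `sqrt(lambda / (n_cycles * window_length))`. The precision depends only
#' on the total recording time `n_cycles * window_length`, not on how it is
#' partitioned into windows.
#'
#' @param event_rate True event rate `lambda`, events/s.
#' @param window_length Recording window length, seconds.
#' @param n_cycles Number of recording windows (cycles).
#' @return SEM of the rate estimate, events/s.
#' @examples
#' poisson_sem(0.082, 60, 85)   # ~0.004 events/s
#' @export
poisson_sem <- function(event_rate, window_length, n_cycles) {
  check_number(event_rate, "event_rate", lower = 0)
  check_number(window_length, "window_length", lower = 0,
               allow_zero = FALSE)
  check_number(n_cycles, "n_cycles", lower = 0, allow_zero = FALSE)
  sqrt(event_rate / (n_cycles * window_length))
}

#' Monte-Carlo SEM of the windowed Poisson rate estimate
#'
#' Draws `n_cycles` Poisson(`event_rate * window_length`) counts per
#' replicate, forms the per-replicate rate estimate (mean of per-window
#' rates) and returns the standard deviation of the estimates across
#' replicates. Converges to [poisson_sem()] as `n_replicates` grows.
#'
#' @param event_rate True event rate, events/s.
#' @param window_length Window length, seconds.
#' @param n_cycles Windows per replicate.
#' @param n_replicates Number of replicate experiments (>= 100).
#' @param seed Integer seed.
#' @return Empirical SEM, events/s.
#' @export
simulate_sem <- function(event_rate, window_length, n_cycles,
                         n_replicates = 2000, seed = 1) {
  check_number(event_rate, "event_rate", lower = 0)
  check_number(window_length, "window_length", lower = 0,
               allow_zero = FALSE)
  check_number(n_cycles, "n_cycles", lower = 1)
  check_number(n_replicates, "n_replicates", lower = 100)
  if (event_rate == 0) return(0)
  with_seed(seed, {
    counts <- matrix(rpois(n_replicates * n_cycles,
                           event_rate * window_length),
                     nrow = n_replicates)
    est <- rowMeans(counts) / window_length
    stats::sd(est)
  })
}

#' Total recording time required for a target precision
#'
#' Inverts [poisson_sem()] for the total time `T = n_cycles *
#' window_length`: `T = lambda / target_sem^2`. Any partition of this time
#' into windows achieves the target; fewer cycles are needed with longer
#' windows.
#'
#' @param event_rate True event rate, events/s.
#' @param target_sem Desired SEM of the rate estimate, events/s.
#' @return Required total recording time, seconds.
#' @examples
#' required_total_time(0.05, 0.004)  # 3125 s
#' @export
required_total_time <- function(event_rate, target_sem) {
  check_number(event_rate, "event_rate", lower = 0)
  check_number(target_sem, "target_sem", lower = 0, allow_zero = FALSE)
  event_rate / target_sem^2
}

#' Precision-optimal window allocation across multiplexed units
#'
#' Assigns each analysis unit a recording window such that all units reach
#' the same relative precision: from `SEM / lambda = rho` it follows that
#' the per-unit total time is `T_i = 1 / (lambda_i * rho^2)`, so slowly
#' growing colonies (small `lambda`) receive strictly longer windows than
#' fast ones. The per-cycle window is `T_i / n_cycles`.
#'
#' @param unit_rates Named numeric vector: unit_id -> event rate, events/s;
#'   all positive.
#' @param target_relative_sem Target `SEM / lambda`, in (0, 1).
#' @param switching_overhead Dead time per switch, seconds.
#' @param n_cycles Number of round-robin cycles over which to spread each
#'   unit's total time (default 1). Non-integer values are floored with a
#'   warning reporting the (slightly worse) achieved precision.
#' @return A [multiplex_schedule()] whose entries carry additional columns
#'   `event_rate`, `total_time` and `predicted_sem`, plus attribute
#'   `n_cycles`.
#' @examples
#' allocate_windows(c(u1 = 0.1, u2 = 0.05), target_relative_sem = 0.1)
#' @export
allocate_windows <- function(unit_rates, target_relative_sem,
                             switching_overhead = 0, n_cycles = 1) {
  if (!is.numeric(unit_rates) || length(unit_rates) == 0L)
    stopf("`unit_rates` must be a non-empty named numeric vector")
  if (is.null(names(unit_rates)) || any(names(unit_rates) == ""))
    stopf("`unit_rates` must be named by unit_id")
  if (any(!is.finite(unit_rates)) || any(unit_rates <= 0))
    stopf("all unit rates must be positive (zero-rate units cannot reach a relative precision target)")
  check_number(target_relative_sem, "target_relative_sem", lower = 0,
               upper = 1, allow_zero = FALSE)
  if (target_relative_sem >= 1)
    stopf("`target_relative_sem` must be in (0, 1)")
  check_number(switching_overhead, "switching_overhead", lower = 0)
  check_number(n_cycles, "n_cycles", lower = 1)
  required_time <- 1 / (unit_rates * target_relative_sem^2)
  window <- required_time / n_cycles   # per-cycle allocation
  n_achieved <- floor(n_cycles)
  if (n_cycles != n_achieved)
    warnf("n_cycles = %g floored to %d; achieved relative SEM is %.4g instead of %.4g",
          n_cycles, n_achieved,
          target_relative_sem * sqrt(n_cycles / n_achieved),
          target_relative_sem)
  total_time <- window * n_achieved
  sched <- multiplex_schedule(names(unit_rates), window,
                              switching_overhead)
  sched$entries$event_rate <- unname(unit_rates)
  sched$entries$total_time <- unname(total_time)
  sched$entries$predicted_sem <-
    sqrt(unname(unit_rates) / unname(total_time))
  attr(sched, "n_cycles") <- n_achieved
  sched
}
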