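make_peak_trace <- function(times, amps, fs = 1000, duration = NULL,
                            width = 0.02) {
  # build a deterministic trace of Gaussian bumps without the RNG
  if (is.null(duration)) duration <- ceiling(max(times)) + 12
  tt <- (seq_len(duration * fs) - 1) / fs
  x <- numeric(length(tt))
  sig <- width / (2 * sqrt(2 * log(2)))
  for (j in seq_along(times))
    x <- x + amps[j] * exp(-(tt - times[j])^2 / (2 * sig^2))
  phase_trace(x, fs, unit_id = "u1")
}

test_that("a flat trace yields no events", {
  tr <- phase_trace(rep(0, 1000 * 40), 1000)
  pk <- detect_peaks(tr, detection_config(threshold = 4e-3))
  expect_equal(nrow(pk), 0)
})

test_that("injected peaks are recovered at their times with populated fields", {
  times <- 11 + (0:9)                  # 10 peaks, 1 s apart
  tr <- make_peak_trace(times, rep(4e-3, 10))
  pk <- detect_peaks(tr, detection_config(threshold = 2e-3))
  expect_equal(nrow(pk), 10)
  expect_true(all(abs(pk$time - times) <= 1 / 1000 + 1e-12))
  expect_true(all(pk$amplitude >= 2e-3))
  # filtering broadens the 20 ms pulse somewhat; width stays in range
  expect_true(all(pk$width > 0.01 & pk$width < 0.06))
  expect_true(!is.unsorted(pk$time))
})

test_that("maxima closer than min_separation merge keeping the larger", {
  tr <- make_peak_trace(c(20, 20.005), c(3e-3, 5e-3))
  pk <- detect_peaks(tr, detection_config(threshold = 1e-3,
                                          min_separation = 0.05))
  expect_equal(nrow(pk), 1)
  # the two bumps 5 ms apart superpose; the kept maximum is the larger
  expect_gt(pk$amplitude, 4e-3)
  expect_lt(abs(pk$time - 20.005), 0.01)
})

test_that("raising the threshold never increases the event count", {
  set.seed(7)
  times <- 12 + cumsum(runif(15, 0.3, 2))
  amps <- runif(15, 1e-3, 6e-3)
  tr <- make_peak_trace(times, amps)
  tr$samples <- tr$samples + rnorm(length(tr$samples), 0, 2e-4)
  counts <- vapply(c(0.5, 1, 2, 3, 4, 5) * 1e-3, function(th)
    nrow(detect_peaks(tr, detection_config(threshold = th))), integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("detection meets the operational false-positive/negative bounds at default SNR", {
  # sensitivity >= 0.99 for 4e-3 deg peaks in 5e-4 deg noise
  set.seed(11)
  times <- 12 + cumsum(runif(60, 0.5, 2))
  dur <- ceiling(max(times)) + 12
  ev <- event_stream("u1", times)
  nm <- noise_model(gaussian_sd = 5e-4, peak_amplitude_log_sd = 0,
                    peak_width_sd = 0)
  tr <- synthesize_trace(ev, nm, 1000, dur, seed = 12)
  pk <- detect_peaks(tr, detection_config(threshold = 2e-3))
  matched <- vapply(times, function(t0)
    any(abs(pk$time - t0) < 0.025), logical(1))
  expect_gte(mean(matched), 0.99)
  # false positives <= 0.01 events/s on event-free noise
  tr0 <- synthesize_trace(event_stream("u1"), nm, 1000, 200, seed = 13)
  fp <- nrow(detect_peaks(tr0, detection_config(threshold = 2e-3)))
  expect_lte(fp / 180, 0.01)
})

test_that("window counting matches the brute-force histogram oracle", {
  expect_equal(
    count_peaks_in_windows(data.frame(time = numeric(0)), 60,
                           c(0, 600))$count,
    rep(0L, 10))
  # half-open convention: 470 s lies in [240, 480)
  got <- count_peaks_in_windows(data.frame(time = c(10, 250, 470)),
                                240, c(0, 720))
  expect_equal(got$count,
               oracle_window_counts(c(10, 250, 470), 240, c(0, 720)))
  expect_equal(got$count, c(1L, 2L, 0L))
  expect_equal(got$window_start, c(0, 240, 480))
  # randomized fixtures against the oracle
  for (s in 1:5) {
    set.seed(s)
    times <- sort(runif(40, 0, 1000))
    wl <- sample(c(30, 60, 240), 1)
    expect_equal(
      count_peaks_in_windows(data.frame(time = times), wl,
                             c(0, 1000))$count,
      oracle_window_counts(times, wl, c(0, 1000)))
  }
})

test_that("an event on a window boundary counts in the later window only", {
  got <- count_peaks_in_windows(data.frame(time = 240), 240, c(0, 720))
  expect_equal(got$count, c(0L, 1L, 0L))
})

test_that("trailing partial windows are discarded and counts conserve events", {
  set.seed(21)
  times <- sort(runif(50, 0, 950))
  got <- count_peaks_in_windows(data.frame(time = times), 240, c(0, 950))
  expect_equal(nrow(got), 3)           # 950/240 -> 3 full windows
  covered <- times < 720
  expect_equal(sum(got$count), sum(covered))
})

test_that("degenerate inputs are rejected", {
  expect_error(detection_config(threshold = 0), "threshold")
  expect_error(detection_config(band_low = 30, band_high = 0.1),
               "band_high")
  expect_error(count_peaks_in_windows(data.frame(time = 1), 0, c(0, 10)),
               "window_length")
  expect_error(count_peaks_in_windows(data.frame(time = 1), 10, c(5, 5)),
               "segment")
  tr_empty <- phase_trace(numeric(0), 1000)
  expect_equal(nrow(detect_peaks(tr_empty)), 0)
})
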