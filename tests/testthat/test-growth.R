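test_that("peak-rate normalization follows count / (Nbar * hours)", {
  meta <- analysis_unit_meta("u1", 500, 500)
  cts <- data.frame(unit_id = "u1", window_start = c(0, 240, 480),
                    window_length = 240, count = c(24L, 0L, 12L))
  s <- normalize_peak_rate(cts, meta)
  expect_equal(s$peak_rate_norm, c(0.72, 0, 0.36))
  # Nbar is the arithmetic mean of start/end counts
  meta2 <- analysis_unit_meta("u1", 400, 600)
  expect_equal(normalize_peak_rate(cts, meta2)$peak_rate_norm[1], 0.72)
})

test_that("units with zero average cell count are not normalizable", {
  meta <- analysis_unit_meta("u9", 0, 0)
  cts <- data.frame(unit_id = "u9", window_start = 0,
                    window_length = 240, count = 1L)
  expect_error(normalize_peak_rate(cts, meta), "not normalizable")
})

test_that("budding correction scales by (1 + BI)", {
  expect_equal(correct_for_budding(0.288, 0), 0.288)
  expect_equal(correct_for_budding(0.288, 0.6), 0.4608)
  # FACS budding index 0.68 as config example
  expect_equal(correct_for_budding(1, 0.68), 1.68)
  expect_equal(correct_for_budding(c(0.2, 0.3), 0.5), c(0.3, 0.45))
  expect_error(correct_for_budding(0.3, -0.1), "budding_index")
  expect_error(correct_for_budding(0.3, 1.2), "budding_index")
})

test_that("a single condition keeps every window", {
  m <- media_schedule("YPD", 0)
  s <- data.frame(unit_id = "u1", condition = NA_character_,
                  window_start = seq(0, 2160, by = 240),
                  window_length = 240, count = 1L,
                  peak_rate_norm = 0.3)
  out <- segment_by_condition(s, m)
  expect_equal(nrow(out), nrow(s))
  expect_true(all(out$condition == "YPD"))
  expect_equal(out$peak_rate_norm, s$peak_rate_norm)
})

test_that("windows at a media switch are assigned by brute-force containment", {
  m <- media_schedule(c("A", "B"), c(0, 36000), switch_duration = 40)
  starts <- seq(0, 72000 - 240, by = 240)
  s <- data.frame(unit_id = "u1", condition = NA_character_,
                  window_start = starts, window_length = 240, count = 1L,
                  peak_rate_norm = 0.3)
  out <- segment_by_condition(s, m, buffer = 40)
  # oracle: full containment outside switch +/- buffer
  oracle <- function(ws) {
    we <- ws + 240
    if (we <= 36000 - 40) "A"
    else if (ws >= 36000 + 40) "B"
    else NA_character_
  }
  expected <- vapply(starts, oracle, character(1))
  dropped <- starts[is.na(expected)]
  expect_true(all(dropped >= 36000 - 240 - 40 & dropped <= 36000 + 40))
  expect_false(any(out$window_start %in% dropped))
  expect_equal(out$condition,
               expected[!is.na(expected)][match(out$window_start,
                                                starts[!is.na(expected)])])
  # the window containing the switch itself is gone
  expect_false(any(out$window_start <= 36000 &
                   out$window_start + 240 > 36000))
})

test_that("a schedule whose buffers swallow every window warns and returns empty", {
  m <- media_schedule(c("A", "B"), c(0, 120), switch_duration = 40)
  s <- data.frame(unit_id = "u1", condition = NA_character_,
                  window_start = 0, window_length = 240, count = 1L,
                  peak_rate_norm = 0.3)
  expect_warning(out <- segment_by_condition(s, m, buffer = 40),
                 "no windows")
  expect_equal(nrow(out), 0)
})

test_that("condition summaries match the textbook mean/SEM", {
  s <- data.frame(unit_id = "u1", condition = "YPD",
                  window_start = c(0, 240, 480), window_length = 240,
                  count = 1L, peak_rate_norm = c(0.2, 0.3, 0.4))
  est <- condition_summary(s, budding_index = 0.6)
  expect_equal(est$mean_peak_rate, 0.3)
  expect_equal(est$sem_peak_rate, 0.1 / sqrt(3))
  expect_equal(est$n_windows, 3L)
  expect_equal(est$growth_rate, 0.3 * 1.6)
  expect_equal(est$sem_growth_rate, 0.1 / sqrt(3) * 1.6)
  # constant series: SEM exactly 0
  s$peak_rate_norm <- 0.25
  expect_equal(condition_summary(s, 0)$sem_peak_rate, 0)
  # single window: SEM 0 and flagged undefined
  est1 <- condition_summary(s[1, ], 0.6)
  expect_equal(est1$sem_peak_rate, 0)
  expect_false(est1$sem_defined)
  expect_error(condition_summary(s[0, ]), "empty")
})

test_that("relative change reproduces the worked percentages", {
  expect_equal(round(relative_change(0.196, 0.32)), 63)
  expect_equal(relative_change(0.25, 0.30), 20)
  expect_equal(relative_change(0.4, 0.4), 0)
  expect_error(relative_change(0, 0.3), "positive")
})

test_that("normalization cancels colony size: different pad counts, same per-cell rate", {
  # reproduces the equality of the two- and three-pad analysis units
  a <- recover_rate(0.288, 400, 12 * 3600, seed = 31)
  b <- recover_rate(0.288, 600, 12 * 3600, seed = 32)
  sa <- condition_summary(a, 0); sb <- condition_summary(b, 0)
  pooled <- sqrt(sa$sem_peak_rate^2 + sb$sem_peak_rate^2)
  expect_lt(abs(sa$mean_peak_rate - sb$mean_peak_rate), 3 * pooled)
})

test_that("the recovered peak rate is unbiased to within 1% over 200 runs", {
  means <- vapply(1:200, function(s)
    mean(recover_rate(0.288, 400, 6 * 3600, seed = 400 + s)$peak_rate_norm),
    numeric(1))
  expect_lt(abs(mean(means) - 0.288) / 0.288, 0.01)
})

test_that("window length trades variance for resolution but not the mean", {
  cp <- colony_params(0.3, pad_capacity = 400)
  sim <- simulate_colony(cp, 120000, seed = 51)
  meta <- analysis_unit_meta("u1", 400, 400)
  r1 <- normalize_peak_rate(
    count_peaks_in_windows(sim$events, 60, c(0, 120000)), meta)
  r2 <- normalize_peak_rate(
    count_peaks_in_windows(sim$events, 120, c(0, 120000)), meta)
  ratio <- var(r1$peak_rate_norm) / var(r2$peak_rate_norm)
  expect_gt(ratio, 1.6); expect_lt(ratio, 2.4)
  expect_equal(mean(r1$peak_rate_norm), mean(r2$peak_rate_norm),
               tolerance = 0.02)
})

test_that("parameter recovery at the published scale: 0.288/h within 2 SEM", {
  r <- recover_rate(0.288, 400, 6 * 3600, seed = 61)   # 90 windows
  expect_gte(nrow(r), 80)
  est <- condition_summary(r, 0)
  expect_lt(abs(est$mean_peak_rate - 0.288), 2 * est$sem_peak_rate + 1e-9)
})
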