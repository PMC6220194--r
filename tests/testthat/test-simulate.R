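test_that("zero growth rate gives no events and a constant colony", {
  cp <- colony_params(0, pad_capacity = 400, initial_cells = 10)
  sim <- simulate_colony(cp, duration = 3600, seed = 1)
  expect_equal(nrow(sim$events$events), 0)
  expect_equal(sim$cell_count_fn(c(0, 1800, 3600)), rep(10, 3))
  expect_true(is.infinite(sim$fill_time))
})

test_that("a pre-filled pad has fill_time 0 and events from the start", {
  cp <- colony_params(0.5, pad_capacity = 100, initial_cells = 100)
  sim <- simulate_colony(cp, duration = 10 * 3600, seed = 2)
  expect_equal(sim$fill_time, 0)
  expect_gt(nrow(sim$events$events), 0)
  expect_lt(min(sim$events$events$time), 3600)
})

test_that("deterministic-exponential fill: count non-decreasing, constant after fill, no early events", {
  cp <- colony_params(0.4, pad_capacity = 400, initial_cells = 25)
  sim <- simulate_colony(cp, duration = 40 * 3600, seed = 3)
  # analytic fill time: log(K/N0)/r hours
  expect_equal(sim$fill_time, log(400 / 25) / 0.4 * 3600)
  tt <- seq(0, 40 * 3600, by = 600)
  nn <- sim$cell_count_fn(tt)
  expect_true(all(diff(nn) >= 0))
  expect_true(all(nn[tt > sim$fill_time] == 400))
  expect_true(all(sim$events$events$time > sim$fill_time))
  expect_true(all(diff(sim$events$events$time) > 0))
})

test_that("stochastic-birth fill reaches capacity and blocks early events", {
  cp <- colony_params(0.4, pad_capacity = 50, initial_cells = 5,
                      fill_model = "stochastic-birth")
  sim <- simulate_colony(cp, duration = 40 * 3600, seed = 4)
  expect_true(is.finite(sim$fill_time))
  expect_equal(sim$cell_count_fn(sim$fill_time + 1), 50)
  expect_true(all(sim$events$events$time > sim$fill_time))
})

test_that("post-fill events follow the closed-form Poisson mean over many seeds", {
  # rate 0.288/h per cell, capacity 400, 10 h post-fill observation:
  # expected events 0.288*400*10 = 1152; Monte-Carlo mean over 200 seeds
  # must land within 3*sqrt(1152/200) of it
  cp <- colony_params(0.288, pad_capacity = 400)
  n <- vapply(1:200, function(s)
    nrow(simulate_colony(cp, 10 * 3600, s)$events$events), integer(1))
  expect_lt(abs(mean(n) - 1152), 3 * sqrt(1152 / 200))
})

test_that("interval counts pass a chi-square Poisson goodness-of-fit over 500 replicates", {
  cp <- colony_params(0.288, pad_capacity = 400)
  lam <- 0.288 * 400 * 0.1            # 6-min intervals
  cnt <- unlist(lapply(1:500, function(s) {
    ev <- simulate_colony(cp, 1800, s)$events$events$time
    tabulate(findInterval(ev, seq(0, 1800, by = 360)), 5)
  }))
  br <- unique(c(-0.5, stats::qpois(seq(0.1, 0.9, 0.1), lam) + 0.5, Inf))
  obs <- table(cut(cnt, br))
  p <- diff(stats::ppois(c(br[1], br[-1] - 0.5), lam))
  pval <- suppressWarnings(
    stats::chisq.test(as.vector(obs), p = p / sum(p))$p.value)
  expect_gt(pval, 0.001)
})

test_that("budded flags are Bernoulli(budding_index)", {
  cp <- colony_params(0.288, pad_capacity = 400, budding_index = 0.6)
  ev <- simulate_colony(cp, 12 * 3600, seed = 5)$events$events
  expect_gt(nrow(ev), 1000)
  phat <- mean(ev$budded)
  ci99 <- 2.576 * sqrt(0.6 * 0.4 / nrow(ev))
  expect_lt(abs(phat - 0.6), ci99)
})

test_that("identical seeds give bit-identical simulations", {
  cp <- colony_params(0.3, pad_capacity = 200, initial_cells = 50)
  a <- simulate_colony(cp, 3600 * 5, seed = 42)
  b <- simulate_colony(cp, 3600 * 5, seed = 42)
  expect_identical(a$events$events, b$events$events)
  expect_identical(a$fill_time, b$fill_time)
  c_ <- simulate_colony(cp, 3600 * 5, seed = 43)
  expect_false(identical(a$events$events, c_$events$events))
})

test_that("invalid colony parameters are rejected", {
  expect_error(colony_params(-1), "growth_rate_per_cell")
  expect_error(colony_params(0.3, pad_capacity = 0), "pad_capacity")
  expect_error(colony_params(0.3, initial_cells = 500, pad_capacity = 400),
               "initial_cells")
  expect_error(colony_params(0.3, budding_index = 1.5), "budding_index")
  expect_error(colony_params(NaN), "growth_rate_per_cell")
})

test_that("media_rate_fn ramps linearly over the switch and is constant elsewhere", {
  m <- media_schedule(c("YPD", "Ca", "YPD"), c(0, 6, 16) * 3600,
                      switch_duration = 40)
  f <- media_rate_fn(m, c(YPD = 0.32, Ca = 0.196))
  expect_equal(f(c(0, 3 * 3600, 6 * 3600 - 1)), rep(0.32, 3))
  expect_equal(f(6 * 3600 + 20), (0.32 + 0.196) / 2)   # mid-ramp
  expect_equal(f(c(6 * 3600 + 40, 10 * 3600)), rep(0.196, 2))
  expect_equal(f(16 * 3600 + 40), 0.32)
  expect_error(media_rate_fn(m, c(YPD = 0.32)), "Ca")
})

test_that("thinned media-modulated events recover the piecewise mean", {
  m <- media_schedule(c("fast", "slow"), c(0, 4 * 3600))
  f <- media_rate_fn(m, c(fast = 0.4, slow = 0.1))
  cp <- colony_params(0.4, pad_capacity = 400)
  n1 <- 0; n2 <- 0
  for (s in 1:60) {
    ev <- simulate_colony(cp, 8 * 3600, s, rate_fn = f)$events$events$time
    n1 <- n1 + sum(ev < 4 * 3600)
    n2 <- n2 + sum(ev >= 4 * 3600)
  }
  exp1 <- 0.4 * 400 * 4 * 60; exp2 <- 0.1 * 400 * 4 * 60
  expect_lt(abs(n1 - exp1) / exp1, 0.02)
  expect_lt(abs(n2 - exp2) / exp2, 0.04)
})

test_that("media_schedule validates segment ordering", {
  expect_error(media_schedule(c("a", "b"), c(100, 200)), "start at time 0")
  expect_error(media_schedule(c("a", "b"), c(0, 0)), "strictly increasing")
  expect_error(media_schedule(character(0), numeric(0)), "non-empty")
})
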