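mk_mask <- function(n_sleep = 30, n_awake = 5, bin = 60) {
  nb <- n_sleep + n_awake
  sleep <- c(rep(TRUE, n_sleep), rep(FALSE, n_awake))
  m <- data.frame(bin_start_s = seq(0, by = bin, length.out = nb),
                  bin_end_s = seq(bin, by = bin, length.out = nb),
                  speed_ok = sleep, mua_ok = sleep, sleep = sleep)
  m$cum_sleep_s <- cumsum(bin * sleep)
  class(m) <- c("rk_sleep_mask", class(m))
  m
}

mk_behavior <- function() {
  list(summary = data.frame(
    epoch = c("RUN1_T1", "RUN1_T2"), track_id = 1:2,
    laps = c(16, 4), time_immobile_s = c(300, 100),
    time_mobile_s = c(300, 100), mean_moving_speed_cms = 20,
    duration_s = c(600, 200)))
}

test_that("session metrics implement the rate arithmetic and bias conservation", {
  mask <- mk_mask()
  # 54 track-1 sleep events spread over the 30-min window -> 0.03 events/s
  t1_times <- seq(5, 1795, length.out = 54)
  ev <- data.frame(start_s = t1_times, end_s = t1_times + 0.2, epoch = "POST1",
                   track_id = 1L, state = "sleep")
  ev2 <- data.frame(start_s = c(300.5, 900.5), end_s = c(300.7, 900.7),
                    epoch = "POST1", track_id = 2L, state = "sleep")
  events <- rbind(ev, ev2)
  cands <- data.frame(start_s = c(10, 20), end_s = c(10.2, 20.2),
                      epoch = c("RUN1_T1", "RUN1_T2"))
  met <- compute_session_metrics(events, cands, list(POST1 = mask), mk_behavior())
  s <- met$sleep
  expect_equal(s$sleep_rate[s$track_id == 1], 54 / 1800)
  expect_equal(s$sleep_count_win[s$track_id == 2], 2)
  expect_true(all(s$window_complete))
  # zero events -> zero rates
  met0 <- compute_session_metrics(events[0, ], cands[0, ], list(POST1 = mask),
                                  mk_behavior())
  expect_true(all(met0$sleep$sleep_rate == 0))
  # bias trace ends at total T1 - total T2
  b <- met$bias$POST1
  expect_equal(b$bias[nrow(b)], 54 - 2)
})

test_that("simple regression reports adjusted R2, p and errors on degenerate x", {
  x <- 1:10
  fit <- suppressWarnings(regress_simple(x, 2 * x + 1))
  expect_equal(fit$r2, 1)
  expect_equal(fit$slope, 2)
  expect_lt(fit$p, 1e-10)
  expect_error(regress_simple(rep(1, 10), rnorm(10)), "zero variance")
  expect_error(regress_simple(1:2, 1:2), "3 points")
  set.seed(31)
  noise <- regress_simple(rnorm(300), rnorm(300))
  expect_lt(abs(noise$r2), 0.05)
})

test_that("the mixed model recovers a single true standardized effect", {
  d <- simulate_metric_batch(n_animals = 4, n_sessions = 10, beta = 0.6, seed = 3)
  fit <- regress_mixed(d, "sleep_rate",
                       c("awake_rate", "awake_number", "theta_sequences",
                         "time_on_track"), "animal")
  co <- fit$coefficients
  expect_true(co$significant[co$term == "awake_number"])
  expect_gt(co$beta[co$term == "awake_number"], 0.3)
  expect_false(any(co$significant[co$term != "awake_number"]))

  # constant response: all betas zero
  d0 <- d; d0$sleep_rate <- 1
  fit0 <- suppressWarnings(suppressMessages(
    regress_mixed(d0, "sleep_rate",
                  c("awake_rate", "awake_number"), "animal")))
  expect_true(all(abs(fit0$coefficients$beta) < 1e-8))

  # permuted response: no effect recovered (fixed seed)
  set.seed(5)
  dp <- d; dp$sleep_rate <- sample(dp$sleep_rate)
  fitp <- suppressWarnings(suppressMessages(
    regress_mixed(dp, "sleep_rate",
                  c("awake_rate", "awake_number", "theta_sequences",
                    "time_on_track"), "animal")))
  expect_false(any(fitp$coefficients$significant))
  expect_error(regress_mixed(d[d$animal == 1, ], "sleep_rate",
                             "awake_number", "animal"), "grouping levels")
})

test_that("per-cell regression links awake and sleep participation differences", {
  cells <- data.frame(awake_diff = c(-4, -2, 0, 1, 3, 6),
                      sleep_rate_diff = c(-4, -2, 0, 1, 3, 6) * 0.002)
  fit <- suppressWarnings(per_cell_replay_regression(cells))
  expect_false(fit$skipped)
  expect_equal(fit$r2, 1)
  expect_equal(fit$slope, 0.002)
  expect_true(per_cell_replay_regression(cells[1, ])$skipped)
  # shuffled pairing: slope near zero
  set.seed(41)
  big <- data.frame(awake_diff = rnorm(200, 0, 3),
                    sleep_rate_diff = rnorm(200, 0, 0.005))
  expect_lt(abs(per_cell_replay_regression(big)$r2), 0.05)
})

test_that("the paired Wilcoxon comparison handles ties, minimal p and power", {
  same <- compare_tracks(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(same$p, 1)
  shifted <- compare_tracks(2:7 + seq(0.5, 3, by = 0.5), 2:7)
  expect_equal(shifted$p, 2 / 2^6)   # minimal attainable two-sided p at n = 6
  set.seed(43)
  power <- mean(replicate(200, {
    t2 <- rnorm(15)
    compare_tracks(t2 + 1 + rnorm(15, 0, 0.8), t2)$p < 0.05
  }))
  expect_gte(power, 0.8)
})

test_that("dual-cell participation tables difference awake and sleep membership", {
  roster <- data.frame(unit_id = 1:6, principal = TRUE,
                       place_t1 = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE),
                       place_t2 = c(TRUE, TRUE, FALSE, FALSE, TRUE, TRUE))
  mk <- function(t, epoch, track, state, units) {
    data.frame(start_s = t, end_s = t + 0.2, epoch = epoch, track_id = track,
               state = state, units = I(list(units)))
  }
  events <- rbind(
    mk(110, "RUN1_T1", 1L, "awake-local", c(1, 2, 3)),
    mk(120, "RUN1_T1", 1L, "awake-local", c(1, 3)),
    mk(130, "RUN1_T2", 2L, "awake-local", c(2, 5)),
    mk(210, "POST1", 1L, "sleep", c(1, 4)),
    mk(220, "POST1", 2L, "sleep", c(2, 6)))
  tab <- dual_cell_replay_table(events, roster, "POST1", window_s = 100)
  expect_equal(tab$unit_id, c(1, 2))
  expect_equal(tab$awake_diff, c(2 - 0, 1 - 1))     # cell 1: two T1 awake events
  expect_equal(tab$sleep_rate_diff, c(1 / 100, -1 / 100))
})
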