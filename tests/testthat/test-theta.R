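pure_band <- function(freq, dur = 10, fs = 1000, amp = 1, noise = 0) {
  x <- amp * cos(2 * pi * freq * (seq_len(dur * fs) - 1) / fs)
  if (noise > 0) x <- x + rnorm(length(x), 0, noise)
  band_filter_hilbert(list(fs = fs, start_s = 0, samples = x), c(4, 12))
}

const_linpos <- function(dur = 10, pos = 100, speed = 20, dt = 0.04) {
  tt <- seq(0, dur, by = dt)
  data.frame(time_s = tt, lin_cm = pos + cumsum(rep(0, length(tt))),
             speed_cms = speed, on_track = TRUE)
}

test_that("theta cycles are detected trough-to-trough with duration/speed/zone filters", {
  tb <- pure_band(8)
  lp <- const_linpos()
  cyc <- detect_theta_cycles(tb, lp, list(start = 0, end = 10), 200)
  expect_gt(nrow(cyc), 70)
  expect_lt(nrow(cyc), 82)
  expect_equal(median(cyc$duration_s), 0.125, tolerance = 0.01)
  expect_true(all(cyc$duration_s >= 0.08 & cyc$duration_s <= 0.2))

  # 13 Hz -> ~77 ms cycles, all below the 80-ms floor (interior window
  # avoids filter edge transients)
  tb13 <- pure_band(13)
  expect_equal(nrow(detect_theta_cycles(tb13, lp, list(start = 0.5, end = 9.5), 200)), 0)

  # speed filter and reward-zone exclusion
  slow <- const_linpos(speed = 2)
  expect_equal(nrow(detect_theta_cycles(tb, slow, list(start = 0, end = 10), 200)), 0)
  zone <- const_linpos(pos = 10)
  expect_equal(nrow(detect_theta_cycles(tb, zone, list(start = 0, end = 10), 200)), 0)

  flat <- band_filter_hilbert(list(fs = 1000, start_s = 0, samples = rep(0, 5000)),
                              c(4, 12))
  expect_equal(nrow(detect_theta_cycles(flat, lp, list(start = 0, end = 5), 200)), 0)
})

test_that("alternating-extrema detection matches the reference scan on a noisy trace", {
  set.seed(13)
  x <- cos(2 * pi * 8 * (1:4000) / 1000) + 0.4 * rnorm(4000)
  f <- replaykit:::band_filter(x, 1000, c(4, 12))
  thr <- 0.25 * median(abs(f))
  got <- replaykit:::alternating_extrema(f, thr)
  ref <- extrema_oracle(f, thr)
  expect_equal(got$index, ref$index)
  expect_equal(got$type, ref$type)
})

test_that("cycles with fewer than 2 active units are excluded from decoding", {
  laps <- data.frame(lap = 1, start_s = 0, end_s = 10)
  cyc <- data.frame(start_s = 1, end_s = 1.125, duration_s = 0.125, mid_s = 1.06,
                    position_cm = 100, speed_cms = 20, direction = 1)
  rate <- matrix(rexp(5 * 20, 1 / 5), 5, 20, dimnames = list(1:5, NULL))
  m <- structure(list(rate = rate, occupancy_s = rep(1, 20), bin_cm = 10,
                      edges = seq(0, 200, 10), track_length = 200,
                      smoothed = TRUE, direction = "out"),
                 class = "rk_ratemaps")
  lm <- list(list(out = m, `in` = m))
  one_unit <- data.frame(unit_id = 1, time_s = c(1.02, 1.05, 1.09))
  expect_length(decode_theta_windows(cyc, one_unit, lm, laps, 1), 0)
  two_units <- rbind(one_unit, data.frame(unit_id = 2, time_s = 1.06))
  expect_length(decode_theta_windows(cyc, two_units, lm, laps, 1), 1)
  expect_length(decode_theta_windows(cyc, one_unit[0, ], lm, laps, 1), 0)
})

test_that("averaging centres, mirrors and resamples cycle posteriors", {
  nb <- 20
  P <- matrix(0, nb, 8)
  for (j in 1:8) P[9 + j %/% 3, j] <- 1   # gentle forward sweep near bin 10
  d1 <- list(prob = P, pos_cm = (1:nb - 0.5) * 10, times = 1:8,
             position_cm = 95, direction = 1)
  avg1 <- average_theta_sequences(list(d1, d1), bin_cm = 10)
  # identical cycles: average equals the single centred posterior
  avg_single <- average_theta_sequences(list(d1), bin_cm = 10)
  expect_equal(avg1$average, avg_single$average)
  expect_equal(avg1$n_cycles, 2)

  # a pair mirrored around the animal's position aligns after mirroring
  pos_bin <- 10
  Pm <- matrix(0, nb, 8)
  for (k in seq_len(nb)) {
    src <- 2 * pos_bin - k
    if (src >= 1 && src <= nb) Pm[k, ] <- P[src, ]
  }
  d2 <- list(prob = Pm, pos_cm = (1:nb - 0.5) * 10, times = 1:8,
             position_cm = 95, direction = -1)
  avg2 <- average_theta_sequences(list(d1, d2), bin_cm = 10)
  expect_equal(avg2$average, avg_single$average, tolerance = 1e-9)
})

test_that("theta significance requires beating all three shuffles", {
  cfg <- analysis_config(n_shuffles = 100)
  rate <- matrix(rexp(8 * 20, 1 / 5), 8, 20, dimnames = list(1:8, NULL))
  m <- structure(list(rate = rate, occupancy_s = rep(1, 20), bin_cm = 10,
                      edges = seq(0, 200, 10), track_length = 200,
                      smoothed = TRUE, direction = "out"),
                 class = "rk_ratemaps")
  set.seed(21)
  # structureless spiking -> near-chance significance rate
  reps <- replicate(20, {
    counts <- matrix(rpois(8 * 10, 0.5), 8, 10, dimnames = list(1:8, NULL))
    post <- decode_posterior(counts, list(`1` = m), 0.01)
    d <- list(prob = post$prob, pos_cm = post$pos_cm, times = (1:10) * 0.01,
              counts = counts, position_cm = 100, direction = 1)
    sc <- score_theta_significance(d, m, 1, cfg)
    expect_true(all(is.na(sc$p)) || all(sc$p > 0 & sc$p <= 1))
    isTRUE(sc$significant)
  })
  expect_lt(mean(reps), 0.25)
})
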