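sine_trace <- function(freq, fs = 1000, dur = 10, amp = 1) {
  list(channel_id = 1L, fs = fs, start_s = 0,
       samples = amp * sin(2 * pi * freq * (seq_len(dur * fs) - 1) / fs))
}

test_that("channel selection ranks channels by band power", {
  one <- list(sine_trace(8))
  sel1 <- select_channels(one)
  expect_equal(sel1$theta, 1)
  expect_equal(sel1$ripple, 1)
  expect_equal(sel1$contrast, 1)

  two <- list(sine_trace(8), sine_trace(180))
  sel2 <- select_channels(two)
  expect_equal(sel2$theta, 1)
  expect_equal(sel2$ripple, 2)
  expect_equal(sel2$contrast, 1)
  expect_error(select_channels(list()), "no LFP")

  # known band SNRs: selection matches integrated band-power ranking
  set.seed(1)
  mk <- function(th, rp) {
    n <- 20000
    s <- th * sin(2 * pi * 8 * (1:n) / 1000) +
      rp * sin(2 * pi * 180 * (1:n) / 1000) + rnorm(n, 0, 0.5)
    list(channel_id = 1L, fs = 1000, start_s = 0, samples = s)
  }
  chans <- list(mk(2, 0.3), mk(0.5, 1.5), mk(1, 1))
  sel3 <- select_channels(chans)
  expect_equal(sel3$theta, 1)
  expect_equal(sel3$ripple, 2)
})

test_that("zero-phase band filtering yields analytic amplitude and phase", {
  tr <- sine_trace(8, dur = 6)
  bs <- band_filter_hilbert(tr, c(4, 12))
  mid <- 1000:5000
  expect_equal(mean(bs$amplitude[mid]), 1, tolerance = 0.02)
  expect_lt(stats::sd(bs$amplitude[mid]), 0.02)
  # phase advances at 8 Hz: unwrapped slope = 2*pi*8 per second
  dphi <- diff(bs$phase[mid])
  dphi[dphi < -pi] <- dphi[dphi < -pi] + 2 * pi
  expect_equal(mean(dphi) * tr$fs / (2 * pi), 8, tolerance = 0.01)

  # out-of-band attenuation >= 20 dB through the theta filter
  out <- band_filter_hilbert(sine_trace(50, dur = 6), c(4, 12))
  expect_lt(mean(out$amplitude[mid]), 0.1)

  # zero-phase symmetry: filtering the reversed signal reverses the output
  x <- sine_trace(8, dur = 4)$samples + 0.1 * sin(2 * pi * 23 * (1:4000) / 1000)
  f1 <- band_filter_hilbert(list(fs = 1000, start_s = 0, samples = x), c(4, 12))
  f2 <- band_filter_hilbert(list(fs = 1000, start_s = 0, samples = rev(x)), c(4, 12))
  expect_lt(max(abs(f2$filtered[1000:3000] - rev(f1$filtered)[1000:3000])), 0.05)
  expect_error(band_filter_hilbert(sine_trace(8, fs = 100), c(125, 300)),
               "sample rate too low")
})

test_that("putative-sleep bins require both immobility and elevated MUA", {
  fs <- 10
  n <- 1800       # 180 s -> three 60-s bins
  z <- c(rep(0.5, 600), rep(0.5, 600), rep(-1, 600))
  mua <- structure(list(start_s = 0, fs = fs, z = z, rate_hz = 1), class = "rk_mua")
  speed <- list(time_s = (seq_len(n) - 1) / fs,
                speed_cms = c(rep(0, 600), rep(5, 600), rep(0, 600)))
  mask <- detect_putative_sleep(speed, mua, list(start = 0, end = 180))
  expect_equal(mask$sleep, c(TRUE, FALSE, FALSE))
  expect_equal(mask$cum_sleep_s, c(60, 60, 60))
  expect_error(detect_putative_sleep(speed, mua, list(start = 0, end = 30)),
               "shorter than one sleep bin")
})

test_that("the cumulative-sleep window extracts exactly the requested time", {
  mask <- data.frame(bin_start_s = seq(0, 540, by = 60),
                     bin_end_s = seq(60, 600, by = 60),
                     speed_ok = TRUE, mua_ok = TRUE,
                     sleep = c(TRUE, FALSE, rep(TRUE, 8)))
  mask$cum_sleep_s <- cumsum(60 * mask$sleep)
  sw <- sleep_window(mask, 300)
  expect_true(sw$complete)
  expect_equal(sum(sw$intervals$end_s - sw$intervals$start_s), 300)
  sw2 <- sleep_window(mask, 270)   # truncates the final bin
  expect_equal(sum(sw2$intervals$end_s - sw2$intervals$start_s), 270)
  sw3 <- sleep_window(mask, 1e6)
  expect_false(sw3$complete)
  expect_equal(sw3$total_s, sum(60 * mask$sleep))
})

test_that("the LFP control labels states by the printed threshold rules", {
  nb <- 6; fs <- 2; bin <- 60
  n <- nb * bin * fs
  # bins 1-3 awake-like (high theta, moving); bins 4-6 match the printed
  # NREM rule: low theta power but high theta/delta ratio
  th_amp <- rep(c(2, 2, 2, 0.5, 0.5, 0.5), each = bin * fs)
  de_amp <- rep(c(2, 2, 2, 0.1, 0.1, 0.1), each = bin * fs)
  mkband <- function(a) structure(list(band = c(0, 1), fs = fs, start_s = 0,
                                       filtered = a, phase = a * 0, amplitude = a),
                                  class = "rk_band")
  speed <- list(time_s = (seq_len(n) - 1) / fs,
                speed_cms = rep(c(8, 8, 8, 0, 0, 0), each = bin * fs))
  mask <- data.frame(bin_start_s = seq(0, by = bin, length.out = nb),
                     bin_end_s = seq(bin, by = bin, length.out = nb),
                     sleep = c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE))
  out <- lfp_sleep_control(mkband(th_amp), mkband(de_amp), speed,
                           list(start = 0, end = nb * bin), mask = mask)
  expect_equal(out$labels$state[1:3], rep("awake", 3))
  expect_equal(out$labels$state[4:6], rep("NREM", 3))
  expect_equal(out$agreement, 1.0)
})

test_that("putative sleep recovers the generator's true sleep intervals", {
  ss <- small_session()
  beh <- small_behavior()
  speed <- replaykit:::session_speed(beh$position)
  cfg <- analysis_config()
  top_u <- replaykit:::top_units_by_count(ss$session$spikes, ss$session$units)
  w <- epoch_window(ss$session, "POST1")
  mz <- mua_zscore(ss$session$spikes, w, cfg, units = top_u)
  mask <- detect_putative_sleep(speed, mz, w, cfg)
  truth <- ss$truth$sleep_intervals
  truth <- truth[truth$epoch == "POST1", ]
  true_in_bin <- vapply(seq_len(nrow(mask)), function(b) {
    ov <- sum(replaykit:::interval_overlap(mask$bin_start_s[b], mask$bin_end_s[b],
                                           truth$start_s, truth$end_s))
    ov / (mask$bin_end_s[b] - mask$bin_start_s[b]) > 0.5
  }, logical(1))
  jacc <- sum(mask$sleep & true_in_bin) / sum(mask$sleep | true_in_bin)
  expect_gte(jacc, 0.9)
})
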