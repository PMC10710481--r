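test_that("weighted correlation handles canonical and degenerate posteriors", {
  expect_equal(weighted_correlation(diag(5)), 1)
  expect_equal(weighted_correlation(diag(5)[, 5:1]), -1)
  expect_equal(weighted_correlation(matrix(1 / 25, 5, 5)), 0)
  expect_true(is.na(weighted_correlation(matrix(c(0, 1, 0), 3, 4))))  # zero x-variance
  expect_true(is.na(weighted_correlation(matrix(0, 3, 3))))
})

test_that("weighted correlation equals the brute-force evaluation on random matrices", {
  set.seed(7)
  for (k in 1:30) {
    M <- sample(2:8, 1); N <- sample(2:8, 1)
    p <- matrix(rexp(M * N), M, N)
    x <- sort(runif(M, 0, 100)); tt <- sort(runif(N, 0, 1))
    r <- weighted_correlation(p, x, tt)
    expect_equal(r, wcorr_oracle(p, x, tt), tolerance = 1e-12)
    expect_true(r >= -1 && r <= 1)
  }
  # the batched form agrees with the scalar form
  p <- matrix(rexp(6 * 4), 6, 4)
  x <- 1:6; tt <- 1:4
  big <- cbind(p, 2 * p, p[, 4:1])
  rb <- replaykit:::wcorr_blocks(big, x, tt, 4, 3)
  expect_equal(rb, c(weighted_correlation(p, x, tt),
                     weighted_correlation(p, x, tt),
                     weighted_correlation(p[, 4:1], x, tt)), tolerance = 1e-12)
})

flat_speed <- function(end, v = 0) list(time_s = seq(0, end, by = 0.04),
                                        speed_cms = rep(v, length(seq(0, end, by = 0.04))))

mua_from_z <- function(z, fs = 1000) {
  structure(list(start_s = 0, fs = fs, z = z, rate_hz = 1), class = "rk_mua")
}

test_that("candidate detection thresholds, merges and filters events", {
  cfg <- analysis_config()
  n <- 5000
  flat <- mua_from_z(rep(0, n) - 0.1)
  rz <- list(time_s = (seq_len(n) - 1) / 1000, z = rep(5, n))
  spikes <- poisson_spikes(1:10, 0, 5, 20)
  expect_equal(nrow(detect_candidates(spikes, flat, rz, flat_speed(5),
                                      list(start = 0, end = 5), cfg)), 0)

  # two bursts 40 ms apart -> one merged event
  z <- rep(-0.1, n)
  z[2000:2120] <- 5
  z[2160:2280] <- 5
  cands <- detect_candidates(spikes, mua_from_z(z), rz, flat_speed(5),
                             list(start = 0, end = 5), cfg)
  expect_equal(nrow(cands), 1)
  expect_lt(cands$start_s, 2.01)
  expect_gt(cands$end_s, 2.27)

  # same bursts 200 ms apart stay separate events
  z2 <- rep(-0.1, n)
  z2[2000:2120] <- 5
  z2[2320:2440] <- 5
  cands2 <- detect_candidates(spikes, mua_from_z(z2), rz, flat_speed(5),
                              list(start = 0, end = 5), cfg)
  expect_equal(nrow(cands2), 2)

  # a burst core longer than 300 ms is discarded
  z3 <- rep(-0.1, n); z3[2000:2400] <- 5
  expect_equal(nrow(detect_candidates(spikes, mua_from_z(z3), rz, flat_speed(5),
                                      list(start = 0, end = 5), cfg)), 0)
  # ripple gate: no ripple power -> no events
  rz0 <- list(time_s = rz$time_s, z = rep(0, n))
  expect_equal(nrow(detect_candidates(spikes, mua_from_z(z), rz0, flat_speed(5),
                                      list(start = 0, end = 5), cfg)), 0)
  # speed filter: events during movement are excluded
  expect_equal(nrow(detect_candidates(spikes, mua_from_z(z), rz, flat_speed(5, 12),
                                      list(start = 0, end = 5), cfg)), 0)
  # unit filter: fewer than 5 active units
  sp4 <- poisson_spikes(1:4, 0, 5, 20)
  expect_equal(nrow(detect_candidates(sp4, mua_from_z(z), rz, flat_speed(5),
                                      list(start = 0, end = 5), cfg)), 0)
})

test_that("track assignment follows significance and the bias rule", {
  cfg <- analysis_config()
  sc <- function(s1, s2, bias) {
    structure(list(scored = TRUE, n_bins = 10, bias = bias,
                   track1 = list(r = 0.8, significant = s1),
                   track2 = list(r = 0.5, significant = s2)),
              class = "rk_replay_score")
  }
  expect_equal(assign_track(sc(TRUE, FALSE, 0.9), cfg)$track_id, 1L)
  expect_equal(assign_track(sc(FALSE, TRUE, 0.1), cfg)$track_id, 2L)
  expect_equal(assign_track(sc(FALSE, FALSE, 0.9), cfg)$status, "not_significant")
  multi <- assign_track(sc(TRUE, TRUE, 0.55), cfg)
  expect_equal(multi$status, "multi_track_discarded")
  expect_equal(assign_track(sc(TRUE, TRUE, 0.61), cfg)$track_id, 1L)
  expect_equal(assign_track(sc(TRUE, TRUE, 0.39), cfg)$track_id, 2L)
  ns <- assign_track(structure(list(scored = FALSE, n_bins = 3),
                               class = "rk_replay_score"), cfg)
  expect_equal(ns$status, "not_scored")
})

test_that("an injected compressed sequence is significant for its source track only", {
  ss <- small_session()
  maps <- small_decode_maps(1)
  cfg <- analysis_config(n_shuffles = 300)
  centers <- ss$truth$field_centers[, 1]
  uid <- rownames(maps[["1"]]$rate)
  on1 <- as.integer(uid)[!is.na(centers[as.integer(uid)])]
  ord <- on1[order(centers[on1])]
  t0 <- 1e5   # outside the session; spikes table is local to this test
  times <- t0 + seq(0.01, 0.29, length.out = length(ord))
  spikes <- data.frame(unit_id = rep(ord, each = 3),
                       time_s = rep(times, each = 3) + c(-0.004, 0, 0.004))
  spikes <- spikes[order(spikes$unit_id, spikes$time_s), ]
  sc <- score_significance(spikes, list(start_s = t0, end_s = t0 + 0.3),
                           maps, cfg, seed = 99)
  expect_true(sc$scored)
  expect_true(sc$track1$significant)
  expect_false(sc$track2$significant)
  expect_gt(sc$bias, 0.6)
  expect_gt(abs(sc$track1$r), 0.7)
  asg <- assign_track(sc, cfg)
  expect_equal(asg$track_id, 1L)

  # too few 20-ms bins -> not scored
  short <- score_significance(spikes, list(start_s = t0, end_s = t0 + 0.08),
                              maps, cfg, seed = 99)
  expect_false(short$scored)
})

test_that("event splitting uses the mid-third MUA trough and respects half criteria", {
  maps <- small_decode_maps(1)
  cfg <- analysis_config(n_shuffles = 50)
  # flat MUA -> midpoint at the event centre
  z <- rep(0.5, 2000)
  mua <- mua_from_z(z)
  ev <- data.frame(start_s = 0.5, end_s = 1.3)
  spikes <- poisson_spikes(as.integer(rownames(maps[["1"]]$rate)), 0.4, 1.4, 8)
  halves <- split_event(spikes, ev, mua, maps, cfg, seed = 1)
  if (length(halves)) {
    for (h in halves) {
      expect_true(abs(h$start_s - 0.9) < 0.05 || abs(h$end_s - 0.9) < 0.05)
      expect_gte(h$end_s - h$start_s, cfg$event_min_dur_s)
    }
  }
  # both halves under 100 ms -> no split emitted
  ev2 <- data.frame(start_s = 0.5, end_s = 0.65)
  expect_length(split_event(spikes, ev2, mua, maps, cfg, seed = 1), 0)
})

test_that("state labels distinguish sleep, rest and local/remote awake replay", {
  epochs <- data.frame(label = c("PRE", "RUN1_T1", "POST1"),
                       start_s = c(0, 100, 200), end_s = c(100, 200, 400))
  mask <- data.frame(bin_start_s = c(200, 260, 320), bin_end_s = c(260, 320, 380),
                     sleep = c(TRUE, FALSE, TRUE))
  masks <- list(POST1 = mask)
  expect_equal(label_state(210, 1L, epochs, masks), "sleep")
  expect_equal(label_state(270, 1L, epochs, masks), "rest")
  expect_equal(label_state(150, 1L, epochs, masks), "awake-local")
  expect_equal(label_state(150, 2L, epochs, masks), "awake-remote")
  expect_error(label_state(500, 1L, epochs, masks), "outside any epoch")
})

test_that("decoding-free SWR classification uses the selective-cell margin", {
  roster <- data.frame(unit_id = 1:20,
                       principal = TRUE,
                       place_t1 = c(rep(TRUE, 8), rep(FALSE, 8), rep(TRUE, 4)),
                       place_t2 = c(rep(FALSE, 8), rep(TRUE, 8), rep(TRUE, 4)))
  epochs <- data.frame(label = c("PRE", "RUN1_T1", "POST1"),
                       start_s = c(0, 100, 200), end_s = c(100, 200, 400))
  mk_ev <- function(units, t) data.frame(start_s = t, end_s = t + 0.2,
                                         units = I(list(units)))
  ev <- rbind(mk_ev(1:6, 210),          # 75% of T1-selective, 0% of T2
              mk_ev(9:14, 220),         # the reverse
              mk_ev(c(1:4, 9:12, 17), 230))  # 50% vs 50% -> unlabeled
  spikes <- data.frame(unit_id = 17, time_s = c(210.1, 230.1))
  out <- classify_swr_by_selective_cells(ev, roster, spikes, epochs)
  expect_equal(out$event_labels, c(1L, 2L, NA))

  # margin rule: proportions 0.5 vs 0.4 is below the 20-point margin
  ev2 <- mk_ev(c(1:4, 9:11, 20), 240)   # 4/8 vs 3/8
  out2 <- classify_swr_by_selective_cells(ev2, roster, spikes, epochs)
  expect_true(is.na(out2$event_labels))

  # events built from one track's cells are labelled >= 90% correctly
  set.seed(11)
  evs <- do.call(rbind, lapply(1:30, function(i) {
    tr <- sample(1:2, 1)
    pool <- if (tr == 1) 1:8 else 9:16
    mk_ev(c(sample(pool, 5), sample(17:20, 2)), 200 + i)
  }))
  truth <- vapply(evs$units, function(u) if (min(u) <= 8) 1L else 2L, 1L)
  out3 <- classify_swr_by_selective_cells(evs, roster, spikes, epochs)
  ok <- !is.na(out3$event_labels)
  expect_gt(mean(ok), 0.8)
  expect_gte(mean(out3$event_labels[ok] == truth[ok]), 0.9)
})
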