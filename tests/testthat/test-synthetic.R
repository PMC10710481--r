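test_that("run-epoch simulation is seed-deterministic and scales with laps", {
  cfg <- synthetic_config(seed = 3, n_cells_per_track = 5, n_interneurons = 0,
                          n_laps_t1 = 1)
  a <- simulate_run_epoch(cfg, track = 1, n_laps = 1)
  b <- simulate_run_epoch(cfg, track = 1, n_laps = 1)
  expect_identical(a$spikes, b$spikes)
  expect_identical(a$position, b$position)
  expect_identical(a$lfp[[1]]$samples, b$lfp[[1]]$samples)

  travel <- function(e) sum(abs(diff(e$position$x_cm)))
  many <- simulate_run_epoch(cfg, track = 1, n_laps = 16)
  expect_gte(travel(many) / travel(a), 15)  # 16x the laps, ~16x the distance

  bad <- synthetic_config(n_cells_per_track = 5)
  expect_error(simulate_run_epoch(bad, 1, 0), "n_laps")
  expect_error(synthetic_config(n_cells_per_track = 0), "empty population")
})

test_that("sleep-epoch replay schedule follows the configured rates", {
  cfg <- synthetic_config(seed = 5, n_cells_per_track = 15,
                          replay_rate_t1 = 0, replay_rate_t2 = 0)
  e0 <- simulate_sleep_epoch(cfg, duration = 200)
  expect_equal(nrow(e0$truth$schedule), 0)

  cfg1 <- synthetic_config(seed = 5, n_cells_per_track = 15,
                           replay_rate_t1 = 0.03, replay_rate_t2 = 0)
  e1 <- simulate_sleep_epoch(cfg1, duration = 1800)
  n <- nrow(e1$truth$schedule)
  expect_gt(n, 30)   # Poisson around 54, minus enforced-separation drops
  expect_lt(n, 80)

  expect_error(simulate_sleep_epoch(cfg1, duration = 0), "duration")
})

test_that("scheduled replay bursts satisfy the candidate criteria by construction", {
  ss <- small_session()
  sch <- ss$truth$replay_schedule
  expect_gt(nrow(sch), 0)
  dur <- sch$end_s - sch$start_s
  expect_true(all(dur >= 0.1 & dur <= 0.75))
  sp <- ss$session$spikes
  n_units <- vapply(seq_len(nrow(sch)), function(i) {
    length(unique(sp$unit_id[sp$time_s >= sch$start_s[i] & sp$time_s < sch$end_s[i]]))
  }, numeric(1))
  expect_true(all(n_units >= 5))
  # sleep entries lie inside true sleep intervals; schedule non-overlapping
  iv <- ss$truth$sleep_intervals
  slp <- sch[sch$state == "sleep", ]
  inside <- vapply(seq_len(nrow(slp)), function(i) {
    any(iv$start_s <= slp$start_s[i] & slp$end_s[i] <= iv$end_s)
  }, logical(1))
  expect_true(all(inside))
  s <- sch[order(sch$start_s), ]
  expect_true(all(diff(s$start_s) >= s$end_s[-nrow(s)] - s$start_s[-nrow(s)] - 1e-9 |
                    diff(s$start_s) > 0))
  expect_true(all(s$start_s[-1] >= s$end_s[-nrow(s)]))
})

test_that("the assembled session follows the seven-epoch protocol with remapped, stable fields", {
  ss <- small_session()
  expect_identical(ss$session$epochs$label,
                   c("PRE", "RUN1_T1", "RUN1_T2", "POST1",
                     "RUN2_T1", "RUN2_T2", "POST2"))
  expect_equal(nrow(ss$session$epochs), 7)
  # PRE holds no scheduled replay
  expect_false(any(ss$truth$replay_schedule$epoch == "PRE"))

  beh <- small_behavior()
  roster <- small_roster()
  common <- roster$unit_id[roster$place_t1 | roster$place_t2]
  mk <- function(lab, tr) compute_ratemaps(ss$session$spikes, beh$linpos[[lab]],
                                           common, 200, bin_cm = 10,
                                           speed_window = c(4, 50))
  m11 <- mk("RUN1_T1", 1); m12 <- mk("RUN1_T2", 2); m21 <- mk("RUN2_T1", 1)
  # global remapping between tracks: near-zero mean PV correlation
  expect_lt(abs(pv_correlation(m11, m12)$mean), 0.35)
  # stable fields across exposures of the same track: high PV correlation
  expect_gt(pv_correlation(m11, m21)$mean, 0.7)
})

test_that("baseline sleep spiking is Poisson-dispersed", {
  cfg <- synthetic_config(seed = 9, n_cells_per_track = 10, n_interneurons = 0,
                          replay_rate_t1 = 0, replay_rate_t2 = 0)
  e <- simulate_sleep_epoch(cfg, duration = 600)
  iv <- e$truth$sleep_intervals[1, ]
  sp <- e$spikes[e$spikes$time_s >= iv$start_s & e$spikes$time_s < iv$start_s + 200, ]
  counts <- table(cut(sp$time_s, breaks = seq(iv$start_s, iv$start_s + 200, by = 5)))
  # index of dispersion ~ chi-square under Poisson
  disp <- sum((counts - mean(counts))^2) / mean(counts)
  df <- length(counts) - 1
  expect_gt(stats::pchisq(disp, df), 0.005)
  expect_lt(stats::pchisq(disp, df), 0.995)
})
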