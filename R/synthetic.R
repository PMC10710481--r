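#' Configuration for the synthetic two-track session generator
#'
#' The generator emulates the statistical structure the analysis pipeline
#' assumes: two linear tracks with globally remapped, stable place fields;
#' lap-structured running with theta-modulated, phase-precessing place-cell
#' spiking; rest/sleep epochs with ripple-band bursts carrying time-compressed
#' replay sequences; and multi-unit activity with burst structure. All
#' randomness flows from one integer seed; per-epoch streams are derived by
#' fixed offsets, so a fixed config yields a byte-identical session.
#'
#' @param seed integer RNG seed.
#' @param n_cells_per_track place cells with a field on each track; a
#'   fraction `dual_frac` of them carry fields on both tracks.
#' @param dual_frac fraction of each track's cells that are dual-track.
#' @param n_interneurons narrow-waveform, high-rate units (excluded by the
#'   principal-cell classifier but contributing to multi-unit activity).
#' @param track_length cm (default 200).
#' @param n_laps_t1,n_laps_t2 laps run on each track during the first
#'   exposure (defaults 16 and 4).
#' @param run_speed_mean,run_speed_sd traversal speed distribution (cm/s).
#' @param pause_mean_s mean reward pause at each track end (s); pauses host
#'   the awake replay events.
#' @param theta_freq theta frequency, Hz (default 8).
#' @param theta_mod_depth depth of theta modulation of in-field firing (0-1:
#'   mixture weight of the phase-tuned component).
#' @param theta_phase_conc von Mises concentration of the phase tuning;
#'   higher values give tighter phase locking and stronger theta sequences.
#' @param peak_rate in-field peak firing rate, Hz.
#' @param field_width Gaussian place-field s.d., cm.
#' @param noise_rate baseline Poisson rate per unit on the track, Hz.
#' @param sleep_base_rate,restbox_awake_rate baseline unit rates (Hz) during
#'   rest-box sleep and awake bouts.
#' @param interneuron_rate constant rate of interneuron units, Hz.
#' @param pre_duration true-sleep seconds in the PRE epoch.
#' @param sleep_duration true-sleep seconds in each POST epoch.
#' @param run2_duration approximate duration of each re-exposure epoch (s);
#'   converted into a lap count.
#' @param replay_rate_t1,replay_rate_t2 sleep replay rates (events per second
#'   of true sleep) embedded in the POST epochs.
#' @param awake_replay_rate awake replay rate (events per second of reward
#'   pause) on the tracks.
#' @param remote_frac proportion of awake replay drawn from the other track.
#' @param forward_frac proportion of forward (vs reverse) replay.
#' @param replay_compression ratio of virtual replay speed to running speed.
#' @param replay_spike_jitter_s s.d. of spike-time jitter inside a replay burst.
#' @param lfp_sample_rate Hz (default 1000).
#' @param position_sample_rate Hz (default 25, matching 25-fps tracking).
#' @param n_lfp_channels number of synthesized LFP channels (>= 1).
#' @return object of class `rk_synth_config`.
#' @export
synthetic_config <- function(seed = 1L,
                             n_cells_per_track = 50,
                             dual_frac = 0.3,
                             n_interneurons = 5,
                             track_length = 200,
                             n_laps_t1 = 16,
                             n_laps_t2 = 4,
                             run_speed_mean = 20,
                             run_speed_sd = 2,
                             pause_mean_s = 8,
                             theta_freq = 8,
                             theta_mod_depth = 0.8,
                             theta_phase_conc = 4,
                             peak_rate = 15,
                             field_width = 15,
                             noise_rate = 0.1,
                             sleep_base_rate = 0.6,
                             restbox_awake_rate = 0.25,
                             interneuron_rate = 8,
                             pre_duration = 300,
                             sleep_duration = 1800,
                             run2_duration = 900,
                             replay_rate_t1 = 0.03,
                             replay_rate_t2 = 0.02,
                             awake_replay_rate = 0.1,
                             remote_frac = 0.1,
                             forward_frac = 0.7,
                             replay_compression = 20,
                             replay_spike_jitter_s = 0.008,
                             lfp_sample_rate = 1000,
                             position_sample_rate = 25,
                             n_lfp_channels = 2) {
  cfg <- as.list(environment())
  rates <- c("run_speed_mean", "theta_freq", "peak_rate", "noise_rate",
             "sleep_base_rate", "restbox_awake_rate", "interneuron_rate",
             "replay_rate_t1", "replay_rate_t2", "awake_replay_rate",
             "lfp_sample_rate", "position_sample_rate")
  for (k in rates) if (cfg[[k]] < 0) stop("'", k, "' must be >= 0")
  if (cfg$n_laps_t1 < 1 || cfg$n_laps_t2 < 1) stop("lap counts must be >= 1")
  if (cfg$n_cells_per_track < 1) stop("empty population")
  structure(cfg, class = "rk_synth_config")
}

mix_seed <- function(seed, stream) {
  as.integer((abs(as.numeric(seed)) * 1009 + stream * 9176 + 17) %% 2147483647)
}

# Unit population shared by all epochs. Units 1..n1 have track-1 fields,
# the last n1 of the place cells have track-2 fields, the overlap is dual.
draw_population <- function(cfg) {
  n1 <- cfg$n_cells_per_track
  n_dual <- round(cfg$dual_frac * n1)
  n_place <- 2L * n1 - n_dual
  L <- cfg$track_length
  centers <- matrix(NA_real_, nrow = n_place + cfg$n_interneurons, ncol = 2)
  t1_units <- seq_len(n1)
  t2_units <- seq.int(n_place - n1 + 1L, n_place)
  centers[t1_units, 1] <- runif(n1, 5, L - 5)
  centers[t2_units, 2] <- runif(n1, 5, L - 5)
  hwhm <- c(pmax(550, rnorm(n_place, 750, 80)),
            if (cfg$n_interneurons > 0) pmax(200, rnorm(cfg$n_interneurons, 350, 30)))
  list(n_units = n_place + cfg$n_interneurons,
       n_place = n_place,
       interneurons = if (cfg$n_interneurons > 0) seq.int(n_place + 1L, n_place + cfg$n_interneurons) else integer(0),
       field_centers = centers,
       half_width_us = hwhm)
}

track_geometry <- function(cfg) {
  L <- cfg$track_length
  data.frame(track_id = c(1L, 2L), length_cm = c(L, L),
             x0 = c(0, 0), y0 = c(0, 100), x1 = c(L, L), y1 = c(0, 100))
}
# rest box centre, well off both tracks
restbox_center <- function(cfg) c(cfg$track_length / 2, 200)

# Piecewise-linear lap profile: pause, out, pause, back, pause, ...
# Returns keypoints (t, x, moving) plus lap and pause tables.
build_run_profile <- function(cfg, n_laps, t0) {
  v <- pmin(40, pmax(8, rnorm(2 * n_laps, cfg$run_speed_mean, cfg$run_speed_sd)))
  pauses <- cfg$pause_mean_s * runif(2 * n_laps + 1, 0.7, 1.3)
  L <- cfg$track_length
  t <- t0; kp_t <- t; kp_x <- 0; kp_m <- FALSE
  lap_start <- lap_end <- numeric(n_laps)
  pause_start <- pause_end <- numeric(2 * n_laps + 1)
  pause_start[1] <- t; t <- t + pauses[1]; pause_end[1] <- t
  kp_t <- c(kp_t, t); kp_x <- c(kp_x, 0); kp_m <- c(kp_m, FALSE)
  for (lap in seq_len(n_laps)) {
    lap_start[lap] <- t
    t <- t + L / v[2 * lap - 1]                        # outbound
    kp_t <- c(kp_t, t); kp_x <- c(kp_x, L); kp_m <- c(kp_m, TRUE)
    pause_start[2 * lap] <- t; t <- t + pauses[2 * lap]; pause_end[2 * lap] <- t
    kp_t <- c(kp_t, t); kp_x <- c(kp_x, L); kp_m <- c(kp_m, FALSE)
    t <- t + L / v[2 * lap]                            # inbound
    lap_end[lap] <- t
    kp_t <- c(kp_t, t); kp_x <- c(kp_x, 0); kp_m <- c(kp_m, TRUE)
    pause_start[2 * lap + 1] <- t; t <- t + pauses[2 * lap + 1]; pause_end[2 * lap + 1] <- t
    kp_t <- c(kp_t, t); kp_x <- c(kp_x, 0); kp_m <- c(kp_m, FALSE)
  }
  list(kp = data.frame(t = kp_t, x = kp_x),
       t_end = t,
       laps = data.frame(lap = seq_len(n_laps), start_s = lap_start, end_s = lap_end),
       pauses = data.frame(start_s = pause_start, end_s = pause_end))
}

lin_at <- function(profile, times) stats::approx(profile$kp$t, profile$kp$x, xout = times, rule = 2)$y

# Linear position -> 2-D coordinates on a track segment.
track_xy <- function(tracks, track_id, lin) {
  g <- tracks[tracks$track_id == track_id, ]
  f <- lin / g$length_cm
  cbind(g$x0 + f * (g$x1 - g$x0), g$y0 + f * (g$y1 - g$y0))
}

# Compressed replay burst: units fire in field order along a virtual
# trajectory. Returns spikes plus the trajectory span; NULL if the track has
# too few cells on any span (never at default densities).
make_replay_burst <- function(t_start, dur, centers, L, direction, vspeed, jitter,
                              min_units = 5) {
  span <- min(vspeed * dur, L)
  for (try in 1:10) {
    if (direction > 0) {
      xs <- runif(1, 0, L - span); xe <- xs + span
    } else {
      xs <- runif(1, span, L); xe <- xs - span
    }
    on_path <- which(!is.na(centers) & centers >= min(xs, xe) & centers <= max(xs, xe))
    if (length(on_path) >= min_units) break
  }
  if (length(on_path) < min_units) return(NULL)
  pass <- t_start + abs(centers[on_path] - xs) / vspeed
  n_spk <- 1 + rpois(length(on_path), 2)
  times <- rep(pass, n_spk) + rnorm(sum(n_spk), 0, jitter)
  times <- pmin(pmax(times, t_start), t_start + dur - 1e-4)
  list(spikes = data.frame(unit_id = rep(on_path, n_spk), time_s = times),
       x_start = xs, x_end = xe)
}

# 1/f ("pink") background noise via spectral shaping, unit variance.
pink_noise <- function(n) {
  m <- stats::nextn(n, c(2, 3, 5))
  X <- stats::fft(rnorm(m))
  f <- c(1, seq_len(m - 1))
  f <- pmin(f, m - f + 1)  # two-sided frequency index
  x <- Re(stats::fft(X / sqrt(f), inverse = TRUE))[seq_len(n)] / m
  x / stats::sd(x)
}

# Band-limited noise burst with Gaussian envelope, for ripple events.
ripple_burst <- function(n, fs, band = c(150, 250)) {
  wn <- rnorm(n + 200)
  bf <- signal::butter(2, band / (fs / 2), type = "pass")
  x <- signal::filtfilt(bf, wn)[101:(100 + n)]
  env <- exp(-0.5 * ((seq_len(n) - n / 2) / (n / 6))^2)
  x <- x / stats::sd(x) * env
  x
}

# Assemble LFP channels for one epoch from a shared event list.
# theta_amp / delta_amp are vectors over samples (already masked).
build_lfp <- function(cfg, t0, t_end, theta_amp, delta_amp, events) {
  fs <- cfg$lfp_sample_rate
  n <- round((t_end - t0) * fs)
  tt <- t0 + (seq_len(n) - 1) / fs
  nch <- max(1L, cfg$n_lfp_channels)
  theta_gain <- c(1.0, 0.3, rep(0.6, max(0, nch - 2)))
  ripple_gain <- c(0.4, 1.0, rep(0.6, max(0, nch - 2)))
  ripple_track <- numeric(n)
  if (NROW(events)) {
    for (i in seq_len(NROW(events))) {
      i0 <- max(1L, floor((events$start_s[i] - t0) * fs) + 1L)
      i1 <- min(n, ceiling((events$end_s[i] - t0) * fs))
      if (i1 > i0 + 10) {
        ripple_track[i0:i1] <- ripple_track[i0:i1] + ripple_burst(i1 - i0 + 1L, fs)
      }
    }
  }
  theta_wave <- cos(2 * pi * cfg$theta_freq * tt)
  delta_wave <- cos(2 * pi * 2.0 * tt)
  lapply(seq_len(nch), function(ch) {
    base <- 20 * pink_noise(n)
    band_sd <- stats::sd(band_filter(base[seq_len(min(n, 20000))], fs, c(125, 300)))
    sig <- base +
      theta_gain[ch] * theta_amp * theta_wave +
      theta_gain[ch] * delta_amp * delta_wave +
      ripple_gain[ch] * 8 * band_sd * ripple_track
    list(channel_id = ch, fs = fs, start_s = t0, samples = sig)
  })
}

# Inhomogeneous-Poisson place-cell spikes for a run epoch, via thinning.
run_spikes <- function(cfg, pop, track_id, profile, t0, t_end) {
  L <- cfg$track_length
  f <- cfg$theta_freq
  depth <- cfg$theta_mod_depth
  w <- cfg$field_width
  kp <- profile$kp
  dur <- t_end - t0
  out <- vector("list", pop$n_units)
  for (u in seq_len(pop$n_units)) {
    if (u %in% pop$interneurons) {
      nmax <- rpois(1, cfg$interneuron_rate * dur)
      out[[u]] <- data.frame(unit_id = u, time_s = sort(runif(nmax, t0, t_end)))
      next
    }
    cc <- pop$field_centers[u, track_id]
    kap <- cfg$theta_phase_conc
    vm_peak <- 1 / (exp(-kap) * besselI(kap, 0))   # von Mises peak/mean ratio
    rmax <- cfg$noise_rate +
      if (!is.na(cc)) cfg$peak_rate * ((1 - depth) + depth * vm_peak) else 0
    ncand <- rpois(1, rmax * dur * 1.02)
    if (ncand == 0) { out[[u]] <- NULL; next }
    tc <- sort(runif(ncand, t0, t_end))
    lam <- rep(cfg$noise_rate, ncand)
    if (!is.na(cc)) {
      x <- lin_at(profile, tc)
      dirn <- sign(lin_at(profile, tc + 0.04) - lin_at(profile, tc - 0.04))
      spd <- abs(lin_at(profile, tc + 0.2) - lin_at(profile, tc - 0.2)) / 0.4
      moving <- spd > 4
      G <- exp(-0.5 * ((x - cc) / w)^2)
      # linear phase-position coupling within the field (phase precession);
      # the sweep runs behind-to-ahead within each trough-to-trough cycle
      d <- pmax(-1, pmin(1, (x - cc) * dirn / (2 * w)))
      psi <- pi * (2 - d)
      phase <- 2 * pi * f * tc
      # unit-mean phase tuning: flat/von-Mises mixture with weight `depth`
      mod <- (1 - depth) + depth * vm_peak * exp(kap * (cos(phase - psi) - 1))
      lam <- lam + ifelse(moving, cfg$peak_rate * G * mod, 0)
    }
    keep <- runif(ncand) < lam / (rmax * 1.0001)
    out[[u]] <- if (any(keep)) data.frame(unit_id = u, time_s = tc[keep]) else NULL
  }
  do.call(rbind, out[!vapply(out, is.null, logical(1))])
}

#' Simulate one run epoch on a linear track
#'
#' Lap-structured back-and-forth running with reward pauses at the track
#' ends, theta-modulated phase-precessing place-cell spiking, a theta-band
#' LFP during movement, and awake replay bursts (with ripple-band LFP
#' transients) injected during the immobility pauses.
#'
#' @param config an [synthetic_config()].
#' @param track track id (1 or 2).
#' @param n_laps number of out-and-back laps (>= 1).
#' @param population optional unit population (internal; drawn from the
#'   config seed when omitted so the epoch is self-contained).
#' @param t0 epoch start time (s).
#' @param stream RNG sub-stream index (fixed offsets per epoch).
#' @return list with `position` (time_s, x_cm, y_cm), `spikes`, `lfp`,
#'   `t_end`, and `truth` (lap table + awake replay schedule fragment).
#' @export
simulate_run_epoch <- function(config, track, n_laps, population = NULL,
                               t0 = 0, stream = 2L) {
  set.seed(mix_seed(config$seed, stream))
  if (config$n_cells_per_track < 1) stop("empty population")
  if (n_laps < 1) stop("n_laps must be >= 1")
  if (is.null(population)) population <- draw_population(config)
  tracks <- track_geometry(config)
  profile <- build_run_profile(config, n_laps, t0)
  t_end <- profile$t_end
  L <- config$track_length

  # position samples: on-track profile plus small tracking noise
  pt <- seq(t0, t_end - 1e-9, by = 1 / config$position_sample_rate)
  lin <- lin_at(profile, pt)
  xy <- track_xy(tracks, track, lin)
  position <- data.frame(time_s = pt,
                         x_cm = xy[, 1] + rnorm(length(pt), 0, 0.3),
                         y_cm = xy[, 2] + rnorm(length(pt), 0, 0.3))

  spikes <- run_spikes(config, population, track, profile, t0, t_end)

  # awake replay during reward pauses
  vspeed <- config$run_speed_mean * config$replay_compression
  sched <- list()
  pauses <- profile$pauses
  for (p in seq_len(nrow(pauses))) {
    len <- pauses$end_s[p] - pauses$start_s[p]
    usable <- len - 1.2
    if (usable <= 0.5) next
    k <- rpois(1, config$awake_replay_rate * usable)
    if (k == 0) next
    starts <- sort(runif(k, pauses$start_s[p] + 0.4, pauses$end_s[p] - 0.8))
    starts <- starts[c(TRUE, diff(starts) > 0.9)]
    for (s in starts) {
      dur <- runif(1, 0.15, 0.35)
      ev_track <- if (runif(1) < config$remote_frac) 3L - track else track
      dirn <- if (runif(1) < config$forward_frac) 1 else -1
      b <- make_replay_burst(s, dur, population$field_centers[, ev_track], L,
                             dirn, vspeed, config$replay_spike_jitter_s)
      if (is.null(b)) next
      spikes <- rbind(spikes, b$spikes)
      sched[[length(sched) + 1]] <- data.frame(
        start_s = s, end_s = s + dur, track_id = ev_track,
        direction = dirn, x_start = b$x_start, x_end = b$x_end,
        state = "awake", stringsAsFactors = FALSE)
    }
  }
  schedule <- if (length(sched)) do.call(rbind, sched) else
    data.frame(start_s = numeric(0), end_s = numeric(0), track_id = integer(0),
               direction = numeric(0), x_start = numeric(0), x_end = numeric(0),
               state = character(0))

  # LFP: theta while moving, ripple transients at awake replay events
  fs <- config$lfp_sample_rate
  nlf <- round((t_end - t0) * fs)
  lt <- t0 + (seq_len(nlf) - 1) / fs
  spd <- abs(lin_at(profile, lt + 0.2) - lin_at(profile, lt - 0.2)) / 0.4
  theta_amp <- 40 * moving_average(as.numeric(spd > 4), fs)
  lfp <- build_lfp(config, t0, t_end, theta_amp, numeric(nlf), schedule)

  spikes <- spikes[order(spikes$unit_id, spikes$time_s), ]
  rownames(spikes) <- NULL
  laps <- profile$laps
  laps$track_id <- track
  list(position = position, spikes = spikes, lfp = lfp, t_end = t_end,
       truth = list(laps = laps, schedule = schedule,
                    pauses = profile$pauses))
}

#' Simulate a rest-box sleep epoch with embedded replay
#'
#' Alternating awake and putative-sleep bouts in the rest box. Sleep bouts
#' carry elevated baseline spiking, delta-band LFP, and scheduled
#' time-compressed replay bursts (each 150-350 ms, >= 5 units, with a
#' coincident ripple-band LFP transient); awake bouts have low multi-unit
#' activity, gentle movement, and theta-band LFP. Replay events are placed
#' only inside true sleep bouts and never overlap.
#'
#' @param config an [synthetic_config()].
#' @param population unit population (drawn from the seed when omitted).
#' @param duration target seconds of true sleep (> 0); the epoch itself is
#'   longer by the interleaved awake bouts.
#' @param rates length-2 vector of replay rates (events per second of true
#'   sleep) for tracks 1 and 2.
#' @param t0 epoch start time (s).
#' @param stream RNG sub-stream index.
#' @return list with `position`, `spikes`, `lfp`, `t_end`, and `truth`
#'   (replay schedule + true sleep intervals).
#' @export
simulate_sleep_epoch <- function(config, population = NULL, duration = config$sleep_duration,
                                 rates = c(config$replay_rate_t1, config$replay_rate_t2),
                                 t0 = 0, stream = 4L) {
  if (duration <= 0) stop("duration must be > 0")
  set.seed(mix_seed(config$seed, stream))
  if (is.null(population)) population <- draw_population(config)
  L <- config$track_length

  # bout structure: awake 1-2 min alternating with sleep 4-8 min; bout
  # lengths are whole minutes so the 1-min sleep-mask grid can resolve them
  sleep_left <- duration
  t <- t0
  bouts <- list()
  bouts[[1]] <- data.frame(start_s = t, end_s = t + 60, sleep = FALSE)
  t <- bouts[[1]]$end_s
  while (sleep_left > 0) {
    d <- min(sleep_left, 60 * sample(4:8, 1))
    bouts[[length(bouts) + 1]] <- data.frame(start_s = t, end_s = t + d, sleep = TRUE)
    t <- t + d
    sleep_left <- sleep_left - d
    if (sleep_left > 0) {
      d <- 60 * sample(1:2, 1)
      bouts[[length(bouts) + 1]] <- data.frame(start_s = t, end_s = t + d, sleep = FALSE)
      t <- t + d
    }
  }
  bouts <- do.call(rbind, bouts)
  t_end <- t
  sleep_iv <- bouts[bouts$sleep, c("start_s", "end_s")]

  # replay schedule: Poisson per track over true sleep time, non-overlapping
  sched <- list()
  sleep_len <- sleep_iv$end_s - sleep_iv$start_s
  cum0 <- cumsum(c(0, head(sleep_len, -1)))
  map_to_abs <- function(u) {  # u in [0, duration) on the cumulative-sleep axis
    i <- findInterval(u, cum0)
    sleep_iv$start_s[i] + (u - cum0[i])
  }
  for (tr in 1:2) {
    k <- rpois(1, rates[tr] * duration)
    if (k == 0) next
    for (i in seq_len(k)) {
      s <- map_to_abs(runif(1, 0, duration - 0.5))
      dur <- runif(1, 0.15, 0.35)
      dirn <- if (runif(1) < config$forward_frac) 1 else -1
      sched[[length(sched) + 1]] <- data.frame(
        start_s = s, end_s = s + dur, track_id = tr, direction = dirn,
        x_start = NA_real_, x_end = NA_real_, state = "sleep")
    }
  }
  schedule <- if (length(sched)) do.call(rbind, sched) else
    data.frame(start_s = numeric(0), end_s = numeric(0), track_id = integer(0),
               direction = numeric(0), x_start = numeric(0), x_end = numeric(0),
               state = character(0))
  if (nrow(schedule)) {
    schedule <- schedule[order(schedule$start_s), ]
    keep <- c(TRUE, diff(schedule$start_s) > 0.9)  # enforce separation
    schedule <- schedule[keep, ]
    rownames(schedule) <- NULL
  }

  # baseline spiking per bout, plus replay bursts
  vspeed <- config$run_speed_mean * config$replay_compression
  out <- vector("list", nrow(bouts) + nrow(schedule))
  idx <- 1L
  for (b in seq_len(nrow(bouts))) {
    base <- if (bouts$sleep[b]) config$sleep_base_rate else config$restbox_awake_rate
    len <- bouts$end_s[b] - bouts$start_s[b]
    for (u in seq_len(population$n_units)) {
      # interneurons track population state: halved rate in quiet waking
      r <- if (u %in% population$interneurons) {
        config$interneuron_rate * (if (bouts$sleep[b]) 1 else 0.5)
      } else base
      nspk <- rpois(1, r * len)
      if (nspk > 0) {
        out[[idx]] <- data.frame(unit_id = u,
                                 time_s = runif(nspk, bouts$start_s[b], bouts$end_s[b]))
        idx <- idx + 1L
      }
    }
  }
  keep_ev <- rep(TRUE, nrow(schedule))
  if (nrow(schedule)) {
    for (i in seq_len(nrow(schedule))) {
      b <- make_replay_burst(schedule$start_s[i],
                             schedule$end_s[i] - schedule$start_s[i],
                             population$field_centers[, schedule$track_id[i]],
                             L, schedule$direction[i], vspeed,
                             config$replay_spike_jitter_s)
      if (is.null(b)) { keep_ev[i] <- FALSE; next }
      schedule$x_start[i] <- b$x_start; schedule$x_end[i] <- b$x_end
      out[[idx]] <- b$spikes; idx <- idx + 1L
    }
    schedule <- schedule[keep_ev, ]
  }
  spikes <- do.call(rbind, out[seq_len(idx - 1L)])
  spikes <- spikes[order(spikes$unit_id, spikes$time_s), ]
  rownames(spikes) <- NULL

  # position: Ornstein-Uhlenbeck wander around the rest-box centre; awake
  # bouts move at ~6 cm/s, sleep bouts are nearly still
  ctr <- restbox_center(config)
  pr <- config$position_sample_rate
  pt <- seq(t0, t_end - 1e-9, by = 1 / pr)
  in_sleep <- rep(FALSE, length(pt))
  for (i in seq_len(nrow(sleep_iv))) {
    in_sleep[pt >= sleep_iv$start_s[i] & pt < sleep_iv$end_s[i]] <- TRUE
  }
  # persistent-velocity wander (AR(1) velocity, ~1-s correlation) so quiet
  # waking reads as genuine slow movement, not tracking jitter
  tgt <- ifelse(in_sleep, 0.4, 6) / sqrt(pi / 2)     # per-axis velocity sd
  phi <- exp(-1 / (pr * 1.0))
  sig_v <- tgt * sqrt(1 - phi^2)
  np <- length(pt)
  ex <- rnorm(np) * sig_v; ey <- rnorm(np) * sig_v
  vx <- numeric(np); vy <- numeric(np)
  x <- numeric(np); y <- numeric(np)
  x[1] <- ctr[1]; y[1] <- ctr[2]
  for (i in 2:np) {
    vx[i] <- phi * vx[i - 1] + ex[i]
    vy[i] <- phi * vy[i - 1] + ey[i]
    x[i] <- x[i - 1] + vx[i] / pr - 0.01 * (x[i - 1] - ctr[1])
    y[i] <- y[i - 1] + vy[i] / pr - 0.01 * (y[i - 1] - ctr[2])
  }
  position <- data.frame(time_s = pt, x_cm = x, y_cm = y)

  # LFP: delta during sleep, theta during awake bouts, ripples at replay
  fs <- config$lfp_sample_rate
  nlf <- round((t_end - t0) * fs)
  lt <- t0 + (seq_len(nlf) - 1) / fs
  sl <- rep(FALSE, nlf)
  for (i in seq_len(nrow(sleep_iv))) {
    sl[lt >= sleep_iv$start_s[i] & lt < sleep_iv$end_s[i]] <- TRUE
  }
  delta_amp <- 35 * moving_average(as.numeric(sl), fs)
  theta_amp <- 25 * moving_average(as.numeric(!sl), fs)
  lfp <- build_lfp(config, t0, t_end, theta_amp, delta_amp, schedule)

  list(position = position, spikes = spikes, lfp = lfp, t_end = t_end,
       truth = list(schedule = schedule,
                    sleep_intervals = data.frame(start_s = sleep_iv$start_s,
                                                 end_s = sleep_iv$end_s)))
}

#' Simulate a full two-track session with ground truth
#'
#' Assembles the seven-epoch protocol (PRE, RUN1_T1, RUN1_T2, POST1,
#' RUN2_T1, RUN2_T2, POST2) with independent field maps per track (global
#' remapping) and identical maps across exposures of the same track. The
#' PRE epoch contains no scheduled replay; POST epochs embed sleep replay
#' at the configured per-track rates.
#'
#' @param config an [synthetic_config()].
#' @return list with `session` (an [rk_session()]) and `truth`:
#'   `field_centers` (units x 2 matrix, NA where no field),
#'   `replay_schedule`, `sleep_intervals`, `laps`, `pauses`, `interneurons`.
#' @export
simulate_session <- function(config) {
  set.seed(mix_seed(config$seed, 1L))
  pop <- draw_population(config)
  tracks <- track_geometry(config)
  lap_time <- 2 * config$track_length / config$run_speed_mean + 2 * config$pause_mean_s
  n_laps_run2 <- max(1L, round(config$run2_duration / lap_time))

  pre <- simulate_sleep_epoch(config, pop, duration = config$pre_duration,
                              rates = c(0, 0), t0 = 0, stream = 11L)
  r1t1 <- simulate_run_epoch(config, 1L, config$n_laps_t1, pop, t0 = pre$t_end, stream = 12L)
  r1t2 <- simulate_run_epoch(config, 2L, config$n_laps_t2, pop, t0 = r1t1$t_end, stream = 13L)
  post1 <- simulate_sleep_epoch(config, pop, duration = config$sleep_duration,
                                rates = c(config$replay_rate_t1, config$replay_rate_t2),
                                t0 = r1t2$t_end, stream = 14L)
  r2t1 <- simulate_run_epoch(config, 1L, n_laps_run2, pop, t0 = post1$t_end, stream = 15L)
  r2t2 <- simulate_run_epoch(config, 2L, n_laps_run2, pop, t0 = r2t1$t_end, stream = 16L)
  post2 <- simulate_sleep_epoch(config, pop, duration = config$sleep_duration,
                                rates = c(config$replay_rate_t1, config$replay_rate_t2),
                                t0 = r2t2$t_end, stream = 17L)

  parts <- list(PRE = pre, RUN1_T1 = r1t1, RUN1_T2 = r1t2, POST1 = post1,
                RUN2_T1 = r2t1, RUN2_T2 = r2t2, POST2 = post2)
  starts <- c(0, pre$t_end, r1t1$t_end, r1t2$t_end, post1$t_end, r2t1$t_end, r2t2$t_end)
  ends <- c(pre$t_end, r1t1$t_end, r1t2$t_end, post1$t_end, r2t1$t_end, r2t2$t_end, post2$t_end)
  epochs <- data.frame(label = EPOCH_LABELS, start_s = starts, end_s = ends)

  spikes <- do.call(rbind, lapply(parts, `[[`, "spikes"))
  spikes <- spikes[order(spikes$unit_id, spikes$time_s), ]
  rownames(spikes) <- NULL
  position <- do.call(rbind, lapply(parts, `[[`, "position"))
  rownames(position) <- NULL

  nch <- length(pre$lfp)
  lfp <- lapply(seq_len(nch), function(ch) {
    list(channel_id = ch, fs = config$lfp_sample_rate, start_s = 0,
         samples = unlist(lapply(parts, function(p) p$lfp[[ch]]$samples),
                          use.names = FALSE))
  })

  span <- post2$t_end
  cnt <- table(factor(spikes$unit_id, levels = seq_len(pop$n_units)))
  units <- data.frame(unit_id = seq_len(pop$n_units),
                      half_width_us = pop$half_width_us,
                      mean_rate_hz = as.numeric(cnt) / span)

  session <- rk_session(units = units, spikes = spikes, position = position,
                        lfp = lfp, epochs = epochs, tracks = tracks)

  add_epoch <- function(df, label) { if (NROW(df)) df$epoch <- label; df }
  schedule <- do.call(rbind, c(
    lapply(names(parts), function(nm) {
      sc <- parts[[nm]]$truth$schedule
      add_epoch(sc, nm)
    })))
  sleep_iv <- do.call(rbind, lapply(c("PRE", "POST1", "POST2"), function(nm) {
    add_epoch(parts[[nm]]$truth$sleep_intervals, nm)
  }))
  laps <- do.call(rbind, lapply(c("RUN1_T1", "RUN1_T2", "RUN2_T1", "RUN2_T2"),
                                function(nm) add_epoch(parts[[nm]]$truth$laps, nm)))
  pauses <- do.call(rbind, lapply(c("RUN1_T1", "RUN1_T2", "RUN2_T1", "RUN2_T2"),
                                  function(nm) add_epoch(parts[[nm]]$truth$pauses, nm)))
  rownames(schedule) <- rownames(sleep_iv) <- rownames(laps) <- NULL

  list(session = session,
       truth = list(field_centers = pop$field_centers,
                    interneurons = pop$interneurons,
                    replay_schedule = schedule,
                    sleep_intervals = sleep_iv,
                    laps = laps,
                    pauses = pauses))
}

#' Match detected events to a ground-truth schedule by time overlap
#'
#' @param detected data.frame with `start_s`, `end_s` and optionally
#'   `track_id` columns.
#' @param schedule ground-truth schedule (`start_s`, `end_s`, `track_id`).
#' @param min_overlap_s minimum overlap (s) to count a match.
#' @return list with `recall`, `precision`, `track_accuracy` (over matched
#'   pairs where both sides carry a track id) and the match index vectors.
#' @export
match_replay_events <- function(detected, schedule, min_overlap_s = 0.05) {
  if (!NROW(schedule)) {
    return(list(recall = NA_real_, precision = if (NROW(detected)) 0 else NA_real_,
                track_accuracy = NA_real_, matched_truth = integer(0)))
  }
  if (!NROW(detected)) {
    return(list(recall = 0, precision = NA_real_, track_accuracy = NA_real_,
                matched_truth = integer(0)))
  }
  hit_truth <- logical(nrow(schedule))
  match_of_det <- rep(NA_integer_, nrow(detected))
  for (i in seq_len(nrow(detected))) {
    ov <- interval_overlap(detected$start_s[i], detected$end_s[i],
                           schedule$start_s, schedule$end_s)
    j <- which.max(ov)
    if (ov[j] >= min_overlap_s) {
      hit_truth[j] <- TRUE
      match_of_det[i] <- j
    }
  }
  acc <- NA_real_
  if (!is.null(detected$track_id)) {
    m <- !is.na(match_of_det) & !is.na(detected$track_id)
    if (any(m)) acc <- mean(detected$track_id[m] == schedule$track_id[match_of_det[m]])
  }
  list(recall = mean(hit_truth),
       precision = mean(!is.na(match_of_det)),
       track_accuracy = acc,
       matched_truth = which(hit_truth),
       match_of_detected = match_of_det)
}
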