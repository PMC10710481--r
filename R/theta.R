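#' Detect theta cycles from the filtered theta-band LFP
#'
#' Peak-trough detection: local extrema of the theta-band trace whose
#' absolute value exceeds 25% of the median absolute amplitude of the
#' signal; consecutive same-type extrema are collapsed to the largest.
#' Cycles run trough-to-trough and are discarded when shorter than 80 ms or
#' longer than 200 ms, when running speed is below 5 cm/s, or when the
#' animal is in a reward zone (within 20 cm of a track end).
#'
#' @param theta_band `rk_band` of the theta channel (covering the epoch).
#' @param linpos linearized position for the epoch.
#' @param epoch list(start, end).
#' @param track_length cm.
#' @param config an [analysis_config()].
#' @return data.frame of cycles: `start_s`, `end_s`, `duration_s`, `mid_s`,
#'   `position_cm`, `speed_cms`, `direction` (+1 outbound, -1 inbound).
#' @export
detect_theta_cycles <- function(theta_band, linpos, epoch, track_length,
                                config = analysis_config()) {
  tt <- band_time(theta_band)
  sel <- tt >= epoch$start & tt < epoch$end
  f <- theta_band$filtered[sel]
  tt <- tt[sel]
  ext <- alternating_extrema(f, config$theta_prominence_frac * stats::median(abs(f)))
  if (!nrow(ext)) {
    return(data.frame(start_s = numeric(0), end_s = numeric(0),
                      duration_s = numeric(0), mid_s = numeric(0),
                      position_cm = numeric(0), speed_cms = numeric(0),
                      direction = numeric(0)))
  }
  tr_i <- ext$index[ext$type == "trough"]
  if (length(tr_i) < 2) {
    return(data.frame(start_s = numeric(0), end_s = numeric(0),
                      duration_s = numeric(0), mid_s = numeric(0),
                      position_cm = numeric(0), speed_cms = numeric(0),
                      direction = numeric(0)))
  }
  start <- tt[tr_i[-length(tr_i)]]
  end <- tt[tr_i[-1]]
  mid <- (start + end) / 2
  dur <- end - start
  pos <- stats::approx(linpos$time_s, linpos$lin_cm, xout = mid, rule = 2)$y
  spd <- stats::approx(linpos$time_s, linpos$speed_cms, xout = mid, rule = 2)$y
  dirn <- position_direction(linpos)
  dirv <- stats::approx(linpos$time_s, dirn, xout = mid, method = "constant", rule = 2)$y
  keep <- dur >= config$theta_cycle_min_s & dur <= config$theta_cycle_max_s &
    spd >= config$theta_speed_min_cms &
    pos > config$endzone_cm & pos < track_length - config$endzone_cm
  data.frame(start_s = start, end_s = end, duration_s = dur, mid_s = mid,
             position_cm = pos, speed_cms = spd,
             direction = ifelse(dirv >= 0, 1, -1))[keep, , drop = FALSE]
}

# alternating peak/trough sequence above an absolute-amplitude threshold;
# consecutive same-type extrema collapse to the larger-magnitude one.
alternating_extrema <- function(f, threshold) {
  n <- length(f)
  if (n < 3) return(data.frame(index = integer(0), type = character(0)))
  d <- diff(f)
  pk <- which(d[-length(d)] > 0 & d[-1] <= 0) + 1L
  tr <- which(d[-length(d)] < 0 & d[-1] >= 0) + 1L
  pk <- pk[f[pk] > threshold]
  tr <- tr[f[tr] < -threshold]
  if (!length(pk) && !length(tr)) return(data.frame(index = integer(0), type = character(0)))
  ext <- rbind(data.frame(index = pk, type = "peak"),
               data.frame(index = tr, type = "trough"))
  ext <- ext[order(ext$index), ]
  keep_idx <- integer(0); keep_type <- character(0)
  for (i in seq_len(nrow(ext))) {
    if (length(keep_type) && keep_type[length(keep_type)] == ext$type[i]) {
      prev <- keep_idx[length(keep_idx)]
      better <- if (ext$type[i] == "peak") f[ext$index[i]] > f[prev] else f[ext$index[i]] < f[prev]
      if (better) keep_idx[length(keep_idx)] <- ext$index[i]
    } else {
      keep_idx <- c(keep_idx, ext$index[i])
      keep_type <- c(keep_type, ext$type[i])
    }
  }
  data.frame(index = keep_idx, type = keep_type)
}

#' Build per-lap directional smoothed ratemaps
#'
#' One smoothed (Gaussian sd = 1 bin) directional ratemap per lap and
#' running direction, used for within-cycle theta decoding.
#'
#' @param spikes spike table.
#' @param linpos linearized position for the run epoch.
#' @param unit_ids decoding units.
#' @param laps lap table (`lap`, `start_s`, `end_s`).
#' @param track_length cm.
#' @param config an [analysis_config()].
#' @return nested list `[[lap]][[direction]]` of `rk_ratemaps`.
#' @export
lap_directional_maps <- function(spikes, linpos, unit_ids, laps, track_length,
                                 config = analysis_config()) {
  speed_win <- c(config$place_speed_min_cms, config$place_speed_max_cms)
  out <- list()
  for (i in seq_len(nrow(laps))) {
    w <- list(start = laps$start_s[i], end = laps$end_s[i])
    out[[i]] <- lapply(c(out = "out", `in` = "in"), function(d) {
      tryCatch(
        compute_ratemaps(spikes, linpos, unit_ids, track_length,
                         bin_cm = config$bin_size_decode_cm,
                         speed_window = speed_win,
                         smooth_sd_bins = config$map_smooth_sd_bins,
                         direction = d, window = w),
        error = function(e) NULL)
    })
  }
  out
}

#' Decode spikes within theta cycles
#'
#' Each retained cycle is decoded in 10-ms windows against the smoothed
#' directional ratemap of the lap it occurred in; cycles with fewer than 2
#' active decoding units, or outside any lap, are skipped.
#'
#' @param cycles cycle table from [detect_theta_cycles()].
#' @param spikes spike table.
#' @param lap_maps from [lap_directional_maps()].
#' @param laps lap table matching `lap_maps`.
#' @param track_id track being decoded.
#' @param config an [analysis_config()].
#' @return list of decoded cycles: each with `cycle` (row index), `prob`,
#'   `pos_cm`, `times`, `counts`, `position_cm`, `direction`.
#' @export
decode_theta_windows <- function(cycles, spikes, lap_maps, laps, track_id,
                                 config = analysis_config()) {
  tau <- config$tau_theta_s
  out <- list()
  if (!nrow(cycles)) return(out)
  for (i in seq_len(nrow(cycles))) {
    li <- which(laps$start_s <= cycles$mid_s[i] & cycles$mid_s[i] < laps$end_s)
    if (!length(li)) next
    dkey <- if (cycles$direction[i] > 0) "out" else "in"
    m <- lap_maps[[li[1]]][[dkey]]
    if (is.null(m)) next
    uid <- rownames(m$rate)
    B <- floor((cycles$end_s[i] - cycles$start_s[i]) / tau)
    if (B < 2) next
    bc <- bin_spike_counts(spikes, uid, cycles$start_s[i], cycles$end_s[i], tau)
    if (sum(rowSums(bc$counts) > 0) < config$theta_min_units) next
    maps <- stats::setNames(list(m), as.character(track_id))
    post <- decode_posterior(bc$counts, maps, tau,
                             rate_floor = config$rate_floor_hz, times = bc$times)
    out[[length(out) + 1]] <- list(cycle = i, prob = post$prob,
                                   pos_cm = post$pos_cm, times = bc$times,
                                   counts = bc$counts,
                                   position_cm = cycles$position_cm[i],
                                   direction = cycles$direction[i])
  }
  out
}

#' Average position-centred theta-cycle posteriors
#'
#' Re-registers each decoded cycle so the animal's current position is at
#' 0 cm (span +/- 40 cm), mirrors the inbound direction so sweeps point the
#' same way, resamples the time axis of every cycle to a common number of
#' columns, and averages element-wise.
#'
#' @param decoded list from [decode_theta_windows()].
#' @param bin_cm decode bin size (cm).
#' @param center_cm half-span of the centred position axis (default 40).
#' @param n_time_bins columns of the normalized cycle (default 10).
#' @return list with `average` (centred-positions x time matrix), `offsets`
#'   (centred axis, cm), `n_cycles`.
#' @export
average_theta_sequences <- function(decoded, bin_cm, center_cm = 40,
                                    n_time_bins = 10) {
  if (!length(decoded)) return(list(average = NULL, offsets = numeric(0), n_cycles = 0))
  half <- floor(center_cm / bin_cm)
  nb <- 2 * half + 1
  acc <- matrix(0, nb, n_time_bins)
  cnt <- matrix(0, nb, n_time_bins)
  for (d in decoded) {
    pos_bin <- round((d$position_cm - d$pos_cm[1]) / bin_cm) + 1L
    nr <- nrow(d$prob)
    # resample time axis to n_time_bins columns
    src <- seq(1, ncol(d$prob), length.out = n_time_bins)
    P <- t(apply(d$prob, 1, function(row) stats::approx(seq_along(row), row, xout = src)$y))
    if (ncol(d$prob) == 1) P <- matrix(d$prob[, 1], nr, n_time_bins)
    for (k in seq_len(nr)) {
      off <- k - pos_bin
      if (d$direction < 0) off <- -off
      r <- off + half + 1L
      if (r >= 1 && r <= nb) {
        acc[r, ] <- acc[r, ] + P[k, ]
        cnt[r, ] <- cnt[r, ] + 1
      }
    }
  }
  avg <- acc / pmax(cnt, 1)
  avg[cnt == 0] <- NA
  list(average = avg, offsets = (-half:half) * bin_cm, n_cycles = length(decoded))
}

#' Score theta-sequence significance for one decoded cycle
#'
#' The sequence score is the weighted correlation between decoded position
#' and time within the cycle, signed by running direction so a
#' behind-to-ahead sweep scores positive. It is compared against the
#' `1 - alpha` quantile of three shuffle distributions: spike-train
#' circular shift (re-decoded), circular shift of position within each time
#' bin, and circular shift of the decoded phase axis within each position
#' bin (which preserves the position-probability marginal). Significant
#' when the score exceeds all three.
#'
#' @param d one decoded-cycle entry from [decode_theta_windows()].
#' @param maps the `rk_ratemaps` used to decode that cycle.
#' @param track_id track id.
#' @param config an [analysis_config()].
#' @param alpha significance level (default `config$alpha`).
#' @return list with `r` (signed, direction-adjusted), `significant`, `p`
#'   (3 permutation p-values).
#' @export
score_theta_significance <- function(d, maps, track_id,
                                     config = analysis_config(),
                                     alpha = config$alpha) {
  nshuf <- config$n_shuffles
  dirn <- d$direction
  sub <- d$prob
  xpos <- d$pos_cm
  r_obs <- weighted_correlation(sub, xpos, d$times) * dirn
  if (is.na(r_obs)) return(list(r = NA_real_, significant = FALSE, p = rep(NA_real_, 3)))
  mlist <- stats::setNames(list(maps), as.character(track_id))
  B <- ncol(d$counts)
  shuf1 <- shuffle_spike_trains(d$counts, mlist, config$tau_theta_s, track_id,
                                xpos, d$times, nshuf, config) * dirn
  shuf2 <- shuffle_posterior_columns(sub, xpos, d$times, nshuf) * dirn
  shuf3 <- shuffle_posterior_rows(sub, xpos, d$times, nshuf) * dirn
  q <- 1 - alpha
  qs <- vapply(list(shuf1, shuf2, shuf3),
               function(s) stats::quantile(s, q, na.rm = TRUE, names = FALSE),
               numeric(1))
  pv <- vapply(list(shuf1, shuf2, shuf3), function(s) {
    (1 + sum(s >= r_obs, na.rm = TRUE)) / (1 + sum(!is.na(s)))
  }, numeric(1))
  list(r = r_obs, significant = all(r_obs > qs), p = pv)
}

# circular shift of the time (phase) axis independently per position bin
shuffle_posterior_rows <- function(sub, xpos, times, nshuf) {
  nb <- nrow(sub); B <- ncol(sub)
  cols <- matrix(0:(B - 1), nb, B, byrow = TRUE)
  rowi <- rep(seq_len(nb), times = B)
  big <- matrix(0, nb, B * nshuf)
  for (s in seq_len(nshuf)) {
    k <- sample.int(B, nb, replace = TRUE) - 1L
    M <- ((cols - k) %% B) + 1L
    big[, ((s - 1L) * B + 1L):(s * B)] <- matrix(sub[cbind(rowi, as.vector(M))], nb, B)
  }
  wcorr_blocks(big, xpos, times, B, nshuf)
}

#' Detect and score theta sequences for one run epoch
#'
#' Full theta pipeline for one run epoch: theta-band filtering of the
#' selected channel, cycle detection, per-lap directional smoothed maps,
#' within-cycle decoding, significance scoring and the position-centred
#' average. When `config$theta_max_cycles` is finite and fewer than the
#' number of decodable cycles, a random subsample of that size is scored
#' and the significant-sequence count is estimated by scaling the
#' subsample's significant fraction to all decoded cycles.
#'
#' @param session an `rk_session`.
#' @param linpos linearized position for the epoch.
#' @param laps lap table for the epoch.
#' @param unit_ids decoding units (place cells of the track).
#' @param epoch_label run epoch label (e.g. "RUN1_T1").
#' @param theta_channel channel index (from [select_channels()]).
#' @param config an [analysis_config()].
#' @return list with `cycles`, `n_cycles`, `n_decoded`, `n_significant`,
#'   `results` (per scored cycle), `average`.
#' @export
detect_theta_sequences <- function(session, linpos, laps, unit_ids,
                                   epoch_label, theta_channel = 1,
                                   config = analysis_config()) {
  w <- epoch_window(session, epoch_label)
  tr <- as.integer(sub(".*_T", "", epoch_label))
  track_length <- session$tracks$length_cm[tr]
  ch <- session$lfp[[theta_channel]]
  i0 <- max(1L, floor((w$start - ch$start_s) * ch$fs) + 1L)
  i1 <- min(length(ch$samples), ceiling((w$end - ch$start_s) * ch$fs))
  seg <- list(channel_id = ch$channel_id, fs = ch$fs,
              start_s = ch$start_s + (i0 - 1) / ch$fs,
              samples = ch$samples[i0:i1])
  tb <- band_filter_hilbert(seg, config$theta_band_hz, order = config$filter_order)
  cycles <- detect_theta_cycles(tb, linpos, w, track_length, config)
  lm <- lap_directional_maps(session$spikes, linpos, unit_ids, laps,
                             track_length, config)
  decoded <- decode_theta_windows(cycles, session$spikes, lm, laps, tr, config)
  n_dec <- length(decoded)
  idx <- seq_len(n_dec)
  if (is.finite(config$theta_max_cycles) && n_dec > config$theta_max_cycles) {
    idx <- sort(sample(idx, config$theta_max_cycles))
  }
  results <- lapply(idx, function(i) {
    d <- decoded[[i]]
    li <- which(laps$start_s <= cycles$mid_s[d$cycle] & cycles$mid_s[d$cycle] < laps$end_s)
    m <- lm[[li[1]]][[if (d$direction > 0) "out" else "in"]]
    sc <- score_theta_significance(d, m, tr, config)
    c(list(cycle = d$cycle), sc)
  })
  n_sig_sub <- sum(vapply(results, function(r) isTRUE(r$significant), logical(1)))
  n_sig <- if (length(idx)) round(n_sig_sub / length(idx) * n_dec) else 0L
  avg <- average_theta_sequences(decoded, config$bin_size_decode_cm,
                                 config$theta_center_cm)
  list(cycles = cycles, n_cycles = nrow(cycles), n_decoded = n_dec,
       n_significant = n_sig, results = results, average = avg)
}
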