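# Zero-phase Butterworth band-pass (forward and reverse filtering).
band_filter <- function(x, fs, band, order = 4) {
  if (fs <= 2 * band[2]) stop("sample rate too low for requested band")
  bf <- signal::butter(order, band / (fs / 2), type = "pass")
  signal::filtfilt(bf, x)
}

#' Band-pass filter an LFP trace and extract instantaneous phase/amplitude
#'
#' Zero-phase (forward-reverse) Butterworth filtering followed by the
#' analytic-signal construction. Phase is in radians in `[-pi, pi)`;
#' amplitude is the analytic-signal magnitude. When `smooth_s > 0` the
#' amplitude is additionally smoothed with a moving average of that width
#' (used for ripple-power event detection).
#'
#' @param trace LFP channel entry (list with `fs`, `samples`, `start_s`) or
#'   a numeric vector (then `fs` must be given).
#' @param band length-2 numeric band (Hz).
#' @param fs sampling rate, required when `trace` is a bare vector.
#' @param order Butterworth order (default 4).
#' @param smooth_s amplitude moving-average width in seconds (default 0).
#' @return list of class `rk_band`: `band`, `fs`, `start_s`, `filtered`,
#'   `phase`, `amplitude`.
#' @export
band_filter_hilbert <- function(trace, band, fs = NULL, order = 4, smooth_s = 0) {
  if (is.list(trace)) {
    fs <- trace$fs; x <- trace$samples; start_s <- trace$start_s %||% 0
  } else {
    if (is.null(fs)) stop("fs required for a bare numeric trace")
    x <- trace; start_s <- 0
  }
  filt <- band_filter(x, fs, band, order)
  a <- analytic_signal(filt)
  amp <- Mod(a)
  if (smooth_s > 0) amp <- moving_average(amp, round(smooth_s * fs))
  ph <- Arg(a)
  ph[ph >= pi] <- -pi
  structure(list(band = band, fs = fs, start_s = start_s,
                 filtered = filt, phase = ph, amplitude = amp),
            class = "rk_band")
}

band_time <- function(bs) bs$start_s + (seq_along(bs$filtered) - 1) / bs$fs

#' Select LFP channels by spectral band power
#'
#' Computes each channel's Welch power spectral density (2-s windows, 50%
#' overlap by default) and picks: the channel with the highest theta-band
#' power, the one with the highest ripple-band power, the one with the
#' highest delta-band power, and the channel with the largest difference in
#' normalized theta minus ripple power (the theta/ripple-contrast channel).
#'
#' @param lfp list of LFP channel entries (a session's `lfp` field).
#' @param config an [analysis_config()].
#' @param max_s use at most this many seconds per channel for the PSD
#'   (default 300; the spectrum is stationary by construction).
#' @return list with channel indices `theta`, `ripple`, `delta`, `contrast`
#'   and the per-channel band-power matrix `band_power`.
#' @export
select_channels <- function(lfp, config = analysis_config(), max_s = 300) {
  if (!length(lfp)) stop("no LFP channels")
  bp <- t(vapply(lfp, function(ch) {
    x <- ch$samples
    if (length(x) > max_s * ch$fs) x <- x[seq_len(max_s * ch$fs)]
    psd <- welch_psd(x, ch$fs, config$psd_window_s, config$psd_overlap)
    bsum <- function(b) sum(psd$power[psd$freq >= b[1] & psd$freq <= b[2]])
    tot <- sum(psd$power)
    c(theta = bsum(config$theta_band_hz), ripple = bsum(config$ripple_band_hz),
      delta = bsum(config$delta_band_hz), total = tot)
  }, numeric(4)))
  contrast <- bp[, "theta"] / bp[, "total"] - bp[, "ripple"] / bp[, "total"]
  list(theta = unname(which.max(bp[, "theta"])),
       ripple = unname(which.max(bp[, "ripple"])),
       delta = unname(which.max(bp[, "delta"])),
       contrast = unname(which.max(contrast)),
       band_power = bp)
}

#' Smoothed, z-scored multi-unit activity
#'
#' Pools spikes across units, bins them at 1 ms, smooths with a Gaussian
#' kernel (sigma 5 ms), and z-scores. The z-score baseline (mean/sd) is the
#' whole window by default, or only the samples where `baseline_mask` is
#' TRUE (used in run epochs to score bursts against immobility activity
#' rather than locomotor theta firing).
#'
#' @param spikes spike table (`unit_id`, `time_s`).
#' @param window list(start, end) in seconds.
#' @param config an [analysis_config()].
#' @param units optional unit-id subset (e.g. the top third by spike count
#'   for sleep scoring).
#' @param baseline_times optional list(time_s, ok) logical trace; the z
#'   baseline is computed over samples whose nearest entry is TRUE.
#' @return list of class `rk_mua`: `start_s`, `fs`, `z` (numeric vector),
#'   `rate_hz` (unsmoothed rate trace mean).
#' @export
mua_zscore <- function(spikes, window, config = analysis_config(),
                       units = NULL, baseline_times = NULL) {
  if (!is.null(units)) spikes <- spikes[spikes$unit_id %in% units, ]
  st <- spikes$time_s[spikes$time_s >= window$start & spikes$time_s < window$end]
  fs <- 1 / config$mua_bin_s
  n <- max(2L, ceiling((window$end - window$start) * fs))
  counts <- tabulate(pmin(n, floor((st - window$start) * fs) + 1L), nbins = n)
  sm <- gauss_smooth(counts, config$mua_smooth_sd_s * fs)
  if (!is.null(baseline_times)) {
    tt <- window$start + (seq_len(n) - 1) / fs
    ok <- stats::approx(baseline_times$time_s, as.numeric(baseline_times$ok),
                        xout = tt, method = "constant", rule = 2)$y > 0.5
    mu <- mean(sm[ok]); sdv <- stats::sd(sm[ok])
  } else {
    mu <- mean(sm); sdv <- stats::sd(sm)
  }
  z <- if (!is.finite(sdv) || sdv == 0) rep(0, n) else (sm - mu) / sdv
  structure(list(start_s = window$start, fs = fs, z = z,
                 rate_hz = mean(counts) * fs),
            class = "rk_mua")
}

mua_time <- function(m) m$start_s + (seq_along(m$z) - 1) / m$fs

top_units_by_count <- function(spikes, units, frac = 1 / 3) {
  cnt <- table(factor(spikes$unit_id, levels = units$unit_id))
  k <- max(1L, ceiling(length(units$unit_id) * frac))
  as.integer(names(sort(cnt, decreasing = TRUE))[seq_len(k)])
}

#' Score putative sleep in 1-minute bins
#'
#' A bin is putative sleep when the animal's mean speed is below
#' `sleep_speed_max_cms` (4 cm/s) and the z-scored multi-unit activity of
#' the most active units (top third by total spike count) is above 0.
#' The returned mask carries the cumulative sleep clock.
#'
#' @param speed list(time_s, speed_cms) covering the epoch.
#' @param mua an `rk_mua` (z-scored MUA of the top-third units) covering the
#'   epoch.
#' @param epoch list(start, end).
#' @param config an [analysis_config()].
#' @return data.frame of class `rk_sleep_mask`: `bin_start_s`, `bin_end_s`,
#'   `speed_ok`, `mua_ok`, `sleep`, `cum_sleep_s`.
#' @export
detect_putative_sleep <- function(speed, mua, epoch, config = analysis_config()) {
  bin <- config$sleep_bin_s
  if (epoch$end - epoch$start < bin) stop("epoch shorter than one sleep bin")
  edges <- seq(epoch$start, epoch$end, by = bin)
  if (tail(edges, 1) < epoch$end) edges <- c(edges, epoch$end)
  nb <- length(edges) - 1L
  tz <- mua_time(mua)
  speed_ok <- mua_ok <- logical(nb)
  for (b in seq_len(nb)) {
    sv <- speed$speed_cms[speed$time_s >= edges[b] & speed$time_s < edges[b + 1]]
    zv <- mua$z[tz >= edges[b] & tz < edges[b + 1]]
    speed_ok[b] <- length(sv) > 0 && mean(sv) < config$sleep_speed_max_cms
    mua_ok[b] <- length(zv) > 0 && mean(zv) > config$sleep_mua_z_min
  }
  sleep <- speed_ok & mua_ok
  out <- data.frame(bin_start_s = edges[-length(edges)], bin_end_s = edges[-1],
                    speed_ok = speed_ok, mua_ok = mua_ok, sleep = sleep)
  out$cum_sleep_s <- cumsum((out$bin_end_s - out$bin_start_s) * sleep)
  class(out) <- c("rk_sleep_mask", class(out))
  out
}

#' Extract the first `window_s` seconds of cumulative sleep
#'
#' Returns the intervals of flagged sleep bins whose cumulative sleep time
#' covers exactly `window_s` seconds (the final bin is truncated); if less
#' sleep exists, all of it is returned with `complete = FALSE`.
#'
#' @param mask an `rk_sleep_mask`.
#' @param window_s seconds of cumulative sleep to extract (default 1800).
#' @return list with `intervals` (start_s, end_s), `total_s`, `complete`.
#' @export
sleep_window <- function(mask, window_s = 1800) {
  sel <- mask[mask$sleep, , drop = FALSE]
  if (!nrow(sel)) {
    return(list(intervals = data.frame(start_s = numeric(0), end_s = numeric(0)),
                total_s = 0, complete = FALSE))
  }
  lens <- sel$bin_end_s - sel$bin_start_s
  cum <- cumsum(lens)
  k <- which(cum >= window_s)[1]
  if (is.na(k)) {
    iv <- data.frame(start_s = sel$bin_start_s, end_s = sel$bin_end_s)
    return(list(intervals = iv, total_s = sum(lens), complete = FALSE))
  }
  iv <- data.frame(start_s = sel$bin_start_s[seq_len(k)],
                   end_s = sel$bin_end_s[seq_len(k)])
  excess <- cum[k] - window_s
  iv$end_s[k] <- iv$end_s[k] - excess
  list(intervals = iv, total_s = window_s, complete = TRUE)
}

#' LFP-based sleep-state control scoring
#'
#' Control method for the MUA-based putative-sleep score, using theta power
#' and the theta/delta ratio. Per 1-min bin: awake = high z-scored theta
#' power (>0.5) and speed above 4 cm/s; NREM = low theta z (<0.5), speed
#' below 4 cm/s and theta/delta ratio z > 0.5; REM = theta z > 0.5, speed
#' below 4 cm/s and ratio z > 0.5. NREM and REM are merged into an
#' LFP-sleep mask which is correlated against the MUA-based mask.
#'
#' @param theta_band `rk_band` for the theta channel.
#' @param delta_band `rk_band` for the delta channel.
#' @param speed list(time_s, speed_cms).
#' @param epoch list(start, end).
#' @param mask optional `rk_sleep_mask` to compare against.
#' @param config an [analysis_config()].
#' @return list with `labels` (per-bin state in {awake, NREM, REM, other}),
#'   `lfp_sleep` logical vector, and `agreement` (Pearson correlation with
#'   `mask$sleep`, NA when no mask given).
#' @export
lfp_sleep_control <- function(theta_band, delta_band, speed, epoch,
                              mask = NULL, config = analysis_config()) {
  if (is.null(theta_band) || is.null(delta_band)) stop("no LFP channels selected")
  bin <- config$sleep_bin_s
  edges <- seq(epoch$start, epoch$end, by = bin)
  if (tail(edges, 1) < epoch$end) edges <- c(edges, epoch$end)
  nb <- length(edges) - 1L
  tt <- band_time(theta_band)
  td <- band_time(delta_band)
  th_pow <- theta_band$amplitude^2
  de_pow <- delta_band$amplitude^2
  th_bin <- de_bin <- sp_bin <- numeric(nb)
  for (b in seq_len(nb)) {
    th_bin[b] <- mean(th_pow[tt >= edges[b] & tt < edges[b + 1]])
    de_bin[b] <- mean(de_pow[td >= edges[b] & td < edges[b + 1]])
    sp_bin[b] <- mean(speed$speed_cms[speed$time_s >= edges[b] & speed$time_s < edges[b + 1]])
  }
  th_z <- zscore(th_bin)
  ratio_z <- zscore(th_bin / pmax(de_bin, .Machine$double.eps))
  lab <- rep("other", nb)
  lab[th_z > 0.5 & sp_bin > config$sleep_speed_max_cms] <- "awake"
  lab[th_z < 0.5 & sp_bin < config$sleep_speed_max_cms & ratio_z > 0.5] <- "NREM"
  lab[th_z > 0.5 & sp_bin < config$sleep_speed_max_cms & ratio_z > 0.5] <- "REM"
  lfp_sleep <- lab %in% c("NREM", "REM")
  agreement <- NA_real_
  if (!is.null(mask)) {
    m <- mask$sleep[seq_len(min(nb, nrow(mask)))]
    l <- lfp_sleep[seq_len(length(m))]
    agreement <- if (stats::sd(m) == 0 || stats::sd(l) == 0) {
      as.numeric(all(m == l))
    } else {
      stats::cor(as.numeric(m), as.numeric(l))
    }
  }
  list(labels = data.frame(bin_start_s = edges[-length(edges)], state = lab),
       lfp_sleep = lfp_sleep, agreement = agreement)
}
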