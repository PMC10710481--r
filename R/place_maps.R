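#' Occupancy-normalized firing ratemaps
#'
#' Builds per-unit firing-rate vectors over position bins: the speed-filtered
#' spike histogram divided by the total dwell time in each bin. Optionally
#' restricted to one running direction and/or a time window (e.g. one lap),
#' and optionally smoothed with a Gaussian kernel. Zero-occupancy bins have
#' rate 0 and are marked by the returned occupancy vector.
#'
#' @param spikes spike table (`unit_id`, `time_s`).
#' @param linpos linearized position for the relevant epoch
#'   (`time_s`, `lin_cm`, `speed_cms`, optional `on_track`).
#' @param unit_ids units to map (row order of the result).
#' @param track_length cm.
#' @param bin_cm bin size (2 cm for visualization, 10 cm for decoding).
#' @param speed_window spikes and occupancy restricted to speeds within
#'   this range (default c(4, 50) cm/s); `NULL` disables filtering.
#' @param smooth_sd_bins Gaussian smoothing s.d. in bins (0 = raw; raw maps
#'   are the only ones used for Bayesian decoding).
#' @param direction `"both"`, `"out"` (increasing position) or `"in"`.
#' @param window optional list(start, end) restricting the time range.
#' @return list of class `rk_ratemaps`: `rate` (units x bins, Hz),
#'   `occupancy_s`, `bin_cm`, `edges`, `track_length`, `smoothed`,
#'   `direction`.
#' @export
compute_ratemaps <- function(spikes, linpos, unit_ids, track_length,
                             bin_cm = 10, speed_window = c(4, 50),
                             smooth_sd_bins = 0, direction = "both",
                             window = NULL) {
  nb <- ceiling(track_length / bin_cm)
  edges <- seq(0, nb * bin_cm, by = bin_cm)
  lp <- linpos
  if (!is.null(window)) {
    lp <- lp[lp$time_s >= window$start & lp$time_s < window$end, ]
  }
  if (nrow(lp) < 2) stop("zero total occupancy")
  dt <- stats::median(diff(lp$time_s))
  ok <- rep(TRUE, nrow(lp))
  if (!is.null(lp$on_track)) ok <- ok & lp$on_track
  if (!is.null(speed_window)) {
    ok <- ok & lp$speed_cms >= speed_window[1] & lp$speed_cms <= speed_window[2]
  }
  if (direction != "both") {
    dirn <- position_direction(lp)
    ok <- ok & if (direction == "out") dirn > 0 else dirn < 0
  }
  lp_ok <- lp[ok, ]
  if (!nrow(lp_ok)) stop("zero total occupancy")
  bin_of <- function(x) pmin(nb, pmax(1L, floor(x / bin_cm) + 1L))
  occ <- tabulate(bin_of(lp_ok$lin_cm), nbins = nb) * dt

  sp <- spikes[spikes$unit_id %in% unit_ids, ]
  if (!is.null(window)) {
    sp <- sp[sp$time_s >= window$start & sp$time_s < window$end, ]
  }
  # interpolate position/validity at spike times; spikes in filtered-out
  # samples are dropped with their occupancy
  okn <- stats::approx(lp$time_s, as.numeric(ok), xout = sp$time_s,
                       method = "constant", rule = 2)$y > 0.5
  sp <- sp[okn & sp$time_s >= min(lp$time_s) & sp$time_s <= max(lp$time_s), ]
  spx <- stats::approx(lp$time_s, lp$lin_cm, xout = sp$time_s, rule = 2)$y
  rate <- matrix(0, nrow = length(unit_ids), ncol = nb,
                 dimnames = list(unit_ids, NULL))
  if (nrow(sp)) {
    cnt <- table(factor(sp$unit_id, levels = unit_ids), factor(bin_of(spx), levels = seq_len(nb)))
    rate <- unclass(cnt) / rep(pmax(occ, .Machine$double.eps), each = length(unit_ids))
    rate[, occ == 0] <- 0
    dimnames(rate) <- list(unit_ids, NULL)
  }
  if (smooth_sd_bins > 0) {
    rate <- t(apply(rate, 1, gauss_smooth, sigma = smooth_sd_bins))
  }
  structure(list(rate = rate, occupancy_s = occ, bin_cm = bin_cm,
                 edges = edges, track_length = track_length,
                 smoothed = smooth_sd_bins > 0, direction = direction),
            class = "rk_ratemaps")
}

# running direction per position sample: sign of the (smoothed) derivative
position_direction <- function(lp, smooth_s = 0.5) {
  n <- nrow(lp)
  d <- numeric(n)
  if (n > 2) {
    d[2:(n - 1)] <- lp$lin_cm[3:n] - lp$lin_cm[1:(n - 2)]
    d[1] <- d[2]; d[n] <- d[n - 1]
  }
  dt <- stats::median(diff(lp$time_s))
  sign(moving_average(d, round(smooth_s / dt)))
}

#' Classify principal cells and place cells
#'
#' Principal cells: waveform half-width-half-max above 500 microseconds and
#' session-wide mean rate below 5 Hz. A principal cell is a place cell on a
#' track when its unsmoothed ratemap there (spikes speed-filtered to
#' 4-50 cm/s) has a peak rate above 1 Hz. Units with missing half-width are
#' excluded with a warning.
#'
#' @param session an `rk_session`.
#' @param linpos named list of linearized-position frames per run epoch (as
#'   produced by [summarize_behavior()]).
#' @param config an [analysis_config()].
#' @return data.frame roster: `unit_id`, `principal`, `place_t1`,
#'   `place_t2`, `peak_t1_hz`, `peak_t2_hz`.
#' @export
classify_units <- function(session, linpos, config = analysis_config()) {
  u <- session$units
  missing_hw <- is.na(u$half_width_us)
  if (any(missing_hw)) {
    warning(sum(missing_hw), " unit(s) excluded: missing waveform half-width")
  }
  principal <- !missing_hw &
    u$half_width_us > config$hwhm_min_us &
    u$mean_rate_hz < config$principal_max_rate_hz
  speed_win <- c(config$place_speed_min_cms, config$place_speed_max_cms)
  peak <- matrix(0, nrow(u), 2)
  for (tr in 1:2) {
    labs <- intersect(paste0(c("RUN1_T", "RUN2_T"), tr), names(linpos))
    if (!length(labs)) next
    lp <- do.call(rbind, linpos[labs])
    maps <- compute_ratemaps(session$spikes, lp, u$unit_id,
                             session$tracks$length_cm[tr],
                             bin_cm = config$bin_size_decode_cm,
                             speed_window = speed_win, smooth_sd_bins = 0)
    peak[, tr] <- apply(maps$rate, 1, max)
  }
  data.frame(unit_id = u$unit_id,
             principal = principal,
             place_t1 = principal & peak[, 1] > config$place_peak_min_hz,
             place_t2 = principal & peak[, 2] > config$place_peak_min_hz,
             peak_t1_hz = peak[, 1], peak_t2_hz = peak[, 2])
}

#' Population-vector correlation between two map sets
#'
#' Correlates, at each position bin, the population rate vector of one map
#' set with the other's, over the common units. The null distribution is
#' obtained by permuting unit identities of the second set.
#'
#' @param maps_a,maps_b `rk_ratemaps` (or bare units x bins matrices with
#'   unit ids as rownames) on matching bins.
#' @param n_shuffle number of unit-identity permutations (default 0).
#' @return list with `per_bin` (correlation per position bin), `mean`, and
#'   `shuffle_means` (length `n_shuffle`).
#' @export
pv_correlation <- function(maps_a, maps_b, n_shuffle = 0) {
  a <- if (inherits(maps_a, "rk_ratemaps")) maps_a$rate else maps_a
  b <- if (inherits(maps_b, "rk_ratemaps")) maps_b$rate else maps_b
  common <- intersect(rownames(a), rownames(b))
  if (length(common) < 2) stop("need at least 2 common units")
  a <- a[common, , drop = FALSE]
  b <- b[common, , drop = FALSE]
  stopifnot(ncol(a) == ncol(b))
  bin_cor <- function(m1, m2) {
    vapply(seq_len(ncol(m1)), function(j) {
      v1 <- m1[, j]; v2 <- m2[, j]
      if (stats::sd(v1) == 0 || stats::sd(v2) == 0) return(NA_real_)
      stats::cor(v1, v2)
    }, numeric(1))
  }
  per_bin <- bin_cor(a, b)
  shuffle_means <- numeric(n_shuffle)
  for (s in seq_len(n_shuffle)) {
    shuffle_means[s] <- mean(bin_cor(a, b[sample(nrow(b)), , drop = FALSE]),
                             na.rm = TRUE)
  }
  list(per_bin = per_bin, mean = mean(per_bin, na.rm = TRUE),
       shuffle_means = shuffle_means)
}
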