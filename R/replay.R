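#' Weighted correlation of a decoded posterior
#'
#' Correlation between position and time across a posterior probability
#' matrix, weighting each (position, time) cell by its decoded probability:
#' weighted means of x and t, weighted covariance, and their normalized
#' ratio. Returns `NA` when the weighted variance of either coordinate is
#' zero (degenerate posterior).
#'
#' @param prob positions x time-bins matrix of non-negative weights.
#' @param x position-bin coordinates (default row indices).
#' @param t time-bin coordinates (default column indices).
#' @return weighted correlation in `[-1, 1]`, or `NA`.
#' @export
weighted_correlation <- function(prob, x = NULL, t = NULL) {
  if (is.null(x)) x <- seq_len(nrow(prob))
  if (is.null(t)) t <- seq_len(ncol(prob))
  W <- sum(prob)
  if (W <= 0) return(NA_real_)
  mx <- sum(prob * x) / W
  ct <- colSums(prob)
  mt <- sum(ct * t) / W
  dx <- x - mx
  dt <- t - mt
  cov_xt <- sum(prob * (dx %o% dt)) / W
  cov_xx <- sum(prob * dx^2) / W
  cov_tt <- sum(ct * dt^2) / W
  den <- sqrt(cov_xx * cov_tt)
  if (den <= 0) return(NA_real_)
  cov_xt / den
}

# batched weighted correlation over S consecutive blocks of B columns
wcorr_blocks <- function(P, x, tvec, B, S) {
  grp <- rep(seq_len(S), each = B)
  t_col <- rep(tvec, S)
  cs <- colSums(P)
  xtP <- as.numeric(crossprod(P, x))
  x2tP <- as.numeric(crossprod(P, x^2))
  Sw <- rowsum(cs, grp)[, 1]
  Sx <- rowsum(xtP, grp)[, 1]
  St <- rowsum(cs * t_col, grp)[, 1]
  Sxx <- rowsum(x2tP, grp)[, 1]
  Stt <- rowsum(cs * t_col^2, grp)[, 1]
  Sxt <- rowsum(xtP * t_col, grp)[, 1]
  mx <- Sx / Sw; mt <- St / Sw
  cov_xt <- Sxt / Sw - mx * mt
  cov_xx <- Sxx / Sw - mx^2
  cov_tt <- Stt / Sw - mt^2
  den <- sqrt(pmax(cov_xx, 0) * pmax(cov_tt, 0))
  unname(ifelse(den > 0, cov_xt / den, NA_real_))
}

# z-scored (optionally baseline-masked) smoothed ripple-band amplitude
ripple_zscore <- function(band, window, baseline_times = NULL) {
  tt <- band_time(band)
  sel <- tt >= window$start & tt < window$end
  a <- band$amplitude[sel]
  tt <- tt[sel]
  if (!is.null(baseline_times)) {
    ok <- stats::approx(baseline_times$time_s, as.numeric(baseline_times$ok),
                        xout = tt, method = "constant", rule = 2)$y > 0.5
    mu <- mean(a[ok]); sdv <- stats::sd(a[ok])
  } else {
    mu <- mean(a); sdv <- stats::sd(a)
  }
  list(time_s = tt, z = if (sdv > 0) (a - mu) / sdv else rep(0, length(a)))
}

#' Detect candidate sharp-wave-ripple / multi-unit burst events
#'
#' Multi-unit activity (1-ms bins, Gaussian-smoothed with sigma 5 ms,
#' z-scored) is thresholded at z > 3; each supra-threshold burst core (kept
#' only if at most 300 ms long) is extended to the nearest z = 0 crossings
#' on either side. Events must reach ripple-band z > 3 (0.1-s-smoothed
#' Hilbert amplitude), events within 50 ms of each other are combined, and
#' the survivors are filtered: excluded while speed is above 5 cm/s, and
#' required to involve at least 5 active units and last 100-750 ms.
#'
#' @param spikes spike table (used for participating units).
#' @param mua `rk_mua` z-score trace covering the window (all units).
#' @param ripple_z list(time_s, z) of smoothed ripple-band amplitude z.
#' @param speed list(time_s, speed_cms).
#' @param window list(start, end).
#' @param config an [analysis_config()].
#' @return data.frame of candidate events: `start_s`, `end_s`,
#'   `duration_s`, `peak_mua_z`, `peak_ripple_z`, `n_units`, `units`
#'   (list column of participating unit ids). Zero rows when MUA is flat.
#' @export
detect_candidates <- function(spikes, mua, ripple_z, speed, window,
                              config = analysis_config()) {
  z <- mua$z
  n <- length(z)
  runs <- true_runs(z > config$mua_z_thresh)
  if (!nrow(runs)) return(empty_candidates())
  dt <- 1 / mua$fs
  t_of <- function(i) mua$start_s + (i - 1) * dt
  ib <- which(z <= 0)                 # sorted z<=0 crossing indices
  keep_run <- (runs$end - runs$start + 1L) * dt <= config$mua_burst_max_s
  runs <- runs[keep_run, , drop = FALSE]
  if (!nrow(runs)) return(empty_candidates())
  li <- findInterval(runs$start, ib)  # last below-zero index before burst
  s0 <- ifelse(li >= 1, ib[pmax(li, 1)], 1L)
  ri <- findInterval(runs$end, ib) + 1L
  e0 <- ifelse(ri <= length(ib), ib[pmin(ri, length(ib))], n)
  ivs <- unique(cbind(t_of(s0), t_of(e0)))
  ivs <- ivs[order(ivs[, 1]), , drop = FALSE]

  # ripple-power gate (ripple_z times are uniform and sorted)
  rz_t0 <- ripple_z$time_s[1]
  rz_dt <- ripple_z$time_s[2] - rz_t0
  rz_n <- length(ripple_z$z)
  rz_max <- function(s, e) {
    i0 <- max(1L, ceiling((s - rz_t0) / rz_dt) + 1L)
    i1 <- min(rz_n, floor((e - rz_t0) / rz_dt) + 1L)
    if (i1 < i0) return(-Inf)
    max(ripple_z$z[i0:i1])
  }
  keep <- vapply(seq_len(nrow(ivs)),
                 function(i) rz_max(ivs[i, 1], ivs[i, 2]) > config$ripple_z_thresh,
                 logical(1))
  ivs <- ivs[keep, , drop = FALSE]
  if (!nrow(ivs)) return(empty_candidates())

  # combine events within the merge gap (or overlapping)
  merged <- ivs[1, , drop = FALSE]
  for (i in seq_len(nrow(ivs))[-1]) {
    last <- nrow(merged)
    if (ivs[i, 1] - merged[last, 2] < config$event_merge_gap_s) {
      merged[last, 2] <- max(merged[last, 2], ivs[i, 2])
    } else {
      merged <- rbind(merged, ivs[i, , drop = FALSE])
    }
  }

  sp <- spikes_in_window(spikes, window$start, window$end)
  sp <- sp[order(sp$time_s), ]
  sp_t <- sp$time_s
  spd_sel <- speed$time_s >= window$start & speed$time_s < window$end
  spd_t <- speed$time_s[spd_sel]
  spd_v <- speed$speed_cms[spd_sel]
  out <- lapply(seq_len(nrow(merged)), function(i) {
    s <- merged[i, 1]; e <- merged[i, 2]
    j0 <- findInterval(s, spd_t) + 1L
    j1 <- findInterval(e, spd_t)
    if (j1 >= j0 && mean(spd_v[j0:j1]) > config$event_speed_max_cms) return(NULL)
    dur <- e - s
    if (dur < config$event_min_dur_s || dur > config$event_max_dur_s) return(NULL)
    k0 <- findInterval(s, sp_t, left.open = TRUE) + 1L
    k1 <- findInterval(e, sp_t, left.open = TRUE)
    uu <- if (k1 >= k0) unique(sp$unit_id[k0:k1]) else integer(0)
    if (length(uu) < config$event_min_units) return(NULL)
    i0 <- max(1L, floor((s - mua$start_s) / dt) + 1L)
    i1 <- min(n, ceiling((e - mua$start_s) / dt))
    data.frame(start_s = s, end_s = e, duration_s = dur,
               peak_mua_z = max(z[i0:i1]), peak_ripple_z = rz_max(s, e),
               n_units = length(uu), units = I(list(sort(uu))))
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) return(empty_candidates())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

empty_candidates <- function() {
  data.frame(start_s = numeric(0), end_s = numeric(0), duration_s = numeric(0),
             peak_mua_z = numeric(0), peak_ripple_z = numeric(0),
             n_units = integer(0), units = I(list()))
}

#' Score a candidate event's replay significance for both tracks
#'
#' The event is decoded in 20-ms windows over the concatenated two-track
#' space; events spanning fewer than five windows are not scored. For each
#' track, the magnitude of the weighted correlation between decoded
#' position and time on that track's posterior sub-matrix is compared to
#' the `1 - alpha` quantile of three shuffle distributions:
#'
#' 1. *Spike-train circular shift* - each unit's spike-count vector is
#'    independently circularly shifted across the event's time bins, then
#'    the event is re-decoded;
#' 2. *Place-field shift* - each of the scored track's ratemaps is
#'    circularly shifted in space by a random number of bins, then the
#'    event is re-decoded;
#' 3. *Circular shift of position* - each time bin's posterior vector is
#'    independently circularly shifted within the scored track.
#'
#' An event is significant for a track when its score exceeds all three
#' shuffle quantiles. Forward and reverse sequences are both admissible, so
#' the score is the absolute weighted correlation (the signed value is
#' reported).
#'
#' @param spikes spike table.
#' @param event one-row data.frame (or list) with `start_s`, `end_s`.
#' @param maps named list (`"1"`, `"2"`) of unsmoothed decode `rk_ratemaps`
#'   whose rows are the decoding units.
#' @param config an [analysis_config()].
#' @param alpha significance level (0.05; 0.025 for split halves).
#' @param seed optional integer; set per event for reproducible shuffles.
#' @return list of class `rk_replay_score`: `scored`, `n_bins`, and per
#'   track `r`, `abs_r`, `p` (3 permutation p-values), `significant`;
#'   plus `bias` (track-1 posterior mass fraction).
#' @export
score_significance <- function(spikes, event, maps, config = analysis_config(),
                               alpha = config$alpha, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tau <- config$tau_replay_s
  uid <- rownames(maps[[1]]$rate)
  B <- floor((event$end_s - event$start_s) / tau + 1e-9)
  if (B < 5) {
    return(structure(list(scored = FALSE, n_bins = B), class = "rk_replay_score"))
  }
  bc <- bin_spike_counts(spikes, uid, event$start_s, event$end_s, tau)
  counts <- bc$counts
  nshuf <- config$n_shuffles
  post <- decode_posterior(counts, maps, tau, rate_floor = config$rate_floor_hz,
                           times = bc$times)
  mass <- vapply(c(1L, 2L), function(tr) sum(posterior_track(post, tr)), numeric(1))
  bias <- if (sum(mass) > 0) mass[1] / sum(mass) else NA_real_

  res <- list(scored = TRUE, n_bins = B, bias = bias)
  for (tr in c(1L, 2L)) {
    sub <- posterior_track(post, tr)
    xpos <- post$pos_cm[post$track == tr]
    r_obs <- weighted_correlation(sub, x = xpos, t = bc$times)
    shuf1 <- shuffle_spike_trains(counts, maps, tau, tr, xpos, bc$times, nshuf, config)
    shuf2 <- shuffle_place_fields(counts, maps, tau, tr, xpos, bc$times, nshuf, config)
    shuf3 <- shuffle_posterior_columns(sub, xpos, bc$times, nshuf)
    q <- 1 - alpha
    sig <- !is.na(r_obs) &&
      all(abs(r_obs) > vapply(list(shuf1, shuf2, shuf3),
                              function(s) stats::quantile(abs(s), q, na.rm = TRUE, names = FALSE),
                              numeric(1)))
    pv <- vapply(list(shuf1, shuf2, shuf3), function(s) {
      (1 + sum(abs(s) >= abs(r_obs), na.rm = TRUE)) / (1 + sum(!is.na(s)))
    }, numeric(1))
    res[[paste0("track", tr)]] <- list(r = r_obs, abs_r = abs(r_obs),
                                       p = pv, significant = isTRUE(sig))
  }
  structure(res, class = "rk_replay_score")
}

# shuffle 1: independent circular time-shift of each unit's count vector,
# re-decoded (joint two-track normalization), scored on track `tr`.
shuffle_spike_trains <- function(counts, maps, tau, tr, xpos, times, nshuf, config) {
  N <- nrow(counts); B <- ncol(counts)
  big <- matrix(0, N, B * nshuf)
  colbase <- matrix(0:(B - 1), N, B, byrow = TRUE)
  rowi <- rep(seq_len(N), times = B)
  for (s in seq_len(nshuf)) {
    k <- sample.int(B, N, replace = TRUE) - 1L
    M <- ((colbase - k) %% B) + 1L
    big[, ((s - 1L) * B + 1L):(s * B)] <- counts[cbind(rowi, as.vector(M))]
  }
  rownames(big) <- rownames(counts)
  post <- decode_posterior(big, maps, tau, rate_floor = config$rate_floor_hz)
  wcorr_blocks(post$prob[post$track == tr, , drop = FALSE], xpos, times, B, nshuf)
}

# shuffle 2: circular spatial shift of each ratemap of the scored track,
# re-decoded with the other track's maps intact. Shifted log-maps for all
# shuffles are stacked so the decode is a single matrix product.
shuffle_place_fields <- function(counts, maps, tau, tr, xpos, times, nshuf, config) {
  uid <- rownames(counts)
  floorr <- config$rate_floor_hz
  R_tr <- maps[[as.character(tr)]]$rate[uid, , drop = FALSE]
  other <- setdiff(names(maps), as.character(tr))
  N <- nrow(R_tr); nb <- ncol(R_tr); B <- ncol(counts)
  L_tr <- log(pmax(R_tr, floorr))
  colbase <- matrix(0:(nb - 1), N, nb, byrow = TRUE)
  rowi <- rep(seq_len(N), times = nb)
  L_big <- matrix(0, N, nb * nshuf)
  E <- matrix(0, nb, nshuf)
  for (s in seq_len(nshuf)) {
    k <- sample.int(nb, N, replace = TRUE) - 1L
    gi <- cbind(rowi, as.vector(((colbase - k) %% nb) + 1L))
    L_big[, ((s - 1L) * nb + 1L):(s * nb)] <- L_tr[gi]
    E[, s] <- tau * colSums(matrix(R_tr[gi], N, nb))
  }
  lpb <- crossprod(L_big, counts)                     # (nb*nshuf) x B
  X <- matrix(aperm(array(lpb, c(nb, nshuf, B)), c(1, 3, 2)), nb, B * nshuf)
  X <- X - E[, rep(seq_len(nshuf), each = B)]
  if (length(other)) {
    R_ot <- maps[[other[1]]]$rate[uid, , drop = FALSE]
    L_ot <- log(pmax(R_ot, floorr))
    lp_ot <- crossprod(L_ot, counts) - tau * colSums(R_ot)
    Z <- rbind(X, lp_ot[, rep(seq_len(B), times = nshuf), drop = FALSE])
  } else {
    Z <- X
  }
  mx <- Z[cbind(max.col(t(Z), ties.method = "first"), seq_len(ncol(Z)))]
  P <- exp(sweep(Z, 2, mx))
  P <- sweep(P, 2, colSums(P), "/")
  wcorr_blocks(P[seq_len(nb), , drop = FALSE], xpos, times, B, nshuf)
}

# shuffle 3: independent circular shift of each time bin's posterior vector
# within the scored track (post-decoding).
shuffle_posterior_columns <- function(sub, xpos, times, nshuf) {
  nb <- nrow(sub); B <- ncol(sub)
  rows <- matrix(0:(nb - 1), nb, B)
  coli <- rep(seq_len(B), each = nb)
  big <- matrix(0, nb, B * nshuf)
  for (s in seq_len(nshuf)) {
    k <- sample.int(nb, B, replace = TRUE) - 1L
    M <- ((rows - rep(k, each = nb)) %% nb) + 1L
    big[, ((s - 1L) * B + 1L):(s * B)] <- sub[cbind(as.vector(M), coli)]
  }
  wcorr_blocks(big, xpos, times, B, nshuf)
}

#' Assign a significant event to a track via the Bayesian bias score
#'
#' An event significant for one track is assigned to it. An event
#' significant for both tracks (a multi-track event) is assigned by the
#' Bayesian bias score - the summed posterior mass of one track divided by
#' the total across tracks - and must exceed 0.6 for the winning track,
#' otherwise the event is discarded.
#'
#' @param score an `rk_replay_score`.
#' @param config an [analysis_config()].
#' @return list with `track_id` (1, 2, or NA), `status` in
#'   {"assigned", "multi_track_discarded", "not_significant", "not_scored"}.
#' @export
assign_track <- function(score, config = analysis_config()) {
  if (!isTRUE(score$scored)) return(list(track_id = NA_integer_, status = "not_scored"))
  s1 <- score$track1$significant; s2 <- score$track2$significant
  if (!s1 && !s2) return(list(track_id = NA_integer_, status = "not_significant"))
  if (s1 && !s2) return(list(track_id = 1L, status = "assigned"))
  if (s2 && !s1) return(list(track_id = 2L, status = "assigned"))
  b1 <- score$bias; b2 <- 1 - score$bias
  if (is.na(b1)) return(list(track_id = NA_integer_, status = "multi_track_discarded"))
  if (b1 > config$bias_threshold) return(list(track_id = 1L, status = "assigned"))
  if (b2 > config$bias_threshold) return(list(track_id = 2L, status = "assigned"))
  list(track_id = NA_integer_, status = "multi_track_discarded")
}

#' Split a failed candidate event at its multi-unit activity trough
#'
#' For events that fail whole-event significance, the midpoint is the
#' minimum of the smoothed multi-unit activity within the middle third of
#' the event (ties resolve to the centre). Each half that still satisfies
#' the candidate criteria (duration and unit count) is decoded and scored
#' independently at alpha = 0.025.
#'
#' @param spikes spike table.
#' @param event one-row candidate event.
#' @param mua `rk_mua` covering the event.
#' @param maps decode maps, as in [score_significance()].
#' @param config an [analysis_config()].
#' @param seed optional integer for reproducible shuffles.
#' @return list of half-event records (possibly empty): each has
#'   `start_s`, `end_s`, `score` (an `rk_replay_score`), `assignment`.
#' @export
split_event <- function(spikes, event, mua, maps, config = analysis_config(),
                        seed = NULL) {
  tt <- mua_time(mua)
  dur <- event$end_s - event$start_s
  lo <- event$start_s + dur / 3
  hi <- event$start_s + 2 * dur / 3
  sel <- which(tt >= lo & tt <= hi)
  if (!length(sel)) return(list())
  zmid <- mua$z[sel]
  mins <- which(zmid == min(zmid))
  mid_i <- mins[ceiling(length(mins) / 2)]      # tie-break: centre
  midpoint <- tt[sel[mid_i]]
  halves <- list(list(start_s = event$start_s, end_s = midpoint),
                 list(start_s = midpoint, end_s = event$end_s))
  out <- list()
  for (h in halves) {
    d <- h$end_s - h$start_s
    if (d < config$event_min_dur_s || d > config$event_max_dur_s) next
    uu <- unique(spikes$unit_id[spikes$time_s >= h$start_s & spikes$time_s < h$end_s])
    if (length(uu) < config$event_min_units) next
    sc <- score_significance(spikes, h, maps, config,
                             alpha = config$alpha_split, seed = seed)
    out[[length(out) + 1]] <- list(start_s = h$start_s, end_s = h$end_s,
                                   score = sc,
                                   assignment = assign_track(sc, config))
  }
  out
}

#' Label the behavioral state of an assigned replay event
#'
#' Events in rest epochs (PRE/POST) are *sleep* replay when they fall in a
#' putative-sleep minute bin (speed < 4 cm/s with multi-unit z > 0),
#' otherwise *rest* replay. Events in run epochs are *awake-local* when the
#' decoded track matches the track the animal is on, else *awake-remote*.
#'
#' @param event_time event start time (s).
#' @param track_id assigned track (1 or 2).
#' @param epochs the session's epoch table.
#' @param sleep_masks named list of `rk_sleep_mask` per rest epoch label.
#' @return one of "sleep", "rest", "awake-local", "awake-remote".
#' @export
label_state <- function(event_time, track_id, epochs, sleep_masks) {
  i <- which(epochs$start_s <= event_time & event_time < epochs$end_s)
  if (!length(i)) stop("event outside any epoch")
  lab <- epochs$label[i[1]]
  if (grepl("^RUN", lab)) {
    cur <- as.integer(sub(".*_T", "", lab))
    return(if (!is.na(track_id) && track_id == cur) "awake-local" else "awake-remote")
  }
  mask <- sleep_masks[[lab]]
  if (is.null(mask)) return("rest")
  b <- which(mask$bin_start_s <= event_time & event_time < mask$bin_end_s)
  if (length(b) && mask$sleep[b[1]]) "sleep" else "rest"
}

#' Decoding-independent SWR classification by track-selective cells
#'
#' Labels candidate SWR events as track-1 or track-2 reactivation when the
#' proportion of that track's selective place cells (cells with a field on
#' only one track) active in the event is at least 20 percentage points
#' greater than the other track's proportion. For the non-overlapping
#' population of dual-track cells, per-epoch-phase (PRE/RUN/POST)
#' differences in firing rate and participation between track-1- and
#' track-2-labelled events are returned.
#'
#' @param events candidate-event data.frame with `start_s`, `end_s`,
#'   `units` list column.
#' @param roster classification roster from [classify_units()].
#' @param spikes spike table.
#' @param epochs session epoch table.
#' @param config an [analysis_config()].
#' @return list with `event_labels` (per event: NA, 1, or 2) and
#'   `cell_stats` (per dual cell per phase: rate and participation
#'   differences, track 1 minus track 2).
#' @export
classify_swr_by_selective_cells <- function(events, roster, spikes, epochs,
                                            config = analysis_config()) {
  sel1 <- roster$unit_id[roster$place_t1 & !roster$place_t2]
  sel2 <- roster$unit_id[roster$place_t2 & !roster$place_t1]
  dual <- roster$unit_id[roster$place_t1 & roster$place_t2]
  n_ev <- NROW(events)
  if (!length(sel1) || !length(sel2) || n_ev == 0) {
    return(list(event_labels = rep(NA_integer_, n_ev),
                cell_stats = data.frame()))
  }
  labels <- rep(NA_integer_, n_ev)
  for (i in seq_len(n_ev)) {
    uu <- events$units[[i]]
    p1 <- length(intersect(uu, sel1)) / length(sel1)
    p2 <- length(intersect(uu, sel2)) / length(sel2)
    if (p1 >= p2 + config$swr_selective_margin) labels[i] <- 1L
    else if (p2 >= p1 + config$swr_selective_margin) labels[i] <- 2L
  }
  phase_of <- function(tt) {
    lab <- epochs$label[findInterval(tt, epochs$start_s)]
    ifelse(lab == "PRE", "PRE", ifelse(grepl("^RUN", lab), "RUN", "POST"))
  }
  ev_phase <- phase_of(events$start_s)
  stats_rows <- list()
  for (ph in c("PRE", "RUN", "POST")) {
    for (tr in 1:2) {
      idx <- which(ev_phase == ph & labels == tr)
      assign(paste0("idx", tr), idx)
    }
    if (!length(idx1) || !length(idx2)) next
    dur1 <- sum(events$end_s[idx1] - events$start_s[idx1])
    dur2 <- sum(events$end_s[idx2] - events$start_s[idx2])
    for (u in dual) {
      in_ev <- function(idx) {
        vapply(idx, function(i) {
          sum(spikes$unit_id == u & spikes$time_s >= events$start_s[i] &
                spikes$time_s < events$end_s[i])
        }, numeric(1))
      }
      c1 <- in_ev(idx1); c2 <- in_ev(idx2)
      stats_rows[[length(stats_rows) + 1]] <- data.frame(
        unit_id = u, phase = ph,
        rate_diff_hz = sum(c1) / dur1 - sum(c2) / dur2,
        participation_diff = mean(c1 > 0) - mean(c2 > 0))
    }
  }
  list(event_labels = labels,
       cell_stats = if (length(stats_rows)) do.call(rbind, stats_rows) else data.frame())
}
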