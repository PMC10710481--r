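#' Clean raw position tracking
#'
#' Removes tracking glitches by two rules applied against the last retained
#' sample: a maximum distance jump of `jump_limit` cm between consecutive
#' samples, and an implied speed above `speed_limit` cm/s. Discarded samples
#' are replaced by linear interpolation at their original timestamps, so the
#' output has the same time base as the input. Cleaning is idempotent.
#'
#' @param raw data.frame with `time_s`, `x_cm`, `y_cm`.
#' @param jump_limit cm (default 40).
#' @param speed_limit cm/s (default 100).
#' @return cleaned data.frame of the same shape.
#' @export
clean_position <- function(raw, jump_limit = 40, speed_limit = 100) {
  if (nrow(raw) < 2) stop("need at least 2 position samples")
  n <- nrow(raw)
  keep <- logical(n)
  keep[1] <- TRUE
  last <- 1L
  for (i in 2:n) {
    d <- sqrt((raw$x_cm[i] - raw$x_cm[last])^2 + (raw$y_cm[i] - raw$y_cm[last])^2)
    dt <- raw$time_s[i] - raw$time_s[last]
    if (d <= jump_limit && (dt <= 0 || d / dt <= speed_limit)) {
      keep[i] <- TRUE
      last <- i
    }
  }
  if (sum(keep) < 2) stop("tracking unusable: all position samples discarded")
  out <- raw
  out$x_cm <- stats::approx(raw$time_s[keep], raw$x_cm[keep], xout = raw$time_s, rule = 2)$y
  out$y_cm <- stats::approx(raw$time_s[keep], raw$y_cm[keep], xout = raw$time_s, rule = 2)$y
  out
}

#' Linearize position onto a track and compute speed
#'
#' Projects 2-D position samples onto the track axis, giving the distance
#' travelled along the track, and computes instantaneous speed as the
#' centred-difference derivative of the linearized coordinate. Samples far
#' off the track axis (rest box) are flagged `on_track = FALSE`.
#'
#' @param cleaned cleaned position data.frame (`time_s`, `x_cm`, `y_cm`).
#' @param track one row of a session's `tracks` table.
#' @param off_track_cm perpendicular distance beyond which a sample is
#'   considered off the track (default 30 cm).
#' @return data.frame `time_s`, `lin_cm`, `speed_cms`, `on_track`.
#' @export
linearize_position <- function(cleaned, track, off_track_cm = 30) {
  vx <- track$x1 - track$x0
  vy <- track$y1 - track$y0
  len2 <- vx^2 + vy^2
  if (len2 <= 0) stop("degenerate track geometry")
  px <- cleaned$x_cm - track$x0
  py <- cleaned$y_cm - track$y0
  f <- pmin(1, pmax(0, (px * vx + py * vy) / len2))
  lin <- f * track$length_cm
  perp <- sqrt(pmax(0, px^2 + py^2 - (f * sqrt(len2))^2))
  n <- nrow(cleaned)
  tt <- cleaned$time_s
  speed <- numeric(n)
  if (n > 2) {
    # position is smoothed before differentiating so tracking jitter does
    # not masquerade as movement
    dt <- stats::median(diff(tt))
    lin_s <- moving_average(lin, round(0.4 / dt))
    speed[2:(n - 1)] <- abs(lin_s[3:n] - lin_s[1:(n - 2)]) / (tt[3:n] - tt[1:(n - 2)])
    speed[1] <- speed[2]; speed[n] <- speed[n - 1]
  }
  data.frame(time_s = tt, lin_cm = lin, speed_cms = speed,
             on_track = perp <= off_track_cm)
}

#' Segment behavior on a track: laps, immobility, mobility
#'
#' A lap is one full out-and-back traversal: starting from one end zone
#' (within `endzone_cm` of a track end, the reward-zone span), visiting the
#' opposite end zone and returning. Immobile time is the total time with
#' (smoothed) speed below `immobility_speed`; mobile time is the remainder,
#' so the two sum to the epoch duration.
#'
#' @param lin linearized position (from [linearize_position()]).
#' @param epoch list(start, end) or a row of the epochs table; the samples
#'   are restricted to this window.
#' @param track_length cm.
#' @param immobility_speed cm/s (default 4).
#' @param endzone_cm end-zone span for lap detection (default 20).
#' @param smooth_s moving-average window applied to speed before
#'   thresholding (default 0.4 s; 0 disables).
#' @return list with `summary` (one-row data.frame: laps, time_immobile_s,
#'   time_mobile_s, mean_moving_speed_cms, duration_s) and `laps`
#'   (lap index, start_s, end_s).
#' @export
segment_behavior <- function(lin, epoch, track_length,
                             immobility_speed = 4, endzone_cm = 20,
                             smooth_s = 0.4) {
  start <- epoch$start_s %||% epoch$start
  end <- epoch$end_s %||% epoch$end
  sel <- lin$time_s >= start & lin$time_s < end
  if (sum(sel) < 2) stop("epoch shorter than one position sample")
  d <- lin[sel, ]
  dt <- stats::median(diff(d$time_s))
  spd <- d$speed_cms
  if (smooth_s > 0) spd <- moving_average(spd, round(smooth_s / dt))
  dur <- end - start
  immobile <- sum(spd < immobility_speed) * dt
  immobile <- min(immobile, dur)
  moving <- spd >= immobility_speed

  # lap detection: walk the sequence of end-zone visits
  zone <- ifelse(d$lin_cm < endzone_cm, 1L,
                 ifelse(d$lin_cm > track_length - endzone_cm, 2L, 0L))
  vis_i <- which(zone != 0L)
  laps <- data.frame(lap = integer(0), start_s = numeric(0), end_s = numeric(0))
  if (length(vis_i)) {
    z <- zone[vis_i]
    chg <- c(TRUE, diff(z) != 0L)
    z <- z[chg]; zi <- vis_i[chg]      # compressed visit sequence
    home <- z[1]
    nlap <- 0L
    k <- 1L
    while (k + 2L <= length(z)) {
      # z[k] == home, z[k+1] == other, z[k+2] == home completes a lap
      nlap <- nlap + 1L
      laps <- rbind(laps, data.frame(lap = nlap,
                                     start_s = d$time_s[zi[k]],
                                     end_s = d$time_s[zi[k + 2L]]))
      k <- k + 2L
    }
  }
  summary <- data.frame(
    laps = nrow(laps),
    time_immobile_s = immobile,
    time_mobile_s = dur - immobile,
    mean_moving_speed_cms = if (any(moving)) mean(spd[moving]) else 0,
    duration_s = dur)
  list(summary = summary, laps = laps)
}

#' Behavior summary for all run epochs of a session
#'
#' Cleans, linearizes and segments each RUN epoch of the session with the
#' configured thresholds.
#'
#' @param session an `rk_session`.
#' @param config an [analysis_config()].
#' @return list with `summary` (one row per run epoch), `laps`, and `linpos`
#'   (named list of linearized-position frames per run epoch).
#' @export
summarize_behavior <- function(session, config = analysis_config()) {
  # clean within each epoch: the carry between rest box and track is a
  # teleport for the jump rule, so cleaning never spans epoch boundaries
  pos <- do.call(rbind, lapply(seq_len(nrow(session$epochs)), function(i) {
    sel <- session$position$time_s >= session$epochs$start_s[i] &
      session$position$time_s < session$epochs$end_s[i]
    clean_position(session$position[sel, ], config$pos_jump_limit_cm,
                   config$pos_speed_limit_cms)
  }))
  rownames(pos) <- NULL
  run_epochs <- session$epochs[grepl("^RUN", session$epochs$label), ]
  summaries <- list(); laps <- list(); linpos <- list()
  for (i in seq_len(nrow(run_epochs))) {
    lab <- run_epochs$label[i]
    tr <- as.integer(sub(".*_T", "", lab))
    track <- session$tracks[session$tracks$track_id == tr, ]
    sel <- pos$time_s >= run_epochs$start_s[i] & pos$time_s < run_epochs$end_s[i]
    lp <- linearize_position(pos[sel, ], track)
    seg <- segment_behavior(lp, list(start = run_epochs$start_s[i],
                                     end = run_epochs$end_s[i]),
                            track$length_cm,
                            config$immobility_speed_cms, config$endzone_cm,
                            config$speed_smooth_s)
    s <- seg$summary
    s$epoch <- lab; s$track_id <- tr
    summaries[[lab]] <- s
    if (nrow(seg$laps)) { seg$laps$epoch <- lab; seg$laps$track_id <- tr }
    laps[[lab]] <- seg$laps
    linpos[[lab]] <- lp
  }
  list(summary = do.call(rbind, summaries),
       laps = do.call(rbind, laps[vapply(laps, nrow, 1L) > 0]),
       linpos = linpos,
       position = pos)
}

# speed over the whole session (2-D, from cleaned positions) as a function
# usable in any epoch (rest box included).
session_speed <- function(position, smooth_s = 0.4, max_speed = 100) {
  n <- nrow(position)
  tt <- position$time_s
  w <- round(max(smooth_s, 0.4) / stats::median(diff(tt)))
  xs <- moving_average(position$x_cm, w)   # de-jitter before differentiating
  ys <- moving_average(position$y_cm, w)
  dx <- c(0, sqrt(diff(xs)^2 + diff(ys)^2))
  dt <- c(Inf, diff(tt))
  spd <- pmin(dx / dt, max_speed)   # caps epoch-boundary teleports
  spd[1] <- spd[2]
  if (smooth_s > 0) spd <- moving_average(spd, round(smooth_s / stats::median(diff(tt))))
  list(time_s = tt, speed_cms = spd)
}
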