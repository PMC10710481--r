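#' Run the full replay analysis on a session
#'
#' Orchestrates every stage: position cleaning/linearization and behavior
#' segmentation; LFP channel selection and ripple-band filtering; unit and
#' place-cell classification; unsmoothed 10-cm decoding maps per exposure;
#' decoding quality control on the re-exposures; putative-sleep scoring of
#' the rest epochs; candidate SWR/MUA event detection in every epoch;
#' weighted-correlation significance scoring against the three shuffle
#' nulls (with splitting of failed events); track assignment and
#' behavioral-state labelling; optional theta-sequence detection on the run
#' epochs; and the session metric table.
#'
#' Events in PRE/RUN1/POST1 are decoded with the first-exposure maps,
#' events in RUN2/POST2 with the re-exposure maps. Multi-unit and ripple
#' z-scores are baselined per epoch; in run epochs the baseline is
#' restricted to immobility (speed at or below the event speed ceiling) so
#' locomotor theta firing does not mask immobility bursts.
#'
#' @param session an `rk_session`.
#' @param config an [analysis_config()].
#' @param do_theta run the theta-sequence stage (default TRUE).
#' @param epochs restrict candidate detection to these epoch labels
#'   (default: all seven).
#' @return list with `behavior`, `channels`, `roster`, `maps`
#'   (per exposure), `qc`, `sleep_masks`, `candidates`, `events`, `theta`,
#'   `theta_counts`, `metrics`, `config`.
#' @export
run_replay_analysis <- function(session, config = analysis_config(),
                                do_theta = TRUE, epochs = NULL) {
  behavior <- summarize_behavior(session, config)
  speed <- session_speed(behavior$position, config$speed_smooth_s)
  chans <- select_channels(session$lfp, config)
  ripple_band <- band_filter_hilbert(session$lfp[[chans$ripple]],
                                     config$ripple_band_hz,
                                     order = config$filter_order,
                                     smooth_s = config$ripple_smooth_s)
  roster <- classify_units(session, behavior$linpos, config)
  place_units <- roster$unit_id[roster$place_t1 | roster$place_t2]
  if (length(place_units) < 2) stop("fewer than 2 place cells")

  decode_maps <- function(labs) {
    stats::setNames(lapply(1:2, function(tr) {
      lab <- labs[tr]
      compute_ratemaps(session$spikes, behavior$linpos[[lab]], place_units,
                       session$tracks$length_cm[tr],
                       bin_cm = config$bin_size_decode_cm,
                       speed_window = c(config$place_speed_min_cms,
                                        config$place_speed_max_cms),
                       smooth_sd_bins = 0)
    }), c("1", "2"))
  }
  maps <- list(exp1 = decode_maps(c("RUN1_T1", "RUN1_T2")),
               exp2 = decode_maps(c("RUN2_T1", "RUN2_T2")))
  qc <- decoding_qc(session, behavior$linpos, maps$exp2, place_units, config)

  top_u <- top_units_by_count(session$spikes, session$units, config$sleep_top_frac)
  rest_epochs <- intersect(c("PRE", "POST1", "POST2"), session$epochs$label)
  sleep_masks <- stats::setNames(lapply(rest_epochs, function(lab) {
    w <- epoch_window(session, lab)
    m <- mua_zscore(session$spikes, w, config, units = top_u)
    detect_putative_sleep(speed, m, w, config)
  }), rest_epochs)

  scan_epochs <- epochs %||% session$epochs$label
  immobile <- list(time_s = speed$time_s,
                   ok = speed$speed_cms <= config$event_speed_max_cms)
  cand_list <- list(); ev_rows <- list(); ev_counter <- 0L
  for (lab in scan_epochs) {
    w <- epoch_window(session, lab)
    is_run <- grepl("^RUN", lab)
    bl <- if (is_run) immobile else NULL
    mua_all <- mua_zscore(session$spikes, w, config, baseline_times = bl)
    rz <- ripple_zscore(ripple_band, w, baseline_times = bl)
    cands <- detect_candidates(session$spikes, mua_all, rz, speed, w, config)
    if (nrow(cands)) cands$epoch <- lab
    cand_list[[lab]] <- cands
    use_maps <- if (lab %in% c("PRE", "RUN1_T1", "RUN1_T2", "POST1")) maps$exp1 else maps$exp2
    for (i in seq_len(nrow(cands))) {
      ev_counter <- ev_counter + 1L
      ev <- cands[i, ]
      sc <- score_significance(session$spikes, ev, use_maps, config,
                               seed = mix_seed(config$seed, 100000L + ev_counter))
      asg <- assign_track(sc, config)
      recs <- list(list(ev = ev, sc = sc, asg = asg, split = FALSE))
      if (asg$status == "not_significant") {
        halves <- split_event(session$spikes, ev, mua_all, use_maps, config,
                              seed = mix_seed(config$seed, 200000L + ev_counter))
        for (h in halves) {
          if (h$assignment$status == "assigned") {
            uu <- unique(session$spikes$unit_id[session$spikes$time_s >= h$start_s &
                                                  session$spikes$time_s < h$end_s])
            hev <- data.frame(start_s = h$start_s, end_s = h$end_s,
                              duration_s = h$end_s - h$start_s,
                              peak_mua_z = ev$peak_mua_z,
                              peak_ripple_z = ev$peak_ripple_z,
                              n_units = length(uu), units = I(list(sort(uu))),
                              epoch = lab)
            recs <- c(recs, list(list(ev = hev, sc = h$score,
                                      asg = h$assignment, split = TRUE)))
          }
        }
        recs <- recs[-1]          # drop the failed whole event from output?
        recs <- c(list(list(ev = ev, sc = sc, asg = asg, split = FALSE)), recs)
      }
      for (r in recs) {
        sc <- r$sc
        ev_rows[[length(ev_rows) + 1L]] <- data.frame(
          start_s = r$ev$start_s, end_s = r$ev$end_s, epoch = lab,
          n_units = r$ev$n_units, n_bins = sc$n_bins %||% NA_integer_,
          scored = isTRUE(sc$scored),
          r_t1 = if (isTRUE(sc$scored)) sc$track1$r else NA_real_,
          r_t2 = if (isTRUE(sc$scored)) sc$track2$r else NA_real_,
          sig_t1 = isTRUE(sc$scored) && sc$track1$significant,
          sig_t2 = isTRUE(sc$scored) && sc$track2$significant,
          bias_t1 = if (isTRUE(sc$scored)) sc$bias else NA_real_,
          track_id = r$asg$track_id, status = r$asg$status,
          split = r$split, units = I(list(r$ev$units[[1]])))
      }
    }
  }
  candidates <- do.call(rbind, cand_list[vapply(cand_list, nrow, 1L) > 0])
  if (is.null(candidates)) candidates <- cbind(empty_candidates(), epoch = character(0))
  rownames(candidates) <- NULL
  events <- if (length(ev_rows)) do.call(rbind, ev_rows) else NULL
  if (!is.null(events)) {
    events$state <- NA_character_
    for (i in which(!is.na(events$track_id))) {
      events$state[i] <- label_state(events$start_s[i], events$track_id[i],
                                     session$epochs, sleep_masks)
    }
    rownames(events) <- NULL
  }

  theta <- list(); theta_counts <- NULL
  if (do_theta) {
    run_labs <- intersect(c("RUN1_T1", "RUN1_T2", "RUN2_T1", "RUN2_T2"),
                          session$epochs$label)
    tc_rows <- list()
    for (lab in run_labs) {
      tr <- as.integer(sub(".*_T", "", lab))
      uid <- roster$unit_id[roster[[paste0("place_t", tr)]]]
      laps <- behavior$laps[behavior$laps$epoch == lab, , drop = FALSE]
      if (length(uid) < config$theta_min_units || !nrow(laps)) next
      th <- detect_theta_sequences(session, behavior$linpos[[lab]], laps, uid,
                                   lab, chans$theta, config)
      theta[[lab]] <- th
      tc_rows[[lab]] <- data.frame(epoch = lab, track_id = tr,
                                   n_cycles = th$n_cycles,
                                   n_sequences = th$n_significant)
    }
    theta_counts <- if (length(tc_rows)) do.call(rbind, tc_rows) else NULL
  }

  assigned <- if (!is.null(events)) {
    events[!is.na(events$track_id), , drop = FALSE]
  } else {
    data.frame(start_s = numeric(0), end_s = numeric(0), epoch = character(0),
               track_id = integer(0), state = character(0))
  }
  metrics <- compute_session_metrics(assigned, candidates, sleep_masks,
                                     behavior, theta_counts, config)
  list(behavior = behavior, channels = chans, roster = roster, maps = maps,
       qc = qc, sleep_masks = sleep_masks, candidates = candidates,
       events = events, theta = theta, theta_counts = theta_counts,
       metrics = metrics, config = config)
}

#' Per-dual-cell awake/sleep replay participation differences
#'
#' For each dual-track place cell, counts the local awake replay events the
#' cell spiked in (track 1 minus track 2) and its sleep replay
#' participation rate difference in the given POST epoch, producing the
#' table consumed by [per_cell_replay_regression()].
#'
#' @param events assigned event table (with `units` list column and
#'   `state`).
#' @param roster roster from [classify_units()].
#' @param post_epoch POST epoch label whose sleep events are used.
#' @param window_s sleep window length used as the rate denominator.
#' @return data.frame with `unit_id`, `awake_diff`, `sleep_rate_diff`.
#' @export
dual_cell_replay_table <- function(events, roster, post_epoch = "POST1",
                                   window_s = 1800) {
  dual <- roster$unit_id[roster$place_t1 & roster$place_t2]
  if (!length(dual)) return(data.frame())
  part_count <- function(ev, u) {
    if (!NROW(ev)) return(rep(0, length(u)))
    vapply(u, function(x) sum(vapply(ev$units, function(s) x %in% s, logical(1))), numeric(1))
  }
  awake <- events[!is.na(events$state) & events$state == "awake-local", , drop = FALSE]
  run_phase <- if (post_epoch == "POST1") c("RUN1_T1", "RUN1_T2") else c("RUN2_T1", "RUN2_T2")
  awake <- awake[awake$epoch %in% run_phase, , drop = FALSE]
  sleep <- events[!is.na(events$state) & events$state == "sleep" &
                    events$epoch == post_epoch, , drop = FALSE]
  a1 <- part_count(awake[awake$track_id == 1, ], dual)
  a2 <- part_count(awake[awake$track_id == 2, ], dual)
  s1 <- part_count(sleep[sleep$track_id == 1, ], dual)
  s2 <- part_count(sleep[sleep$track_id == 2, ], dual)
  data.frame(unit_id = dual, awake_diff = a1 - a2,
             sleep_rate_diff = (s1 - s2) / window_s)
}
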