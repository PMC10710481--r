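#' Session-level replay, theta and behavior metrics
#'
#' Computes per-track headline quantities: sleep replay rate over the first
#' 30 min of cumulative sleep of each POST epoch (events divided by 30 min;
#' when less sleep exists the rate uses the available time and is flagged),
#' rest replay rate (rest-labelled events per second of non-sleep POST
#' time), local awake replay count and rate (events per second of immobile
#' time on the track), candidate SWR counts/rates on the track, theta
#' cycle/sequence counts, time on track, the cumulative replay bias trace
#' (track 1 minus track 2 event counts against cumulative sleep time), and
#' the replay-rate decay slope (rate per 10-min cumulative-sleep bin).
#'
#' @param events labelled event table (columns `start_s`, `end_s`, `epoch`,
#'   `track_id`, `state`; only assigned events are counted).
#' @param candidates candidate-event table with `epoch` (for awake SWR
#'   counts).
#' @param sleep_masks named list of `rk_sleep_mask` per rest epoch.
#' @param behavior behavior summary from [summarize_behavior()].
#' @param theta_counts optional data.frame (`epoch`, `track_id`,
#'   `n_cycles`, `n_sequences`).
#' @param config an [analysis_config()].
#' @return list with `sleep` (per POST epoch x track), `awake` (per run
#'   epoch x track), `bias` (per POST epoch: cumulative-bias trace), and
#'   `decay` (per POST epoch x track: rate-vs-sleep-time slope).
#' @export
compute_session_metrics <- function(events, candidates, sleep_masks, behavior,
                                    theta_counts = NULL,
                                    config = analysis_config()) {
  win_s <- config$sleep_window_s
  sleep_rows <- list()
  bias <- list()
  decay_rows <- list()
  for (ep in intersect(c("POST1", "POST2"), names(sleep_masks))) {
    mask <- sleep_masks[[ep]]
    sw <- sleep_window(mask, win_s)
    denom <- if (sw$complete) win_s else sw$total_s
    in_win <- function(tt) {
      if (!nrow(sw$intervals)) return(rep(FALSE, length(tt)))
      rowSums(outer(tt, sw$intervals$start_s, ">=") &
                outer(tt, sw$intervals$end_s, "<")) > 0
    }
    ep_ev <- events[events$epoch == ep & !is.na(events$track_id), , drop = FALSE]
    total_sleep <- max(mask$cum_sleep_s)
    ep_dur <- max(mask$bin_end_s) - min(mask$bin_start_s)
    rest_time <- ep_dur - total_sleep
    for (tr in 1:2) {
      tr_ev <- ep_ev[ep_ev$track_id == tr, , drop = FALSE]
      slp <- tr_ev[tr_ev$state == "sleep", , drop = FALSE]
      n_sleep_win <- sum(in_win(slp$start_s))
      n_rest <- sum(tr_ev$state == "rest")
      sleep_rows[[paste(ep, tr)]] <- data.frame(
        epoch = ep, track_id = tr,
        sleep_count_win = n_sleep_win,
        sleep_rate = if (denom > 0) n_sleep_win / denom else NA_real_,
        rest_count = n_rest,
        rest_rate = if (rest_time > 0) n_rest / rest_time else NA_real_,
        window_complete = sw$complete)
    }
    # cumulative bias over sleep bins (track 1 minus track 2)
    sl_bins <- mask[mask$sleep, , drop = FALSE]
    if (nrow(sl_bins)) {
      count_in_bin <- function(tr) {
        slp <- ep_ev[ep_ev$track_id == tr & ep_ev$state == "sleep", , drop = FALSE]
        vapply(seq_len(nrow(sl_bins)), function(b) {
          sum(slp$start_s >= sl_bins$bin_start_s[b] & slp$start_s < sl_bins$bin_end_s[b])
        }, numeric(1))
      }
      c1 <- count_in_bin(1); c2 <- count_in_bin(2)
      bias[[ep]] <- data.frame(cum_sleep_s = sl_bins$cum_sleep_s,
                               bias = cumsum(c1) - cumsum(c2))
      # decay slope: rate per 10-min cumulative-sleep bin
      for (tr in 1:2) {
        cc <- if (tr == 1) c1 else c2
        gb <- floor((sl_bins$cum_sleep_s - 1e-9) / 600)
        rate_bin <- tapply(cc, gb, sum) / tapply(rep(config$sleep_bin_s, length(gb)), gb, sum)
        mid <- (as.numeric(names(rate_bin)) + 0.5) * 600
        slope <- if (length(rate_bin) >= 2) {
          unname(stats::coef(stats::lm(as.numeric(rate_bin) ~ mid))[2])
        } else NA_real_
        decay_rows[[paste(ep, tr)]] <- data.frame(epoch = ep, track_id = tr,
                                                  decay_slope = slope)
      }
    }
  }
  awake_rows <- list()
  bs <- behavior$summary
  for (i in seq_len(NROW(bs))) {
    ep <- bs$epoch[i]; tr <- bs$track_id[i]
    ev <- events[events$epoch == ep, , drop = FALSE]
    n_local <- sum(ev$state == "awake-local", na.rm = TRUE)
    n_swr <- sum(candidates$epoch == ep)
    imm <- bs$time_immobile_s[i]
    row <- data.frame(epoch = ep, track_id = tr,
                      awake_local_count = n_local,
                      awake_local_rate = if (imm > 0) n_local / imm else NA_real_,
                      swr_count = n_swr,
                      swr_rate = if (imm > 0) n_swr / imm else NA_real_,
                      time_on_track_s = bs$duration_s[i],
                      time_immobile_s = imm)
    if (!is.null(theta_counts)) {
      tc <- theta_counts[theta_counts$epoch == ep, , drop = FALSE]
      row$theta_cycles <- if (nrow(tc)) tc$n_cycles[1] else NA_integer_
      row$theta_sequences <- if (nrow(tc)) tc$n_sequences[1] else NA_integer_
    }
    awake_rows[[i]] <- row
  }
  list(sleep = do.call(rbind, sleep_rows),
       awake = do.call(rbind, awake_rows),
       bias = bias,
       decay = if (length(decay_rows)) do.call(rbind, decay_rows) else NULL)
}

#' Simple linear regression report
#'
#' Ordinary least squares of `y` on `x`, reporting the slope, adjusted R
#' squared (as `r2`, matching the convention of reporting explained
#' variance adjusted for model size; the unadjusted value is `r2_plain`),
#' the two-sided p-value and n.
#'
#' @param x,y numeric vectors (>= 3 finite pairs).
#' @return data.frame with `r2`, `r2_plain`, `p`, `n`, `slope`,
#'   `intercept`.
#' @export
regress_simple <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 points")
  if (stats::sd(x) == 0) stop("zero variance in x")
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  p <- if (nrow(sm$coefficients) > 1) sm$coefficients[2, 4] else NA_real_
  data.frame(r2 = sm$adj.r.squared, r2_plain = sm$r.squared, p = p,
             n = length(x), slope = unname(stats::coef(fit)[2]),
             intercept = unname(stats::coef(fit)[1]))
}

#' Random-intercept mixed-effect regression on standardized variables
#'
#' Fits `response ~ predictors + (1 | group)` after converting the response
#' and every predictor to z-scores, so the standardized beta coefficients
#' compare the relative weight of each fixed effect. 95% confidence
#' intervals are Wald intervals; a predictor is significant when its CI
#' excludes zero. Singular fits are reported with a warning flag.
#'
#' @param data data.frame containing all variables.
#' @param response response column name.
#' @param predictors character vector of fixed-effect column names.
#' @param group grouping column name (random intercept, e.g. animal id).
#' @return list with `coefficients` (term, beta, ci_lo, ci_hi,
#'   significant), `singular`, `n`, `fit`.
#' @export
regress_mixed <- function(data, response, predictors, group) {
  if (length(unique(data[[group]])) < 2) stop("need >= 2 grouping levels")
  d <- data
  for (v in c(response, predictors)) {
    s <- stats::sd(d[[v]])
    d[[v]] <- if (is.finite(s) && s > 0) (d[[v]] - mean(d[[v]])) / s else d[[v]] * 0
  }
  if (stats::sd(d[[response]]) == 0) {
    co <- data.frame(term = predictors, beta = 0, ci_lo = 0, ci_hi = 0,
                     significant = FALSE)
    return(list(coefficients = co, singular = TRUE, n = nrow(d), fit = NULL))
  }
  fml <- stats::as.formula(paste(response, "~",
                                 paste(predictors, collapse = " + "),
                                 "+ (1 |", group, ")"))
  fit <- lme4::lmer(fml, data = d)
  singular <- lme4::isSingular(fit)
  ci <- stats::confint(fit, method = "Wald")
  fe <- lme4::fixef(fit)
  rows <- lapply(predictors, function(p) {
    data.frame(term = p, beta = unname(fe[p]),
               ci_lo = ci[p, 1], ci_hi = ci[p, 2],
               significant = ci[p, 1] > 0 | ci[p, 2] < 0)
  })
  list(coefficients = do.call(rbind, rows), singular = singular,
       n = nrow(d), fit = fit)
}

#' Per-cell awake-to-sleep replay regression for one session
#'
#' For dual-track place cells, regresses each cell's difference in sleep
#' replay participation rate (track 1 minus track 2) on its difference in
#' local awake replay participation count (track 1 minus track 2). Sessions
#' with fewer than 5 dual-track cells are skipped with a flag.
#'
#' @param cells data.frame with `awake_diff` and `sleep_rate_diff` per
#'   dual-track cell.
#' @return data.frame with `skipped`, and when fitted `r2`, `p`, `slope`,
#'   `n`.
#' @export
per_cell_replay_regression <- function(cells) {
  if (NROW(cells) < 5) {
    return(data.frame(skipped = TRUE, r2 = NA_real_, p = NA_real_,
                      slope = NA_real_, n = NROW(cells)))
  }
  fit <- regress_simple(cells$awake_diff, cells$sleep_rate_diff)
  data.frame(skipped = FALSE, r2 = fit$r2, p = fit$p, slope = fit$slope,
             n = fit$n)
}

#' Paired two-sided Wilcoxon signed-rank comparison between tracks
#'
#' @param t1,t2 paired per-session values for tracks 1 and 2.
#' @return list with `statistic`, `p`, `n`.
#' @export
compare_tracks <- function(t1, t2) {
  stopifnot(length(t1) == length(t2))
  d <- t1 - t2
  if (all(d == 0)) return(list(statistic = 0, p = 1, n = length(d)))
  wt <- suppressWarnings(stats::wilcox.test(t1, t2, paired = TRUE,
                                            alternative = "two.sided"))
  list(statistic = unname(wt$statistic), p = wt$p.value, n = length(d))
}

#' Metric-level batch generator for regression parameter recovery
#'
#' Draws per-session, per-track metric sets in which the sleep replay rate
#' is driven only by the awake replay count (slope `beta` on z-scales) plus
#' an animal-level random intercept and noise; the other candidate
#' predictors vary but carry no effect. Used to verify that the mixed model
#' recovers the true driver.
#'
#' @param n_animals number of animals.
#' @param n_sessions sessions per animal.
#' @param beta true standardized effect of awake replay number.
#' @param sigma residual s.d. on the z-scale (default 0.4).
#' @param seed RNG seed.
#' @return data.frame with columns `animal`, `sleep_rate`, `awake_rate`,
#'   `awake_number`, `theta_sequences`, `time_on_track`.
#' @export
simulate_metric_batch <- function(n_animals = 4, n_sessions = 10, beta = 0.6,
                                  sigma = 0.4, seed = 1) {
  set.seed(seed)
  rows <- list()
  for (a in seq_len(n_animals)) {
    u_a <- rnorm(1, 0, 0.3)
    for (s in seq_len(n_sessions)) {
      awake_number <- rnorm(1)
      awake_rate <- rnorm(1)
      theta_seq <- rnorm(1)
      time_on_track <- rnorm(1)
      y <- u_a + beta * awake_number + sigma * rnorm(1)
      rows[[length(rows) + 1]] <- data.frame(
        animal = factor(a), sleep_rate = y, awake_rate = awake_rate,
        awake_number = awake_number, theta_sequences = theta_seq,
        time_on_track = time_on_track)
    }
  }
  do.call(rbind, rows)
}
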