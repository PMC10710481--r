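# Shared fixtures: one small synthetic session reused across test files
# (built once per test run), plus independent brute-force oracles.

.fixture_env <- new.env(parent = emptyenv())

small_synth_config <- function(seed = 7, ...) {
  synthetic_config(seed = seed, n_cells_per_track = 15, n_interneurons = 3,
                   n_laps_t1 = 4, n_laps_t2 = 2, pre_duration = 100,
                   sleep_duration = 360, run2_duration = 220,
                   pause_mean_s = 7, ...)
}

small_session <- function() {
  if (is.null(.fixture_env$ss)) {
    .fixture_env$ss <- simulate_session(small_synth_config())
  }
  .fixture_env$ss
}

small_behavior <- function() {
  if (is.null(.fixture_env$beh)) {
    .fixture_env$beh <- summarize_behavior(small_session()$session, analysis_config())
  }
  .fixture_env$beh
}

small_roster <- function() {
  if (is.null(.fixture_env$roster)) {
    .fixture_env$roster <- classify_units(small_session()$session,
                                          small_behavior()$linpos,
                                          analysis_config())
  }
  .fixture_env$roster
}

small_decode_maps <- function(exposure = 1) {
  key <- paste0("maps", exposure)
  if (is.null(.fixture_env[[key]])) {
    ss <- small_session()
    roster <- small_roster()
    pu <- roster$unit_id[roster$place_t1 | roster$place_t2]
    labs <- paste0("RUN", exposure, "_T", 1:2)
    .fixture_env[[key]] <- stats::setNames(lapply(1:2, function(tr) {
      compute_ratemaps(ss$session$spikes, small_behavior()$linpos[[labs[tr]]],
                       pu, 200, bin_cm = 10, speed_window = c(4, 50))
    }), c("1", "2"))
  }
  .fixture_env[[key]]
}

# --- independent oracles ---------------------------------------------------

# Direct evaluation of the naive Bayes posterior: for each time bin,
# P(x) * prod_i f_i(x)^n_i * exp(-tau * sum_i f_i(x)), normalized.
decode_oracle <- function(counts, rates, tau, rate_floor = 0.01, prior = NULL) {
  nb <- ncol(rates); nt <- ncol(counts)
  if (is.null(prior)) prior <- rep(1 / nb, nb)
  post <- matrix(0, nb, nt)
  for (j in seq_len(nt)) {
    for (b in seq_len(nb)) {
      p <- prior[b]
      for (i in seq_len(nrow(rates))) {
        p <- p * max(rates[i, b], rate_floor)^counts[i, j]
      }
      post[b, j] <- p * exp(-tau * sum(rates[, b]))
    }
    post[, j] <- post[, j] / sum(post[, j])
  }
  post
}

# Direct evaluation of the weighted mean/covariance/correlation sums.
wcorr_oracle <- function(prob, x = seq_len(nrow(prob)), t = seq_len(ncol(prob))) {
  W <- 0; Sx <- 0; St <- 0
  M <- nrow(prob); N <- ncol(prob)
  for (i in seq_len(M)) for (j in seq_len(N)) {
    W <- W + prob[i, j]
    Sx <- Sx + prob[i, j] * x[i]
    St <- St + prob[i, j] * t[j]
  }
  mx <- Sx / W; mt <- St / W
  cxt <- 0; cxx <- 0; ctt <- 0
  for (i in seq_len(M)) for (j in seq_len(N)) {
    cxt <- cxt + prob[i, j] * (x[i] - mx) * (t[j] - mt)
    cxx <- cxx + prob[i, j] * (x[i] - mx)^2
    ctt <- ctt + prob[i, j] * (t[j] - mt)^2
  }
  (cxt / W) / sqrt((cxx / W) * (ctt / W))
}

# Reference position-cleaning scan: keep a sample only when both rules hold
# against the last kept sample, then interpolate.
clean_oracle <- function(raw, jump = 40, vmax = 100) {
  keep <- 1L
  for (i in 2:nrow(raw)) {
    l <- keep[length(keep)]
    d <- sqrt((raw$x_cm[i] - raw$x_cm[l])^2 + (raw$y_cm[i] - raw$y_cm[l])^2)
    dt <- raw$time_s[i] - raw$time_s[l]
    if (d <= jump && (dt <= 0 || d / dt <= vmax)) keep <- c(keep, i)
  }
  out <- raw
  out$x_cm <- approx(raw$time_s[keep], raw$x_cm[keep], raw$time_s, rule = 2)$y
  out$y_cm <- approx(raw$time_s[keep], raw$y_cm[keep], raw$time_s, rule = 2)$y
  out
}

# Reference alternating-extrema scan over a filtered trace.
extrema_oracle <- function(f, thr) {
  cand <- list()
  for (i in 2:(length(f) - 1)) {
    if (f[i] > f[i - 1] && f[i] >= f[i + 1] && f[i] > thr) {
      cand[[length(cand) + 1]] <- list(i = i, type = "peak")
    } else if (f[i] < f[i - 1] && f[i] <= f[i + 1] && f[i] < -thr) {
      cand[[length(cand) + 1]] <- list(i = i, type = "trough")
    }
  }
  keep <- list()
  for (c_ in cand) {
    k <- length(keep)
    if (k > 0 && keep[[k]]$type == c_$type) {
      better <- if (c_$type == "peak") f[c_$i] > f[keep[[k]]$i] else f[c_$i] < f[keep[[k]]$i]
      if (better) keep[[k]] <- c_
    } else {
      keep[[length(keep) + 1]] <- c_
    }
  }
  data.frame(index = vapply(keep, function(e) e$i, 1),
             type = vapply(keep, function(e) e$type, ""))
}

# Flat-rate Poisson spike table over a window (structureless events).
poisson_spikes <- function(unit_ids, start, end, rate) {
  rows <- lapply(unit_ids, function(u) {
    n <- rpois(1, rate * (end - start))
    if (n == 0) return(NULL)
    data.frame(unit_id = u, time_s = sort(runif(n, start, end)))
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) out <- data.frame(unit_id = integer(0), time_s = numeric(0))
  out[order(out$unit_id, out$time_s), ]
}
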