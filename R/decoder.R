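#' Bin spike counts in non-overlapping windows
#'
#' @param spikes spike table (`unit_id`, `time_s`).
#' @param unit_ids units (row order of the count matrix).
#' @param start,end window bounds (s); the last partial bin is dropped.
#' @param tau window length (s).
#' @return list with `counts` (units x windows matrix) and `times` (window
#'   centers, s).
#' @export
bin_spike_counts <- function(spikes, unit_ids, start, end, tau) {
  nb <- floor((end - start) / tau + 1e-9)
  if (nb < 1) stop("window shorter than one time bin")
  sp <- spikes[spikes$unit_id %in% unit_ids &
                 spikes$time_s >= start & spikes$time_s < start + nb * tau, ]
  bj <- floor((sp$time_s - start) / tau) + 1L
  counts <- unclass(table(factor(sp$unit_id, levels = unit_ids),
                          factor(bj, levels = seq_len(nb))))
  dimnames(counts) <- list(unit_ids, NULL)
  list(counts = counts, times = start + (seq_len(nb) - 0.5) * tau)
}

#' Naive Bayes position decoding from spike counts
#'
#' For each time window of length tau, the posterior over position bins is
#' proportional to `P(x) * prod_i f_i(x)^n_i * exp(-tau * sum_i f_i(x))`,
#' where `f_i(x)` is unit i's (unsmoothed) ratemap and `n_i` its spike
#' count. Computed in log space, and normalized jointly across the
#' concatenated position bins of all supplied tracks, so each time-bin
#' column sums to 1 over both tracks.
#'
#' @param counts units x windows spike-count matrix (rownames = unit ids).
#' @param maps list of `rk_ratemaps` (one per track, named or indexed by
#'   track id); each must contain rows for every counting unit.
#' @param tau window length (s).
#' @param rate_floor floor (Hz) applied inside the `f_i(x)^n_i` term only,
#'   so empty unsmoothed bins do not produce `log(0)`.
#' @param prior prior over concatenated bins (`NULL` = uniform).
#' @param times optional window-center times carried through.
#' @return object of class `rk_posterior`: `prob` (concatenated bins x
#'   windows, columns sum to 1), `track` (track id per bin), `pos_cm`
#'   (within-track bin center per bin), `tau`, `times`, `counts`.
#' @export
decode_posterior <- function(counts, maps, tau, rate_floor = 0.01,
                             prior = NULL, times = NULL) {
  uid <- rownames(counts)
  Rs <- lapply(maps, function(m) {
    r <- if (inherits(m, "rk_ratemaps")) m$rate else m
    if (!all(uid %in% rownames(r))) stop("mismatched unit sets between counts and maps")
    r[uid, , drop = FALSE]
  })
  track_ids <- as.integer(if (!is.null(names(maps))) names(maps) else seq_along(maps))
  nb <- vapply(Rs, ncol, 1L)
  track <- rep(track_ids, nb)
  pos <- unlist(lapply(seq_along(Rs), function(k) {
    bc <- if (inherits(maps[[k]], "rk_ratemaps")) maps[[k]]$bin_cm else NA
    if (is.na(bc)) seq_len(nb[k]) - 0.5 else (seq_len(nb[k]) - 0.5) * bc
  }), use.names = FALSE)
  R <- do.call(cbind, Rs)                          # units x all bins
  L <- log(pmax(R, rate_floor))
  E <- tau * colSums(R)
  logpost <- crossprod(L, counts) - E              # bins x windows
  if (!is.null(prior)) logpost <- logpost + log(prior)
  mx <- logpost[cbind(max.col(t(logpost), ties.method = "first"),
                      seq_len(ncol(logpost)))]
  pr <- exp(sweep(logpost, 2, mx))
  pr <- sweep(pr, 2, colSums(pr), "/")
  structure(list(prob = pr, track = track, pos_cm = pos, tau = tau,
                 times = times, counts = counts),
            class = "rk_posterior")
}

# posterior sub-matrix for one track
posterior_track <- function(post, track_id) {
  post$prob[post$track == track_id, , drop = FALSE]
}

#' Decoding error and session quality control
#'
#' Decodes run-epoch spikes in non-overlapping 250-ms windows with the
#' unsmoothed 10-cm maps, and measures the difference between the animal's
#' true location and the maximum-a-posteriori position. Windows where the
#' MAP bin falls on the wrong track score the track length (a cap). A
#' session passes when the median error on the tested epochs is at or below
#' the 15-cm bound.
#'
#' @param session an `rk_session`.
#' @param linpos named list of per-epoch linearized positions.
#' @param maps list of `rk_ratemaps` per track (unsmoothed, 10-cm bins).
#' @param unit_ids decoding units (place cells).
#' @param config an [analysis_config()].
#' @param epochs epoch labels to test (default the two re-exposures).
#' @return list of class `rk_qc`: `median_error_cm` (per epoch), `errors`,
#'   `confusion` (true-bin x decoded-bin counts), `pass`.
#' @export
decoding_qc <- function(session, linpos, maps, unit_ids,
                        config = analysis_config(),
                        epochs = c("RUN2_T1", "RUN2_T2")) {
  errs <- list()
  nbins <- sum(vapply(maps, function(m) ncol(m$rate), 1L))
  confusion <- matrix(0L, nbins, nbins)
  for (lab in epochs) {
    if (!lab %in% names(linpos)) stop("no run windows: epoch ", lab, " missing")
    w <- epoch_window(session, lab)
    tr <- as.integer(sub(".*_T", "", lab))
    bc <- bin_spike_counts(session$spikes, unit_ids, w$start, w$end, config$tau_run_s)
    post <- decode_posterior(bc$counts, maps, config$tau_run_s,
                             rate_floor = config$rate_floor_hz, times = bc$times)
    lp <- linpos[[lab]]
    true_pos <- stats::approx(lp$time_s, lp$lin_cm, xout = bc$times, rule = 2)$y
    spd <- stats::approx(lp$time_s, lp$speed_cms, xout = bc$times, rule = 2)$y
    moving <- spd > config$place_speed_min_cms
    map_bin <- apply(post$prob, 2, which.max)
    err <- ifelse(post$track[map_bin] == tr,
                  abs(post$pos_cm[map_bin] - true_pos),
                  session$tracks$length_cm[tr])
    errs[[lab]] <- err[moving]
    # confusion over concatenated bins, moving windows only
    tb_local <- pmin(ncol(maps[[tr]]$rate),
                     floor(true_pos / maps[[tr]]$bin_cm) + 1L)
    offset <- if (tr == 1L) 0L else ncol(maps[[1]]$rate)
    tb <- tb_local + offset
    for (i in which(moving)) confusion[tb[i], map_bin[i]] <- confusion[tb[i], map_bin[i]] + 1L
  }
  med <- vapply(errs, stats::median, numeric(1))
  if (!length(unlist(errs))) stop("no run windows to score")
  structure(list(median_error_cm = med, errors = errs, confusion = confusion,
                 pass = all(med <= config$qc_max_median_error_cm)),
            class = "rk_qc")
}
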