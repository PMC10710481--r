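#' Construct a recording session
#'
#' A session bundles the raw observables of one two-track recording day:
#' sorted unit spike times (with waveform half-width-at-half-max, used to
#' separate principal cells from narrow-waveform units), 2-D position
#' samples, LFP traces, the seven-epoch protocol table
#' (PRE, RUN1_T1, RUN1_T2, POST1, RUN2_T1, RUN2_T2, POST2) and the track
#' geometries. Times are in seconds from session start, positions in cm,
#' intervals are half-open `[start, end)`.
#'
#' @param units data.frame with columns `unit_id`, `half_width_us`,
#'   `mean_rate_hz`.
#' @param spikes data.frame with columns `unit_id`, `time_s` (sorted
#'   ascending within unit).
#' @param position data.frame with columns `time_s`, `x_cm`, `y_cm`.
#' @param lfp list of traces, each a list with `channel_id`, `fs` (Hz),
#'   `start_s`, and numeric `samples` (microvolt). May be empty.
#' @param epochs data.frame with columns `label`, `start_s`, `end_s`;
#'   non-overlapping and in chronological order.
#' @param tracks data.frame with columns `track_id`, `length_cm`,
#'   `x0`, `y0`, `x1`, `y1` (endpoint coordinates).
#' @return object of class `rk_session`.
#' @export
rk_session <- function(units, spikes, position, lfp, epochs, tracks) {
  s <- structure(
    list(units = units, spikes = spikes, position = position,
         lfp = lfp, epochs = epochs, tracks = tracks),
    class = "rk_session")
  validate_session(s)
}

EPOCH_LABELS <- c("PRE", "RUN1_T1", "RUN1_T2", "POST1", "RUN2_T1", "RUN2_T2", "POST2")

validate_session <- function(s) {
  stopifnot(is.data.frame(s$units), is.data.frame(s$spikes),
            is.data.frame(s$position), is.data.frame(s$epochs),
            is.data.frame(s$tracks), is.list(s$lfp))
  if (nrow(s$spikes)) {
    ord <- order(s$spikes$unit_id, s$spikes$time_s)
    by_unit <- split(s$spikes$time_s, s$spikes$unit_id)
    if (any(vapply(by_unit, is.unsorted, logical(1)))) {
      stop("invalid spike train: spike times must be sorted ascending within unit")
    }
  }
  e <- s$epochs
  if (nrow(e) > 1) {
    if (is.unsorted(e$start_s, strictly = TRUE)) stop("invalid epochs: not in chronological order")
    if (any(e$start_s[-1] < e$end_s[-nrow(e)])) stop("invalid epochs: overlapping intervals")
  }
  if (any(e$end_s <= e$start_s)) stop("invalid epochs: end <= start")
  span_end <- max(e$end_s)
  if (nrow(s$spikes) && (any(s$spikes$time_s < 0) || any(s$spikes$time_s > span_end))) {
    stop("invalid spike train: spike outside the session span")
  }
  s
}

#' @export
print.rk_session <- function(x, ...) {
  cat("<rk_session> ", nrow(x$units), " units, ", nrow(x$spikes), " spikes, ",
      nrow(x$epochs), " epochs, ", length(x$lfp), " LFP channel(s), span ",
      round(max(x$epochs$end_s), 1), " s\n", sep = "")
  invisible(x)
}

#' Restrict a spike table to a time window
#' @param spikes spike data.frame (`unit_id`, `time_s`).
#' @param start,end half-open window bounds (s).
#' @return spike data.frame subset.
#' @export
spikes_in_window <- function(spikes, start, end) {
  spikes[spikes$time_s >= start & spikes$time_s < end, , drop = FALSE]
}

#' Look up one epoch interval
#' @param session an `rk_session`.
#' @param label one of the seven protocol labels.
#' @return list(start, end).
#' @export
epoch_window <- function(session, label) {
  i <- match(label, session$epochs$label)
  if (is.na(i)) stop("no epoch labelled '", label, "'")
  list(start = session$epochs$start_s[i], end = session$epochs$end_s[i])
}

#' Write a session to a directory
#'
#' Writes `session.json` (manifest: units, epochs, tracks, LFP metadata),
#' `spikes.tsv`, `position.tsv` and one raw little-endian float32 file per
#' LFP channel. Bit-stable for a fixed session.
#'
#' @param session an `rk_session`.
#' @param path directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  lfp_meta <- lapply(session$lfp, function(ch) {
    list(channel_id = ch$channel_id, fs = ch$fs, start_s = ch$start_s %||% 0,
         file = paste0("lfp_", ch$channel_id, ".f32"), n = length(ch$samples))
  })
  manifest <- list(
    format = "replaykit-session", version = 1L,
    files = list(spikes = "spikes.tsv", position = "position.tsv"),
    units = session$units, epochs = session$epochs, tracks = session$tracks,
    lfp = lfp_meta)
  writeLines(jsonlite::toJSON(manifest, digits = NA, auto_unbox = TRUE, pretty = TRUE),
             file.path(path, "session.json"))
  utils::write.table(session$spikes, file.path(path, "spikes.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(session$position, file.path(path, "position.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  for (ch in session$lfp) {
    con <- file(file.path(path, paste0("lfp_", ch$channel_id, ".f32")), "wb")
    writeBin(as.numeric(ch$samples), con, size = 4, endian = "little")
    close(con)
  }
  invisible(path)
}

#' Read a session from a directory written by [write_session()]
#'
#' All session invariants (sorted spikes, ordered non-overlapping epochs,
#' spikes inside the session span) are re-checked on load.
#'
#' @param path session directory containing `session.json`.
#' @return an `rk_session`.
#' @export
read_session <- function(path) {
  mf <- file.path(path, "session.json")
  if (!file.exists(mf)) stop("missing component: session.json")
  manifest <- jsonlite::fromJSON(mf, simplifyDataFrame = TRUE)
  for (k in c("units", "epochs", "tracks", "files")) {
    if (is.null(manifest[[k]])) stop("missing component: manifest lacks '", k, "'")
  }
  spk_file <- file.path(path, manifest$files$spikes)
  pos_file <- file.path(path, manifest$files$position)
  if (!file.exists(spk_file)) stop("missing component: ", manifest$files$spikes)
  if (!file.exists(pos_file)) stop("missing component: ", manifest$files$position)
  spikes <- utils::read.table(spk_file, header = TRUE, sep = "\t")
  position <- utils::read.table(pos_file, header = TRUE, sep = "\t")
  lfp <- list()
  lm <- manifest$lfp
  if (!is.null(lm) && NROW(lm) > 0) {
    lm <- as.data.frame(lm)
    for (i in seq_len(nrow(lm))) {
      f <- file.path(path, lm$file[i])
      if (!file.exists(f)) stop("missing component: ", lm$file[i])
      con <- file(f, "rb")
      samples <- readBin(con, numeric(), n = lm$n[i], size = 4, endian = "little")
      close(con)
      lfp[[i]] <- list(channel_id = lm$channel_id[i], fs = lm$fs[i],
                       start_s = lm$start_s[i], samples = samples)
    }
  }
  rk_session(units = as.data.frame(manifest$units),
             spikes = spikes, position = position, lfp = lfp,
             epochs = as.data.frame(manifest$epochs),
             tracks = as.data.frame(manifest$tracks))
}
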