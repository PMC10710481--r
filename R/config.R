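#' Analysis configuration
#'
#' Bundles every numeric threshold used by the pipeline, defaulting to the
#' values the analysis was designed around. Pass named overrides to change
#' any of them; unknown names raise an error so typos are caught early.
#'
#' Key groups:
#' * position cleaning: `pos_jump_limit_cm` (40), `pos_speed_limit_cms` (100)
#' * behavior: `immobility_speed_cms` (4), `speed_smooth_s` (0.4),
#'   `endzone_cm` (20, reward-zone span used for lap detection)
#' * unit classification: `hwhm_min_us` (500), `principal_max_rate_hz` (5),
#'   `place_peak_min_hz` (1), `place_speed_min_cms` (4), `place_speed_max_cms` (50)
#' * ratemaps: `bin_size_decode_cm` (10), `bin_size_viz_cm` (2),
#'   `map_smooth_sd_bins` (1)
#' * decoding: `tau_run_s` (0.25), `tau_replay_s` (0.02), `tau_theta_s` (0.01),
#'   `rate_floor_hz` (0.01), `qc_max_median_error_cm` (15)
#' * candidate events: `mua_bin_s` (0.001), `mua_smooth_sd_s` (0.005),
#'   `mua_z_thresh` (3), `mua_burst_max_s` (0.3), `ripple_z_thresh` (3),
#'   `ripple_smooth_s` (0.1), `event_merge_gap_s` (0.05),
#'   `event_speed_max_cms` (5), `event_min_units` (5), `event_min_dur_s` (0.1),
#'   `event_max_dur_s` (0.75)
#' * significance: `n_shuffles` (1000), `alpha` (0.05), `alpha_split` (0.025),
#'   `bias_threshold` (0.6)
#' * sleep scoring: `sleep_bin_s` (60), `sleep_speed_max_cms` (4),
#'   `sleep_mua_z_min` (0), `sleep_top_frac` (1/3), `sleep_window_s` (1800)
#' * LFP: `theta_band_hz` (4-12), `ripple_band_hz` (125-300),
#'   `delta_band_hz` (1-4), `filter_order` (4), `psd_window_s` (2),
#'   `psd_overlap` (0.5)
#' * theta sequences: `theta_cycle_min_s` (0.08), `theta_cycle_max_s` (0.2),
#'   `theta_speed_min_cms` (5), `theta_prominence_frac` (0.25),
#'   `theta_min_units` (2), `theta_center_cm` (40), `theta_max_cycles` (Inf)
#' * decoding-free SWR classification: `swr_selective_margin` (0.2)
#'
#' @param ... named overrides of any default listed above.
#' @return an object of class `rk_config` (named list).
#' @export
analysis_config <- function(...) {
  defaults <- list(
    seed = 1L,
    # position cleaning / behavior
    pos_jump_limit_cm = 40,
    pos_speed_limit_cms = 100,
    immobility_speed_cms = 4,
    speed_smooth_s = 0.4,
    endzone_cm = 20,
    # unit classification
    hwhm_min_us = 500,
    principal_max_rate_hz = 5,
    place_peak_min_hz = 1,
    place_speed_min_cms = 4,
    place_speed_max_cms = 50,
    # ratemaps
    bin_size_decode_cm = 10,
    bin_size_viz_cm = 2,
    map_smooth_sd_bins = 1,
    # decoding
    tau_run_s = 0.25,
    tau_replay_s = 0.02,
    tau_theta_s = 0.01,
    rate_floor_hz = 0.01,
    qc_max_median_error_cm = 15,
    # candidate replay events
    mua_bin_s = 0.001,
    mua_smooth_sd_s = 0.005,
    mua_z_thresh = 3,
    mua_burst_max_s = 0.3,
    ripple_z_thresh = 3,
    ripple_smooth_s = 0.1,
    event_merge_gap_s = 0.05,
    event_speed_max_cms = 5,
    event_min_units = 5,
    event_min_dur_s = 0.1,
    event_max_dur_s = 0.75,
    # shuffle significance
    n_shuffles = 1000L,
    alpha = 0.05,
    alpha_split = 0.025,
    bias_threshold = 0.6,
    # putative sleep
    sleep_bin_s = 60,
    sleep_speed_max_cms = 4,
    sleep_mua_z_min = 0,
    sleep_top_frac = 1 / 3,
    sleep_window_s = 1800,
    # LFP
    theta_band_hz = c(4, 12),
    ripple_band_hz = c(125, 300),
    delta_band_hz = c(1, 4),
    filter_order = 4L,
    psd_window_s = 2,
    psd_overlap = 0.5,
    # theta sequences
    theta_cycle_min_s = 0.08,
    theta_cycle_max_s = 0.2,
    theta_speed_min_cms = 5,
    theta_prominence_frac = 0.25,
    theta_min_units = 2,
    theta_center_cm = 40,
    theta_max_cycles = Inf,
    # decoding-independent SWR classification
    swr_selective_margin = 0.2
  )
  overrides <- list(...)
  if (length(overrides)) {
    if (is.null(names(overrides)) || any(names(overrides) == "")) {
      stop("all configuration overrides must be named")
    }
    unknown <- setdiff(names(overrides), names(defaults))
    if (length(unknown)) {
      stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
    }
    defaults <- utils::modifyList(defaults, overrides)
  }
  check_config(defaults)
  structure(defaults, class = "rk_config")
}

check_config <- function(cfg) {
  dimensional <- c(
    "pos_jump_limit_cm", "pos_speed_limit_cms", "speed_smooth_s", "endzone_cm",
    "hwhm_min_us", "principal_max_rate_hz", "place_peak_min_hz",
    "bin_size_decode_cm", "bin_size_viz_cm", "tau_run_s", "tau_replay_s",
    "tau_theta_s", "rate_floor_hz", "qc_max_median_error_cm", "mua_bin_s",
    "mua_smooth_sd_s", "mua_burst_max_s", "ripple_smooth_s",
    "event_merge_gap_s", "event_min_dur_s", "event_max_dur_s", "sleep_bin_s",
    "sleep_window_s", "theta_cycle_min_s", "theta_cycle_max_s",
    "theta_center_cm"
  )
  for (k in dimensional) {
    if (!is.numeric(cfg[[k]]) || any(cfg[[k]] <= 0)) {
      stop("configuration key '", k, "' must be positive")
    }
  }
  if (cfg$n_shuffles < 1) stop("n_shuffles must be >= 1")
  invisible(cfg)
}

#' Load an analysis configuration from a YAML file
#'
#' Unspecified keys take their defaults (see [analysis_config()]); unknown
#' keys raise an error. An empty (or missing-content) file yields the full
#' default configuration.
#'
#' @param path path to a YAML file of key-value overrides.
#' @param quiet if `FALSE`, the fully resolved configuration is echoed via
#'   `message()` so every run logs the thresholds and seed it used.
#' @return an `rk_config` object.
#' @export
load_config <- function(path, quiet = TRUE) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  cfg <- do.call(analysis_config, raw)
  if (!quiet) {
    message("resolved configuration:")
    message(paste(utils::capture.output(utils::str(unclass(cfg))), collapse = "\n"))
  }
  cfg
}

#' @export
print.rk_config <- function(x, ...) {
  cat("<rk_config> ", length(x), " keys; seed=", x$seed,
      ", n_shuffles=", x$n_shuffles, "\n", sep = "")
  invisible(x)
}
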