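#' Simulation configuration for the synthetic drift generator
#'
#' Bundles every parameter of the synthetic longitudinal experiment: the
#' recording schedule (8 days at 2-day spacing, 2 environments, 5 trials of
#' 3 min at 20 Hz), the linear track geometry (96 cm, 24 bins of 4 cm), the
#' tuning and rate model of the simulated ensemble, the day-to-day drift
#' dynamics, and the optional fluorescence / footprint forward models.
#'
#' The drift model has three knobs. `recruitment_persistence` is the
#' probability that a cell active on one recording day is still active on the
#' next recording day (a 2-day step of a 2-state Markov chain whose stationary
#' activity level is `active_fraction`). `shared_drift_sigma` and
#' `env_drift_sigma` are per-calendar-day standard deviations of Gaussian
#' log-rate random walks; the shared walk is common to both environments and
#' carries the cross-environment "timestamp", the environment-specific walk is
#' private to each environment.
#'
#' @param n_cells number of simulated cells.
#' @param day_values calendar days of the recording schedule.
#' @param trials_per_session trials per (day, environment) session.
#' @param trial_duration trial length in seconds.
#' @param frame_rate imaging frame rate in Hz.
#' @param track_length linear track length in cm.
#' @param n_bins number of spatial bins (`n_bins * bin width = track_length`).
#' @param place_cell_fraction probability that a cell is place-tuned.
#' @param field_width place-field Gaussian sd in cm.
#' @param base_rate mean event rate of an active cell, events/s.
#' @param recruitment_persistence P(active on day d+2 | active on day d).
#' @param active_fraction stationary probability that a cell is active on a day.
#' @param env_active_prob probability that a day-active cell expresses events
#'   in a given environment (conditionally independent across environments).
#' @param shared_drift_sigma per-day sd of the shared log-rate random walk.
#' @param env_drift_sigma per-day sd of the environment-specific walk.
#' @param env_gain_sigma sd of a static per-cell, per-environment log-rate
#'   offset (rate remapping: cells express different rates in the two
#'   environments from day one).
#' @param shared_recruitment if `TRUE` (default) one recruitment chain per
#'   cell governs both environments (day-to-day turnover is coherent across
#'   environments); if `FALSE` each environment runs an independent chain,
#'   removing the recruitment component of the cross-environment timestamp.
#' @param remap_mode if `TRUE` field positions are drawn independently per
#'   environment (global remapping); if `FALSE` the two environments share
#'   field positions.
#' @param run_speed running speed in cm/s for the constant-speed lap model.
#' @param pause_mean mean dwell (s) of the exponential pauses at track ends.
#' @param amplitude_meanlog,amplitude_sdlog log-normal event-amplitude
#'   parameters (dF/F units).
#' @param kernel_rise,kernel_decay double-exponential calcium kernel time
#'   constants in seconds (`kernel_decay > kernel_rise`).
#' @param noise_sigma additive Gaussian trace noise sd, dF/F units.
#' @param fov_size field-of-view side in micrometers.
#' @param footprint_radius footprint Gaussian sd in micrometers.
#' @param footprint_jitter per-session, per-axis sd of a cell centroid's
#'   displacement from its base position, in micrometers.
#' @param min_cell_separation minimum distance between base centroids in
#'   micrometers (cell bodies exclude one another).
#' @param seed root seed; all stages derive named substreams from it.
#'
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_cells = 200,
                       day_values = seq(1, 15, by = 2),
                       trials_per_session = 5,
                       trial_duration = 180,
                       frame_rate = 20,
                       track_length = 96,
                       n_bins = 24,
                       place_cell_fraction = 0.7,
                       field_width = 5,
                       base_rate = 0.05,
                       recruitment_persistence = 0.8,
                       active_fraction = 0.6,
                       env_active_prob = 0.9,
                       shared_drift_sigma = 0.12,
                       env_drift_sigma = 0.06,
                       env_gain_sigma = 0.4,
                       shared_recruitment = TRUE,
                       remap_mode = TRUE,
                       run_speed = 20,
                       pause_mean = 1,
                       amplitude_meanlog = log(0.3),
                       amplitude_sdlog = 0.4,
                       kernel_rise = 0.05,
                       kernel_decay = 1,
                       noise_sigma = 0.02,
                       fov_size = 250,
                       footprint_radius = 6,
                       footprint_jitter = 1.5,
                       min_cell_separation = 15,
                       seed = 1L) {
  cfg <- list(
    n_cells = as.integer(n_cells), day_values = as.integer(day_values),
    n_days = length(day_values), trials_per_session = as.integer(trials_per_session),
    trial_duration = trial_duration, frame_rate = frame_rate,
    track_length = track_length, n_bins = as.integer(n_bins),
    bin_width = track_length / n_bins,
    place_cell_fraction = place_cell_fraction, field_width = field_width,
    base_rate = base_rate, recruitment_persistence = recruitment_persistence,
    active_fraction = active_fraction, env_active_prob = env_active_prob,
    shared_drift_sigma = shared_drift_sigma, env_drift_sigma = env_drift_sigma,
    env_gain_sigma = env_gain_sigma,
    shared_recruitment = isTRUE(shared_recruitment),
    remap_mode = isTRUE(remap_mode), run_speed = run_speed,
    pause_mean = pause_mean,
    amplitude_meanlog = amplitude_meanlog, amplitude_sdlog = amplitude_sdlog,
    kernel_rise = kernel_rise, kernel_decay = kernel_decay,
    noise_sigma = noise_sigma, fov_size = fov_size,
    footprint_radius = footprint_radius, footprint_jitter = footprint_jitter,
    min_cell_separation = min_cell_separation,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_cells < 1L) stop("n_cells must be positive")
  if (cfg$trial_duration <= 0 || cfg$frame_rate <= 0)
    stop("invalid config: trial duration and frame rate must be positive")
  if (cfg$trials_per_session < 1L) stop("trials_per_session must be positive")
  if (any(diff(cfg$day_values) <= 0)) stop("day_values must be increasing")
  probs <- c(cfg$place_cell_fraction, cfg$recruitment_persistence,
             cfg$active_fraction, cfg$env_active_prob)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  rates <- c(cfg$base_rate, cfg$shared_drift_sigma, cfg$env_drift_sigma,
             cfg$noise_sigma, cfg$footprint_jitter)
  if (any(rates < 0)) stop("rates and sigmas must be non-negative")
  if (cfg$track_length <= 0 || cfg$n_bins < 5L)
    stop("track must be positive with at least 5 bins")
  if (abs(cfg$n_bins * cfg$bin_width - cfg$track_length) > 1e-9)
    stop("n_bins * bin width must equal track_length")
  if (cfg$kernel_decay <= cfg$kernel_rise || cfg$kernel_rise <= 0)
    stop("kernel must satisfy kernel_decay > kernel_rise > 0")
  if (cfg$footprint_radius <= 0) stop("footprint_radius must be positive")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>", x$n_cells, "cells,", x$n_days, "days x 2 env x",
      x$trials_per_session, "trials,", x$track_length, "cm track\n")
  cat("  drift: persistence", x$recruitment_persistence,
      "shared sd", x$shared_drift_sigma, "env sd", x$env_drift_sigma,
      if (x$remap_mode) "(remapping)" else "(common fields)", "\n")
  invisible(x)
}

#' Deterministic named RNG substream
#'
#' Derives a stage-specific seed from a root seed and a stream name, so every
#' pipeline stage draws from its own reproducible stream independently of
#' which other stages run.
#'
#' @param seed integer root seed.
#' @param name character stream name.
#' @return an integer seed below 2^31.
#' @export
substream_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.numeric(seed) * 48271 + h * 16807) %% 2147483587)
}

session_key <- function(env, day) paste0(env, "_d", day)
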