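#' Simulate linearized-track trajectories for every session
#'
#' Constant-speed back-and-forth laps with exponentially distributed pauses at
#' the track ends (the ends are where rewards are consumed, so real animals
#' dwell there; the pauses exercise the running-speed filter and the end-bin
#' exclusion downstream). Direction flips only at the ends.
#'
#' @param config a [sim_config()].
#' @param seed optional integer; defaults to the config's trajectory substream.
#' @return a data.frame with one row per frame: `env`, `day`, `trial`,
#'   `frame`, `time_s` (within trial), `position_cm`, `velocity_cm_s`
#'   (signed), `direction` (`"left"`/`"right"`; the last running direction
#'   during pauses).
#' @export
simulate_trajectory <- function(config, seed = NULL) {
  validate_sim_config(config)
  if (is.null(seed)) seed <- substream_seed(config$seed, "trajectory")
  set.seed(seed)
  fr <- config$frame_rate
  n_frames <- round(config$trial_duration * fr)
  L <- config$track_length
  v <- config$run_speed
  step <- v / fr

  one_trial <- function() {
    pos <- numeric(0); vel <- numeric(0)
    cur <- 0; dir <- 1
    while (length(pos) < n_frames) {
      # one traversal
      k <- ceiling(L / step)
      seg <- cur + dir * step * seq_len(k)
      seg <- pmin(pmax(seg, 0), L)
      pos <- c(pos, seg)
      vel <- c(vel, rep(dir * v, k))
      cur <- seg[k]
      dir <- -dir
      if (config$pause_mean > 0) {
        p_frames <- round(stats::rexp(1, 1 / config$pause_mean) * fr)
        if (p_frames > 0) {
          pos <- c(pos, rep(cur, p_frames))
          vel <- c(vel, rep(0, p_frames))
        }
      }
    }
    list(pos = pos[seq_len(n_frames)], vel = vel[seq_len(n_frames)])
  }

  out <- vector("list", 2L * config$n_days * config$trials_per_session)
  i <- 0L
  for (env in c("A", "B")) for (day in config$day_values) {
    for (trial in seq_len(config$trials_per_session)) {
      tr <- one_trial()
      dir_lab <- ifelse(tr$vel > 0, "right", ifelse(tr$vel < 0, "left", NA))
      # carry last running direction through pauses
      dir_lab <- fill_forward(dir_lab, default = "right")
      i <- i + 1L
      out[[i]] <- data.frame(
        env = env, day = day, trial = trial, frame = seq_len(n_frames),
        time_s = (seq_len(n_frames) - 1) / fr,
        position_cm = tr$pos, velocity_cm_s = tr$vel,
        direction = dir_lab, stringsAsFactors = FALSE
      )
    }
  }
  traj <- do.call(rbind, out)
  rownames(traj) <- NULL
  traj
}

fill_forward <- function(x, default) {
  if (is.na(x[1])) x[1] <- default
  for (i in seq_along(x)[-1]) if (is.na(x[i])) x[i] <- x[i - 1]
  x
}

#' Build the generative ensemble model
#'
#' Each cell gets a tuning curve (Gaussian place field on top of a small
#' uniform floor, or flat for untuned cells), a base log-rate, a day-resolved
#' active flag from a 2-state Markov chain shared across environments
#' (persistence `recruitment_persistence` per 2-day step, stationary activity
#' `active_fraction`), an expression flag per environment, and two log-rate
#' random walks: one shared between environments and one private to each.
#' Field centers are constant across days; with `remap_mode` they are drawn
#' independently per environment.
#'
#' @param config a [sim_config()].
#' @param seed optional integer; defaults to the config's model substream.
#' @return an object of class `ensemble_model`.
#' @export
build_ensemble_model <- function(config, seed = NULL) {
  validate_sim_config(config)
  if (is.null(seed)) seed <- substream_seed(config$seed, "ensemble")
  set.seed(seed)
  n <- config$n_cells
  nd <- config$n_days
  days <- config$day_values

  is_place <- stats::runif(n) < config$place_cell_fraction
  lo <- 2 * config$bin_width + config$field_width
  hi <- config$track_length - lo
  center_A <- stats::runif(n, lo, hi)
  center_B <- if (config$remap_mode) stats::runif(n, lo, hi) else center_A
  base_log_rate <- log(config$base_rate) + stats::rnorm(n, 0, 0.3)

  # shared recruitment chain: persistence p per recording-day step,
  # stationary occupancy pi -> q01 = pi (1 - p) / (1 - pi)
  p11 <- config$recruitment_persistence
  pi0 <- config$active_fraction
  p01 <- if (pi0 >= 1) 1 else min(1, pi0 * (1 - p11) / (1 - pi0))
  markov_chain <- function() {
    a <- matrix(FALSE, n, nd)
    a[, 1] <- stats::runif(n) < pi0
    for (d in seq_len(nd)[-1]) {
      u <- stats::runif(n)
      a[, d] <- ifelse(a[, d - 1], u < p11, u < p01)
    }
    a
  }
  active <- array(FALSE, c(n, nd, 2), dimnames = list(NULL, NULL, c("A", "B")))
  if (config$shared_recruitment) {
    active_day <- markov_chain()
    for (e in 1:2)
      active[, , e] <- active_day & (matrix(stats::runif(n * nd), n, nd) <
                                       config$env_active_prob)
  } else {
    for (e in 1:2)
      active[, , e] <- markov_chain() &
        (matrix(stats::runif(n * nd), n, nd) < config$env_active_prob)
    active_day <- active[, , 1] | active[, , 2]
  }

  walk <- function(sigma) {
    eta <- matrix(0, n, nd)
    if (sigma > 0 && nd > 1) {
      for (d in 2:nd) {
        dt <- days[d] - days[d - 1]
        eta[, d] <- eta[, d - 1] + stats::rnorm(n, 0, sigma * sqrt(dt))
      }
    }
    eta
  }
  eta_shared <- walk(config$shared_drift_sigma)
  eta_env <- array(0, c(n, nd, 2), dimnames = list(NULL, NULL, c("A", "B")))
  eta_env[, , 1] <- walk(config$env_drift_sigma)
  eta_env[, , 2] <- walk(config$env_drift_sigma)
  env_gain <- matrix(stats::rnorm(2 * n, 0, config$env_gain_sigma), n, 2,
                     dimnames = list(NULL, c("A", "B")))

  model <- list(
    config = config, is_place = is_place,
    field_center = cbind(A = center_A, B = center_B),
    base_log_rate = base_log_rate,
    active_day = active_day, active = active,
    eta_shared = eta_shared, eta_env = eta_env, env_gain = env_gain
  )
  class(model) <- "ensemble_model"
  model
}

# tuning curve evaluated at positions x (cm) for one cell in one environment;
# position-averaged value is ~1 so base_rate is the mean rate of a lap
tuning_at <- function(model, cell, env, x) {
  cfg <- model$config
  if (!model$is_place[cell]) return(rep(1, length(x)))
  c0 <- model$field_center[cell, env]
  fw <- cfg$field_width
  floor_lvl <- 0.02
  g <- floor_lvl + exp(-(x - c0)^2 / (2 * fw^2))
  # normalize by the track-average so exp(log-rate) is the mean rate
  xs <- seq(0, cfg$track_length, length.out = 481)
  norm <- mean(floor_lvl + exp(-(xs - c0)^2 / (2 * fw^2)))
  g / norm
}

cell_log_rate <- function(model, cell, day_idx, env) {
  e <- match(env, c("A", "B"))
  model$base_log_rate[cell] + model$env_gain[cell, e] +
    model$eta_shared[cell, day_idx] + model$eta_env[cell, day_idx, e]
}

#' Simulate calcium events from the ensemble model and a trajectory
#'
#' Events are drawn from an inhomogeneous Poisson process whose intensity is
#' `active flag x exp(log-rate) x tuning(position)`; amplitudes are
#' log-normal. Event times sit on the frame grid of the trajectory.
#'
#' @param model an [build_ensemble_model()] result.
#' @param traj a trajectory from [simulate_trajectory()] covering the same
#'   sessions.
#' @param seed optional integer; defaults to the config's events substream.
#' @return an event table data.frame: `cell_id`, `env`, `day`, `trial`,
#'   `time_s`, `amplitude`, `position_cm`, `velocity_cm_s`, `direction`.
#' @export
simulate_events <- function(model, traj, seed = NULL) {
  stopifnot(inherits(model, "ensemble_model"))
  cfg <- model$config
  if (is.null(seed)) seed <- substream_seed(cfg$seed, "events")
  set.seed(seed)
  need <- expand.grid(day = cfg$day_values, env = c("A", "B"),
                      stringsAsFactors = FALSE)
  have <- unique(traj[, c("env", "day")])
  if (!all(paste(need$env, need$day) %in% paste(have$env, have$day)))
    stop("trajectory does not cover the model's sessions")

  dt <- 1 / cfg$frame_rate
  out <- list(); k <- 0L
  for (e in 1:2) {
    env <- c("A", "B")[e]
    for (d in seq_len(cfg$n_days)) {
      day <- cfg$day_values[d]
      ses <- traj[traj$env == env & traj$day == day, ]
      pos <- ses$position_cm
      cells <- which(model$active[, d, e])
      for (cell in cells) {
        lam <- exp(cell_log_rate(model, cell, d, env)) *
          tuning_at(model, cell, env, pos) * dt
        total <- sum(lam)
        n_ev <- stats::rpois(1, total)
        if (n_ev == 0) next
        idx <- sample.int(length(lam), n_ev, replace = TRUE, prob = lam)
        idx <- sort(idx)
        k <- k + 1L
        out[[k]] <- data.frame(
          cell_id = cell, env = env, day = day,
          trial = ses$trial[idx], time_s = ses$time_s[idx],
          amplitude = stats::rlnorm(n_ev, cfg$amplitude_meanlog,
                                    cfg$amplitude_sdlog),
          position_cm = pos[idx], velocity_cm_s = ses$velocity_cm_s[idx],
          direction = ses$direction[idx], stringsAsFactors = FALSE
        )
      }
    }
  }
  if (k == 0L) return(empty_event_table())
  ev <- do.call(rbind, out)
  ev <- ev[order(ev$env, ev$day, ev$trial, ev$time_s, ev$cell_id), ]
  rownames(ev) <- NULL
  ev
}

empty_event_table <- function() {
  data.frame(cell_id = integer(0), env = character(0), day = integer(0),
             trial = integer(0), time_s = numeric(0), amplitude = numeric(0),
             position_cm = numeric(0), velocity_cm_s = numeric(0),
             direction = character(0), stringsAsFactors = FALSE)
}

#' Double-exponential calcium kernel
#'
#' `k(t) = exp(-t/decay) - exp(-t/rise)`, scaled to unit peak. The analytic
#' peak time is `rise * decay / (decay - rise) * log(decay / rise)`.
#'
#' @param t times in seconds (t >= 0).
#' @param rise,decay time constants in seconds, `decay > rise > 0`.
#' @return kernel values, peak value 1.
#' @export
calcium_kernel <- function(t, rise, decay) {
  stopifnot(decay > rise, rise > 0)
  tpk <- rise * decay / (decay - rise) * log(decay / rise)
  pk <- exp(-tpk / decay) - exp(-tpk / rise)
  ifelse(t < 0, 0, (exp(-t / decay) - exp(-t / rise)) / pk)
}

#' Render dF/F traces from an event table
#'
#' Each event contributes `amplitude x calcium_kernel` at its frame; trials of
#' a session are concatenated (kernels do not bleed between trials), and
#' i.i.d. Gaussian noise of sd `noise_sigma` is added. The rendering is linear
#' in the event table.
#'
#' @param events an event table.
#' @param config the [sim_config()].
#' @param seed optional integer; defaults to the config's trace substream.
#' @param sessions character vector of session keys (`"A_d1"` style) to
#'   render; default all sessions in the schedule.
#' @return a named list of sessions, each a frames x cells matrix (columns =
#'   master cell ids 1..n_cells) with attribute `time_s`.
#' @export
render_fluorescence <- function(events, config, seed = NULL, sessions = NULL) {
  validate_sim_config(config)
  if (is.null(seed)) seed <- substream_seed(config$seed, "traces")
  set.seed(seed)
  fr <- config$frame_rate
  n_frames <- round(config$trial_duration * fr)
  total_frames <- n_frames * config$trials_per_session
  kern_t <- seq(0, 6 * config$kernel_decay, by = 1 / fr)
  kern <- calcium_kernel(kern_t, config$kernel_rise, config$kernel_decay)
  all_keys <- as.vector(outer(c("A", "B"), config$day_values, session_key))
  if (is.null(sessions)) sessions <- all_keys
  stopifnot(all(sessions %in% all_keys))

  out <- list()
  for (key in sessions) {
    parts <- strsplit(key, "_d")[[1]]
    env <- parts[1]; day <- as.integer(parts[2])
    tr <- matrix(0, total_frames, config$n_cells)
    ev <- events[events$env == env & events$day == day, , drop = FALSE]
    if (nrow(ev) > 0) {
      frame0 <- (ev$trial - 1) * n_frames + round(ev$time_s * fr) + 1L
      for (r in seq_len(nrow(ev))) {
        f0 <- frame0[r]
        # clip kernel at end of the event's trial
        last <- min(ev$trial[r] * n_frames, f0 + length(kern) - 1L)
        span <- f0:last
        tr[span, ev$cell_id[r]] <- tr[span, ev$cell_id[r]] +
          ev$amplitude[r] * kern[seq_along(span)]
      }
    }
    if (config$noise_sigma > 0)
      tr <- tr + matrix(stats::rnorm(length(tr), 0, config$noise_sigma),
                        nrow(tr))
    attr(tr, "time_s") <- (seq_len(total_frames) - 1) / fr
    out[[key]] <- tr
  }
  structure(out, class = "trace_set", frame_rate = fr)
}

#' Render per-session spatial footprints with jitter
#'
#' Each cell has a fixed base centroid in the field of view; per session the
#' centroid is jittered by an isotropic Gaussian of sd `footprint_jitter` and
#' a Gaussian blob of sd `footprint_radius` is rendered on a 1 um/px patch.
#' Only cells active in the session (either environment on that day appears in
#' its own session) get a footprint, mirroring per-session cell extraction.
#' Ground-truth identity is stored per footprint.
#'
#' @param model an `ensemble_model`.
#' @param config the [sim_config()].
#' @param seed optional integer; defaults to the config's footprint substream.
#' @return an object of class `footprint_set`: per-session lists with
#'   `truth_id`, `centroids` (um), `patches` (weight matrices with `origin`
#'   attribute, 1 um/px).
#' @export
render_footprints <- function(model, config, seed = NULL) {
  stopifnot(inherits(model, "ensemble_model"))
  if (is.null(seed)) seed <- substream_seed(config$seed, "footprints")
  set.seed(seed)
  n <- config$n_cells
  margin <- 4 * config$footprint_radius
  # dart-throwing placement with a hard minimum separation (somata exclude
  # one another); falls back to the best draw if the FOV gets crowded
  base <- matrix(NA_real_, n, 2)
  min_sep2 <- config$min_cell_separation^2
  for (i in seq_len(n)) {
    for (try in 1:200) {
      cand <- stats::runif(2, margin, config$fov_size - margin)
      if (i == 1) break
      prev <- base[seq_len(i - 1), , drop = FALSE]
      if (min((prev[, 1] - cand[1])^2 + (prev[, 2] - cand[2])^2) >= min_sep2)
        break
    }
    base[i, ] <- cand
  }
  half <- ceiling(3 * config$footprint_radius)
  px <- seq(-half, half)

  sessions <- list()
  for (e in 1:2) for (d in seq_len(config$n_days)) {
    key <- session_key(c("A", "B")[e], config$day_values[d])
    ids <- which(model$active[, d, e])
    if (length(ids) == 0) {
      sessions[[key]] <- list(truth_id = integer(0),
                              centroids = matrix(numeric(0), 0, 2),
                              patches = list())
      next
    }
    jit <- matrix(stats::rnorm(2 * length(ids), 0, config$footprint_jitter),
                  ncol = 2)
    cent <- base[ids, , drop = FALSE] + jit
    patches <- vector("list", length(ids))
    for (i in seq_along(ids)) {
      cx <- cent[i, 1]; cy <- cent[i, 2]
      ox <- round(cx) - half; oy <- round(cy) - half
      gx <- exp(-((round(cx) + px - cx)^2) / (2 * config$footprint_radius^2))
      gy <- exp(-((round(cy) + px - cy)^2) / (2 * config$footprint_radius^2))
      w <- outer(gx, gy)
      attr(w, "origin") <- c(ox, oy)
      patches[[i]] <- w
    }
    sessions[[key]] <- list(truth_id = ids, centroids = cent,
                            patches = patches)
  }
  structure(list(sessions = sessions, um_per_px = 1, base_centroids = base,
                 config = config),
            class = "footprint_set")
}

#' Generate a complete synthetic dataset
#'
#' Runs trajectory, ensemble-model, event, and (optionally) trace and
#' footprint generation from the config's root seed. With the default drift
#' settings the within- and across-environment ensemble correlations decay
#' with elapsed days while field positions of recurring cells stay put.
#'
#' @param config a [sim_config()].
#' @param include_traces render dF/F traces (memory-heavy; default FALSE).
#' @param include_footprints render spatial footprints (default FALSE).
#' @return a list with `config`, `trajectory`, `model`, `events`, optionally
#'   `traces` and `footprints`, and `truth` (ground-truth summary).
#' @export
generate_dataset <- function(config, include_traces = FALSE,
                             include_footprints = FALSE) {
  validate_sim_config(config)
  traj <- simulate_trajectory(config)
  model <- build_ensemble_model(config)
  events <- simulate_events(model, traj)
  out <- list(config = config, trajectory = traj, model = model,
              events = events)
  if (include_traces) out$traces <- render_fluorescence(events, config)
  if (include_footprints)
    out$footprints <- render_footprints(model, config)
  out$truth <- list(
    is_place = model$is_place, field_center = model$field_center,
    active = model$active, seed = config$seed
  )
  class(out) <- "drift_dataset"
  out
}

#' @export
print.drift_dataset <- function(x, ...) {
  cat("<drift_dataset>", x$config$n_cells, "cells,",
      nrow(x$events), "events over", x$config$n_days, "days x 2 env\n")
  invisible(x)
}
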