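test_that("config validation rejects impossible parameter combinations", {
  expect_error(sim_config(trial_duration = 0), "positive")
  expect_error(sim_config(frame_rate = -1), "positive")
  expect_error(sim_config(place_cell_fraction = 1.4), "probabilities")
  expect_error(sim_config(kernel_rise = 0.5, kernel_decay = 0.1), "kernel")
  expect_silent(validate_sim_config(sim_config()))
})

test_that("constant-speed lap kinematics complete the expected traversals", {
  cfg <- sim_config(n_cells = 1, day_values = 1, trials_per_session = 1,
                    run_speed = 20, pause_mean = 0, seed = 1)
  traj <- simulate_trajectory(cfg)
  tr <- traj[traj$env == "A", ]
  # end-to-end traversals = arrivals at a track end
  arrivals <- sum(diff(sign(tr$velocity_cm_s)) != 0) +
    (tr$position_cm[nrow(tr)] %in% c(0, cfg$track_length))
  expect_equal(floor(20 * 180 / 96), 37)
  expect_equal(arrivals, 37)
})

test_that("trajectories stay on the track and conserve trial time", {
  cfg <- sim_config(n_cells = 1, day_values = c(1, 3), seed = 3)
  traj <- simulate_trajectory(cfg)
  expect_gte(min(traj$position_cm), 0)
  expect_lte(max(traj$position_cm), cfg$track_length)
  # per-frame displacement bounded by speed / frame rate
  for (key in c("A", "B")) {
    tr <- traj[traj$env == key & traj$day == 1 & traj$trial == 1, ]
    expect_lte(max(abs(diff(tr$position_cm))),
               cfg$run_speed / cfg$frame_rate + 1e-9)
  }
  # occupancy conservation: frames per trial x dt = trial duration
  frames <- table(traj$env, traj$day, traj$trial)
  expect_true(all(frames == cfg$trial_duration * cfg$frame_rate))
  # pauses at the ends exist (exercise the speed filter downstream)
  expect_gt(sum(traj$velocity_cm_s == 0), 0)
})

test_that("degenerate ensemble configs behave as limits", {
  cfg <- sim_config(n_cells = 30, place_cell_fraction = 0, seed = 2)
  m <- build_ensemble_model(cfg)
  expect_false(any(m$is_place))
  expect_equal(tuning_at <- driftclock:::tuning_at(m, 1, "A", c(5, 48, 90)),
               rep(1, 3))

  cfg0 <- sim_config(n_cells = 30, shared_drift_sigma = 0,
                     env_drift_sigma = 0, recruitment_persistence = 1,
                     active_fraction = 0.99, env_active_prob = 1, seed = 2)
  m0 <- build_ensemble_model(cfg0)
  expect_true(all(m0$eta_shared == 0))
  expect_true(all(m0$eta_env == 0))
  # persistence 1: activity constant across days
  expect_true(all(m0$active[, 1, ] == m0$active[, cfg0$n_days, ]))
})

test_that("recruitment follows the 2-state Markov chain closed form", {
  p11 <- 0.8; pi0 <- 0.6
  cfg <- sim_config(n_cells = 2000, recruitment_persistence = p11,
                    active_fraction = pi0, env_active_prob = 1, seed = 9)
  m <- build_ensemble_model(cfg)
  a <- m$active_day
  # k-step transition of the chain: P(active at d+k | active at d)
  p01 <- pi0 * (1 - p11) / (1 - pi0)
  lambda <- p11 - p01                      # second eigenvalue
  for (k in c(1, 3, 7)) {
    theor <- pi0 + (1 - pi0) * lambda^k
    src <- a[, 1]
    est <- mean(a[src, 1 + k])
    se <- sqrt(theor * (1 - theor) / sum(src))
    expect_lt(abs(est - theor), 3 * se + 1e-12)
  }
})

test_that("event generation matches Poisson statistics and tuning", {
  cfg <- sim_config(n_cells = 40, day_values = 1, seed = 4,
                    place_cell_fraction = 0, base_rate = 0.1)
  traj <- simulate_trajectory(cfg)
  m <- build_ensemble_model(cfg)
  # homogeneous rate 0.1 ev/s for every cell, always active
  m$base_log_rate[] <- log(0.1)
  m$eta_shared[] <- 0; m$eta_env[] <- 0; m$env_gain[] <- 0
  m$active[] <- TRUE
  ev <- simulate_events(m, traj, seed = 21)
  counts <- tabulate(ev$cell_id[ev$env == "A"], nbins = cfg$n_cells)
  # 900 s per session at 0.1 ev/s: mean 90; pooled cells give a tight check
  expect_lt(abs(mean(counts) - 90), 3 * sqrt(90 / cfg$n_cells))
  # individual counts within the Poisson 99% interval most of the time
  band <- qpois(c(0.005, 0.995), 90)
  expect_gt(mean(counts >= band[1] & counts <= band[2]), 0.9)

  # all rates zero: empty table
  m0 <- m; m0$active[] <- FALSE
  expect_equal(nrow(simulate_events(m0, traj, seed = 5)), 0)

  # place-tuned events concentrate around the field center
  cfg2 <- sim_config(n_cells = 1, day_values = 1, place_cell_fraction = 1,
                     field_width = 5, base_rate = 0.3, pause_mean = 0,
                     seed = 8)
  m2 <- build_ensemble_model(cfg2)
  m2$active[] <- TRUE
  ev2 <- simulate_events(m2, simulate_trajectory(cfg2), seed = 8)
  ev2 <- ev2[ev2$env == "A" & abs(ev2$velocity_cm_s) > 1, ]
  frac <- mean(abs(ev2$position_cm - m2$field_center[1, "A"]) <= 10)
  expect_gte(frac, 0.8)
})

test_that("fluorescence rendering is linear with an analytic kernel peak", {
  cfg <- sim_config(n_cells = 2, day_values = 1, trials_per_session = 1,
                    noise_sigma = 0, seed = 1)
  empty <- driftclock:::empty_event_table()
  tr0 <- render_fluorescence(empty, cfg, sessions = "A_d1")
  expect_true(all(tr0[["A_d1"]] == 0))

  one <- data.frame(cell_id = 1L, env = "A", day = 1L, trial = 1L,
                    time_s = 60, amplitude = 1, position_cm = 10,
                    velocity_cm_s = 20, direction = "right")
  tr1 <- render_fluorescence(one, cfg, sessions = "A_d1")
  expect_lt(abs(max(tr1[["A_d1"]][, 1]) - 1), 0.01)  # unit-peak kernel

  two <- one; two$cell_id <- 2L; two$time_s <- 100; two$amplitude <- 0.4
  tr2 <- render_fluorescence(two, cfg, sessions = "A_d1")
  tr12 <- render_fluorescence(rbind(one, two), cfg, sessions = "A_d1")
  expect_equal(tr12[["A_d1"]], tr1[["A_d1"]] + tr2[["A_d1"]],
               ignore_attr = TRUE)
})

test_that("footprint jitter follows the 2-D Gaussian displacement law", {
  cfg <- sim_config(n_cells = 150, footprint_jitter = 0, seed = 6)
  fp0 <- render_footprints(build_ensemble_model(cfg), cfg)
  s1 <- fp0$sessions[[1]]
  # zero jitter: session centroids coincide with base centroids
  expect_equal(s1$centroids, fp0$base_centroids[s1$truth_id, ],
               ignore_attr = TRUE)

  cfg2 <- sim_config(n_cells = 150, footprint_jitter = 2, seed = 6)
  fp2 <- render_footprints(build_ensemble_model(cfg2), cfg2)
  d <- unlist(lapply(fp2$sessions, function(s) {
    sqrt(rowSums((s$centroids - fp2$base_centroids[s$truth_id, ])^2))
  }))
  # Rayleigh(sigma = 2): P(d < 5) = 1 - exp(-25/8)
  theor <- 1 - exp(-25 / 8)
  se <- sqrt(theor * (1 - theor) / length(d))
  expect_lt(abs(mean(d < 5) - theor), 3 * se)
  expect_gte(mean(d < 5), 0.93)
})

test_that("datasets are reproducible and correctly sized", {
  cfg <- sim_config(n_cells = 25, seed = 13)
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_identical(d1$events, d2$events)
  expect_identical(d1$model$eta_shared, d2$model$eta_shared)
  # 8 days x 2 environments x 5 trials
  tt <- unique(d1$trajectory[, c("env", "day", "trial")])
  expect_equal(nrow(tt), 8 * 2 * 5)
  expect_true(all(d1$events$time_s >= 0 &
                    d1$events$time_s < cfg$trial_duration))
  expect_true(all(d1$events$trial %in% 1:5))
})

test_that("shared drift makes same-day environments more alike than distant days", {
  deltas <- sapply(1:6, function(s) {
    cfg <- sim_config(n_cells = 60, seed = 100 + s, env_drift_sigma = 0)
    ds <- generate_dataset(cfg)
    av <- build_activity_vectors(ds$events, cfg$n_cells, cfg$day_values)
    C <- suppressWarnings(stats::cor(cbind(av$V[, , 1], av$V[, , 2])))
    same_day <- mean(C[cbind(1:8, 9:16)])
    far <- mean(c(C[1, 16], C[8, 9]))    # 14-day cross-environment pairs
    same_day - far
  })
  expect_gt(mean(deltas), 0)
  expect_gt(mean(deltas > 0), 0.7)
})

test_that("event tables round-trip through the CSV dialect", {
  ds <- fixture_dataset()
  path <- withr::local_tempfile(fileext = ".csv")
  write_event_table(ds$events, path)
  back <- read_event_table(path)
  expect_equal(back$cell_id, ds$events$cell_id)
  expect_equal(back$time_s, ds$events$time_s, tolerance = 1e-12)
  expect_error(read_event_table(
    withr::local_tempfile(lines = "cell_id,env\n1,A", fileext = ".csv")),
    "missing column")
})
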