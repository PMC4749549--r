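test_that("spatial information matches its closed forms", {
  # uniform rate map: 0 bits/event
  expect_equal(spatial_information(uniform_map(rep(3, 20))), 0)
  # two bins, p = (1/2, 1/2), r = (2, 0): 1 bit/event
  expect_equal(spatial_information(uniform_map(c(2, 0))), 1)
  # delta map over n equally occupied bins: log2(n) bits/event
  for (n in c(4, 10, 20)) {
    r <- c(rep(0, n - 1), 5)
    expect_equal(spatial_information(uniform_map(r)), log2(n))
  }
  # invariance to a common positive rescaling of rates
  set.seed(2)
  r <- rexp(20)
  expect_equal(spatial_information(uniform_map(r)),
               spatial_information(uniform_map(7.3 * r)))
  expect_error(spatial_information(uniform_map(rep(0, 20))), "undefined")
})

test_that("rate maps apply speed filter, binning and kernel smoothing", {
  cfg <- sim_config(n_cells = 1, day_values = 1, seed = 5)
  traj <- simulate_trajectory(cfg)
  tr <- traj[traj$env == "A" & traj$day == 1, ]
  bins <- track_bins()

  # stationary events are removed by the speed filter
  ev0 <- data.frame(cell_id = 1, env = "A", day = 1, trial = 1,
                    time_s = 1, amplitude = 1, position_cm = 50,
                    velocity_cm_s = 0, direction = "right")
  m0 <- compute_rate_map(ev0, tr, "right")
  expect_equal(m0$n_events, 0)

  # single running event in bin 12: smoothed map is the kernel at bin 12
  # (up to the near-uniform occupancy of the constant-speed trajectory)
  ev1 <- ev0; ev1$position_cm <- 46; ev1$velocity_cm_s <- 20
  m1 <- compute_rate_map(ev1, tr, "right")
  expect_equal(m1$n_events, 1)
  k <- driftclock:::gauss_kernel(1.5, 5)
  on_kernel <- m1$rate[10:14] / max(m1$rate[10:14])
  expect_equal(on_kernel, k / max(k), tolerance = 0.05)
  expect_equal(m1$peak_bin, 12)
  expect_equal(m1$field_cm, bins$centers_cm[12])
  expect_true(all(m1$rate[c(1:8, 16:24)] < 1e-9, na.rm = TRUE))

  # valid occupancy probabilities sum to one
  expect_equal(sum(m1$occupancy_p[bins$valid]), 1)
  expect_error(compute_rate_map(ev1, tr[tr$direction == "left", ], "right"),
               "occupancy")
})

test_that("shuffle significance attains its floor and flags ineligible cells", {
  cfg <- sim_config(n_cells = 1, day_values = 1, place_cell_fraction = 1,
                    field_width = 3, base_rate = 0.2, seed = 12)
  ds_tr <- simulate_trajectory(cfg)
  tr <- ds_tr[ds_tr$env == "A" & ds_tr$day == 1, ]
  # perfect single-bin cell with 50 events
  ev <- data.frame(cell_id = 1, env = "A", day = 1,
                   trial = rep(1:5, each = 10),
                   time_s = rep(seq(5, 130, length.out = 10), 5),
                   amplitude = 1, position_cm = 46, velocity_cm_s = 20,
                   direction = "right")
  map <- compute_rate_map(ev, tr, "right")
  pf <- place_field_significance(map, n_shuffles = 1000, seed = 3)
  expect_equal(pf$p, 1 / 1001)
  expect_true(pf$is_place_cell)

  # 5 events: ineligible, no p-value
  map5 <- compute_rate_map(ev[1:5, ], tr, "right")
  pf5 <- place_field_significance(map5, n_shuffles = 100, seed = 3)
  expect_false(pf5$eligible)
  expect_true(is.na(pf5$p))
  expect_error(place_field_significance(map, n_shuffles = 0), "n_shuffles")
})

test_that("the shuffle test is calibrated on occupancy-null cells", {
  # events drawn from the occupancy distribution itself: p uniform,
  # type-I error at alpha = 0.05 within binomial bounds
  cfg <- sim_config(n_cells = 1, day_values = 1, seed = 23)
  traj <- simulate_trajectory(cfg)
  tr <- traj[traj$env == "A" & traj$day == 1, ]
  bins <- track_bins()
  run <- tr[abs(tr$velocity_cm_s) > 1 & tr$direction == "right", ]
  set.seed(99)
  n_cells <- 400
  rejected <- logical(n_cells)
  for (i in seq_len(n_cells)) {
    idx <- sample.int(nrow(run), 30, replace = TRUE)
    ev <- data.frame(cell_id = 1, env = "A", day = 1, trial = run$trial[idx],
                     time_s = run$time_s[idx], amplitude = 1,
                     position_cm = run$position_cm[idx],
                     velocity_cm_s = run$velocity_cm_s[idx],
                     direction = "right")
    map <- compute_rate_map(ev, tr, "right", bins = bins)
    pf <- place_field_significance(map, n_shuffles = 199, seed = 1000 + i)
    rejected[i] <- pf$p <= 0.05
  }
  band <- 2.58 * sqrt(0.05 * 0.95 / n_cells)
  expect_lt(abs(mean(rejected) - 0.05), band + 0.01)
})

test_that("field-shift distributions separate stable fields from the identity null", {
  set.seed(4)
  n <- 300
  f1 <- data.frame(master_id = 1:n, field_cm = runif(n, 8, 88))
  # identical maps on both days: all shifts zero
  same <- centroid_shift_distribution(f1, f1, n_null_pairs = 500, seed = 5)
  expect_true(all(same$observed == 0))
  # null symmetric about zero by construction
  expect_lt(abs(mean(same$null > 0) - mean(same$null < 0)), 0.02)
  # stable fields with small wobble: observed KS-distinct from null
  f2 <- data.frame(master_id = 1:n,
                   field_cm = pmin(88, pmax(8, f1$field_cm + rnorm(n, 0, 2))))
  res <- centroid_shift_distribution(f1, f2, n_null_pairs = 500, seed = 5)
  expect_lt(res$ks$p.value, 0.01)
  expect_gt(mean(abs(res$null)), mean(abs(res$observed)))
  expect_error(centroid_shift_distribution(f1[1, ], f1[2, ]), "2 cells")
})

test_that("population-vector correlation is symmetric, unit on self, null on noise", {
  ds <- fixture_dataset()
  maps <- session_rate_maps(ds$events, ds$trajectory, "A", 1,
                            seq_len(ds$config$n_cells))
  self <- population_vector_correlation(maps, maps)
  expect_equal(self$mean_correlation, 1)

  mapsB <- session_rate_maps(ds$events, ds$trajectory, "B", 1,
                             seq_len(ds$config$n_cells))
  expect_equal(population_vector_correlation(maps, mapsB)$mean_correlation,
               population_vector_correlation(mapsB, maps)$mean_correlation,
               tolerance = 1e-12)

  # independent random maps: correlation within 0.1 of zero
  set.seed(6)
  rnd <- function() list(left = matrix(rexp(500 * 24), 500, 24),
                         right = matrix(rexp(500 * 24), 500, 24))
  pv0 <- population_vector_correlation(rnd(), rnd())
  expect_lt(abs(pv0$mean_correlation), 0.1)
})

test_that("the higher of the two track alignments is returned", {
  set.seed(8)
  base <- list(left = matrix(rexp(200 * 24), 200, 24),
               right = matrix(rexp(200 * 24), 200, 24))
  # construct maps matching base only after the end-to-end reversal
  flipped <- list(left = 0.2 * matrix(rexp(200 * 24), 200, 24) +
                    base$right[, 24:1],
                  right = 0.2 * matrix(rexp(200 * 24), 200, 24) +
                    base$left[, 24:1])
  one <- population_vector_correlation(base, flipped)
  both <- population_vector_correlation(base, flipped, both_alignments = TRUE)
  expect_equal(both$alignment, 2L)
  expect_gt(both$mean_correlation, one$mean_correlation)
})

test_that("within-environment stability at 14 days exceeds cross-environment similarity", {
  ds <- fixture_dataset()
  cells <- seq_len(ds$config$n_cells)
  mA1 <- session_rate_maps(ds$events, ds$trajectory, "A", 1, cells)
  mA15 <- session_rate_maps(ds$events, ds$trajectory, "A", 15, cells)
  within14 <- population_vector_correlation(mA1, mA15)$mean_correlation
  across0 <- mean(vapply(c(1, 7, 15), function(d) {
    mA <- session_rate_maps(ds$events, ds$trajectory, "A", d, cells)
    mB <- session_rate_maps(ds$events, ds$trajectory, "B", d, cells)
    population_vector_correlation(mA, mB,
                                  both_alignments = TRUE)$mean_correlation
  }, numeric(1)))
  expect_gt(within14, across0)
})
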