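# independent brute-force ordinal oracle: enumerate every permutation of the
# day labels, compute the mean neighbor correlation directly, and collapse
# reversal duplicates
ordinal_oracle <- function(C) {
  n <- nrow(C)
  P <- pracma::perms(seq_len(n))
  obj <- apply(P, 1, function(p)
    mean(C[cbind(p[-n], p[-1])]))
  canonical <- P[, 1] < P[, n]
  best <- P[which.max(obj), ]
  if (best[1] > best[n]) best <- rev(best)
  list(best = best,
       best_objective = max(obj),
       p_true = sum(obj[canonical] >= obj[canonical][
         which(apply(P[canonical, , drop = FALSE], 1, function(p)
           all(p == seq_len(n))))]) / sum(canonical))
}

test_that("activity vectors are additive, full-length and partitioned by epoch", {
  ds <- fixture_dataset()
  av <- fixture_vectors()
  n <- ds$config$n_cells
  expect_equal(dim(av$V), c(n, 8, 2))
  expect_equal(av$V[, , 1], apply(av$v[, , , 1], c(1, 2), sum))
  run <- build_activity_vectors(ds$events, n, ds$config$day_values,
                                epoch = "running",
                                track_length = ds$config$track_length)
  stat <- build_activity_vectors(ds$events, n, ds$config$day_values,
                                 epoch = "stationary",
                                 track_length = ds$config$track_length)
  # running + stationary never exceed the unrestricted counts (end-zone
  # running events are excluded from the running subset)
  expect_true(all(run$V + stat$V <= av$V))
  expect_gt(sum(run$V), 0)
  expect_gt(sum(stat$V), 0)
  bad <- ds$events[1, ]; bad$cell_id <- n + 5L
  expect_error(build_activity_vectors(bad, n, ds$config$day_values),
               "master list")
})

test_that("ordinal decoder reproduces the 3-day toy case by hand", {
  C <- matrix(c(1, .9, .2, .9, 1, .5, .2, .5, 1), 3, 3)
  # embed the correlation structure exactly via an oracle on C itself:
  # only 3 ordering classes exist; <1,2,3> scores (.9+.5)/2
  orc <- ordinal_oracle(C)
  expect_equal(orc$best, c(1, 2, 3))
  expect_equal(orc$best_objective, 0.7)
  expect_equal(nrow(driftclock:::ordering_classes(3)), 3)
})

test_that("ordinal decoder equals the brute-force oracle on small instances", {
  set.seed(17)
  for (nd in 3:6) {
    for (rep in 1:3) {
      V <- array(rnorm(40 * nd * 2), c(40, nd, 2))
      res <- ordinal_decoder(V, "A")
      orc <- ordinal_oracle(stats::cor(V[, , 1]))
      expect_equal(res$objective, orc$best_objective)
      same <- all(res$ordering == orc$best) ||
        all(res$ordering == rev(orc$best))
      expect_true(same)
      expect_equal(res$p_value, orc$p_true)
    }
  }
})

test_that("ordinal decoder enumerates 20160 classes and is reversal-invariant", {
  expect_equal(nrow(driftclock:::ordering_classes(8)), 20160)
  av <- fixture_vectors()
  res <- ordinal_decoder(av$V, "both")
  expect_equal(res$n_orderings, 20160)
  # reversal invariance of the objective justifies the /2: recompute the
  # objective on the reversed best ordering
  C <- (stats::cor(av$V[, , 1]) + stats::cor(av$V[, , 2])) / 2
  o <- res$ordering
  obj_fwd <- mean(C[cbind(o[-8], o[-1])])
  o2 <- rev(o)
  obj_rev <- mean(C[cbind(o2[-8], o2[-1])])
  expect_equal(obj_fwd, obj_rev)
})

test_that("monotone correlation decay makes the chronological order optimal", {
  # Toeplitz correlations strictly decreasing in |day gap|
  set.seed(23)
  n <- 400; nd <- 8
  base <- matrix(rnorm(n * nd), n, nd)
  V <- array(0, c(n, nd, 2))
  for (e in 1:2) {
    x <- matrix(0, n, nd)
    x[, 1] <- base[, 1]
    for (d in 2:nd) x[, d] <- 0.75 * x[, d - 1] +
        sqrt(1 - 0.75^2) * base[, d]
    V[, , e] <- x + 3
  }
  res <- ordinal_decoder(V, "A")
  expect_true(res$correct)
  expect_equal(res$p_value, 1 / 20160)
})

test_that("within-environment decoding is exact under strong drift and errs to neighbors without the same day", {
  av <- fixture_vectors()
  out <- within_env_decoder(av, "A")
  expect_gt(decoder_summary(out)$accuracy, 0.8)
  expect_true(all(out$error_days %in% -7:7))

  ex <- within_env_decoder(av, "A", exclude_same_day = TRUE)
  expect_true(all(ex$error_days != 0))
  # neighboring recording days are the modal inference
  expect_gt(mean(abs(ex$error_days) == 1), 0.5)
})

test_that("a test vector matching one session pattern dominates", {
  set.seed(31)
  n <- 80; nd <- 8; nt <- 5
  v <- array(rpois(n * nd * nt * 2, 3), c(n, nd, nt, 2))
  av <- structure(list(V = apply(v, c(1, 2, 4), sum), v = v,
                       day_values = seq(1, 15, 2)),
                  class = "activity_vectors")
  # make day 4's trial-2 test vector a copy of its training pattern
  target <- av$V[, 4, 1] - v[, 4, 2, 1]
  test_v <- v[, , , 1]
  test_v[, 4, 2] <- target
  out <- within_env_decoder(av, "A", test_v = test_v)
  expect_equal(out$inferred_day[out$true_day == 4 & out$trial == 2], 4)
})

test_that("label-shuffled data decodes at chance", {
  av <- fixture_vectors()
  shufs <- shuffle_day_labels(av, n_shuffles = 20, seed = 7)
  # invariants: per-cell day-count multisets preserved
  s1 <- shufs[[1]]
  expect_equal(apply(s1$V[, , 1], 1, sort), apply(av$V[, , 1], 1, sort))
  expect_equal(sum(s1$v), sum(av$v))

  # decode the original test trials against shuffled training patterns;
  # accuracies cluster by shuffle, so the SE is taken over shuffles
  accs <- vapply(shufs, function(s) {
    errs <- unlist(lapply(1:2, function(e)
      within_env_decoder(s, c("A", "B")[e],
                         test_v = av$v[, , , e])$error_days))
    mean(errs == 0)
  }, numeric(1))
  se <- stats::sd(accs) / sqrt(length(accs))
  expect_lt(abs(mean(accs) - 0.125), 3 * se)
})

test_that("across-environment decoding needs a shared timestamp", {
  # identical environments: trivially perfect
  av <- fixture_vectors()
  twin <- av
  twin$V[, , 2] <- av$V[, , 1]
  twin$v[, , , 2] <- av$v[, , , 1]
  out <- across_env_decoder(twin, "A", level = "session")
  expect_equal(decoder_summary(out)$accuracy, 1)

  # shared drift present: above chance over seeds
  hits <- 0; total <- 0
  for (s in 1:5) {
    cfg <- sim_config(n_cells = 100, seed = 200 + s, env_drift_sigma = 0.02)
    ds <- generate_dataset(cfg)
    avs <- build_activity_vectors(ds$events, cfg$n_cells, cfg$day_values)
    o <- across_env_decoder(avs, "A", level = "session")
    hits <- hits + sum(o$error_days == 0); total <- total + nrow(o)
  }
  expect_lt(stats::pbinom(hits - 1, total, 0.125, lower.tail = FALSE), 0.01)

  # falsification: no shared component, accuracy within binomial noise
  hits0 <- 0; total0 <- 0
  for (s in 1:5) {
    cfg <- sim_config(n_cells = 100, seed = 300 + s, shared_drift_sigma = 0,
                      env_drift_sigma = 0.12, shared_recruitment = FALSE)
    ds <- generate_dataset(cfg)
    avs <- build_activity_vectors(ds$events, cfg$n_cells, cfg$day_values)
    o <- across_env_decoder(avs, "A", level = "session")
    hits0 <- hits0 + sum(o$error_days == 0); total0 <- total0 + nrow(o)
  }
  p_lo <- stats::pbinom(hits0, total0, 0.125)
  p_hi <- stats::pbinom(hits0 - 1, total0, 0.125, lower.tail = FALSE)
  expect_gt(min(p_lo, p_hi), 0.005)  # two-sided: consistent with chance

  # trial-level decoder also runs above chance on the default regime
  otr <- across_env_decoder(av, "A", level = "trial")
  expect_gt(decoder_summary(otr)$accuracy, 0.125)
})

test_that("decoding improves with drift strength and with test-segment duration", {
  accs <- vapply(c(0, 0.06, 0.12), function(sig) {
    cfg <- sim_config(n_cells = 80, seed = 55, shared_drift_sigma = sig)
    ds <- generate_dataset(cfg)
    avs <- build_activity_vectors(ds$events, cfg$n_cells, cfg$day_values)
    decoder_summary(within_env_decoder(avs, "A"))$accuracy
  }, numeric(1))
  expect_true(all(diff(accs) >= -1e-9))

  ds <- fixture_dataset()
  av <- fixture_vectors()
  seg_accs <- vapply(c(1, 10, 60, 180), function(tau) {
    tv <- segment_test_vectors(ds$events, "A", ds$config$n_cells, tau,
                               seed = 77)
    out <- within_env_decoder(av, "A", test_v = tv)
    decoder_summary(out)$accuracy
  }, numeric(1))
  expect_true(all(diff(seg_accs) >= -1e-9))
  expect_gt(seg_accs[4], seg_accs[1])
})

test_that("label shuffling destroys the ordinal temporal structure", {
  av <- fixture_vectors()
  true_obj <- ordinal_decoder(av$V, "both")$true_objective
  shufs <- shuffle_day_labels(av, n_shuffles = 10, seed = 19)
  worse <- vapply(shufs, function(s)
    ordinal_decoder(s$V, "both")$true_objective < true_obj, logical(1))
  expect_gte(sum(worse), 9)
})
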