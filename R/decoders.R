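#' Build ensemble activity vectors from an event table
#'
#' An activity vector counts each master cell's events within an episode (a
#' trial or a whole session); cells absent from a session contribute zeros.
#' Optional event-level restrictions filter events before counting:
#' running epochs (speed above `speed_min` and more than `end_margin` cm from
#' either track end), stationary epochs (the complement on speed; end-zone
#' events are excluded from the running subset only), or a time window within
#' each trial.
#'
#' @param events event table.
#' @param n_cells master-list size; events referencing larger ids error.
#' @param day_values calendar days of the schedule.
#' @param trials_per_session trials per session.
#' @param epoch `"all"`, `"running"` or `"stationary"`.
#' @param window optional `c(start_s, end_s)` within-trial time window.
#' @param speed_min running-speed threshold, cm/s.
#' @param track_length,end_margin geometry of the end-zone exclusion (cm).
#' @return object of class `activity_vectors`: `V` (cells x days x env
#'   session counts), `v` (cells x days x trials x env trial counts),
#'   `day_values`.
#' @export
build_activity_vectors <- function(events, n_cells,
                                   day_values = seq(1, 15, 2),
                                   trials_per_session = 5,
                                   epoch = c("all", "running", "stationary"),
                                   window = NULL, speed_min = 1,
                                   track_length = 96, end_margin = 8) {
  epoch <- match.arg(epoch)
  if (nrow(events) > 0 && any(events$cell_id > n_cells | events$cell_id < 1))
    stop("event references a cell outside the registered master list")
  ev <- events
  if (epoch == "running") {
    ev <- ev[abs(ev$velocity_cm_s) >= speed_min &
               ev$position_cm > end_margin &
               ev$position_cm < track_length - end_margin, , drop = FALSE]
  } else if (epoch == "stationary") {
    ev <- ev[abs(ev$velocity_cm_s) < speed_min, , drop = FALSE]
  }
  if (!is.null(window))
    ev <- ev[ev$time_s >= window[1] & ev$time_s < window[2], , drop = FALSE]

  nd <- length(day_values); nt <- trials_per_session
  v <- array(0L, c(n_cells, nd, nt, 2),
             dimnames = list(NULL, NULL, NULL, c("A", "B")))
  if (nrow(ev) > 0) {
    cnt <- table(factor(ev$cell_id, levels = seq_len(n_cells)),
                 factor(match(ev$day, day_values), levels = seq_len(nd)),
                 factor(ev$trial, levels = seq_len(nt)),
                 factor(match(ev$env, c("A", "B")), levels = 1:2))
    v[] <- as.integer(cnt)
  }
  V <- apply(v, c(1, 2, 4), sum)
  dimnames(V) <- list(NULL, NULL, c("A", "B"))
  structure(list(V = V, v = v, day_values = day_values),
            class = "activity_vectors")
}

# Pearson correlation with a zero-variance guard
pearson_safe <- function(x, y) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

#' Ordinal time decoder
#'
#' Recovers the chronological order of the recording days from unlabeled
#' session activity patterns by maximizing the mean Pearson correlation
#' between patterns placed on neighboring days, over every possible ordering
#' of the days up to reversal (8!/2 = 20160 classes for 8 days). When both
#' environments are included, the objective averages both environments'
#' neighbor correlations under a common day ordering. The permutation
#' p-value of the true chronological order is the fraction of ordering
#' classes whose objective is at least the true order's.
#'
#' @param V activity-vector array cells x days x env.
#' @param envs `"A"`, `"B"` or `"both"`.
#' @param cells optional master-cell subset (indices).
#' @return list `ordering` (best ordering, canonical direction), `objective`,
#'   `true_objective`, `p_value`, `n_orderings`, `correct` (best ordering is
#'   the chronological one up to reversal).
#' @export
ordinal_decoder <- function(V, envs = c("both", "A", "B"), cells = NULL) {
  envs <- match.arg(envs)
  nd <- dim(V)[2]
  if (!is.null(cells)) V <- V[cells, , , drop = FALSE]
  es <- switch(envs, A = 1L, B = 2L, both = 1:2)
  C <- lapply(es, function(e) stats::cor(V[, , e]))
  P <- ordering_classes(nd)
  obj <- numeric(nrow(P))
  for (j in seq_len(nd - 1)) {
    idx <- cbind(P[, j], P[, j + 1])
    step <- Reduce(`+`, lapply(C, function(m) m[idx])) / length(C)
    obj <- obj + step
  }
  obj <- obj / (nd - 1)
  best <- which.max(obj)
  true_row <- which(apply(P, 1, function(p) all(p == seq_len(nd))))
  list(
    ordering = P[best, ], objective = obj[best],
    true_objective = obj[true_row],
    p_value = sum(obj >= obj[true_row]) / nrow(P),
    n_orderings = nrow(P),
    correct = all(P[best, ] == seq_len(nd)),
    objectives = obj
  )
}

# all orderings of 1..n up to reversal: canonical rows have first < last
ordering_classes <- function(n) {
  P <- pracma::perms(seq_len(n))
  P[P[, 1] < P[, n], , drop = FALSE]
}

# normalized-correlation argmax shared by the within/across decoders:
# score(d) = corr(test, train[, d]) - mean_d' corr(ref[, d'], train[, d])
normalized_argmax <- function(test, train, ref, candidates) {
  scores <- rep(NA_real_, ncol(train))
  for (d in candidates) {
    c0 <- pearson_safe(test, train[, d])
    if (is.na(c0)) next
    norm <- mean(vapply(seq_len(ncol(ref)), function(dp)
      pearson_safe(ref[, dp], train[, d]), numeric(1)), na.rm = TRUE)
    scores[d] <- c0 - norm
  }
  if (all(is.na(scores))) return(list(day = NA_integer_, score = NA_real_))
  day <- which.max(scores)  # which.max takes the earliest on ties
  list(day = day, score = scores[day])
}

#' Within-environment time decoder
#'
#' Infers the recording day of single-trial episodes from one environment by
#' correlating each test trial against leave-trial-out session patterns of
#' the same environment. For test trial j of day i, the training pattern of
#' candidate day d is that day's session vector minus its own trial-j vector
#' (the corresponding trial index is excluded from every training session to
#' evade bias), and each correlation is normalized by subtracting the mean
#' correlation of trial-j vectors from all days with that training pattern.
#' The inferred day maximizes the normalized correlation; ties go to the
#' earlier day. With `exclude_same_day` the test day itself is removed from
#' the candidates, so errors are at least one recording-day step.
#'
#' @param av an [build_activity_vectors()] object (training vectors).
#' @param env `"A"` or `"B"`.
#' @param exclude_same_day drop the true day from the candidate set.
#' @param cells optional master-cell subset.
#' @param test_v optional replacement test vectors (cells x days x trials),
#'   e.g. short-segment vectors; training patterns still come from `av`.
#' @return object of class `decoder_output`: data.frame `env,true_day,trial,
#'   inferred_day,error_days,score` with the day columns in recording-day
#'   indices (1..8).
#' @export
within_env_decoder <- function(av, env, exclude_same_day = FALSE,
                               cells = NULL, test_v = NULL) {
  e <- match(env, c("A", "B"))
  nd <- dim(av$V)[2]; nt <- dim(av$v)[3]
  sel <- if (is.null(cells)) seq_len(dim(av$V)[1]) else cells
  V <- av$V[sel, , e]
  v <- av$v[sel, , , e]
  tv <- if (is.null(test_v)) v else test_v[sel, , , drop = FALSE]
  rows <- list(); k <- 0L
  for (j in seq_len(nt)) {
    train <- V - v[, , j]                 # leave trial j out of every session
    ref <- tv[, , j]
    for (i in seq_len(nd)) {
      test <- tv[, i, j]
      if (stats::sd(test) == 0) next      # zero-variance test item: skip
      cand <- seq_len(nd)
      if (exclude_same_day) cand <- cand[cand != i]
      if (length(cand) == 0) stop("all candidate days excluded")
      res <- normalized_argmax(test, train, ref, cand)
      if (is.na(res$day)) next
      k <- k + 1L
      rows[[k]] <- data.frame(env = env, true_day = i, trial = j,
                              inferred_day = res$day,
                              error_days = res$day - i, score = res$score)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("decoder_output", class(out))
  out
}

#' Across-environment time decoder
#'
#' Infers the day of episodes from one environment using the other
#' environment's session patterns as training data; only activity components
#' shared between environments (the drift "timestamp") can support it. At the
#' session level, the test session vector from E1 is correlated against every
#' session vector of E2, normalizing by the mean correlation of all E1
#' session vectors with that E2 pattern. At the trial level, the matching
#' trial index is left out of every E2 training session, mirroring the
#' within-environment decoder.
#'
#' @param av an [build_activity_vectors()] object.
#' @param test_env environment the test episodes come from (`"A"` or `"B"`).
#' @param level `"session"` or `"trial"`.
#' @param exclude_same_day drop the true day from the candidates.
#' @param cells optional master-cell subset.
#' @return `decoder_output` data.frame (trial = NA at session level).
#' @export
across_env_decoder <- function(av, test_env, level = c("session", "trial"),
                               exclude_same_day = FALSE, cells = NULL) {
  level <- match.arg(level)
  e1 <- match(test_env, c("A", "B")); e2 <- 3L - e1
  nd <- dim(av$V)[2]; nt <- dim(av$v)[3]
  sel <- if (is.null(cells)) seq_len(dim(av$V)[1]) else cells
  V1 <- av$V[sel, , e1]; V2 <- av$V[sel, , e2]
  rows <- list(); k <- 0L
  if (level == "session") {
    for (i in seq_len(nd)) {
      test <- V1[, i]
      if (stats::sd(test) == 0) next
      cand <- seq_len(nd)
      if (exclude_same_day) cand <- cand[cand != i]
      res <- normalized_argmax(test, V2, V1, cand)
      if (is.na(res$day)) next
      k <- k + 1L
      rows[[k]] <- data.frame(env = test_env, true_day = i, trial = NA,
                              inferred_day = res$day,
                              error_days = res$day - i, score = res$score)
    }
  } else {
    v1 <- av$v[sel, , , e1]; v2 <- av$v[sel, , , e2]
    for (j in seq_len(nt)) {
      train <- V2 - v2[, , j]
      ref <- v1[, , j]
      for (i in seq_len(nd)) {
        test <- v1[, i, j]
        if (stats::sd(test) == 0) next
        cand <- seq_len(nd)
        if (exclude_same_day) cand <- cand[cand != i]
        res <- normalized_argmax(test, train, ref, cand)
        if (is.na(res$day)) next
        k <- k + 1L
        rows[[k]] <- data.frame(env = test_env, true_day = i, trial = j,
                                inferred_day = res$day,
                                error_days = res$day - i, score = res$score)
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("decoder_output", class(out))
  out
}

#' Summary statistics of a decoder output
#' @param output a `decoder_output`.
#' @return list `accuracy` (exact-day), `neighbor_rate` (|error| <= 1),
#'   `error_table`, `n`.
#' @export
decoder_summary <- function(output) {
  list(accuracy = mean(output$error_days == 0),
       neighbor_rate = mean(abs(output$error_days) <= 1),
       error_table = table(output$error_days),
       n = nrow(output))
}

#' Shuffle day labels per cell
#'
#' Each cell's sequence of per-day activity patterns is independently
#' permuted across days (separately per environment), preserving the
#' within-cell multiset of per-day counts while destroying temporal
#' adjacency. Used as the chance control for all decoders: the ordinal
#' decoder runs directly on the shuffled session patterns, and the
#' trial-level decoders decode the original (unshuffled) test episodes
#' against shuffled training patterns (pass the original trial vectors as
#' `test_v`), which drives exact-day accuracy to 1/8.
#'
#' @param av an [build_activity_vectors()] object.
#' @param n_shuffles number of shuffled replicas.
#' @param seed RNG seed.
#' @return list of `activity_vectors` objects.
#' @export
shuffle_day_labels <- function(av, n_shuffles = 10, seed = 1) {
  set.seed(seed)
  nc <- dim(av$V)[1]; nd <- dim(av$V)[2]
  out <- vector("list", n_shuffles)
  for (s in seq_len(n_shuffles)) {
    sh <- av
    for (e in 1:2) {
      perm <- t(vapply(seq_len(nc), function(i) sample.int(nd),
                       integer(nd)))
      for (i in seq_len(nc)) {
        sh$V[i, , e] <- av$V[i, perm[i, ], e]
        sh$v[i, , , e] <- av$v[i, perm[i, ], , e]
      }
    }
    out[[s]] <- sh
  }
  out
}

#' Trial-segment test vectors for duration-limited decoding
#'
#' Counts events in a contiguous window of `duration` seconds within each
#' trial, starting at a seeded random offset, to probe how much test data the
#' within-environment decoder needs.
#'
#' @param events event table.
#' @param env environment.
#' @param n_cells master-list size.
#' @param duration segment length in seconds.
#' @param trial_duration full trial length in seconds.
#' @param day_values,trials_per_session schedule.
#' @param seed RNG seed for the offsets.
#' @return array cells x days x trials of segment counts.
#' @export
segment_test_vectors <- function(events, env, n_cells, duration,
                                 trial_duration = 180,
                                 day_values = seq(1, 15, 2),
                                 trials_per_session = 5, seed = 1) {
  set.seed(seed)
  nd <- length(day_values); nt <- trials_per_session
  out <- array(0L, c(n_cells, nd, nt))
  ev0 <- events[events$env == env, ]
  for (i in seq_len(nd)) for (j in seq_len(nt)) {
    off <- stats::runif(1, 0, max(0, trial_duration - duration))
    ev <- ev0[ev0$day == day_values[i] & ev0$trial == j &
                ev0$time_s >= off & ev0$time_s < off + duration, ]
    if (nrow(ev) > 0)
      out[, i, j] <- tabulate(ev$cell_id, nbins = n_cells)
  }
  out
}
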