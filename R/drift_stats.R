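#' Event-rate table over cells, days, trials and environments
#'
#' Rates are events per minute; cells unregistered (or silent) in a session
#' have rate 0.
#'
#' @param events event table with master `cell_id`s.
#' @param n_cells master-list size.
#' @param day_values recording-day calendar values.
#' @param trials_per_session trials per session.
#' @param trial_duration trial length in seconds.
#' @return list `trial_rate` (array cells x days x trials x env),
#'   `session_rate` (cells x days x env, events/min), `active` (cells x days
#'   x env logical, at least one event), `day_values`.
#' @export
event_rate_table <- function(events, n_cells, day_values = seq(1, 15, 2),
                             trials_per_session = 5, trial_duration = 180) {
  nd <- length(day_values)
  nt <- trials_per_session
  tr <- array(0, c(n_cells, nd, nt, 2),
              dimnames = list(NULL, NULL, NULL, c("A", "B")))
  if (nrow(events) > 0) {
    di <- match(events$day, day_values)
    ei <- match(events$env, c("A", "B"))
    idx <- cbind(events$cell_id, di, events$trial, ei)
    cnt <- table(factor(events$cell_id, levels = seq_len(n_cells)),
                 factor(di, levels = seq_len(nd)),
                 factor(events$trial, levels = seq_len(nt)),
                 factor(ei, levels = 1:2))
    tr[] <- as.numeric(cnt) / (trial_duration / 60)
  }
  ses <- apply(tr, c(1, 2, 4), mean)  # events/min averaged over trials
  dimnames(ses) <- list(NULL, NULL, c("A", "B"))
  list(trial_rate = tr, session_rate = ses,
       active = apply(tr, c(1, 2, 4), sum) > 0, day_values = day_values)
}

#' Ensemble correlation matrix across all sessions
#'
#' Pearson correlations between the session-level ensemble activity patterns
#' of all (day, environment) sessions, plus mean-correlation decay curves vs
#' elapsed days split into within- and across-environment pairs.
#'
#' @param V activity-vector array cells x days x env (see
#'   [build_activity_vectors()]).
#' @param day_values calendar days.
#' @return list `matrix` (2*nd x 2*nd, sessions ordered day-major within
#'   env A then env B), `curves` (data.frame lag_days, pair
#'   ("within"/"across"), mean, sem, n).
#' @export
ensemble_correlation_matrix <- function(V, day_values = seq(1, 15, 2)) {
  nd <- dim(V)[2]
  M <- cbind(V[, , 1], V[, , 2])
  keys <- c(paste0("A_d", day_values), paste0("B_d", day_values))
  sds <- apply(M, 2, stats::sd)
  if (any(sds == 0))
    stop("zero-variance activity vector in session ", keys[which(sds == 0)[1]])
  C <- stats::cor(M)
  dimnames(C) <- list(keys, keys)
  env_of <- rep(c("A", "B"), each = nd)
  day_of <- rep(day_values, 2)
  rows <- list(); k <- 0L
  lags <- sort(unique(abs(as.vector(outer(day_values, day_values, "-")))))
  for (pair in c("within", "across")) {
    for (lag in lags) {
      vals <- c()
      for (i in seq_len(2 * nd)) for (j in seq_len(2 * nd)) {
        if (i >= j && lag == 0 && pair == "within") next
        if (i > j) next
        same_env <- env_of[i] == env_of[j]
        if ((pair == "within") != same_env) next
        if (abs(day_of[i] - day_of[j]) != lag) next
        if (i == j) next
        vals <- c(vals, C[i, j])
      }
      if (length(vals) == 0) next
      k <- k + 1L
      rows[[k]] <- data.frame(lag_days = lag, pair = pair,
                              mean = mean(vals),
                              sem = stats::sd(vals) / sqrt(length(vals)),
                              n = length(vals))
    }
  }
  list(matrix = C, curves = do.call(rbind, rows))
}

#' Recurrence probability vs elapsed days
#'
#' P(cell active at day d + lag in environment E2 | active at day d in E1),
#' averaged over day pairs, reported within-environment (E2 = E1) and
#' across-environment (E2 != E1).
#'
#' @param active logical array cells x days x env.
#' @param day_values calendar days.
#' @return data.frame `lag_days`, `pair`, `probability`, `n_pairs`.
#' @export
recurrence_probability <- function(active, day_values = seq(1, 15, 2)) {
  nd <- dim(active)[2]
  rows <- list(); k <- 0L
  lags <- sort(unique(abs(as.vector(outer(day_values, day_values, "-")))))
  for (pair in c("within", "across")) {
    for (lag in lags) {
      num <- 0; den <- 0
      for (d1 in seq_len(nd)) for (d2 in seq_len(nd)) {
        if (day_values[d2] - day_values[d1] != lag) next
        for (e1 in 1:2) {
          e2s <- if (pair == "within") e1 else setdiff(1:2, e1)
          for (e2 in e2s) {
            src <- active[, d1, e1]
            den <- den + sum(src)
            num <- num + sum(src & active[, d2, e2])
          }
        }
      }
      if (den == 0) next
      k <- k + 1L
      rows[[k]] <- data.frame(lag_days = lag, pair = pair,
                              probability = num / den, n_pairs = den)
    }
  }
  do.call(rbind, rows)
}

#' Activity divergence between the two environments on one day
#'
#' The mean absolute trial-rate difference across environments divided by the
#' mean absolute trial-rate difference within environments, averaged over all
#' cells and trial pairs. A ratio of 1 means the environments are no more
#' different than repeated trials of the same environment.
#'
#' @param rates an [event_rate_table()].
#' @param day_idx recording-day index (1-based).
#' @return the divergence ratio (dimensionless).
#' @export
activity_divergence <- function(rates, day_idx) {
  tr <- rates$trial_rate
  nt <- dim(tr)[3]
  if (nt < 2) stop("need at least 2 trials per environment")
  a <- tr[, day_idx, , 1, drop = FALSE]; dim(a) <- c(dim(tr)[1], nt)
  b <- tr[, day_idx, , 2, drop = FALSE]; dim(b) <- c(dim(tr)[1], nt)
  cross <- mean(abs(
    a[, rep(seq_len(nt), times = nt)] - b[, rep(seq_len(nt), each = nt)]))
  same_pairs <- utils::combn(nt, 2)
  same <- mean(abs(cbind(
    a[, same_pairs[1, ], drop = FALSE] - a[, same_pairs[2, ], drop = FALSE],
    b[, same_pairs[1, ], drop = FALSE] - b[, same_pairs[2, ], drop = FALSE])))
  if (same == 0) stop("zero within-environment divergence; ratio undefined")
  cross / same
}

#' Peak displacement between environments
#'
#' Mean absolute distance between a cell's peak-activity locations in the two
#' environments, over cells place-coding in both. Track alignment (identity
#' or reversed) should be chosen beforehand by the higher global
#' population-vector correlation; pass `alignment = 2` to reverse the second
#' environment's positions.
#'
#' @param peaks_1,peaks_2 data.frames `master_id`, `field_cm`.
#' @param track_length cm, used to mirror positions under alignment 2.
#' @param alignment 1 (identity) or 2 (reversed second track).
#' @return mean displacement in cm.
#' @export
peak_displacement <- function(peaks_1, peaks_2, track_length = 96,
                              alignment = 1L) {
  common <- intersect(peaks_1$master_id, peaks_2$master_id)
  if (length(common) == 0) stop("no cells place-coding in both environments")
  p1 <- peaks_1$field_cm[match(common, peaks_1$master_id)]
  p2 <- peaks_2$field_cm[match(common, peaks_2$master_id)]
  if (alignment == 2L) p2 <- track_length - p2
  mean(abs(p1 - p2))
}

#' Longest monotonic sub-sequence of a session-rate series
#'
#' The series of consecutive-day rate differences is reduced to signs; the
#' statistic is the length of the longest run of identical nonzero signs
#' (ties, i.e. zero differences, break runs as they evidence neither trend).
#' For an 8-day series the statistic lies in 0..7 (7 = fully monotonic).
#'
#' @param rates numeric vector of session rates (one per recording day).
#' @return integer run length.
#' @export
maximal_monotonic_sequence <- function(rates) {
  s <- sign(diff(rates))
  best <- 0L; run <- 0L; prev <- 0
  for (x in s) {
    if (x != 0 && x == prev) run <- run + 1L
    else if (x != 0) run <- 1L
    else run <- 0L
    prev <- x
    best <- max(best, run)
  }
  best
}

#' Distribution of monotonic-sequence lengths against a shuffle null
#'
#' @param rate_mat cells x days matrix of session rates.
#' @param n_shuffles per-cell random day permutations in the null.
#' @param seed RNG seed.
#' @return list `observed` (per-cell lengths), `null` (pooled shuffled
#'   lengths).
#' @export
monotonic_sequence_distribution <- function(rate_mat, n_shuffles = 100,
                                            seed = 1) {
  observed <- apply(rate_mat, 1, maximal_monotonic_sequence)
  set.seed(seed)
  nd <- ncol(rate_mat)
  null <- replicate(n_shuffles, {
    shuf <- t(apply(rate_mat, 1, function(r) r[sample.int(nd)]))
    apply(shuf, 1, maximal_monotonic_sequence)
  })
  list(observed = observed, null = as.vector(null))
}

#' Monotonicity score of a session-rate series
#'
#' Over all day pairs (28 for 8 days), the number of pairs where the later
#' day has the higher rate minus the number where the earlier day has the
#' higher rate, normalized by the number of pairs. +1 for monotonically
#' increasing, -1 for decreasing; tied pairs count for neither.
#'
#' @param rates numeric vector of session rates.
#' @return score in [-1, 1].
#' @export
monotonicity_score <- function(rates) {
  n <- length(rates)
  pairs <- utils::combn(n, 2)
  d <- rates[pairs[2, ]] - rates[pairs[1, ]]
  (sum(d > 0) - sum(d < 0)) / ncol(pairs)
}

#' Session-rate CV against a matched stationary Poisson null
#'
#' For cells active in all sessions, the coefficient of variation of session
#' rates is compared with simulated cells emitting Poisson counts at the same
#' mean rate in sessions of the same duration. Drifting cells exceed the
#' Poisson CV.
#'
#' @param rate_mat cells x days matrix of session rates (events/min),
#'   restricted to always-active cells.
#' @param session_minutes session duration in minutes.
#' @param n_sim simulated Poisson cells per real cell.
#' @param seed RNG seed.
#' @return list `cv` (per real cell), `null_cv` (pooled simulated CVs),
#'   `ks` (two-sample test real vs null).
#' @export
rate_cv_poisson_null <- function(rate_mat, session_minutes = 15,
                                 n_sim = 10, seed = 1) {
  means <- rowMeans(rate_mat)
  keep <- means > 0
  rate_mat <- rate_mat[keep, , drop = FALSE]
  means <- means[keep]
  cv <- apply(rate_mat, 1, function(r) stats::sd(r) / mean(r))
  set.seed(seed)
  nd <- ncol(rate_mat)
  null_cv <- unlist(lapply(seq_along(means), function(i) {
    counts <- matrix(stats::rpois(n_sim * nd, means[i] * session_minutes),
                     n_sim, nd)
    apply(counts, 1, function(x) if (mean(x) == 0) NA else
      stats::sd(x) / mean(x))
  }))
  null_cv <- null_cv[!is.na(null_cv)]
  ks <- suppressWarnings(stats::ks.test(cv, null_cv))
  list(cv = cv, null_cv = null_cv, ks = ks)
}

#' Population monotonicity: rate vs lag from each cell's peak day
#'
#' Each cell's session rates are normalized by their maximum and aligned to
#' the day of the maximum (earliest day on ties), so every cell contributes 1
#' at lag 0; the curve is the average over cells per lag. A shuffle control
#' permutes each cell's days before alignment. Optionally the analysis is
#' restricted to each cell's maximal run of consecutive active days.
#'
#' @param rate_mat cells x days matrix of session rates.
#' @param shuffle permute each cell's day order first.
#' @param segment_only restrict each cell to its longest consecutive-active
#'   run (activity = nonzero rate) before alignment.
#' @param seed RNG seed for the shuffle.
#' @return data.frame `lag`, `mean`, `sem`, `n`.
#' @export
population_monotonicity <- function(rate_mat, shuffle = FALSE,
                                    segment_only = FALSE, seed = 1) {
  nd <- ncol(rate_mat)
  if (shuffle) set.seed(seed)
  acc <- list()
  for (i in seq_len(nrow(rate_mat))) {
    r <- rate_mat[i, ]
    if (shuffle) r <- r[sample.int(nd)]
    days <- seq_len(nd)
    if (segment_only) {
      runs <- rle(r > 0)
      if (!any(runs$values)) next
      lens <- runs$lengths; ends <- cumsum(lens)
      act <- which(runs$values)
      bi <- act[which.max(lens[act])]
      days <- (ends[bi] - lens[bi] + 1):ends[bi]
      r <- r[days]
    }
    if (max(r) <= 0) next
    peak <- days[which.max(r)]
    acc[[length(acc) + 1]] <- data.frame(lag = days - peak, val = r / max(r))
  }
  all <- do.call(rbind, acc)
  agg <- stats::aggregate(val ~ lag, all, function(x)
    c(mean = mean(x), sem = stats::sd(x) / sqrt(length(x)), n = length(x)))
  data.frame(lag = agg$lag, mean = agg$val[, "mean"],
             sem = agg$val[, "sem"], n = agg$val[, "n"])
}
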