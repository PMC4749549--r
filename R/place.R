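#' Spatial bin layout of the linear track
#'
#' The track is divided into `n_bins` equal bins; the two bins at each end are
#' excluded from all spatial statistics (rewards are consumed there and the
#' animal is mostly stationary), so with the default 24 bins of 4 cm the valid
#' bins are 3..22.
#'
#' @param n_bins number of bins.
#' @param track_length track length in cm.
#' @param exclude_end_bins bins dropped at each end.
#' @return list with `breaks`, `centers_cm`, `valid` (logical).
#' @export
track_bins <- function(n_bins = 24, track_length = 96, exclude_end_bins = 2) {
  breaks <- seq(0, track_length, length.out = n_bins + 1)
  valid <- rep(TRUE, n_bins)
  if (exclude_end_bins > 0) {
    valid[seq_len(exclude_end_bins)] <- FALSE
    valid[n_bins - seq_len(exclude_end_bins) + 1] <- FALSE
  }
  list(breaks = breaks, centers_cm = (breaks[-1] + breaks[-(n_bins + 1)]) / 2,
       valid = valid, n_bins = n_bins)
}

# truncated Gaussian smoothing kernel (sigma in bins, size in bins, odd)
gauss_kernel <- function(sigma = 1.5, size = 5) {
  half <- (size - 1) / 2
  k <- exp(-(seq(-half, half))^2 / (2 * sigma^2))
  k / sum(k)
}

smooth_bins <- function(x, kernel) {
  half <- (length(kernel) - 1) / 2
  padded <- c(rep(0, half), x, rep(0, half))
  out <- numeric(length(x))
  for (i in seq_along(x))
    out[i] <- sum(padded[i:(i + 2 * half)] * rev(kernel))
  out
}

#' Compute a per-cell, per-direction rate map
#'
#' Considers only frames where the animal runs faster than `speed_min` in the
#' requested direction, bins time spent and event counts, smooths both maps
#' with a truncated Gaussian kernel (sigma 1.5 bins, size 5 bins) and divides
#' them. The unsmoothed rate map (used for spatial information) and the
#' occupancy probability over valid bins are kept alongside.
#'
#' @param events event table rows for one cell (may be empty).
#' @param traj trajectory frames for the same session (all cells share it).
#' @param direction `"left"` or `"right"`.
#' @param bins a [track_bins()] layout.
#' @param frame_rate Hz.
#' @param speed_min running-speed threshold in cm/s.
#' @param sigma,size smoothing kernel parameters in bins.
#' @return object of class `rate_map`: `rate` (smoothed), `rate_raw`,
#'   `occupancy_s`, `occupancy_p` (normalized over valid bins), `n_events`,
#'   `peak_bin`, `field_cm`, `valid`, `direction`.
#' @export
compute_rate_map <- function(events, traj, direction, bins = track_bins(),
                             frame_rate = 20, speed_min = 1,
                             sigma = 1.5, size = 5) {
  run <- traj[abs(traj$velocity_cm_s) > speed_min &
                traj$direction == direction, ]
  occ_counts <- tabulate(bin_of(run$position_cm, bins), nbins = bins$n_bins)
  occupancy_s <- occ_counts / frame_rate
  if (sum(occupancy_s[bins$valid]) == 0)
    stop("no valid occupancy in direction ", direction)
  if (nrow(events) > 0) {
    ev <- events[abs(events$velocity_cm_s) > speed_min &
                   events$direction == direction, ]
  } else ev <- events
  ev_counts <- if (nrow(ev) > 0)
    tabulate(bin_of(ev$position_cm, bins), nbins = bins$n_bins)
  else rep(0, bins$n_bins)

  kernel <- gauss_kernel(sigma, size)
  occ_s <- smooth_bins(occupancy_s, kernel)
  ev_s <- smooth_bins(ev_counts, kernel)
  rate <- ifelse(occ_s > 0, ev_s / occ_s, NA_real_)
  rate_raw <- ifelse(occupancy_s > 0, ev_counts / occupancy_s, 0)
  occupancy_p <- occupancy_s * bins$valid / sum(occupancy_s[bins$valid])

  vr <- rate; vr[!bins$valid] <- NA
  peak_bin <- if (all(is.na(vr))) NA_integer_ else which.max(vr)
  structure(list(
    rate = rate, rate_raw = rate_raw, occupancy_s = occupancy_s,
    occupancy_p = occupancy_p, n_events = sum(ev_counts[bins$valid]),
    ev_counts = ev_counts, peak_bin = peak_bin,
    field_cm = if (is.na(peak_bin)) NA_real_ else bins$centers_cm[peak_bin],
    valid = bins$valid, direction = direction, bins = bins
  ), class = "rate_map")
}

bin_of <- function(pos, bins) {
  b <- findInterval(pos, bins$breaks, rightmost.closed = TRUE,
                    all.inside = TRUE)
  pmin(pmax(b, 1L), bins$n_bins)
}

#' Spatial information of a rate map, in bits per event
#'
#' `SI = sum_i p_i (r_i / rbar) log2(r_i / rbar)` over valid bins, where `r_i`
#' is the unsmoothed event rate in bin i, `p_i` the occupancy probability and
#' `rbar = sum_i p_i r_i` the overall mean rate; `0 log 0` is 0.
#'
#' @param map a `rate_map` (or list with `rate_raw`, `occupancy_p`, `valid`).
#' @return spatial information in bits/event (non-negative).
#' @export
spatial_information <- function(map) {
  i <- map$valid
  p <- map$occupancy_p[i]
  r <- map$rate_raw[i]
  rbar <- sum(p * r)
  if (rbar <= 0) stop("mean rate is zero; spatial information undefined")
  x <- r / rbar
  terms <- ifelse(x > 0, p * x * log2(x), 0)
  sum(terms)
}

#' Shuffle test for place-field significance
#'
#' Redraws each event's position from the session/direction occupancy
#' distribution (`n_shuffles` times, default 1000), recomputes the spatial
#' information of each shuffle, and reports `p = (1 + #{SI_shuffle >=
#' SI_obs}) / (n_shuffles + 1)`. Cells with 5 or fewer events are ineligible.
#'
#' @param map a `rate_map`.
#' @param n_shuffles number of shuffles.
#' @param seed RNG seed.
#' @param alpha significance level for the place-cell flag.
#' @return object of class `place_field_result`: `si_bits`, `p`,
#'   `is_place_cell`, `eligible`, `field_cm`, `n_events`.
#' @export
place_field_significance <- function(map, n_shuffles = 1000, seed = 1,
                                     alpha = 0.05) {
  if (n_shuffles < 1) stop("n_shuffles must be at least 1")
  out <- list(si_bits = NA_real_, p = NA_real_, is_place_cell = FALSE,
              eligible = FALSE, field_cm = map$field_cm,
              n_events = map$n_events)
  class(out) <- "place_field_result"
  if (map$n_events <= 5) return(out)
  si_obs <- spatial_information(map)
  i <- map$valid
  p_occ <- map$occupancy_p[i]
  occ_s <- map$occupancy_s[i]
  n_ev <- map$n_events
  set.seed(seed)
  si_sh <- numeric(n_shuffles)
  for (s in seq_len(n_shuffles)) {
    counts <- stats::rmultinom(1, n_ev, p_occ)[, 1]
    r <- ifelse(occ_s > 0, counts / occ_s, 0)
    rbar <- sum(p_occ * r)
    x <- r / rbar
    si_sh[s] <- sum(ifelse(x > 0, p_occ * x * log2(x), 0))
  }
  pval <- (1 + sum(si_sh >= si_obs)) / (n_shuffles + 1)
  out$si_bits <- si_obs
  out$p <- pval
  out$eligible <- TRUE
  out$is_place_cell <- pval <= alpha
  out
}

#' Field-shift distribution between two days with a cell-identity null
#'
#' Observed shifts are the per-cell differences in field position between two
#' days for cells place-coding on both. The null shuffles cell identities on
#' each day independently and pools the resulting shift distributions over
#' `n_null_pairs` shuffle pairs; a two-sample Kolmogorov-Smirnov test
#' compares observed against null.
#'
#' @param fields_i,fields_j data.frames with `master_id` and `field_cm` for
#'   the two days (place cells only).
#' @param n_null_pairs number of shuffle pairs (default 10000).
#' @param seed RNG seed.
#' @param max_null_sample cap on pooled null values retained (memory guard;
#'   the pooled null is subsampled uniformly beyond it).
#' @return list `observed`, `null`, `ks` (htest).
#' @export
centroid_shift_distribution <- function(fields_i, fields_j,
                                        n_null_pairs = 10000, seed = 1,
                                        max_null_sample = 2e6) {
  common <- intersect(fields_i$master_id, fields_j$master_id)
  if (length(common) < 2)
    stop("fewer than 2 cells place-coding on both days")
  fi <- fields_i$field_cm[match(common, fields_i$master_id)]
  fj <- fields_j$field_cm[match(common, fields_j$master_id)]
  observed <- fj - fi
  n <- length(common)
  set.seed(seed)
  per_pair <- max(1L, min(n, ceiling(max_null_sample / n_null_pairs)))
  null <- matrix(NA_real_, per_pair, n_null_pairs)
  for (s in seq_len(n_null_pairs)) {
    d <- fj[sample.int(n)] - fi[sample.int(n)]
    null[, s] <- if (per_pair == n) d else d[seq_len(per_pair)]
  }
  null <- as.vector(null)
  ks <- suppressWarnings(stats::ks.test(observed, null))
  list(observed = observed, null = null, ks = ks)
}

#' Mean population-vector correlation between two sets of rate maps
#'
#' The population vector of a spatial bin is the vector of all cells' rates
#' there (both running directions stacked). For each valid bin the Pearson
#' correlation between the two sessions' vectors is computed and the scores
#' are averaged over bins; zero-variance bins are skipped. Because two linear
#' tracks can be traversed in either orientation relative to each other, the
#' cross-environment comparison evaluates both end-to-end alignments (the
#' second reverses bin order and swaps directions) and returns the one with
#' the higher mean correlation.
#'
#' @param maps1,maps2 lists with elements `left` and `right`, each a cells x
#'   bins matrix of smoothed rates on a common registered cell list.
#' @param valid logical vector of valid bins.
#' @param both_alignments evaluate the reversed alignment too (use for
#'   cross-environment comparisons).
#' @return list `mean_correlation`, `per_bin`, `alignment` (1 = identity,
#'   2 = reversed), `skipped_bins`.
#' @export
population_vector_correlation <- function(maps1, maps2,
                                          valid = track_bins()$valid,
                                          both_alignments = FALSE) {
  score_alignment <- function(m2l, m2r) {
    vb <- which(valid)
    per_bin <- rep(NA_real_, length(vb))
    for (k in seq_along(vb)) {
      b <- vb[k]
      v1 <- c(maps1$left[, b], maps1$right[, b])
      v2 <- c(m2l[, b], m2r[, b])
      ok <- !is.na(v1) & !is.na(v2)
      if (stats::sd(v1[ok]) == 0 || stats::sd(v2[ok]) == 0) next
      per_bin[k] <- stats::cor(v1[ok], v2[ok])
    }
    per_bin
  }
  pb1 <- score_alignment(maps2$left, maps2$right)
  best <- list(mean_correlation = mean(pb1, na.rm = TRUE), per_bin = pb1,
               alignment = 1L)
  if (both_alignments) {
    # reversed track: flip bins, swap directions
    nb <- ncol(maps2$left)
    rev_l <- maps2$right[, nb:1, drop = FALSE]
    rev_r <- maps2$left[, nb:1, drop = FALSE]
    pb2 <- score_alignment(rev_l, rev_r)
    m2 <- mean(pb2, na.rm = TRUE)
    if (!is.na(m2) && (is.na(best$mean_correlation) ||
                       m2 > best$mean_correlation))
      best <- list(mean_correlation = m2, per_bin = pb2, alignment = 2L)
  }
  best$skipped_bins <- sum(is.na(best$per_bin))
  best
}

#' Rate maps for all cells of one session
#'
#' @param events event table (all cells).
#' @param traj trajectory.
#' @param env,day session selector.
#' @param cells master cell ids defining row order.
#' @param bins a [track_bins()] layout.
#' @param ... passed to [compute_rate_map()].
#' @return list `left`, `right` (cells x bins smoothed-rate matrices; cells
#'   without valid occupancy-normalized rates get zero rows), plus `bins`.
#' @export
session_rate_maps <- function(events, traj, env, day, cells,
                              bins = track_bins(), ...) {
  tr <- traj[traj$env == env & traj$day == day, ]
  ev <- events[events$env == env & events$day == day, ]
  out <- list()
  for (dir in c("left", "right")) {
    m <- matrix(0, length(cells), bins$n_bins)
    for (i in seq_along(cells)) {
      map <- compute_rate_map(ev[ev$cell_id == cells[i], , drop = FALSE],
                              tr, dir, bins = bins, ...)
      r <- map$rate
      r[is.na(r)] <- 0
      m[i, ] <- r
    }
    out[[dir]] <- m
  }
  out$bins <- bins
  out
}
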