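#' Detection parameters for calcium events
#'
#' Thresholds follow the slow/fast indicator convention: candidate events must
#' cross `mad_threshold` raw median absolute deviations (MAD, no normal
#' consistency constant — the integer multipliers absorb it), and within a
#' transient a peak must stand `peak_over_prev` MAD above the preceding trough
#' and `peak_over_next` MAD above the following trough to count as a separate
#' event. Kinetics: the fitted decay time must lie within `decay_tol` times
#' the configured indicator decay, and the decay/rise ratio must be at least
#' `decay_rise_ratio_min`.
#'
#' @param indicator `"slow"` (thresholds 4 / 4 / 2) or `"fast"` (5 / 5 / 2.5).
#' @param mad_threshold,peak_over_prev,peak_over_next MAD multiples; defaults
#'   set by `indicator`.
#' @param lowpass_cutoff low-pass cutoff in Hz.
#' @param baseline_window sliding-median baseline window in seconds.
#' @param neighbor_radius centroid distance in um defining neighbor cells.
#' @param crosstalk_window window in seconds within which neighboring cells may
#'   not both register an event (closed interval on |dt|).
#' @param dedup_correlation event-train correlation above which the lower-
#'   amplitude member of a neighbor pair is discarded.
#' @param dedup_bin bin width in seconds for the event-train correlation.
#' @param decay_rise_ratio_min minimum decay-to-rise time ratio.
#' @param indicator_decay nominal indicator decay constant in seconds.
#' @param decay_tol multiplicative tolerance band on the fitted decay.
#' @param frame_rate sampling rate in Hz.
#' @return an object of class `detection_params`.
#' @export
detection_params <- function(indicator = c("slow", "fast"),
                             mad_threshold = NULL,
                             peak_over_prev = NULL,
                             peak_over_next = NULL,
                             lowpass_cutoff = 2,
                             baseline_window = 20,
                             neighbor_radius = 18,
                             crosstalk_window = 0.2,
                             dedup_correlation = 0.9,
                             dedup_bin = 0.1,
                             decay_rise_ratio_min = 2,
                             indicator_decay = 1,
                             decay_tol = c(0.2, 5),
                             frame_rate = 20) {
  indicator <- match.arg(indicator)
  defs <- if (indicator == "slow") c(4, 4, 2) else c(5, 5, 2.5)
  p <- list(
    indicator = indicator,
    mad_threshold = if (is.null(mad_threshold)) defs[1] else mad_threshold,
    peak_over_prev = if (is.null(peak_over_prev)) defs[2] else peak_over_prev,
    peak_over_next = if (is.null(peak_over_next)) defs[3] else peak_over_next,
    lowpass_cutoff = lowpass_cutoff, baseline_window = baseline_window,
    neighbor_radius = neighbor_radius, crosstalk_window = crosstalk_window,
    dedup_correlation = dedup_correlation, dedup_bin = dedup_bin,
    decay_rise_ratio_min = decay_rise_ratio_min,
    indicator_decay = indicator_decay, decay_tol = decay_tol,
    frame_rate = frame_rate
  )
  with(p, {
    if (any(c(mad_threshold, peak_over_prev, peak_over_next,
              lowpass_cutoff, baseline_window) <= 0))
      stop("thresholds must be positive")
    if (crosstalk_window < 1 / frame_rate)
      stop("crosstalk_window must cover at least one frame")
  })
  class(p) <- "detection_params"
  p
}

#' Preprocess a dF/F trace for event detection
#'
#' Removes slow baseline fluctuations by subtracting a sliding-window median
#' (20 s by default), then applies a zero-phase second-order Butterworth
#' low-pass filter at `lowpass_cutoff`.
#'
#' @param trace numeric dF/F series.
#' @param params a [detection_params()].
#' @return filtered series, same length as the input.
#' @export
preprocess_trace <- function(trace, params) {
  n <- length(trace)
  k <- round(params$baseline_window * params$frame_rate)
  if (n <= k) stop("trace shorter than the baseline window")
  if (k %% 2 == 0) k <- k + 1
  detrended <- trace - stats::runmed(trace, k, endrule = "median")
  wc <- params$lowpass_cutoff / (params$frame_rate / 2)
  if (wc >= 1) return(detrended)
  bf <- signal::butter(2, wc, type = "low")
  as.numeric(signal::filtfilt(bf, detrended))
}

# local maxima indices of x (strict on the left, non-strict on the right)
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
}

#' Detect calcium events in a preprocessed trace
#'
#' Candidate peaks are local maxima above `mad_threshold` MADs of the trace.
#' Within a contiguous supra-threshold transient, consecutive maxima separated
#' by a shallow trough are merged: the later peak must rise `peak_over_prev`
#' MAD above the intervening trough and the earlier must drop `peak_over_next`
#' MAD to it for both to survive; otherwise only the higher peak is kept, so a
#' single transient yields a single event. Retained peaks must then pass the
#' kinetic filter (decay constant within `decay_tol` of the indicator decay,
#' decay/rise ratio at least `decay_rise_ratio_min`); a decay that cannot be
#' observed before the trace (or transient) ends is not held against the
#' event. The event time is the time of the peak.
#'
#' @param trace preprocessed dF/F series (see [preprocess_trace()]).
#' @param params a [detection_params()].
#' @param mad_value optionally, a precomputed MAD (raw, unscaled).
#' @return data.frame `frame`, `time_s`, `amplitude`; empty on a flat trace.
#' @export
detect_events <- function(trace, params, mad_value = NULL) {
  m <- if (is.null(mad_value)) stats::mad(trace, constant = 1) else mad_value
  empty <- data.frame(frame = integer(0), time_s = numeric(0),
                      amplitude = numeric(0))
  if (!is.finite(m) || m <= 0) return(empty)
  thr <- params$mad_threshold * m
  peaks <- local_maxima(trace)
  peaks <- peaks[trace[peaks] >= thr]
  if (length(peaks) == 0) return(empty)

  # merge maxima separated by shallow troughs (one event per transient)
  keep <- peaks[1]
  if (length(peaks) > 1) {
    for (p in peaks[-1]) {
      last <- keep[length(keep)]
      trough <- min(trace[last:p])
      distinct <- (trace[p] - trough >= params$peak_over_prev * m) &&
        (trace[last] - trough >= params$peak_over_next * m)
      if (distinct) {
        keep <- c(keep, p)
      } else if (trace[p] > trace[last]) {
        keep[length(keep)] <- p
      }
    }
  }

  ok <- vapply(keep, function(p) kinetics_ok(trace, p, m, params), logical(1))
  keep <- keep[ok]
  data.frame(frame = keep, time_s = (keep - 1) / params$frame_rate,
             amplitude = trace[keep])
}

# kinetic filter: rise and decay times measured symmetrically as the time
# between the peak and the 1/e-of-peak crossings on either side
kinetics_ok <- function(trace, p, m, params) {
  fr <- params$frame_rate
  amp <- trace[p]
  target <- amp * exp(-1)
  # rise: walk back to the 1/e crossing or the preceding trough, whichever
  # comes first (a transient riding a decay starts at the trough, not at
  # the earlier transient's baseline)
  on <- p
  while (on > 1 && trace[on - 1] < trace[on] && trace[on] > target)
    on <- on - 1
  rise <- max((p - on) / fr, 1 / fr)
  after <- which(trace[p:length(trace)] <= target)
  if (length(after) == 0) return(TRUE)  # decay unobserved: cannot reject
  decay <- (after[1] - 1) / fr
  lo <- params$decay_tol[1] * params$indicator_decay
  hi <- params$decay_tol[2] * params$indicator_decay
  if (decay < lo || decay > hi) return(FALSE)
  decay / rise >= params$decay_rise_ratio_min
}

#' Detect events for every cell of a trace set
#'
#' Runs [preprocess_trace()] and [detect_events()] per cell and session and
#' assembles a raw (pre-crosstalk) event table.
#'
#' @param traces a `trace_set` (named list of frames x cells session
#'   matrices, as returned by [render_fluorescence()]).
#' @param params a [detection_params()].
#' @param trial_frames frames per trial, used to recover trial/time indices.
#' @return event table with `cell_id,env,day,trial,time_s,amplitude`.
#' @export
detect_events_traces <- function(traces, params,
                                 trial_frames = 180 * params$frame_rate) {
  out <- list(); k <- 0L
  for (key in names(traces)) {
    parts <- strsplit(key, "_d")[[1]]
    mat <- traces[[key]]
    for (cell in seq_len(ncol(mat))) {
      x <- preprocess_trace(mat[, cell], params)
      ev <- detect_events(x, params)
      if (nrow(ev) == 0) next
      k <- k + 1L
      out[[k]] <- data.frame(
        cell_id = cell, env = parts[1], day = as.integer(parts[2]),
        trial = (ev$frame - 1) %/% trial_frames + 1L,
        time_s = ((ev$frame - 1) %% trial_frames) / params$frame_rate,
        amplitude = ev$amplitude
      )
    }
  }
  if (k == 0L) return(empty_event_table()[, 1:6])
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Resolve crosstalk between neighboring cells
#'
#' Cells whose session centroids are closer than `neighbor_radius` um are
#' neighbors. Among neighbor cells' events falling within
#' `crosstalk_window` of each other (closed interval on |dt|), only the
#' event with the highest peak is retained. Additionally, neighbor pairs
#' whose binned event trains (bin `dedup_bin`) correlate above
#' `dedup_correlation` lose the member with the lower mean peak amplitude
#' entirely (duplicate component of one cell).
#'
#' @param events event table (must contain `cell_id,env,day,trial,time_s,
#'   amplitude`).
#' @param centroids per-session centroids: a function or list mapping a
#'   session key (`"A_d1"`) to a matrix with rows = cell ids present, and
#'   row names the cell ids; or a single matrix (cells x 2) used for all
#'   sessions.
#' @param params a [detection_params()].
#' @param session_duration seconds per session (for binning); default from
#'   trials present.
#' @return filtered event table.
#' @export
resolve_crosstalk <- function(events, centroids, params,
                              session_duration = NULL) {
  if (nrow(events) == 0) return(events)
  keys <- unique(paste0(events$env, "_d", events$day))
  keep_rows <- rep(TRUE, nrow(events))
  for (key in keys) {
    rows <- which(paste0(events$env, "_d", events$day) == key & keep_rows)
    ev <- events[rows, ]
    cent <- if (is.matrix(centroids)) centroids
            else if (is.function(centroids)) centroids(key)
            else centroids[[key]]
    cells <- sort(unique(ev$cell_id))
    if (any(!cells %in% as.integer(rownames(cent))))
      stop("missing footprint centroid for a cell with events in ", key)
    idx <- match(cells, as.integer(rownames(cent)))
    d <- as.matrix(stats::dist(cent[idx, , drop = FALSE]))
    nb <- d < params$neighbor_radius & upper.tri(d)
    pairs <- which(nb, arr.ind = TRUE)
    if (nrow(pairs) == 0) next

    # absolute session time for windowing across trials
    tdur <- if (is.null(session_duration))
      stats::median(tapply(ev$time_s, ev$trial, max)) + 1 else session_duration
    abs_t <- (ev$trial - 1) * tdur + ev$time_s

    # duplicate-component rule first: correlated event trains
    drop_cell <- logical(length(cells))
    breaks <- seq(0, max(abs_t) + params$dedup_bin, by = params$dedup_bin)
    counts <- lapply(seq_along(cells), function(i) {
      tabulate(findInterval(abs_t[ev$cell_id == cells[i]], breaks),
               nbins = length(breaks))
    })
    for (r in seq_len(nrow(pairs))) {
      i <- pairs[r, 1]; j <- pairs[r, 2]
      if (drop_cell[i] || drop_cell[j]) next
      ci <- counts[[i]]; cj <- counts[[j]]
      if (stats::sd(ci) == 0 || stats::sd(cj) == 0) next
      if (stats::cor(ci, cj) > params$dedup_correlation) {
        mi <- mean(ev$amplitude[ev$cell_id == cells[i]])
        mj <- mean(ev$amplitude[ev$cell_id == cells[j]])
        drop_cell[if (mi < mj) i else j] <- TRUE
      }
    }
    dropped <- ev$cell_id %in% cells[drop_cell]

    # window rule: keep only the highest peak among coincident neighbor events
    alive <- !dropped
    ord <- order(-ev$amplitude)
    for (r in ord) {
      if (!alive[r]) next
      ni <- match(ev$cell_id[r], cells)
      partners <- c(pairs[pairs[, 1] == ni, 2], pairs[pairs[, 2] == ni, 1])
      if (length(partners) == 0) next
      clash <- alive & ev$cell_id %in% cells[partners] &
        abs(abs_t - abs_t[r]) <= params$crosstalk_window &
        ev$amplitude <= ev$amplitude[r] & seq_along(alive) != r
      alive[clash] <- FALSE
    }
    keep_rows[rows[!alive]] <- FALSE
  }
  out <- events[keep_rows, ]
  rownames(out) <- NULL
  out
}
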