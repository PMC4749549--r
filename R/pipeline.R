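#' Pipeline configuration
#'
#' Bundles stage toggles, the simulation config, detection parameters,
#' registration choices and decoder options for [run_pipeline()].
#'
#' @param sim a [sim_config()].
#' @param detection a [detection_params()] or NULL to skip trace detection
#'   (events are then taken directly from the generator).
#' @param registration_method `"truth"` (use ground-truth identities),
#'   `"correlation"` or `"distance"`.
#' @param registration_threshold threshold for the chosen method (NULL =
#'   method default).
#' @param run_place compute place-field statistics.
#' @param run_drift compute drift statistics.
#' @param run_decoders run the three time decoders.
#' @param n_label_shuffles chance-control shuffles for the decoders.
#' @param place_shuffles shuffles for place-field significance.
#' @param out_dir output directory (NULL = no files written).
#' @param seed global seed overriding the sim config's.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(),
                            detection = NULL,
                            registration_method = c("truth", "correlation",
                                                    "distance"),
                            registration_threshold = NULL,
                            run_place = TRUE, run_drift = TRUE,
                            run_decoders = TRUE,
                            n_label_shuffles = 10,
                            place_shuffles = 1000,
                            out_dir = NULL, seed = NULL) {
  registration_method <- match.arg(registration_method)
  if (!is.null(seed)) sim$seed <- as.integer(seed)
  structure(list(sim = sim, detection = detection,
                 registration_method = registration_method,
                 registration_threshold = registration_threshold,
                 run_place = run_place, run_drift = run_drift,
                 run_decoders = run_decoders,
                 n_label_shuffles = n_label_shuffles,
                 place_shuffles = place_shuffles,
                 out_dir = out_dir),
            class = "pipeline_config")
}

# tiny polynomial content hash for provenance records
content_hash <- function(x) {
  bytes <- as.integer(charToRaw(paste(deparse(x), collapse = "")))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Run the full analysis pipeline on synthetic data
#'
#' Executes generate -> (detect) -> register -> place -> drift -> decode with
#' the configured toggles, returns a report bundle and (optionally) writes
#' module CSVs, a JSON summary and a provenance record under `out_dir`.
#'
#' @param config a [pipeline_config()].
#' @return list with `dataset`, `registration` (if footprint-based),
#'   `place` (per-cell results), `drift`, `decoders`, `summary`,
#'   `provenance`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  cfg <- config$sim
  stage <- "generate"
  res <- tryCatch({
    need_fp <- config$registration_method != "truth"
    dataset <- generate_dataset(cfg, include_traces = FALSE,
                                include_footprints = need_fp)
    events <- dataset$events

    registration <- NULL
    n_master <- cfg$n_cells
    if (need_fp) {
      stage <- "register"
      registration <- register_cells(dataset$footprints,
                                     method = config$registration_method,
                                     threshold = config$registration_threshold)
      events <- apply_registration(events, dataset$footprints, registration)
      n_master <- attr(registration, "n_master")
    }

    place <- NULL
    if (config$run_place) {
      stage <- "place"
      place <- place_cell_table(events, dataset$trajectory, cfg,
                                n_shuffles = config$place_shuffles)
    }

    stage <- "drift"
    rates <- event_rate_table(events, n_master, cfg$day_values,
                              cfg$trials_per_session, cfg$trial_duration)
    av <- build_activity_vectors(events, n_master, cfg$day_values,
                                 cfg$trials_per_session,
                                 track_length = cfg$track_length)
    drift <- NULL
    if (config$run_drift) {
      drift <- list(
        correlation = ensemble_correlation_matrix(av$V, cfg$day_values),
        recurrence = recurrence_probability(rates$active, cfg$day_values)
      )
    }

    decoders <- NULL
    if (config$run_decoders) {
      stage <- "decode"
      decoders <- list(
        ordinal = ordinal_decoder(av$V, "both"),
        within_A = decoder_summary(within_env_decoder(av, "A")),
        within_B = decoder_summary(within_env_decoder(av, "B")),
        across_session = decoder_summary(
          across_env_decoder(av, "A", level = "session")),
        across_trial = decoder_summary(
          across_env_decoder(av, "A", level = "trial"))
      )
      if (config$n_label_shuffles > 0) {
        shuf <- shuffle_day_labels(av, config$n_label_shuffles,
                                   seed = substream_seed(cfg$seed, "labelshuf"))
        accs <- vapply(shuf, function(s)
          decoder_summary(within_env_decoder(s, "A",
                                             test_v = av$v[, , , 1])
          )$accuracy, numeric(1))
        decoders$within_A_shuffled_accuracy <- mean(accs)
      }
    }

    summary <- list(
      n_cells = cfg$n_cells, n_events = nrow(events),
      place_cell_fraction = if (!is.null(place))
        mean(place$is_place_cell[place$eligible]) else NA,
      ordinal_p = if (!is.null(decoders)) decoders$ordinal$p_value else NA,
      within_A_accuracy = if (!is.null(decoders))
        decoders$within_A$accuracy else NA,
      across_session_accuracy = if (!is.null(decoders))
        decoders$across_session$accuracy else NA
    )
    provenance <- list(config_hash = content_hash(unclass(config)),
                       seed = cfg$seed,
                       package_version = as.character(
                         utils::packageVersion("driftclock")))
    list(dataset = dataset, registration = registration, place = place,
         drift = drift, decoders = decoders, rates = rates, vectors = av,
         summary = summary, provenance = provenance)
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_event_table(res$dataset$events,
                      file.path(config$out_dir, "events.csv"))
    if (!is.null(res$registration))
      write_registration_table(res$registration,
                               file.path(config$out_dir, "registration.csv"))
    if (!is.null(res$place))
      utils::write.csv(res$place, file.path(config$out_dir, "place_cells.csv"),
                       row.names = FALSE)
    jsonlite::write_json(res$summary,
                         file.path(config$out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(res$provenance,
                         file.path(config$out_dir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  res
}

# map local per-session ids in a footprint-derived registration back onto
# event cell ids (which carry ground-truth identity in synthetic data)
apply_registration <- function(events, footprints, registration) {
  out <- events
  for (key in unique(paste0(events$env, "_d", events$day))) {
    ses <- footprints$sessions[[key]]
    reg <- registration[registration$session_key == key, ]
    lookup <- rep(NA_integer_, max(ses$truth_id, 1))
    lookup[ses$truth_id[reg$local_id]] <- reg$master_id
    rows <- paste0(events$env, "_d", events$day) == key
    mapped <- lookup[events$cell_id[rows]]
    out$cell_id[rows] <- mapped
  }
  out[!is.na(out$cell_id), ]
}

#' Per-cell place-field results for every session
#'
#' Runs [compute_rate_map()] and [place_field_significance()] for every cell
#' with events in each (env, day, direction) and returns a tidy table.
#'
#' @param events event table.
#' @param traj trajectory.
#' @param cfg a [sim_config()] (bin layout and schedule).
#' @param n_shuffles shuffles for the significance test.
#' @param alpha place-cell significance level.
#' @return data.frame `cell_id,env,day,direction,si_bits,p,eligible,
#'   is_place_cell,field_cm,n_events`.
#' @export
place_cell_table <- function(events, traj, cfg, n_shuffles = 1000,
                             alpha = 0.05) {
  bins <- track_bins(cfg$n_bins, cfg$track_length)
  rows <- list(); k <- 0L
  for (env in c("A", "B")) for (day in cfg$day_values) {
    tr <- traj[traj$env == env & traj$day == day, ]
    ev <- events[events$env == env & events$day == day, ]
    for (cell in sort(unique(ev$cell_id))) {
      for (dir in c("left", "right")) {
        map <- compute_rate_map(ev[ev$cell_id == cell, ], tr, dir,
                                bins = bins, frame_rate = cfg$frame_rate)
        pf <- place_field_significance(
          map, n_shuffles = n_shuffles, alpha = alpha,
          seed = substream_seed(cfg$seed, paste("pf", cell, env, day, dir)))
        k <- k + 1L
        rows[[k]] <- data.frame(cell_id = cell, env = env, day = day,
                                direction = dir, si_bits = pf$si_bits,
                                p = pf$p, eligible = pf$eligible,
                                is_place_cell = pf$is_place_cell,
                                field_cm = pf$field_cm,
                                n_events = pf$n_events)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Validate pipeline input files
#'
#' Schema checks for the CSV interfaces: event-table header and value
#' domains, registration-table header, and referential integrity of
#' registration session keys against the events.
#'
#' @param events_path path to an event-table CSV.
#' @param registration_path optional path to a registration CSV.
#' @return character vector of violations (empty if well-formed).
#' @export
validate_inputs <- function(events_path, registration_path = NULL) {
  violations <- character(0)
  ev <- tryCatch(utils::read.csv(events_path, stringsAsFactors = FALSE),
                 error = function(e) NULL)
  if (is.null(ev)) return(paste("unreadable events file:", events_path))
  violations <- c(violations, check_event_table(ev))
  if (!is.null(registration_path)) {
    reg <- tryCatch(utils::read.csv(registration_path,
                                    stringsAsFactors = FALSE),
                    error = function(e) NULL)
    if (is.null(reg))
      return(c(violations,
               paste("unreadable registration file:", registration_path)))
    need <- c("master_id", "session_key", "local_id", "score", "method")
    miss <- setdiff(need, names(reg))
    if (length(miss) > 0)
      violations <- c(violations, paste("registration missing column(s):",
                                        paste(miss, collapse = ", ")))
    if (!length(miss) && nrow(ev) > 0 &&
        all(c("env", "day") %in% names(ev))) {
      keys <- unique(paste0(ev$env, "_d", ev$day))
      bad <- setdiff(unique(reg$session_key), keys)
      if (length(bad) > 0)
        violations <- c(violations,
                        paste("registration cites unknown session(s):",
                              paste(bad, collapse = ", ")))
    }
  }
  violations
}
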