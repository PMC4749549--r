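# Shared fixtures, generated once per test run and cached.
.fixtures <- new.env(parent = emptyenv())

# default-regime dataset used by drift / decoder / place tests
fixture_dataset <- function() {
  if (is.null(.fixtures$ds)) {
    cfg <- sim_config(n_cells = 120, seed = 42)
    .fixtures$ds <- generate_dataset(cfg)
    .fixtures$av <- build_activity_vectors(.fixtures$ds$events, cfg$n_cells,
                                           cfg$day_values,
                                           track_length = cfg$track_length)
  }
  .fixtures$ds
}

fixture_vectors <- function() {
  fixture_dataset()
  .fixtures$av
}

# registration consistency against ground truth: fraction of assignments
# agreeing with the first master id seen for each true cell
registration_consistency <- function(reg, fp) {
  seen <- list(); ok <- 0
  for (r in seq_len(nrow(reg))) {
    tid <- as.character(
      fp$sessions[[reg$session_key[r]]]$truth_id[reg$local_id[r]])
    if (is.null(seen[[tid]])) seen[[tid]] <- reg$master_id[r]
    if (seen[[tid]] == reg$master_id[r]) ok <- ok + 1
  }
  ok / nrow(reg)
}

# uniform-occupancy rate_map object for closed-form spatial-information tests
uniform_map <- function(rates, occupancy = NULL) {
  n <- length(rates)
  occ <- if (is.null(occupancy)) rep(1, n) else occupancy
  p <- occ / sum(occ)
  structure(list(rate_raw = rates, rate = rates, occupancy_p = p,
                 occupancy_s = occ, n_events = sum(rates * occ),
                 valid = rep(TRUE, n)),
            class = "rate_map")
}
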