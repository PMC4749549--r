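#' Read and write event tables
#'
#' The on-disk dialect is plain CSV with header
#' `cell_id,env,day,trial,time_s,amplitude,position_cm,velocity_cm_s`.
#' The in-memory table may carry extra columns (e.g. `direction`); they are
#' dropped on write and recomputed on demand.
#'
#' @param events an event table data.frame.
#' @param path file path.
#' @return `read_event_table` returns the event table; `write_event_table`
#'   returns `path` invisibly.
#' @export
write_event_table <- function(events, path) {
  cols <- c("cell_id", "env", "day", "trial", "time_s", "amplitude",
            "position_cm", "velocity_cm_s")
  stopifnot(all(cols %in% names(events)))
  utils::write.csv(events[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_event_table
#' @export
read_event_table <- function(path) {
  ev <- utils::read.csv(path, stringsAsFactors = FALSE)
  violations <- check_event_table(ev)
  if (length(violations) > 0)
    stop("invalid event table: ", paste(violations, collapse = "; "))
  ev
}

check_event_table <- function(ev) {
  cols <- c("cell_id", "env", "day", "trial", "time_s", "amplitude",
            "position_cm", "velocity_cm_s")
  miss <- setdiff(cols, names(ev))
  v <- character(0)
  if (length(miss) > 0)
    v <- c(v, paste("missing column(s):", paste(miss, collapse = ", ")))
  if (nrow(ev) > 0 && !length(miss)) {
    if (!all(ev$env %in% c("A", "B"))) v <- c(v, "env outside {A,B}")
    if (any(ev$time_s < 0)) v <- c(v, "negative time_s")
    if (any(ev$trial < 1)) v <- c(v, "trial index < 1")
  }
  v
}

#' Read and write registration tables
#'
#' CSV dialect: `master_id,session_key,local_id,score,method`.
#' @param table a registration table data.frame.
#' @param path file path.
#' @export
write_registration_table <- function(table, path) {
  cols <- c("master_id", "session_key", "local_id", "score", "method")
  stopifnot(all(cols %in% names(table)))
  utils::write.csv(table[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_registration_table
#' @export
read_registration_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write ground-truth sidecar as JSON
#' @param dataset a `drift_dataset`.
#' @param path file path.
#' @export
write_ground_truth <- function(dataset, path) {
  truth <- list(
    seed = dataset$config$seed,
    n_cells = dataset$config$n_cells,
    is_place = dataset$truth$is_place,
    field_center_A = unname(dataset$truth$field_center[, "A"]),
    field_center_B = unname(dataset$truth$field_center[, "B"]),
    active_days = apply(dataset$truth$active, c(1, 3), function(a)
      paste(which(a), collapse = ","))
  )
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
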