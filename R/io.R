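#' Read and write trace CSV files
#'
#' Traces are stored as plain CSV with columns `observer`, `condition`,
#' `block`, `trial`, `time_ms`, `target_pos_deg`, `eye_pos_deg` (plus any
#' processing columns). The reader restores canonical ordering, checks the
#' time grid of every trial for gaps, and rejects duplicated
#' (observer, condition, block, trial, time_ms) keys.
#'
#' @param traces Long trace tibble.
#' @param path File path.
#' @return `write_trace_csv()` returns `path` invisibly;
#'   `read_trace_csv()` returns the trace tibble.
#' @export
write_trace_csv <- function(traces, path) {
  readr::write_csv(traces, path)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  tr <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("observer", "condition", "block", "trial", "time_ms",
            "eye_pos_deg")
  miss <- setdiff(need, names(tr))
  if (length(miss)) {
    abort(paste0("trace file lacks required column(s): ",
                 paste(miss, collapse = ", ")))
  }
  tr <- arrange(tr, .data$observer, .data$condition, .data$block,
                .data$trial, .data$time_ms)
  check <- tr |>
    group_by(.data$observer, .data$condition, .data$block, .data$trial) |>
    summarise(
      dup = anyDuplicated(.data$time_ms) > 0,
      gap_at = {
        d <- diff(.data$time_ms)
        if (length(d) && any(abs(d - d[1]) > 1e-9)) {
          .data$time_ms[which(abs(d - d[1]) > 1e-9)[1] + 1]
        } else NA_real_
      },
      .groups = "drop"
    )
  if (any(check$dup)) abort("duplicated time stamps within a trial")
  if (any(!is.na(check$gap_at))) {
    bad <- check[!is.na(check$gap_at), ][1, ]
    abort(sprintf("non-uniform time grid in trial %s/%s/%d/%d at t = %g ms",
                  bad$observer, bad$condition, bad$block, bad$trial,
                  bad$gap_at))
  }
  tr
}

#' Read and write trial-table CSV files
#'
#' Trial tables hold one row per trial (`observer`, `condition`, `block`,
#' `trial`, `leftward_velocity`, plus event or ground-truth columns). The
#' reader restores canonical (observer, condition, block, trial) order and
#' rejects duplicated keys with the offending line.
#'
#' @param table Trial tibble.
#' @param path File path.
#' @return `write_trial_table_csv()` returns `path` invisibly;
#'   `read_trial_table_csv()` returns the tibble.
#' @export
write_trial_table_csv <- function(table, path) {
  readr::write_csv(table, path)
  invisible(path)
}

#' @rdname write_trial_table_csv
#' @export
read_trial_table_csv <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("observer", "condition", "block", "trial")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    abort(paste0("trial table lacks required column(s): ",
                 paste(miss, collapse = ", ")))
  }
  key <- paste(tab$observer, tab$condition, tab$block, tab$trial)
  if (anyDuplicated(key)) {
    abort(sprintf("duplicated (observer, condition, block, trial) key at line %d",
                  which(duplicated(key))[1] + 1L))
  }
  arrange(tab, .data$observer, .data$condition, .data$block, .data$trial)
}

#' Serialize and restore a pipeline configuration
#'
#' Configurations round-trip losslessly through a plain-text key-value
#' (YAML) file.
#'
#' @param config A [pursuit_config()].
#' @param path File path.
#' @return `write_config()` returns `path` invisibly; `read_config()`
#'   returns a `pursuit_config`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pursuit_config"))
  lst <- unclass(config)
  lst$sim <- unclass(lst$sim)
  yaml::write_yaml(lst, path, precision = 15)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  lst <- yaml::read_yaml(path)
  sim <- lst$sim
  lst$sim <- NULL
  cfg <- do.call(pursuit_config, lst)
  if (!is.null(sim)) cfg$sim <- do.call(sim_model, sim)
  cfg
}

#' Hash of a configuration
#'
#' Stable hash embedded in every pipeline artifact so stages refuse to mix
#' artifacts produced under different configurations.
#'
#' @param config A [pursuit_config()].
#' @return A character hash.
#' @export
config_hash <- function(config) {
  lst <- unclass(config)
  lst$sim <- unclass(lst$sim)
  rlang::hash(lst)
}
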