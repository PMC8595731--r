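#' Run the end-to-end pipeline
#'
#' Executes the requested stages in their fixed order
#' `simulate -> preprocess -> events -> history -> distribution`, writing
#' one CSV artifact per stage into `out_dir` plus a run log (configuration
#' hash, seed, per-stage row counts, warnings). Later stages read the
#' artifacts of earlier ones, so a partial run needs its predecessors'
#' artifacts in `out_dir`; artifacts carry the configuration hash and the
#' runner refuses to consume artifacts from a different configuration
#' unless `allow_mixed_config = TRUE`. Re-running with an identical
#' configuration and seed reproduces identical artifacts.
#'
#' Artifacts: `traces.csv`, `trials.csv` (simulate); `processed.csv`
#' (preprocess); `events.csv` (events); `lme_table.csv` + `node.csv`
#' (history); `histogram.csv` + `medians.csv` (distribution);
#' `run_log.txt`.
#'
#' @param config A [pursuit_config()].
#' @param out_dir Output directory (created if missing).
#' @param stages Subset of
#'   `c("simulate", "preprocess", "events", "history", "distribution")`.
#' @param n_observers Observers to simulate (simulate stage).
#' @param conditions Conditions to simulate.
#' @param seed Integer seed governing the whole simulated cohort.
#' @param max_blocks Optional cap on blocks per condition (smoke runs).
#' @param allow_mixed_config Override the configuration-hash check.
#' @return Invisibly, a named list of artifact paths.
#' @export
run_pipeline <- function(config = pursuit_config(),
                         out_dir,
                         stages = c("simulate", "preprocess", "events",
                                    "history", "distribution"),
                         n_observers = 2,
                         conditions = c("predictable", "unpredictable"),
                         seed = 1,
                         max_blocks = NULL,
                         allow_mixed_config = FALSE) {
  order_all <- c("simulate", "preprocess", "events", "history",
                 "distribution")
  stages <- match.arg(stages, order_all, several.ok = TRUE)
  if (is.unsorted(match(stages, order_all))) {
    abort("stages must be requested in pipeline order: simulate, preprocess, events, history, distribution")
  }
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  hash <- config_hash(config)
  paths <- list(
    traces = file.path(out_dir, "traces.csv"),
    trials = file.path(out_dir, "trials.csv"),
    processed = file.path(out_dir, "processed.csv"),
    events = file.path(out_dir, "events.csv"),
    lme = file.path(out_dir, "lme_table.csv"),
    node = file.path(out_dir, "node.csv"),
    histogram = file.path(out_dir, "histogram.csv"),
    medians = file.path(out_dir, "medians.csv"),
    log = file.path(out_dir, "run_log.txt")
  )
  log_lines <- c(
    sprintf("config_hash: %s", hash),
    sprintf("seed: %d", seed),
    sprintf("stages: %s", paste(stages, collapse = ","))
  )
  note <- function(...) {
    log_lines <<- c(log_lines, sprintf(...))
  }
  need_artifact <- function(path, stage) {
    if (!file.exists(path)) {
      abort(sprintf("stage `%s` needs missing input artifact: %s", stage, path))
    }
    invisible(path)
  }
  check_hash <- function(tab, stage) {
    h <- attr(tab, "config_hash") %||% tab$config_hash[1]
    if (!allow_mixed_config && !is.null(h) && !is.na(h) && h != hash) {
      abort(sprintf("stage `%s`: artifact was produced under a different configuration (hash %s != %s); pass allow_mixed_config = TRUE to override",
                    stage, h, hash))
    }
    tab$config_hash <- NULL
    tab
  }
  stamp <- function(tab) {
    tab$config_hash <- hash
    tab
  }

  if ("simulate" %in% stages) {
    trials <- simulate_cohort(n_observers, conditions, config$sim, seed,
                              config, max_blocks = max_blocks)
    synth <- synthesize_eye_trace(trials, config$sim, seed, config)
    trials <- left_join(
      trials,
      select(synth$truth, "observer", "condition", "block", "trial",
             "true_onset_ms", "usable"),
      by = c("observer", "condition", "block", "trial")
    )
    write_trace_csv(stamp(synth$traces), paths$traces)
    write_trial_table_csv(stamp(trials), paths$trials)
    note("simulate: %d trials, %d trace samples", nrow(trials),
         nrow(synth$traces))
  }
  if ("preprocess" %in% stages) {
    traces <- check_hash(read_trace_csv(need_artifact(paths$traces,
                                                      "preprocess")),
                         "preprocess")
    processed <- preprocess_cohort(traces, config)
    write_trace_csv(stamp(processed), paths$processed)
    note("preprocess: %d samples", nrow(processed))
  }
  trials_tab <- NULL
  if (any(c("events", "history", "distribution") %in% stages)) {
    trials_tab <- check_hash(
      read_trial_table_csv(need_artifact(paths$trials, "events")), "events")
  }
  if ("events" %in% stages) {
    processed <- check_hash(
      read_trace_csv(need_artifact(paths$processed, "events")), "events")
    ev <- detect_events(processed, config) |>
      left_join(select(trials_tab, "observer", "condition", "block", "trial",
                       "leftward_velocity"),
                by = c("observer", "condition", "block", "trial"))
    write_trial_table_csv(stamp(ev), paths$events)
    rate <- inclusion_rate(ev)
    note("events: %d trials, %.1f%% included", nrow(ev),
         100 * mean(ev$included))
  }
  ev_tab <- NULL
  if (any(c("history", "distribution") %in% stages)) {
    ev_tab <- check_hash(
      read_trial_table_csv(need_artifact(paths$events, "history")),
      "history")
  }
  if ("history" %in% stages) {
    unpred <- filter(ev_tab, .data$condition == "unpredictable")
    grid <- model_grid_and_select(unpred, config$max_lag)
    lme_tab <- purrr::imap(grid$models, function(m, i) {
      if (is.null(m)) return(NULL)
      mutate(m$fixed, model = i, aic = m$aic, .before = 1)
    }) |> bind_rows()
    readr::write_csv(stamp(lme_tab), paths$lme)
    cls <- rank_classify(unpred, config$node_frac)
    node <- purrr::map(1:2, function(l) {
      bind_rows(
        mutate(node_sort(cls, l, "behavior"), lag = l, by = "behavior"),
        mutate(node_sort(cls, l, "stimulus"), lag = l, by = "stimulus")
      )
    }) |> bind_rows()
    readr::write_csv(mutate(node, config_hash = hash), paths$node)
    note("history: selected model %d of %d", grid$selected,
         nrow(grid$table))
  }
  if ("distribution" %in% stages) {
    norm <- normalize_timings(ev_tab)
    hist <- pooled_histogram(norm, config$hist_binwidth)
    readr::write_csv(mutate(hist$counts, config_hash = hash),
                     paths$histogram)
    readr::write_csv(mutate(hist$medians, config_hash = hash),
                     paths$medians)
    note("distribution: %d groups", nrow(hist$medians))
  }
  writeLines(log_lines, paths$log)
  invisible(paths)
}
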