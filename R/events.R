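#' Steady-state velocity and deceleration-onset threshold
#'
#' Pools the smoothed eye velocity over the steady-state window (default
#' 700-500 ms before target reversal) across all supplied trials of one
#' observer x condition, and sets the deceleration-onset threshold at 80%
#' of the pooled mean.
#'
#' @param processed Long tibble of preprocessed trials (needs `time_ms` and
#'   `vel_smooth`).
#' @param config A [pursuit_config()] (`steady_state_window`,
#'   `threshold_frac`).
#' @return A list with `mean_velocity`, `threshold`, `n_trials`.
#' @examples
#' # two constant trials at 10 and 20 deg/s -> threshold 12
#' @export
compute_steady_state_threshold <- function(processed,
                                           config = pursuit_config()) {
  stopifnot(is.data.frame(processed))
  if (nrow(processed) == 0) abort("no trials supplied")
  w <- config$steady_state_window
  ss <- processed |>
    filter(.data$time_ms >= w[1], .data$time_ms <= w[2])
  if (nrow(ss) == 0) {
    abort("no samples in the steady-state window; traces must cover it")
  }
  mv <- mean(ss$vel_smooth)
  list(mean_velocity = mv, threshold = config$threshold_frac * mv,
       n_trials = nrow(dplyr::distinct(
         ss, dplyr::pick(dplyr::any_of(c("observer", "condition", "block", "trial"))))))
}

# Shared detection core on one (time, velocity) pair. Returns the
# deceleration onset (sample resolution) and eye reversal (sub-sample,
# linear interpolation at the zero crossing), or NAs when undetected.
# Sustained-crossing rule: the onset is the first sample of the
# below-threshold run that contains the first sub-zero sample at or after
# `search_start_ms`.
detect_onset_reversal <- function(time_ms, vel, threshold,
                                  search_start_ms = -500) {
  in_win <- which(time_ms >= search_start_ms)
  if (length(in_win) < 2) {
    return(list(onset_ms = NA_real_, reversal_ms = NA_real_))
  }
  z_rel <- which(vel[in_win] < 0)
  if (length(z_rel) == 0) {
    return(list(onset_ms = NA_real_, reversal_ms = NA_real_))
  }
  z <- in_win[z_rel[1]]
  i <- z
  while (i > 1 && time_ms[i - 1] >= search_start_ms &&
           vel[i - 1] < threshold) {
    i <- i - 1
  }
  onset_ms <- time_ms[i]
  if (z == 1) {
    reversal_ms <- time_ms[z]
  } else {
    v0 <- vel[z - 1]
    v1 <- vel[z]
    reversal_ms <- if (v0 <= 0) time_ms[z - 1] else
      time_ms[z - 1] + (time_ms[z] - time_ms[z - 1]) * v0 / (v0 - v1)
  }
  list(onset_ms = onset_ms, reversal_ms = reversal_ms)
}

#' Detect the deceleration onset of one trial
#'
#' The onset is the earliest time in the search window at which the smoothed
#' eye velocity falls below the steady-state threshold and stays below it
#' continuously until the eye-reversal (zero) crossing. Returns `NA` when no
#' such time exists (e.g. the velocity never crosses zero).
#'
#' @param trial Preprocessed single-trial tibble (`time_ms`, `vel_smooth`).
#' @param threshold Velocity threshold (deg/s), from
#'   [compute_steady_state_threshold()].
#' @param search_start_ms Start of the onset search window (ms).
#' @return Onset time in ms, or `NA_real_` when undetected.
#' @export
detect_deceleration_onset <- function(trial, threshold,
                                      search_start_ms = -500) {
  detect_onset_reversal(trial$time_ms, trial$vel_smooth, threshold,
                        search_start_ms)$onset_ms
}

#' Detect the timing of eye reversal of one trial
#'
#' First time after the deceleration onset at which the smoothed eye
#' velocity falls below 0 deg/s, with linear sub-sample interpolation
#' between the bracketing samples.
#'
#' @inheritParams detect_deceleration_onset
#' @param onset_ms Detected onset (ms); `NA` propagates to `NA`.
#' @return Reversal time in ms, or `NA_real_`.
#' @export
detect_eye_reversal <- function(trial, onset_ms) {
  if (is.na(onset_ms)) return(NA_real_)
  idx <- which(trial$time_ms >= onset_ms)
  z_rel <- which(trial$vel_smooth[idx] < 0)
  if (length(z_rel) == 0) return(NA_real_)
  z <- idx[z_rel[1]]
  if (z == 1) return(trial$time_ms[1])
  v0 <- trial$vel_smooth[z - 1]
  v1 <- trial$vel_smooth[z]
  if (v0 <= 0) return(trial$time_ms[z - 1])
  trial$time_ms[z - 1] + (trial$time_ms[z] - trial$time_ms[z - 1]) * v0 / (v0 - v1)
}

#' Mean eye deceleration between onset and reversal
#'
#' Arithmetic mean of the event-stage acceleration samples in
#' `[onset, reversal]`.
#'
#' @param trial Preprocessed single-trial tibble (`time_ms`,
#'   `accel_smooth`).
#' @param onset_ms,reversal_ms Detected event times (ms).
#' @return Mean acceleration (deg/s^2), or `NA_real_` for degenerate spans
#'   (fewer than 2 samples) or undetected events.
#' @export
mean_deceleration <- function(trial, onset_ms, reversal_ms) {
  if (is.na(onset_ms) || is.na(reversal_ms) || onset_ms >= reversal_ms) {
    return(NA_real_)
  }
  sel <- trial$time_ms >= onset_ms & trial$time_ms <= reversal_ms
  if (sum(sel) < 2) return(NA_real_)
  mean(trial$accel_smooth[sel])
}

#' Apply the trial exclusion rules
#'
#' A trial is excluded when the deceleration onset is earlier than -300 ms
#' relative to target reversal (`early_onset`), when the eye reversal
#' occurs after +100 ms (`late_reversal`), or when either event is
#' undetected (`undetected`).
#'
#' @param events Tibble with columns `onset_ms`, `reversal_ms`.
#' @param config A [pursuit_config()].
#' @return `events` with columns `included` (logical) and
#'   `exclusion_reason` (`"none"`, `"early_onset"`, `"late_reversal"`,
#'   `"undetected"`).
#' @export
apply_exclusion <- function(events, config = pursuit_config()) {
  stopifnot(all(c("onset_ms", "reversal_ms") %in% names(events)))
  lo <- config$exclusion_onset_min_ms
  hi <- config$exclusion_reversal_max_ms
  events |>
    mutate(
      exclusion_reason = dplyr::case_when(
        is.na(.data$onset_ms) | is.na(.data$reversal_ms) ~ "undetected",
        .data$onset_ms < lo ~ "early_onset",
        .data$reversal_ms > hi ~ "late_reversal",
        TRUE ~ "none"
      ),
      included = .data$exclusion_reason == "none"
    )
}

#' Inclusion rate per observer and condition
#'
#' @param events Event tibble with `observer`, `condition`, `included`.
#' @return A list with `per_observer` (tibble: observer, condition, n,
#'   n_included, rate) and `summary` (tibble per condition: mean, SD, range
#'   of the per-observer percentage).
#' @export
inclusion_rate <- function(events) {
  if (nrow(events) == 0) abort("empty event table")
  per <- events |>
    group_by(.data$observer, .data$condition) |>
    summarise(n = n(), n_included = sum(.data$included),
              rate = mean(.data$included), .groups = "drop")
  summ <- per |>
    group_by(.data$condition) |>
    summarise(mean_pct = 100 * mean(.data$rate),
              sd_pct = 100 * sd(.data$rate),
              min_pct = 100 * min(.data$rate),
              max_pct = 100 * max(.data$rate), .groups = "drop")
  list(per_observer = per, summary = summ)
}

#' Detect predictive-pursuit events for a preprocessed cohort
#'
#' For each observer x condition, computes the steady-state threshold from
#' all trials, detects the deceleration onset, eye reversal and mean
#' deceleration per trial, and applies the exclusion rules.
#'
#' @param processed Long preprocessed trace tibble (from
#'   [preprocess_cohort()]).
#' @param config A [pursuit_config()].
#' @return A trial-events tibble: `observer`, `condition`, `block`,
#'   `trial`, `leftward_velocity` (when present in `processed`),
#'   `onset_ms`, `reversal_ms`, `mean_decel`, `included`,
#'   `exclusion_reason`, `threshold`.
#' @export
detect_events <- function(processed, config = pursuit_config()) {
  groups <- processed |>
    dplyr::group_split(.data$observer, .data$condition)
  out <- purrr::map(groups, function(g) {
    stats <- compute_steady_state_threshold(g, config)
    g |>
      dplyr::group_split(.data$block, .data$trial) |>
      purrr::map(function(tr) {
        det <- detect_onset_reversal(tr$time_ms, tr$vel_smooth,
                                     stats$threshold,
                                     config$onset_search_start_ms)
        md <- mean_deceleration(tr, det$onset_ms, det$reversal_ms)
        row <- tibble::tibble(
          observer = tr$observer[1], condition = tr$condition[1],
          block = tr$block[1], trial = tr$trial[1],
          onset_ms = det$onset_ms, reversal_ms = det$reversal_ms,
          mean_decel = md, threshold = stats$threshold
        )
        if ("leftward_velocity" %in% names(tr)) {
          row$leftward_velocity <- tr$leftward_velocity[1]
        }
        row
      }) |>
      bind_rows()
  }) |>
    bind_rows() |>
    apply_exclusion(config)
  arrange(out, .data$observer, .data$condition, .data$block, .data$trial)
}
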