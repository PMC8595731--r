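#' Generate a stimulus sequence for one observer
#'
#' Builds the trial table of an irregular triangular-waveform session. Every
#' trial is a rightward ramp at 16 deg/s followed by a leftward ramp whose
#' velocity is one of 4, 8, 12, 16, 20, 24, 28 deg/s. In the predictable
#' condition the leftward velocity is fixed within a block (7 blocks x 30
#' trials, block order a random permutation of the seven velocities); in the
#' unpredictable condition each of 5 blocks holds all seven velocities seven
#' times in randomized order (49 trials per block).
#'
#' @param condition `"predictable"` or `"unpredictable"`.
#' @param observer Observer label.
#' @param seed Integer seed; identical seeds give identical sequences.
#' @param config A [pursuit_config()].
#'
#' @return A tibble with columns `observer`, `condition`, `block`, `trial`,
#'   `rightward_velocity`, `leftward_velocity`.
#' @examples
#' seq <- generate_stimulus_sequence("predictable", "s01", seed = 7)
#' nrow(seq)  # 210
#' @export
generate_stimulus_sequence <- function(condition,
                                       observer = "s01",
                                       seed = 1,
                                       config = pursuit_config()) {
  if (length(condition) != 1 || !condition %in% c("predictable", "unpredictable")) {
    abort("`condition` must be one of \"predictable\", \"unpredictable\"")
  }
  lev <- config$velocity_levels
  local_seed(seed, {
    if (condition == "predictable") {
      order <- sample(lev)
      blocks <- purrr::map(seq_along(order), function(b) {
        tibble::tibble(block = b, trial = 1:30, leftward_velocity = order[b])
      })
    } else {
      blocks <- purrr::map(1:5, function(b) {
        tibble::tibble(block = b, trial = 1:49,
                       leftward_velocity = sample(rep(lev, 7)))
      })
    }
    out <- bind_rows(blocks)
  })
  tibble::tibble(
    observer = observer,
    condition = condition,
    block = out$block,
    trial = out$trial,
    rightward_velocity = config$rightward_velocity,
    leftward_velocity = out$leftward_velocity
  )
}

#' Render the target trajectory of a stimulus sequence
#'
#' Expands a trial table into the continuous triangular target waveform on a
#' 1 kHz grid, block by block (each block restarts at the common starting
#' position). There is no pause between ramps: each rightward ramp covers
#' the travel distance at the fixed rightward velocity and each leftward
#' ramp covers it at the trial's leftward velocity.
#'
#' @param trials A trial table from [generate_stimulus_sequence()] (one
#'   observer; may hold several blocks).
#' @param config A [pursuit_config()].
#'
#' @return A tibble with columns `block`, `trial`, `time_ms` (per-block
#'   clock), `target_pos_deg`, `target_vel_deg_s`. The right-to-left
#'   reversal times are attached as the attribute `"reversals"`, a tibble
#'   with `block`, `trial`, `reversal_ms`, `leftward_duration_ms`.
#' @export
render_target_trajectory <- function(trials, config = pursuit_config()) {
  stopifnot(is.data.frame(trials), nrow(trials) > 0)
  travel <- config$travel_distance_deg
  v_right <- config$rightward_velocity
  dt <- 1000 / config$sample_rate_hz   # ms
  right_dur <- 1000 * travel / v_right # ms

  per_block <- trials |>
    dplyr::group_split(.data$block)
  samples <- vector("list", length(per_block))
  revs <- vector("list", length(per_block))
  for (bi in seq_along(per_block)) {
    blk <- per_block[[bi]]
    left_dur <- 1000 * travel / blk$leftward_velocity
    trial_dur <- right_dur + left_dur
    t_start <- cumsum(c(0, trial_dur[-length(trial_dur)]))
    reversal_ms <- t_start + right_dur
    tr_samples <- purrr::map(seq_len(nrow(blk)), function(i) {
      t <- seq(t_start[i], t_start[i] + trial_dur[i] - dt, by = dt)
      tl <- t - t_start[i]
      vel <- ifelse(tl < right_dur, v_right, -blk$leftward_velocity[i])
      pos <- ifelse(
        tl < right_dur,
        -travel / 2 + v_right * tl / 1000,
        travel / 2 - blk$leftward_velocity[i] * (tl - right_dur) / 1000
      )
      tibble::tibble(block = blk$block[1], trial = blk$trial[i],
                     time_ms = t, target_pos_deg = pos, target_vel_deg_s = vel)
    })
    samples[[bi]] <- bind_rows(tr_samples)
    revs[[bi]] <- tibble::tibble(
      block = blk$block[1], trial = blk$trial,
      reversal_ms = reversal_ms, leftward_duration_ms = left_dur
    )
  }
  out <- bind_rows(samples)
  attr(out, "reversals") <- bind_rows(revs)
  out
}
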