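#' Simulate eye-reversal timings from the history-weighted model
#'
#' Draws the timing of eye reversal for every trial of a stimulus sequence
#' from the autoregressive history model of [sim_model()]. History resets at
#' block boundaries; within the first `K` trials of a block (`K` = number of
#' lags) unavailable lags contribute 0 and the trial is flagged `burn_in`.
#'
#' @param trials A trial table (one or more observers) from
#'   [generate_stimulus_sequence()].
#' @param model A [sim_model()].
#' @param seed Integer seed. Per-(observer, block) streams are derived from
#'   it, so the timings of a block do not depend on the other blocks.
#'
#' @return `trials` with added columns `true_reversal_ms` and `burn_in`.
#' @examples
#' tr <- generate_stimulus_sequence("unpredictable", seed = 1)
#' tt <- simulate_reversal_timings(tr, sim_model(noise_sd = 0), seed = 1)
#' @export
simulate_reversal_timings <- function(trials, model = sim_model(), seed = 1) {
  stopifnot(is.data.frame(trials), inherits(model, "pursuit_sim_model"))
  ks <- length(model$beta_stim)
  kb <- length(model$beta_behav)
  kmax <- max(ks, kb, 1L)

  trials <- arrange(trials, .data$observer, .data$block, .data$trial)
  obs_levels <- unique(trials$observer)
  intercepts <- local_seed(derive_seed(seed, 1L), {
    stats::setNames(rnorm(length(obs_levels), 0, model$subject_intercept_sd),
                    obs_levels)
  })

  out <- trials |>
    dplyr::group_split(.data$observer, .data$block) |>
    purrr::map(function(blk) {
      obs_i <- match(blk$observer[1], obs_levels)
      eps <- local_seed(derive_seed(seed, 2L, obs_i, blk$block[1]), {
        rnorm(nrow(blk), 0, model$noise_sd)
      })
      v <- blk$leftward_velocity
      t_rev <- numeric(nrow(blk))
      b0 <- model$beta0 + intercepts[[blk$observer[1]]]
      for (i in seq_len(nrow(blk))) {
        s_hist <- 0
        if (ks > 0) {
          for (k in seq_len(min(ks, i - 1))) s_hist <- s_hist + model$beta_stim[k] * v[i - k]
        }
        b_hist <- 0
        if (kb > 0) {
          for (k in seq_len(min(kb, i - 1))) b_hist <- b_hist + model$beta_behav[k] * t_rev[i - k]
        }
        t_rev[i] <- b0 + s_hist + b_hist + eps[i]
      }
      blk$true_reversal_ms <- t_rev
      blk$burn_in <- blk$trial <= kmax
      blk
    }) |>
    bind_rows()
  arrange(out, .data$observer, .data$block, .data$trial)
}

#' Simulate a cohort of observers at the timing level
#'
#' Convenience wrapper: stimulus sequences plus history-model reversal
#' timings for `n_observers` observers, without rendering eye traces. This
#' is the input the history and distribution stages consume.
#'
#' @param n_observers Number of observers.
#' @param conditions Conditions to simulate for every observer.
#' @param model A [sim_model()].
#' @param seed Integer seed.
#' @param config A [pursuit_config()].
#' @param max_blocks Optional cap on blocks per condition (quick looks and
#'   smoke tests); `NULL` keeps the full design.
#'
#' @return A trial tibble with `true_reversal_ms` and `burn_in` columns.
#' @export
simulate_cohort <- function(n_observers = 12,
                            conditions = c("predictable", "unpredictable"),
                            model = sim_model(),
                            seed = 1,
                            config = pursuit_config(),
                            max_blocks = NULL) {
  obs <- sprintf("s%02d", seq_len(n_observers))
  trials <- purrr::map(seq_along(obs), function(i) {
    purrr::map(conditions, function(cond) {
      generate_stimulus_sequence(
        cond, obs[i],
        seed = derive_seed(seed, 3L, i, match(cond, c("predictable", "unpredictable"))),
        config = config
      )
    }) |> bind_rows()
  }) |> bind_rows()
  if (!is.null(max_blocks)) {
    trials <- filter(trials, .data$block <= max_blocks)
  }
  simulate_reversal_timings(trials, model, seed = seed)
}

# Minimum-jerk unit step profile on s in [0, 1].
min_jerk <- function(s) {
  s <- pmin(pmax(s, 0), 1)
  10 * s^3 - 15 * s^4 + 6 * s^5
}

# Raised-cosine phase at which a ramp from v1 down to v2 crosses zero.
raised_cosine_zero_phase <- function(v1, v2) {
  stopifnot(v1 > 0, v2 < 0)
  acos(1 - 2 * v1 / (v1 - v2)) / pi
}

#' Synthesize eye-position traces with known ground truth
#'
#' Renders one 1 kHz eye-position trace per trial over a window around the
#' right-to-left target reversal (time 0). During steady state the eye moves
#' at `pursuit_gain` times the target velocity; around the reversal the eye
#' velocity follows a raised-cosine deceleration from the rightward
#' steady-state velocity to the leftward one, crossing 0 deg/s exactly at
#' the trial's simulated reversal timing. The true deceleration onset (ramp
#' start) leads the reversal by a per-trial uniform draw. Gaussian position
#' noise and minimum-jerk catch-up saccades are added on top.
#'
#' @param trials Trial table with `true_reversal_ms` (from
#'   [simulate_reversal_timings()]).
#' @param model A [sim_model()].
#' @param seed Integer seed.
#' @param config A [pursuit_config()]; `trace_window_ms` sets the rendered
#'   window relative to the target reversal.
#'
#' @return A list with elements
#'   \describe{
#'     \item{traces}{tibble `observer, condition, block, trial, time_ms,
#'       target_pos_deg, eye_pos_deg`}
#'     \item{truth}{tibble of ground-truth events per trial:
#'       `true_reversal_ms`, `true_onset_ms`, `usable`}
#'     \item{saccades}{tibble of injected saccade intervals
#'       (`start_ms`, `end_ms`)}
#'   }
#' @export
synthesize_eye_trace <- function(trials, model = sim_model(), seed = 1,
                                 config = pursuit_config()) {
  stopifnot(is.data.frame(trials))
  if (nrow(trials) == 0) {
    return(list(
      traces = tibble::tibble(observer = character(), condition = character(),
                              block = integer(), trial = integer(),
                              time_ms = numeric(), target_pos_deg = numeric(),
                              eye_pos_deg = numeric()),
      truth = tibble::tibble(observer = character(), condition = character(),
                             block = integer(), trial = integer(),
                             true_reversal_ms = numeric(),
                             true_onset_ms = numeric(), usable = logical()),
      saccades = tibble::tibble(observer = character(),
                                condition = character(), block = integer(),
                                trial = integer(), start_ms = numeric(),
                                end_ms = numeric())
    ))
  }
  if (!"true_reversal_ms" %in% names(trials)) {
    abort("`trials` must carry `true_reversal_ms`; run simulate_reversal_timings() first")
  }
  win <- config$trace_window_ms
  dt <- 1000 / config$sample_rate_hz
  t <- seq(win[1], win[2], by = dt)
  n <- length(t)
  g <- model$pursuit_gain
  v_r <- config$rightward_velocity
  travel <- config$travel_distance_deg

  rows <- vector("list", nrow(trials))
  truths <- vector("list", nrow(trials))
  saccs <- vector("list", nrow(trials))
  for (i in seq_len(nrow(trials))) {
    tr <- trials[i, ]
    sd_i <- derive_seed(seed, 4L, i)
    v_l <- tr$leftward_velocity
    t_rev <- tr$true_reversal_ms

    target_vel <- ifelse(t < 0, v_r, -v_l)
    target_pos <- ifelse(t < 0, travel / 2 + v_r * t / 1000,
                         travel / 2 - v_l * t / 1000)

    res <- local_seed(sd_i, {
      lead <- runif(1, model$onset_lead_range[1], model$onset_lead_range[2])
      onset <- t_rev - lead
      v1 <- g * v_r
      v2 <- -g * v_l
      s0 <- raised_cosine_zero_phase(v1, v2)
      ramp_dur <- lead / s0
      usable <- onset > win[1] + 100 && t_rev < win[2] - 100
      s <- (t - onset) / ramp_dur
      eye_vel <- ifelse(s <= 0, v1,
                        ifelse(s >= 1, v2, v1 + (v2 - v1) * (1 - cos(pi * s)) / 2))
      # trapezoidal integration so central differencing recovers eye_vel
      incr <- dt / 1000 * (eye_vel[-1] + eye_vel[-n]) / 2
      eye_pos <- target_pos[1] + c(0, cumsum(incr))

      sac <- NULL
      if (model$saccade_rate > 0) {
        span_s <- (win[2] - win[1] - 200) / 1000
        n_sac <- rpois(1, model$saccade_rate * span_s)
        if (n_sac > 0) {
          starts <- sort(runif(n_sac, win[1] + 100, win[2] - 150))
          durs <- runif(n_sac, model$saccade_duration_range[1],
                        model$saccade_duration_range[2])
          amps <- runif(n_sac, model$saccade_amplitude_range[1],
                        model$saccade_amplitude_range[2])
          for (j in seq_len(n_sac)) {
            dir <- if (starts[j] < t_rev) 1 else -1
            eye_pos <- eye_pos + dir * amps[j] * min_jerk((t - starts[j]) / durs[j])
          }
          sac <- tibble::tibble(start_ms = starts, end_ms = starts + durs)
        }
      }
      if (model$position_noise_sd > 0) {
        eye_pos <- eye_pos + rnorm(n, 0, model$position_noise_sd)
      }
      list(eye_pos = eye_pos, onset = onset, usable = usable, sac = sac)
    })

    rows[[i]] <- tibble::tibble(
      observer = tr$observer, condition = tr$condition,
      block = tr$block, trial = tr$trial,
      time_ms = t, target_pos_deg = target_pos, eye_pos_deg = res$eye_pos
    )
    truths[[i]] <- tibble::tibble(
      observer = tr$observer, condition = tr$condition,
      block = tr$block, trial = tr$trial,
      true_reversal_ms = t_rev, true_onset_ms = res$onset, usable = res$usable
    )
    if (!is.null(res$sac)) {
      saccs[[i]] <- tibble::tibble(
        observer = tr$observer, condition = tr$condition,
        block = tr$block, trial = tr$trial,
        start_ms = res$sac$start_ms, end_ms = res$sac$end_ms
      )
    }
  }
  list(
    traces = bind_rows(rows),
    truth = bind_rows(truths),
    saccades = if (length(purrr::compact(saccs))) bind_rows(saccs) else
      tibble::tibble(observer = character(), condition = character(),
                     block = integer(), trial = integer(),
                     start_ms = numeric(), end_ms = numeric())
  )
}
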