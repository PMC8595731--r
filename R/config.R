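#' Pipeline configuration
#'
#' Bundles every numeric constant of the analysis pipeline with its default:
#' 1 kHz sampling, an 80-point 30 Hz FIR low-pass, a 1000 deg/s^2 saccade
#' acceleration criterion with 10 ms padding, a 40 ms moving-average window,
#' the (-700, -500) ms steady-state window with an 80% velocity threshold,
#' event exclusion bounds (-300, +100) ms, a 20% node-classification
#' fraction, history lags up to 5, and a 0.25 histogram bin width. The `sim`
#' element holds the generative model used by the synthetic-data stage (see
#' [sim_model()]).
#'
#' @param ... Named overrides for any configuration field. Unknown names are
#'   an error. `sim` may be given as a list of [sim_model()] overrides.
#'
#' @return A named list of class `pursuit_config`.
#' @examples
#' cfg <- pursuit_config(ma_window_ms = 50)
#' cfg$saccade_threshold
#' @export
pursuit_config <- function(...) {
  cfg <- list(
    sample_rate_hz = 1000,
    fir_order = 80,
    fir_cutoff_hz = 30,
    saccade_threshold = 1000,   # deg/s^2
    saccade_pad_ms = 10,
    ma_window_ms = 40,
    steady_state_window = c(-700, -500),  # ms relative to target reversal
    threshold_frac = 0.8,
    onset_search_start_ms = -500,
    exclusion_onset_min_ms = -300,
    exclusion_reversal_max_ms = 100,
    node_frac = 0.2,
    max_lag = 5,
    hist_binwidth = 0.25,
    travel_distance_deg = 24,
    rightward_velocity = 16,    # deg/s
    velocity_levels = c(4, 8, 12, 16, 20, 24, 28),
    trace_window_ms = c(-1500, 800),
    sim = sim_model()
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(cfg))
    if (length(bad) || is.null(names(dots)) || any(names(dots) == "")) {
      abort(paste0("unknown configuration field(s): ",
                   paste(bad, collapse = ", ")))
    }
    if ("sim" %in% names(dots) && !inherits(dots$sim, "pursuit_sim_model")) {
      dots$sim <- do.call(sim_model, as.list(dots$sim))
    }
    cfg[names(dots)] <- dots
  }
  validate_config(cfg)
  structure(cfg, class = "pursuit_config")
}

validate_config <- function(cfg) {
  pos <- c("sample_rate_hz", "fir_cutoff_hz", "saccade_threshold",
           "ma_window_ms", "threshold_frac", "node_frac", "hist_binwidth",
           "travel_distance_deg", "rightward_velocity")
  for (f in pos) {
    if (!is.numeric(cfg[[f]]) || cfg[[f]] <= 0) {
      abort(paste0("configuration field `", f, "` must be positive"))
    }
  }
  if (cfg$fir_order < 2) abort("`fir_order` must be >= 2")
  if (cfg$max_lag < 1 || cfg$max_lag > 5) abort("`max_lag` must be in 1..5")
  if (diff(cfg$steady_state_window) <= 0) {
    abort("`steady_state_window` must be an increasing (start, end) pair")
  }
  invisible(cfg)
}

#' Generative model for synthetic reversal timings and eye traces
#'
#' Defines the history-weighted behavioral model used to simulate the timing
#' of eye reversal, plus the trace-level parameters (pursuit gain, position
#' noise, catch-up saccades). The timing of eye reversal on trial n is
#' \deqn{T_n = \beta_0 + b_{obs} + \sum_k \beta^{stim}_k V_{n-k} +
#'   \sum_k \beta^{behav}_k T_{n-k} + \varepsilon_n,}
#' with a per-observer random intercept \eqn{b_{obs}} and i.i.d. Gaussian
#' noise. Histories reset at block boundaries; within the first `K` trials of
#' a block, unavailable lags contribute 0 (burn-in rule) and those trials are
#' flagged as burn-in.
#'
#' Defaults are the fitted full-history model reported for unpredictable
#' tracking of the seven-velocity ramp stimulus (intercept 30.620 ms;
#' stimulus-lag weights -0.096, -0.417, -0.215, 0.034, -0.074 ms per deg/s;
#' behavior-lag weights 0.078, 0.093, 0.029, 0.001, 0.029), with a residual
#' SD of 32.5 ms implied by the reported standard errors.
#'
#' @param beta0 Fixed intercept (ms).
#' @param subject_intercept_sd SD of the per-observer random intercept (ms).
#' @param beta_stim Stimulus-history weights, lags 1..K (ms per deg/s).
#' @param beta_behav Behavior-history weights, lags 1..K (dimensionless).
#' @param noise_sd Residual SD of the timing model (ms).
#' @param pursuit_gain Steady-state eye/target velocity ratio (0, 1.2].
#' @param saccade_rate Mean catch-up saccade rate (per second).
#' @param saccade_amplitude_range Saccade amplitude range (deg).
#' @param saccade_duration_range Saccade duration range (ms).
#' @param position_noise_sd Gaussian position noise SD (deg).
#' @param onset_lead_range Range (ms) of the lead of the true deceleration
#'   onset ahead of the true eye reversal; drawn uniformly per trial.
#'
#' @return A list of class `pursuit_sim_model`.
#' @examples
#' m <- sim_model(noise_sd = 0, saccade_rate = 0)
#' m$beta0
#' @export
sim_model <- function(beta0 = 30.620,
                      subject_intercept_sd = 10,
                      beta_stim = c(-0.096, -0.417, -0.215, 0.034, -0.074),
                      beta_behav = c(0.078, 0.093, 0.029, 0.001, 0.029),
                      noise_sd = 32.5,
                      pursuit_gain = 0.95,
                      saccade_rate = 1,
                      saccade_amplitude_range = c(1, 3),
                      saccade_duration_range = c(20, 40),
                      position_noise_sd = 0.05,
                      onset_lead_range = c(100, 250)) {
  m <- list(
    beta0 = beta0,
    subject_intercept_sd = subject_intercept_sd,
    beta_stim = beta_stim,
    beta_behav = beta_behav,
    noise_sd = noise_sd,
    pursuit_gain = pursuit_gain,
    saccade_rate = saccade_rate,
    saccade_amplitude_range = saccade_amplitude_range,
    saccade_duration_range = saccade_duration_range,
    position_noise_sd = position_noise_sd,
    onset_lead_range = onset_lead_range
  )
  if (m$subject_intercept_sd < 0 || m$noise_sd < 0 || m$position_noise_sd < 0) {
    abort("all standard deviations in `sim_model()` must be >= 0")
  }
  if (m$pursuit_gain <= 0 || m$pursuit_gain > 1.2) {
    abort("`pursuit_gain` must be in (0, 1.2]")
  }
  if (length(m$beta_stim) > 5 || length(m$beta_behav) > 5) {
    abort("history weights support at most 5 lags")
  }
  if (m$saccade_rate < 0) abort("`saccade_rate` must be >= 0")
  if (sum(abs(m$beta_behav)) >= 1) {
    warn("sum(|beta_behav|) >= 1: autoregressive timing model may be nonstationary")
  }
  structure(m, class = "pursuit_sim_model")
}
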