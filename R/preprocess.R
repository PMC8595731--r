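#' Central-difference differentiation
#'
#' Differentiates a uniformly sampled signal with the central difference
#' `v[i] = (x[i+1] - x[i-1]) / (2 dt)`; the endpoints use one-sided
#' differences so the output keeps the input length. Exact for quadratics at
#' interior points.
#'
#' @param x Numeric vector (e.g. eye position in deg).
#' @param dt Sample interval in seconds (default 1 kHz).
#' @return Numeric vector of the same length (e.g. deg/s).
#' @examples
#' differentiate_central(seq(0, 1, by = 0.016), dt = 0.001)[2]  # 16
#' @export
differentiate_central <- function(x, dt = 0.001) {
  n <- length(x)
  if (n < 3) abort("differentiate_central() needs at least 3 samples")
  v <- numeric(n)
  v[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / (2 * dt)
  v[1] <- (x[2] - x[1]) / dt
  v[n] <- (x[n] - x[n - 1]) / dt
  v
}

#' Design the low-pass FIR filter
#'
#' Hamming-window linear-phase low-pass of the given order (order 80 gives
#' 81 taps), normalized to unit DC gain.
#'
#' @param order Filter order.
#' @param cutoff_hz Passband edge in Hz.
#' @param fs Sampling rate in Hz.
#' @return Numeric vector of `order + 1` symmetric coefficients.
#' @export
design_lowpass_fir <- function(order = 80, cutoff_hz = 30, fs = 1000) {
  if (cutoff_hz <= 0 || cutoff_hz >= fs / 2) {
    abort("`cutoff_hz` must lie in (0, fs/2)")
  }
  h <- signal::fir1(order, cutoff_hz / (fs / 2), type = "low")
  as.numeric(h) / sum(h)
}

#' Frequency response magnitude of an FIR filter
#'
#' @param h FIR coefficients.
#' @param freq_hz Frequencies at which to evaluate (Hz).
#' @param fs Sampling rate (Hz).
#' @return Magnitude response at each frequency.
#' @export
fir_response <- function(h, freq_hz, fs = 1000) {
  k <- seq_along(h) - 1
  vapply(freq_hz, function(f) {
    Mod(sum(h * exp(-2i * pi * f * k / fs)))
  }, numeric(1))
}

#' Zero-phase FIR low-pass filtering
#'
#' Applies a symmetric (linear-phase) FIR kernel as a single centered
#' convolution with odd-reflection edge padding, which is zero-phase and has
#' exactly the designed magnitude response. Odd reflection continues linear
#' trends through the edges, so steady-state ramps are not distorted.
#'
#' @param x Numeric vector, longer than the filter.
#' @param h FIR coefficients from [design_lowpass_fir()] (odd length).
#' @return Filtered vector of the same length.
#' @export
lowpass_fir <- function(x, h = design_lowpass_fir()) {
  n <- length(x)
  m <- (length(h) - 1) / 2
  if (m != round(m)) abort("`h` must have odd length (even filter order)")
  if (n <= length(h)) {
    abort(paste0("trace length (", n, ") must exceed the filter length (",
                 length(h), ")"))
  }
  left <- 2 * x[1] - x[(m + 1):2]
  right <- 2 * x[n] - x[(n - 1):(n - m)]
  xp <- c(left, x, right)
  y <- stats::filter(xp, h, method = "convolution", sides = 2)
  as.numeric(y[(m + 1):(m + n)])
}

#' Detect saccades from an acceleration trace
#'
#' Flags runs of samples whose absolute acceleration exceeds the criterion
#' (default 1000 deg/s^2), pads each run by a margin on both sides, and
#' merges overlapping runs.
#'
#' @param accel Acceleration trace (deg/s^2).
#' @param time_ms Time stamps (ms), same length as `accel`.
#' @param threshold Acceleration criterion (deg/s^2).
#' @param pad_ms Padding added to each side of a supra-threshold run (ms).
#' @return A tibble with columns `start_ms`, `end_ms` (possibly 0 rows),
#'   disjoint and sorted.
#' @export
detect_saccades <- function(accel, time_ms, threshold = 1000, pad_ms = 10) {
  stopifnot(length(accel) == length(time_ms))
  over <- abs(accel) > threshold
  if (!any(over)) {
    return(tibble::tibble(start_ms = numeric(), end_ms = numeric()))
  }
  r <- rle(over)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  idx <- which(r$values)
  iv <- tibble::tibble(
    start_ms = time_ms[starts[idx]] - pad_ms,
    end_ms = time_ms[ends[idx]] + pad_ms
  )
  merge_intervals(iv)
}

merge_intervals <- function(iv) {
  if (nrow(iv) <= 1) return(iv)
  iv <- arrange(iv, .data$start_ms)
  out_s <- iv$start_ms[1]
  out_e <- iv$end_ms[1]
  for (i in 2:nrow(iv)) {
    if (iv$start_ms[i] <= out_e[length(out_e)]) {
      out_e[length(out_e)] <- max(out_e[length(out_e)], iv$end_ms[i])
    } else {
      out_s <- c(out_s, iv$start_ms[i])
      out_e <- c(out_e, iv$end_ms[i])
    }
  }
  tibble::tibble(start_ms = out_s, end_ms = out_e)
}

#' Remove saccade intervals and fill the gaps by linear interpolation
#'
#' Samples inside each interval are replaced by the straight line between
#' the last retained sample before the gap and the first after it. Gaps
#' touching the trace boundary are filled with the nearest retained value
#' (with a warning).
#'
#' @param x Velocity trace (deg/s).
#' @param time_ms Time stamps (ms).
#' @param intervals Tibble with `start_ms`, `end_ms` (from
#'   [detect_saccades()]).
#' @return A list with `values` (interpolated trace) and `interpolated`
#'   (logical provenance flag per sample).
#' @export
remove_and_interpolate <- function(x, time_ms, intervals) {
  stopifnot(length(x) == length(time_ms))
  flag <- rep(FALSE, length(x))
  if (is.null(intervals) || nrow(intervals) == 0) {
    return(list(values = x, interpolated = flag))
  }
  for (i in seq_len(nrow(intervals))) {
    flag <- flag | (time_ms >= intervals$start_ms[i] &
                      time_ms <= intervals$end_ms[i])
  }
  if (all(flag)) {
    warn("all samples fall inside saccade intervals; trace left unchanged")
    return(list(values = x, interpolated = flag))
  }
  vals <- x
  if (flag[1] || flag[length(x)]) {
    warn("saccade interval touches the trace boundary; filled with nearest retained value")
  }
  keep <- which(!flag)
  vals[flag] <- approx(time_ms[keep], x[keep], xout = time_ms[flag],
                       rule = 2)$y
  list(values = vals, interpolated = flag)
}

#' Centered moving average
#'
#' Boxcar mean over a centered window (an odd number of samples; a 40 ms
#' window at 1 kHz uses 41 samples). Edges use shrinking windows so the
#' trace length is preserved.
#'
#' @param x Numeric vector.
#' @param window_ms Window length in ms.
#' @param fs Sampling rate in Hz.
#' @return Smoothed vector of the same length.
#' @export
moving_average <- function(x, window_ms = 40, fs = 1000) {
  n <- length(x)
  half <- floor(window_ms * fs / 1000 / 2)
  w <- 2 * half + 1
  if (w > n) abort("moving-average window exceeds trace length")
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Preprocess one eye-position trace
#'
#' Runs the fixed preprocessing chain on a single trial:
#' differentiate (central difference) -> 30 Hz FIR low-pass -> saccade
#' detection on the FIR-filtered acceleration -> removal and linear
#' interpolation of saccades in the velocity trace -> 40 ms moving average.
#' Acceleration is recomputed from the interpolated velocity; the
#' event-stage acceleration is the derivative of the moving-averaged
#' velocity, so that the mean deceleration between detected events is
#' consistent with the velocity trace they were detected on.
#'
#' @param trace Tibble for one trial with columns `time_ms`, `eye_pos_deg`
#'   on a uniform 1 kHz grid.
#' @param config A [pursuit_config()].
#' @return The input tibble with added columns `vel_filt`, `accel_filt`
#'   (saccade-detection acceleration), `saccade`, `interpolated`,
#'   `vel_clean` (interpolated, filtered), `vel_smooth` (moving-averaged),
#'   `accel_smooth` (event-stage acceleration).
#' @export
preprocess_trace <- function(trace, config = pursuit_config()) {
  stopifnot(is.data.frame(trace),
            all(c("time_ms", "eye_pos_deg") %in% names(trace)))
  t <- trace$time_ms
  dtms <- diff(t)
  if (length(t) < 3 || any(abs(dtms - dtms[1]) > 1e-9)) {
    abort("trace must be uniformly sampled with >= 3 samples")
  }
  dt <- dtms[1] / 1000
  h <- design_lowpass_fir(config$fir_order, config$fir_cutoff_hz,
                          config$sample_rate_hz)
  vel_raw <- differentiate_central(trace$eye_pos_deg, dt)
  vel_filt <- lowpass_fir(vel_raw, h)
  accel_filt <- lowpass_fir(differentiate_central(vel_filt, dt), h)
  sacc <- detect_saccades(accel_filt, t, config$saccade_threshold,
                          config$saccade_pad_ms)
  interp <- remove_and_interpolate(vel_filt, t, sacc)
  vel_clean <- interp$values
  vel_smooth <- moving_average(vel_clean, config$ma_window_ms,
                               config$sample_rate_hz)
  accel_smooth <- differentiate_central(vel_smooth, dt)
  out <- trace
  out$vel_filt <- vel_filt
  out$accel_filt <- accel_filt
  out$saccade <- interp$interpolated
  out$interpolated <- interp$interpolated
  out$vel_clean <- vel_clean
  out$vel_smooth <- vel_smooth
  out$accel_smooth <- accel_smooth
  out
}

#' Preprocess every trial of a cohort
#'
#' Applies [preprocess_trace()] to each `(observer, condition, block,
#' trial)` group of a long trace table.
#'
#' @param traces Long tibble of traces (as produced by
#'   [synthesize_eye_trace()]).
#' @param config A [pursuit_config()].
#' @return A long tibble with the added preprocessing columns.
#' @export
preprocess_cohort <- function(traces, config = pursuit_config()) {
  traces |>
    dplyr::group_split(.data$observer, .data$condition, .data$block,
                       .data$trial) |>
    purrr::map(preprocess_trace, config = config) |>
    bind_rows()
}
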