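test_that("stimulus sequences satisfy the block design of both conditions", {
  cfg <- pursuit_config()
  pred <- generate_stimulus_sequence("predictable", "s01", seed = 7)
  expect_equal(nrow(pred), 210)
  expect_equal(length(unique(pred$block)), 7)
  per_block <- split(pred$leftward_velocity, pred$block)
  expect_true(all(vapply(per_block, function(v) length(unique(v)) == 1,
                         logical(1))))
  expect_setequal(vapply(per_block, function(v) v[1], numeric(1)),
                  cfg$velocity_levels)
  expect_true(all(pred$rightward_velocity == 16))

  unp <- generate_stimulus_sequence("unpredictable", "s01", seed = 7)
  expect_equal(nrow(unp), 245)
  expect_equal(length(unique(unp$block)), 5)
  for (v in split(unp$leftward_velocity, unp$block)) {
    expect_equal(unname(table(factor(v, levels = cfg$velocity_levels))),
                 rep(7L, 7), ignore_attr = TRUE)
  }
  expect_true(all(unp$leftward_velocity %in% cfg$velocity_levels))
})

test_that("identical seeds reproduce identical sequences; bad input rejected", {
  a <- generate_stimulus_sequence("unpredictable", "s02", seed = 11)
  b <- generate_stimulus_sequence("unpredictable", "s02", seed = 11)
  expect_identical(a, b)
  c <- generate_stimulus_sequence("unpredictable", "s02", seed = 12)
  expect_false(identical(a$leftward_velocity, c$leftward_velocity))
  expect_error(generate_stimulus_sequence("sinusoidal"), "predictable")
})

test_that("target trajectory ramp durations and travel distance are exact", {
  trials <- tibble::tibble(
    observer = "s01", condition = "unpredictable", block = 1L,
    trial = 1:3, rightward_velocity = 16, leftward_velocity = c(4, 24, 16)
  )
  traj <- render_target_trajectory(trials)
  revs <- attr(traj, "reversals")
  # rightward ramp: 24 deg at 16 deg/s = 1500 ms; leftward: 24000 / v ms
  expect_equal(revs$reversal_ms, c(1500, 1500 + 6000 + 1500,
                                   1500 + 6000 + 1500 + 1000 + 1500))
  expect_equal(revs$leftward_duration_ms, c(6000, 1000, 1500))
  # velocity integrates to +-24 deg over each ramp (1 kHz Riemann sum)
  seg <- traj[traj$trial == 1 & traj$time_ms < 1500, ]
  expect_equal(sum(seg$target_vel_deg_s) / 1000, 24, tolerance = 16 / 24000)
  # position continuous at every ramp junction
  expect_lt(max(abs(diff(traj$target_pos_deg))), 0.033)
})

test_that("degenerate timing model yields the constant intercept", {
  trials <- generate_stimulus_sequence("unpredictable", seed = 3)
  m <- sim_model(beta0 = -50, subject_intercept_sd = 0, noise_sd = 0,
                 beta_stim = numeric(0), beta_behav = numeric(0))
  tt <- simulate_reversal_timings(trials, m, seed = 5)
  expect_true(all(tt$true_reversal_ms == -50))
})

test_that("a negative lag-2 stimulus weight lowers timings after fast trials", {
  trials <- generate_stimulus_sequence("unpredictable", seed = 9)
  m <- sim_model(beta0 = 0, subject_intercept_sd = 0, noise_sd = 0,
                 beta_stim = c(0, -2), beta_behav = numeric(0))
  tt <- simulate_reversal_timings(trials, m, seed = 5) |>
    dplyr::group_by(observer, block) |>
    dplyr::mutate(v2 = dplyr::lag(leftward_velocity, 2)) |>
    dplyr::ungroup() |>
    dplyr::filter(!is.na(v2))
  m_fast <- mean(tt$true_reversal_ms[tt$v2 == 28])
  m_slow <- mean(tt$true_reversal_ms[tt$v2 == 4])
  expect_lt(m_fast, m_slow)
  expect_equal(m_fast - m_slow, -2 * 24, tolerance = 1e-9)
})

test_that("near-unit autoregressive weights trigger a stationarity warning", {
  expect_warning(sim_model(beta_behav = c(0.6, 0.5)), "nonstationar")
  expect_silent(sim_model())
})

test_that("timing simulation is deterministic and block-order invariant", {
  trials <- generate_stimulus_sequence("unpredictable", seed = 1)
  m <- sim_model()
  a <- simulate_reversal_timings(trials, m, seed = 2)
  b <- simulate_reversal_timings(trials, m, seed = 2)
  expect_identical(a, b)
  # per-(observer, block) streams: feeding blocks in shuffled row order
  # leaves each block's timings unchanged
  shuffled <- trials[sample(nrow(trials)), ]
  c <- simulate_reversal_timings(shuffled, m, seed = 2)
  expect_equal(a$true_reversal_ms, c$true_reversal_ms)
  # burn-in marks exactly the first 5 trials of each block
  expect_equal(sum(a$burn_in), 5 * 5)
})

test_that("noiseless unit-gain traces track the target in steady state", {
  trials <- generate_stimulus_sequence("unpredictable", seed = 2)[1, ]
  m <- noiseless_model(pursuit_gain = 1)
  tt <- simulate_reversal_timings(trials, m, seed = 1)
  syn <- synthesize_eye_trace(tt, m, seed = 1)
  tr <- syn$traces
  vel <- differentiate_central(tr$eye_pos_deg, 0.001)
  steady <- tr$time_ms > -1400 & tr$time_ms < syn$truth$true_onset_ms - 20
  expect_lt(max(abs(vel[steady] - 16)), 1e-6)
  # velocity crosses zero at the trial's simulated reversal timing
  i <- which(tr$time_ms >= floor(syn$truth$true_reversal_ms))[1]
  expect_lt(abs(tr$time_ms[i] - syn$truth$true_reversal_ms), 1.01)
  expect_true(vel[i - 1] >= 0 && vel[i + 1] <= 0)
})

test_that("injected minimum-jerk saccades exceed the acceleration criterion", {
  # 2 deg over 30 ms: peak acceleration of the min-jerk step is
  # A * 10/sqrt(3) / T^2 = 2 * 5.7735 / 0.0009 ~ 12830 deg/s^2
  t <- seq(0, 200) / 1000
  pos <- 2 * predpursuit:::min_jerk((t - 0.08) / 0.03)
  acc <- differentiate_central(differentiate_central(pos, 0.001), 0.001)
  expect_gt(max(abs(acc)), 1000)
  expect_equal(max(abs(acc)), 2 * 10 / sqrt(3) / 0.03^2, tolerance = 0.03)
})

test_that("empty trial lists and out-of-span timings are handled", {
  empty <- synthesize_eye_trace(
    tibble::tibble(observer = character(), condition = character(),
                   block = integer(), trial = integer(),
                   leftward_velocity = numeric(),
                   true_reversal_ms = numeric()))
  expect_equal(nrow(empty$traces), 0)
  trials <- generate_stimulus_sequence("unpredictable", seed = 2)[1, ]
  trials$true_reversal_ms <- 5000  # beyond the rendered window
  syn <- synthesize_eye_trace(trials, noiseless_model(), seed = 1)
  expect_false(syn$truth$usable)
})

test_that("trace synthesis is bit-for-bit deterministic", {
  trials <- generate_stimulus_sequence("unpredictable", seed = 2)[1:3, ]
  m <- sim_model()
  tt <- simulate_reversal_timings(trials, m, seed = 4)
  a <- synthesize_eye_trace(tt, m, seed = 4)
  b <- synthesize_eye_trace(tt, m, seed = 4)
  expect_identical(a, b)
})
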