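test_that("rank classification labels the 20% tails per cell", {
  tab <- make_trial_table(seq(-100, by = 2, length.out = 30))
  cls <- rank_classify(tab)
  expect_equal(sum(cls$node_class == "UPPER"), 6)   # floor(0.2 * 30)
  expect_equal(sum(cls$node_class == "LOWER"), 6)
  expect_true(all(cls$reversal_ms[cls$node_class == "UPPER"] <
                    min(cls$reversal_ms[cls$node_class == "LOWER"])))
  tab10 <- make_trial_table(c(5, 1, 9, 3, 7, 2, 8, 4, 6, 0))
  cls10 <- rank_classify(tab10)
  expect_setequal(cls10$reversal_ms[cls10$node_class == "UPPER"], c(0, 1))
  expect_setequal(cls10$reversal_ms[cls10$node_class == "LOWER"], c(8, 9))
})

test_that("ties are broken by stable original order; small cells skipped", {
  tab <- make_trial_table(rep(0, 10))
  cls <- rank_classify(tab)
  expect_equal(cls$node_class[1:2], c("UPPER", "UPPER"))
  expect_equal(cls$node_class[9:10], c("LOWER", "LOWER"))
  expect_equal(sum(cls$node_class == "UPPER"),
               sum(cls$node_class == "LOWER"))
  small <- make_trial_table(1:4)
  expect_warning(rank_classify(small), "skipped")
})

test_that("node sorting respects lags, blocks and the generative sign", {
  # strong positive lag-1 behavior weight: trials after UPPER (early)
  # responses are earlier than trials after LOWER responses
  m <- sim_model(beta0 = 0, subject_intercept_sd = 0, noise_sd = 20,
                 beta_stim = numeric(0), beta_behav = 0.6)
  co <- simulate_cohort(4, "unpredictable", m, seed = 31)
  co$reversal_ms <- co$true_reversal_ms
  cls <- rank_classify(co)
  ns <- node_sort(cls, lag = 1, by = "behavior")
  expect_true(all(ns$mean_upper < ns$mean_lower))
  # stimulus mode with a negative lag-2 stimulus weight
  m2 <- sim_model(beta0 = 0, subject_intercept_sd = 0, noise_sd = 5,
                  beta_stim = c(0, -2), beta_behav = numeric(0))
  co2 <- simulate_cohort(4, "unpredictable", m2, seed = 32)
  co2$reversal_ms <- co2$true_reversal_ms
  ns2 <- node_sort(co2, lag = 2, by = "stimulus")
  expect_true(all(ns2$mean_fast < ns2$mean_slow))
  # lag-1 groups in 2-trial blocks: only each block's trial 2 is
  # classifiable, and lags never reach into the previous block
  tiny <- dplyr::bind_rows(
    make_trial_table(c(-10, -20), block = 1L),
    make_trial_table(c(-30, -40), block = 2L)
  )
  tiny$node_class <- c("UPPER", "middle", "LOWER", "middle")
  ns3 <- node_sort(tiny, lag = 1, by = "behavior")
  expect_equal(ns3$n_upper, 1)
  expect_equal(ns3$n_lower, 1)
  expect_equal(ns3$mean_upper, -20)  # block-1 trial 2 only
  expect_equal(ns3$mean_lower, -40)  # block-2 trial 2 only
})

test_that("null history gives no node contrast beyond sampling error", {
  m <- sim_model(beta0 = 0, subject_intercept_sd = 0, noise_sd = 30,
                 beta_stim = numeric(0), beta_behav = numeric(0))
  co <- simulate_cohort(12, "unpredictable", m, seed = 33)
  co$reversal_ms <- co$true_reversal_ms
  ns <- node_sort(co, lag = 2, by = "stimulus")
  d <- ns$mean_fast - ns$mean_slow
  sem <- sd(d) / sqrt(length(d))
  expect_lt(abs(mean(d)), 3 * sem + 1e-9)
})

test_that("paired t reproduces a hand-computed example and edge cases", {
  # differences (2, -1, 3, 0, 1): mean 1, sd sqrt(2.5), t = sqrt(2),
  # df = 4, p = 0.2301996, d = 1/sqrt(2.5)
  a <- c(12, 9, 13, 10, 11)
  b <- c(10, 10, 10, 10, 10)
  res <- paired_t(a, b)
  expect_equal(res$t, 1.4142136, tolerance = 1e-6)
  expect_equal(res$df, 4)
  expect_equal(res$p, 0.2301996, tolerance = 1e-6)
  expect_equal(res$cohens_d, 0.6324555, tolerance = 1e-6)
  expect_warning(res0 <- paired_t(c(2, 2, 2, 2), c(1, 1, 1, 1)),
                 "zero variance")
  expect_equal(res0$p, 0)
  expect_error(paired_t(1:2, 2:3), "3 pairs")
})

test_that("history design drops burn-in rows, crosses no blocks, is complete-case", {
  co <- simulate_cohort(2, "unpredictable", sim_model(), seed = 41)
  co$reversal_ms <- co$true_reversal_ms
  d5 <- build_history_design(co, 5)
  expect_equal(nrow(d5), 2 * 5 * 44)  # 49-trial blocks lose their first 5
  d1 <- build_history_design(dplyr::filter(co, observer == "s01",
                                           block == 1), 1)
  expect_equal(nrow(d1), 48)
  # no predictor references a previous block: lag-5 stimulus of the first
  # response row equals trial 1 of the same block
  first_rows <- d5 |>
    dplyr::group_by(observer, block) |>
    dplyr::slice(1) |>
    dplyr::ungroup()
  t1 <- co |>
    dplyr::filter(trial == 1) |>
    dplyr::select(observer, block, v1 = leftward_velocity)
  cmp <- dplyr::left_join(first_rows, t1, by = c("observer", "block"))
  expect_equal(cmp$stim_lag5, cmp$v1)
  # excluding one mid-block trial removes the rows whose behavior lags
  # touch it (complete-case), but not their stimulus information
  co2 <- co
  co2$included <- !(co2$observer == "s01" & co2$block == 1 & co2$trial == 20)
  d_ex <- build_history_design(co2, 5)
  gone <- dplyr::filter(d_ex, observer == "s01", block == 1,
                        trial %in% 20:25)
  expect_equal(nrow(gone), 0)
  expect_equal(nrow(d5) - nrow(d_ex), 6)  # trials 20 (response) + 21..25
})

test_that("the LME recovers a noiseless linear model exactly", {
  co <- simulate_cohort(3, "unpredictable",
                        sim_model(beta0 = 25, subject_intercept_sd = 0,
                                  noise_sd = 0,
                                  beta_stim = c(-0.5, 0.3),
                                  beta_behav = c(0.2, -0.1)),
                        seed = 51)
  co$reversal_ms <- co$true_reversal_ms
  design <- build_history_design(co, 2)
  fit <- fit_lme(design, 2, 2)
  expect_equal(fit$fixed$estimate,
               c(25, -0.5, 0.3, 0.2, -0.1), tolerance = 1e-6)
})

test_that("with no between-observer variance the LME matches pooled OLS", {
  m <- sim_model(subject_intercept_sd = 0)
  co <- simulate_cohort(6, "unpredictable", m, seed = 52)
  co$reversal_ms <- co$true_reversal_ms
  design <- build_history_design(co, 2)
  fit <- fit_lme(design, 2, 2)
  ols <- lm(y ~ stim_lag1 + stim_lag2 + behav_lag1 + behav_lag2,
            data = design)
  expect_equal(fit$fixed$estimate, unname(coef(ols)), tolerance = 1e-2)
  expect_lt(fit$ranef_sd, 1.5)
})

test_that("the 15-model grid shares rows and AIC ignores response shifts", {
  co <- simulate_cohort(3, "unpredictable", sim_model(), seed = 53)
  co$reversal_ms <- co$true_reversal_ms
  grid <- model_grid_and_select(co, 5)
  expect_length(grid$models, 15)
  expect_true(all(vapply(grid$models, function(m) m$n, numeric(1)) ==
                    nrow(grid$design)))
  expect_equal(grid$table$ks, c(1:5, rep(0, 5), 1:5))
  expect_equal(grid$table$kb, c(rep(0, 5), 1:5, 1:5))
  co_shift <- co
  co_shift$reversal_ms <- co_shift$reversal_ms + 250
  grid2 <- model_grid_and_select(co_shift, 5)
  expect_equal(grid2$table$aic, grid$table$aic, tolerance = 1e-6)
  expect_equal(grid2$selected, grid$selected)
  tg <- tidy(grid)
  expect_true(all(c("model", "aic", "selected", "term") %in% names(tg)))
})

test_that("VIF matches its closed forms and the inverse-correlation oracle", {
  n <- 400
  x1 <- rep(c(1, -1), n / 2)
  x2 <- rep(c(1, 1, -1, -1), n / 4)  # orthogonal to x1
  v <- compute_vif(data.frame(x1 = x1, x2 = x2))
  expect_equal(v$vif, c(1, 1), tolerance = 1e-12)
  expect_warning(vc <- compute_vif(data.frame(a = x1, b = 2 * x1)),
                 "collinear")
  expect_true(all(is.infinite(vc$vif)))
  # empirical correlation exactly 0.5 -> VIF = 1/(1 - 0.25) = 4/3
  z2 <- stats::residuals(lm(x2 ~ x1))
  z2 <- z2 / sqrt(mean(z2^2))
  x2c <- 0.5 * x1 + sqrt(0.75) * z2
  v2 <- compute_vif(data.frame(x1 = x1, x2 = x2c))
  expect_equal(v2$vif, c(4 / 3, 4 / 3), tolerance = 1e-9)
  # random designs: diagonal of the inverse correlation matrix
  set.seed(61)
  for (i in 1:10) {
    X <- matrix(rnorm(100 * 4), ncol = 4) %*%
      (diag(4) + matrix(runif(16, 0, 0.4), 4))
    got <- compute_vif(as.data.frame(X))$vif
    want <- diag(solve(stats::cor(X)))
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("within-subject correlation removes between-subject confounds", {
  d <- tibble::tibble(
    observer = rep(c("a", "b", "c"), each = 10),
    x = rep(1:10, 3),
    y = 2 * rep(1:10, 3) + rep(c(0, 50, -30), each = 10)
  )
  expect_equal(within_subject_correlation(d, "x", "y")$r, 1)
  # between-subject trend opposite to the (absent) within-subject relation
  set.seed(71)
  d2 <- tibble::tibble(
    observer = rep(letters[1:6], each = 50),
    x = rep(1:6, each = 50) * 10 + rnorm(300),
    y = rep(1:6, each = 50) * 10 + rnorm(300)
  )
  r_raw <- cor(d2$x, d2$y)
  r_w <- within_subject_correlation(d2, "x", "y")$r
  expect_gt(r_raw, 0.9)
  expect_lt(abs(r_w), 0.25)
  # equals the ANCOVA route: partial correlation of x in y ~ subject + x
  fit <- lm(y ~ observer + x, data = d2)
  tval <- summary(fit)$coefficients["x", "t value"]
  dfr <- fit$df.residual
  r_ancova <- sign(tval) * sqrt(tval^2 / (tval^2 + dfr))
  expect_equal(r_w, r_ancova, tolerance = 1e-10)
})
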