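# Independent oracles and fixture builders shared across the test files.
# Every oracle here recomputes the quantity from its definition, by a
# different route than the package implementation.

# ---- brute-force event-detection oracle -------------------------------
# Scans every candidate onset sample and applies the predicates literally:
# the onset is the earliest in-window sample that is below threshold with
# every later sample up to (and including) the first sub-zero sample also
# below threshold; the reversal is that sub-zero crossing, interpolated.
oracle_detect <- function(time_ms, vel, threshold, search_start = -500) {
  win <- which(time_ms >= search_start)
  und <- list(onset_ms = NA_real_, reversal_ms = NA_real_)
  if (length(win) < 2) return(und)
  zcand <- win[vel[win] < 0]
  if (length(zcand) == 0) return(und)
  z <- zcand[1]
  onset <- NA_real_
  for (i in win[win <= z]) {
    if (vel[i] < threshold && all(vel[i:z] < threshold)) {
      onset <- time_ms[i]
      break
    }
  }
  if (is.na(onset)) return(und)
  if (z == 1 || vel[z - 1] <= 0) {
    rev <- time_ms[max(z - 1, 1)]
    if (z == 1) rev <- time_ms[1]
  } else {
    v0 <- vel[z - 1]
    rev <- time_ms[z - 1] + (time_ms[z] - time_ms[z - 1]) * v0 / (v0 - vel[z])
  }
  list(onset_ms = onset, reversal_ms = rev)
}

# Random smooth velocity traces exercising dips, recoveries and flat cases.
random_velocity_trace <- function() {
  t <- seq(-800, 300)
  base <- runif(1, 10, 20)
  # smooth noise: moving-average of white noise
  noise <- stats::filter(rnorm(length(t) + 60, 0, runif(1, 0, 4)),
                         rep(1 / 30, 30), sides = 2)
  noise <- as.numeric(noise[31:(30 + length(t))])
  decay_at <- runif(1, -250, 50)
  slope <- runif(1, 0.02, 0.3)
  v <- base - pmax(t - decay_at, 0) * slope + noise
  if (runif(1) < 0.2) v <- abs(v) + 0.5  # never crosses zero
  if (runif(1) < 0.3) {
    # transient dip that recovers (exercises the sustained rule)
    at <- runif(1, -450, -250)
    v <- v - 8 * exp(-((t - at) / 15)^2)
  }
  list(time_ms = t, vel = v, threshold = runif(1, 6, 14))
}

# ---- trial/trace fixture builders -------------------------------------
# A minimal preprocessed-trial tibble from an explicit velocity profile.
make_processed_trial <- function(time_ms, vel, observer = "s01",
                                 condition = "unpredictable", block = 1L,
                                 trial = 1L) {
  dt <- (time_ms[2] - time_ms[1]) / 1000
  accel <- predpursuit::differentiate_central(vel, dt)
  tibble::tibble(
    observer = observer, condition = condition, block = block,
    trial = trial, time_ms = time_ms, vel_smooth = vel,
    accel_smooth = accel
  )
}

# A small trial table with explicit reversal timings.
make_trial_table <- function(reversal_ms, observer = "s01",
                             condition = "unpredictable", block = 1L,
                             leftward_velocity = 16, included = TRUE) {
  n <- length(reversal_ms)
  tibble::tibble(
    observer = observer, condition = condition, block = block,
    trial = seq_len(n), leftward_velocity = leftward_velocity,
    reversal_ms = reversal_ms,
    included = rep_len(included, n)
  )
}

# ---- dip LP oracle ----------------------------------------------------
# Linear-programming computation of the dip from its definition: minimize
# d over unimodal cdfs G within sup-distance d of the empirical cdf. Mode
# candidates: an atom at each distinct data value and (optionally) a
# continuous mode on a grid inside each gap, whose junction value joins
# both curvature chains. Small n only.
dip_lp <- function(x, interior_grid = 0) {
  x <- sort(x)
  n <- length(x)
  u <- unique(x)
  m <- length(u)
  if (m == 1) return(0)
  cnt <- as.numeric(table(factor(x, levels = u)))
  cu <- cumsum(cnt) / n
  cl <- c(0, cu[-m])
  solve_chain <- function(xs_l, lo_l, hi_l, xs_r, lo_r, hi_r, shared) {
    J <- length(xs_l); K <- length(xs_r)
    nv <- J + K + 1 - as.integer(shared)
    iv_l <- seq_len(J)
    iv_r <- if (shared) c(J, J + seq_len(K - 1)) else J + seq_len(K)
    idd <- nv
    A1 <- NULL; b1 <- NULL; A2 <- NULL; b2 <- NULL
    le <- function(row, rhs) { A1 <<- rbind(A1, row); b1 <<- c(b1, rhs) }
    ge <- function(row, rhs) { A2 <<- rbind(A2, row); b2 <<- c(b2, rhs) }
    zr <- function() numeric(nv)
    band <- function(iv, lo, hi) {
      r <- zr(); r[iv] <- 1; r[idd] <- -1; le(r, lo)   # g - d <= lower corner
      r <- zr(); r[iv] <- 1; r[idd] <- 1; ge(r, hi)    # g + d >= upper corner
      r <- zr(); r[iv] <- 1; le(r, 1)
    }
    for (i in seq_len(J)) band(iv_l[i], lo_l[i], hi_l[i])
    for (j in seq_len(K)) {
      if (shared && j == 1) next
      band(iv_r[j], lo_r[j], hi_r[j])
    }
    mono <- function(i1, i2) { r <- zr(); r[i1] <- 1; r[i2] <- -1; le(r, 0) }
    if (J >= 2) for (i in 1:(J - 1)) mono(iv_l[i], iv_l[i + 1])
    if (K >= 2) for (j in 1:(K - 1)) mono(iv_r[j], iv_r[j + 1])
    if (!shared) mono(iv_l[J], iv_r[1])
    if (J >= 3) for (i in 2:(J - 1)) {
      d1 <- xs_l[i] - xs_l[i - 1]; d2 <- xs_l[i + 1] - xs_l[i]
      r <- zr(); r[iv_l[i - 1]] <- -d2; r[iv_l[i]] <- d1 + d2
      r[iv_l[i + 1]] <- -d1
      le(r, 0)
    }
    if (K >= 3) for (j in 2:(K - 1)) {
      d1 <- xs_r[j] - xs_r[j - 1]; d2 <- xs_r[j + 1] - xs_r[j]
      r <- zr(); r[iv_r[j - 1]] <- d2; r[iv_r[j]] <- -(d1 + d2)
      r[iv_r[j + 1]] <- d1
      le(r, 0)
    }
    obj <- zr(); obj[idd] <- 1
    res <- tryCatch(boot::simplex(a = obj, A1 = A1, b1 = b1,
                                  A2 = A2, b2 = b2),
                    error = function(e) NULL)
    if (is.null(res) || res$solved != 1) return(Inf)
    res$value
  }
  best <- Inf
  for (k in seq_len(m)) {
    d <- solve_chain(
      xs_l = u[1:k], lo_l = cl[1:k],
      hi_l = c(if (k > 1) cu[1:(k - 1)], cl[k]),
      xs_r = u[k:m], lo_r = c(cu[k], if (k < m) cl[(k + 1):m]),
      hi_r = cu[k:m], shared = FALSE
    )
    best <- min(best, d)
  }
  if (interior_grid > 0 && m >= 2) {
    for (k in 1:(m - 1)) {
      for (g in seq_len(interior_grid)) {
        xm <- u[k] + (u[k + 1] - u[k]) * g / (interior_grid + 1)
        d <- solve_chain(
          xs_l = c(u[1:k], xm), lo_l = c(cl[1:k], cu[k]),
          hi_l = c(cu[1:k], cu[k]),
          xs_r = c(xm, u[(k + 1):m]), lo_r = c(cu[k], cl[(k + 1):m]),
          hi_r = c(cu[k], cu[(k + 1):m]), shared = TRUE
        )
        best <- min(best, d)
      }
    }
  }
  best
}

# noiseless simulation model used by recovery tests
noiseless_model <- function(...) {
  args <- list(noise_sd = 0, subject_intercept_sd = 0, saccade_rate = 0,
               position_noise_sd = 0)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(sim_model, args)
}
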