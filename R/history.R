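#' Rank-classify trials into UPPER / LOWER nodes
#'
#' Within each (observer, target velocity) cell, ranks the included trials'
#' eye-reversal timings in ascending order and labels the earliest
#' `floor(frac * n)` trials `"UPPER"` and the latest `floor(frac * n)`
#' `"LOWER"`; the rest are `"middle"`. Ties are broken by stable original
#' trial order. Cells with fewer than `min_cell` included trials are skipped
#' with a warning.
#'
#' @param table Trial table with `observer`, `leftward_velocity`,
#'   `reversal_ms`, and (optionally) `included`.
#' @param frac Classified fraction per tail (default 0.2).
#' @param min_cell Minimum cell size.
#' @return `table` with an added `node_class` column (`NA` for excluded
#'   trials or skipped cells).
#' @export
rank_classify <- function(table, frac = 0.2, min_cell = 5) {
  stopifnot(all(c("observer", "leftward_velocity", "reversal_ms") %in%
                  names(table)))
  if (!"included" %in% names(table)) table$included <- TRUE
  table$.row_id <- seq_len(nrow(table))
  cls <- table |>
    filter(.data$included, !is.na(.data$reversal_ms)) |>
    group_by(.data$observer, .data$leftward_velocity) |>
    dplyr::group_modify(function(g, key) {
      n_cell <- nrow(g)
      if (n_cell < min_cell) {
        warn(sprintf("cell observer=%s velocity=%s has %d (< %d) trials; skipped",
                     key$observer, key$leftward_velocity, n_cell, min_cell))
        g$node_class <- NA_character_
        return(g)
      }
      k <- floor(frac * n_cell)
      ord <- order(g$reversal_ms)  # stable for ties
      lab <- rep("middle", n_cell)
      if (k > 0) {
        lab[ord[seq_len(k)]] <- "UPPER"
        lab[ord[seq(n_cell - k + 1, n_cell)]] <- "LOWER"
      }
      g$node_class <- lab
      g
    }) |>
    ungroup() |>
    select(".row_id", "node_class")
  out <- left_join(table, cls, by = ".row_id")
  out$.row_id <- NULL
  out
}

#' Node-sort trials by a property of a preceding trial
#'
#' Groups each analyzable trial by a categorical property of its n-`lag`
#' trial: for `by = "behavior"`, whether that trial was classified UPPER or
#' LOWER (see [rank_classify()]); for `by = "stimulus"`, whether its target
#' velocity was the slowest or fastest level (default 4 vs 28 deg/s). Lags
#' never cross block boundaries. Per observer, the mean current-trial
#' eye-reversal timing of each group is returned, together with the pooled
#' "right node" mean over both groups.
#'
#' @param table Trial table (sorted within observer/block/trial) with
#'   `reversal_ms`, `included`, and `node_class` for behavior mode.
#' @param lag Which preceding trial to classify by (1 or 2).
#' @param by `"behavior"` or `"stimulus"`.
#' @param stim_levels Slow/fast velocities for stimulus mode.
#' @return Tibble per observer: `mean_upper` / `mean_lower` (behavior) or
#'   `mean_slow` / `mean_fast` (stimulus), group counts, and `mean_both`.
#'   Observers with an empty group are dropped with a message.
#' @export
node_sort <- function(table, lag = 1, by = c("behavior", "stimulus"),
                      stim_levels = c(4, 28)) {
  by <- match.arg(by)
  stopifnot(lag %in% 1:2 || (lag >= 1 && lag <= 5))
  if (!"included" %in% names(table)) table$included <- TRUE
  if (by == "behavior" && !"node_class" %in% names(table)) {
    abort("behavior mode needs a `node_class` column; run rank_classify() first")
  }
  lagged <- table |>
    arrange(.data$observer, .data$block, .data$trial) |>
    group_by(.data$observer, .data$block) |>
    mutate(
      prev_class = if (by == "behavior") lag(.data$node_class, lag) else NA,
      prev_vel = lag(.data$leftward_velocity, lag)
    ) |>
    ungroup() |>
    filter(.data$included, !is.na(.data$reversal_ms))
  if (by == "behavior") {
    lagged <- lagged |>
      filter(.data$prev_class %in% c("UPPER", "LOWER")) |>
      mutate(grp = ifelse(.data$prev_class == "UPPER", "upper", "lower"))
  } else {
    lagged <- lagged |>
      filter(.data$prev_vel %in% stim_levels) |>
      mutate(grp = ifelse(.data$prev_vel == stim_levels[1], "slow", "fast"))
  }
  wide <- lagged |>
    group_by(.data$observer, .data$grp) |>
    summarise(m = mean(.data$reversal_ms), k = n(), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "grp", values_from = c("m", "k"))
  need <- if (by == "behavior") c("m_upper", "m_lower") else c("m_slow", "m_fast")
  missing_cols <- setdiff(need, names(wide))
  for (cn in missing_cols) wide[[cn]] <- NA_real_
  drop <- !stats::complete.cases(wide[need])
  if (any(drop)) {
    inform(sprintf("dropping %d observer(s) with an empty node group", sum(drop)))
    wide <- wide[!drop, , drop = FALSE]
  }
  both <- lagged |>
    group_by(.data$observer) |>
    summarise(mean_both = mean(.data$reversal_ms), .groups = "drop")
  out <- left_join(wide, both, by = "observer")
  names(out) <- sub("^m_", "mean_", names(out))
  names(out) <- sub("^k_", "n_", names(out))
  out
}

#' Paired t test with Cohen's d
#'
#' Standard two-sided paired t statistic on per-observer means, with
#' Cohen's d computed as `mean(diff) / sd(diff)`.
#'
#' @param a,b Paired numeric vectors (e.g. per-observer group means).
#' @return A tibble with `t`, `df`, `p`, `cohens_d`, `mean_diff`, `n`.
#' @export
paired_t <- function(a, b) {
  stopifnot(length(a) == length(b))
  if (length(a) < 3) abort("paired_t() needs at least 3 pairs")
  d <- a - b
  if (sd(d) == 0) {
    warn("zero variance of paired differences; p reported as exact 0/1 edge case")
    p <- if (mean(d) == 0) 1 else 0
    return(tibble::tibble(t = if (mean(d) == 0) 0 else Inf * sign(mean(d)),
                          df = length(d) - 1, p = p,
                          cohens_d = if (mean(d) == 0) 0 else Inf * sign(mean(d)),
                          mean_diff = mean(d), n = length(d)))
  }
  tt <- stats::t.test(a, b, paired = TRUE)
  tibble::tibble(
    t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
    cohens_d = mean(d) / sd(d), mean_diff = mean(d), n = length(d)
  )
}

#' Build the lagged history design
#'
#' Pairs each analyzable trial's eye-reversal timing with the target
#' velocities and eye-reversal timings of the preceding `max_lag` trials.
#' Lags never cross block boundaries; the first `max_lag` trials of each
#' block enter only as predictors. Rows whose current trial is excluded, or
#' whose behavior lags reference an excluded/undetected trial, are dropped
#' (complete-case rule). All models of the grid are fitted on this common
#' row set so their AICs are comparable.
#'
#' @param table Trial table with `observer`, `block`, `trial`,
#'   `leftward_velocity`, `reversal_ms`, and optionally `included`.
#' @param max_lag Number of lags (default 5).
#' @return A tibble with `observer`, `y` (current reversal timing), and
#'   predictors `stim_lag1..K`, `behav_lag1..K`.
#' @export
build_history_design <- function(table, max_lag = 5) {
  stopifnot(max_lag >= 1)
  if (!"included" %in% names(table)) table$included <- TRUE
  tab <- table |>
    arrange(.data$observer, .data$block, .data$trial) |>
    mutate(t_obs = ifelse(.data$included, .data$reversal_ms, NA_real_))
  lagged <- tab |>
    group_by(.data$observer, .data$block) |>
    mutate(.in_block = row_number())
  for (k in seq_len(max_lag)) {
    lagged <- lagged |>
      mutate(!!paste0("stim_lag", k) := lag(.data$leftward_velocity, k),
             !!paste0("behav_lag", k) := lag(.data$t_obs, k))
  }
  lagged <- lagged |> ungroup()
  pred_cols <- c(paste0("stim_lag", seq_len(max_lag)),
                 paste0("behav_lag", seq_len(max_lag)))
  out <- lagged |>
    filter(.data$.in_block > max_lag, .data$included, !is.na(.data$t_obs)) |>
    filter(stats::complete.cases(dplyr::pick(dplyr::all_of(pred_cols)))) |>
    mutate(y = .data$t_obs) |>
    select("observer", "block", "trial", "y", dplyr::all_of(pred_cols))
  out
}

#' Fit one linear mixed-effects history model
#'
#' Maximum-likelihood fit of the current eye-reversal timing on the given
#' stimulus / behavior lags with a per-observer random intercept. Wald t
#' statistics use residual degrees of freedom `n - p` (p = number of fixed
#' effects). AIC is `2k - 2 logLik` with k counting all estimated
#' parameters (fixed effects, random-intercept variance, residual
#' variance).
#'
#' @param design Design tibble from [build_history_design()].
#' @param ks Number of stimulus lags in the model (0..`max_lag`).
#' @param kb Number of behavior lags (0..`max_lag`); `(0, 0)` is an error.
#' @return An object of class `pursuit_lme`: a list with `fixed` (tibble
#'   of estimates, SE, t, df, p), `ranef_sd`, `sigma`, `aic`, `loglik`,
#'   `n`, `ks`, `kb`, `singular`, and the underlying `fit`.
#' @export
fit_lme <- function(design, ks, kb) {
  if (ks == 0 && kb == 0) abort("at least one history term is required")
  if (length(unique(design$observer)) < 2) {
    abort("fit_lme() needs >= 2 observers for the random intercept")
  }
  preds <- c(if (ks > 0) paste0("stim_lag", seq_len(ks)),
             if (kb > 0) paste0("behav_lag", seq_len(kb)))
  missing_p <- setdiff(preds, names(design))
  if (length(missing_p)) {
    abort(paste0("design lacks predictor(s): ", paste(missing_p, collapse = ", ")))
  }
  fml <- stats::as.formula(
    paste("y ~", paste(preds, collapse = " + "), "+ (1 | observer)"))
  fit <- lme4::lmer(fml, data = design, REML = FALSE,
                    control = lme4::lmerControl(check.conv.singular = "ignore",
                                                calc.derivs = FALSE))
  singular <- lme4::isSingular(fit)
  if (singular) {
    inform("singular random-intercept fit (variance estimated at 0)")
  }
  est <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  n <- nrow(design)
  p <- length(est)
  df <- n - p
  tval <- est / se
  fixed <- tibble::tibble(
    term = names(est), estimate = unname(est), se = unname(se),
    t = unname(tval), df = df, p = 2 * pt(-abs(unname(tval)), df)
  )
  vc <- as.data.frame(lme4::VarCorr(fit))
  structure(list(
    fixed = fixed,
    ranef_sd = vc$sdcor[vc$grp == "observer"],
    sigma = vc$sdcor[vc$grp == "Residual"],
    aic = AIC(fit), loglik = as.numeric(logLik(fit)),
    n = n, ks = ks, kb = kb, singular = singular, fit = fit
  ), class = "pursuit_lme")
}

#' @export
print.pursuit_lme <- function(x, ...) {
  cat(sprintf("History LME: %d stimulus lag(s), %d behavior lag(s), n = %d\n",
              x$ks, x$kb, x$n))
  cat(sprintf("AIC %.3f | random-intercept SD %.3f | residual SD %.3f\n",
              x$aic, x$ranef_sd, x$sigma))
  print(as.data.frame(x$fixed), digits = 4)
  invisible(x)
}

#' Fit the 15-model history grid and select by AIC
#'
#' Fits the full grid of history models on a common design: models 1-5 use
#' stimulus lags 1..k alone, models 6-10 behavior lags 1..k alone, and
#' models 11-15 both sets with lags 1..k. All models share the same response
#' rows, and the model with minimum AIC is selected. Models that fail to fit
#' are skipped with a prominent warning and selection proceeds over the
#' fitted subset.
#'
#' @param table Trial table (see [build_history_design()]).
#' @param max_lag Deepest lag of the grid (default 5).
#' @return A list of class `pursuit_lme_grid` with `models` (list of
#'   [fit_lme()] results, ids 1-15), `table` (tidy summary: model id,
#'   predictor counts, AIC), `selected` (id of the minimum-AIC model), and
#'   `design`.
#' @export
model_grid_and_select <- function(table, max_lag = 5) {
  design <- build_history_design(table, max_lag)
  spec <- tibble::tibble(
    model = seq_len(3 * max_lag),
    ks = c(seq_len(max_lag), rep(0, max_lag), seq_len(max_lag)),
    kb = c(rep(0, max_lag), seq_len(max_lag), seq_len(max_lag))
  )
  models <- vector("list", nrow(spec))
  for (i in seq_len(nrow(spec))) {
    models[[i]] <- tryCatch(
      fit_lme(design, spec$ks[i], spec$kb[i]),
      error = function(e) {
        warning(sprintf("model %d failed to fit: %s; selection proceeds over the fitted subset",
                        spec$model[i], conditionMessage(e)), call. = FALSE)
        NULL
      }
    )
  }
  aics <- purrr::map_dbl(models, function(m) if (is.null(m)) NA_real_ else m$aic)
  sel <- spec$model[which.min(aics)]
  structure(list(
    models = models,
    table = mutate(spec, aic = aics, n = nrow(design)),
    selected = sel,
    design = design
  ), class = "pursuit_lme_grid")
}

#' @export
print.pursuit_lme_grid <- function(x, ...) {
  cat(sprintf("History LME grid: %d models on %d rows; selected model %d (min AIC)\n",
              nrow(x$table), x$table$n[1], x$selected))
  print(as.data.frame(x$table), digits = 6)
  invisible(x)
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R^2_j)`, with `R^2_j` from the ordinary regression of
#' predictor j on the remaining predictors. Perfectly collinear predictors
#' get `Inf` and the collinear set is reported in a warning.
#'
#' @param design Data frame of predictors, or a [build_history_design()]
#'   result (its `stim_lag*` / `behav_lag*` columns are used).
#' @return Tibble with `term` and `vif`.
#' @export
compute_vif <- function(design) {
  if (all(c("y", "observer") %in% names(design))) {
    design <- design |>
      select(dplyr::starts_with("stim_lag"), dplyr::starts_with("behav_lag"))
  }
  x <- as.data.frame(design)
  if (ncol(x) < 2) abort("compute_vif() needs at least 2 predictors")
  vifs <- vapply(seq_len(ncol(x)), function(j) {
    fit <- lm(x[[j]] ~ ., data = x[-j])
    # a perfectly collinear predictor trips lm's perfect-fit warning;
    # it is reported as Inf below instead
    r2 <- suppressWarnings(summary(fit)$r.squared)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  if (any(is.infinite(vifs))) {
    warning(paste0("perfectly collinear predictor(s): ",
                   paste(names(x)[is.infinite(vifs)], collapse = ", ")),
            call. = FALSE)
  }
  tibble::tibble(term = names(x), vif = vifs)
}

#' Within-subject (repeated-observations) correlation
#'
#' Correlation between two repeatedly measured variables after removing
#' per-subject means (the analysis-of-covariance decomposition), so that
#' between-subject differences in level do not contribute. The p-value uses
#' the within-subject degrees of freedom `N - k - 1` (N pairs, k subjects).
#'
#' @param data Data frame.
#' @param x,y Column names (strings) of the paired measurements.
#' @param subject Column name of the subject identifier.
#' @return Tibble with `r`, `df`, `p`, `n`, `n_subjects`.
#' @export
within_subject_correlation <- function(data, x, y, subject = "observer") {
  d <- tibble::tibble(
    x = data[[x]], y = data[[y]], s = as.character(data[[subject]])
  ) |>
    filter(!is.na(.data$x), !is.na(.data$y))
  if (length(unique(d$s)) < 2) abort("need >= 2 subjects")
  counts <- table(d$s)
  if (any(counts < 3)) abort("need >= 3 pairs per subject")
  cen <- d |>
    group_by(.data$s) |>
    mutate(xc = .data$x - mean(.data$x), yc = .data$y - mean(.data$y)) |>
    ungroup()
  if (sd(cen$xc) == 0 || sd(cen$yc) == 0) {
    inform("a variable has no within-subject variance; correlation undefined")
    return(tibble::tibble(r = NA_real_, df = NA_real_, p = NA_real_,
                          n = nrow(d), n_subjects = length(unique(d$s))))
  }
  r <- cor(cen$xc, cen$yc)
  dfw <- nrow(d) - length(unique(d$s)) - 1
  tstat <- r * sqrt(dfw / (1 - r^2))
  tibble::tibble(r = r, df = dfw, p = 2 * pt(-abs(tstat), dfw),
                 n = nrow(d), n_subjects = length(unique(d$s)))
}
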