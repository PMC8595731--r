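#' Normalize eye-reversal timings per observer
#'
#' Because the location and spread of eye-reversal timings differ across
#' observers, each observer's timings are normalized using the pool of all
#' of that observer's included trials from both conditions combined:
#' `z = (T - center) / scale` with `center` the pooled mean and `scale` the
#' pooled (population) SD. `method = "center"` subtracts the mean only.
#'
#' @param table Trial table with `observer`, `condition`, `reversal_ms`,
#'   and optionally `included`.
#' @param method `"zscore"` (default) or `"center"`.
#' @return `table` (included trials only) with an added `normalized`
#'   column; the per-observer constants are attached as the attribute
#'   `"constants"` (tibble: observer, center, scale).
#' @export
normalize_timings <- function(table, method = c("zscore", "center")) {
  method <- match.arg(method)
  if (!"included" %in% names(table)) table$included <- TRUE
  tab <- filter(table, .data$included, !is.na(.data$reversal_ms))
  if (nrow(tab) == 0) abort("no included trials to normalize")
  consts <- tab |>
    group_by(.data$observer) |>
    summarise(
      center = mean(.data$reversal_ms),
      scale = sqrt(mean((.data$reversal_ms - mean(.data$reversal_ms))^2)),
      .groups = "drop"
    )
  if (any(consts$scale == 0)) {
    abort("an observer has zero timing SD; normalization undefined")
  }
  if (method == "center") consts$scale <- 1
  out <- tab |>
    left_join(consts, by = "observer") |>
    mutate(normalized = (.data$reversal_ms - .data$center) / .data$scale) |>
    select(-"center", -"scale")
  attr(out, "constants") <- consts
  out
}

#' Pooled histogram of normalized timings
#'
#' Bins the normalized eye-reversal timings in fixed-width bins (default
#' 0.25) with edges anchored at 0, pooled across observers, one
#' distribution per group: each predictable-condition target velocity, and
#' the unpredictable condition as a whole.
#'
#' @param normalized Output of [normalize_timings()].
#' @param binwidth Bin width on the normalized scale.
#' @return A list of class `pursuit_histogram` with `counts` (tibble:
#'   group, bin_left, bin_right, count), `medians` (tibble: group, median,
#'   n), and `binwidth`.
#' @export
pooled_histogram <- function(normalized, binwidth = 0.25) {
  stopifnot(all(is.finite(normalized$normalized)))
  grouped <- normalized |>
    mutate(group = ifelse(
      .data$condition == "unpredictable", "unpredictable",
      paste0(.data$leftward_velocity, " deg/s")
    ))
  counts <- grouped |>
    mutate(bin_left = floor(.data$normalized / binwidth) * binwidth) |>
    dplyr::count(.data$group, .data$bin_left, name = "count") |>
    mutate(bin_right = .data$bin_left + binwidth) |>
    select("group", "bin_left", "bin_right", "count") |>
    arrange(.data$group, .data$bin_left)
  medians <- grouped |>
    group_by(.data$group) |>
    summarise(median = median(.data$normalized), n = n(), .groups = "drop")
  structure(list(counts = counts, medians = medians, binwidth = binwidth),
            class = "pursuit_histogram")
}

#' @export
print.pursuit_histogram <- function(x, ...) {
  cat(sprintf("Pooled normalized-timing histogram (bin %.2f)\n", x$binwidth))
  print(as.data.frame(x$medians), digits = 3)
  invisible(x)
}

#' Hartigan dip statistic
#'
#' Minimum over all unimodal distribution functions of the sup-norm
#' distance to the empirical cdf. Small values indicate a unimodal sample;
#' the smallest possible value for n distinct points is `1/(2n)`.
#'
#' @param x Numeric vector.
#' @return The dip statistic (a single number).
#' @export
dip_statistic <- function(x) {
  x <- x[is.finite(x)]
  dip_stat_cpp(as.numeric(x))
}

#' Dip test of unimodality (bootstrap against the uniform null)
#'
#' Compares the sample's dip statistic with the null distribution of the
#' dip of uniform samples of the same size (the least favorable unimodal
#' case), estimated by Monte Carlo. The p-value is the fraction of null
#' dips at least as large as the observed one.
#'
#' @param x Numeric vector (n >= 50 recommended).
#' @param n_boot Number of uniform null replicates.
#' @param seed Integer seed for the null draws.
#' @param null_dips Optional precomputed null dip values for this n (e.g.
#'   reused across several tests); overrides `n_boot`/`seed`.
#' @return A tibble with `dip`, `p`, `n`, `n_boot`.
#' @export
unimodality_check <- function(x, n_boot = 500, seed = 1, null_dips = NULL) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 50) warn("dip test with n < 50 has little power")
  d <- dip_stat_cpp(as.numeric(x))
  if (is.null(null_dips)) {
    null_dips <- local_seed(seed, {
      vapply(seq_len(n_boot), function(i) dip_stat_cpp(runif(n)), numeric(1))
    })
  }
  p <- (1 + sum(null_dips >= d)) / (1 + length(null_dips))
  tibble::tibble(dip = d, p = p, n = n, n_boot = length(null_dips))
}
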