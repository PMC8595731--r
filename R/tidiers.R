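#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a fitted history LME
#'
#' @param x A `pursuit_lme` from [fit_lme()].
#' @param ... Unused.
#' @return A tibble with one row per fixed effect: `term`, `estimate`,
#'   `se`, `t`, `df`, `p`.
#' @exportS3Method generics::tidy
tidy.pursuit_lme <- function(x, ...) {
  x$fixed
}

#' One-row summary of a fitted history LME
#'
#' @param x A `pursuit_lme`.
#' @param ... Unused.
#' @return A one-row tibble: `n`, `ks`, `kb`, `aic`, `loglik`,
#'   `ranef_sd`, `sigma`, `singular`.
#' @exportS3Method generics::glance
glance.pursuit_lme <- function(x, ...) {
  tibble::tibble(n = x$n, ks = x$ks, kb = x$kb, aic = x$aic,
                 loglik = x$loglik, ranef_sd = x$ranef_sd, sigma = x$sigma,
                 singular = x$singular)
}

#' Tidy a fitted model grid
#'
#' @param x A `pursuit_lme_grid` from [model_grid_and_select()].
#' @param ... Unused.
#' @return A tibble with one row per (model, fixed effect), carrying each
#'   model's AIC and whether it was selected.
#' @exportS3Method generics::tidy
tidy.pursuit_lme_grid <- function(x, ...) {
  purrr::imap(x$models, function(m, i) {
    if (is.null(m)) return(NULL)
    mutate(m$fixed, model = i, aic = m$aic, selected = i == x$selected,
           .before = 1)
  }) |> bind_rows()
}

#' One-row-per-model summary of a fitted model grid
#'
#' @param x A `pursuit_lme_grid`.
#' @param ... Unused.
#' @return The grid table (model id, lag counts, AIC, shared row count)
#'   with a `selected` flag.
#' @exportS3Method generics::glance
glance.pursuit_lme_grid <- function(x, ...) {
  mutate(x$table, selected = .data$model == x$selected)
}
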