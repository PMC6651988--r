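#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a synthetic-control fit
#'
#' @param x An `scm_fit`.
#' @param what `"path"` (default): year, observed, synthetic, gap, period;
#'   `"weights"`: donor weights with the "~ 0" display convention;
#'   `"importance"`: predictor importance weights.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy scm_fit
#' @export
tidy.scm_fit <- function(x, what = c("path", "weights", "importance"), ...) {
  what <- match.arg(what)
  switch(what,
    path = x$path,
    weights = format_weights(x$weights),
    importance = tibble::tibble(
      predictor = x$predictor_matrices$row_names,
      v = as.numeric(x$importance)
    )
  )
}

#' One-row summary of a synthetic-control fit
#'
#' @param x An `scm_fit`.
#' @param ... Unused.
#' @return A one-row tibble: treated unit, policy year, predictor count,
#'   matching objective, pre-policy MSPE, effect summary columns, importance
#'   mode and seed.
#' @method glance scm_fit
#' @export
glance.scm_fit <- function(x, ...) {
  eff <- summarize_effect(x)
  tibble::tibble(
    treated_unit = x$meta$treated_unit,
    policy_year = x$meta$policy_year,
    n_donors = length(x$weights$w),
    k_predictors = x$predictor_matrices$k,
    objective = x$objective,
    pre_mspe = x$pre_mspe,
    mean_post_gap = eff$mean_post_gap,
    relative_effect = eff$relative_effect,
    v_mode = x$v_mode,
    seed = x$seed
  )
}

#' Tidy a placebo permutation result
#'
#' @param x A `placebo_result`.
#' @param what `"units"` (default): per-unit effect, MSPE ratio and exclusion
#'   status; `"gaps"`: long gap series for treated and placebo units.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy placebo_result
#' @export
tidy.placebo_result <- function(x, what = c("units", "gaps"), ...) {
  what <- match.arg(what)
  switch(what, units = x$per_unit, gaps = x$gaps)
}

#' One-row summary of a placebo permutation result
#'
#' @param x A `placebo_result`.
#' @param ... Unused.
#' @return A one-row tibble: treated effect, pseudo p-value, counts of
#'   retained/excluded/extreme units and the MSPE-ratio threshold.
#' @method glance placebo_result
#' @export
glance.placebo_result <- function(x, ...) {
  tibble::tibble(
    treated_unit = x$treated_unit,
    treated_effect = x$treated_effect,
    treated_pre_mspe = x$treated_pre_mspe,
    pseudo_p = x$pseudo_p,
    n_placebo = nrow(x$per_unit),
    n_retained = length(x$retained_units),
    n_excluded = length(x$excluded_units),
    n_extreme = length(x$extreme_units),
    ratio_threshold = x$ratio_threshold
  )
}

#' Tidy the DiD coefficient table
#'
#' @param x A `did_fit`.
#' @param ... Unused.
#' @return A tibble with `term`, `estimate`, `std_error`, `statistic`,
#'   `p_value`, `conf_low`, `conf_high`.
#' @method tidy did_fit
#' @export
tidy.did_fit <- function(x, ...) x$coefficients

#' One-row summary of a DiD fit
#'
#' @param x A `did_fit`.
#' @param ... Unused.
#' @return A one-row tibble: the interaction estimate (`beta3`), its CI and
#'   p-value, SE mode, R-squared and observation count.
#' @method glance did_fit
#' @export
glance.did_fit <- function(x, ...) {
  s <- summary(x$model)
  tibble::tibble(
    beta3 = x$beta3,
    conf_low = x$ci[1],
    conf_high = x$ci[2],
    p_value = x$p_value,
    se_mode = x$se_mode,
    r_squared = s$r.squared,
    sigma = s$sigma,
    nobs = stats::nobs(x$model)
  )
}
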