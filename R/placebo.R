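#' In-space placebo permutation test
#'
#' Reassigns treatment status to each donor in turn, refits the synthetic
#' control with the identical predictor specification, and compares the
#' treated unit's effect (the mean post-policy gap, in absolute value) with
#' the distribution of placebo effects. Placebo units whose pre-policy MSPE
#' exceeds `ratio_threshold` times the treated unit's MSPE are excluded
#' before computing the pseudo p-value: a large placebo gap on top of a poor
#' pre-policy fit reflects lack of fit, not a policy-sized shock.
#'
#' By default the genuinely treated unit is dropped from every placebo donor
#' pool, so the real treatment cannot contaminate placebo counterfactuals;
#' set `include_treated_in_pools = TRUE` to keep it (appropriate under a null
#' where no unit is actually treated, e.g. calibration simulations).
#'
#' @param panel An `scm_panel`.
#' @param spec A [predictor_spec()] shared by the treated and placebo fits.
#' @param ratio_threshold Exclusion threshold on the MSPE ratio
#'   (placebo pre-MSPE / treated pre-MSPE); strictly-greater ratios are
#'   excluded. Default 5.
#' @param include_treated_in_pools Keep the truly treated unit in placebo
#'   donor pools? Default `FALSE`.
#' @param v Importance-weight mode passed to [fit_synthetic_control()].
#' @param seed Seed shared by all fits.
#' @param treated_fit Optional pre-computed `scm_fit` for the treated unit
#'   (must come from the same panel/spec); avoids refitting.
#' @param ... Passed to [fit_synthetic_control()].
#' @return A `placebo_result`: per-unit summaries, exclusions with reasons,
#'   the pseudo p-value, and long-format gap series for plotting.
#' @export
#' @examples
#' p <- make_study_fixture("outpatient-like")
#' pl <- run_placebo(p, v = "equal")
#' glance(pl)
run_placebo <- function(panel, spec = predictor_spec(), ratio_threshold = 5,
                        include_treated_in_pools = FALSE, v = "auto",
                        seed = 1L, treated_fit = NULL, ...) {
  stopifnot(inherits(panel, "scm_panel"))
  m <- panel_meta(panel)
  if (length(m$donors) < 3) {
    stop("placebo test needs >= 3 donors so every placebo fit keeps >= 2",
         call. = FALSE)
  }
  fit1 <- treated_fit %||%
    suppressWarnings(fit_synthetic_control(panel, spec, v = v, seed = seed, ...))
  stopifnot(inherits(fit1, "scm_fit"))
  treated_effect <- mean(fit1$path$gap[fit1$path$period == "post"])

  per_unit <- purrr::map(m$donors, function(d) {
    pool <- c(setdiff(m$donors, d),
              if (include_treated_in_pools) m$treated_unit)
    sub <- panel[panel$unit %in% c(d, pool), , drop = FALSE]
    pseudo <- new_panel(tibble::as_tibble(sub),
                        outcome = m$outcome, covariates = m$covariates,
                        treated_unit = d, policy_year = m$policy_year)
    fit <- tryCatch(
      suppressWarnings(fit_synthetic_control(pseudo, spec, v = v, seed = seed,
                                             poor_fit_mspe = Inf, ...)),
      error = function(e) e
    )
    if (inherits(fit, "error")) {
      return(tibble::tibble(unit = d, pre_mspe = NA_real_,
                            mean_post_gap = NA_real_, failed = TRUE,
                            reason = conditionMessage(fit),
                            gaps = list(NULL)))
    }
    tibble::tibble(
      unit = d,
      pre_mspe = fit$pre_mspe,
      mean_post_gap = mean(fit$path$gap[fit$path$period == "post"]),
      failed = FALSE,
      reason = NA_character_,
      gaps = list(fit$path[, c("year", "gap")])
    )
  })
  per_unit <- dplyr::bind_rows(per_unit)
  per_unit$mspe_ratio <- per_unit$pre_mspe / fit1$pre_mspe
  per_unit$excluded <- per_unit$failed |
    (!is.na(per_unit$mspe_ratio) & per_unit$mspe_ratio > ratio_threshold)
  per_unit$reason <- dplyr::case_when(
    per_unit$failed ~ paste("fit failed:", per_unit$reason),
    per_unit$excluded ~ paste0("MSPE ratio ",
                               format(round(per_unit$mspe_ratio, 2), nsmall = 2),
                               " > ", ratio_threshold),
    TRUE ~ NA_character_
  )

  retained <- per_unit[!per_unit$excluded, , drop = FALSE]
  extreme <- retained$unit[abs(retained$mean_post_gap) >= abs(treated_effect)]
  pseudo_p <- if (nrow(retained) == 0) NA_real_
              else length(extreme) / nrow(retained)

  gaps_long <- dplyr::bind_rows(
    tibble::tibble(unit = m$treated_unit,
                   year = fit1$path$year, gap = fit1$path$gap,
                   role = "treated"),
    purrr::pmap_dfr(per_unit[!per_unit$failed, c("unit", "gaps")],
                    function(unit, gaps) {
                      tibble::tibble(unit = unit, year = gaps$year,
                                     gap = gaps$gap, role = "placebo")
                    })
  )

  structure(list(
    per_unit = per_unit[, c("unit", "pre_mspe", "mean_post_gap", "mspe_ratio",
                            "excluded", "reason")],
    gaps = gaps_long,
    treated_unit = m$treated_unit,
    treated_effect = treated_effect,
    treated_pre_mspe = fit1$pre_mspe,
    ratio_threshold = ratio_threshold,
    excluded_units = per_unit$unit[per_unit$excluded],
    retained_units = retained$unit,
    extreme_units = extreme,
    pseudo_p = pseudo_p,
    include_treated_in_pools = include_treated_in_pools,
    seed = as.integer(seed),
    treated_fit = fit1
  ), class = "placebo_result")
}

#' Exclude units by MSPE ratio
#'
#' Applies the lack-of-fit filter used by [run_placebo()]: units whose
#' pre-policy MSPE ratio (placebo / treated) is strictly greater than the
#' threshold are excluded from the placebo comparison.
#'
#' @param ratios Named numeric vector of per-unit MSPE ratios, or a data
#'   frame with `unit` and `mspe_ratio` columns.
#' @param threshold Positive cutoff; strictly-greater ratios are excluded.
#' @return Character vector of excluded unit labels.
#' @export
#' @examples
#' mspe_filter(c(a = 2, b = 6, c = 4.9, d = 5.1), 5)  # "b" "d"
mspe_filter <- function(ratios, threshold = 5) {
  stopifnot(is.numeric(threshold), length(threshold) == 1, threshold > 0)
  if (is.data.frame(ratios)) {
    ratios <- stats::setNames(ratios$mspe_ratio, ratios$unit)
  }
  stopifnot(is.numeric(ratios), !is.null(names(ratios)), all(ratios > 0,
                                                             na.rm = TRUE))
  names(ratios)[!is.na(ratios) & ratios > threshold]
}

#' Pseudo p-value from placebo effect summaries
#'
#' The proportion of retained placebo units whose absolute effect is at
#' least as large as the treated unit's. Exposed separately so the
#' arithmetic of the permutation comparison can be driven from externally
#' supplied summaries.
#'
#' @param placebo_effects Numeric vector of retained placebo mean post-policy
#'   gaps.
#' @param treated_effect The treated unit's mean post-policy gap.
#' @return Proportion in \[0, 1\]; `NA` when no units are retained.
#' @export
placebo_pvalue <- function(placebo_effects, treated_effect) {
  stopifnot(is.numeric(placebo_effects), is.numeric(treated_effect),
            length(treated_effect) == 1)
  if (length(placebo_effects) == 0) return(NA_real_)
  mean(abs(placebo_effects) >= abs(treated_effect))
}

#' @export
print.placebo_result <- function(x, ...) {
  cat("# placebo_result: treated =", x$treated_unit,
      "| effect =", format(round(x$treated_effect, 2), nsmall = 2), "pp\n")
  cat("# retained", length(x$retained_units), "of",
      nrow(x$per_unit), "placebo units (MSPE ratio threshold ",
      x$ratio_threshold, ")\n")
  if (length(x$excluded_units)) {
    cat("# excluded:", paste(x$excluded_units, collapse = ", "), "\n")
  }
  cat("# pseudo p-value =", format(x$pseudo_p, digits = 3),
      if (length(x$extreme_units))
        paste0("(as-extreme: ", paste(x$extreme_units, collapse = ", "), ")")
      else "(no placebo as extreme)", "\n")
  invisible(x)
}
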