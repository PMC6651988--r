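#' Difference-in-differences design matrix
#'
#' Expands a panel into the regression layout
#' `Y_it = gamma + b1*treat + b2*post + b3*treat:post + b X_it + e_it`:
#' one row per unit-year with treatment-group and post-period dummies, their
#' interaction, and covariates entered as raw yearly values.
#'
#' @param panel An `scm_panel`.
#' @param covariates Covariate names to include; `"all"` (default) for every
#'   covariate in the panel, `NULL` or `character()` for none.
#' @return A tibble with `unit`, `year`, `outcome`, `treat`, `post`,
#'   `treat_post` and the covariate columns.
#' @export
build_did_design <- function(panel, covariates = "all") {
  stopifnot(inherits(panel, "scm_panel"))
  m <- panel_meta(panel)
  covs <- if (identical(covariates, "all")) m$covariates
          else as.character(covariates %||% character())
  missing_cov <- setdiff(covs, m$covariates)
  if (length(missing_cov)) {
    stop("covariate(s) not in panel: ", paste(missing_cov, collapse = ", "),
         call. = FALSE)
  }
  df <- tibble::as_tibble(panel)
  tibble::tibble(
    unit = df$unit,
    year = df$year,
    outcome = df[[m$outcome]],
    treat = as.integer(df$unit == m$treated_unit),
    post = as.integer(df$year >= m$policy_year),
    treat_post = as.integer(df$unit == m$treated_unit &
                              df$year >= m$policy_year)
  ) |>
    dplyr::bind_cols(df[, covs, drop = FALSE])
}

#' Fit the difference-in-differences cross-validation regression
#'
#' Ordinary least squares of the outcome on a treated-unit dummy, a
#' post-period dummy, their interaction and (optionally) covariates. The
#' policy effect is the interaction coefficient: the change in the treated
#' unit's outcome over and above the change in the controls. This is the
#' standard cross-check on a synthetic-control estimate; it relies on the
#' parallel-trends assumption the synthetic control relaxes.
#'
#' @param panel An `scm_panel`.
#' @param covariates Covariates entered at raw yearly values; `"all"`
#'   (default), a character vector, or `NULL` for none.
#' @param se_mode `"classical"` (homoskedastic OLS, default) or `"cluster"`
#'   (cluster-robust by unit, t critical values on n_clusters - 1 degrees of
#'   freedom).
#' @param conf_level Confidence level for the interaction CI. Default 0.95.
#' @return A `did_fit`: the underlying `lm`, a tidy coefficient table,
#'   `beta3` (effect estimate, pp), `ci` and `p_value` for the interaction,
#'   and the `se_mode` used.
#' @export
#' @examples
#' p <- generate_panel(dgp_config(parallel_trends = TRUE, tau = -5, seed = 3))
#' fit_did(p)$beta3
fit_did <- function(panel, covariates = "all",
                    se_mode = c("classical", "cluster"), conf_level = 0.95) {
  se_mode <- match.arg(se_mode)
  design <- build_did_design(panel, covariates)
  covs <- setdiff(names(design), c("unit", "year", "outcome", "treat", "post",
                                   "treat_post"))
  if (all(design$treat == 0) || all(design$treat_post == 0)) {
    stop("degenerate design: column 'treat_post' has no variation",
         call. = FALSE)
  }
  rhs <- c("treat", "post", "treat_post", covs)
  fml <- stats::reformulate(rhs, response = "outcome")
  model <- stats::lm(fml, data = design)

  aliased <- names(stats::coef(model))[is.na(stats::coef(model))]
  if (length(aliased)) {
    stop("rank-deficient design: column(s) ",
         paste(aliased, collapse = ", "), " are collinear", call. = FALSE)
  }

  if (se_mode == "classical") {
    vc <- stats::vcov(model)
    df_t <- model$df.residual
  } else {
    vc <- sandwich::vcovCL(model, cluster = design$unit)
    df_t <- length(unique(design$unit)) - 1
  }
  ct <- lmtest::coeftest(model, vcov. = vc, df = df_t)
  ci <- lmtest::coefci(model, vcov. = vc, df = df_t, level = conf_level)

  coefs <- tibble::tibble(
    term = rownames(ct),
    estimate = unname(ct[, "Estimate"]),
    std_error = unname(ct[, "Std. Error"]),
    statistic = unname(ct[, "t value"]),
    p_value = unname(ct[, "Pr(>|t|)"]),
    conf_low = unname(ci[, 1]),
    conf_high = unname(ci[, 2])
  )
  b3 <- coefs[coefs$term == "treat_post", ]

  structure(list(
    model = model,
    coefficients = coefs,
    beta3 = b3$estimate,
    ci = c(b3$conf_low, b3$conf_high),
    p_value = b3$p_value,
    se_mode = se_mode,
    conf_level = conf_level,
    covariates = covs,
    design = design
  ), class = "did_fit")
}

#' @export
print.did_fit <- function(x, ...) {
  cat("# did_fit (", x$se_mode, " SEs): effect (interaction) = ",
      format(round(x$beta3, 3), nsmall = 3), " pp, ",
      100 * x$conf_level, "% CI [",
      format(round(x$ci[1], 3), nsmall = 3), ", ",
      format(round(x$ci[2], 3), nsmall = 3), "], p = ",
      format.pval(x$p_value, digits = 3), "\n", sep = "")
  invisible(x)
}
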