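#' Specify the predictors used to match treated and donors
#'
#' The matching distance compares units on (i) covariates aggregated as
#' pre-policy means and (ii) the outcome itself in selected pre-policy years
#' ("outcome lags"). By default every covariate in the panel and every
#' pre-policy year's outcome enter as predictors.
#'
#' @param covariates Character vector of covariate names, or `"all"` to use
#'   every covariate the panel carries.
#' @param outcome_lags Integer vector of pre-policy years whose outcome values
#'   are matched on, or `"all"` for every pre-policy year.
#' @return A `predictor_spec` object.
#' @export
predictor_spec <- function(covariates = "all", outcome_lags = "all") {
  if (!identical(covariates, "all")) covariates <- as.character(covariates)
  if (!identical(outcome_lags, "all")) outcome_lags <- as.integer(outcome_lags)
  structure(list(covariates = covariates, outcome_lags = outcome_lags),
            class = "predictor_spec")
}

resolve_spec <- function(spec, meta) {
  covs <- if (identical(spec$covariates, "all")) meta$covariates
          else spec$covariates
  lags <- if (identical(spec$outcome_lags, "all")) meta$pre_years
          else spec$outcome_lags
  missing_cov <- setdiff(covs, meta$covariates)
  if (length(missing_cov)) {
    stop("covariate(s) not in panel: ", paste(missing_cov, collapse = ", "),
         call. = FALSE)
  }
  bad_lags <- setdiff(lags, meta$pre_years)
  if (length(bad_lags)) {
    stop("outcome lag(s) outside the pre-policy period: ",
         paste(bad_lags, collapse = ", "), call. = FALSE)
  }
  if (length(covs) + length(lags) == 0) {
    stop("predictor spec is empty: need at least one covariate or outcome lag",
         call. = FALSE)
  }
  list(covariates = covs, outcome_lags = as.integer(lags))
}

#' Build treated and donor predictor matrices
#'
#' Assembles the k-vector `X1` (treated unit) and the k-by-J matrix `X0`
#' (donors): one row per covariate, holding its pre-policy mean per unit, and
#' one row per outcome lag, holding that year's outcome per unit. Rows are
#' standardized (centered and scaled across all J+1 units) for the weight
#' optimization, so that predictors measured in persons, currency and
#' percentages contribute comparably to the matching distance; the raw-scale
#' matrices and the standardization record are retained for balance reporting.
#'
#' @param panel An `scm_panel`.
#' @param spec A [predictor_spec()].
#' @return A `predictor_matrices` object: standardized `X1`, `X0`, raw
#'   `X1_raw`, `X0_raw`, `row_names`, `center`, `scale`, donor labels and `k`.
#' @export
build_predictor_matrices <- function(panel, spec = predictor_spec()) {
  stopifnot(inherits(panel, "scm_panel"), inherits(spec, "predictor_spec"))
  m <- panel_meta(panel)
  rs <- resolve_spec(spec, m)
  units <- m$units  # treated first

  rows <- list()
  for (cv in rs$covariates) {
    pre <- panel[panel$year %in% m$pre_years, c("unit", cv)]
    means <- tapply(pre[[cv]], pre$unit, mean, na.rm = TRUE)[units]
    all_missing <- names(means)[!is.finite(means)]
    if (length(all_missing)) {
      stop("covariate '", cv, "' entirely missing in the pre-policy period ",
           "for unit(s): ", paste(all_missing, collapse = ", "), call. = FALSE)
    }
    rows[[paste0(cv, " (pre-period mean)")]] <- as.numeric(means)
  }
  ymat <- outcome_matrix(panel, units = units)
  for (lag in rs$outcome_lags) {
    rows[[paste0(m$outcome, " (", lag, ")")]] <- ymat[as.character(lag), ]
  }

  raw <- do.call(rbind, rows)
  colnames(raw) <- units
  center <- rowMeans(raw)
  scale <- apply(raw, 1, stats::sd)
  scale[scale == 0 | !is.finite(scale)] <- 1
  std <- (raw - center) / scale

  structure(list(
    X1 = std[, 1], X0 = std[, -1, drop = FALSE],
    X1_raw = raw[, 1], X0_raw = raw[, -1, drop = FALSE],
    row_names = rownames(raw), center = center, scale = scale,
    treated_unit = units[1], donors = units[-1], k = nrow(raw),
    spec = rs
  ), class = "predictor_matrices")
}

#' @export
print.predictor_matrices <- function(x, ...) {
  cat("# predictor_matrices: k =", x$k, "predictors,", length(x$donors),
      "donors\n")
  cat(paste0("  - ", x$row_names, collapse = "\n"), "\n")
  invisible(x)
}

#' Normalized predictor importance weights
#'
#' @param v Nonnegative numeric vector of length k; normalized to sum to one.
#' @return An `importance_weights` object (numeric vector summing to 1).
#' @export
importance_weights <- function(v) {
  stopifnot(is.numeric(v), length(v) >= 1, all(is.finite(v)))
  if (any(v < 0)) stop("importance weights must be nonnegative", call. = FALSE)
  s <- sum(v)
  if (s <= 0) stop("importance weights must have positive sum", call. = FALSE)
  structure(as.numeric(v / s), class = "importance_weights")
}

#' Solve for donor weights on the simplex
#'
#' Finds the donor weight vector `W` minimizing the weighted matching
#' distance `(X1 - X0 W)' V (X1 - X0 W)` subject to `w_j >= 0` and
#' `sum(w_j) = 1` — a convex quadratic program over the probability simplex,
#' solved with an active-set method. Weights are stored at full precision;
#' the print method displays weights below 0.001 as "~ 0".
#'
#' @param pm A [build_predictor_matrices()] result.
#' @param v Importance weights: an [importance_weights()] vector, a bare
#'   nonnegative vector (normalized internally), or `NULL` for equal weights.
#' @return A `donor_weights` object: named weight vector `w`, the achieved
#'   `objective` (squared distance, standardized predictor scale) and the `v`
#'   used.
#' @export
solve_weights <- function(pm, v = NULL) {
  stopifnot(inherits(pm, "predictor_matrices"))
  k <- pm$k
  J <- length(pm$donors)
  if (J < 2) stop("need at least 2 donors", call. = FALSE)
  v <- if (is.null(v)) importance_weights(rep(1, k)) else importance_weights(v)
  if (length(v) != k) {
    stop("importance weights have length ", length(v), ", expected ", k,
         call. = FALSE)
  }

  X0 <- pm$X0
  X1 <- pm$X1
  H <- 2 * crossprod(X0, as.numeric(v) * X0)
  ridge <- 1e-9 * max(mean(diag(H)), 1)
  H <- H + ridge * diag(J)
  f <- as.numeric(-2 * crossprod(X0, as.numeric(v) * X1))

  sol <- tryCatch(
    suppressWarnings(
      pracma::quadprog(H, f, Aeq = matrix(1, 1, J), beq = 1, lb = rep(0, J))
    ),
    error = function(e) {
      stop("weight optimization failed: ", conditionMessage(e), call. = FALSE)
    }
  )
  w <- sol$xmin
  w[w < 0 & w > -1e-7] <- 0
  if (any(w < 0) || abs(sum(w) - 1) > 1e-6) {
    stop("weight optimization returned an infeasible solution (status ",
         sol$eflag, ")", call. = FALSE)
  }
  w <- w / sum(w)
  names(w) <- pm$donors
  obj <- weight_objective(pm, w, v)
  structure(list(w = w, objective = obj, v = v), class = "donor_weights")
}

# squared weighted matching distance on the standardized predictor scale
weight_objective <- function(pm, w, v) {
  d <- pm$X1 - as.numeric(pm$X0 %*% w)
  sum(as.numeric(v) * d^2)
}

#' @export
print.donor_weights <- function(x, digits = 3, ...) {
  cat("# donor_weights (objective =", format(x$objective, digits = 6), ")\n")
  shown <- ifelse(x$w < 0.001, "~ 0", format(round(x$w, digits), nsmall = digits))
  for (i in seq_along(x$w)) cat("  ", names(x$w)[i], ": ", shown[i], "\n", sep = "")
  invisible(x)
}

#' Format donor weights for display
#'
#' Applies the reporting convention of showing weights under 0.001 as "~ 0"
#' while keeping full precision in the numeric column.
#'
#' @param w A `donor_weights` object or named numeric weight vector.
#' @return A tibble with `unit`, `weight` and `display` columns.
#' @export
format_weights <- function(w) {
  if (inherits(w, "donor_weights")) w <- w$w
  tibble::tibble(
    unit = names(w),
    weight = unname(as.numeric(w)),
    display = unname(ifelse(w < 0.001, "~ 0",
                            format(round(w, 3), nsmall = 3)))
  )
}
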