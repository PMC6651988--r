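#' Build a validated policy-evaluation panel
#'
#' Constructs an `scm_panel`, the tabular container used throughout the
#' package: one row per unit-year, an outcome column in percentage points,
#' and zero or more covariate columns. Exactly one unit is marked as treated
#' and a policy year splits the calendar into a pre-policy fitting window and
#' a post-policy evaluation window.
#'
#' @param data A data frame with one row per unit-year.
#' @param outcome Name of the outcome column (percentage points, 0-100).
#' @param treated_unit Label of the single treated unit; every other unit
#'   forms the donor pool.
#' @param policy_year First post-policy calendar year. Must leave at least
#'   two pre-policy years and one post-policy year inside the observed range.
#' @param covariates Character vector of covariate column names (may be
#'   empty). Covariate cells may be missing; outcome cells may not.
#' @param unit,year Names of the unit-label and calendar-year columns.
#'
#' @return A tibble of class `scm_panel` with columns `unit`, `year`, the
#'   outcome and the covariates, carrying the design annotations as
#'   attributes (see [panel_meta()]).
#' @export
#' @examples
#' df <- expand.grid(unit = c("A", "B", "C"), year = 2008:2012)
#' df$y <- 50 + rnorm(nrow(df))
#' as_panel(df, outcome = "y", treated_unit = "A", policy_year = 2011)
as_panel <- function(data, outcome, treated_unit, policy_year,
                     covariates = character(), unit = "unit", year = "year") {
  stopifnot(is.data.frame(data), is.character(outcome), length(outcome) == 1)
  for (col in c(unit, year, outcome, covariates)) {
    if (!col %in% names(data)) {
      stop("column '", col, "' not found in `data`", call. = FALSE)
    }
  }
  out <- tibble::as_tibble(data)
  out <- dplyr::rename(out, unit = !!rlang::sym(unit), year = !!rlang::sym(year))
  out <- dplyr::select(out, "unit", "year",
                       dplyr::all_of(c(outcome, covariates)))
  out$unit <- as.character(out$unit)
  out$year <- as.integer(out$year)
  out <- dplyr::arrange(out, match(.data$unit, unique(.data$unit)), .data$year)
  out <- tibble::as_tibble(lapply(out, unname))  # drop stray input attributes

  validate_panel_frame(out, outcome, covariates, treated_unit, policy_year)

  new_panel(out,
            outcome = outcome, covariates = covariates,
            treated_unit = as.character(treated_unit),
            policy_year = as.integer(policy_year))
}

new_panel <- function(df, outcome, covariates, treated_unit, policy_year,
                      adjustment = NULL) {
  structure(
    df,
    outcome = outcome,
    covariates = covariates,
    treated_unit = treated_unit,
    policy_year = policy_year,
    adjustment = adjustment,
    class = c("scm_panel", class(tibble::tibble()))
  )
}

validate_panel_frame <- function(df, outcome, covariates, treated_unit,
                                 policy_year) {
  dup <- df[duplicated(df[c("unit", "year")]), , drop = FALSE]
  if (nrow(dup) > 0) {
    stop("duplicate unit-year rows: ",
         paste(unique(paste(dup$unit, dup$year)), collapse = ", "),
         call. = FALSE)
  }
  units <- unique(df$unit)
  if (!treated_unit %in% units) {
    stop("treated unit '", treated_unit, "' not present in panel", call. = FALSE)
  }
  if (length(units) < 3) {
    stop("need at least 2 donor units (J >= 2); panel has ",
         length(units) - 1, call. = FALSE)
  }
  years <- sort(unique(df$year))
  gaps <- setdiff(seq(min(years), max(years)), years)
  if (length(gaps) > 0) {
    stop("year gap(s) in panel: ", paste(gaps, collapse = ", "), call. = FALSE)
  }
  # balanced grid: every unit observed every year
  counts <- table(df$unit)
  if (any(counts != length(years))) {
    bad <- names(counts)[counts != length(years)]
    stop("unbalanced panel: unit(s) ", paste(bad, collapse = ", "),
         " missing some years", call. = FALSE)
  }
  pre <- years[years < policy_year]
  post <- years[years >= policy_year]
  if (length(pre) < 2 || length(post) < 1) {
    stop("policy year ", policy_year, " must leave >= 2 pre-policy and ",
         ">= 1 post-policy years (observed ", min(years), "-", max(years), ")",
         call. = FALSE)
  }
  y <- df[[outcome]]
  if (anyNA(y)) stop("missing outcome values are not allowed", call. = FALSE)
  if (any(y < 0 | y > 100)) {
    stop("outcome must lie in [0, 100] percentage points", call. = FALSE)
  }
  invisible(df)
}

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble

#' Strip a panel down to a plain tibble
#'
#' Drops the `scm_panel` class and its design-annotation attributes,
#' returning just the unit-year data.
#'
#' @param x An `scm_panel`.
#' @param ... Unused.
#' @return A bare tibble.
#' @method as_tibble scm_panel
#' @export
as_tibble.scm_panel <- function(x, ...) {
  tibble::as_tibble(stats::setNames(lapply(names(x), function(n) x[[n]]),
                                    names(x)))
}

#' Panel design annotations
#'
#' @param panel An `scm_panel`.
#' @return A list with elements `outcome`, `covariates`, `treated_unit`,
#'   `policy_year`, `units` (treated first), `donors`, `years`, `pre_years`,
#'   `post_years` and `adjustment` (the donor-level adjustment record, or
#'   `NULL` if none was applied).
#' @export
panel_meta <- function(panel) {
  stopifnot(inherits(panel, "scm_panel"))
  units <- unique(panel$unit)
  treated <- attr(panel, "treated_unit")
  years <- sort(unique(panel$year))
  t0 <- attr(panel, "policy_year")
  list(
    outcome = attr(panel, "outcome"),
    covariates = attr(panel, "covariates"),
    treated_unit = treated,
    policy_year = t0,
    units = c(treated, setdiff(units, treated)),
    donors = setdiff(units, treated),
    years = years,
    pre_years = years[years < t0],
    post_years = years[years >= t0],
    adjustment = attr(panel, "adjustment")
  )
}

#' @export
print.scm_panel <- function(x, ...) {
  m <- panel_meta(x)
  cat("# scm_panel: ", length(m$units), " units (", length(m$donors),
      " donors), years ", min(m$years), "-", max(m$years),
      ", policy year ", m$policy_year, "\n", sep = "")
  cat("# treated: ", m$treated_unit, "; outcome: ", m$outcome, sep = "")
  if (length(m$covariates)) {
    cat("; covariates: ", paste(m$covariates, collapse = ", "), sep = "")
  }
  cat("\n")
  if (!is.null(m$adjustment)) {
    cat("# donor-level adjustment: ", format_adjustment(m$adjustment), "\n",
        sep = "")
  }
  NextMethod()
}

format_adjustment <- function(adj) {
  paste0(
    vapply(adj, function(a) {
      paste0(if (a$mode == "additive") paste0("-", a$offset, " pp")
             else paste0("x(1 - ", a$offset, "/100)"),
             if (isTRUE(a$out_of_range)) " [out-of-range flagged]" else "")
    }, character(1)),
    collapse = "; ")
}

#' Extract the outcome matrix of a panel
#'
#' @param panel An `scm_panel`.
#' @param units Unit labels selecting (and ordering) columns; defaults to all
#'   units, treated first.
#' @param years Calendar years selecting rows; defaults to all years.
#' @return A years-by-units numeric matrix with dimnames.
#' @export
outcome_matrix <- function(panel, units = NULL, years = NULL) {
  m <- panel_meta(panel)
  units <- units %||% m$units
  years <- years %||% m$years
  wide <- tidyr::pivot_wider(panel[, c("unit", "year", m$outcome)],
                             names_from = "unit",
                             values_from = dplyr::all_of(m$outcome))
  wide <- dplyr::arrange(wide, .data$year)
  mat <- as.matrix(wide[, units, drop = FALSE])
  rownames(mat) <- wide$year
  mat[as.character(years), , drop = FALSE]
}

#' Shift donor-pool outcomes by a fixed offset
#'
#' Applies a level adjustment to every donor's outcome in every year, leaving
#' the treated unit and all covariates untouched. This mirrors the practice of
#' re-levelling a donor pool whose outcome sits persistently above (or below)
#' a structurally unique treated unit, so that a convex combination of donors
#' can reach the treated unit's pre-policy trajectory.
#'
#' The default interpretation is additive: `offset` percentage points are
#' subtracted from each donor outcome. A relative mode (`mode = "relative"`)
#' rescales donor outcomes by `1 - offset/100` instead.
#'
#' @param panel An `scm_panel`.
#' @param offset Finite numeric adjustment. Positive values lower donor
#'   outcomes.
#' @param mode `"additive"` (subtract `offset` percentage points, the default)
#'   or `"relative"` (multiply by `1 - offset/100`).
#' @return A new `scm_panel` with adjusted donor outcomes. The adjustment is
#'   recorded in the panel's metadata (see [panel_meta()]) so downstream
#'   reports can state it. If any adjusted outcome leaves `[0, 100]` a warning
#'   is raised and the record is flagged, but the values are kept as computed.
#' @export
#' @examples
#' p <- generate_panel(dgp_config(seed = 1))
#' adj <- adjust_donor_level(p, 10)
#' panel_meta(adj)$adjustment
adjust_donor_level <- function(panel, offset, mode = c("additive", "relative")) {
  stopifnot(inherits(panel, "scm_panel"), is.numeric(offset),
            length(offset) == 1, is.finite(offset))
  mode <- match.arg(mode)
  m <- panel_meta(panel)
  df <- tibble::as_tibble(panel)
  is_donor <- df$unit != m$treated_unit
  y <- df[[m$outcome]]
  y[is_donor] <- if (mode == "additive") y[is_donor] - offset
                 else y[is_donor] * (1 - offset / 100)
  out_of_range <- any(y[is_donor] < 0 | y[is_donor] > 100)
  if (out_of_range && offset != 0) {
    warning("donor-level adjustment pushes some outcomes outside [0, 100]; ",
            "values kept and flagged in metadata", call. = FALSE)
  }
  df[[m$outcome]] <- y
  record <- list(offset = offset, mode = mode, out_of_range = out_of_range)
  new_panel(df,
            outcome = m$outcome, covariates = m$covariates,
            treated_unit = m$treated_unit, policy_year = m$policy_year,
            adjustment = c(m$adjustment, list(record)))
}

#' Read a panel from CSV
#'
#' Two layouts are supported. `"wide"` (one row per unit-year with one column
#' per variable) is the tidy interchange layout; `"long"` is a key-value
#' layout with columns `unit, year, variable, value`, melted on read.
#'
#' @inheritParams as_panel
#' @param path Path to a UTF-8 CSV file with a header row.
#' @param layout `"wide"` or `"long"`.
#' @param variable,value Column names holding the variable key and value in
#'   the long layout.
#' @return An `scm_panel`.
#' @export
read_panel <- function(path, outcome, treated_unit, policy_year,
                       covariates = character(), layout = c("wide", "long"),
                       unit = "unit", year = "year",
                       variable = "variable", value = "value") {
  layout <- match.arg(layout)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  # utils::read.csv parses doubles with correct rounding, so a write -> read
  # -> write cycle is byte-stable
  df <- tibble::as_tibble(utils::read.csv(path, check.names = FALSE))
  if (layout == "long") {
    for (col in c(unit, year, variable, value)) {
      if (!col %in% names(df)) {
        stop("long layout requires column '", col, "'", call. = FALSE)
      }
    }
    key <- paste(df[[unit]], df[[year]], df[[variable]])
    if (anyDuplicated(key)) {
      stop("duplicate unit-year rows: ",
           paste(utils::head(unique(key[duplicated(key)]), 3), collapse = ", "),
           call. = FALSE)
    }
    df <- tidyr::pivot_wider(df, id_cols = dplyr::all_of(c(unit, year)),
                             names_from = dplyr::all_of(variable),
                             values_from = dplyr::all_of(value))
  }
  as_panel(df, outcome = outcome, treated_unit = treated_unit,
           policy_year = policy_year, covariates = covariates,
           unit = unit, year = year)
}

#' Write a panel to canonical long CSV
#'
#' Writes the key-value long layout (`unit, year, variable, value`) plus an
#' optional JSON sidecar recording the design annotations and any donor-level
#' adjustment, so a written panel is self-describing.
#'
#' @param panel An `scm_panel`.
#' @param path Output CSV path.
#' @param sidecar Write `<path>.json` with the panel metadata? Default `TRUE`.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path, sidecar = TRUE) {
  m <- panel_meta(panel)
  long <- tidyr::pivot_longer(tibble::as_tibble(panel),
                              cols = dplyr::all_of(c(m$outcome, m$covariates)),
                              names_to = "variable", values_to = "value")
  long <- dplyr::arrange(long, match(.data$unit, m$units), .data$year,
                         match(.data$variable, c(m$outcome, m$covariates)))
  readr::write_csv(long, path, progress = FALSE)
  if (sidecar) {
    meta <- list(outcome = m$outcome, covariates = m$covariates,
                 treated_unit = m$treated_unit, policy_year = m$policy_year,
                 adjustment = m$adjustment, layout = "long",
                 writer = paste0("synthgap ",
                                 as.character(utils::packageVersion("synthgap"))))
    jsonlite::write_json(meta, paste0(path, ".json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  invisible(path)
}
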