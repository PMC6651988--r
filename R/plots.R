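#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a synthetic-control fit
#'
#' @param object An `scm_fit`.
#' @param type `"path"` (observed vs synthetic trajectories, default) or
#'   `"gap"` (the per-year gap around zero).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot scm_fit
#' @export
autoplot.scm_fit <- function(object, type = c("path", "gap"), ...) {
  type <- match.arg(type)
  t0 <- object$meta$policy_year
  if (type == "path") {
    long <- tidyr::pivot_longer(object$path, c("observed", "synthetic"),
                                names_to = "series", values_to = "value")
    ggplot2::ggplot(long, ggplot2::aes(.data$year, .data$value,
                                       linetype = .data$series)) +
      ggplot2::geom_line() +
      ggplot2::geom_vline(xintercept = t0 - 0.5, linetype = "dotted") +
      ggplot2::labs(x = "year", y = "outcome (pp)",
                    title = paste("Observed vs synthetic:",
                                  object$meta$treated_unit)) +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(object$path, ggplot2::aes(.data$year, .data$gap)) +
      ggplot2::geom_line() +
      ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
      ggplot2::geom_vline(xintercept = t0 - 0.5, linetype = "dotted") +
      ggplot2::labs(x = "year", y = "gap (observed - synthetic, pp)",
                    title = paste("Gap series:", object$meta$treated_unit)) +
      ggplot2::theme_minimal()
  }
}

#' Plot a placebo permutation result
#'
#' @param object A `placebo_result`.
#' @param type `"gaps"` (treated gap over the retained placebo gap cloud,
#'   default) or `"histogram"` (placebo mean effects with the treated effect
#'   and its negation as dashed reference lines).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot placebo_result
#' @export
autoplot.placebo_result <- function(object, type = c("gaps", "histogram"),
                                    ...) {
  type <- match.arg(type)
  if (type == "gaps") {
    keep <- c(object$treated_unit, object$retained_units)
    g <- object$gaps[object$gaps$unit %in% keep, ]
    ggplot2::ggplot(g, ggplot2::aes(.data$year, .data$gap,
                                    group = .data$unit,
                                    colour = .data$role,
                                    linewidth = .data$role)) +
      ggplot2::geom_line() +
      ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
      ggplot2::scale_colour_manual(values = c(treated = "black",
                                              placebo = "grey70")) +
      ggplot2::scale_linewidth_manual(values = c(treated = 1, placebo = 0.4)) +
      ggplot2::labs(x = "year", y = "gap (pp)",
                    title = "Treated gap vs placebo gaps") +
      ggplot2::theme_minimal()
  } else {
    eff <- object$per_unit[!object$per_unit$excluded, ]
    ggplot2::ggplot(eff, ggplot2::aes(.data$mean_post_gap)) +
      ggplot2::geom_histogram(bins = 10, fill = "grey80", colour = "grey40") +
      ggplot2::geom_vline(xintercept = c(-1, 1) * abs(object$treated_effect),
                          linetype = "dashed") +
      ggplot2::labs(x = "placebo mean post-policy gap (pp)", y = "count",
                    title = "Placebo effects vs treated effect") +
      ggplot2::theme_minimal()
  }
}

#' Plot every unit's outcome trajectory
#'
#' @param panel An `scm_panel`.
#' @return A ggplot with the treated unit highlighted and the policy year
#'   marked.
#' @export
plot_panel_trends <- function(panel) {
  m <- panel_meta(panel)
  df <- tibble::as_tibble(panel)
  df$role <- ifelse(df$unit == m$treated_unit, "treated", "donor")
  ggplot2::ggplot(df, ggplot2::aes(.data$year, .data[[m$outcome]],
                                   group = .data$unit, colour = .data$role)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = m$policy_year - 0.5, linetype = "dotted") +
    ggplot2::scale_colour_manual(values = c(treated = "black",
                                            donor = "grey70")) +
    ggplot2::labs(x = "year", y = paste0(m$outcome, " (pp)"),
                  title = "Outcome trajectories") +
    ggplot2::theme_minimal()
}
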