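#' Plot a concordance table
#'
#' Dot-and-interval chart of discordancy rates per variable, major rates
#' emphasised, faceted by variable group.
#'
#' @param object A `neo_concordance` tibble from [concordance_table()] or
#'   [compare_cohorts()].
#' @param which `"major"` or `"any"` discordancy.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.neo_concordance <- function(object, which = c("major", "any"), ...) {
  which <- match.arg(which)
  df <- tibble::as_tibble(object)
  df$rate <- df[[paste0(which, "_rate")]]
  df$lower <- df[[paste0(which, "_lower")]]
  df$upper <- df[[paste0(which, "_upper")]]
  df <- df[!is.na(df$rate), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rate,
                                   y = stats::reorder(.data$variable, .data$rate))) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$lower, xmax = .data$upper),
                            height = 0.25) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$group), scales = "free_y",
                        space = "free_y") +
    ggplot2::labs(x = sprintf("%s discordancy (%%), 95%% CI", which), y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a diagnostic-accuracy table
#'
#' Forest-style chart of sensitivity, specificity and PPV per binary
#' variable with Clopper-Pearson intervals.
#'
#' @param object A `neo_accuracy` tibble from [accuracy_table()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.neo_accuracy <- function(object, ...) {
  long <- tibble::as_tibble(object) |>
    tidyr::pivot_longer(dplyr::matches("^(sensitivity|specificity|ppv)_"),
                        names_to = c("metric", ".value"), names_sep = "_(?=[a-z]+$)") |>
    dplyr::filter(!is.na(.data$estimate))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$estimate, y = .data$variable)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$lower, xmax = .data$upper),
                            height = 0.25) +
    ggplot2::facet_wrap(ggplot2::vars(.data$metric)) +
    ggplot2::labs(x = "estimate (%), 95% CI", y = NULL) +
    ggplot2::theme_minimal()
}

#' Box plot of per-centre missingness
#'
#' Shows unit-to-unit variation in data completeness for one or more
#' variables, one box per variable over the centre-level missing
#' percentages.
#'
#' @param data A tibble of infants with a centre column.
#' @param variables Character vector of variables to profile.
#' @param centre Centre column name.
#' @return A ggplot object.
#' @export
plot_centre_completeness <- function(data, variables, centre = "centre_id") {
  per <- dplyr::bind_rows(purrr::map(variables, function(v) {
    dplyr::mutate(centre_distribution(data, v, centre)$by_centre, variable = v)
  }))
  ggplot2::ggplot(per, ggplot2::aes(x = .data$variable, y = .data$pct_missing)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = NULL, y = "missing data per centre (%)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
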