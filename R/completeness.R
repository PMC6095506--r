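#' Completeness profile of a database
#'
#' Percentage of rows with a non-missing value for each variable,
#' optionally split by grouping keys (e.g. year of birth) and repeated for
#' a subgroup (e.g. infants born before 32 weeks of gestation). A joint
#' row reports the percentage of rows complete on the whole variable list
#' at once. "Missing" means `NA` or a sentinel-coded value.
#'
#' @param data A tibble (one row per infant).
#' @param variables Character vector of column names to profile.
#' @param group_keys Optional character vector of grouping columns.
#' @param subgroup_filter Optional predicate `function(data)` returning a
#'   logical row mask; profiled rows are added with `subgroup =
#'   subgroup_label`.
#' @param subgroup_label Label for the subgroup rows.
#' @param sentinels Values treated as missing besides `NA`.
#' @return A tibble of class `neo_completeness`: `variable` (including
#'   `"all_variables"`), any group keys, `subgroup`, `n`, `n_complete`,
#'   `pct_complete` (`NA` with a zero denominator).
#' @examples
#' df <- tibble::tibble(steroids = c(TRUE, NA, TRUE, NA, rep(TRUE, 6)),
#'                      sex = rep("male", 10))
#' completeness_table(df, c("steroids", "sex"))
#' @export
completeness_table <- function(data, variables, group_keys = NULL,
                               subgroup_filter = NULL, subgroup_label = "subgroup",
                               sentinels = c("", "unknown", "Not stated")) {
  absent <- setdiff(variables, names(data))
  if (length(absent)) {
    stop_field("variables", paste("not in data:", paste(absent, collapse = ", ")))
  }
  is_missing <- function(x) is.na(x) | (as.character(x) %in% sentinels)
  profile_one <- function(df, label) {
    miss_mat <- purrr::map(variables, function(v) is_missing(df[[v]]))
    df$.complete_all <- !Reduce(`|`, miss_mat)
    grouped <- if (is.null(group_keys)) dplyr::group_by(df) else
      dplyr::group_by(df, dplyr::across(dplyr::all_of(group_keys)))
    per_var <- purrr::map(variables, function(v) {
      grouped |>
        dplyr::summarise(variable = v, n = dplyr::n(),
                         n_complete = sum(!is_missing(.data[[v]])), .groups = "drop")
    })
    joint <- grouped |>
      dplyr::summarise(variable = "all_variables", n = dplyr::n(),
                       n_complete = sum(.data$.complete_all), .groups = "drop")
    dplyr::bind_rows(per_var, joint) |>
      dplyr::mutate(subgroup = label,
                    pct_complete = ifelse(.data$n > 0, 100 * .data$n_complete / .data$n,
                                          NA_real_))
  }
  out <- profile_one(data, "all")
  if (!is.null(subgroup_filter)) {
    mask <- subgroup_filter(data)
    out <- dplyr::bind_rows(out, profile_one(data[mask, , drop = FALSE], subgroup_label))
  }
  cols <- c("variable", group_keys, "subgroup", "n", "n_complete", "pct_complete")
  out <- dplyr::select(out, dplyr::all_of(cols))
  class(out) <- c("neo_completeness", class(out))
  out
}

#' Per-centre missingness distribution for one variable
#'
#' Supports box-plot style reporting of unit-to-unit variation in data
#' completeness: the percentage of missing values per centre, and its
#' five-number summary (minimum, quartiles, maximum) across centres.
#' Quartiles use linear interpolation between order statistics
#' (`stats::quantile` type 7).
#'
#' @param data A tibble with a centre column.
#' @param variable Column name to profile.
#' @param centre Name of the centre column, default `"centre_id"`.
#' @param sentinels Values treated as missing besides `NA`.
#' @return A list of class `neo_centre_dist`: `by_centre` (tibble
#'   `centre_id`, `n`, `n_missing`, `pct_missing`) and `summary` (one row:
#'   `variable`, `n_centres`, `min`, `q1`, `median`, `q3`, `max`).
#' @export
centre_distribution <- function(data, variable, centre = "centre_id",
                                sentinels = c("", "unknown", "Not stated")) {
  if (!centre %in% names(data)) stop_field("centre", "column not found")
  if (!variable %in% names(data)) stop_field("variable", "column not found")
  by_centre <- data |>
    dplyr::group_by(centre_id = .data[[centre]]) |>
    dplyr::summarise(
      n = dplyr::n(),
      n_missing = sum(is.na(.data[[variable]]) |
                        as.character(.data[[variable]]) %in% sentinels),
      .groups = "drop") |>
    dplyr::mutate(pct_missing = 100 * .data$n_missing / .data$n)
  q <- quantile(by_centre$pct_missing, c(0, 0.25, 0.5, 0.75, 1), type = 7)
  out <- list(
    by_centre = by_centre,
    summary = tibble::tibble(variable = variable, n_centres = nrow(by_centre),
                             min = q[[1]], q1 = q[[2]], median = q[[3]],
                             q3 = q[[4]], max = q[[5]]))
  class(out) <- "neo_centre_dist"
  out
}

#' @export
print.neo_centre_dist <- function(x, ...) {
  s <- x$summary
  cat(sprintf("missing %% of '%s' across %d centres: min %.1f, Q1 %.1f, median %.1f, Q3 %.1f, max %.1f\n",
              s$variable, s$n_centres, s$min, s$q1, s$median, s$q3, s$max))
  invisible(x)
}

#' Population-coverage ratios from user-supplied denominators
#'
#' Registry coverage of the birth population needs external national
#' denominators (live births per stratum); this utility only computes the
#' ratios once those are supplied.
#'
#' @param records Named or plain numeric vector of registry record counts
#'   per stratum.
#' @param births Live-birth denominators, aligned with `records`.
#' @return A tibble with `stratum`, `records`, `births`, `coverage_pct`.
#' @export
coverage_ratio <- function(records, births) {
  if (length(records) != length(births)) stop_field("births", "length mismatch")
  if (any(births <= 0)) stop_field("births", "denominators must be positive")
  tibble::tibble(stratum = names(records) %||% as.character(seq_along(records)),
                 records = as.numeric(records), births = as.numeric(births),
                 coverage_pct = 100 * as.numeric(records) / as.numeric(births))
}
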