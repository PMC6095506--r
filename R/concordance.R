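#' Classify gold-versus-EPR value pairs under a tolerance rule
#'
#' Grades each pair as `agree`, `minor`, `major` or `not_comparable`.
#' A pair is `not_comparable` whenever either value is missing: infants
#' with missing data are excluded from discordancy calculations, never
#' counted as discordant. For banded kinds (`date`, `count`, `continuous`)
#' the grade is set by the absolute difference against the rule's
#' `agree_max` / `minor_max`; for `binary`, `categorical` and `set` kinds
#' any difference is major.
#'
#' @param gold,epr Paired value vectors (dates, numerics, characters or
#'   logicals, matching the rule's kind).
#' @param rule A single-row rule, e.g. one row of [default_rules()].
#' @return A factor with levels `agree`, `minor`, `major`,
#'   `not_comparable`.
#' @examples
#' rule <- dplyr::filter(default_rules(), variable == "central_line_days")
#' classify_agreement(c(10, 10, 10, 10), c(12, 13, 15, NA), rule)
#' @export
classify_agreement <- function(gold, epr, rule) {
  if (nrow(rule) != 1L) stop_field("rule", "expected exactly one rule row")
  if (length(gold) != length(epr)) stop_field("epr", "gold and epr lengths differ")
  lv <- c("agree", "minor", "major", "not_comparable")
  missing <- is.na(gold) | is.na(epr)
  out <- rep(NA_character_, length(gold))
  out[missing] <- "not_comparable"
  cmp <- !missing
  if (rule$kind %in% c("binary", "categorical", "set")) {
    same <- as.character(gold[cmp]) == as.character(epr[cmp])
    out[cmp] <- ifelse(same, "agree", "major")
  } else {
    if (!is.numeric(gold) && !inherits(gold, "Date")) {
      stop_field("gold", sprintf("rule kind '%s' needs numeric or Date values", rule$kind))
    }
    d <- abs(as.numeric(gold[cmp]) - as.numeric(epr[cmp]))
    out[cmp] <- ifelse(d <= rule$agree_max, "agree",
                       ifelse(d <= rule$minor_max, "minor", "major"))
  }
  factor(out, levels = lv)
}

#' Discordancy rate with its 95% confidence interval
#'
#' Computes the percentage of comparable pairs graded discordant, with the
#' interval method switched on the point estimate: rates below 5% use the
#' exact Poisson approximation to the binomial (the interval for the
#' discordant count, scaled by the comparable n); rates of 5% or more use
#' the Agresti–Coull interval, which has better coverage there.
#'
#' @param classes A classification factor from [classify_agreement()].
#' @param which `"any"` counts minor + major discordancies; `"major"`
#'   counts major only.
#' @param conf Confidence level.
#' @return A one-row tibble: `n_comparable`, `k`, `rate`, `lower`, `upper`
#'   (percentages), `ci_method`. With no comparable pairs the rate and
#'   bounds are `NA` and `ci_method` is `"undefined"`.
#' @examples
#' cls <- factor(rep(c("agree", "major"), c(1256, 2)),
#'               levels = c("agree", "minor", "major", "not_comparable"))
#' discordancy_rate(cls, "major")  # 0.2% (0.02-0.6), Poisson
#' @export
discordancy_rate <- function(classes, which = c("any", "major"), conf = 0.95) {
  which <- match.arg(which)
  tab <- table(factor(classes, levels = c("agree", "minor", "major", "not_comparable")))
  n <- sum(tab[c("agree", "minor", "major")])
  k <- if (which == "major") tab[["major"]] else tab[["minor"]] + tab[["major"]]
  if (n == 0L) {
    return(tibble::tibble(n_comparable = 0L, k = 0L, rate = NA_real_,
                          lower = NA_real_, upper = NA_real_, ci_method = "undefined"))
  }
  rate <- 100 * k / n
  if (rate < 5) {
    ci <- ci_poisson_exact(k, n, conf)
    method <- "poisson"
  } else {
    ci <- ci_agresti_coull(k, n, conf)
    method <- "agresti_coull"
  }
  tibble::tibble(n_comparable = as.integer(n), k = as.integer(k), rate = rate,
                 lower = 100 * ci$lower, upper = 100 * ci$upper, ci_method = method)
}

#' Per-variable concordance table from paired derived data
#'
#' Joins the gold and EPR derived tables on their keys and, for every rule
#' whose variable both tables carry, tallies missingness, grades the pairs
#' and computes any/major discordancy rates with intervals. This is the
#' engine behind [compare_cohorts()] and works on any pair of keyed wide
#' tables (infant-level or episode-level).
#'
#' @param gold_df,epr_df Wide tibbles with the same key columns and one
#'   column per compared variable.
#' @param rules Rule tibble, see [default_rules()].
#' @param by Key column names joining the two tables.
#' @param conf Confidence level for the intervals.
#' @return A tibble of class `neo_concordance`: one row per variable with
#'   `n_pairs`, `missing_gold`, `missing_epr`, `n_comparable`, `n_minor`,
#'   `n_major`, and any/major rates with bounds and method.
#' @export
concordance_table <- function(gold_df, epr_df, rules = default_rules(),
                              by = "infant_id", conf = 0.95) {
  validate_rules(rules)
  shared <- intersect(rules$variable, intersect(names(gold_df), names(epr_df)))
  rules <- dplyr::filter(rules, .data$variable %in% shared)
  paired <- dplyr::inner_join(
    dplyr::select(gold_df, dplyr::all_of(c(by, shared))),
    dplyr::select(epr_df, dplyr::all_of(c(by, shared))),
    by = by, suffix = c("_gold", "_epr"))
  out <- purrr::map(seq_len(nrow(rules)), function(i) {
    rule <- rules[i, ]
    g <- paired[[paste0(rule$variable, "_gold")]]
    e <- paired[[paste0(rule$variable, "_epr")]]
    cls <- classify_agreement(g, e, rule)
    any_row <- discordancy_rate(cls, "any", conf)
    maj_row <- discordancy_rate(cls, "major", conf)
    tibble::tibble(
      variable = rule$variable, level = rule$level, group = rule$group,
      n_pairs = length(g),
      missing_gold = sum(is.na(g)), missing_epr = sum(is.na(e)),
      n_comparable = any_row$n_comparable,
      n_minor = sum(cls == "minor"), n_major = sum(cls == "major"),
      any_rate = any_row$rate, any_lower = any_row$lower, any_upper = any_row$upper,
      any_ci_method = any_row$ci_method,
      major_rate = maj_row$rate, major_lower = maj_row$lower, major_upper = maj_row$upper,
      major_ci_method = maj_row$ci_method)
  })
  out <- dplyr::bind_rows(out)
  class(out) <- c("neo_concordance", class(out))
  out
}

#' Bland–Altman limits of agreement for paired continuous differences
#'
#' For continuous items the audit reports the mean and median of the
#' gold-minus-EPR differences and 95% limits of agreement, mean ± 1.96 SD.
#' Zero variance collapses the limits onto the mean (identical data is
#' perfect agreement, not an error).
#'
#' @param differences Numeric vector of paired differences; `NA`s dropped.
#' @return A one-row tibble: `n`, `mean_diff`, `median_diff`, `loa_lower`,
#'   `loa_upper`.
#' @examples
#' limits_of_agreement(c(-1, 0, 1))  # mean 0, limits -1.96, 1.96
#' @export
limits_of_agreement <- function(differences) {
  d <- differences[!is.na(differences)]
  if (length(d) < 3L) stop_field("differences", "need at least 3 non-missing pairs")
  m <- mean(d)
  s <- sd(d)
  tibble::tibble(n = length(d), mean_diff = m, median_diff = stats::median(d),
                 loa_lower = m - 1.96 * s, loa_upper = m + 1.96 * s)
}
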