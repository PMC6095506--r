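#' Tolerance-band rule table for the 44 compared items
#'
#' Each audited variable carries a preset rule saying how a gold-versus-EPR
#' value pair is graded. For binary, categorical and set-valued items any
#' difference is a major discordancy. For day-count and date items the
#' absolute difference is partitioned into agree / minor / major bands:
#'
#' * care-day counts and length of stay: within ±2 days agree, ±3–4 days
#'   minor, ±5 or more days major;
#' * expected date of delivery (EDD) and gestational age: within ±2 days
#'   agree, ±3–6 days minor, ≥7 days major;
#' * day of first milk: exact agree, ±1 day minor, ≥2 days major;
#' * antibiotic and antacid day counts: exact agree, ±1–2 days minor,
#'   more than 2 days major;
#' * birth weight: within 10 g agree, 11–100 g minor, >100 g major;
#' * 5-minute Apgar: exact agree, ±1 minor, ≥2 major.
#'
#' Bands are config-overridable: pass an edited copy of this tibble to
#' [compare_cohorts()], or round-trip it through [write_rules()] /
#' [read_rules()].
#'
#' @return A tibble with one row per compared item: `variable`, `level`
#'   (`"infant"` or `"episode"`), `group` (characteristic / process /
#'   process_14d / outcome), `kind` (`binary`, `categorical`, `set`,
#'   `date`, `count`, `continuous`), and numeric `agree_max` / `minor_max`
#'   (`NA` for kinds where any difference is major). A pair agrees when
#'   `|delta| <= agree_max`, is minor when `agree_max < |delta| <=
#'   minor_max`, else major.
#' @examples
#' default_rules()
#' @export
default_rules <- function() {
  r <- function(variable, level, group, kind, agree_max = NA_real_, minor_max = NA_real_) {
    tibble::tibble(variable = variable, level = level, group = group, kind = kind,
                   agree_max = agree_max, minor_max = minor_max)
  }
  dplyr::bind_rows(
    # 16 patient characteristics (infant level)
    r("edd",                 "infant", "characteristic", "date", 2, 6),
    r("ga_days",             "infant", "characteristic", "count", 2, 6),
    r("month_of_birth",      "infant", "characteristic", "categorical"),
    r("year_of_birth",       "infant", "characteristic", "categorical"),
    r("birth_weight",        "infant", "characteristic", "continuous", 10, 100),
    r("sex",                 "infant", "characteristic", "categorical"),
    r("apgar5",              "infant", "characteristic", "count", 0, 1),
    r("born_here",           "infant", "characteristic", "binary"),
    r("multiple",            "infant", "characteristic", "categorical"),
    r("birth_order",         "infant", "characteristic", "categorical"),
    r("maternal_yob",        "infant", "characteristic", "categorical"),
    r("maternal_ethnicity",  "infant", "characteristic", "categorical"),
    r("maternal_lsoa",       "infant", "characteristic", "categorical"),
    r("antenatal_steroids",  "infant", "characteristic", "binary"),
    r("delivery_mode",       "infant", "characteristic", "categorical"),
    r("instrumental",        "infant", "characteristic", "binary"),
    # 17 processes: 7 episode-level, 3 infant-level, 7 in the first 14 days
    r("intensive_days",       "episode", "process", "count", 2, 4),
    r("high_dependency_days", "episode", "process", "count", 2, 4),
    r("central_line_days",    "episode", "process", "count", 2, 4),
    r("length_of_stay",       "episode", "process", "count", 2, 4),
    r("transfer_out",         "episode", "process", "binary"),
    r("discharge_month",      "episode", "process", "categorical"),
    r("discharge_year",       "episode", "process", "categorical"),
    r("pda_surgery",          "infant", "process", "binary"),
    r("pda_medical",          "infant", "process", "binary"),
    r("rop_treatment",        "infant", "process", "binary"),
    r("day_of_first_milk",    "infant", "process_14d", "count", 0, 1),
    r("first_milk_types",     "infant", "process_14d", "set"),
    r("milk_summary_14d",     "infant", "process_14d", "set"),
    r("antibiotics_any_14d",  "infant", "process_14d", "binary"),
    r("antibiotic_days_14d",  "infant", "process_14d", "count", 0, 2),
    r("antacid_any_14d",      "infant", "process_14d", "binary"),
    r("antacid_days_14d",     "infant", "process_14d", "count", 0, 2),
    # 11 clinical outcomes (infant level)
    r("rop_worst_stage",      "infant", "outcome", "categorical"),
    r("oxygen_at_36w",        "infant", "outcome", "binary"),
    r("mech_support_at_36w",  "infant", "outcome", "binary"),
    r("nec_perforation",      "infant", "outcome", "binary"),
    r("gi_perforation",       "infant", "outcome", "binary"),
    r("nec_surgery",          "infant", "outcome", "binary"),
    r("hpi",                  "infant", "outcome", "binary"),
    r("hydrocephalus",        "infant", "outcome", "binary"),
    r("pvl",                  "infant", "outcome", "binary"),
    r("porencephalic_cyst",   "infant", "outcome", "binary"),
    r("survival",             "infant", "outcome", "binary")
  )
}

#' Read or write a rule table as CSV
#'
#' @param rules A rule tibble as returned by [default_rules()].
#' @param path File path.
#' @return `read_rules()` returns a validated rule tibble; `write_rules()`
#'   returns `path` invisibly.
#' @export
write_rules <- function(rules, path) {
  validate_rules(rules)
  readr::write_csv(rules, path)
  invisible(path)
}

#' @rdname write_rules
#' @export
read_rules <- function(path) {
  rules <- readr::read_csv(path, show_col_types = FALSE,
                           col_types = readr::cols(
                             variable = "c", level = "c", group = "c", kind = "c",
                             agree_max = "d", minor_max = "d"))
  validate_rules(rules)
  rules
}

validate_rules <- function(rules) {
  need <- c("variable", "level", "group", "kind", "agree_max", "minor_max")
  if (!all(need %in% names(rules))) {
    stop_field("rules", paste("missing columns:",
                              paste(setdiff(need, names(rules)), collapse = ", ")))
  }
  if (anyDuplicated(rules$variable)) stop_field("rules", "duplicate variable names")
  if (!all(rules$level %in% c("infant", "episode"))) stop_field("level", "must be infant or episode")
  kinds <- c("binary", "categorical", "set", "date", "count", "continuous")
  if (!all(rules$kind %in% kinds)) stop_field("kind", paste("must be one of", paste(kinds, collapse = ", ")))
  banded <- rules$kind %in% c("date", "count", "continuous")
  if (any(banded & (is.na(rules$agree_max) | is.na(rules$minor_max)))) {
    stop_field("agree_max/minor_max", "required for date, count and continuous kinds")
  }
  if (any(banded & rules$minor_max < rules$agree_max)) {
    stop_field("minor_max", "must be >= agree_max")
  }
  invisible(rules)
}
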