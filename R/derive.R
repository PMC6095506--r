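#' Gestational age from expected date of delivery
#'
#' The gold database captures the expected date of delivery (EDD, the
#' 40-week date) and derives gestational age at birth from it:
#' `GA = 280 - (edd - birth_date)` days, reported as completed weeks plus
#' remainder days.
#'
#' @param edd,birth_date Date vectors of equal length.
#' @return A tibble with `weeks`, `days` (0–6) and `total_days`.
#' @examples
#' gestational_age(as.Date("2011-03-22"), as.Date("2011-01-11"))  # 30+0
#' @export
gestational_age <- function(edd, birth_date) {
  if (length(edd) != length(birth_date)) stop_field("birth_date", "length mismatch with edd")
  total <- 280L - as.integer(edd - birth_date)
  bad <- !is.na(total) & (total < 140L | total > 322L)
  if (any(bad)) {
    stop_field("edd", sprintf("implied gestational age out of range (20-46 weeks) at position %d",
                              which(bad)[1]))
  }
  tibble::tibble(weeks = total %/% 7L, days = total %% 7L, total_days = total)
}

#' Daily care-level categorisation rule
#'
#' The registry's point-of-care system categorises each care day from raw
#' daily data with unpublished embedded logic; the audit only compares day
#' counts per category, so what matters is that one explicit rule is
#' applied identically to both databases. The default rule: mechanical
#' respiratory support implies intensive care; otherwise supplementary
#' oxygen or a central line implies (at least) high dependency; otherwise
#' special care. Pass any function with the same signature to the deriving
#' functions to use a different rule set.
#'
#' @param daily A daily-record tibble with logical columns `mech_support`,
#'   `oxygen`, `central_line`.
#' @return A character vector (`"intensive"`, `"high_dependency"`,
#'   `"special"`) aligned with the rows of `daily`.
#' @export
default_care_rule <- function(daily) {
  dplyr::case_when(
    daily$mech_support ~ "intensive",
    daily$oxygen | daily$central_line ~ "high_dependency",
    TRUE ~ "special")
}

#' Count qualifying care days
#'
#' Counts, per infant, the non-missing daily records where a condition
#' holds, optionally restricted to a postnatal-day window (postnatal day 1
#' is the date of birth). Missing daily records never count as
#' qualifying — absence of a record is not evidence of absence of care.
#'
#' @param daily Daily-record tibble (`infant_id`, `date`, flag columns,
#'   logical `missing`).
#' @param condition A predicate on the daily columns, tidy-evaluated, e.g.
#'   `antibiotics` or `central_line & !oxygen`.
#' @param window Optional `c(first, last)` postnatal-day window, inclusive;
#'   requires `infants`.
#' @param infants Infant tibble with `infant_id` and `birth_date`, needed
#'   when `window` is given.
#' @return A tibble `infant_id`, `n_days` covering every infant in
#'   `daily` (zero when no day qualifies).
#' @examples
#' daily <- tibble::tibble(infant_id = "a", date = as.Date("2020-01-01") + 0:13,
#'                         antibiotics = rep(c(TRUE, FALSE), c(5, 9)),
#'                         missing = FALSE)
#' count_days(daily, antibiotics)
#' @export
count_days <- function(daily, condition, window = NULL, infants = NULL) {
  cond <- rlang::enquo(condition)
  d <- daily
  if (!is.null(window)) {
    if (is.null(infants)) stop_field("infants", "required when a postnatal window is given")
    d <- dplyr::inner_join(d, dplyr::select(infants, "infant_id", "birth_date"),
                           by = "infant_id")
    d <- dplyr::mutate(d, .pnd = as.integer(.data$date - .data$birth_date) + 1L)
    d <- dplyr::filter(d, .data$.pnd >= window[1], .data$.pnd <= window[2])
  }
  counts <- d |>
    dplyr::filter(!.data$missing) |>
    dplyr::filter(!!cond) |>
    dplyr::count(.data$infant_id, name = "n_days")
  tibble::tibble(infant_id = unique(daily$infant_id)) |>
    dplyr::left_join(counts, by = "infant_id") |>
    dplyr::mutate(n_days = dplyr::coalesce(.data$n_days, 0L))
}

#' Episode-level derived variables
#'
#' Computes, for each episode of care, the compared process variables:
#' intensive and high-dependency care days (via the care-level rule),
#' central-line days, length of stay (admission to discharge inclusive),
#' whether the episode ended in transfer to another hospital, and the
#' discharge month and year. Day counts only include non-missing daily
#' records, so each count is at most the length of stay.
#'
#' @param cohort A cohort list with `episodes` and `daily` tibbles (see
#'   [generate_cohort()] for the schema).
#' @param care_rule A care-level rule function, see [default_care_rule()].
#' @return A tibble keyed by (`infant_id`, `episode`) with the derived
#'   columns above plus `unit_id` and the episode outcome flags.
#' @export
derive_episodes <- function(cohort, care_rule = default_care_rule) {
  daily <- cohort$daily
  daily$care_level <- care_rule(daily)
  day_counts <- daily |>
    dplyr::filter(!.data$missing) |>
    dplyr::group_by(.data$infant_id, .data$episode) |>
    dplyr::summarise(
      intensive_days = sum(.data$care_level == "intensive"),
      high_dependency_days = sum(.data$care_level == "high_dependency"),
      central_line_days = sum(.data$central_line),
      .groups = "drop")
  cohort$episodes |>
    dplyr::left_join(day_counts, by = c("infant_id", "episode")) |>
    dplyr::mutate(
      dplyr::across(dplyr::ends_with("_days"), ~ dplyr::coalesce(.x, 0L)),
      length_of_stay = as.integer(.data$discharge_date - .data$admission_date) + 1L,
      discharge_month = as.integer(format(.data$discharge_date, "%m")),
      discharge_year = as.integer(format(.data$discharge_date, "%Y"))) |>
    dplyr::select("infant_id", "episode", "unit_id", "admission_date",
                  "intensive_days", "high_dependency_days", "central_line_days",
                  "length_of_stay", "transfer_out", "discharge_month",
                  "discharge_year", dplyr::any_of(c("pda_surgery", "pda_medical",
                                                    "rop_treatment", "discharge_alive")))
}

#' Respiratory status at 36 weeks postmenstrual age
#'
#' Bronchopulmonary dysplasia is operationalised as supplementary oxygen on
#' the day the infant reaches 36 weeks postmenstrual age; mechanical
#' respiratory support on that day is reported alongside. The assessment
#' day is computed from the EDD (`edd - 28` days), avoiding the truncation
#' error of rounding to completed weeks. An infant discharged home or dead
#' before that day is not assessable (`not_in_care`); an infant in care
#' whose daily record for that day is absent or flagged missing gets the
#' distinct status `missing_record`. The default denominator policy counts
#' infants in care on the assessment day; `"any_record"` instead requires a
#' usable daily record.
#'
#' @param infants,episodes,daily Cohort tables (see [generate_cohort()]).
#' @param policy Denominator policy, `"in_care"` (default) or
#'   `"any_record"`.
#' @return A tibble per infant: `pma36_date`, `pma36_status`
#'   (`assessed` / `not_in_care` / `missing_record`), logical
#'   `oxygen_at_36w` and `mech_support_at_36w` (`NA` unless assessed).
#' @export
pma36_status <- function(infants, episodes, daily, policy = c("in_care", "any_record")) {
  policy <- match.arg(policy)
  base <- infants |>
    dplyr::select("infant_id", "edd") |>
    dplyr::mutate(pma36_date = .data$edd - 28L)
  in_care <- episodes |>
    dplyr::inner_join(base, by = "infant_id") |>
    dplyr::filter(.data$admission_date <= .data$pma36_date,
                  .data$discharge_date >= .data$pma36_date) |>
    dplyr::distinct(.data$infant_id) |>
    dplyr::mutate(in_care = TRUE)
  day_rec <- daily |>
    dplyr::inner_join(base, by = "infant_id") |>
    dplyr::filter(.data$date == .data$pma36_date) |>
    dplyr::select("infant_id", "oxygen", "mech_support", "missing")
  out <- base |>
    dplyr::left_join(in_care, by = "infant_id") |>
    dplyr::left_join(day_rec, by = "infant_id") |>
    dplyr::mutate(
      in_care = dplyr::coalesce(.data$in_care, FALSE),
      usable = !is.na(.data$missing) & !.data$missing,
      pma36_status = dplyr::case_when(
        !.data$in_care & policy == "in_care" ~ "not_in_care",
        policy == "any_record" & !.data$usable ~
          ifelse(.data$in_care, "missing_record", "not_in_care"),
        .data$in_care & !.data$usable ~ "missing_record",
        TRUE ~ "assessed"),
      oxygen_at_36w = ifelse(.data$pma36_status == "assessed", .data$oxygen, NA),
      mech_support_at_36w = ifelse(.data$pma36_status == "assessed", .data$mech_support, NA))
  dplyr::select(out, "infant_id", "pma36_date", "pma36_status",
                "oxygen_at_36w", "mech_support_at_36w")
}

#' Feeding profile over the first 14 postnatal days
#'
#' Derives, per infant, the postnatal day of the first milk feed, the set
#' of milk types given on that day, and the summary set of milk types
#' (mother's breast milk, human donor milk, formula) over the window.
#' Postnatal day 1 is the date of birth; the window is days 1–14
#' inclusive. First-feed fields are only comparable when no missing daily
#' record precedes the first observed feed (an earlier unrecorded feed
#' cannot be ruled out); infants with no observed feed in the window are
#' excluded from the first-feed comparison. The 14-day summary is the
#' union over non-missing days and is only undefined when the whole window
#' is missing.
#'
#' @param infants Infant tibble with `birth_date`.
#' @param daily Daily-record tibble.
#' @param window Postnatal-day window, default `c(1, 14)`.
#' @return A tibble per infant: `day_of_first_milk`, `first_milk_types`
#'   (canonical `+`-joined string, e.g. `"MBM+formula"`),
#'   `first_feed_status` (`ok` / `no_feed` / `masked`), `milk_summary_14d`
#'   and `milk_summary_status` (`ok` / `all_missing`).
#' @export
milk_profile <- function(infants, daily, window = c(1, 14)) {
  d <- daily |>
    dplyr::inner_join(dplyr::select(infants, "infant_id", "birth_date"), by = "infant_id") |>
    dplyr::mutate(pnd = as.integer(.data$date - .data$birth_date) + 1L) |>
    dplyr::filter(.data$pnd >= window[1], .data$pnd <= window[2]) |>
    dplyr::mutate(fed = !.data$missing & (.data$mbm | .data$hdm | .data$formula))
  prof <- d |>
    dplyr::group_by(.data$infant_id) |>
    dplyr::summarise(
      first_day = if (any(fed)) min(pnd[fed]) else NA_integer_,
      masked = !is.na(first_day) && any(missing & pnd < first_day),
      first_types = if (is.na(first_day)) NA_character_ else
        milk_set(any(mbm[pnd == first_day] & !missing[pnd == first_day]),
                 any(hdm[pnd == first_day] & !missing[pnd == first_day]),
                 any(formula[pnd == first_day] & !missing[pnd == first_day])),
      n_observed = sum(!missing),
      summary_14d = milk_set(any(mbm & !missing), any(hdm & !missing),
                             any(formula & !missing)),
      .groups = "drop")
  tibble::tibble(infant_id = unique(daily$infant_id)) |>
    dplyr::left_join(prof, by = "infant_id") |>
    dplyr::mutate(
      n_observed = dplyr::coalesce(.data$n_observed, 0L),
      first_feed_status = dplyr::case_when(
        is.na(.data$first_day) ~ "no_feed",
        .data$masked ~ "masked",
        TRUE ~ "ok"),
      day_of_first_milk = ifelse(.data$first_feed_status == "ok",
                                 .data$first_day, NA_integer_),
      first_milk_types = ifelse(.data$first_feed_status == "ok",
                                .data$first_types, NA_character_),
      milk_summary_status = ifelse(.data$n_observed == 0L, "all_missing", "ok"),
      milk_summary_14d = ifelse(.data$milk_summary_status == "ok",
                                .data$summary_14d, NA_character_)) |>
    dplyr::select("infant_id", "day_of_first_milk", "first_milk_types",
                  "first_feed_status", "milk_summary_14d", "milk_summary_status")
}

#' Combine episode-level values to infant level
#'
#' The audit is run both per episode and per infant over the whole
#' hospitalisation; infant-level values combine the episode values: binary
#' items by any-true, day counts by sum, ordinal worst-grade items by
#' maximum, and survival by the final episode's discharge-alive flag (a
#' death followed by a further episode is a data error).
#'
#' @param values Episode-level vector, ordered by episode.
#' @param combiner One of `"any"`, `"sum"`, `"max"`, `"last"`,
#'   `"survival"`.
#' @return A length-one infant-level value.
#' @examples
#' infant_composite(c(10, 25, 7), "sum")   # total length of stay 42
#' infant_composite(c(1, 3, 2), "max")     # worst grade 3
#' @export
infant_composite <- function(values, combiner = c("any", "sum", "max", "last", "survival")) {
  combiner <- match.arg(combiner)
  if (length(values) == 0L) stop_field("values", "need at least one episode")
  switch(combiner,
    any = any(values, na.rm = TRUE),
    sum = sum(values, na.rm = TRUE),
    max = if (all(is.na(values))) NA else max(values, na.rm = TRUE),
    last = values[length(values)],
    survival = {
      if (any(!values[-length(values)], na.rm = TRUE)) {
        stop_field("values", "death recorded before the final episode")
      }
      values[length(values)]
    })
}

#' Infant-level derived table
#'
#' Assembles the full infant-level comparison table: characteristics taken
#' or computed from the infant records (gestational age in days is derived
#' from EDD and birth date when both are present, else from the recorded
#' weeks + days), episode composites (PDA surgery and medical treatment,
#' ROP treatment, total length of stay, survival to final discharge),
#' feeding and medication profiles over the first 14 postnatal days, and
#' respiratory status at 36 weeks postmenstrual age.
#'
#' @param cohort A cohort list (`infants`, `episodes`, `daily`).
#' @param care_rule Care-level rule function.
#' @param pma_policy Denominator policy for the 36-week assessment, see
#'   [pma36_status()].
#' @return A wide tibble keyed by `infant_id`, one column per compared
#'   variable (see [default_rules()] for the list).
#' @export
derive_infants <- function(cohort, care_rule = default_care_rule,
                           pma_policy = "in_care") {
  infants <- cohort$infants
  episodes <- dplyr::arrange(cohort$episodes, .data$infant_id, .data$episode)

  chars <- infants |>
    dplyr::mutate(
      ga_days = ifelse(!is.na(.data$edd) & !is.na(.data$birth_date),
                       280L - as.integer(.data$edd - .data$birth_date),
                       .data$ga_weeks * 7L + .data$ga_extra_days),
      month_of_birth = as.integer(format(.data$birth_date, "%m")),
      year_of_birth = as.integer(format(.data$birth_date, "%Y"))) |>
    dplyr::select("infant_id", "centre_id", "edd", "birth_date", "ga_days",
                  "month_of_birth", "year_of_birth", "birth_weight", "sex",
                  "apgar5", "born_here", "multiple", "birth_order",
                  "maternal_yob", "maternal_ethnicity", "maternal_lsoa",
                  "antenatal_steroids", "delivery_mode", "instrumental",
                  "rop_worst_stage", "nec_perforation", "gi_perforation",
                  "nec_surgery", "hpi", "hydrocephalus", "pvl",
                  "porencephalic_cyst")

  comp <- episodes |>
    dplyr::group_by(.data$infant_id) |>
    dplyr::summarise(
      pda_surgery = infant_composite(.data$pda_surgery, "any"),
      pda_medical = infant_composite(.data$pda_medical, "any"),
      rop_treatment = infant_composite(.data$rop_treatment, "any"),
      length_of_stay_total = sum(as.integer(.data$discharge_date - .data$admission_date) + 1L),
      survival = infant_composite(.data$discharge_alive, "survival"),
      .groups = "drop")

  abx <- count_days(cohort$daily, .data$antibiotics, window = c(1, 14), infants = infants) |>
    dplyr::rename(antibiotic_days_14d = "n_days")
  antacid <- count_days(cohort$daily, .data$antacid, window = c(1, 14), infants = infants) |>
    dplyr::rename(antacid_days_14d = "n_days")
  window_obs <- count_days(cohort$daily, TRUE, window = c(1, 14), infants = infants) |>
    dplyr::rename(n_window_obs = "n_days")
  milk <- milk_profile(infants, cohort$daily)
  pma <- pma36_status(infants, episodes, cohort$daily, policy = pma_policy)

  chars |>
    dplyr::left_join(comp, by = "infant_id") |>
    dplyr::left_join(abx, by = "infant_id") |>
    dplyr::left_join(antacid, by = "infant_id") |>
    dplyr::left_join(window_obs, by = "infant_id") |>
    dplyr::mutate(
      # a whole-window gap leaves the medication items undefined, not zero
      antibiotic_days_14d = ifelse(.data$n_window_obs > 0L,
                                   .data$antibiotic_days_14d, NA_integer_),
      antacid_days_14d = ifelse(.data$n_window_obs > 0L,
                                .data$antacid_days_14d, NA_integer_),
      antibiotics_any_14d = .data$antibiotic_days_14d > 0L,
      antacid_any_14d = .data$antacid_days_14d > 0L) |>
    dplyr::select(-"n_window_obs") |>
    dplyr::left_join(milk, by = "infant_id") |>
    dplyr::left_join(dplyr::select(pma, -"pma36_date"), by = "infant_id")
}
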