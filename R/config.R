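#' Default outcome prevalences for the synthetic cohort
#'
#' Infant-level prevalences of the binary processes and outcomes used by
#' [generate_cohort()], chosen to match a very preterm multi-centre trial
#' cohort: survival to discharge 92.1%, bronchopulmonary dysplasia (oxygen
#' at 36 weeks postmenstrual age) 49.0% of assessable infants, mechanical
#' support at 36 weeks 24.4%, medical PDA treatment 20.3%, and rarer
#' surgical and cranial-ultrasound outcomes between 1.9% and 5.8%.
#'
#' @return A named numeric vector of probabilities.
#' @export
default_prevalences <- function() {
  c(pda_surgery = 0.048, pda_medical = 0.203, rop_treatment = 0.033,
    oxygen_at_36w = 0.490, mech_support_at_36w = 0.244,
    nec_perforation = 0.034, gi_perforation = 0.044, nec_surgery = 0.058,
    hpi = 0.042, hydrocephalus = 0.019, porencephalic_cyst = 0.031,
    pvl = 0.032, survival = 0.921)
}

#' Configuration for the synthetic gold cohort
#'
#' Describes the cohort the simulator emulates: a very preterm cohort
#' recruited across multiple neonatal units, with 1–4 episodes of care per
#' infant (transfers between hospitals, return transfers allowed), daily
#' care records from birth to final discharge, and binary outcomes at
#' configurable prevalences. Defaults follow a realistic multi-centre
#' trial: 1310 infants, 24 units, gestational ages 23+0 to 31+6 completed
#' weeks, and a transfer probability giving about 1.8 episodes per infant.
#'
#' @param n_infants Number of infants (>= 1).
#' @param n_units Number of neonatal units.
#' @param transfer_prob Per-episode probability of onward transfer; the
#'   episode count is 1 + a geometric draw, truncated at 4 episodes.
#' @param ga_range Completed-weeks gestational-age range, within 22–44.
#' @param outcome_prevalences Named probabilities overriding (a subset of)
#'   [default_prevalences()].
#' @param recruitment_start First possible birth date.
#' @param recruitment_months Length of the recruitment window in months.
#' @param seed Integer seed; recorded in the cohort metadata so any run
#'   can be reproduced exactly.
#' @return An object of class `cohort_config`.
#' @examples
#' cohort_config(n_infants = 100, seed = 1)
#' @export
cohort_config <- function(n_infants = 1310, n_units = 24, transfer_prob = 0.47,
                          ga_range = c(23, 31),
                          outcome_prevalences = default_prevalences(),
                          recruitment_start = as.Date("2010-07-01"),
                          recruitment_months = 37, seed = NULL) {
  if (!is.numeric(n_infants) || length(n_infants) != 1 || is.na(n_infants) || n_infants < 1) {
    stop_field("n_infants", "must be a single integer >= 1")
  }
  if (!is.numeric(n_units) || length(n_units) != 1 || n_units < 1) {
    stop_field("n_units", "must be a single integer >= 1")
  }
  if (!is_prob(transfer_prob) || length(transfer_prob) != 1) {
    stop_field("transfer_prob", "must be a probability in [0, 1]")
  }
  if (length(ga_range) != 2 || any(ga_range < 22) || any(ga_range > 44) ||
      ga_range[1] > ga_range[2]) {
    stop_field("ga_range", "must be an increasing completed-weeks interval within [22, 44]")
  }
  prev <- default_prevalences()
  if (length(outcome_prevalences)) {
    unknown <- setdiff(names(outcome_prevalences), names(prev))
    if (length(unknown)) {
      stop_field("outcome_prevalences", paste("unknown outcome:", paste(unknown, collapse = ", ")))
    }
    if (!is_prob(outcome_prevalences)) {
      stop_field("outcome_prevalences", "must be probabilities in [0, 1]")
    }
    prev[names(outcome_prevalences)] <- outcome_prevalences
  }
  structure(list(n_infants = as.integer(n_infants), n_units = as.integer(n_units),
                 transfer_prob = transfer_prob, ga_range = as.integer(ga_range),
                 outcome_prevalences = prev,
                 recruitment_start = as.Date(recruitment_start),
                 recruitment_months = as.integer(recruitment_months),
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "cohort_config")
}

# variable sets the error model may touch
misclassifiable_vars <- function() {
  c("sex", "born_here", "multiple", "antenatal_steroids", "delivery_mode",
    "instrumental", "maternal_ethnicity", "maternal_lsoa", "maternal_yob",
    "rop_worst_stage", "nec_perforation", "gi_perforation", "nec_surgery",
    "hpi", "hydrocephalus", "pvl", "porencephalic_cyst", "survival",
    "pda_surgery", "pda_medical", "rop_treatment",
    "oxygen_at_36w", "mech_support_at_36w",
    "first_milk_types", "milk_summary_14d")
}

jitterable_vars <- function() {
  c("edd", "day_of_first_milk", "central_line_days", "antibiotic_days_14d",
    "antacid_days_14d", "length_of_stay", "intensive_days")
}

missable_vars <- function() {
  c("edd", "ga", "birth_weight", "sex", "apgar5", "born_here", "multiple",
    "birth_order", "maternal_yob", "maternal_ethnicity", "maternal_lsoa",
    "antenatal_steroids", "delivery_mode", "instrumental",
    "rop_worst_stage", "nec_perforation", "gi_perforation", "nec_surgery",
    "hpi", "hydrocephalus", "pvl", "porencephalic_cyst", "daily")
}

#' Error model for the EPR registry twin
#'
#' Specifies the perturbations [make_epr_twin()] injects into a copy of
#' the gold cohort, each logged per cell in the truth log so the pipeline's
#' estimates can be checked against known injection rates:
#'
#' * `missing_prob` — per-variable (optionally per-centre) probability of
#'   blanking a value; the special variable `"daily"` instead flags one
#'   random daily record in the first 14 postnatal days as missing.
#' * `misclass_prob` — per-variable probability of a categorical swap or
#'   binary flip.
#' * `day_jitter` — per-variable distribution over integer day offsets;
#'   for day-count variables the underlying daily grid is edited so that
#'   the derived count moves by the offset, for `edd` and
#'   `length_of_stay` the stored dates shift.
#' * `linkage_failure_prob` — probability an infant's registry identifier
#'   cannot be supplied, leaving the infant unlinkable.
#' * `episode_drop_prob` — probability an episode is absent from the
#'   registry extract.
#'
#' @param missing_prob Named numeric vector (variable -> probability) or a
#'   tibble with columns `variable`, `centre_id`, `prob`.
#' @param misclass_prob Named numeric vector (variable -> probability).
#' @param day_jitter Named list; each element a numeric distribution whose
#'   names are integer offsets and whose values sum to 1.
#' @param linkage_failure_prob,episode_drop_prob Single probabilities.
#' @return An object of class `error_model`. `zero_error_model()` is the
#'   identity model: the twin equals the gold cohort on every compared
#'   variable.
#' @examples
#' error_model(misclass_prob = c(hydrocephalus = 0.05),
#'             day_jitter = list(central_line_days = c(`0` = 0.9, `5` = 0.1)))
#' @export
error_model <- function(missing_prob = NULL, misclass_prob = NULL, day_jitter = NULL,
                        linkage_failure_prob = 0, episode_drop_prob = 0) {
  if (!is.null(missing_prob)) {
    if (is.data.frame(missing_prob)) {
      need <- c("variable", "centre_id", "prob")
      if (!all(need %in% names(missing_prob))) {
        stop_field("missing_prob", "tibble form needs columns variable, centre_id, prob")
      }
      vars <- unique(missing_prob$variable)
      if (!is_prob(missing_prob$prob)) stop_field("missing_prob", "probabilities must lie in [0, 1]")
    } else {
      vars <- names(missing_prob)
      if (is.null(vars) || !is_prob(missing_prob)) {
        stop_field("missing_prob", "must be a named vector of probabilities")
      }
    }
    unknown <- setdiff(vars, missable_vars())
    if (length(unknown)) {
      stop_field("missing_prob", paste("unknown variable:", paste(unknown, collapse = ", ")))
    }
  }
  if (!is.null(misclass_prob)) {
    if (is.null(names(misclass_prob)) || !is_prob(misclass_prob)) {
      stop_field("misclass_prob", "must be a named vector of probabilities")
    }
    unknown <- setdiff(names(misclass_prob), misclassifiable_vars())
    if (length(unknown)) {
      stop_field("misclass_prob", paste("unknown variable:", paste(unknown, collapse = ", ")))
    }
  }
  if (!is.null(day_jitter)) {
    unknown <- setdiff(names(day_jitter), jitterable_vars())
    if (length(unknown)) {
      stop_field("day_jitter", paste("unknown variable:", paste(unknown, collapse = ", ")))
    }
    for (v in names(day_jitter)) {
      d <- day_jitter[[v]]
      offs <- suppressWarnings(as.integer(names(d)))
      if (any(is.na(offs)) || !is.numeric(d) || any(d < 0) || abs(sum(d) - 1) > 1e-8) {
        stop_field("day_jitter", sprintf("distribution for '%s' must have integer offsets and sum to 1", v))
      }
    }
  }
  if (!is_prob(linkage_failure_prob) || length(linkage_failure_prob) != 1) {
    stop_field("linkage_failure_prob", "must be a probability in [0, 1]")
  }
  if (!is_prob(episode_drop_prob) || length(episode_drop_prob) != 1) {
    stop_field("episode_drop_prob", "must be a probability in [0, 1]")
  }
  structure(list(missing_prob = missing_prob, misclass_prob = misclass_prob,
                 day_jitter = day_jitter, linkage_failure_prob = linkage_failure_prob,
                 episode_drop_prob = episode_drop_prob),
            class = "error_model")
}

#' @rdname error_model
#' @export
zero_error_model <- function() error_model()
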