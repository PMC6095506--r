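#' Write or read a cohort as plain CSV tables
#'
#' A cohort is stored as three CSVs (`infants.csv`, `episodes.csv`,
#' `daily.csv`, ISO-8601 dates, UTF-8) plus a JSON sidecar with the
#' generating configuration and seed. Registry twins additionally store
#' `id_map.csv` and `truth_log.csv`.
#'
#' @param cohort A `neo_cohort` or `neo_epr` list.
#' @param dir Directory to write into (created if needed).
#' @return `write_cohort()` returns `dir` invisibly; `read_cohort()`
#'   returns the cohort list.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(cohort$infants, file.path(dir, "infants.csv"))
  readr::write_csv(cohort$episodes, file.path(dir, "episodes.csv"))
  readr::write_csv(cohort$daily, file.path(dir, "daily.csv"))
  if (!is.null(cohort$id_map)) readr::write_csv(cohort$id_map, file.path(dir, "id_map.csv"))
  if (!is.null(cohort$truth_log)) {
    readr::write_csv(cohort$truth_log, file.path(dir, "truth_log.csv"))
  }
  meta <- list(class = class(cohort)[1],
               seed = cohort$config$seed,
               config = unclass(cohort$config))
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       null = "null", Date = "ISO8601")
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  rd <- function(f) readr::read_csv(file.path(dir, f), show_col_types = FALSE)
  out <- list(infants = rd("infants.csv"), episodes = rd("episodes.csv"),
              daily = rd("daily.csv"))
  meta_path <- file.path(dir, "meta.json")
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path)
    cfg <- meta$config
    if (!is.null(cfg)) {
      out$config <- cohort_config(
        n_infants = cfg$n_infants, n_units = cfg$n_units,
        transfer_prob = cfg$transfer_prob, ga_range = unlist(cfg$ga_range),
        outcome_prevalences = unlist(cfg$outcome_prevalences),
        recruitment_start = as.Date(cfg$recruitment_start),
        recruitment_months = cfg$recruitment_months, seed = cfg$seed)
    }
    cls <- meta$class %||% "neo_cohort"
  } else {
    cls <- "neo_cohort"
  }
  if (file.exists(file.path(dir, "id_map.csv"))) {
    out$id_map <- rd("id_map.csv")
    cls <- "neo_epr"
  }
  if (file.exists(file.path(dir, "truth_log.csv"))) out$truth_log <- rd("truth_log.csv")
  class(out) <- cls
  out
}

#' Configuration for a full validation run
#'
#' Exactly one data source must be given: either a `simulate` block (a
#' [cohort_config()] plus an [error_model()]) or `inputs` pointing at
#' previously written gold and registry cohort directories.
#'
#' @param simulate `list(cohort = cohort_config(), error = error_model())`.
#' @param inputs `list(gold = <dir>, epr = <dir>)`.
#' @param rules Tolerance rule tibble.
#' @param out_dir Output directory for the report bundle.
#' @param seed Integer seed governing all randomness of the run.
#' @param admission_tolerance Episode-matching tolerance in days.
#' @return An object of class `run_config`.
#' @export
run_config <- function(simulate = NULL, inputs = NULL, rules = default_rules(),
                       out_dir = tempfile("neovalid_run_"), seed = 1,
                       admission_tolerance = 1) {
  if (is.null(simulate) == is.null(inputs)) {
    stop_field("simulate/inputs", "exactly one data source must be given")
  }
  if (!is.null(simulate)) {
    if (!inherits(simulate$cohort, "cohort_config")) {
      stop_field("simulate", "needs a $cohort cohort_config")
    }
    if (!inherits(simulate$error %||% zero_error_model(), "error_model")) {
      stop_field("simulate", "$error must be an error_model")
    }
    simulate$error <- simulate$error %||% zero_error_model()
  }
  validate_rules(rules)
  structure(list(simulate = simulate, inputs = inputs, rules = rules,
                 out_dir = out_dir, seed = as.integer(seed),
                 admission_tolerance = admission_tolerance),
            class = "run_config")
}

#' Run the full validation pipeline
#'
#' Orchestrates simulate (or load) -> link -> derive -> compare -> report.
#' The report bundle written to `config$out_dir` mirrors the audit's
#' published table shapes: the linkage/exclusion audit, infant- and
#' episode-level concordance tables with intervals, the
#' diagnostic-accuracy table, completeness by year of birth with the
#' under-32-weeks subgroup, per-centre missingness for the least complete
#' characteristics, a plain-text summary, and a `metadata.json` carrying
#' the seed and a hash of the configuration. The run is deterministic
#' given the seed; on failure, partial outputs are removed.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list of class `neo_report` with the in-memory
#'   results (`linked`, `comparison`, `accuracy`, `completeness`,
#'   `centre_missing`, `paths`).
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) stop_field("config", "must be a run_config")
  set.seed(config$seed)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  emit <- function(df, name) {
    path <- file.path(config$out_dir, name)
    readr::write_csv(df, path)
    written <<- c(written, path)
    path
  }
  tryCatch({
    if (!is.null(config$simulate)) {
      gold <- generate_cohort(config$simulate$cohort)
      epr <- make_epr_twin(gold, config$simulate$error,
                           seed = config$seed + 1L)
    } else {
      gold <- read_cohort(config$inputs$gold)
      epr <- read_cohort(config$inputs$epr)
    }
    linked <- link_infants(gold, epr, config$admission_tolerance)
    comparison <- compare_cohorts(gold, epr, linked, rules = config$rules)
    accuracy <- accuracy_table(comparison$gold_infants, comparison$epr_infants,
                               rules = config$rules)
    profiled <- c("edd", "birth_weight", "sex", "apgar5", "maternal_ethnicity",
                  "maternal_lsoa", "delivery_mode", "antenatal_steroids")
    epr_chars <- comparison$epr_infants |>
      dplyr::mutate(year_of_birth = as.integer(format(.data$birth_date, "%Y")))
    completeness <- completeness_table(
      epr_chars, profiled, group_keys = "year_of_birth",
      subgroup_filter = function(d) !is.na(d$ga_days) & d$ga_days < 32 * 7,
      subgroup_label = "<32w")
    centre_missing <- dplyr::bind_rows(purrr::map(
      c("edd", "apgar5", "maternal_ethnicity", "maternal_lsoa", "delivery_mode"),
      function(v) {
        cd <- centre_distribution(comparison$epr_infants, v)
        dplyr::mutate(cd$by_centre, variable = v, .before = 1)
      }))

    write_exclusion_audit(linked, file.path(config$out_dir, "exclusion_audit.csv"))
    written <- c(written, file.path(config$out_dir, "exclusion_audit.csv"))
    emit(tibble::as_tibble(comparison$infant), "concordance_infant.csv")
    emit(tibble::as_tibble(comparison$episode), "concordance_episode.csv")
    emit(tibble::as_tibble(accuracy), "accuracy.csv")
    emit(tibble::as_tibble(completeness), "completeness.csv")
    emit(centre_missing, "centre_missing.csv")

    meta <- list(seed = config$seed, config_hash = rlang::hash(unclass(config)),
                 n_gold_infants = nrow(gold$infants),
                 n_linked_infants = linked$summary$n_linked,
                 n_episode_pairs = linked$summary$n_episode_pairs,
                 created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
    jsonlite::write_json(meta, file.path(config$out_dir, "metadata.json"),
                         auto_unbox = TRUE)
    written <- c(written, file.path(config$out_dir, "metadata.json"))

    summary_path <- file.path(config$out_dir, "summary.txt")
    lines <- c(
      sprintf("validation run (seed %d, config %s)", config$seed,
              rlang::hash(unclass(config))),
      sprintf("linked %d of %d infants; %d episode pairs analysed",
              linked$summary$n_linked, linked$summary$n_gold,
              linked$summary$n_episode_pairs),
      "",
      "infant-level major discordancy (%):",
      sprintf("  %-24s %6s  n=%d", comparison$infant$variable,
              round_rate(comparison$infant$major_rate),
              comparison$infant$n_comparable))
    writeLines(lines, summary_path)
    written <- c(written, summary_path)

    out <- list(linked = linked, comparison = comparison, accuracy = accuracy,
                completeness = completeness, centre_missing = centre_missing,
                paths = written, seed = config$seed)
    class(out) <- "neo_report"
    invisible(out)
  }, error = function(e) {
    unlink(written)
    stop(e)
  })
}

#' @export
print.neo_report <- function(x, ...) {
  cat(sprintf("validation report (seed %d): %d files in %s\n", x$seed,
              length(x$paths), dirname(x$paths[1])))
  print(x$linked)
  invisible(x)
}
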