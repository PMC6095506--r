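#' Generate a synthetic gold cohort
#'
#' Simulates a very preterm cohort of the kind collected on trial clinical
#' record forms: one row per infant with characteristics and outcomes, one
#' row per episode of care (continuous admission at one neonatal unit,
#' with transfers and return transfers between units), and one daily
#' record per in-patient day carrying care flags (mechanical support,
#' supplementary oxygen, central line), feeds (mother's breast milk, donor
#' milk, formula) and medications (antibiotics, antacid).
#'
#' Outcome flags are drawn independently given a gestational-age stratum
#' (relative risk 2 below 28 weeks, marginal probability equal to the
#' configured prevalence), except survival, which gates discharge-based
#' variables: non-survivors die early and their final episode ends in
#' death. Day-count variables are never sampled directly — they emerge
#' from the daily grid, so the derivation code paths are always exercised.
#' Status at 36 weeks postmenstrual age is made consistent with the grid:
#' the oxygen and mechanical-support flags on the assessment day
#' (`edd - 28`) equal the drawn outcome for infants still in care then.
#'
#' @param config A [cohort_config()].
#' @return A list of class `neo_cohort` with tibbles `infants`, `episodes`,
#'   `daily` and the `config` (including the seed) as metadata.
#' @examples
#' cohort <- generate_cohort(cohort_config(n_infants = 50, seed = 1))
#' nrow(cohort$infants)
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) stop_field("config", "must be a cohort_config")
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_infants
  units <- sprintf("U%02d", seq_len(config$n_units))
  prev <- config$outcome_prevalences

  # gestational age: completed weeks weighted towards the top of the range
  ga_weeks_opts <- seq(config$ga_range[1], config$ga_range[2])
  w <- seq_along(ga_weeks_opts)
  ga_w <- sample(ga_weeks_opts, n, replace = TRUE, prob = w / sum(w))
  ga_total <- ga_w * 7L + sample(0:6, n, replace = TRUE)

  birth_date <- config$recruitment_start +
    sample.int(round(config$recruitment_months * 30.4), n, replace = TRUE) - 1L
  edd <- birth_date + (280L - ga_total)

  low_ga <- ga_w < 28
  strat_draw <- function(p) {
    # stratified Bernoulli with relative risk 2 below 28w, marginal = p
    f_low <- mean(low_ga)
    p_high <- p / (2 * f_low + (1 - f_low))
    pr <- clamp(ifelse(low_ga, 2 * p_high, p_high), 0, 1)
    runif(n) < pr
  }

  survival <- !strat_draw(1 - prev[["survival"]])
  bpd <- strat_draw(prev[["oxygen_at_36w"]])
  # mechanical support at 36w is drawn within the oxygen-dependent group
  p_mech_given_bpd <- clamp(prev[["mech_support_at_36w"]] / prev[["oxygen_at_36w"]], 0, 1)
  mech36 <- bpd & runif(n) < p_mech_given_bpd

  centre <- sample(units, n, replace = TRUE, prob = rexp(length(units)) + 0.3)

  infants <- tibble::tibble(
    infant_id = sprintf("G%05d", seq_len(n)),
    centre_id = centre,
    birth_date = birth_date,
    edd = edd,
    ga_weeks = ga_total %/% 7L,
    ga_extra_days = ga_total %% 7L,
    birth_weight = as.integer(pmax(400, round(rnorm(n, 1000 + 170 * (ga_w - 28), 220)))),
    sex = sample(c("male", "female"), n, replace = TRUE),
    apgar5 = sample(0:10, n, replace = TRUE,
                    prob = c(rep(0.005, 5), 0.02, 0.05, 0.11, 0.24, 0.3, 0.255)),
    multiple = sample(c("singleton", "twin", "triplet"), n, replace = TRUE,
                      prob = c(0.72, 0.25, 0.03)),
    maternal_yob = sample(1970:1995, n, replace = TRUE),
    maternal_ethnicity = sample(
      c("White British", "White Other", "Mixed", "Asian or Asian British",
        "Black or Black British", "Other", "Not stated"),
      n, replace = TRUE, prob = c(0.55, 0.12, 0.04, 0.12, 0.11, 0.03, 0.03)),
    maternal_lsoa = sprintf("E01%06d", sample.int(32844, n, replace = TRUE)),
    antenatal_steroids = runif(n) < 0.88,
    delivery_mode = sample(c("caesarean", "vaginal"), n, replace = TRUE,
                           prob = c(0.55, 0.45)),
    born_here = runif(n) < 0.95,
    rop_worst_stage = pmax(0L, pmin(4L, rpois(n, pmax(0.1, (29 - ga_w) * 0.35)))),
    nec_perforation = strat_draw(prev[["nec_perforation"]]),
    gi_perforation = strat_draw(prev[["gi_perforation"]]),
    nec_surgery = strat_draw(prev[["nec_surgery"]]),
    hpi = strat_draw(prev[["hpi"]]),
    hydrocephalus = strat_draw(prev[["hydrocephalus"]]),
    pvl = strat_draw(prev[["pvl"]]),
    porencephalic_cyst = strat_draw(prev[["porencephalic_cyst"]]))
  infants$instrumental <- infants$delivery_mode == "vaginal" & runif(n) < 0.12
  infants$birth_order <- ifelse(infants$multiple == "singleton", 1L,
                                ifelse(infants$multiple == "twin",
                                       sample(1:2, n, replace = TRUE),
                                       sample(1:3, n, replace = TRUE)))

  # total stay: survivors go home around 37w postmenstrual age; deaths are early
  dis_pma <- round(rnorm(n, 259, 10.5))
  death_day <- 1L + as.integer(round(rexp(n, 1 / 20)))
  los_total <- ifelse(survival,
                      pmax(7L, dis_pma - ga_total),
                      pmax(2L, pmin(death_day, pmax(7L, dis_pma - ga_total)))) |>
    as.integer()

  # episode pathway: 1 + geometric number of transfers, truncated at 4
  n_ep <- 1L + pmin(rgeom(n, 1 - config$transfer_prob), 3L)
  n_ep <- pmin(n_ep, los_total)

  infant_flags <- tibble::tibble(
    infant_id = infants$infant_id,
    pda_surgery = strat_draw(prev[["pda_surgery"]]),
    pda_medical = strat_draw(prev[["pda_medical"]]),
    rop_treatment = strat_draw(prev[["rop_treatment"]]))

  episodes <- build_episodes(infants$infant_id, centre, units, birth_date,
                             los_total, n_ep, survival, infant_flags)
  daily <- build_daily(infants, episodes, ga_w, ga_total, los_total,
                       survival, bpd, mech36)

  out <- list(infants = infants, episodes = episodes, daily = daily, config = config)
  class(out) <- "neo_cohort"
  out
}

build_episodes <- function(ids, centre, units, birth_date, los_total, n_ep,
                           survival, infant_flags) {
  per <- purrr::pmap(
    list(ids, centre, birth_date, los_total, n_ep, survival),
    function(id, ctr, bd, los, k, surv) {
      # split the stay into k contiguous blocks of >= 1 day
      cuts <- if (k > 1L) sort(sample(seq_len(los - 1L), k - 1L)) else integer(0)
      lens <- diff(c(0L, cuts, los))
      path <- ctr
      while (length(path) < k) {
        prev2 <- if (length(path) >= 2) path[length(path) - 1L] else NULL
        nxt <- if (!is.null(prev2) && runif(1) < 0.3) prev2 else
          sample(setdiff(units, path[length(path)]), 1)
        path <- c(path, nxt)
      }
      adm <- bd + c(0L, cumsum(lens))[seq_len(k)]
      tibble::tibble(infant_id = id, episode = seq_len(k), unit_id = path,
                     admission_date = adm,
                     discharge_date = adm + lens - 1L,
                     transfer_out = seq_len(k) < k,
                     discharge_alive = seq_len(k) < k | surv)
    })
  episodes <- dplyr::bind_rows(per)
  # episode outcomes land in one randomly chosen episode of the infant
  for (v in c("pda_surgery", "pda_medical", "rop_treatment")) {
    episodes[[v]] <- FALSE
    pos <- infant_flags$infant_id[infant_flags[[v]]]
    idx <- episodes |>
      dplyr::mutate(row = dplyr::row_number()) |>
      dplyr::filter(.data$infant_id %in% pos) |>
      dplyr::group_by(.data$infant_id) |>
      dplyr::slice_sample(n = 1) |>
      dplyr::pull(.data$row)
    episodes[[v]][idx] <- TRUE
  }
  episodes
}

build_daily <- function(infants, episodes, ga_w, ga_total, los_total,
                        survival, bpd, mech36) {
  n <- nrow(infants)
  # per-infant durations driving the daily flags
  d_mech <- rpois(n, pmax(0.5, (30 - ga_w) * 2.5))
  d_oxy <- d_mech + rpois(n, pmax(1, (31 - ga_w) * 4))
  d_cl <- 2L + rpois(n, pmax(2, (30 - ga_w) * 2))
  abx1 <- ifelse(runif(n) < 0.85, sample(2:7, n, replace = TRUE), 0L)
  abx2_start <- ifelse(runif(n) < 0.3, 10L + sample.int(15, n, replace = TRUE), NA_integer_)
  abx2_len <- 1L + rpois(n, 4)
  antacid_user <- runif(n) < 0.25
  antacid_start <- 5L + rpois(n, 5)
  antacid_len <- 1L + rpois(n, 9)
  first_feed <- 1L + rpois(n, 2)
  mbm_user <- runif(n) < 0.92
  formula_user <- runif(n) < 0.45
  formula_start <- first_feed + rpois(n, 4)
  hdm_user <- runif(n) < 0.15
  mbm_user[!mbm_user & !formula_user & !hdm_user] <- TRUE
  assess_day <- 253L - ga_total  # postnatal day at 36w postmenstrual age

  idx <- rep.int(seq_len(n), los_total)
  t <- sequence(los_total)
  ep_map <- episodes |>
    dplyr::select("infant_id", "episode", "admission_date", "discharge_date")
  daily <- tibble::tibble(
    infant_id = infants$infant_id[idx],
    date = infants$birth_date[idx] + t - 1L,
    mech_support = t <= d_mech[idx],
    oxygen = t <= d_oxy[idx],
    central_line = t <= d_cl[idx],
    antibiotics = t <= abx1[idx] |
      (!is.na(abx2_start[idx]) & t >= abx2_start[idx] & t < abx2_start[idx] + abx2_len[idx]),
    antacid = antacid_user[idx] & t >= antacid_start[idx] &
      t < antacid_start[idx] + antacid_len[idx],
    mbm = mbm_user[idx] & t >= first_feed[idx],
    hdm = hdm_user[idx] & t >= first_feed[idx] & t <= first_feed[idx] + 4L,
    formula = formula_user[idx] & t >= formula_start[idx],
    missing = FALSE)
  # pin the 36w assessment day to the drawn outcome for infants still in care
  at36 <- t == assess_day[idx]
  daily$oxygen[at36] <- bpd[idx][at36]
  daily$mech_support[at36] <- mech36[idx][at36]
  daily$oxygen <- daily$oxygen | daily$mech_support
  # attach the episode each day belongs to
  daily |>
    dplyr::inner_join(ep_map, by = "infant_id", relationship = "many-to-many") |>
    dplyr::filter(.data$date >= .data$admission_date, .data$date <= .data$discharge_date) |>
    dplyr::select(-"admission_date", -"discharge_date")
}

#' @export
print.neo_cohort <- function(x, ...) {
  cat(sprintf("synthetic cohort: %d infants, %d episodes, %d care days (seed %s)\n",
              nrow(x$infants), nrow(x$episodes), nrow(x$daily),
              x$config$seed %||% "unset"))
  invisible(x)
}
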